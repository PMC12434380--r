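---
title: "Connectome-based prediction of prospective symptom severity: models and methods"
author: "cpmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmnet)
```

## The problem

Resting-state functional connectivity summarizes how synchronized the
activity of brain regions is: for each participant, the parcellated fMRI
time series yield a symmetric matrix of Fisher r-to-z transformed Pearson
correlations (a *connectome*). With an N-region parcellation there are
E = N(N−1)/2 unique region pairs ("edges"); for the 352-region space used
as the default here, E = 61,776. Connectome-based predictive modeling
(CPM) asks whether these edges, measured at baseline, predict a
*future* clinical outcome — here a t-score-like internalizing-symptom
(depression/anxiety) severity score one year later — beyond what baseline
severity and nuisance variables already explain.

cpmnet implements the full procedure: connectome construction, rank-based
edge screening, network-strength scoring, a strength-to-outcome linear
model evaluated under leave-half-sites-out cross-validation, permutation
significance, external validation of a fixed edge set in an independent
cohort, and canonical-network characterization. Because the cohorts this
design targets are restricted-access, the package ships a calibrated
synthetic-cohort generator so every stage is testable end to end.

## The CPM procedure

One call to `cpm(cohort, ...)` runs, per iteration:

1. **Site split.** The acquisition sites are halved at random: ⌈S/2⌉
   sites (all of their participants) form the training set, the rest the
   test set. Splitting sites rather than participants prevents leakage
   through site effects and through families, which never span sites.
2. **Edge screening (training only).** Each edge is correlated with the
   follow-up score by Spearman rank correlation — covariate-adjusted by
   default (partial Spearman given baseline score, sex, age, mean
   framewise displacement); a plain-Spearman mode is available via
   `adjust = FALSE`. Edges with p < α (default 0.001, strict) are
   retained. Rank correlation is used because the severity scores are
   skewed; p-values use the t approximation
   t = ρ√((n−2−k)/(1−ρ²)), adequate at the hundreds-to-thousands of
   training participants this design assumes.
3. **Network strength.** For each participant, the selected edges are
   summed as absolute z-values into a single scalar. The absolute-value
   sum (rather than separate positive/negative networks) is the variant
   implemented throughout.
4. **Strength model and evaluation.** Ordinary least squares of the
   outcome on strength is fit in the training set; the fitted line maps
   test-set strengths to predicted scores. Performance is the partial
   Spearman correlation between observed and predicted follow-up scores
   in the test set, *always* adjusted for the four covariates, whatever
   the screening mode — predicting the baseline score or motion is not
   an achievement.

Per-iteration correlations are averaged into `mean_rho`. Iterations where
no edge survives screening are excluded from the mean and counted
(`n_zero_edge`); scoring them as zero would bias the statistic toward the
null, and the count itself is a useful instability diagnostic.

**Consensus network.** Alongside the cross-validated estimate, the edges
passing the screen on the *full* cohort form the consensus network
(`consensus_network()`), the object that travels: `predict()` and
`apply_network()` use it on new cohorts, and the characterization module
summarizes it.

## Permutation significance

Because training and test sets overlap across iterations, parametric
p-values on `mean_rho` would overstate the degrees of freedom. Instead,
`cpm_permute()` relinks each participant's connectome to another
participant's complete phenotype record (outcome and covariates move
together, preserving their joint structure), reruns the cross-validation,
and reports `p_perm`: the proportion of permuted mean correlations
strictly larger than the observed one. Ties count as "not larger", per
the strict-proportion definition; a plus-one estimator is available but
off by default.

A design point discovered while validating the test: each permutation
must rerun the *same number* of CV iterations as the observed statistic.
The variance of a mean over m iterations is a + b/m, with a the
dataset-level component and b the split-to-split component; b dominates
here (measured ≈ 0.0028 vs ≈ 0.0004 at n = 500, 6 sites), so evaluating
permutations with fewer iterations inflates the null spread and makes the
test conservative (a pilot with 5 permutation iterations against a
20-iteration observed statistic rejected 0 of 40 true nulls at 0.05).
With matched counts the observed and permuted statistics are
exchangeable under the null and the test is exactly calibrated — the
package's default. The computational cost of full-fidelity permutation is
absorbed by the screening engine (below).

## External validation and specificity

`apply_network()` scores an independent cohort on a fixed network mask;
`evaluate_extension()` reports the plain and covariate-adjusted Spearman
correlations between strengths and the follow-up outcome plus MAE/RMSE of
predicted scores. MAE/RMSE require a strength→score calibration line;
by default it is refit on the extension cohort (and the choice is recorded
in the output), since a discovery-cohort line need not be on the same
scale — pass `calibration =` to use the discovery model instead.
`specificity_scan()` ranks candidate outcomes by |partial ρ| with no
multiplicity correction: it is a descriptive ranking, not a family of
tests.

## Characterization

`pair_counts()` groups a mask's edges by canonical-network pair
(seven cortical networks plus subcortex) and normalizes each observed
count by the pair's share of all possible edges:
normalized = (observed/|mask|) / (possible/E). Values above 1 flag
overrepresented pairs. This ratio-of-proportions is the natural reading
of count normalization by possible pair sizes; the raw observed/possible
ratio is also emitted so either convention is available. `region_degree()`
reports per-region incidence (handshake identity: degrees sum to twice
the mask size), and `fc_profiles()` averages each participant's z-values
within (pair, association-sign) cells, omitting empty cells rather than
reporting zeros.

The default parcellation (`make_parcellation()`) is deliberately
synthetic: it reproduces the combinatorial structure (333 cortical
regions round-robin across seven networks, 19 subcortical) without
reproducing any published atlas assignment; any user-supplied parcellation
TSV with a canonical-network column is accepted.

## The synthetic cohort generator

`simulate_cohort()` draws, per participant, a latent vulnerability
v ~ N(0,1), shared within sibling pairs with intra-family correlation 0.5
(families never straddle sites). The baseline score is a monotone
sinh–arcsinh skewing of a Gaussian latent correlated a = 0.5 with v, then
affinely calibrated; the follow-up latent is
y = β·base_std + c·v + σε with c = 0.3 and β solved in closed form so the
baseline–follow-up Pearson correlation hits its target exactly in
population (the skew attenuation κ = corr(s(Z), Z) has a closed form up
to one deterministic quadrature). Planted edges receive γ·v on top of
background noise; `gamma_for_edge_r()` converts a target marginal
edge–outcome correlation into γ analytically, and the identity is checked
against a large Monte-Carlo draw in the test suite.

Choices worth stating:

* **Planted loadings share one sign.** The strength feature sums |z|;
  with mixed-sign loadings the contributions of oppositely-signed edges
  cancel in expectation and no strength signal survives, which would make
  any planted benchmark vacuous. One shared sign makes the planted
  ground truth coherently recoverable.
* **Edge noise.** Background edges are N(0.25, 0.15²) in z-units with a
  per-site, per-edge offset of SD 0.05 — values typical of across-subject
  edge variability in Fisher-z connectomes.
* **Skew** defaults to ε = 0.35, a mild right tail consistent with
  "stable, positively skewed" screening-population severity scores; the
  published moments constrain mean and SD only, so the tail shape is a
  modeling choice.
* **The clinical cohort preset is a mixture.** The printed clinical and
  control group moments, mixed with the clinical fraction implied by the
  pooled mean, reproduce the printed pooled SD exactly; the within-group
  baseline–follow-up correlation is solved so the pooled correlation hits
  its target. Group labels are emitted in the `group` column.
* **Motion** is drawn with a configurable correlation to the outcome
  (default 0, matching the near-zero published associations); a nonzero
  value exists to stress-test covariate adjustment.
* Presets: `abcd_like` (n = 3718, 21 sites, base 53.51 ± 6.02, follow-up
  53.48 ± 6.06, r = 0.68, 52.9% F) and `banda_like` (n = 150, one site,
  base 49.11 ± 15.28, follow-up 44.62 ± 11.39, r = 0.63, 61.3% F).

What the generator does *not* emulate: autocorrelated hemodynamics,
scanner-specific artifacts, non-Gaussian edge distributions, or
missing-data patterns. Passing tests therefore demonstrate that the
*pipeline* is correct and calibrated, not that real resting-state data
carry this much (or this clean a) signal.

## Numerical engine

Screening all E edges inside every split of every permutation is the cost
center: a 20-iteration fit with 200 full-fidelity permutations runs
4,020 screens. Three structural facts make this cheap:

* the ascending order of each edge column is computed once per cohort;
  subset ranks for any split are then a linear scan (ties get midranks,
  matching `rank(., ties.method = "average")`), and a row permutation
  only relabels the cached orders;
* tie-free columns (the generic case for continuous data) take a faster
  scan that skips value comparisons;
* the partial-correlation algebra never residualizes the edge matrix:
  with ye the residualized ranked outcome, ⟨x_res, y_res⟩ = ⟨x, ye⟩ and
  ‖x_res‖² = x'x − (C'x)'(C'C)⁻¹(C'x), so one fused C++ pass per screen
  accumulates every needed cross-product without materializing the rank
  matrix.

Inside the CV loop the retention rule p < α is applied as
|ρ| > t/√(df + t²) with t the two-sided critical value — identical to
thresholding the p-value, without computing E p-values per split.
Correlations feeding `atanh` are clipped to ±(1 − 10⁻⁷) so degenerate
series stay finite; screened columns with (numerically) zero rank
variance are reported as ρ = 0, p = 1 and never selected.

## Reproducibility and scale

Every stochastic entry point takes a seed; `run_cpm_study()` derives
per-stage seeds from one master seed and writes a manifest (config
snapshot, seeds, package version, output digests). Identical config and
seed give identical numeric outputs.

Problem sizes used by the test suite are chosen to exercise every code
path at desk scale: the type-I calibration experiment runs 100 null
cohorts (n = 500, E = 1,035, 6 sites) with 20 CV iterations and 200
full-fidelity permutations each; planted-recovery and robustness checks
use n = 2,000 cohorts; generator calibration averages ten n = 3,718
replicates (the severity model is independent of the edge-space size, so
those use a small region count). Full-scale data (n ≈ 3,700 × 61,776
edges, ≈ 1.8 GB as doubles) is supported by the same code but is not
exercised in tests.

## Known limitations

* The strength model is a single combined |z| sum; the classic
  positive/negative two-network CPM variant is not implemented.
* Edge p-values rely on the t approximation; for cohorts of a few dozen
  participants per training set the screen's size is approximate (the
  permutation test remains exact).
* MAE/RMSE in external validation depend on which calibration line is
  used; both options are supported and the choice is recorded, but they
  are not comparable across conventions.
* The generator plants linear, homoscedastic edge signal; it cannot
  probe robustness to nonlinear brain–behavior coupling.
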