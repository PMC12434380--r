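#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Ascending order (1-based row indices) of every column. Computed once per
// cohort: subset ranks for any cross-validation split or permutation are
// then obtained by a linear scan instead of a fresh sort.
// [[Rcpp::export(name = ".order_columns")]]
IntegerMatrix order_columns(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  IntegerMatrix out(n, p);
  const double* xp = REAL(x);
  int* op = INTEGER(out);
  std::vector<int> idx(n);
  for (int j = 0; j < p; ++j) {
    const double* col = xp + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      if (!R_finite(col[i])) stop("non-finite value in column %d", j + 1);
      idx[i] = i;
    }
    std::sort(idx.begin(), idx.end(),
              [col](int a, int b) { return col[a] < col[b]; });
    int* ocol = op + (size_t)j * n;
    for (int i = 0; i < n; ++i) ocol[i] = idx[i] + 1;
  }
  return out;
}

// Midrank (average-tie) ranks of the rows `rows` of every column of x,
// using the precomputed column orders. Row k of the result corresponds to
// rows[k]; ties receive the mean of the ranks they span, matching
// rank(x, ties.method = "average").
// [[Rcpp::export(name = ".column_has_ties")]]
LogicalVector column_has_ties(NumericMatrix x, IntegerMatrix ord) {
  int n = x.nrow(), p = x.ncol();
  LogicalVector out(p);
  const double* xp = REAL(x);
  const int* op = INTEGER(ord);
  for (int j = 0; j < p; ++j) {
    const double* col = xp + (size_t)j * n;
    const int* ocol = op + (size_t)j * n;
    bool t = false;
    for (int i = 1; i < n && !t; ++i)
      t = col[ocol[i] - 1] == col[ocol[i - 1] - 1];
    out[j] = t;
  }
  return out;
}

// [[Rcpp::export(name = ".subset_rank_columns")]]
NumericMatrix subset_rank_columns(NumericMatrix x, IntegerMatrix ord,
                                  IntegerVector rows,
                                  Nullable<LogicalVector> has_ties = R_NilValue) {
  int n = x.nrow(), p = x.ncol(), m = rows.size();
  if (ord.nrow() != n || ord.ncol() != p)
    stop("order matrix does not match the data matrix");
  std::vector<int> pos(n, -1);
  for (int k = 0; k < m; ++k) {
    int r = rows[k] - 1;
    if (r < 0 || r >= n) stop("row index out of range");
    if (pos[r] != -1) stop("duplicate row index");
    pos[r] = k;
  }
  const int* tiesp = NULL;
  if (has_ties.isNotNull()) {
    LogicalVector hv(has_ties);
    if (hv.size() != p) stop("has_ties length must match the column count");
    tiesp = LOGICAL(hv);
  }
  NumericMatrix out(m, p);
  const double* xp = REAL(x);
  const int* op = INTEGER(ord);
  double* outp = REAL(out);
  std::vector<int> seq_pos(m + 1);  // +1: the branchless scan may write one
  std::vector<double> seq_val(m + 1);  // scratch slot past the last member
  for (int j = 0; j < p; ++j) {
    const double* col = xp + (size_t)j * n;
    const int* ocol = op + (size_t)j * n;
    double* rcol = outp + (size_t)j * m;
    if (tiesp && !tiesp[j]) {
      // tie-free column: the scan position is the rank
      int c = 0;
      for (int t = 0; t < n; ++t) {
        int pk = pos[ocol[t] - 1];
        seq_pos[c] = pk;
        c += (pk >= 0);
      }
      if (c != m) stop("order matrix is inconsistent with the data matrix");
      for (int k = 0; k < m; ++k) rcol[seq_pos[k]] = k + 1;
      continue;
    }
    // branchless subset scan: non-members write into a slot that the next
    // member overwrites, so only membership advances the cursor
    int c = 0;
    for (int t = 0; t < n; ++t) {
      int i = ocol[t] - 1;
      int pk = pos[i];
      seq_pos[c] = pk;
      seq_val[c] = col[i];
      c += (pk >= 0);
    }
    if (c != m) stop("order matrix is inconsistent with the data matrix");
    // assign midranks over runs of equal values
    int a = 0;
    while (a < m) {
      int b = a;
      while (b + 1 < m && seq_val[b + 1] == seq_val[a]) ++b;
      double r = 0.5 * (a + b) + 1.0;
      for (int k = a; k <= b; ++k) rcol[seq_pos[k]] = r;
      a = b + 1;
    }
  }
  return out;
}

// Fused screening pass: for every edge column, compute subset midranks and
// accumulate the cross-products needed for the (partial) Spearman screen —
//   num_j  = <r_j, ye>                       (ye is residualized/centered)
//   ssx_j  = ||r_j||^2 - (C'r_j)' Ginv (C'r_j)
// without materializing the m x E rank matrix. C carries the intercept
// (and ranked covariates when adjusting); Ginv = (C'C)^-1.
// [[Rcpp::export(name = ".screen_stats")]]
List screen_stats(NumericMatrix x, IntegerMatrix ord, IntegerVector rows,
                  LogicalVector has_ties, NumericVector ye, NumericMatrix C,
                  NumericMatrix Ginv) {
  int n = x.nrow(), p = x.ncol(), m = rows.size();
  int kc = C.ncol();
  if (ord.nrow() != n || ord.ncol() != p)
    stop("order matrix does not match the data matrix");
  if (ye.size() != m || C.nrow() != m)
    stop("ye and C must have one entry per subset row");
  if (Ginv.nrow() != kc || Ginv.ncol() != kc)
    stop("Ginv dimension mismatch");
  std::vector<int> pos(n, -1);
  for (int k = 0; k < m; ++k) {
    int r = rows[k] - 1;
    if (r < 0 || r >= n) stop("row index out of range");
    if (pos[r] != -1) stop("duplicate row index");
    pos[r] = k;
  }
  NumericVector num(p), ssx(p), ssx_raw(p);
  const double* xp = REAL(x);
  const int* op = INTEGER(ord);
  const int* tiesp = LOGICAL(has_ties);
  const double* yep = REAL(ye);
  const double* Cp = REAL(C);
  const double* Gp = REAL(Ginv);
  std::vector<int> seq_pos(m + 1);
  std::vector<double> seq_val(m + 1);
  std::vector<double> r(m), cx(kc);
  for (int j = 0; j < p; ++j) {
    const double* col = xp + (size_t)j * n;
    const int* ocol = op + (size_t)j * n;
    if (!tiesp[j]) {
      int c = 0;
      for (int t = 0; t < n; ++t) {
        int pk = pos[ocol[t] - 1];
        seq_pos[c] = pk;
        c += (pk >= 0);
      }
      if (c != m) stop("order matrix is inconsistent with the data matrix");
      for (int k = 0; k < m; ++k) r[seq_pos[k]] = k + 1;
    } else {
      int c = 0;
      for (int t = 0; t < n; ++t) {
        int i = ocol[t] - 1;
        int pk = pos[i];
        seq_pos[c] = pk;
        seq_val[c] = col[i];
        c += (pk >= 0);
      }
      if (c != m) stop("order matrix is inconsistent with the data matrix");
      int a = 0;
      while (a < m) {
        int b = a;
        while (b + 1 < m && seq_val[b + 1] == seq_val[a]) ++b;
        double rr = 0.5 * (a + b) + 1.0;
        for (int k = a; k <= b; ++k) r[seq_pos[k]] = rr;
        a = b + 1;
      }
    }
    double nj = 0, ssq = 0;
    for (int i = 0; i < m; ++i) {
      nj += r[i] * yep[i];
      ssq += r[i] * r[i];
    }
    for (int q = 0; q < kc; ++q) {
      const double* ccol = Cp + (size_t)q * m;
      double s = 0;
      for (int i = 0; i < m; ++i) s += ccol[i] * r[i];
      cx[q] = s;
    }
    double quad = 0;
    for (int q = 0; q < kc; ++q)
      for (int q2 = 0; q2 < kc; ++q2)
        quad += cx[q] * Gp[q + (size_t)q2 * kc] * cx[q2];
    num[j] = nj;
    ssx_raw[j] = ssq;
    ssx[j] = ssq - quad;
  }
  return List::create(_["num"] = num, _["ssx"] = ssx,
                      _["ssx_raw"] = ssx_raw);
}

// colSums(x^2) without materializing x^2.
// [[Rcpp::export(name = ".col_sumsq")]]
NumericVector col_sumsq(NumericMatrix x) {
  int n = x.nrow(), p = x.ncol();
  NumericVector out(p);
  const double* xp = REAL(x);
  for (int j = 0; j < p; ++j) {
    const double* col = xp + (size_t)j * n;
    double s = 0;
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    out[j] = s;
  }
  return out;
}

// Per-participant sum of |z| over the masked columns: the network-strength
// score.
// [[Rcpp::export(name = ".strength_sums")]]
NumericVector strength_sums(NumericMatrix x, IntegerVector cols) {
  int n = x.nrow(), m = cols.size();
  NumericVector out(n);
  const double* xp = REAL(x);
  double* outp = REAL(out);
  for (int k = 0; k < m; ++k) {
    int j = cols[k] - 1;
    if (j < 0 || j >= x.ncol()) stop("mask column index out of range");
    const double* col = xp + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      double v = col[i];
      if (!R_finite(v)) stop("non-finite edge value inside the mask");
      outp[i] += std::fabs(v);
    }
  }
  return out;
}
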