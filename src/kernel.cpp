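#include <Rcpp.h>
using namespace Rcpp;

// Deterministic viability-selection update of an allele frequency.
// Numerator/denominator form with dominance h and inbreeding F:
//   x' = [x^2 s + x(1-x) s (F + h - hF) + x] /
//        [x^2 s + x(1-x) s (F + 2h - 2hF) + 1]
// s may be length 1 (constant coefficient) or one value per frequency
// (frequency-dependent selection, already evaluated at x).
static inline double select_one(double x, double s, double hnum, double hden) {
  double num = x * x * s + x * (1.0 - x) * s * hnum + x;
  double den = x * x * s + x * (1.0 - x) * s * hden + 1.0;
  double p = num / den;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

// [[Rcpp::export(name = ".select_expected_cpp")]]
NumericVector select_expected_cpp(NumericVector x, NumericVector s,
                                  double h, double F) {
  R_xlen_t n = x.size();
  bool svec = s.size() > 1;
  if (svec && s.size() != n) stop("length of s must be 1 or length(x)");
  double hnum = F + h - h * F;
  double hden = F + 2.0 * h - 2.0 * h * F;
  NumericVector out(n);
  double s0 = s[0];
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = select_one(x[i], svec ? s[i] : s0, hnum, hden);
  return out;
}

// Fused selection + binomial drift: one pass over the mutation block.
// Drift draws k ~ Binomial(Ne, x_sel) through R's own generator, so a run
// seeded with set.seed() is reproducible and draw-for-draw identical to
// rbinom(n, Ne, select_expected(x, ...)) / Ne computed in R.
// Boundaries 0 and 1 are absorbing and skip the draw (Binomial(Ne, 0) = 0
// and Binomial(Ne, 1) = Ne with probability one).
// [[Rcpp::export(name = ".select_drift_cpp")]]
NumericVector select_drift_cpp(NumericVector x, NumericVector s,
                               double h, double F, int Ne) {
  R_xlen_t n = x.size();
  bool svec = s.size() > 1;
  if (svec && s.size() != n) stop("length of s must be 1 or length(x)");
  if (Ne < 1) stop("Ne must be >= 1");
  double hnum = F + h - h * F;
  double hden = F + 2.0 * h - 2.0 * h * F;
  double dNe = (double) Ne;
  NumericVector out(n);
  double s0 = s[0];
  for (R_xlen_t i = 0; i < n; ++i) {
    double p = select_one(x[i], svec ? s[i] : s0, hnum, hden);
    if (p <= 0.0) { out[i] = 0.0; continue; }
    if (p >= 1.0) { out[i] = 1.0; continue; }
    out[i] = R::rbinom(dNe, p) / dNe;
  }
  return out;
}

// ---- in-place engine primitives ------------------------------------------
// The simulation state lives in one preallocated (capacity x P) frequency
// matrix plus parallel origin-ID vectors; only the first n rows are active.
// These helpers mutate that buffer directly so a generation update performs
// no R-level copies of the mutation block.

// Conservative migration gather over the active rows:
// out[i, j] = sum_k m[k, j] * freq[i, k].
// [[Rcpp::export(name = ".migrate_block_cpp")]]
NumericMatrix migrate_block_cpp(NumericMatrix freq, int n, NumericMatrix m) {
  int P = freq.ncol();
  NumericMatrix out(n, P);
  for (int j = 0; j < P; ++j) {
    for (int k = 0; k < P; ++k) {
      double w = m(k, j);
      if (w == 0.0) continue;
      const double* src = &freq(0, k);
      double* dst = &out(0, j);
      for (int i = 0; i < n; ++i) dst[i] += w * src[i];
    }
  }
  return out;
}

// Copy of one active column (e.g. to evaluate a frequency-dependent
// selection function in R).
// [[Rcpp::export(name = ".active_column_cpp")]]
NumericVector active_column_cpp(NumericMatrix freq, int n, int j) {
  NumericVector out(n);
  const double* src = &freq(0, j - 1);
  std::copy(src, src + n, out.begin());
  return out;
}

// Selection + drift for one population, writing the realized offspring
// frequencies into column j of the state buffer.
// [[Rcpp::export(name = ".select_drift_inplace_cpp")]]
void select_drift_inplace_cpp(NumericMatrix freq, int n, int j,
                              NumericVector x, NumericVector s,
                              double h, double F, int Ne) {
  bool svec = s.size() > 1;
  if (svec && s.size() != n) stop("length of s must be 1 or n");
  if (Ne < 1) stop("Ne must be >= 1");
  double hnum = F + h - h * F;
  double hden = F + 2.0 * h - 2.0 * h * F;
  double dNe = (double) Ne;
  double s0 = s[0];
  double* col = &freq(0, j - 1);
  for (int i = 0; i < n; ++i) {
    double p = select_one(x[i], svec ? s[i] : s0, hnum, hden);
    if (p <= 0.0) col[i] = 0.0;
    else if (p >= 1.0) col[i] = 1.0;
    else col[i] = R::rbinom(dNe, p) / dNe;
  }
}

// Founding event: duplicate the source population's active frequencies
// into the target column.
// [[Rcpp::export(name = ".copy_column_cpp")]]
void copy_column_cpp(NumericMatrix freq, int n, int src, int tgt) {
  const double* s = &freq(0, src - 1);
  double* t = &freq(0, tgt - 1);
  std::copy(s, s + n, t);
}

// Append nj new mutations for population j at starting frequency x0, with
// origin IDs (gen, j, 1..nj). Caller guarantees capacity; rows may hold
// stale values from before a compaction, so every column is reset.
// [[Rcpp::export(name = ".append_rows_cpp")]]
void append_rows_cpp(NumericMatrix freq, IntegerVector og, IntegerVector op,
                     IntegerVector oi, int n, int nj, int j, double x0,
                     int gen) {
  int P = freq.ncol();
  for (int k = 0; k < P; ++k) {
    double* col = &freq(0, k);
    std::fill(col + n, col + n + nj, 0.0);
  }
  double* col = &freq(0, j - 1);
  std::fill(col + n, col + n + nj, x0);
  for (int i = 0; i < nj; ++i) {
    og[n + i] = gen;
    op[n + i] = j;
    oi[n + i] = i + 1;
  }
}

// In-place compaction: drop rows lost (frequency 0 in every extant
// population) or fixed (frequency 1 in every extant population), moving
// survivors to the top of the buffer with order preserved.
// Returns (new active count, number of fixed rows removed).
// [[Rcpp::export(name = ".compact_cpp")]]
IntegerVector compact_cpp(NumericMatrix freq, IntegerVector og,
                          IntegerVector op, IntegerVector oi, int n,
                          LogicalVector extant) {
  int P = freq.ncol();
  std::vector<int> ex;
  for (int k = 0; k < P; ++k) if (extant[k]) ex.push_back(k);
  int nex = (int) ex.size();
  if (nex == 0 || n == 0)
    return IntegerVector::create(n, 0);
  int w = 0, nfix = 0;
  for (int i = 0; i < n; ++i) {
    double sum = 0.0;
    for (int k = 0; k < nex; ++k) sum += freq(i, ex[k]);
    if (sum == 0.0) continue;               // lost everywhere
    if (sum == (double) nex) { ++nfix; continue; }  // fixed everywhere
    if (w != i) {
      for (int k = 0; k < P; ++k) freq(w, k) = freq(i, k);
      og[w] = og[i]; op[w] = op[i]; oi[w] = oi[i];
    }
    ++w;
  }
  return IntegerVector::create(w, nfix);
}
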