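#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Banded forward pass of the allele-frequency HMM.
//
// Pmats:      list of K x K transition matrices (row l -> column k mass),
//             banded or dense; amat/bmat give, per model, the first and last
//             nonzero row index of each column (approximation A2); 0/-1 marks
//             an empty column.
// step_model: length-T integer (1-based); entry t gives the model carrying
//             the chain from column t-1 to column t (entry 1 unused).
// logE:       K x T natural-log emission matrix (column 1 unused).
// one_derived: per-step flag; when the step has exactly one derived lineage
//             the beam window is forced down to bin 1.
// approx_b:   compute each column only inside the expanded 99.9%-mass window
//             of the previous column (approximation B); entries outside are
//             exactly zero.
// Columns are rescaled to max 1 with the log scale accumulated, so the
// log-likelihood is log(sum(F[,T])) + logscale[T].
// [[Rcpp::export(name = ".hmm_forward_cpp")]]
List hmm_forward_cpp(List Pmats, IntegerVector step_model, NumericMatrix logE,
                     int init_bin, LogicalVector one_derived,
                     bool approx_b, NumericVector x, List amat, List bmat,
                     bool keep_matrix) {
  const int K = logE.nrow();
  const int T = logE.ncol();
  NumericMatrix F;
  if (keep_matrix) F = NumericMatrix(K, T);
  NumericVector logscale(T);
  std::vector<double> prev(K, 0.0), cur(K, 0.0);
  prev[init_bin - 1] = 1.0;
  if (keep_matrix) F(init_bin - 1, 0) = 1.0;
  bool ok = true;
  double loglik = 0.0;

  const int nm = Pmats.size();
  std::vector<NumericMatrix> P(nm);
  std::vector<IntegerVector> A(nm), B(nm);
  for (int m = 0; m < nm; ++m) {
    P[m] = as<NumericMatrix>(Pmats[m]);
    A[m] = as<IntegerVector>(amat[m]);
    B[m] = as<IntegerVector>(bmat[m]);
  }

  for (int t = 1; t < T; ++t) {
    const int m = step_model[t] - 1;
    int w_lo = 0, w_hi = K - 1;
    if (approx_b) {
      double S = 0.0;
      for (int k = 0; k < K; ++k) S += prev[k];
      const double trim = 5e-4 * S;
      int alpha = 0, beta = K - 1;
      double cum = 0.0;
      while (alpha < K - 1 && cum + prev[alpha] <= trim) { cum += prev[alpha]; ++alpha; }
      cum = 0.0;
      while (beta > 0 && cum + prev[beta] <= trim) { cum += prev[beta]; --beta; }
      if (beta < alpha) beta = alpha;
      if (one_derived[t]) alpha = 0;
      const double xa = x[alpha], xb = x[beta];
      const double lo_f = xa - 2.0 * (xb - xa) - 0.1;
      const double hi_f = xb + 2.0 * (xb - xa) + 0.1;
      while (w_lo < K && x[w_lo] <= lo_f) ++w_lo;
      while (w_hi >= 0 && x[w_hi] >= hi_f) --w_hi;
      if (w_lo > w_hi) { w_lo = alpha; w_hi = beta; }
    }
    double maxlog = R_NegInf;
    std::vector<double> lg(K, R_NegInf);
    for (int k = w_lo; k <= w_hi; ++k) {
      const double le = logE(k, t);
      if (le == R_NegInf) continue;
      const int a = A[m][k], b = B[m][k];
      if (a < 1 || b < a) continue;
      double acc = 0.0;
      const double *col = &P[m](0, k);
      for (int l = a - 1; l <= b - 1; ++l) acc += prev[l] * col[l];
      if (acc > 0.0) {
        const double v = std::log(acc) + le;
        lg[k] = v;
        if (v > maxlog) maxlog = v;
      }
    }
    if (maxlog == R_NegInf) {  // impossible data: chain has no mass left
      ok = false;
      loglik = R_NegInf;
      break;
    }
    for (int k = 0; k < K; ++k)
      cur[k] = (lg[k] == R_NegInf) ? 0.0 : std::exp(lg[k] - maxlog);
    logscale[t] = logscale[t - 1] + maxlog;
    if (keep_matrix) for (int k = 0; k < K; ++k) F(k, t) = cur[k];
    std::swap(prev, cur);
  }
  if (ok) {
    double S = 0.0;
    for (int k = 0; k < K; ++k) S += prev[k];
    loglik = std::log(S) + logscale[T - 1];
  }
  return List::create(_["F"] = F, _["logscale"] = logscale,
                      _["loglik"] = loglik, _["ok"] = ok);
}

// Banded backward pass. Uses the row bands lo/hi of each model (the
// transpose analogue of approximation A2); no beam windowing is applied.
// Columns are rescaled to max 1 with the log scale accumulated.
// [[Rcpp::export(name = ".hmm_backward_cpp")]]
List hmm_backward_cpp(List Pmats, IntegerVector step_model, NumericMatrix logE,
                      List lomat, List himat) {
  const int K = logE.nrow();
  const int T = logE.ncol();
  NumericMatrix Bm(K, T);
  NumericVector logscale(T);
  const int nm = Pmats.size();
  std::vector<NumericMatrix> P(nm);
  std::vector<IntegerVector> LO(nm), HI(nm);
  for (int m = 0; m < nm; ++m) {
    P[m] = as<NumericMatrix>(Pmats[m]);
    LO[m] = as<IntegerVector>(lomat[m]);
    HI[m] = as<IntegerVector>(himat[m]);
  }
  for (int k = 0; k < K; ++k) Bm(k, T - 1) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const int m = step_model[t + 1] - 1;
    double emax = R_NegInf;
    for (int l = 0; l < K; ++l) {
      const double le = logE(l, t + 1);
      if (le > emax) emax = le;
    }
    if (emax == R_NegInf) emax = 0.0;  // all-impossible column; handled below
    std::vector<double> e(K);
    for (int l = 0; l < K; ++l) {
      const double le = logE(l, t + 1);
      e[l] = (le == R_NegInf) ? 0.0 : std::exp(le - emax);
    }
    double cmax = 0.0;
    for (int k = 0; k < K; ++k) {
      const int a = LO[m][k], b = HI[m][k];
      double acc = 0.0;
      for (int l = a - 1; l <= b - 1; ++l)
        acc += P[m](k, l) * e[l] * Bm(l, t + 1);
      Bm(k, t) = acc;
      if (acc > cmax) cmax = acc;
    }
    if (cmax <= 0.0) {
      logscale[t] = R_NegInf;
    } else {
      for (int k = 0; k < K; ++k) Bm(k, t) /= cmax;
      logscale[t] = logscale[t + 1] + emax + std::log(cmax);
    }
  }
  return List::create(_["B"] = Bm, _["logscale"] = logscale);
}
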