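#include <Rcpp.h>
using namespace Rcpp;

// Negative forward log-likelihood of a movement HMM.
//
// Observations are step lengths (gamma, mean/SD parameterization) and
// turning angles (wrapped Cauchy); angles are absent on the first step of
// each burst and their term is omitted there. Transition probabilities vary
// with time of day through a row-wise multinomial logit with the diagonal
// as reference: eta_ij(h) = z(h) . beta_ij, Gamma_ij = exp(eta_ij) / (1 +
// sum_{j'!=i} exp(eta_ij')). Hours are passed as indices into the matrix Z
// of covariate rows (one row per distinct hour value), so the K x K matrix
// is built once per distinct hour per evaluation.
//
// l, logl        : step lengths and their logs (length T)
// cosphi, sinphi : cos/sin of turning angles (junk where hasangle == 0)
// hasangle       : 1 where a turning angle is observed
// newburst       : 1 where a burst starts (initial distribution applied)
// hidx           : 0-based row index into Z per step
// tbeta          : K*(K-1) x p transition coefficients (row order: (1,2),
//                  (1,3).. (2,1), ... diagonal skipped)
// zmass          : per-state point mass at zero step length (used only when
//                  use_zmass is true)
//
// Returns +1e10 for parameter values where the likelihood degenerates, so
// the optimizer treats them as very poor rather than crashing.
// [[Rcpp::export]]
double hmm_nll_cpp(NumericVector mu, NumericVector sigma,
                   NumericVector muphi, NumericVector rho,
                   NumericVector zmass, bool use_zmass,
                   NumericMatrix tbeta, NumericVector delta,
                   NumericVector l, NumericVector logl,
                   NumericVector cosphi, NumericVector sinphi,
                   IntegerVector hasangle, IntegerVector newburst,
                   IntegerVector hidx, NumericMatrix Z) {
  const int T = l.size();
  const int K = mu.size();
  const int H = Z.nrow();
  const int p = Z.ncol();
  const double BAD = 1e10;

  // per-state gamma constants and wrapped-Cauchy constants
  std::vector<double> shape(K), rate(K), gconst(K), wc(K), cmu(K), smu(K),
      r2(K);
  for (int k = 0; k < K; ++k) {
    if (!(mu[k] > 0.0) || !(sigma[k] > 0.0) || rho[k] < 0.0 || rho[k] >= 1.0)
      return BAD;
    shape[k] = (mu[k] / sigma[k]) * (mu[k] / sigma[k]);
    rate[k] = mu[k] / (sigma[k] * sigma[k]);
    gconst[k] = shape[k] * std::log(rate[k]) - std::lgamma(shape[k]);
    wc[k] = (1.0 - rho[k] * rho[k]) / (2.0 * M_PI);
    cmu[k] = std::cos(muphi[k]);
    smu[k] = std::sin(muphi[k]);
    r2[k] = 1.0 + rho[k] * rho[k];
    if (!std::isfinite(gconst[k])) return BAD;
  }

  // transition matrices per distinct hour
  std::vector<double> G(H * K * K);
  for (int h = 0; h < H; ++h) {
    int r = 0;
    for (int i = 0; i < K; ++i) {
      double denom = 1.0;
      std::vector<double> e(K, 0.0);
      for (int j = 0; j < K; ++j) {
        if (j == i) continue;
        double eta = 0.0;
        for (int c = 0; c < p; ++c) eta += tbeta(r, c) * Z(h, c);
        ++r;
        e[j] = std::exp(eta);
        denom += e[j];
      }
      if (!std::isfinite(denom) || denom <= 0.0) return BAD;
      for (int j = 0; j < K; ++j)
        G[(h * K + i) * K + j] = (j == i ? 1.0 : e[j]) / denom;
    }
  }

  std::vector<double> alpha(K), tmp(K);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    const int h = hidx[t];
    for (int k = 0; k < K; ++k) {
      double dens;
      if (use_zmass && l[t] == 0.0) {
        dens = zmass[k];
      } else {
        double g = std::exp((shape[k] - 1.0) * logl[t] - rate[k] * l[t] +
                            gconst[k]);
        if (use_zmass) g *= (1.0 - zmass[k]);
        dens = g;
      }
      if (hasangle[t]) {
        double denomw =
            r2[k] - 2.0 * rho[k] * (cosphi[t] * cmu[k] + sinphi[t] * smu[k]);
        dens *= wc[k] / denomw;
      }
      tmp[k] = dens;
    }
    double s = 0.0;
    if (newburst[t]) {
      for (int k = 0; k < K; ++k) {
        alpha[k] = delta[k] * tmp[k];
        s += alpha[k];
      }
    } else {
      double prev[16];
      for (int k = 0; k < K; ++k) prev[k] = alpha[k];
      for (int k = 0; k < K; ++k) {
        double a = 0.0;
        for (int i = 0; i < K; ++i) a += prev[i] * G[(h * K + i) * K + k];
        alpha[k] = a * tmp[k];
        s += alpha[k];
      }
    }
    if (!(s > 0.0) || !std::isfinite(s)) return BAD;
    ll += std::log(s);
    for (int k = 0; k < K; ++k) alpha[k] /= s;
  }
  return -ll;
}
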