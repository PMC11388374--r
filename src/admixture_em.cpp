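#include <Rcpp.h>
using namespace Rcpp;

// log-likelihood of admixture vector q given per-site genotype
// likelihoods (S x 3) and panel frequencies (S x K):
//   l(q) = sum_s log sum_g GL(s,g) * Binom(g; 2, h(s)),  h = sum_k q_k f_k
static double admix_ll(const double *gl, const double *fr, int S, int K,
                       const std::vector<double> &q) {
  double ll = 0.0;
  for (int s = 0; s < S; ++s) {
    double h = 0.0;
    for (int k = 0; k < K; ++k) h += q[k] * fr[k * S + s];
    if (h < 1e-9) h = 1e-9;
    if (h > 1.0 - 1e-9) h = 1.0 - 1e-9;
    const double u = 1.0 - h;
    ll += std::log(gl[s] * u * u + gl[S + s] * 2.0 * h * u +
                   gl[2 * S + s] * h * h);
  }
  return ll;
}

// [[Rcpp::export]]
double admixture_loglik_cpp(NumericMatrix gl, NumericMatrix freqs,
                            NumericVector q) {
  std::vector<double> qq(q.begin(), q.end());
  return admix_ll(REAL(gl), REAL(freqs), gl.nrow(), freqs.ncol(), qq);
}

// EM for supervised admixture.  Per site, each of the two allele copies
// is allocated to population k with probability q_k f_k / h (derived
// copy) or q_k (1-f_k) / (1-h) (ancestral copy), weighted by the
// genotype posterior; the update averages allocations over 2S copies.
// [[Rcpp::export]]
List em_admixture_cpp(NumericMatrix gl, NumericMatrix freqs,
                      NumericVector q0, double tol, int maxit) {
  const int S = gl.nrow(), K = freqs.ncol();
  if (freqs.nrow() != S) stop("gl and freqs must cover the same sites");
  if (q0.size() != K) stop("q0 length must match panel size");
  const double *pg = REAL(gl), *pf = REAL(freqs);
  const double *g0 = pg, *g1 = pg + S, *g2 = pg + 2 * S;
  std::vector<double> q(q0.begin(), q0.end()), qnew(K), hvec(S);
  double ll_old = R_NegInf, ll = R_NegInf;
  bool converged = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    // h = freqs %*% q, column-wise for cache friendliness
    std::fill(hvec.begin(), hvec.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double qk = q[k];
      const double *fk = pf + (size_t)k * S;
      for (int s = 0; s < S; ++s) hvec[s] += qk * fk[s];
    }
    ll = 0.0;
    // per-site responsibilities -> per-copy allocation coefficients
    std::vector<double> ca(S), cb(S);
    for (int s = 0; s < S; ++s) {
      double h = hvec[s];
      if (h < 1e-9) h = 1e-9;
      if (h > 1.0 - 1e-9) h = 1.0 - 1e-9;
      const double u = 1.0 - h;
      const double w0 = g0[s] * u * u;
      const double w1 = g1[s] * 2.0 * h * u;
      const double w2 = g2[s] * h * h;
      const double tot = w0 + w1 + w2;
      ll += std::log(tot);
      const double eg = (w1 + 2.0 * w2) / tot;  // E[derived copies]
      ca[s] = eg / h;
      cb[s] = (2.0 - eg) / u;
    }
    for (int k = 0; k < K; ++k) {
      const double *fk = pf + (size_t)k * S;
      double acc = 0.0;
      for (int s = 0; s < S; ++s)
        acc += fk[s] * ca[s] + (1.0 - fk[s]) * cb[s];
      qnew[k] = q[k] * acc;
    }
    double sum = 0.0;
    for (int k = 0; k < K; ++k) sum += qnew[k];
    for (int k = 0; k < K; ++k) q[k] = qnew[k] / sum;
    if (it > 1 && ll - ll_old < tol) { converged = true; break; }
    ll_old = ll;
  }
  const double ll_final = admix_ll(pg, pf, S, K, q);
  return List::create(_["q"] = NumericVector(q.begin(), q.end()),
                      _["loglik"] = ll_final,
                      _["iters"] = std::min(it, maxit),
                      _["converged"] = converged);
}
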