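// EM for the binomial admixture model:
//   n_ij ~ Bin(c_i, p_ij),  p_ij = sum_k q_ik f_kj
// with per-sample trial counts c_i (2 for diploid, configurable for the
// pseudo-haploid coding). Missing entries carry obsmask = 0. The updates
// are the classic complete-data EM (one allele-origin latent variable per
// trial), which guarantees a monotone log-likelihood.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static double loglik(const mat& n, const mat& cn, const mat& obsmask,
                     const mat& P) {
  return accu((n % log(P) + cn % log(1.0 - P)) % obsmask);
}

// [[Rcpp::export]]
Rcpp::List admix_em_cpp(const arma::mat& n, const arma::mat& obsmask,
                        const arma::vec& cvec, arma::mat Q, arma::mat F,
                        int max_iter, double tol) {
  const double eps = 1e-9;
  const uword M = n.n_cols;
  mat cn = (cvec * ones<rowvec>(M)) - n;     // c_i - n_ij
  cn %= obsmask;
  mat nm = n % obsmask;
  vec denomQ = (obsmask * ones<vec>(M)) % cvec;  // sum_j c_i over observed
  denomQ.replace(0.0, 1.0);                      // all-missing sample guard

  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  double ll_prev = -datum::inf;
  bool converged = false;

  int it = 0;
  for (; it < max_iter; ++it) {
    mat P = clamp(Q * F, eps, 1.0 - eps);
    double ll = loglik(nm, cn, obsmask, P);
    trace.push_back(ll);
    if (it > 0 && ll - ll_prev < tol) { converged = true; break; }
    ll_prev = ll;

    mat A = nm / P;
    mat B = cn / (1.0 - P);
    mat Qn = Q % (A * F.t() + B * (1.0 - F).t());
    Qn.each_col() /= denomQ;
    Qn.each_col() /= sum(Qn, 1);               // exact simplex projection
    mat Fa = F % (Q.t() * A);
    mat Fb = (1.0 - F) % (Q.t() * B);
    mat Fn = Fa / (Fa + Fb);
    uvec bad = find_nonfinite(Fn);             // 0/0: column with no data
    if (!bad.is_empty()) Fn.elem(bad) = F.elem(bad);
    Q = Qn;
    F = Fn;
  }
  if (!converged) {
    mat P = clamp(Q * F, eps, 1.0 - eps);
    trace.push_back(loglik(nm, cn, obsmask, P));
  }
  return Rcpp::List::create(
    Rcpp::Named("Q") = Q,
    Rcpp::Named("F") = F,
    Rcpp::Named("loglik_trace") = trace,
    Rcpp::Named("n_iter") = it,
    Rcpp::Named("converged") = converged);
}
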