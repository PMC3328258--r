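// Goldman-Yang pairwise likelihood kernel.
//
// The 61-state reversible codon rate matrix is rebuilt for every (kappa,
// omega) evaluation, symmetrised in the pi^(1/2) inner product and
// eigendecomposed; the pairwise log-likelihood sums n_p * log(pi_i *
// P_ij(t)) over observed codon-pair site patterns. Zero-frequency codons
// (possible under F3x4) are dropped from the state space; a pattern on a
// zero-frequency codon yields a -1e10 penalty rather than -Inf so bounded
// optimisers can recover.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
double gy94_loglik_cpp(double t, double kappa, double omega,
                       const arma::vec& pi,
                       const arma::ivec& edge_i, const arma::ivec& edge_j,
                       const arma::ivec& edge_ts, const arma::ivec& edge_syn,
                       const arma::ivec& pat_i, const arma::ivec& pat_j,
                       const arma::vec& pat_n) {
  const int n = 61;
  mat Q(n, n, fill::zeros);
  for (uword k = 0; k < edge_i.n_elem; ++k) {
    int i = edge_i[k] - 1, j = edge_j[k] - 1;
    double w = pi[j];
    if (edge_ts[k]) w *= kappa;
    if (!edge_syn[k]) w *= omega;
    Q(i, j) = w;
  }
  vec rs = sum(Q, 1);
  Q.diag() = -rs;
  double scale = dot(pi, rs);
  if (!(scale > 0)) return -1e10;
  Q /= scale;

  // restrict to the support of pi
  uvec pos = find(pi > 0);
  vec pis = pi.elem(pos);
  vec sp = sqrt(pis);
  mat Qs = Q.submat(pos, pos);
  mat S = Qs;
  for (uword a = 0; a < pos.n_elem; ++a)
    for (uword b = 0; b < pos.n_elem; ++b)
      S(a, b) *= sp[a] / sp[b];
  S = 0.5 * (S + S.t());
  vec eval;
  mat evec;
  if (!eig_sym(eval, evec, S)) return -1e10;
  mat P = evec * diagmat(exp(eval * t)) * evec.t();
  for (uword a = 0; a < pos.n_elem; ++a)
    for (uword b = 0; b < pos.n_elem; ++b)
      P(a, b) *= sp[b] / sp[a];

  // map full-state index -> support index (-1 if unsupported)
  ivec map(n);
  map.fill(-1);
  for (uword a = 0; a < pos.n_elem; ++a) map[pos[a]] = (int)a;

  double ll = 0.0;
  for (uword p = 0; p < pat_i.n_elem; ++p) {
    int a = map[pat_i[p] - 1], b = map[pat_j[p] - 1];
    if (a < 0 || b < 0) return -1e10;
    double lik = pis[a] * P(a, b);
    if (!(lik > 0)) lik = 1e-300;
    ll += pat_n[p] * std::log(lik);
  }
  return ll;
}
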