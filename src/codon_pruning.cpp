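// Felsenstein pruning over the 61 sense-codon states under the
// Goldman-Yang model. The rate matrix is time-reversible, so transition
// probabilities are computed from one symmetric eigendecomposition per
// omega class and reused across branch lengths. Per-pattern log scaling
// guards against underflow on larger trees.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat buildQ(double kappa, double omega,
                        const arma::vec& pi,
                        const arma::mat& TS, const arma::mat& TV,
                        const arma::mat& SYN) {
  arma::mat fac = (kappa * TS + TV) % (SYN + omega * (1.0 - SYN) % (TS + TV));
  arma::mat Q = fac;
  Q.each_row() %= pi.t();          // Q_ij ~ pi_j
  Q.diag().zeros();
  Q.diag() = -arma::sum(Q, 1);
  double mu = -arma::dot(pi, Q.diag());
  if (mu > 0) Q /= mu;
  return Q;
}

// [[Rcpp::export]]
double codon_loglik_cpp(const arma::imat& edge,        // E x 2, 1-based
                        const arma::vec& edgeLen,
                        const arma::ivec& edgeClass,   // 1-based omega class
                        double kappa,
                        const arma::vec& omegas,
                        const arma::vec& pi,
                        const arma::imat& tipStates,   // ntip x npat, 1-based
                        const arma::vec& patWeights,
                        const arma::mat& TS, const arma::mat& TV,
                        const arma::mat& SYN,
                        int nNode, int nTip) {
  const int ns = pi.n_elem;
  const int npat = tipStates.n_cols;
  const int E = edge.n_rows;
  const int nclass = omegas.n_elem;

  // one eigendecomposition per omega class
  arma::vec d = arma::sqrt(pi);
  std::vector<arma::mat> Lm(nclass), Rm(nclass);
  std::vector<arma::vec> ev(nclass);
  for (int c = 0; c < nclass; ++c) {
    arma::mat Q = buildQ(kappa, omegas[c], pi, TS, TV, SYN);
    arma::mat A = Q;
    A.each_col() %= d;
    A.each_row() /= d.t();
    A = 0.5 * (A + A.t());
    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, A))
      stop("eigendecomposition failed");
    ev[c] = eval;
    Lm[c] = evec;  Lm[c].each_col() /= d;    // D^-1 V
    Rm[c] = evec.t(); Rm[c].each_row() %= d.t();  // V' D
  }

  std::vector<arma::mat> partial(nNode + 1);
  std::vector<bool> seen(nNode + 1, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  for (int e = 0; e < E; ++e) {
    int parent = edge(e, 0), child = edge(e, 1);
    int c = edgeClass[e] - 1;
    arma::mat Ls = Lm[c];
    Ls.each_row() %= arma::exp(ev[c] * edgeLen[e]).t();
    arma::mat P = Ls * Rm[c];
    P.transform([](double x) { return x < 0 ? 0.0 : x; });
    arma::mat contrib(ns, npat);
    if (child <= nTip) {
      // tip: P columns picked by observed state
      contrib.zeros();
      for (int s = 0; s < npat; ++s) {
        int st = tipStates(child - 1, s);
        if (st > 0) contrib.col(s) = P.col(st - 1);
        else contrib.col(s).ones();          // missing data
      }
    } else {
      if (!seen[child]) stop("postorder violated");
      contrib = P * partial[child];
      partial[child].reset();
    }
    arma::rowvec mx = arma::max(contrib, 0);
    mx.transform([](double x) { return x <= 0 ? 1.0 : x; });
    contrib.each_row() /= mx;
    logscale += arma::log(mx);
    if (!seen[parent]) {
      partial[parent] = contrib;
      seen[parent] = true;
    } else {
      partial[parent] %= contrib;
    }
  }

  int root = edge(E - 1, 0);
  arma::rowvec siteL = pi.t() * partial[root];
  double lnL = 0.0;
  for (int s = 0; s < npat; ++s) {
    if (siteL[s] <= 0) return -1e12;  // numerical failure guard
    lnL += patWeights[s] * (std::log(siteL[s]) + logscale[s]);
  }
  return lnL;
}
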