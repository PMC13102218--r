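#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// One EM E-step for the graded response model on a fixed quadrature grid.
//
// resp : n x J integer matrix of categories 0..K-1
// logP : Q x K x J cube, log category probabilities at the quadrature nodes
// logw : length-Q log prior weights
//
// Returns the marginal log-likelihood, the n x Q posterior node weights, and
// the Q x K x J expected category counts ("r-table") the M-step maximises
// against.
// [[Rcpp::export]]
List grm_estep_cpp(const arma::imat& resp, const arma::cube& logP,
                   const arma::vec& logw) {
  const arma::uword n = resp.n_rows, J = resp.n_cols, Q = logP.n_rows;
  arma::mat post(n, Q);
  double marg = 0.0;

  for (arma::uword i = 0; i < n; ++i) {
    arma::vec acc = logw;
    for (arma::uword j = 0; j < J; ++j)
      acc += logP.slice(j).col(resp(i, j));
    const double m = acc.max();
    arma::vec e = arma::exp(acc - m);
    const double s = arma::accu(e);
    marg += m + std::log(s);
    post.row(i) = (e / s).t();
  }

  arma::cube counts(Q, logP.n_cols, J, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    const arma::vec p = post.row(i).t();
    for (arma::uword j = 0; j < J; ++j)
      counts.slice(j).col(resp(i, j)) += p;
  }

  return List::create(_["loglik"] = marg, _["post"] = post,
                      _["counts"] = counts);
}

// Expected complete-data negative log-likelihood of one item and, when
// `grad` is non-null, its gradient, in the ordered parametrization
// (log a1, d_1, log successive gaps of d). `r` is the item's Q x K
// expected-count table.
static double item_eval(const arma::vec& eta, const arma::mat& r,
                        const arma::vec& nodes, const int K,
                        arma::vec* grad) {
  const arma::uword Q = nodes.n_elem;
  const arma::uword Kb = static_cast<arma::uword>(K) - 1;
  const double a1 = std::exp(eta(0));
  arma::vec d(Kb);
  d(0) = eta(1);
  for (arma::uword t = 1; t < Kb; ++t)
    d(t) = d(t - 1) - std::exp(eta(1 + t));

  arma::mat psi(Q, Kb);
  for (arma::uword t = 0; t < Kb; ++t)
    for (arma::uword q = 0; q < Q; ++q)
      psi(q, t) = 1.0 / (1.0 + std::exp(-(a1 * nodes(q) + d(t))));

  arma::mat P(Q, K);
  P.col(0) = 1.0 - psi.col(0);
  for (arma::uword c = 1; c < Kb; ++c)
    P.col(c) = psi.col(c - 1) - psi.col(c);
  P.col(Kb) = psi.col(Kb - 1);
  P.transform([](double x) { return x < 1e-300 ? 1e-300 : x; });

  const double val = -arma::accu(r % arma::log(P));
  if (grad == nullptr) return val;

  const arma::mat ratio = r / P;
  arma::mat A(Q, Kb);
  for (arma::uword t = 0; t < Kb; ++t)
    A.col(t) = psi.col(t) % (1.0 - psi.col(t)) %
               (ratio.col(t + 1) - ratio.col(t));

  const arma::vec G_d = arma::sum(A, 0).t();
  const double G_a1 = arma::accu(nodes % arma::sum(A, 1));
  grad->zeros(eta.n_elem);
  (*grad)(0) = -a1 * G_a1;
  (*grad)(1) = -arma::accu(G_d);
  for (arma::uword m = 0; m + 1 < Kb; ++m) {
    const double gap = std::exp(eta(2 + m));
    double tail = 0.0;
    for (arma::uword t = m + 1; t < Kb; ++t) tail += G_d(t);
    (*grad)(2 + m) = gap * tail;
  }
  return val;
}

// Joint expected complete-data negative log-likelihood and gradient over all
// items (block separable; K entries of eta per item).
// [[Rcpp::export]]
List grm_mstep_eval(const arma::vec& eta, const arma::cube& counts,
                    const arma::vec& nodes, const int K) {
  const arma::uword J = counts.n_slices;
  double val = 0.0;
  arma::vec grad(eta.n_elem, arma::fill::zeros);
  for (arma::uword j = 0; j < J; ++j) {
    const arma::uword off = j * static_cast<arma::uword>(K);
    arma::vec ej = eta.subvec(off, off + K - 1);
    arma::vec gj;
    val += item_eval(ej, counts.slice(j), nodes, K, &gj);
    grad.subvec(off, off + K - 1) = gj;
  }
  return List::create(_["value"] = val, _["gradient"] = grad);
}

// Per-item M-step maximizer: damped Newton with a finite-difference Hessian
// of the analytic gradient and backtracking line search (gradient-descent
// fallback). The returned point never has a larger objective than the warm
// start, so the EM ascent property is preserved.
// [[Rcpp::export]]
arma::vec grm_mstep_opt(const arma::vec& eta, const arma::cube& counts,
                        const arma::vec& nodes, const int K,
                        const int max_iter = 30, const double gtol = 1e-8) {
  const arma::uword J = counts.n_slices;
  arma::vec out(eta.n_elem);
  const double h = 1e-6;

  for (arma::uword j = 0; j < J; ++j) {
    const arma::uword off = j * static_cast<arma::uword>(K);
    const arma::mat& r = counts.slice(j);
    arma::vec x = eta.subvec(off, off + K - 1);
    arma::vec g;
    double f = item_eval(x, r, nodes, K, &g);

    for (int it = 0; it < max_iter; ++it) {
      if (arma::abs(g).max() < gtol) break;

      arma::mat H(K, K);
      for (int p = 0; p < K; ++p) {
        arma::vec xp = x;
        xp(p) += h;
        arma::vec gp;
        item_eval(xp, r, nodes, K, &gp);
        H.col(p) = (gp - g) / h;
      }
      H = 0.5 * (H + H.t());

      arma::vec step;
      bool solved = arma::solve(step, H + 1e-8 * arma::eye(K, K), -g,
                                arma::solve_opts::no_approx);
      if (!solved || !step.is_finite() || arma::dot(step, g) >= 0) {
        step = -g;  // fall back to steepest descent
      }

      double t = 1.0;
      bool improved = false;
      for (int ls = 0; ls < 20; ++ls) {
        arma::vec xn = x + t * step;
        arma::vec gn;
        const double fn = item_eval(xn, r, nodes, K, &gn);
        if (std::isfinite(fn) && fn <= f - 1e-12) {
          x = xn;
          f = fn;
          g = gn;
          improved = true;
          break;
        }
        t *= 0.5;
      }
      if (!improved) break;
    }
    out.subvec(off, off + K - 1) = x;
  }
  return out;
}
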