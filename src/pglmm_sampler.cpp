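// Gibbs/Metropolis sampler for the Bayesian multinomial-logit phylogenetic
// mixed model. The phylogenetic covariance A is eigendecomposed in R
// (A = U diag(d) U'); working in the eigenbasis makes the random-effect
// update O(n) per sweep instead of a dense n x n solve.
//
// Model, J response states, reference state 0, L = J - 1 latent dimensions:
//   l_i = B' x_i + diag(alpha) (U W)_i + e_i,   e_i ~ N(0, Se) (Se fixed)
//   rows of W in the eigenbasis: w_m ~ N(0, d_m * Su)
//   P(y_i = j | l_i) = softmax with baseline category 0
// Priors: vec(B) ~ N(0, vB I); alpha_j ~ N(0, vA) (parameter expansion);
// Su ~ IW(V = I, nu = L). Reported random-effect covariance is
// diag(alpha) Su diag(alpha).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double cat_loglik(const rowvec& l, int y) {
  // log P(y | l), baseline category 0; latents are clipped upstream
  double m = std::max(0.0, l.max());
  double denom = std::exp(-m) + accu(exp(l - m));
  double num = (y == 0) ? -m : l(y - 1) - m;
  return num - std::log(denom);
}

static mat rinvwishart(const mat& S_inv_scale, double nu) {
  // draw from IW(scale, nu) given the *inverse* of the scale: draw
  // Wishart(S_inv_scale^{-1}... ) via Bartlett on the inverse scale
  int p = S_inv_scale.n_rows;
  mat Lc = chol(inv_sympd(S_inv_scale), "lower");
  mat Acn(p, p, fill::zeros);
  for (int i = 0; i < p; ++i) {
    Acn(i, i) = std::sqrt(R::rchisq(nu - i));
    for (int j = 0; j < i; ++j) Acn(i, j) = R::rnorm(0.0, 1.0);
  }
  mat W = Lc * Acn * Acn.t() * Lc.t();   // Wishart(inv(scale), nu)
  return inv_sympd(W);
}

// [[Rcpp::export(name = ".pglmm_sampler")]]
Rcpp::List pglmm_sampler(const arma::ivec& y, const arma::mat& X,
                         const arma::mat& U, const arma::vec& d,
                         const arma::mat& Se, double vB, double vA,
                         int n_iter, int burnin, int thin,
                         double prop_sd, double latent_clip,
                         bool use_random) {
  const int n = y.n_elem, K = X.n_cols;
  const int L = Se.n_rows;               // J - 1 latent dimensions
  const mat Se_inv = inv_sympd(Se);

  mat B(K, L, fill::zeros);              // fixed effects, per latent column
  mat W(n, L, fill::zeros);              // random effects in the eigenbasis
  vec alpha(L, fill::ones);              // parameter-expansion scales
  mat Su = eye(L, L);                    // random-effect covariance (working)
  mat l(n, L, fill::zeros);              // latent variables

  const int n_keep = (n_iter - burnin) / thin;
  mat beta_draws(n_keep, K * L);
  mat sa_draws(n_keep, L * L);
  vec accept(1, fill::zeros);
  int kept = 0;
  long long n_prop = 0, n_acc = 0;

  if (!use_random) alpha.zeros();

  for (int it = 1; it <= n_iter; ++it) {
    mat UW = U * W;                      // random effects, species basis
    mat mu = X * B + UW * diagmat(alpha);

    // 1. latent variables: random-walk MH, species independent given mu
    for (int i = 0; i < n; ++i) {
      rowvec cur = l.row(i);
      rowvec prop = cur;
      for (int j = 0; j < L; ++j) prop(j) += R::rnorm(0.0, prop_sd);
      prop = clamp(prop, -latent_clip, latent_clip);
      rowvec rc = cur - mu.row(i), rp = prop - mu.row(i);
      double logr = cat_loglik(prop, y(i)) - cat_loglik(cur, y(i))
        - 0.5 * as_scalar(rp * Se_inv * rp.t())
        + 0.5 * as_scalar(rc * Se_inv * rc.t());
      ++n_prop;
      if (std::log(R::runif(0.0, 1.0)) < logr) { l.row(i) = prop; ++n_acc; }
    }

    // 2. fixed effects B | l, W, alpha  (conjugate matrix-normal update)
    {
      mat resid = l - UW * diagmat(alpha);   // n x L
      mat XtX = X.t() * X;
      // vec(B) over column-major: precision = Se_inv (x) XtX + I/vB
      mat prec = kron(Se_inv, XtX) + eye(K * L, K * L) / vB;
      vec rhs = vectorise(X.t() * resid * Se_inv);
      mat cholP = chol(prec, "lower");
      vec z(K * L);
      for (unsigned int q = 0; q < z.n_elem; ++q) z(q) = R::rnorm(0.0, 1.0);
      vec mean_b = solve(trimatu(cholP.t()), solve(trimatl(cholP), rhs));
      vec bdraw = mean_b + solve(trimatu(cholP.t()), z);
      B = reshape(bdraw, K, L);
    }

    // 3. random effects W | l, B, alpha, Su — rows independent in eigenbasis
    if (use_random) {
      mat Zt = U.t() * (l - X * B);          // n x L, = D_alpha w_m + e
      mat Da = diagmat(alpha);
      mat G = Da * Se_inv * Da;              // L x L, same for all rows
      mat Su_inv = inv_sympd(Su);
      for (int m = 0; m < n; ++m) {
        mat prec = G + Su_inv / d(m);
        mat cholP = chol(prec, "lower");
        vec rhs = Da * Se_inv * Zt.row(m).t();
        vec z(L);
        for (int q = 0; q < L; ++q) z(q) = R::rnorm(0.0, 1.0);
        vec mean_w = solve(trimatu(cholP.t()), solve(trimatl(cholP), rhs));
        W.row(m) = (mean_w + solve(trimatu(cholP.t()), z)).t();
      }
    }

    // 4. expansion scales alpha | l, B, W  (conjugate, diagonal design)
    if (use_random) {
      mat C = U * W;                         // n x L
      mat resid = l - X * B;                 // n x L
      mat prec(L, L, fill::zeros);
      vec rhs(L, fill::zeros);
      for (int i = 0; i < n; ++i) {
        mat Dc = diagmat(C.row(i));
        prec += Dc * Se_inv * Dc;
        rhs += Dc * Se_inv * resid.row(i).t();
      }
      prec += eye(L, L) / vA;
      mat cholP = chol(prec, "lower");
      vec z(L);
      for (int q = 0; q < L; ++q) z(q) = R::rnorm(0.0, 1.0);
      vec mean_a = solve(trimatu(cholP.t()), solve(trimatl(cholP), rhs));
      alpha = mean_a + solve(trimatu(cholP.t()), z);
    }

    // 5. Su | W  — inverse-Wishart, prior IW(I, L)
    if (use_random) {
      mat S = eye(L, L);
      for (int m = 0; m < n; ++m)
        S += W.row(m).t() * W.row(m) / d(m);
      Su = rinvwishart(inv_sympd(S), (double) (L + n));
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      beta_draws.row(kept) = vectorise(B).t();
      mat Sa = diagmat(alpha) * Su * diagmat(alpha);
      sa_draws.row(kept) = vectorise(Sa).t();
      ++kept;
    }
  }
  accept(0) = (double) n_acc / (double) n_prop;
  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_draws.rows(0, kept - 1),
    Rcpp::Named("sigma_a") = sa_draws.rows(0, kept - 1),
    Rcpp::Named("acceptance") = accept(0));
}
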