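# Pairwise character co-dependence: PGLS with pseudo-continuous state codes
# on the Brownian covariance, a Bayesian multinomial-logit phylogenetic mixed
# model (PGLMM), MCMC diagnostics, and the all-pairs screen.

#' Phylogenetic generalized least squares on coded states
#'
#' GLS regression `y ~ x` with error covariance proportional to the Brownian
#' phylogenetic covariance of the tree (Pagel coefficients fixed at 1, i.e.
#' the untransformed tree). Discrete states enter as their integer codes
#' (pseudo-continuous coding). The solve whitens through the Cholesky factor
#' of V; no explicit inverse is formed. Estimates are invariant to scaling V
#' by a positive constant.
#'
#' @param tree A rooted `phylo` object.
#' @param y_codes,x_codes Named numeric vectors (taxon -> code); taxa with an
#'   `NA` in either variable are dropped, and the tree is pruned to the
#'   jointly scored taxa.
#' @return List of class `gls_fit`: `beta`, `se`, `t`, `p_coef`, `p_global`
#'   (model F test), `sigma2`, `n`, `df_residual`.
#' @export
pgls <- function(tree, y_codes, x_codes) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(y_codes)) || is.null(names(x_codes)))
    stop("y_codes and x_codes must be named by taxon")
  taxa <- intersect(tree$tip.label,
                    intersect(names(y_codes)[!is.na(y_codes)],
                              names(x_codes)[!is.na(x_codes)]))
  if (length(taxa) < 4) stop("fewer than 4 jointly scored taxa")
  tr <- prune_to_taxa(tree, taxa)
  y <- as.numeric(y_codes[tr$tip.label])
  x <- as.numeric(x_codes[tr$tip.label])
  if (length(unique(x)) < 2) stop("constant predictor: x")
  if (length(unique(y)) < 2) stop("constant response: y")
  V <- bm_covariance(tr)
  Lc <- chol(V)  # V = t(Lc) %*% Lc
  wy <- backsolve(Lc, y, transpose = TRUE)
  X <- cbind(`(Intercept)` = 1, x = x)
  wX <- backsolve(Lc, X, transpose = TRUE)
  qrX <- qr(wX)
  if (qrX$rank < ncol(X)) stop("singular design (constant predictor: x)")
  beta <- qr.coef(qrX, wy)
  res <- wy - wX %*% beta
  n <- length(y); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  XtVX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtVX_inv))
  tval <- beta / se
  p_coef <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  # global F test against the intercept-only GLS model
  w1 <- cbind(backsolve(Lc, rep(1, n), transpose = TRUE))
  res0 <- wy - w1 %*% qr.coef(qr(w1), wy)
  rss0 <- sum(res0^2); rss <- sum(res^2)
  Fstat <- ((rss0 - rss) / (p - 1)) / (rss / (n - p))
  p_global <- stats::pf(Fstat, p - 1, n - p, lower.tail = FALSE)
  structure(list(beta = beta, se = se, t = tval, p_coef = p_coef,
                 F = Fstat, p_global = p_global, sigma2 = sigma2, n = n,
                 df_residual = n - p, residuals_whitened = as.vector(res)),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d): slope = %.4f (se %.4f), p = %.3g; global p = %.3g\n",
              x$n, x$beta[2], x$se[2], x$p_coef[2], x$p_global))
  invisible(x)
}

#' Bayesian multinomial-logit phylogenetic mixed model
#'
#' Latent-variable mixed model `l = X beta + Z a + e` for a discrete response
#' with J states (reference = lowest code). For J = 2 a single latent with
#' intercept and slope is fitted; for J > 2 each of the J-1 latents gets its
#' own intercept and slope (no global intercept). The phylogenetic random
#' effect has covariance `Sigma_a (x) A`, with A the Brownian covariance of
#' the tree normalized to unit height. Priors follow the usual multinomial
#' MCMCglmm setup: fixed effects N(0, (1.7 + pi^2/3) I); residual covariance
#' fixed at (I + 1)/J; random-effect covariance inverse-Wishart (V = I,
#' nu = J-1) with parameter expansion (alpha.mu = 0, alpha.V = 1000 I).
#' Sampling is blocked Gibbs in the eigenbasis of A, with Metropolis steps
#' for the latents (clipped to +/- `latent_clip` against overflow).
#'
#' @param tree A rooted `phylo` object.
#' @param response Named integer vector of response states.
#' @param predictor Named numeric/integer vector (pseudo-continuous code).
#' @param iterations,burnin,thinning MCMC settings (desk-scale defaults
#'   1e5 / 1e4 / 1e2).
#' @param seed Integer RNG seed.
#' @param prop_sd Random-walk SD of the latent Metropolis step.
#' @param latent_clip Absolute bound on latents.
#' @param random_effect When `FALSE` the phylogenetic random effect is forced
#'   to zero (sigma_a = 0), giving the phylogeny-free latent logit model (the
#'   limit used to validate the sampler against the multinomial-logit MLE).
#' @return List of class `pglmm_result`: `beta` (draw matrix, columns named),
#'   `sigma_a` (draws of the random-effect (co)variance), `summary`
#'   (posterior mean, latent scale and marginal `mean_rescaled` scale
#'   obtained by dividing by `sqrt(1 + c2 * sigma_e2)` with
#'   `c2 = (16 sqrt(3) / (15 pi))^2`, the standard fixed-residual logit
#'   correction; 95% CI; two-sided posterior p per fixed effect),
#'   `diagnostics`, `converged`, `acceptance`, `reference_state`, `n`.
#' @export
pglmm <- function(tree, response, predictor, iterations = 1e5,
                  burnin = 1e4, thinning = 1e2, seed = 1,
                  prop_sd = 0.8, latent_clip = 20, random_effect = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- intersect(tree$tip.label,
                    intersect(names(response)[!is.na(response)],
                              names(predictor)[!is.na(predictor)]))
  if (length(taxa) < 10) stop("fewer than 10 jointly scored taxa")
  tr <- prune_to_taxa(tree, taxa)
  y_raw <- response[tr$tip.label]
  levels <- sort(unique(y_raw))
  if (length(levels) < 2) stop("response has a single observed state")
  y <- match(y_raw, levels) - 1L
  J <- length(levels)
  L <- J - 1L
  x <- as.numeric(predictor[tr$tip.label])
  X <- cbind(1, x)
  A <- bm_covariance(tr)
  A <- A / max(diag(A))
  eA <- eigen(A, symmetric = TRUE)
  d <- pmax(eA$values, 1e-10)
  Se <- (diag(L) + matrix(1, L, L)) / J
  vB <- 1.7 + pi^2 / 3

  res <- with_seed(seed, .pglmm_sampler(as.integer(y), X, eA$vectors, d, Se,
                                        vB, 1e3, as.integer(iterations),
                                        as.integer(burnin),
                                        as.integer(thinning),
                                        prop_sd, latent_clip,
                                        isTRUE(random_effect)))
  beta <- res$beta
  cn <- as.vector(outer(c("(Intercept)", "slope"), seq_len(L),
                        function(a, b) paste0(a, if (L > 1) paste0(".l", b) else "")))
  colnames(beta) <- cn
  colnames(res$sigma_a) <- as.vector(outer(seq_len(L), seq_len(L),
                                           function(a, b) paste0("sa", a, b)))
  post_p <- apply(beta, 2, function(ch)
    min(1, 2 * min(mean(ch > 0), mean(ch < 0))))
  ci <- t(apply(beta, 2, stats::quantile, probs = c(0.025, 0.975)))
  c2 <- (16 * sqrt(3) / (15 * pi))^2
  rescale <- 1 / sqrt(1 + c2 * rep(diag(Se), each = 2))
  summ <- data.frame(parameter = cn, mean = colMeans(beta),
                     mean_rescaled = colMeans(beta) * rescale,
                     lower95 = ci[, 1], upper95 = ci[, 2], p = post_p,
                     row.names = NULL, stringsAsFactors = FALSE)
  diag_tab <- mcmc_diagnostics(cbind(beta, res$sigma_a))
  conv <- mean(abs(diag_tab$geweke_z) >= 3, na.rm = TRUE) <= 0.2
  structure(list(beta = beta, sigma_a = res$sigma_a, summary = summ,
                 diagnostics = diag_tab, converged = conv,
                 acceptance = res$acceptance,
                 reference_state = levels[1], state_levels = levels,
                 n = length(taxa)),
            class = "pglmm_result")
}

#' @export
print.pglmm_result <- function(x, ...) {
  cat(sprintf("PGLMM (n = %d, reference state %s, %d draws, acc. %.2f)\n",
              x$n, x$reference_state, nrow(x$beta), x$acceptance))
  print(x$summary, digits = 4)
  invisible(x)
}

# AR-based spectral density at frequency zero (Geweke variance estimate).
spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) return(0)
  fit <- tryCatch(stats::ar(x, aic = TRUE,
                            order.max = min(20, length(x) - 2)),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' MCMC convergence diagnostics
#'
#' Lag-1/5/10/50 autocorrelations and the Geweke z score (mean of the first
#' 10% of the chain vs the last 50%, variances estimated by the AR spectral
#' density at frequency zero) for every parameter.
#'
#' @param chains Numeric matrix, one column per parameter (>= 100 rows).
#' @return Data frame: parameter, lag-k autocorrelations, `geweke_z`.
#' @export
mcmc_diagnostics <- function(chains) {
  chains <- as.matrix(chains)
  if (nrow(chains) < 100) stop("need at least 100 retained draws")
  lags <- c(1, 5, 10, 50)
  out <- lapply(seq_len(ncol(chains)), function(j) {
    x <- chains[, j]
    ac <- stats::acf(x, lag.max = max(lags), plot = FALSE,
                     demean = TRUE)$acf[lags + 1]
    n1 <- max(2, floor(0.1 * length(x)))
    x1 <- x[seq_len(n1)]
    x2 <- x[seq(floor(0.5 * length(x)) + 1, length(x))]
    s1 <- spectrum0_ar(x1) / length(x1)
    s2 <- spectrum0_ar(x2) / length(x2)
    z <- if (s1 + s2 == 0) 0 else (mean(x1) - mean(x2)) / sqrt(s1 + s2)
    c(ac, z)
  })
  out <- do.call(rbind, out)
  data.frame(parameter = colnames(chains) %||% paste0("par", seq_len(ncol(chains))),
             acf_lag1 = out[, 1], acf_lag5 = out[, 2], acf_lag10 = out[, 3],
             acf_lag50 = out[, 4], geweke_z = out[, 5],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen all character pairs for phylogenetic correlation
#'
#' Every unordered pair of character columns is tested: the tree is pruned to
#' the jointly scored taxa, PGLS (and optionally PGLMM) is run with the
#' earlier column as response, and significance is called at `alpha`.
#'
#' @param tree A rooted `phylo` object.
#' @param matrix Data frame with a `species` column and >= 2 character
#'   columns (integer codes, `NA` unknown).
#' @param methods Subset of `c("pgls", "pglmm")`.
#' @param alpha Significance level (default 0.05).
#' @param min_n Pairs with fewer jointly scored taxa are skipped with a
#'   warning.
#' @param pglmm_args List of arguments forwarded to [pglmm()].
#' @return Data frame: response, predictor, n, and per-method coefficient,
#'   p value and significance call.
#' @export
correlation_screen <- function(tree, matrix, methods = "pgls", alpha = 0.05,
                               min_n = 10, pglmm_args = list()) {
  stopifnot(is.data.frame(matrix), names(matrix)[1] == "species")
  chars <- names(matrix)[-1]
  if (length(chars) < 2) stop("need at least two characters")
  pairs <- utils::combn(chars, 2)
  rows <- list()
  for (pi in seq_len(ncol(pairs))) {
    resp <- pairs[1, pi]; pred <- pairs[2, pi]
    yv <- stats::setNames(matrix[[resp]], matrix$species)
    xv <- stats::setNames(matrix[[pred]], matrix$species)
    taxa <- intersect(tree$tip.label,
                      intersect(names(yv)[!is.na(yv)], names(xv)[!is.na(xv)]))
    if (length(taxa) < min_n) {
      warning("skipping pair ", resp, " ~ ", pred, ": only ",
              length(taxa), " jointly scored taxa")
      next
    }
    row <- data.frame(response = resp, predictor = pred, n = length(taxa),
                      stringsAsFactors = FALSE)
    if ("pgls" %in% methods) {
      fit <- tryCatch(pgls(tree, yv, xv), error = function(e) NULL)
      row$pgls_coef <- if (is.null(fit)) NA else unname(fit$beta[2])
      row$pgls_p <- if (is.null(fit)) NA else fit$p_global
      row$pgls_significant <- if (is.null(fit)) NA else fit$p_global < alpha
    }
    if ("pglmm" %in% methods) {
      fit <- tryCatch(do.call(pglmm, c(list(tree = tree, response = yv,
                                            predictor = xv), pglmm_args)),
                      error = function(e) NULL)
      if (is.null(fit)) {
        row$pglmm_coef <- NA; row$pglmm_p <- NA; row$pglmm_significant <- NA
      } else {
        slopes <- grepl("^slope", fit$summary$parameter)
        j <- which(slopes)[which.min(fit$summary$p[slopes])]
        row$pglmm_coef <- fit$summary$mean[j]
        row$pglmm_p <- fit$summary$p[j]
        row$pglmm_significant <- fit$summary$p[j] < alpha
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}
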