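# Mk model engine: rate matrices, transition probabilities, pruning
# likelihood, ML fitting with Pagel transformations, AICc/AICw comparison,
# and the lambda likelihood-ratio test of phylogenetic signal.

#' Build an Mk rate matrix
#'
#' Off-diagonal entries are filled from the rate vector according to the
#' model structure: `ER` uses one rate everywhere, `SYM` fills the upper
#' triangle row-wise and mirrors it (`q_ij = q_ji`), `ARD` fills all
#' off-diagonals row-wise. Diagonals are minus the row sums.
#'
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @param k Number of states (>= 2).
#' @param rates Non-negative rate vector: length 1 (ER), `k(k-1)/2` (SYM) or
#'   `k(k-1)` (ARD).
#' @return k x k rate matrix.
#' @export
build_q <- function(structure = c("ER", "SYM", "ARD"), k, rates) {
  structure <- match.arg(structure)
  if (k < 2) stop("k must be >= 2")
  if (any(rates < 0)) stop("rates must be >= 0")
  n_need <- n_rates(structure, k)
  if (length(rates) != n_need)
    stop(structure, " with k = ", k, " needs ", n_need, " rates, got ",
         length(rates))
  Q <- matrix(0, k, k)
  if (structure == "ER") {
    Q[] <- rates
  } else if (structure == "SYM") {
    Q[upper.tri(Q)] <- rates[sym_fill_order(k)]
    Q[lower.tri(Q)] <- t(Q)[lower.tri(Q)]
  } else {
    idx <- which(t(!diag(k)) == 1)  # row-wise off-diagonal order
    tQ <- t(Q)
    tQ[idx] <- rates
    Q <- t(tQ)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# upper.tri() is column-wise; reorder so `rates` is consumed row-wise.
sym_fill_order <- function(k) {
  pos <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  order(order(pos[, "row"], pos[, "col"]))
}

n_rates <- function(structure, k) {
  switch(structure, ER = 1L, SYM = as.integer(k * (k - 1) / 2),
         ARD = as.integer(k * (k - 1)))
}

#' Extract the free rate vector from a rate matrix
#'
#' Inverse of [build_q()] for a given structure.
#'
#' @param Q Rate matrix.
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @return Numeric rate vector.
#' @export
q_rates <- function(Q, structure = c("ER", "SYM", "ARD")) {
  structure <- match.arg(structure)
  k <- nrow(Q)
  if (structure == "ER") return(Q[1, 2])
  if (structure == "SYM") {
    pos <- which(upper.tri(Q), arr.ind = TRUE)
    pos <- pos[order(pos[, "row"], pos[, "col"]), , drop = FALSE]
    return(Q[pos])
  }
  tQ <- t(Q)
  tQ[which(t(!diag(k)) == 1)]
}

# Eigen machinery reused across branches; NULL when Q is defective or
# ill-conditioned (caller falls back to scaling-and-squaring).
q_eigen <- function(Q) {
  e <- tryCatch(eigen(Q), error = function(err) NULL)
  if (is.null(e)) return(NULL)
  V <- e$vectors
  Vi <- tryCatch(solve(V), error = function(err) NULL)
  if (is.null(Vi)) return(NULL)
  cond <- norm(abs(V), "1") * norm(abs(Vi), "1")
  if (!all(is.finite(Mod(Vi))) || !is.finite(cond) || cond > 1e8)
    return(NULL)
  list(values = e$values, V = V, Vi = Vi)
}

p_from_eigen <- function(eg, t) {
  P <- Re(eg$V %*% (exp(eg$values * t) * eg$Vi))
  fix_p(P)
}

fix_p <- function(P) {
  if (any(P < -1e-9)) return(NULL)  # numerically bad; caller retries
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Transition probability matrix of a CTMC
#'
#' `P(t) = expm(Q t)`, computed by eigendecomposition when `Q` is
#' diagonalizable and well-conditioned, otherwise by scaling-and-squaring
#' ([Matrix::expm()]). Tiny negative entries are clipped to zero and rows are
#' renormalized.
#'
#' @param Q Rate matrix.
#' @param t Elapsed time (>= 0).
#' @return Stochastic matrix (rows sum to one).
#' @export
transition_prob <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("t must be >= 0")
  if (t == 0) return(diag(nrow(Q)))
  eg <- q_eigen(Q)
  if (!is.null(eg)) {
    P <- p_from_eigen(eg, t)
    if (!is.null(P)) return(P)
  }
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Transition matrices for every edge of a tree (list indexed by edge row).
# One (n_edges x k) * (k x k^2) multiply in the eigenbasis covers all edges.
edge_probs <- function(Q, ts) {
  k <- nrow(Q)
  eg <- q_eigen(Q)
  if (!is.null(eg)) {
    W <- matrix(0i, k, k * k)  # W[m, (i,j)] = V[i,m] * Vi[m,j]
    for (j in seq_len(k))
      W[, ((j - 1) * k + 1):(j * k)] <- t(eg$V) * eg$Vi[, j]
    Pflat <- Re(exp(outer(ts, eg$values)) %*% W)
    if (min(Pflat) > -1e-9) {
      Pflat[Pflat < 0] <- 0
      out <- vector("list", length(ts))
      for (i in seq_along(ts)) {
        P <- matrix(Pflat[i, ], k, k)
        out[[i]] <- P / rowSums(P)
      }
      return(out)
    }
  }
  lapply(ts, function(t) {
    P <- as.matrix(Matrix::expm(Q * t))
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

# Map a named tip-state vector onto the tree; prune tips with unknown state.
# Returns list(tree, states) with states re-coded 1..k and levels recorded.
align_states <- function(tree, tip_states, prune_unknown = TRUE) {
  if (is.null(names(tip_states))) stop("tip_states must be named by taxon")
  missing <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing) > 0)
    stop("tips without a state: ", paste(utils::head(missing, 5), collapse = ", "))
  x <- tip_states[tree$tip.label]
  if (prune_unknown && anyNA(x)) {
    keep <- tree$tip.label[!is.na(x)]
    if (length(keep) < 2) stop("fewer than two scored tips")
    tree <- prune_to_taxa(tree, keep)
    x <- tip_states[tree$tip.label]
  }
  levels <- sort(unique(x[!is.na(x)]))
  list(tree = tree, states = match(x, levels), levels = levels)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree A rooted `phylo` object.
#' @param tip_states Named integer vector of states (`0..k-1`); `NA` marks an
#'   unknown state and enters as an all-ones partial likelihood.
#' @param Q k x k rate matrix.
#' @param root_prior `"uniform"`, `"stationary"`, or `"conditional-scaled"`
#'   (FitzJohn-style weighting by the scaled conditional likelihoods).
#' @return Log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, tip_states, Q,
                      root_prior = c("uniform", "stationary",
                                     "conditional-scaled")) {
  root_prior <- match.arg(root_prior)
  k <- nrow(Q)
  if (is.null(names(tip_states))) stop("tip_states must be named by taxon")
  x <- tip_states[tree$tip.label]
  if (any(!is.na(x) & (x < 0 | x >= k)))
    stop("state index out of range for a ", k, "-state model")
  pr <- prune_partials(tree, x, Q)
  root_L <- pr$L[ape::Ntip(tree) + 1L, ]
  prior <- root_prior_vec(root_prior, Q, root_L)
  pr$logscale + log(sum(prior * root_L))
}

root_prior_vec <- function(root_prior, Q, root_L) {
  k <- nrow(Q)
  switch(root_prior,
         uniform = rep(1 / k, k),
         stationary = stationary_dist(Q),
         `conditional-scaled` = root_L / sum(root_L))
}

# Post-order conditional likelihoods. Returns L ((ntip+nnode) x k, tips
# one-hot / all-ones, internals = products of child messages, rescaled) plus
# the accumulated log scaling factor and the per-edge P matrices.
prune_partials <- function(tree, x, Q, Plist = NULL) {
  k <- nrow(Q)
  ntip <- ape::Ntip(tree)
  n_tot <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  if (is.null(Plist)) Plist <- edge_probs(Q, po$edge.length)
  L <- matrix(1, n_tot, k)
  for (i in seq_len(ntip))
    if (!is.na(x[i])) { L[i, ] <- 0; L[i, x[i] + 1L] <- 1 }
  logscale <- 0
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    v <- Plist[[e]] %*% L[ch, ]
    L[p, ] <- L[p, ] * v
    s <- max(L[p, ])
    if (s <= 0) return(list(L = L, logscale = -Inf, po = po, Plist = Plist))
    L[p, ] <- L[p, ] / s
    logscale <- logscale + log(s)
  }
  list(L = L, logscale = logscale, po = po, Plist = Plist)
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates (log scale, bounded in `[1e-8, 1e3]`) and, optionally, one Pagel
#' transformation coefficient are optimized by multi-start bounded
#' quasi-Newton (`L-BFGS-B`). Tips with unknown state are pruned before
#' fitting. The sample-size corrected AIC uses the number of tips as sample
#' size: `AICc = -2 lnL + 2p + 2p(p+1)/(n-p-1)`.
#'
#' @param tree A rooted, preferably bifurcating `phylo` object.
#' @param tip_states Named integer vector (`0..k-1`, `NA` = unknown).
#' @param structure `"ER"`, `"SYM"` or `"ARD"`.
#' @param transform_kind `"none"`, `"lambda"`, `"delta"` or `"kappa"`.
#' @param n_starts Number of log-spaced rate starting points (default 25).
#' @param root_prior Root prior passed to [mk_loglik()].
#' @param pendant Pendant-branch handling for the lambda transform
#'   (see [transform_lambda()]).
#' @return A list of class `mk_fit`: `structure`, `transform`, `coefficient`,
#'   `rates`, `Q`, `lnL`, `k`, `n_params`, `n_tips`, `AICc`, `converged`,
#'   `state_levels`.
#' @export
fit_mk <- function(tree, tip_states,
                   structure = c("ER", "SYM", "ARD"),
                   transform_kind = c("none", "lambda", "delta", "kappa"),
                   n_starts = 25, root_prior = "uniform",
                   pendant = "extend") {
  structure <- match.arg(structure)
  transform_kind <- match.arg(transform_kind)
  al <- align_states(tree, tip_states)
  tree <- al$tree
  k <- length(al$levels)
  if (k < 2)
    stop("character is monomorphic among scored tips; remove it ",
         "(likelihood is flat in the rates)")
  x01 <- al$states - 1L
  names(x01) <- tree$tip.label
  nr <- n_rates(structure, k)
  h <- tree_height(tree)
  ntip <- ape::Ntip(tree)

  has_coef <- transform_kind != "none"
  coef_bounds <- switch(transform_kind, none = NULL, lambda = c(0, 1),
                        delta = c(0.01, 3), kappa = c(0.01, 3))
  tr_tree <- function(coef) {
    if (!has_coef) return(tree)
    if (transform_kind == "lambda")
      transform_lambda(tree, coef, pendant = pendant)
    else transform_tree(tree, transform_kind, coef)
  }
  nll <- function(par) {
    rates <- exp(par[seq_len(nr)])
    Q <- build_q(structure, k, rates)
    tt <- if (has_coef) tr_tree(par[nr + 1]) else tree
    ll <- tryCatch(mk_loglik(tt, x01, Q, root_prior = root_prior),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }

  base_rates <- exp(seq(log(0.05 / h), log(25 / h),
                        length.out = max(2, n_starts)))[seq_len(max(1, n_starts))]
  coef_starts <- switch(transform_kind, none = NA, lambda = c(0.9, 0.5, 0.2),
                        delta = c(1, 0.3, 2), kappa = c(1, 0.3, 2))
  lower <- c(rep(log(1e-8), nr), if (has_coef) coef_bounds[1])
  upper <- c(rep(log(1e3), nr), if (has_coef) coef_bounds[2])

  best <- NULL
  for (i in seq_len(max(1, n_starts))) {
    p0 <- rep(log(base_rates[i]), nr)
    if (has_coef)
      p0 <- c(p0, coef_starts[(i - 1) %% length(coef_starts) + 1])
    fit <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed for all starting points")

  rates <- exp(best$par[seq_len(nr)])
  coefficient <- if (has_coef) best$par[nr + 1] else NA_real_
  Q <- build_q(structure, k, rates)
  lnL <- -best$value
  p <- nr + as.integer(has_coef)
  aicc <- -2 * lnL + 2 * p + if (ntip - p - 1 > 0) 2 * p * (p + 1) / (ntip - p - 1) else Inf
  structure(list(structure = structure, transform = transform_kind,
                 coefficient = coefficient, rates = rates, Q = Q, lnL = lnL,
                 k = k, n_params = p, n_tips = ntip, AICc = aicc,
                 converged = best$convergence == 0,
                 state_levels = al$levels),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit: %s%s, k = %d, lnL = %.4f, AICc = %.4f\n",
              x$structure,
              if (x$transform != "none")
                sprintf(" + %s = %.4f", x$transform, x$coefficient) else "",
              x$k, x$lnL, x$AICc))
  invisible(x)
}

#' Compare fitted Mk models with AICc and Akaike weights
#'
#' @param fits List of `mk_fit` objects fitted to the same data.
#' @return Data frame (sorted by AICc) with columns `Model`,
#'   `Transformation`, `Estimator`, `lnL`, `AICc`, `AICw`.
#' @export
compare_models <- function(fits) {
  if (length(fits) == 0) stop("no fits to compare")
  tab <- data.frame(
    Model = vapply(fits, `[[`, "", "structure"),
    Transformation = vapply(fits, `[[`, "", "transform"),
    Estimator = vapply(fits, `[[`, 0, "coefficient"),
    lnL = vapply(fits, `[[`, 0, "lnL"),
    AICc = vapply(fits, `[[`, 0, "AICc"),
    stringsAsFactors = FALSE)
  delta <- tab$AICc - min(tab$AICc)
  w <- exp(-delta / 2)
  tab$AICw <- w / sum(w)
  tab[order(tab$AICc), , drop = FALSE]
}

#' Likelihood-ratio test of phylogenetic signal via Pagel's lambda
#'
#' The Mk likelihood is profiled over the lambda transformation of the tree;
#' the ML estimate is compared with the star-phylogeny null (lambda = 0) by a
#' chi-square LRT with one degree of freedom.
#'
#' @inheritParams fit_mk
#' @return List of class `signal_test`: `lambda_ml`, `lnL_ml`, `lnL_0`,
#'   `lrt`, `p`, plus the two underlying fits.
#' @export
phylo_signal_lambda <- function(tree, tip_states, structure = "ER",
                                n_starts = 5, root_prior = "uniform") {
  fit1 <- fit_mk(tree, tip_states, structure, transform_kind = "lambda",
                 n_starts = n_starts, root_prior = root_prior)
  tree0 <- transform_lambda(tree, 0)
  fit0 <- fit_mk(tree0, tip_states, structure, transform_kind = "none",
                 n_starts = n_starts, root_prior = root_prior)
  lrt <- max(0, 2 * (fit1$lnL - fit0$lnL))
  structure(list(lambda_ml = fit1$coefficient, lnL_ml = fit1$lnL,
                 lnL_0 = fit0$lnL, lrt = lrt,
                 p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 fit_ml = fit1, fit_0 = fit0),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf("lambda_ML = %.4f, LRT = %.3f, p = %.3g\n",
              x$lambda_ml, x$lrt, x$p))
  invisible(x)
}

#' Zero out negligible rates
#'
#' Off-diagonal rates below `floor` are set to zero and the diagonal is
#' recomputed so rows still sum to zero.
#'
#' @param Q Rate matrix.
#' @param floor Threshold below which a rate is considered zero
#'   (default `1e-6`).
#' @return Rate matrix.
#' @export
zero_small_rates <- function(Q, floor = 1e-6) {
  off <- Q
  diag(off) <- 0
  off[off < floor] <- 0
  diag(off) <- -rowSums(off)
  off
}
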