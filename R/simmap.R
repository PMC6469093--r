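# Stochastic character mapping: exact marginal ancestral states by the
# up-down pruning recursion, and full substitution histories sampled by
# node-state draws plus endpoint-conditioned branch paths (uniformization).

#' Exact marginal ancestral-state posteriors
#'
#' Up-down (inside-outside) pruning recursion; these marginals are exact and
#' serve as the reference against which the stochastic-mapping sampler is
#' validated.
#'
#' @param tree A rooted `phylo` object.
#' @param tip_states Named integer vector (`0..k-1`, `NA` = unknown; unknown
#'   tips are pruned first).
#' @param Q k x k rate matrix.
#' @param root_prior `"conditional-scaled"` (default) draws the root from the
#'   scaled conditional likelihoods — the stochastic-mapping convention, whose
#'   node marginals coincide with a flat root prior; `"uniform"` and
#'   `"stationary"` weight the root likelihoods by those priors.
#' @return Matrix (one row per internal node, in `ape` node order starting at
#'   `Ntip+1`) of posterior state probabilities; attribute `tree` holds the
#'   (possibly pruned) tree.
#' @export
ancestral_posterior <- function(tree, tip_states, Q,
                                root_prior = "conditional-scaled") {
  k <- nrow(Q)
  al <- align_states_q(tree, tip_states, k)
  tree <- al$tree
  x <- al$states
  pr <- prune_partials(tree, x, Q)
  ntip <- ape::Ntip(tree)
  n_tot <- ntip + tree$Nnode
  root <- ntip + 1L
  # sampling the scaled conditional likelihoods at the root is equivalent to
  # a flat prior over root states
  prior <- if (root_prior == "conditional-scaled") rep(1 / k, k)
           else root_prior_vec(root_prior, Q, pr$L[root, ])

  # child messages m_e = P_e %*% L_child for every edge, grouped by parent
  po <- pr$po
  msg <- vector("list", nrow(po$edge))
  for (e in seq_len(nrow(po$edge)))
    msg[[e]] <- as.vector(pr$Plist[[e]] %*% pr$L[po$edge[e, 2], ])
  kids <- split(seq_len(nrow(po$edge)), po$edge[, 1])

  up <- matrix(0, n_tot, k)
  up[root, ] <- prior
  marg <- matrix(0, n_tot, k)
  v <- up[root, ] * pr$L[root, ]
  marg[root, ] <- v / sum(v)
  # preorder: parents before children
  cl <- ape::reorder.phylo(tree, "cladewise")
  edge_key <- paste(po$edge[, 1], po$edge[, 2])
  for (i in seq_len(nrow(cl$edge))) {
    p <- cl$edge[i, 1]; ch <- cl$edge[i, 2]
    e <- match(paste(p, ch), edge_key)
    sibs <- setdiff(kids[[as.character(p)]], e)
    m <- up[p, ]
    for (s in sibs) m <- m * msg[[s]]
    u <- as.vector(t(pr$Plist[[e]]) %*% m)
    u <- u / max(u)
    up[ch, ] <- u
    v <- u * pr$L[ch, ]
    marg[ch, ] <- v / sum(v)
  }
  out <- marg[(ntip + 1L):n_tot, , drop = FALSE]
  rownames(out) <- as.character((ntip + 1L):n_tot)
  colnames(out) <- 0:(k - 1)
  attr(out, "tree") <- tree
  attr(out, "state_levels") <- 0:(k - 1)
  out
}

# Prune tips with unknown state and validate raw codes against 0..k-1
# (states index Q directly; unobserved states keep their rows).
align_states_q <- function(tree, tip_states, k) {
  if (is.null(names(tip_states))) stop("tip_states must be named by taxon")
  x <- tip_states[tree$tip.label]
  if (anyNA(x)) {
    keep <- tree$tip.label[!is.na(x)]
    if (length(keep) < 2) stop("fewer than two scored tips")
    tree <- prune_to_taxa(tree, keep)
    x <- tip_states[tree$tip.label]
  }
  if (any(x < 0 | x >= k)) stop("state index out of range for k = ", k)
  list(tree = tree, states = as.integer(x))
}

# Closure caching the uniformization machinery for one Q: dominating rate mu,
# jump matrix R = I + Q/mu, its powers, and P(t) per distinct t.
uniformization_sampler <- function(Q) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  R <- diag(k) + Q / max(mu, .Machine$double.eps)
  Rpow <- list(diag(k), R)  # R^0, R^1
  get_rpow <- function(n) {
    while (length(Rpow) < n + 1)
      Rpow[[length(Rpow) + 1]] <<- Rpow[[length(Rpow)]] %*% R
    Rpow[[n + 1]]
  }
  Pcache <- new.env(parent = emptyenv())
  get_p <- function(t) {
    key <- format(t, digits = 15)
    P <- get0(key, envir = Pcache)
    if (is.null(P)) {
      P <- transition_prob(Q, t)
      assign(key, P, envir = Pcache)
    }
    P
  }
  list(mu = mu, R = R, get_rpow = get_rpow, get_p = get_p, k = k)
}

# One endpoint-conditioned path; `us` is a uniformization_sampler(Q).
sample_branch_path <- function(a, b, t, us, max_jumps = 10000L) {
  mu <- us$mu
  if (mu * t < 1e-14) {
    if (a != b) stop("impossible endpoint pair: P(b | a, t) = 0")
    return(cbind(state = a, duration = t))
  }
  p_ab <- us$get_p(t)[a + 1L, b + 1L]
  if (p_ab <= 0) stop("impossible endpoint pair: P(b | a, t) = 0")
  u <- stats::runif(1) * p_ab
  n <- -1L; cum <- 0
  repeat {
    n <- n + 1L
    if (n > max_jumps) break
    cum <- cum + stats::dpois(n, mu * t) * us$get_rpow(n)[a + 1L, b + 1L]
    if (cum >= u) break
  }
  if (n == 0L) return(cbind(state = a, duration = t))
  # jump chain bridging a -> b in n steps
  s <- integer(n + 1L); s[1] <- a; s[n + 1L] <- b
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      w <- us$R[s[i] + 1L, ] * us$get_rpow(n - i)[, b + 1L]
      s[i + 1L] <- sample.int(us$k, 1, prob = w) - 1L
    }
  }
  times <- c(0, sort(stats::runif(n, 0, t)), t)
  # collapse virtual (self) jumps into segments
  keep <- c(TRUE, diff(s) != 0)
  st <- s[keep]
  bounds <- c(times[c(keep, FALSE)], t)
  cbind(state = st, duration = diff(bounds))
}

#' Sample one endpoint-conditioned branch history
#'
#' Piecewise-constant CTMC path starting in state `a` and ending in state `b`
#' after time `t`, sampled exactly by uniformization (Poisson mixture over
#' the number of jumps of the embedded chain, then a discrete bridge).
#'
#' @param a,b Integer endpoint states (`0..k-1`).
#' @param t Branch duration (> 0).
#' @param Q Rate matrix.
#' @param seed Optional integer seed.
#' @return Matrix with columns `state` and `duration`; durations sum to `t`
#'   and consecutive states differ.
#' @export
conditional_branch_history <- function(a, b, t, Q, seed = NULL) {
  validate_q(Q)
  us <- uniformization_sampler(Q)
  if (is.null(seed)) sample_branch_path(a, b, t, us)
  else with_seed(seed, sample_branch_path(a, b, t, us))
}

#' Sample stochastic character-mapping histories
#'
#' For each draw the root state is sampled from the scaled conditional
#' likelihoods, node states are sampled down the tree from their conditional
#' distributions, and each branch is filled with an endpoint-conditioned
#' substitution path (uniformization). `q_mode = "mcmc"` resamples the free
#' rates of `Q` between draws by Metropolis-Hastings (independent exponential
#' priors centred on the supplied ML rates) with the given burn-in and
#' sampling frequency, mirroring the empirical-Bayes vs full-Bayes options of
#' standard simmap implementations.
#'
#' @param tree A rooted `phylo` object.
#' @param tip_states Named integer vector (`0..k-1`, `NA` pruned).
#' @param Q Fitted rate matrix (ML estimate).
#' @param n_sim Number of histories (> 0).
#' @param burnin,sample_freq MCMC burn-in and thinning (used when
#'   `q_mode = "mcmc"`).
#' @param q_mode `"fixed-ML"` (empirical Bayes, default) or `"mcmc"`.
#' @param structure Rate-matrix structure (needed by the MCMC mode to know
#'   the free rates).
#' @param seed Integer RNG seed.
#' @return List of class `simmap_histories`; each element has `node_states`
#'   (full length `Ntip+Nnode` state vector), `counts` (k x k transition
#'   counts), `segments` (per-edge state/duration matrices). Attributes carry
#'   the tree, edge order, and state levels.
#' @export
sample_histories <- function(tree, tip_states, Q, n_sim = 100, burnin = 0,
                             sample_freq = 1, q_mode = c("fixed-ML", "mcmc"),
                             structure = "ER", seed = 1) {
  q_mode <- match.arg(q_mode)
  if (n_sim <= 0) stop("n_sim must be > 0")
  k <- nrow(Q)
  al <- align_states_q(tree, tip_states, k)
  tree <- al$tree
  x <- stats::setNames(al$states, tree$tip.label)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  cl <- ape::reorder.phylo(tree, "cladewise")

  with_seed(seed, {
    draw_one <- function(pr, us) {
      nstate <- integer(ntip + tree$Nnode)
      rootw <- pr$L[root, ]
      nstate[root] <- sample.int(k, 1, prob = rootw) - 1L
      counts <- matrix(0L, k, k)
      segs <- vector("list", nrow(cl$edge))
      edge_key <- paste(pr$po$edge[, 1], pr$po$edge[, 2])
      for (i in seq_len(nrow(cl$edge))) {
        p <- cl$edge[i, 1]; ch <- cl$edge[i, 2]
        e <- match(paste(p, ch), edge_key)
        w <- pr$Plist[[e]][nstate[p] + 1L, ] * pr$L[ch, ]
        nstate[ch] <- sample.int(k, 1, prob = w) - 1L
        path <- sample_branch_path(nstate[p], nstate[ch],
                                   cl$edge.length[i], us)
        segs[[i]] <- path
        if (nrow(path) > 1)
          for (j in seq_len(nrow(path) - 1))
            counts[path[j, 1] + 1L, path[j + 1, 1] + 1L] <-
              counts[path[j, 1] + 1L, path[j + 1, 1] + 1L] + 1L
      }
      list(node_states = nstate, counts = counts, segments = segs)
    }

    histories <- vector("list", n_sim)
    if (q_mode == "fixed-ML") {
      pr <- prune_partials(tree, x, Q)
      us <- uniformization_sampler(Q)
      for (d in seq_len(n_sim)) histories[[d]] <- draw_one(pr, us)
    } else {
      rates <- q_rates(Q, structure)
      prior_mean <- pmax(rates, 1e-10)
      cur <- rates
      cur_ll <- mk_loglik(tree, x, build_q(structure, k, cur))
      n_iter <- burnin + n_sim * sample_freq
      d <- 0L
      for (it in seq_len(n_iter)) {
        prop <- cur * exp(stats::rnorm(length(cur), 0, 0.2))
        prop_ll <- tryCatch(
          mk_loglik(tree, x, build_q(structure, k, prop)),
          error = function(e) -Inf)
        log_acc <- (prop_ll - cur_ll) +
          sum(stats::dexp(prop, 1 / prior_mean, log = TRUE)) -
          sum(stats::dexp(cur, 1 / prior_mean, log = TRUE)) +
          sum(log(prop)) - sum(log(cur))  # log-scale proposal Jacobian
        if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
          cur <- prop; cur_ll <- prop_ll
        }
        if (it > burnin && (it - burnin) %% sample_freq == 0) {
          d <- d + 1L
          Qd <- build_q(structure, k, cur)
          histories[[d]] <- draw_one(prune_partials(tree, x, Qd),
                                     uniformization_sampler(Qd))
        }
      }
    }
    structure(histories, class = "simmap_histories", tree = tree,
              edge = cl$edge, edge_length = cl$edge.length,
              state_levels = 0:(k - 1), k = k)
  })
}

#' Summarize stochastic-mapping histories
#'
#' @param histories A `simmap_histories` object.
#' @param clades Optional named list of tip-label vectors; for each clade the
#'   proportion of total branch time spent in each state (averaged over
#'   histories) is reported.
#' @return List of class `mapping_summary`: `node_posterior` (internal nodes
#'   x states, empirical frequencies), `mean_counts` (k x k), `n_histories`,
#'   optionally `clade_proportions`.
#' @export
summarize_histories <- function(histories, clades = NULL) {
  stopifnot(inherits(histories, "simmap_histories"))
  if (length(histories) == 0) stop("no histories")
  tree <- attr(histories, "tree")
  k <- attr(histories, "k")
  ntip <- ape::Ntip(tree)
  n_tot <- ntip + tree$Nnode
  edge <- attr(histories, "edge")

  post <- matrix(0, n_tot, k)
  counts <- matrix(0, k, k)
  for (h in histories) {
    post[cbind(seq_len(n_tot), h$node_states + 1L)] <-
      post[cbind(seq_len(n_tot), h$node_states + 1L)] + 1
    counts <- counts + h$counts
  }
  post <- post / length(histories)
  node_post <- post[(ntip + 1L):n_tot, , drop = FALSE]
  rownames(node_post) <- as.character((ntip + 1L):n_tot)
  colnames(node_post) <- attr(histories, "state_levels")
  out <- list(node_posterior = node_post,
              mean_counts = counts / length(histories),
              n_histories = length(histories))

  if (!is.null(clades)) {
    cp <- lapply(clades, function(tips) {
      tips <- intersect(tips, tree$tip.label)
      if (length(tips) < 2) return(rep(NA_real_, k))
      mrca <- ape::getMRCA(tree, tips)
      in_clade <- clade_edges(tree, edge, mrca)
      tot <- numeric(k)
      for (h in histories) {
        for (e in which(in_clade)) {
          seg <- h$segments[[e]]
          for (j in seq_len(nrow(seg)))
            tot[seg[j, 1] + 1L] <- tot[seg[j, 1] + 1L] + seg[j, 2]
        }
      }
      tot / sum(tot)
    })
    names(cp) <- names(clades)
    out$clade_proportions <- cp
  }
  class(out) <- "mapping_summary"
  out
}

# Logical vector over edge rows: is the edge inside the clade rooted at node?
clade_edges <- function(tree, edge, mrca) {
  n_tot <- ape::Ntip(tree) + tree$Nnode
  below <- rep(FALSE, n_tot)
  below[mrca] <- TRUE
  # edges in `edge` are cladewise (parents first)
  inside <- rep(FALSE, nrow(edge))
  for (i in seq_len(nrow(edge))) {
    if (below[edge[i, 1]]) {
      below[edge[i, 2]] <- TRUE
      inside[i] <- TRUE
    }
  }
  inside
}

#' @export
print.mapping_summary <- function(x, ...) {
  cat(sprintf("Stochastic mapping summary over %d histories\n", x$n_histories))
  cat("Mean transition counts:\n")
  print(round(x$mean_counts, 3))
  invisible(x)
}
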