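test_that("exact ancestral posteriors respect symmetry and enumeration", {
  two <- ape::read.tree(text = "(A:1,B:1):0;")
  Q <- build_q("ER", 2, 0.4)
  ap <- ancestral_posterior(two, c(A = 0L, B = 0L), Q)
  expect_gt(ap[1, "0"], 0.5)

  # mirrored data on a symmetric tree: root posterior exactly (1/2, 1/2)
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
  ap4 <- ancestral_posterior(t4, c(A = 0L, B = 1L, C = 1L, D = 0L), Q)
  expect_equal(unname(ap4["5", ]), c(0.5, 0.5), tolerance = 1e-9)

  # brute-force Bayes oracle on a 5-tip tree
  t5 <- ape::read.tree(
    text = "(((A:0.4,B:0.7):0.3,C:0.9):0.5,(D:0.6,E:0.2):0.8):0;")
  set.seed(5)
  Q5 <- random_q(2, "ARD")
  x5 <- c(A = 0L, B = 1L, C = 0L, D = 1L, E = 1L)
  ap5 <- ancestral_posterior(t5, x5, Q5, root_prior = "uniform")
  # enumerate joint internal assignments, marginalize each node
  k <- 2; n_int <- t5$Nnode; ntip <- 5
  Ps <- lapply(t5$edge.length, function(t) series_expm(Q5, t))
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), n_int)))
  joint <- apply(grid, 1, function(g) {
    st <- c(x5[t5$tip.label], g)
    pr <- 1 / k
    for (e in seq_len(nrow(t5$edge)))
      pr <- pr * Ps[[e]][st[t5$edge[e, 1]] + 1, st[t5$edge[e, 2]] + 1]
    pr
  })
  for (node in seq_len(n_int)) {
    marg <- vapply(0:1, function(s) sum(joint[grid[, node] == s]), 0)
    marg <- marg / sum(marg)
    expect_equal(unname(ap5[as.character(ntip + node), ]), marg,
                 tolerance = 1e-9)
  }
})

test_that("conditional branch paths honour endpoints and durations", {
  Q <- build_q("ER", 2, 0.6)
  # a = b over a tiny branch: overwhelmingly the zero-change path
  n_single <- sum(vapply(1:300, function(s)
    nrow(conditional_branch_history(0, 0, 1e-4, Q, seed = s)) == 1, TRUE))
  expect_gte(n_single, 299)

  # a != b: at least one change, correct endpoints, durations sum to t
  for (s in 1:50) {
    p <- conditional_branch_history(0L, 1L, 0.9, Q, seed = s)
    expect_gte(nrow(p), 2)
    expect_equal(unname(p[1, "state"]), 0)
    expect_equal(unname(p[nrow(p), "state"]), 1)
    expect_equal(sum(p[, "duration"]), 0.9, tolerance = 1e-9)
    expect_true(all(diff(p[, "state"]) != 0))
  }

  # impossible endpoint pair: absorbing state
  Qabs <- matrix(c(0, 1, 0, -1), 2, 2)
  expect_error(conditional_branch_history(0, 1, 1, Qabs), "impossible")
})

test_that("change counts match the analytic uniformization distribution", {
  # 2-state ER with rate r: mu = r and the jump chain flips deterministically,
  # so the change count equals the jump count: a parity-truncated Poisson
  r <- 0.7; t_br <- 1.6
  Q <- build_q("ER", 2, r)
  counts <- vapply(1:10000, function(s)
    nrow(conditional_branch_history(0L, 1L, t_br, Q, seed = s)) - 1L, 0L)
  ns <- 0:30
  w <- stats::dpois(ns, r * t_br)
  w[ns %% 2 == 0] <- 0  # odd change counts only for a != b
  probs <- w / sum(w)
  obs <- tabulate(counts + 1L, nbins = length(ns))
  keep <- probs > 5e-4
  chi <- suppressWarnings(
    stats::chisq.test(obs[keep], p = probs[keep] / sum(probs[keep])))
  expect_gt(chi$p.value, 0.01)

  # conditional mean changes for a = b against the same analytic mixture
  counts0 <- vapply(1:10000, function(s)
    nrow(conditional_branch_history(0L, 0L, t_br, Q, seed = 20000 + s)) - 1L,
    0L)
  w0 <- stats::dpois(ns, r * t_br); w0[ns %% 2 == 1] <- 0
  m_true <- sum(ns * w0 / sum(w0))
  sd_true <- sqrt(sum(ns^2 * w0 / sum(w0)) - m_true^2)
  expect_lt(abs(mean(counts0) - m_true), 3 * sd_true / sqrt(length(counts0)))
})

test_that("sampled histories are consistent with data, tree and posteriors", {
  tr <- generate_tree(20, 1, 0, seed = 30)
  Q <- build_q("ER", 2, 0.3)
  sim <- simulate_character(tr, Q, seed = 31)
  x <- sim$tip_states
  h <- sample_histories(tr, x, Q, n_sim = 1500, seed = 32)

  ntip <- ape::Ntip(tr)
  el <- attr(h, "edge_length")
  for (d in c(1, 700, 1500)) {
    # restriction to tips equals the observed states
    expect_identical(h[[d]]$node_states[seq_len(ntip)],
                     unname(x[attr(h, "tree")$tip.label]))
    # branch segment durations sum to branch lengths
    sums <- vapply(h[[d]]$segments, function(s) sum(s[, "duration"]), 0)
    expect_equal(sums, el, tolerance = 1e-9)
  }

  # near-zero rates with constant data: no transitions at all
  xc <- stats::setNames(rep(0L, ntip), tr$tip.label)
  Qtiny <- build_q("ER", 2, 1e-12)
  h0 <- sample_histories(tr, xc, Qtiny, n_sim = 20, seed = 33)
  expect_true(all(vapply(h0, function(d) sum(d$counts), 0) == 0))

  # empirical root frequencies track the exact root marginal
  ap <- ancestral_posterior(tr, x, Q)
  root_freq <- mean(vapply(h, function(d) d$node_states[ntip + 1L], 0L) == 0)
  p <- ap[1, "0"]
  expect_lt(abs(root_freq - p), 3 * sqrt(p * (1 - p) / length(h)) + 1e-12)
})

test_that("history summaries aggregate posteriors, counts and clade time", {
  tr <- generate_tree(15, 1, 0, seed = 40)
  Q <- build_q("ER", 2, 0.4)
  sim <- simulate_character(tr, Q, seed = 41)
  h <- sample_histories(tr, sim$tip_states, Q, n_sim = 50, seed = 42)

  one <- h[1]
  attributes(one) <- attributes(h)
  s1 <- summarize_histories(one)
  expect_true(all(s1$node_posterior %in% c(0, 1)))
  expect_equal(unname(rowSums(s1$node_posterior)),
               rep(1, nrow(s1$node_posterior)))

  # two histories differing only at the root give a (0.5, 0.5) root posterior
  two <- h[1:2]
  two[[2]] <- two[[1]]
  two[[2]]$node_states[ape::Ntip(tr) + 1L] <-
    1L - two[[1]]$node_states[ape::Ntip(tr) + 1L]
  attributes(two) <- attributes(h)
  s2 <- summarize_histories(two)
  expect_equal(unname(s2$node_posterior[1, ]), c(0.5, 0.5))

  sm <- summarize_histories(h, clades = list(half = tr$tip.label[1:7]))
  expect_equal(sum(sm$clade_proportions$half), 1, tolerance = 1e-9)
  expect_equal(dim(sm$mean_counts), c(2, 2))
  expect_error(sample_histories(tr, sim$tip_states, Q, n_sim = 0), "n_sim")
})

test_that("rate-MCMC mode mixes and still reproduces tip data", {
  tr <- generate_tree(15, 1, 0, seed = 50)
  Q <- build_q("ER", 2, 0.4)
  sim <- simulate_character(tr, Q, seed = 51)
  f <- fit_mk(tr, sim$tip_states, "ER", n_starts = 2)
  h <- sample_histories(tr, sim$tip_states, f$Q, n_sim = 40, burnin = 50,
                        sample_freq = 5, q_mode = "mcmc", structure = "ER",
                        seed = 52)
  expect_length(h, 40)
  ntip <- ape::Ntip(tr)
  expect_identical(h[[40]]$node_states[seq_len(ntip)],
                   unname(sim$tip_states[attr(h, "tree")$tip.label]))
})

test_that("mean transition counts are stable across sampler seeds", {
  tr <- generate_tree(20, 1, 0, seed = 60)
  Q <- build_q("ER", 2, 1.2 / tree_height(tr))
  sim <- simulate_character(tr, Q, seed = 61)
  m1 <- summarize_histories(
    sample_histories(tr, sim$tip_states, Q, n_sim = 3000, seed = 62))$mean_counts
  m2 <- summarize_histories(
    sample_histories(tr, sim$tip_states, Q, n_sim = 3000, seed = 63))$mean_counts
  expect_lt(abs(sum(m1) - sum(m2)) / sum(m1), 0.05)
})
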