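# Shared fixtures built in code: small trees, synthetic contour objects, and
# an independent brute-force Mk likelihood oracle.

star_tree <- function(n, len = 1) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, n)
  tr
}

balanced_tree <- function(n, height = 1) {
  tr <- ape::stree(n, "balanced")
  tr <- ape::compute.brlen(tr, 1)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * height / depth
  tr
}

# Minimal hand-made contour object for decision-tree tests.
make_contour <- function(A, S, R, orientation = 0, label = "unclassified",
                         pieces = NULL, id = 1L) {
  list(id = id, boundary = cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
       n_pixels = round(A * 1e4), A = A, S = S, R = R,
       orientation = orientation, label = label, pieces = pieces,
       hu = hu_moments(c(0, 1, 1, 0), c(0, 0, 1, 1)))
}

make_piece <- function(orientation) {
  list(S = 1, R = 10, orientation = orientation,
       polygon = cbind(x = c(0, 10, 10, 0), y = c(0, 0, 1, 1)))
}

# Independent matrix exponential: truncated Taylor series (40 terms).
series_expm <- function(Q, t, terms = 40) {
  k <- nrow(Q)
  P <- diag(k); term <- diag(k)
  for (n in seq_len(terms)) {
    term <- term %*% (Q * t) / n
    P <- P + term
  }
  P
}

# Independent Mk likelihood: exhaustive enumeration over all internal-node
# state assignments, transition probabilities from the series expansion.
enum_loglik <- function(tree, x01, Q, root_prior = rep(1 / nrow(Q), nrow(Q))) {
  k <- nrow(Q)
  ntip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  Ps <- lapply(tree$edge.length, function(t) series_expm(Q, t))
  root <- ntip + 1L
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), n_int)))
  for (g in seq_len(nrow(grid))) {
    st <- c(x01, grid[g, ])
    pr <- root_prior[st[root] + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      a <- st[tree$edge[e, 1]]; b <- st[tree$edge[e, 2]]
      pr <- pr * Ps[[e]][a + 1L, b + 1L]
    }
    total <- total + pr
  }
  log(total)
}

# Random rate matrix of a given structure.
random_q <- function(k, structure = "ER") {
  nr <- switch(structure, ER = 1, SYM = k * (k - 1) / 2, ARD = k * (k - 1))
  build_q(structure, k, stats::runif(nr, 0.2, 1.5))
}
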