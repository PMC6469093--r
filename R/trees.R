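#' Read a rooted Newick tree
#'
#' Thin wrapper around [ape::read.tree()] that validates the result: the tree
#' must be rooted, have branch lengths, and have unique tip labels.
#'
#' @param path Path to a Newick file.
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("Newick parse error in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in '", path, "'")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths: ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Prune a tree to a set of taxa
#'
#' Keeps the induced subtree on `keep`: unbranched internal nodes are
#' suppressed with their branch lengths summed, so root-to-tip depths of the
#' kept taxa are unchanged.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to keep.
#' @return The pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0)
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(keep) < 2) stop("need at least two taxa to keep")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Resolve polytomies with near-zero branches
#'
#' Multifurcations are resolved into bifurcations (children taken left to
#' right after sorting by label, so the resolution is deterministic); every
#' newly created internal branch gets length `eps_fraction` times the total
#' tree height.
#'
#' @param tree A rooted `phylo` object.
#' @param eps_fraction New-branch length as a fraction of tree height
#'   (default `1e-6`, following common practice for comparative analyses that
#'   require strictly dichotomous trees).
#' @return A fully bifurcating `phylo` object.
#' @export
resolve_polytomies <- function(tree, eps_fraction = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.binary(tree)) return(tree)
  # deterministic child order: rotate children of every node alphabetically
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  h <- tree_height(tree)
  res <- ape::multi2di(tree, random = FALSE)
  res$edge.length[res$edge.length == 0] <- eps_fraction * h
  res
}

#' Total height of a rooted tree
#'
#' Maximum root-to-tip path length.
#'
#' @param tree A `phylo` object.
#' @return Numeric scalar (same units as the branch lengths).
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

# Root-to-node path lengths for all nodes (tips first, then internals).
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Pagel's lambda tree transformation
#'
#' Internal branch lengths are multiplied by `lam`. By default pendant
#' branches are then extended so that every tip keeps its original
#' root-to-tip depth, which makes the transformed tree's Brownian covariance
#' equal to the classic lambda-scaled covariance (off-diagonals times
#' `lam`) on ultrametric trees. `pendant = "strict"` leaves pendant branches
#' untouched (pure internal compression).
#'
#' @param tree A rooted `phylo` object.
#' @param lam Lambda in `[0, 1]`.
#' @param pendant `"extend"` (default, covariance-faithful) or `"strict"`.
#' @return Transformed `phylo` object.
#' @export
transform_lambda <- function(tree, lam, pendant = c("extend", "strict")) {
  stopifnot(inherits(tree, "phylo"))
  pendant <- match.arg(pendant)
  if (!is.finite(lam) || lam < 0 || lam > 1)
    stop("lambda must be in [0, 1], got ", lam)
  ntip <- ape::Ntip(tree)
  is_pendant <- tree$edge[, 2] <= ntip
  out <- tree
  out$edge.length[!is_pendant] <- out$edge.length[!is_pendant] * lam
  if (pendant == "extend") {
    # a pendant edge keeps its tip's depth: the compression removed
    # (1 - lam) * depth(parent) above it, so add that back
    depth0 <- node_depths(tree)
    parent_depth <- depth0[tree$edge[is_pendant, 1]]
    out$edge.length[is_pendant] <-
      out$edge.length[is_pendant] + (1 - lam) * parent_depth
  }
  out
}

#' Pagel's delta tree transformation
#'
#' Node heights (root-to-node path lengths) are raised to the power `delta`
#' after normalizing total tree height to one, then rescaled back to the
#' original height. `delta < 1` concentrates change early (near the root),
#' `delta > 1` late.
#'
#' @param tree A rooted `phylo` object.
#' @param delta Positive exponent.
#' @return Transformed `phylo` object.
#' @export
transform_delta <- function(tree, delta) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0, got ", delta)
  h <- tree_height(tree)
  d <- node_depths(tree) / h
  out <- tree
  out$edge.length <- (d[tree$edge[, 2]]^delta - d[tree$edge[, 1]]^delta) * h
  out
}

#' Pagel's kappa tree transformation
#'
#' Every branch length is raised to the power `kappa`; `kappa = 0` sets all
#' branch lengths to one (pure punctuated change at nodes).
#'
#' @param tree A `phylo` object.
#' @param kappa Non-negative exponent.
#' @return Transformed `phylo` object.
#' @export
transform_kappa <- function(tree, kappa) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.finite(kappa) || kappa < 0) stop("kappa must be >= 0, got ", kappa)
  out <- tree
  out$edge.length <- tree$edge.length^kappa
  out
}

#' Apply a named Pagel transformation
#'
#' @param tree A `phylo` object.
#' @param kind One of `"none"`, `"lambda"`, `"delta"`, `"kappa"`.
#' @param coefficient Transformation coefficient (ignored for `"none"`).
#' @return Transformed `phylo` object.
#' @export
transform_tree <- function(tree, kind = c("none", "lambda", "delta", "kappa"),
                           coefficient = 1) {
  kind <- match.arg(kind)
  switch(kind,
         none = tree,
         lambda = transform_lambda(tree, coefficient),
         delta = transform_delta(tree, coefficient),
         kappa = transform_kappa(tree, coefficient))
}

#' Brownian-motion covariance matrix of a tree
#'
#' `V[i, j]` is the root-to-MRCA distance of tips i and j (shared path
#' length); `V[i, i]` is the tip depth. This is the phylogenetic
#' variance-covariance used by PGLS and the phylogenetic mixed model (up to
#' the evolutionary-rate scalar).
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Symmetric matrix with tip labels as dimnames.
#' @export
bm_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::vcv.phylo(tree)
}

# -- subspecies handling ------------------------------------------------------

# First two name tokens (split on space or underscore) = the species binomial.
species_binomial <- function(labels) {
  vapply(strsplit(labels, "[ _]+"), function(tok)
    paste(tok[seq_len(min(2L, length(tok)))], collapse = "_"), character(1))
}

#' Collapse subspecies rows of a character matrix to one row per species
#'
#' Subspecies are recognized by a shared binomial prefix of the `species`
#' label (first two tokens, split on space or underscore). For each species
#' with several rows the rules are applied in order: (1) drop subspecies that
#' have an unknown state when at least one subspecies is fully scored;
#' (2) when the remaining subspecies disagree in some character, keep the one
#' whose states best match the most closely related other species on the
#' tree; (3) if several remain, keep the alphabetically first.
#'
#' @param matrix A data frame whose first column is `species` and remaining
#'   columns are integer character codes (`NA` = unknown).
#' @param tree Optional `phylo` used by rule 2 (tips matched by binomial).
#'   Without a tree rule 2 falls back to the alphabetical tie-break.
#' @return A list with `matrix` (deduplicated, one row per species, labels
#'   replaced by the binomial) and `log` (data frame: label, rule fired).
#' @export
dedup_subspecies <- function(matrix, tree = NULL) {
  stopifnot(is.data.frame(matrix), names(matrix)[1] == "species")
  binom <- species_binomial(matrix$species)
  keep <- rep(TRUE, nrow(matrix))
  log_lab <- character(0); log_rule <- character(0)
  states <- as.matrix(matrix[, -1, drop = FALSE])

  coph <- NULL
  tip_binom <- NULL
  if (!is.null(tree)) {
    coph <- ape::cophenetic.phylo(tree)
    tip_binom <- species_binomial(tree$tip.label)
  }

  for (sp in unique(binom[duplicated(binom)])) {
    idx <- which(binom == sp)
    cand <- idx
    # rule 1: drop partially-scored subspecies if a fully-scored one exists
    n_na <- rowSums(is.na(states[cand, , drop = FALSE]))
    if (any(n_na == 0) && any(n_na > 0)) {
      drop1 <- cand[n_na > 0]
      log_lab <- c(log_lab, matrix$species[drop1])
      log_rule <- c(log_rule, rep("1", length(drop1)))
      keep[drop1] <- FALSE
      cand <- cand[n_na == 0]
    }
    if (length(cand) > 1) {
      disagree <- apply(states[cand, , drop = FALSE], 2,
                        function(col) length(unique(col[!is.na(col)])) > 1)
      if (any(disagree) && !is.null(coph) && sp %in% tip_binom) {
        # rule 2: match against states of the closest other species
        ref <- neighbour_states(sp, tree, coph, tip_binom, matrix, binom)
        if (!is.null(ref)) {
          score <- apply(states[cand, , drop = FALSE], 1, function(row)
            sum(row == ref, na.rm = TRUE))
          best <- cand[score == max(score)]
          drop2 <- setdiff(cand, best)
          if (length(drop2) > 0) {
            log_lab <- c(log_lab, matrix$species[drop2])
            log_rule <- c(log_rule, rep("2", length(drop2)))
            keep[drop2] <- FALSE
            cand <- best
          }
        }
      }
      if (length(cand) > 1) {
        ord <- order(matrix$species[cand])
        drop3 <- cand[ord[-1]]
        log_lab <- c(log_lab, matrix$species[drop3])
        log_rule <- c(log_rule, rep("arbitrary", length(drop3)))
        keep[drop3] <- FALSE
      }
    }
  }
  out <- matrix[keep, , drop = FALSE]
  out$species <- species_binomial(out$species)
  rownames(out) <- NULL
  list(matrix = out,
       log = data.frame(label = log_lab, rule = log_rule,
                        stringsAsFactors = FALSE))
}

# Modal state vector of the species closest (cophenetic) to `sp` on the tree.
neighbour_states <- function(sp, tree, coph, tip_binom, matrix, binom) {
  self_tips <- tree$tip.label[tip_binom == sp]
  other_tips <- tree$tip.label[tip_binom != sp]
  other_tips <- other_tips[tip_binom[match(other_tips, tree$tip.label)] %in% binom]
  if (length(self_tips) == 0 || length(other_tips) == 0) return(NULL)
  d <- coph[self_tips, other_tips, drop = FALSE]
  nearest <- other_tips[which.min(apply(d, 2, min))]
  nb <- species_binomial(nearest)
  rows <- which(binom == nb)
  if (length(rows) == 0) return(NULL)
  st <- as.matrix(matrix[rows, -1, drop = FALSE])
  apply(st, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(NA_integer_)
    as.integer(names(sort(table(col), decreasing = TRUE))[1])
  })
}
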