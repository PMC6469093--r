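# Synthetic inputs: birth-death trees, Mk-simulated characters, and SEM-like
# ground-truth images, so every downstream stage is testable offline.

# Run `expr` under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a time-calibrated birth-death tree
#'
#' Constant-rate birth-death process conditioned on the number of extant
#' tips (via [ape::rphylo()]); the result is rooted, ultrametric and fully
#' bifurcating, with branch lengths in the same time units as the rates.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth_rate Speciation rate per lineage per unit time (> 0).
#' @param death_rate Extinction rate (>= 0, < `birth_rate`).
#' @param seed Integer RNG seed.
#' @return A `phylo` object with tips labelled `t1..tn`.
#' @export
generate_tree <- function(n_tips, birth_rate = 1, death_rate = 0, seed = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!is.finite(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be > 0")
  if (!is.finite(death_rate) || death_rate < 0 || death_rate >= birth_rate)
    stop("death_rate must satisfy 0 <= death_rate < birth_rate")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = birth_rate,
                                      death = death_rate, fossils = FALSE))
  tree
}

validate_q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("Q must be a square matrix")
  off <- Q; diag(off) <- 0
  if (any(off < -1e-12)) stop("Q off-diagonal entries must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("Q rows must sum to zero")
  invisible(Q)
}

# Stationary distribution of a rate matrix (left null vector, normalized).
stationary_dist <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Simulate a discrete character along a tree under an Mk process
#'
#' States (coded `0..k-1`) are sampled root-to-tip on the (optionally
#' lambda-transformed) tree using transition probabilities `expm(Q t)` per
#' branch.
#'
#' @param tree A rooted `phylo` object.
#' @param Q k x k rate matrix (rows sum to zero, off-diagonals >= 0).
#' @param lam Pagel's lambda applied to the tree before simulation (1 = none).
#' @param root_state Integer state in `0..k-1`, or `"stationary"` to draw the
#'   root from the stationary distribution of `Q`.
#' @param seed Integer RNG seed.
#' @return A list of class `simulated_character` with `tip_states` (named
#'   integer vector), `node_states`, `true_Q`, `true_lambda`, `rng_seed`.
#' @export
simulate_character <- function(tree, Q, lam = 1, root_state = "stationary",
                               seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  validate_q(Q)
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  k <- nrow(Q)
  tr <- if (lam == 1) tree else transform_lambda(tree, lam)
  with_seed(seed, {
    ntip <- ape::Ntip(tr)
    n_tot <- ntip + tr$Nnode
    state <- integer(n_tot)
    root <- ntip + 1L
    if (identical(root_state, "stationary")) {
      pi0 <- stationary_dist(Q)
      state[root] <- sample.int(k, 1, prob = pi0) - 1L
    } else {
      if (root_state < 0 || root_state >= k) stop("root_state out of range")
      state[root] <- as.integer(root_state)
    }
    ord <- ape::reorder.phylo(tr, "cladewise")
    # cache transition matrices by branch length
    P_cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(ord$edge))) {
      t_i <- ord$edge.length[i]
      key <- format(t_i, digits = 15)
      P <- get0(key, envir = P_cache)
      if (is.null(P)) {
        P <- transition_prob(Q, t_i)
        assign(key, P, envir = P_cache)
      }
      a <- state[ord$edge[i, 1]]
      state[ord$edge[i, 2]] <- sample.int(k, 1, prob = P[a + 1L, ]) - 1L
    }
    tips <- state[seq_len(ntip)]
    names(tips) <- tr$tip.label
    structure(list(tip_states = tips,
                   node_states = state[(ntip + 1L):n_tot],
                   true_Q = Q, true_lambda = lam, rng_seed = seed),
              class = "simulated_character")
  })
}

# -- ground-truth images ------------------------------------------------------

surface_state_names <- c("smooth", "holes", "straight_channels",
                         "labyrinthine_channels")

# Corner polygon of a rectangle of given centre, length, width, angle (deg).
rect_polygon <- function(cx, cy, len, wid, angle) {
  a <- angle * pi / 180
  ux <- cos(a); uy <- sin(a)        # long axis
  vx <- -sin(a); vy <- cos(a)       # short axis
  hx <- len / 2; hy <- wid / 2
  cbind(x = cx + c(-hx * ux - hy * vx, hx * ux - hy * vx,
                   hx * ux + hy * vx, -hx * ux + hy * vx),
        y = cy + c(-hx * uy - hy * vy, hx * uy - hy * vy,
                   hx * uy + hy * vy, -hx * uy + hy * vy))
}

ellipse_polygon <- function(cx, cy, r1, r2, angle, n = 24) {
  a <- angle * pi / 180
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ex <- r1 * cos(t); ey <- r2 * sin(t)
  cbind(x = cx + ex * cos(a) - ey * sin(a),
        y = cy + ex * sin(a) + ey * cos(a))
}

# Fill a convex polygon into a logical size x size mask (0-based coords,
# x right / y down); returns linear pixel indices.
polygon_pixels <- function(poly, size) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- max(0, floor(xr[1])):min(size - 1, ceiling(xr[2]))
  ys <- max(0, floor(yr[1])):min(size - 1, ceiling(yr[2]))
  if (length(xs) == 0 || length(ys) == 0) return(integer(0))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- point_in_polygon(gx, gy, poly)
  # matrix stored [row = y + 1, col = x + 1]
  (gx[inside]) * size + gy[inside] + 1L
}

# Vectorized even-odd point-in-polygon test.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Generate an SEM-like ground-truth surface image
#'
#' Dark structures (elliptical holes, elongated rectangles for straight
#' channels, chains of rectangles for labyrinthine channels) are drawn on a
#' brighter background, then a linear illumination gradient and Gaussian
#' pixel noise are added. All truth polygons (pixel coordinates, x right /
#' y down, 0-based) are recorded; labyrinthine chains contribute one polygon
#' per segment, each carrying the chain id.
#'
#' @param state One of `"smooth"`, `"holes"`, `"straight_channels"`,
#'   `"labyrinthine_channels"`.
#' @param density Structures per 100x100 px block (0 for smooth). The
#'   default (`NULL`) picks a per-state density giving roughly 8-12% surface
#'   coverage, the regime of typical structured SEM images: 8 holes, 3
#'   straight channels or 2.2 labyrinthine chains per block.
#' @param angle_sd SD (degrees) of channel orientations around the image's
#'   base orientation; ignored for holes/smooth.
#' @param noise_sd Gaussian pixel-noise SD in 8-bit intensity units.
#' @param seed Integer RNG seed (bit-identical pixels for identical seeds).
#' @param size Image side in pixels.
#' @param gradient_amp Peak-to-centre amplitude of the linear illumination
#'   gradient (intensity units).
#' @return A list of class `ground_truth_image`: `pixels` (size x size matrix
#'   of 8-bit intensities, rows = y), `truth_state`, `truth_contours` (list of
#'   `list(polygon, label, orientation, chain)`), `rng_seed`.
#' @export
generate_surface_image <- function(state, density = NULL, angle_sd = 5,
                                   noise_sd = 5, seed = 1, size = 256,
                                   gradient_amp = 25) {
  state <- match.arg(state, surface_state_names)
  if (is.null(density))
    density <- c(smooth = 0, holes = 8, straight_channels = 3,
                 labyrinthine_channels = 2.2)[[state]]
  if (density < 0) stop("density must be >= 0")
  if (angle_sd < 0) stop("angle_sd must be >= 0")
  if (state == "smooth" && density > 0)
    stop("state 'smooth' requires density = 0")
  with_seed(seed, {
    bg <- 175; fg <- 60
    img <- matrix(bg, nrow = size, ncol = size)
    occupied <- matrix(FALSE, nrow = size, ncol = size)
    truth <- list()
    n_struct <- if (state == "smooth") 0L else
      max(1L, round(density * (size / 100)^2))
    base_angle <- stats::runif(1, 0, 180)
    margin <- 6

    add_piece <- function(poly) {
      pix <- polygon_pixels(poly, size)
      if (length(pix) == 0) return(FALSE)
      # rejection against overlap (with a small dilated margin via polygon pad)
      if (any(occupied[pix])) return(FALSE)
      img[pix] <<- fg
      occupied[pix] <<- TRUE
      TRUE
    }

    chain_id <- 0L
    for (s in seq_len(n_struct)) {
      placed <- FALSE
      for (attempt in seq_len(40)) {
        if (state == "holes") {
          r1 <- stats::runif(1, 5, 9)
          r2 <- r1 / stats::runif(1, 1, 2)
          ang <- stats::runif(1, 0, 180)
          cx <- stats::runif(1, r1 + margin, size - r1 - margin)
          cy <- stats::runif(1, r1 + margin, size - r1 - margin)
          poly <- ellipse_polygon(cx, cy, r1, r2, ang)
          big <- ellipse_polygon(cx, cy, r1 + 3, r2 + 3, ang)
          if (any(occupied[polygon_pixels(big, size)])) next
          if (add_piece(poly)) {
            truth[[length(truth) + 1]] <-
              list(polygon = poly, label = "hole", orientation = ang %% 180,
                   chain = NA_integer_)
            placed <- TRUE
          }
        } else if (state == "straight_channels") {
          len <- stats::runif(1, 50, 80)
          wid <- stats::runif(1, 4, 5)
          ang <- (base_angle + stats::rnorm(1, 0, angle_sd)) %% 180
          cx <- stats::runif(1, len / 2 + margin, size - len / 2 - margin)
          cy <- stats::runif(1, len / 2 + margin, size - len / 2 - margin)
          poly <- rect_polygon(cx, cy, len, wid, ang)
          big <- rect_polygon(cx, cy, len + 6, wid + 6, ang)
          if (any(occupied[polygon_pixels(big, size)])) next
          if (add_piece(poly)) {
            truth[[length(truth) + 1]] <-
              list(polygon = poly, label = "straight_channel",
                   orientation = ang, chain = NA_integer_)
            placed <- TRUE
          }
        } else { # labyrinthine chain of rectangles joined at >= 30 deg turns
          m <- sample(2:3, 1)
          lens <- stats::runif(m, 32, 42)
          wid <- 3.5
          ang0 <- (base_angle + stats::rnorm(1, 0, angle_sd)) %% 180
          angs <- numeric(m); angs[1] <- ang0
          for (j in seq_len(m - 1))
            angs[j + 1] <- angs[j] + sample(c(-1, 1), 1) * stats::runif(1, 35, 70)
          # walk segment centres
          span <- sum(lens)
          x0 <- stats::runif(1, span / 2 + margin, size - span / 2 - margin)
          y0 <- stats::runif(1, span / 2 + margin, size - span / 2 - margin)
          polys <- vector("list", m)
          bigs <- vector("list", m)
          px <- x0; py <- y0; ok <- TRUE
          for (j in seq_len(m)) {
            a <- angs[j] * pi / 180
            cxj <- px + cos(a) * lens[j] / 2
            cyj <- py + sin(a) * lens[j] / 2
            polys[[j]] <- rect_polygon(cxj, cyj, lens[j], wid, angs[j])
            bigs[[j]] <- rect_polygon(cxj, cyj, lens[j] + 6, wid + 6, angs[j])
            px <- px + cos(a) * lens[j]
            py <- py + sin(a) * lens[j]
            if (px < margin || px > size - margin ||
                py < margin || py > size - margin) { ok <- FALSE; break }
          }
          if (!ok) next
          all_big <- unlist(lapply(bigs, polygon_pixels, size = size))
          if (any(occupied[all_big])) next
          chain_id <- chain_id + 1L
          for (j in seq_len(m)) {
            pix <- polygon_pixels(polys[[j]], size)
            img[pix] <- fg
            truth[[length(truth) + 1]] <-
              list(polygon = polys[[j]], label = "labyrinthine_channel",
                   orientation = angs[j] %% 180, chain = chain_id)
          }
          # occupy after drawing so consecutive segments may touch each other
          occupied[unlist(lapply(polys, polygon_pixels, size = size))] <- TRUE
          occupied[all_big] <- TRUE
          placed <- TRUE
        }
        if (placed) break
      }
    }

    # linear illumination gradient with random direction
    gdir <- stats::runif(1, 0, 2 * pi)
    xs <- (seq_len(size) - 1) / (size - 1) - 0.5
    grad <- gradient_amp * 2 * (outer(xs, xs, function(y, x)
      cos(gdir) * x + sin(gdir) * y))
    img <- img + grad
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
    img <- pmin(pmax(round(img), 0), 255)
    structure(list(pixels = img, truth_state = state, truth_contours = truth,
                   rng_seed = seed),
              class = "ground_truth_image")
  })
}

#' Write a ground-truth image as PNG plus JSON truth file
#'
#' @param gti A `ground_truth_image`.
#' @param png_path Output PNG path (8-bit grayscale).
#' @param json_path Optional truth JSON path (polygons in 0-based pixel
#'   coordinates, x right / y down).
#' @return `png_path`, invisibly.
#' @export
write_ground_truth <- function(gti, png_path, json_path = NULL) {
  stopifnot(inherits(gti, "ground_truth_image"))
  png::writePNG(gti$pixels / 255, target = png_path)
  if (!is.null(json_path)) {
    truth <- list(state = gti$truth_state,
                  seed = gti$rng_seed,
                  contours = lapply(gti$truth_contours, function(tc)
                    list(label = tc$label, orientation = tc$orientation,
                         chain = tc$chain,
                         x = unname(tc$polygon[, 1]),
                         y = unname(tc$polygon[, 2]))))
    jsonlite::write_json(truth, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(png_path)
}

# -- character matrices -------------------------------------------------------

#' Default per-character Mk settings for the synthetic matrix
#'
#' Mirrors the five scored characters: cell shape (2 states), cell border
#' (5), cell surface (4), ridge (2), life habit (7, the four pure habits plus
#' three combination states). Rates are scaled to the tree height so each
#' character changes a handful of times across the tree.
#'
#' @param tree The generating `phylo` (used only for its height).
#' @return Named list of `list(k, Q, lambda)` specs.
#' @export
default_character_specs <- function(tree) {
  h <- tree_height(tree)
  ks <- c(cell_shape = 2L, cell_border = 5L, cell_surface = 4L,
          ridge = 2L, life_habit = 7L)
  lapply(ks, function(k) {
    r <- 1.5 / ((k - 1) * h)
    list(k = k, Q = build_q("ER", k, r), lambda = 1)
  })
}

#' Simulate a species-by-character matrix
#'
#' One Mk character per column; when `couple` names two characters, both are
#' deterministic functions of a single simulated latent character: the second
#' named character equals the latent, the first is the monotone collapse
#' `floor(latent k1 / k2)` onto its own state count. This gives the
#' correlation tests a known positive with perfect (deterministic)
#' association between the two columns.
#'
#' @param tree A rooted `phylo` object.
#' @param specs Named list of per-character settings (`k`, `Q`, `lambda`),
#'   e.g. from [default_character_specs()].
#' @param couple Optional character vector of two spec names to couple.
#' @param seed Integer RNG seed.
#' @return Data frame: `species` column plus one integer column per character.
#' @export
generate_character_matrix <- function(tree, specs = default_character_specs(tree),
                                      couple = NULL, seed = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(couple)) {
    stopifnot(length(couple) == 2, all(couple %in% names(specs)))
  }
  out <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  ids <- names(specs)
  sub_seed <- function(i) (seed * 131L + i * 7919L) %% .Machine$integer.max
  latent <- NULL
  if (!is.null(couple)) {
    sp2 <- specs[[couple[2]]]
    latent <- simulate_character(tree, sp2$Q, lam = sp2$lambda,
                                 seed = sub_seed(0L))$tip_states
  }
  for (i in seq_along(ids)) {
    nm <- ids[i]
    sp <- specs[[nm]]
    if (!is.null(couple) && nm == couple[2]) {
      out[[nm]] <- as.integer(latent)
    } else if (!is.null(couple) && nm == couple[1]) {
      out[[nm]] <- as.integer(floor(latent * specs[[nm]]$k /
                                      specs[[couple[2]]]$k))
    } else {
      sim <- simulate_character(tree, sp$Q, lam = sp$lambda, seed = sub_seed(i))
      out[[nm]] <- as.integer(sim$tip_states)
    }
  }
  out
}

#' Write a character matrix as CSV
#'
#' Header `species,<character columns>`, integer codes, `NA` for unknown.
#'
#' @param matrix Data frame from [generate_character_matrix()] or compatible.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_character_matrix <- function(matrix, path) {
  utils::write.csv(matrix, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a character matrix CSV
#'
#' @param path CSV with a `species` column and integer-coded characters
#'   (`NA` = unknown).
#' @return Data frame.
#' @export
read_character_matrix <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(m)[1] != "species") stop("first column must be 'species'")
  m
}
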