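# SEM image classification: CLAHE contrast equalization, tiled k-means
# thresholding with a smoothed threshold field, contour detection, ASR
# (area / solidity / rectangle-ratio) classification with Hu-moment training
# matches and convexity-defect subdivision, and the final surface decision
# tree. Images are matrices [row = y, col = x], 8-bit intensities,
# coordinates 0-based with x rightward and y downward.

#' Contrast limited adaptive histogram equalization
#'
#' Per-tile histogram equalization with clipping (CLAHE), used to remove
#' large-scale illumination inhomogeneity before thresholding. A constant
#' image is returned unchanged.
#'
#' @param image Numeric matrix of 8-bit intensities.
#' @param clip_limit CLAHE clip limit (contrast amplification cap).
#' @param tile Tile side in pixels.
#' @return Matrix of the same dimensions, 8-bit range.
#' @export
equalize_contrast <- function(image, clip_limit = 2, tile = 64) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (tile > nrow(image) || tile > ncol(image))
    stop("tile (", tile, " px) larger than image ",
         nrow(image), "x", ncol(image))
  if (diff(range(image)) == 0) return(image)
  nx <- max(2, round(ncol(image) / tile))
  ny <- max(2, round(nrow(image) / tile))
  # pad to multiples of the tile grid (clahe requires it), then crop back
  W <- ceiling(ncol(image) / nx) * nx
  H <- ceiling(nrow(image) / ny) * ny
  m <- matrix(0, H, W)
  m[seq_len(nrow(image)), seq_len(ncol(image))] <- image
  if (W > ncol(image))
    m[, (ncol(image) + 1):W] <- m[, rep(ncol(image), W - ncol(image))]
  if (H > nrow(image))
    m[(nrow(image) + 1):H, ] <- m[rep(nrow(image), H - nrow(image)), ]
  eq <- EBImage::clahe(EBImage::Image(t(m) / 255), nx = nx, ny = ny,
                       bins = 256, limit = clip_limit)
  out <- t(EBImage::imageData(eq))[seq_len(nrow(image)), seq_len(ncol(image))]
  pmin(pmax(round(out * 255), 0), 255)
}

# Two-lowest-of-three k-means threshold for one intensity sample. With fewer
# than k distinct intensities the cluster count degrades gracefully (a
# two-level tile thresholds at the midpoint of its two clusters); NA when the
# sample is constant or the cluster spread is below min_contrast.
kmeans_threshold <- function(vals, k = 3, min_contrast = 0) {
  k_eff <- min(k, length(unique(vals)))
  if (k_eff < 2) return(structure(NA_real_, fallback = TRUE))
  centers <- unique(stats::quantile(vals, (1:k_eff) / (k_eff + 1),
                                    names = FALSE))
  if (length(centers) < k_eff)
    centers <- sort(unique(vals))[seq_len(k_eff)]
  km <- suppressWarnings(stats::kmeans(vals, centers = matrix(centers),
                                       iter.max = 30))
  cc <- sort(as.vector(km$centers))
  if (cc[k_eff] - cc[1] < min_contrast) return(NA_real_)
  mean(cc[1:2])
}

# Gaussian smoothing of a small matrix with NA-aware normalized convolution.
smooth_na <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(-r:r, sd = sigma)
  k2 <- outer(g, g)
  nr <- nrow(m); nc <- ncol(m)
  w <- matrix(0, nr, nc); s <- matrix(0, nr, nc)
  ok <- !is.na(m)
  mv <- ifelse(ok, m, 0)
  for (dy in -r:r) for (dx in -r:r) {
    ys <- pmin(pmax(seq_len(nr) + dy, 1), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1), nc)
    kw <- k2[dy + r + 1, dx + r + 1]
    s <- s + kw * mv[ys, xs, drop = FALSE] * ok[ys, xs, drop = FALSE]
    w <- w + kw * ok[ys, xs, drop = FALSE]
  }
  out <- s / w
  out[w == 0] <- NA
  out
}

#' Tiled k-means local thresholding
#'
#' The image is cut into `tile` x `tile` px tiles (edge tiles truncated);
#' each tile's intensities are clustered with k-means (k = 3, deterministic
#' quantile seeding) and the tile threshold is the mean of the two lowest
#' cluster centres. The tile-threshold field is Gaussian-smoothed
#' (`smooth_sigma` tiles, NA-aware) and interpolated bilinearly to pixels;
#' pixels below their threshold become foreground (dark structures).
#'
#' Tiles with fewer than k distinct intensities fall back to the image-global
#' threshold. Tiles whose cluster-centre spread is below `min_contrast`
#' contain no dark structures and contribute no threshold (their pixels take
#' interpolated values from structured neighbours; an image with no
#' structured tile returns an all-background mask).
#'
#' @param image Numeric matrix of 8-bit intensities.
#' @param tile Tile side in pixels (default 100).
#' @param k Number of intensity clusters (default 3).
#' @param smooth_sigma Gaussian SD for threshold smoothing, in tiles.
#' @param min_contrast Minimum cluster-centre spread (intensity units) for a
#'   tile to be considered structured.
#' @return Logical matrix: TRUE = foreground.
#' @export
local_threshold <- function(image, tile = 100, k = 3, smooth_sigma = 1,
                            min_contrast = 40) {
  stopifnot(is.matrix(image))
  ys <- seq(1, nrow(image), by = tile)
  xs <- seq(1, ncol(image), by = tile)
  th <- matrix(NA_real_, length(ys), length(xs))
  fallback <- matrix(FALSE, length(ys), length(xs))
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    yr <- ys[i]:min(ys[i] + tile - 1, nrow(image))
    xr <- xs[j]:min(xs[j] + tile - 1, ncol(image))
    t_ij <- kmeans_threshold(as.vector(image[yr, xr]), k, min_contrast)
    th[i, j] <- t_ij
    fallback[i, j] <- isTRUE(attr(t_ij, "fallback"))
  }
  if (any(fallback)) {
    vals <- as.vector(image)
    if (length(vals) > 40000) vals <- vals[seq(1, length(vals), length.out = 40000)]
    th[fallback] <- kmeans_threshold(vals, k, min_contrast)
  }
  th <- smooth_na(th, smooth_sigma)
  if (all(is.na(th)))
    return(matrix(FALSE, nrow(image), ncol(image)))
  # bilinear interpolation of tile-centre thresholds to the pixel grid
  yc <- pmin(ys + (tile - 1) / 2, nrow(image))
  xc <- pmin(xs + (tile - 1) / 2, ncol(image))
  # fill remaining NAs from nearest structured tile (flat extension)
  if (anyNA(th)) {
    idx <- which(is.na(th), arr.ind = TRUE)
    okk <- which(!is.na(th), arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      d <- (okk[, 1] - idx[r, 1])^2 + (okk[, 2] - idx[r, 2])^2
      th[idx[r, 1], idx[r, 2]] <- th[okk[which.min(d), 1], okk[which.min(d), 2]]
    }
  }
  interp_rows <- function(mat, at, centers) {
    if (length(centers) == 1) return(matrix(mat[1, ], length(at),
                                            ncol(mat), byrow = TRUE))
    apply(mat, 2, function(col)
      stats::approx(centers, col, xout = at, rule = 2)$y)
  }
  t1 <- interp_rows(th, seq_len(nrow(image)), yc)             # rows -> pixels
  t2 <- t(interp_rows(t(t1), seq_len(ncol(image)), xc))       # cols -> pixels
  image < t2
}

#' Detect contours of a binary mask
#'
#' One contour per connected foreground component (8-connectivity). Each
#' contour carries the ASR descriptors: A (pixel area normalized by image
#' area), S (solidity: pixel count over convex-hull area, hull taken on the
#' boundary-pixel corners so S <= 1), R (minimum-bounding-rectangle side
#' ratio, >= 1) and the long-axis orientation in [0, 180).
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_area Components smaller than this many pixels are dropped
#'   (speckle guard).
#' @return List of contour objects (`id`, `boundary` 0-based pixel-centre
#'   polygon, `n_pixels`, `A`, `S`, `R`, `orientation`,
#'   `label = "unclassified"`, `hu`).
#' @export
detect_contours <- function(mask, min_area = 20) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  labm <- EBImage::imageData(lab)        # dim1 = x, dim2 = y
  counts <- tabulate(labm[labm > 0])
  oc <- EBImage::ocontour(lab)
  img_area <- nrow(mask) * ncol(mask)
  out <- list()
  for (i in seq_along(oc)) {
    if (counts[i] < min_area) next
    b <- oc[[i]]                          # 0-based (x, y) boundary, ordered
    corners <- rbind(cbind(b[, 1] - 0.5, b[, 2] - 0.5),
                     cbind(b[, 1] + 0.5, b[, 2] - 0.5),
                     cbind(b[, 1] + 0.5, b[, 2] + 0.5),
                     cbind(b[, 1] - 0.5, b[, 2] + 0.5))
    hull <- hull_polygon(corners)
    hull_a <- shoelace_area(hull)
    mbr <- min_bounding_rect(corners, pad = 0)
    pix <- which(labm == i, arr.ind = TRUE)   # (x, y) 1-based
    hu <- hu_moments(pix[, 1] - 1, pix[, 2] - 1)
    out[[length(out) + 1]] <- list(
      id = length(out) + 1L,
      boundary = cbind(x = b[, 1], y = b[, 2]),
      n_pixels = counts[i],
      A = counts[i] / img_area,
      S = min(1, counts[i] / max(hull_a, .Machine$double.eps)),
      R = max(1, mbr$ratio),
      orientation = mbr$angle,
      label = "unclassified",
      pieces = NULL,
      hu = hu)
  }
  out
}

# Polygon-based descriptors for a subdivision piece (pixel-centre vertices;
# sides padded by 1 px so they measure pixel extents).
piece_descriptors <- function(poly) {
  a <- shoelace_area(poly)
  hull <- hull_polygon(poly)
  ha <- shoelace_area(hull)
  mbr <- min_bounding_rect(poly, pad = 1)
  list(S = if (ha > 0) a / ha else 1, R = mbr$ratio, orientation = mbr$angle,
       polygon = poly)
}

#' Default Hu-moment training set
#'
#' A small library of canonical shapes: a disk and 2:1 / 3:1 ellipses
#' (holes), and 9:1 / 12:1 rectangles (straight channels). Used by the
#' Hu-moment matching step when the caller provides no curated set.
#'
#' @return List of `list(label, hu)` entries.
#' @export
default_training_set <- function() {
  grid <- expand.grid(x = -40:40, y = -40:40)
  region <- function(keep) grid[keep, , drop = FALSE]
  shapes <- list(
    list(label = "hole", pts = region(grid$x^2 + grid$y^2 <= 10^2)),
    list(label = "hole", pts = region((grid$x / 14)^2 + (grid$y / 7)^2 <= 1)),
    list(label = "hole", pts = region((grid$x / 18)^2 + (grid$y / 6)^2 <= 1)),
    list(label = "straight_channel",
         pts = region(abs(grid$x) <= 27 & abs(grid$y) <= 1.5)),
    list(label = "straight_channel",
         pts = region(abs(grid$x) <= 36 & abs(grid$y) <= 1.5)))
  lapply(shapes, function(s)
    list(label = s$label, hu = hu_moments(s$pts$x, s$pts$y)))
}

#' Classify contours by the ASR criterion
#'
#' Rules are applied in order. (1) Provisional holes need `S > 0.8` and
#' `R < 6`; the provisional holes' areas define a mean and SD, and a hole
#' must additionally lie within `hole_area_sd` SDs of that mean (two-pass,
#' not iterated). (2) Straight channels need `S > 0.5` and `R >= 6`, with no
#' area constraint. (3) Remaining contours adopt the label of their nearest
#' Hu-moment match in the training set when the distance is below
#' `hu_cutoff`. (4) Contours that can be subdivided at their convexity
#' defects into >= 2 pieces, each satisfying the straight-channel rule,
#' become labyrinthine channels (pieces recorded). (5) Anything else stays
#' unclassified.
#'
#' @param contours List from [detect_contours()].
#' @param training_set List of `list(label, hu)`; `NULL` skips step 3 with a
#'   warning.
#' @param hole_area_sd Width of the hole-area filter in SDs (default 2).
#' @param hu_cutoff Maximum Hu distance for a training match.
#' @param defect_min_depth Minimum convexity-defect depth (px) used by the
#'   subdivision step.
#' @return The contour list with `label` (and `pieces` for labyrinthine
#'   contours) filled in.
#' @export
classify_contours <- function(contours, training_set = default_training_set(),
                              hole_area_sd = 2, hu_cutoff = 0.3,
                              defect_min_depth = 4) {
  if (length(contours) == 0) return(contours)
  if (is.null(training_set) || length(training_set) == 0) {
    warning("empty training set: skipping Hu-moment matching")
    training_set <- list()
  }
  S <- vapply(contours, `[[`, 0, "S")
  R <- vapply(contours, `[[`, 0, "R")
  A <- vapply(contours, `[[`, 0, "A")
  prov_hole <- S > 0.8 & R < 6
  mu <- mean(A[prov_hole]); sdev <- stats::sd(A[prov_hole])
  for (i in seq_along(contours)) {
    if (prov_hole[i] &&
        (is.na(sdev) || abs(A[i] - mu) <= hole_area_sd * sdev)) {
      contours[[i]]$label <- "hole"
      next
    }
    if (S[i] > 0.5 && R[i] >= 6) {
      contours[[i]]$label <- "straight_channel"
      next
    }
    if (length(training_set) > 0) {
      d <- vapply(training_set, function(ts)
        hu_distance(contours[[i]]$hu, ts$hu), 0)
      if (min(d) < hu_cutoff) {
        contours[[i]]$label <- training_set[[which.min(d)]]$label
        next
      }
    }
    pieces <- split_at_defects(contours[[i]]$boundary,
                               min_depth = defect_min_depth)
    if (length(pieces) >= 2) {
      pd <- lapply(pieces, piece_descriptors)
      ok <- vapply(pd, function(p) p$S > 0.5 && p$R >= 6, TRUE)
      if (all(ok)) {
        contours[[i]]$label <- "labyrinthine_channel"
        contours[[i]]$pieces <- pd
        next
      }
    }
    contours[[i]]$label <- "unclassified"
  }
  contours
}

#' Force contour labels from an override table
#'
#' Programmatic replacement for interactive manual correction: a named list
#' (or JSON file) mapping contour ids to labels.
#'
#' @param contours Classified contour list.
#' @param overrides Named list `id -> label`, or path to such a JSON file.
#' @return Contour list with the forced labels applied.
#' @export
apply_overrides <- function(contours, overrides) {
  if (is.character(overrides) && length(overrides) == 1)
    overrides <- jsonlite::read_json(overrides, simplifyVector = TRUE)
  if (length(overrides) == 0) return(contours)
  for (nm in names(overrides)) {
    id <- as.integer(nm)
    j <- which(vapply(contours, `[[`, 0L, "id") == id)
    if (length(j) == 1) contours[[j]]$label <- overrides[[nm]]
  }
  contours
}

#' Final surface-state decision tree
#'
#' If the total contour area fraction is below `smooth_cut` the state is
#' smooth. Otherwise holes win when they have the largest covering surface
#' (ties preferring holes). When channels cover more, the SD of the channel
#' orientations (straight channels plus labyrinthine pieces) decides:
#' above `angle_sd_cut` labyrinthine, otherwise straight.
#'
#' @param contours Classified contour list.
#' @param angle_sd_cut Orientation-SD cutoff in degrees (default 25).
#' @param smooth_cut Total-area fraction below which the surface is smooth
#'   (default 0.03).
#' @return List of class `surface_call`: `state`, `code` (0 smooth, 1 holes,
#'   2 straight, 3 labyrinthine), `area_fraction_by_label`,
#'   `channel_angle_sd` (NA when channels are absent).
#' @export
call_surface_state <- function(contours, angle_sd_cut = 25,
                               smooth_cut = 0.03) {
  labs <- vapply(contours, `[[`, "", "label")
  A <- vapply(contours, `[[`, 0, "A")
  frac <- c(hole = sum(A[labs == "hole"]),
            straight_channel = sum(A[labs == "straight_channel"]),
            labyrinthine_channel = sum(A[labs == "labyrinthine_channel"]),
            unclassified = sum(A[labs == "unclassified"]))
  total <- sum(frac)
  angles <- c(
    vapply(contours[labs == "straight_channel"], `[[`, 0, "orientation"),
    unlist(lapply(contours[labs == "labyrinthine_channel"], function(ct)
      vapply(ct$pieces, `[[`, 0, "orientation"))))
  angle_sd <- if (length(angles) > 0) axial_angle_sd(angles) else NA_real_
  chan <- frac[["straight_channel"]] + frac[["labyrinthine_channel"]]
  state <-
    if (total < smooth_cut) "smooth"
    else if (frac[["hole"]] >= chan) "holes"
    else if (!is.na(angle_sd) && angle_sd > angle_sd_cut) "labyrinthine_channels"
    else "straight_channels"
  structure(list(state = state,
                 code = match(state, surface_state_names) - 1L,
                 area_fraction_by_label = frac,
                 total_fraction = total,
                 channel_angle_sd = angle_sd),
            class = "surface_call")
}

#' Classify one grayscale image end to end
#'
#' CLAHE, tiled thresholding, contour detection, ASR classification
#' (optionally corrected by an override table), and the surface decision
#' tree.
#'
#' @param image Matrix of 8-bit intensities, or a `ground_truth_image`, or a
#'   path to a PNG/TIFF file.
#' @param training_set Hu-moment training library
#'   (default [default_training_set()]).
#' @param overrides Optional override table (see [apply_overrides()]).
#' @param clip_limit,clahe_tile CLAHE parameters.
#' @param tile,smooth_sigma,min_contrast Thresholding parameters
#'   (see [local_threshold()]).
#' @param min_area Speckle guard (px) for contour detection.
#' @param angle_sd_cut,smooth_cut Decision-tree cutoffs.
#' @return List: `call` (a `surface_call`) and `contours`.
#' @export
classify_image <- function(image, training_set = default_training_set(),
                           overrides = NULL, clip_limit = 2, clahe_tile = 64,
                           tile = 100, smooth_sigma = 1, min_contrast = 40,
                           min_area = 20, angle_sd_cut = 25,
                           smooth_cut = 0.03) {
  if (inherits(image, "ground_truth_image")) image <- image$pixels
  if (is.character(image)) {
    dat <- EBImage::imageData(EBImage::readImage(image))
    if (length(dim(dat)) == 3) dat <- dat[, , 1]
    image <- t(dat) * 255
  }
  eq <- equalize_contrast(image, clip_limit = clip_limit, tile = clahe_tile)
  mask <- local_threshold(eq, tile = tile, smooth_sigma = smooth_sigma,
                          min_contrast = min_contrast)
  contours <- detect_contours(mask, min_area = min_area)
  contours <- classify_contours(contours, training_set = training_set)
  if (!is.null(overrides)) contours <- apply_overrides(contours, overrides)
  call <- call_surface_state(contours, angle_sd_cut = angle_sd_cut,
                             smooth_cut = smooth_cut)
  list(call = call, contours = contours)
}

#' Classify a batch of images
#'
#' @param images Character vector of file paths, or a list of matrices /
#'   `ground_truth_image`s.
#' @param ... Passed to [classify_image()].
#' @return Data frame: `image`, `state`, `code` (0 smooth, 1 holes,
#'   2 straight channels, 3 labyrinthine channels), per-label fractions and
#'   the channel-orientation SD.
#' @export
classify_images <- function(images, ...) {
  nm <- if (is.character(images)) basename(images)
        else sprintf("image_%03d", seq_along(images))
  rows <- lapply(seq_along(images), function(i) {
    res <- classify_image(if (is.list(images) && !is.matrix(images))
      images[[i]] else if (is.character(images)) images[i] else images[[i]],
      ...)
    f <- res$call$area_fraction_by_label
    data.frame(image = nm[i], state = res$call$state, code = res$call$code,
               frac_holes = f[["hole"]],
               frac_straight = f[["straight_channel"]],
               frac_labyrinthine = f[["labyrinthine_channel"]],
               frac_unclassified = f[["unclassified"]],
               channel_angle_sd = res$call$channel_angle_sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify cell shape from width/length measurements
#'
#' Polygonal when the mean width over mean length ratio is at most 2 (the
#' boundary value is polygonal), wide otherwise. When a cell's length is
#' given as a (min, max) pair the per-cell length is their midpoint, as used
#' for sawtooth borders.
#'
#' @param widths Per-cell left-right extents (> 0).
#' @param lengths Per-cell cranial-caudal extents: a vector, or a 2-column
#'   matrix of (min, max) pairs.
#' @return `"polygonal"` or `"wide"` with attribute `ratio`.
#' @export
classify_cell_shape <- function(widths, lengths) {
  if (is.matrix(lengths)) lengths <- rowMeans(lengths)
  if (length(widths) == 0 || length(lengths) == 0)
    stop("need at least one measured cell")
  if (any(widths <= 0) || any(lengths <= 0))
    stop("widths and lengths must be > 0")
  ratio <- mean(widths) / mean(lengths)
  structure(if (ratio <= 2) "polygonal" else "wide", ratio = ratio)
}

#' Classify cell border from digit measurements
#'
#' The digit-to-cell length ratio (means over the measured cells) is compared
#' with the 0.3 / 0.5 cuts: below 0.3 short digits, within [0.3, 0.5] mild,
#' above 0.5 long. Without digits the border is regular, or sawteeth when the
#' caller says so (sawteeth are recognized descriptively: larger, 5-10 um,
#' irregular, imbricating projections).
#'
#' @param digit_lengths Per-digit lengths (possibly empty).
#' @param cell_lengths Per-cell lengths (> 0).
#' @param sawteeth Logical flag supplied by the caller for sawtooth borders.
#' @return One of `"regular"`, `"short_digits"`, `"mild_digits"`,
#'   `"long_digits"`, `"sawteeth"`, with attribute `ratio` where digits are
#'   present.
#' @export
classify_cell_border <- function(digit_lengths, cell_lengths,
                                 sawteeth = FALSE) {
  if (sawteeth) return("sawteeth")
  if (length(digit_lengths) == 0) return("regular")
  if (any(digit_lengths < 0) || any(cell_lengths <= 0))
    stop("lengths must be positive")
  ratio <- mean(digit_lengths) / mean(cell_lengths)
  state <- if (ratio < 0.3) "short_digits"
           else if (ratio <= 0.5) "mild_digits"
           else "long_digits"
  structure(state, ratio = ratio)
}
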