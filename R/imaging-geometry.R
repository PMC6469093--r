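# Plane-geometry primitives for contour classification: shoelace area,
# convex hulls, minimum-area bounding rectangles (rotating calipers), Hu
# moment invariants, convexity defects, and axial (0-180 degree) angle
# statistics.

#' Signed polygon area by the shoelace formula
#'
#' @param poly Two-column matrix of vertices (x, y), not necessarily closed.
#' @return Absolute area.
#' @export
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex hull vertices (counter-clockwise), as a matrix.
hull_polygon <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  pts[idx, , drop = FALSE]
}

#' Minimum-area bounding rectangle (rotating calipers)
#'
#' For each convex-hull edge direction the points are projected on the edge
#' axis and its normal; the rectangle with the smallest area wins.
#'
#' @param pts Two-column matrix of points (x, y).
#' @param pad Constant added to both side lengths (use 1 when `pts` are pixel
#'   centres so that sides measure pixel extents).
#' @return List: `long`, `short` (side lengths, long >= short), `ratio`
#'   (`long/short`, >= 1), `angle` (long-axis angle, degrees in [0, 180)).
#' @export
min_bounding_rect <- function(pts, pad = 0) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  if (nrow(pts) == 1)
    return(list(long = pad, short = pad, ratio = 1, angle = 0))
  h <- hull_polygon(pts)
  n <- nrow(h)
  if (n == 2) {
    d <- h[2, ] - h[1, ]
    len <- sqrt(sum(d^2)) + pad
    return(list(long = len, short = pad,
                ratio = if (pad > 0) len / pad else Inf,
                angle = (atan2(d[2], d[1]) * 180 / pi) %% 180))
  }
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    e <- h[j, ] - h[i, ]
    elen <- sqrt(sum(e^2))
    if (elen < 1e-12) next
    ux <- e[1] / elen; uy <- e[2] / elen
    p1 <- h[, 1] * ux + h[, 2] * uy       # along edge
    p2 <- -h[, 1] * uy + h[, 2] * ux      # normal
    w <- diff(range(p1)) + pad
    ht <- diff(range(p2)) + pad
    if (is.null(best) || w * ht < best$area) {
      ang <- if (w >= ht) atan2(uy, ux) else atan2(ux, -uy)
      best <- list(area = w * ht, long = max(w, ht), short = min(w, ht),
                   angle = (ang * 180 / pi) %% 180)
    }
  }
  list(long = best$long, short = best$short,
       ratio = best$long / max(best$short, .Machine$double.eps),
       angle = best$angle)
}

#' Hu moment invariants of a pixel region
#'
#' The seven rotation/translation/scale-invariant moments of Hu, computed
#' from the region's pixel coordinates.
#'
#' @param px,py Pixel coordinates of the region (vectors of equal length).
#' @return Numeric vector of length 7.
#' @export
hu_moments <- function(px, py) {
  n <- length(px)
  mx <- mean(px); my <- mean(py)
  x <- px - mx; y <- py - my
  mu <- function(p, q) sum(x^p * y^q)
  m00 <- n
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) * (3 * (n30 + n12)^2 - (n21 + n03)^2)
  c(h1, h2, h3, h4, h5, h6, h7)
}

#' Hu-moment shape distance
#'
#' Log-magnitude comparison of two Hu vectors:
#' `sum_i |m_i^A - m_i^B|` with `m = sign(h) log10 |h|`; components with
#' negligible magnitude in both shapes are skipped.
#'
#' @param ha,hb Hu vectors from [hu_moments()].
#' @return Non-negative distance (0 for identical shapes).
#' @export
hu_distance <- function(ha, hb) {
  m <- function(h) ifelse(abs(h) < 1e-30, 0, sign(h) * log10(abs(h)))
  ma <- m(ha); mb <- m(hb)
  use <- !(ma == 0 & mb == 0)
  if (!any(use)) return(0)
  sum(abs(ma[use] - mb[use]))
}

# Convexity defects of an ordered polygon: for every hull edge, the deepest
# intermediate vertex and its perpendicular distance to the hull chord.
# Returns data.frame(index, depth) sorted by decreasing depth.
convexity_defects <- function(poly) {
  n <- nrow(poly)
  hidx <- grDevices::chull(poly[, 1], poly[, 2])
  # walk the polygon between consecutive hull vertices (polygon order)
  hidx <- sort(hidx)
  out_i <- integer(0); out_d <- numeric(0)
  m <- length(hidx)
  for (a in seq_len(m)) {
    i1 <- hidx[a]
    i2 <- hidx[if (a == m) 1 else a + 1]
    span <- if (a == m) c(seq(i1, n), seq_len(i2)) else seq(i1, i2)
    if (length(span) <= 2) next
    inner <- span[-c(1, length(span))]
    p1 <- poly[i1, ]; p2 <- poly[i2, ]
    ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
    elen <- sqrt(ex^2 + ey^2)
    if (elen < 1e-12) next
    d <- abs((poly[inner, 1] - p1[1]) * ey -
               (poly[inner, 2] - p1[2]) * ex) / elen
    j <- which.max(d)
    out_i <- c(out_i, inner[j])
    out_d <- c(out_d, d[j])
  }
  ord <- order(out_d, decreasing = TRUE)
  data.frame(index = out_i[ord], depth = out_d[ord])
}

# Split an ordered polygon at its deepest convexity defect: a cut runs from
# the defect vertex to the nearest polygon vertex at least n/6 positions away
# along the boundary in both directions. Recurses until no defect deeper than
# min_depth remains (or max_splits reached). Returns list of sub-polygons.
split_at_defects <- function(poly, min_depth = 4, max_splits = 6) {
  n <- nrow(poly)
  if (n < 8 || max_splits <= 0) return(list(poly))
  def <- convexity_defects(poly)
  def <- def[def$depth >= min_depth, , drop = FALSE]
  if (nrow(def) == 0) return(list(poly))
  d <- def$index[1]
  gap <- max(3L, floor(n / 6))
  cand <- seq_len(n)
  ring_dist <- pmin(abs(cand - d), n - abs(cand - d))
  cand <- cand[ring_dist >= gap]
  if (length(cand) == 0) return(list(poly))
  dist2 <- (poly[cand, 1] - poly[d, 1])^2 + (poly[cand, 2] - poly[d, 2])^2
  e <- cand[which.min(dist2)]
  i1 <- min(d, e); i2 <- max(d, e)
  polyA <- poly[i1:i2, , drop = FALSE]
  polyB <- poly[c(i2:n, seq_len(i1)), , drop = FALSE]
  if (nrow(polyA) < 3 || nrow(polyB) < 3) return(list(poly))
  c(split_at_defects(polyA, min_depth, max_splits - 1),
    split_at_defects(polyB, min_depth, max_splits - 1))
}

#' Standard deviation of axial angles
#'
#' Orientations live on [0, 180); angles are re-centred on the circular mean
#' of the doubled angles before the (population) SD is taken, avoiding the
#' 179-vs-1 degree wrap artifact of a naive SD.
#'
#' @param angles_deg Numeric vector of orientations in degrees.
#' @return SD in degrees.
#' @export
axial_angle_sd <- function(angles_deg) {
  a <- (angles_deg %% 180) * pi / 90  # doubled angles in radians
  mu <- atan2(mean(sin(a)), mean(cos(a))) / 2 * 180 / pi
  dev <- ((angles_deg - mu + 90) %% 180) - 90
  sqrt(mean(dev^2))
}
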