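test_that("contrast equalization is deterministic and tames gradients", {
  const <- matrix(120, 128, 128)
  expect_identical(equalize_contrast(const), const)

  g <- generate_surface_image("straight_channels", noise_sd = 3, seed = 2,
                              gradient_amp = 40)
  img <- g$pixels
  tile_means <- function(m, tile = 32) {
    ys <- seq(1, nrow(m), by = tile); xs <- seq(1, ncol(m), by = tile)
    vapply(seq_along(ys), function(i) vapply(seq_along(xs), function(j)
      mean(m[ys[i]:(ys[i] + tile - 1), xs[j]:(xs[j] + tile - 1)]), 0),
      numeric(length(xs)))
  }
  eq <- equalize_contrast(img)
  expect_lt(stats::var(as.vector(tile_means(eq))),
            stats::var(as.vector(tile_means(img))))
  expect_identical(eq, equalize_contrast(img))
  expect_error(equalize_contrast(img, tile = 500), "larger than image")
})

test_that("tiled k-means thresholding recovers structures, not tile seams", {
  # separable two-level image: threshold recovers the structure exactly
  img <- matrix(200, 120, 120)
  img[40:60, 30:80] <- 50
  mask <- local_threshold(img, tile = 60, smooth_sigma = 0)
  expect_identical(unname(which(mask)), unname(which(img == 50)))

  # three well-separated components: tile threshold ~ (c1 + c2) / 2
  set.seed(8)
  c_true <- c(40, 120, 210)
  vals <- c(stats::rnorm(2000, c_true[1], 3), stats::rnorm(4000, c_true[2], 3),
            stats::rnorm(4000, c_true[3], 3))
  tile_img <- matrix(sample(vals, 10000), 100, 100)
  m <- local_threshold(tile_img, tile = 100, smooth_sigma = 0)
  # recover the implied threshold from the mask boundary
  thr_lo <- max(tile_img[m]); thr_hi <- min(tile_img[!m])
  expect_lt(abs((thr_lo + thr_hi) / 2 - mean(c_true[1:2])), 2)

  # a hard illumination step across tiles must not leave a seam contour
  step <- matrix(150, 200, 200)
  step[, 101:200] <- 215
  step[20:30, 40:60] <- 45; step[150:160, 140:165] <- 100
  set.seed(9)
  step <- step + matrix(stats::rnorm(200 * 200, 0, 3), 200, 200)
  mstep <- local_threshold(step, tile = 100, smooth_sigma = 1)
  seam <- mstep[, 99:102]
  seam[20:30, ] <- FALSE  # the genuine structure may touch the seam region
  expect_equal(sum(seam), 0)
  # both structures recovered
  expect_true(all(mstep[22:28, 45:55]))
  expect_true(all(mstep[152:158, 145:160]))

  # a structure-free noisy image yields an all-background mask
  set.seed(10)
  flat <- matrix(180 + stats::rnorm(128^2, 0, 5), 128, 128)
  expect_false(any(local_threshold(flat, tile = 64)))
})

test_that("contour descriptors match disk and rectangle geometry", {
  empty <- matrix(FALSE, 50, 50)
  expect_length(detect_contours(empty), 0)

  disk <- matrix(FALSE, 100, 100)
  yx <- expand.grid(y = 1:100, x = 1:100)
  disk[(yx$y - 50)^2 + (yx$x - 50)^2 <= 20^2] <- TRUE
  cd <- detect_contours(disk)
  expect_length(cd, 1)
  expect_gte(cd[[1]]$S, 0.95)
  expect_lte(cd[[1]]$R, 1.1)

  rect <- matrix(FALSE, 100, 100)
  rect[48:52, 21:80] <- TRUE  # 60 x 5, axis aligned
  cr <- detect_contours(rect)
  expect_length(cr, 1)
  expect_equal(cr[[1]]$R, 12, tolerance = 0.5 / 12)
  expect_lt(min(cr[[1]]$orientation, 180 - cr[[1]]$orientation), 2)

  two <- matrix(FALSE, 200, 200)
  yx2 <- expand.grid(y = 1:200, x = 1:200)
  two[(yx2$y - 50)^2 + (yx2$x - 50)^2 <= 15^2] <- TRUE
  two[(yx2$y - 140)^2 + (yx2$x - 140)^2 <= 10^2] <- TRUE
  ct <- detect_contours(two)
  expect_length(ct, 2)
  a_exp <- sort(c(pi * 15^2, pi * 10^2) / (200 * 200))
  expect_equal(sort(vapply(ct, `[[`, 0, "A")), a_exp, tolerance = 0.05)

  # rotating-calipers invariants on arbitrary blobs
  set.seed(3)
  blob <- matrix(stats::runif(80 * 80) > 0.5, 80, 80)
  for (ct2 in detect_contours(blob, min_area = 10)) {
    expect_gte(ct2$R, 1)
    expect_lte(ct2$S, 1)
    expect_gte(ct2$A, 0); expect_lte(ct2$A, 1)
  }
})

test_that("ASR rules, Hu matching and defect subdivision label contours", {
  # hole and straight-channel rules on real masks
  m <- matrix(FALSE, 200, 200)
  yx <- expand.grid(y = 1:200, x = 1:200)
  m[(yx$y - 40)^2 + (yx$x - 40)^2 <= 12^2] <- TRUE          # disk
  m[(yx$y - 60)^2 / 18^2 + (yx$x - 140)^2 / 9^2 <= 1] <- TRUE # ellipse 2:1
  m[150:154, 30:109] <- TRUE                                 # 80 x 5 channel
  cl <- classify_contours(detect_contours(m))
  labs <- vapply(cl, `[[`, "", "label")
  S <- vapply(cl, `[[`, 0, "S"); R <- vapply(cl, `[[`, 0, "R")
  expect_identical(labs[R < 6], rep("hole", 2))
  expect_identical(labs[R >= 6], "straight_channel")

  # L-shaped contour: fails both rules, splits into two straight arms
  L <- matrix(FALSE, 200, 200)
  L[40:45, 40:109] <- TRUE   # horizontal arm 70 x 6
  L[40:109, 40:45] <- TRUE   # vertical arm 70 x 6
  cL <- suppressWarnings(
    classify_contours(detect_contours(L), training_set = NULL))
  expect_identical(cL[[1]]$label, "labyrinthine_channel")
  expect_gte(length(cL[[1]]$pieces), 2)
  for (p in cL[[1]]$pieces) {
    expect_gte(p$R, 6)
    expect_gt(p$S, 0.5)
    # independent check: each arm is close to an axis-aligned rectangle
    ext <- apply(p$polygon, 2, function(v) diff(range(v)) + 1)
    expect_gte(max(ext) / min(ext), 6)
  }
  orient <- vapply(cL[[1]]$pieces, `[[`, 0, "orientation")
  expect_gt(axial_angle_sd(orient), 25)

  # the 2-SD area filter removes an outlier hole unless Hu matching saves it
  many <- matrix(FALSE, 300, 300)
  yx3 <- expand.grid(y = 1:300, x = 1:300)
  centers <- expand.grid(cy = c(40, 100, 160, 220), cx = c(40, 100, 160))
  for (i in seq_len(nrow(centers)))
    many[(yx3$y - centers$cy[i])^2 + (yx3$x - centers$cx[i])^2 <= 6^2] <- TRUE
  many[(yx3$y - 150)^2 + (yx3$x - 250)^2 <= 40^2] <- TRUE  # giant blob
  cm <- suppressWarnings(
    classify_contours(detect_contours(many), training_set = NULL))
  A <- vapply(cm, `[[`, 0, "A")
  labs <- vapply(cm, `[[`, "", "label")
  expect_identical(unique(labs[A < max(A)]), "hole")
  expect_identical(labs[A == max(A)], "unclassified")

  # Hu library: a training shape matches itself at distance 0 and a disk
  # never matches a 12:1 rectangle
  ts <- default_training_set()
  expect_equal(hu_distance(ts[[1]]$hu, ts[[1]]$hu), 0)
  expect_gt(hu_distance(ts[[1]]$hu, ts[[5]]$hu), 0.3)

  expect_warning(classify_contours(detect_contours(m), training_set = NULL),
                 "training set")
})

test_that("the surface decision tree applies the 3% and 25-degree cuts", {
  holes <- function(A) make_contour(A, 0.95, 1.5, label = "hole")
  chan <- function(A, o) make_contour(A, 0.9, 10, orientation = o,
                                      label = "straight_channel")

  expect_identical(call_surface_state(list(holes(0.02)))$state, "smooth")
  expect_false(call_surface_state(list(holes(0.031)))$state == "smooth")

  mix <- list(holes(0.10), chan(0.05, 10))
  expect_identical(call_surface_state(mix)$state, "holes")
  tie <- list(holes(0.05), chan(0.05, 10))
  expect_identical(call_surface_state(tie)$state, "holes")

  straight <- lapply(seq(0, 10, by = 5), function(o) chan(0.04, o))
  expect_identical(call_surface_state(straight)$state, "straight_channels")
  laby <- lapply(c(0, 40, 80, 120), function(o) chan(0.04, o))
  expect_identical(call_surface_state(laby)$state, "labyrinthine_channels")

  # boundary: exactly at the angle cut stays straight, just above flips
  at_cut <- list(chan(0.04, 0), chan(0.04, 50))     # axial SD = 25
  expect_identical(call_surface_state(at_cut)$state, "straight_channels")
  over <- list(chan(0.04, 0), chan(0.04, 52))       # axial SD = 26
  expect_identical(call_surface_state(over)$state, "labyrinthine_channels")

  # pure function: identical input, identical output
  expect_identical(call_surface_state(mix), call_surface_state(mix))

  # subdividing labyrinthine contours conserves area, so a smooth call can
  # never become non-smooth after subdivision
  lab <- make_contour(0.02, 0.4, 3, label = "labyrinthine_channel",
                      pieces = list(make_piece(0), make_piece(45)))
  expect_identical(call_surface_state(list(lab))$state, "smooth")
  split_as_straight <- list(
    make_contour(0.01, 0.9, 10, 0, label = "straight_channel"),
    make_contour(0.01, 0.9, 10, 45, label = "straight_channel"))
  expect_identical(call_surface_state(split_as_straight)$state, "smooth")
})

test_that("cell shape and border rules honour their published cuts", {
  expect_identical(as.character(classify_cell_shape(30, 20)), "polygonal")
  expect_identical(as.character(classify_cell_shape(60, 20)), "wide")
  expect_identical(as.character(classify_cell_shape(40, 20)), "polygonal")
  # min/max pair: lengths averaged per cell
  expect_identical(as.character(
    classify_cell_shape(30, matrix(c(10, 30), 1))), "polygonal")
  expect_error(classify_cell_shape(10, 0), "> 0")

  expect_identical(as.character(classify_cell_border(2, 10)), "short_digits")
  expect_identical(as.character(classify_cell_border(4, 10)), "mild_digits")
  expect_identical(as.character(classify_cell_border(6, 10)), "long_digits")
  expect_identical(as.character(classify_cell_border(3, 10)), "mild_digits")
  expect_identical(as.character(classify_cell_border(5, 10)), "mild_digits")
  expect_identical(classify_cell_border(numeric(0), 10), "regular")
  expect_identical(classify_cell_border(numeric(0), 10, sawteeth = TRUE),
                   "sawteeth")
  expect_error(classify_cell_border(-1, 10), "positive")
})

test_that("overrides force labels like the manual-correction step", {
  m <- matrix(FALSE, 100, 100)
  m[40:44, 11:90] <- TRUE
  cl <- classify_contours(detect_contours(m))
  expect_identical(cl[[1]]$label, "straight_channel")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(`1` = "hole"), f, auto_unbox = TRUE)
  cl2 <- apply_overrides(cl, f)
  expect_identical(cl2[[1]]$label, "hole")
})

test_that("end-to-end classification is deterministic", {
  g <- generate_surface_image("holes", noise_sd = 5, seed = 77)
  r1 <- classify_image(g)
  r2 <- classify_image(g)
  expect_identical(r1$call, r2$call)
  expect_identical(r1$call$state, "holes")
})
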