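test_that("birth-death tree generator produces valid ultrametric trees", {
  t2 <- generate_tree(2, 1, 0, seed = 42)
  d <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(d[1], d[2], tolerance = 1e-10)

  t50 <- generate_tree(50, 1, 0, seed = 1)
  expect_equal(ape::Ntip(t50), 50)
  expect_equal(t50$Nnode, 49)
  expect_true(ape::is.binary(t50))
  expect_true(all(t50$edge.length > 0))
  expect_true(ape::is.ultrametric(t50))
  expect_equal(length(unique(t50$tip.label)), 50)

  # deterministic given the seed
  expect_identical(ape::write.tree(generate_tree(20, 1, 0.3, seed = 7)),
                   ape::write.tree(generate_tree(20, 1, 0.3, seed = 7)))

  expect_error(generate_tree(1, 1, 0), "n_tips")
  expect_error(generate_tree(10, 0, 0), "birth_rate")
  expect_error(generate_tree(10, 1, 1.5), "death_rate")
})

test_that("pure-birth tree heights match the Yule closed form", {
  # E[height | n tips, rate b] = sum_{k=2}^{n} 1/(b k) for the conditioned
  # Yule process; Monte-Carlo mean over seeds must sit within 3 SE
  n <- 40; b <- 1
  hs <- vapply(1:150, function(s)
    tree_height(generate_tree(n, b, 0, seed = s)), 0)
  expected <- sum(1 / (b * (2:n)))
  expect_lt(abs(mean(hs) - expected), 3 * stats::sd(hs) / sqrt(length(hs)))
})

test_that("Mk simulation honours zero rates, the 2-state kernel and lambda", {
  tr <- generate_tree(30, 1, 0, seed = 3)
  Q0 <- matrix(0, 2, 2)
  sim <- simulate_character(tr, Q0, root_state = 1, seed = 5)
  expect_true(all(sim$tip_states == 1))

  # single branch of length t: P(change) = (1 - exp(-2 r t)) / 2
  two <- ape::read.tree(text = "(A:1,B:0):0;")
  r <- 0.7; t_br <- 1
  Q <- build_q("ER", 2, r)
  changed <- vapply(1:4000, function(s)
    simulate_character(two, Q, root_state = 0, seed = s)$tip_states[["A"]] == 1,
    TRUE)
  p_true <- (1 - exp(-2 * r * t_br)) / 2
  mc_sd <- sqrt(p_true * (1 - p_true) / length(changed))
  expect_lt(abs(mean(changed) - p_true), 3 * mc_sd)

  # lambda = 1 equals the untransformed simulation under the same seed
  s1 <- simulate_character(tr, Q, lam = 1, seed = 11)
  s2 <- simulate_character(tr, Q, seed = 11)
  expect_identical(s1$tip_states, s2$tip_states)

  # malformed Q
  expect_error(simulate_character(tr, matrix(c(-1, 0.5, 0.5, -0.5), 2, 2)),
               "sum to zero")
})

test_that("lambda = 0 makes tip states independent of phylogenetic distance", {
  tr <- generate_tree(100, 1, 0, seed = 9)
  Q <- build_q("ER", 2, 1.5 / tree_height(tr))
  sim <- simulate_character(tr, Q, lam = 0, seed = 13)
  d <- ape::cophenetic.phylo(tr)
  same <- outer(sim$tip_states[rownames(d)], sim$tip_states[colnames(d)], "==")
  stat <- function(m) mean(d[m & upper.tri(d)]) - mean(d[!m & upper.tri(d)])
  obs <- stat(same)
  perm <- vapply(1:199, function(i) {
    set.seed(i)
    p <- sample(rownames(d))
    stat(outer(sim$tip_states[p], sim$tip_states[p], "=="))
  }, 0)
  p_val <- (1 + sum(abs(perm) >= abs(obs))) / 200
  expect_gt(p_val, 0.01)
})

test_that("tip-state frequencies converge to the stationary distribution", {
  # long single branch, asymmetric 2-state rates
  two <- ape::read.tree(text = "(A:60,B:0):0;")
  Q <- build_q("ARD", 2, c(0.3, 0.1))
  pi1 <- 0.3 / 0.4  # stationary probability of state 1
  tips <- vapply(1:3000, function(s)
    simulate_character(two, Q, root_state = 0, seed = s)$tip_states[["A"]], 0L)
  mc_sd <- sqrt(pi1 * (1 - pi1) / length(tips))
  expect_lt(abs(mean(tips == 1) - pi1), 3 * mc_sd)
})

test_that("surface image generator records consistent ground truth", {
  g0 <- generate_surface_image("smooth", noise_sd = 5, seed = 3)
  expect_identical(g0$truth_state, "smooth")
  expect_length(g0$truth_contours, 0)
  expect_error(generate_surface_image("smooth", density = 1), "smooth")

  gs <- generate_surface_image("straight_channels", angle_sd = 5,
                               noise_sd = 5, seed = 3)
  ang <- vapply(gs$truth_contours, `[[`, 0, "orientation")
  expect_lt(axial_angle_sd(ang), 25)

  gl <- generate_surface_image("labyrinthine_channels", angle_sd = 40,
                               noise_sd = 5, seed = 3)
  angl <- vapply(gl$truth_contours, `[[`, 0, "orientation")
  expect_gt(axial_angle_sd(angl), 25)

  # polygons inside image bounds; pixels deterministic given the seed
  for (tc in gl$truth_contours) {
    expect_true(all(tc$polygon >= 0 & tc$polygon <= 255))
  }
  g2 <- generate_surface_image("labyrinthine_channels", angle_sd = 40,
                               noise_sd = 5, seed = 3)
  expect_identical(gl$pixels, g2$pixels)

  # PNG + truth JSON round trip
  png_f <- tempfile(fileext = ".png"); json_f <- tempfile(fileext = ".json")
  write_ground_truth(gs, png_f, json_f)
  back <- png::readPNG(png_f)
  expect_equal(dim(back), dim(gs$pixels))
  truth <- jsonlite::read_json(json_f, simplifyVector = TRUE)
  expect_identical(truth$state, "straight_channels")
})

test_that("character matrices have one state per taxon and honour coupling", {
  tr <- generate_tree(50, 1, 0, seed = 2)
  m <- generate_character_matrix(tr, seed = 4)
  expect_equal(dim(m), c(50, 6))
  expect_false(anyNA(m))
  expect_setequal(m$species, tr$tip.label)

  mc <- generate_character_matrix(tr, couple = c("cell_shape", "cell_border"),
                                  seed = 4)
  # coupled columns are a deterministic function of each other
  tab <- table(mc$cell_border, mc$cell_shape)
  expect_true(all(rowSums(tab > 0) == 1))

  f <- tempfile(fileext = ".csv")
  write_character_matrix(mc, f)
  expect_identical(read_character_matrix(f), mc)
})

test_that("uncoupled characters show no association beyond the permutation null", {
  tr <- generate_tree(200, 1, 0, seed = 6)
  m <- generate_character_matrix(tr, seed = 8)
  cramers_v <- function(a, b) {
    tab <- table(a, b)
    chi <- suppressWarnings(stats::chisq.test(tab)$statistic)
    sqrt(chi / (sum(tab) * (min(dim(tab)) - 1)))
  }
  obs <- cramers_v(m$cell_shape, m$ridge)
  perm <- vapply(1:199, function(i) {
    set.seed(i); cramers_v(m$cell_shape, sample(m$ridge))
  }, 0)
  expect_gt((1 + sum(perm >= obs)) / 200, 0.01)
})
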