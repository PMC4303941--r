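test_that("SOM training honors degenerate and structured inputs", {
  # one profile repeated: every protein on one node, code equals the profile
  x <- matrix(rep(c(0.2, -0.1, 0.4, -0.5), each = 100), 100, 4,
              dimnames = list(sprintf("P%03d", 1:100), NULL))
  m <- suppressWarnings(train_som(x, som_params(rows = 4, cols = 4, epochs = 10,
                                                radius_init = 2, seed = 1)))
  expect_equal(length(unique(m$assignment)), 1L)
  node <- unique(m$assignment)
  expect_equal(unname(m$codes[node, ]), c(0.2, -0.1, 0.4, -0.5), tolerance = 1e-8)

  # identical profiles always co-locate, even in mixed data
  toy <- toy_profiles()
  x2 <- rbind(toy$x, dup1 = toy$x[1, ], dup2 = toy$x[1, ])
  m2 <- suppressWarnings(train_som(x2, som_params(rows = 5, cols = 5, epochs = 15,
                                                  radius_init = 3, seed = 1)))
  expect_equal(unname(m2$assignment["dup1"]), unname(m2$assignment["dup2"]))
  expect_equal(unname(m2$assignment["dup1"]), unname(m2$assignment["P001"]))

  expect_error(train_som(x[, 1, drop = FALSE], som_params(rows = 4, cols = 4)),
               "two time points")
})

test_that("training reduces quantization error and is seed-deterministic", {
  toy <- toy_profiles()
  p <- som_params(rows = 6, cols = 6, epochs = 25, radius_init = 3, seed = 7,
                  init = "random")
  m1 <- suppressWarnings(train_som(toy$x, p))
  m2 <- suppressWarnings(train_som(toy$x, p))
  expect_identical(m1$codes, m2$codes)
  expect_identical(m1$assignment, m2$assignment)
  expect_lte(m1$qe_final, m1$qe_initial)
})

test_that("with a vanishing neighborhood the SOM approaches k-means quality", {
  # oracle: final mean squared quantization distance within 10% of k-means
  # at equal K on a small instance
  set.seed(3)
  x <- matrix(rnorm(300 * 8), 300, 8, dimnames = list(sprintf("P%03d", 1:300), NULL))
  m <- suppressWarnings(train_som(x, som_params(rows = 5, cols = 5, epochs = 60,
                                                radius_init = 2.5,
                                                radius_final = 0.05, seed = 2)))
  msd_som <- mean(rowSums((x - m$codes[m$assignment, ])^2))
  km <- kmeans(x, centers = 25, nstart = 10, iter.max = 100)
  msd_km <- km$tot.withinss / nrow(x)
  expect_lt(msd_som, msd_km * 1.10)
})

test_that("planted antiphase clusters separate on the grid (topology preservation)", {
  toy <- toy_profiles(n_per = 200)
  m <- suppressWarnings(train_som(toy$x, som_params(rows = 10, cols = 10,
                                                    epochs = 40, radius_init = 5,
                                                    seed = 1)))
  g <- somscape:::node_grid(10, 10)
  coords <- cbind(g$row[m$assignment], g$col[m$assignment])
  up <- toy$labels == "up"
  centroid_up <- colMeans(coords[up, , drop = FALSE])
  centroid_down <- colMeans(coords[!up, , drop = FALSE])
  between <- sqrt(sum((centroid_up - centroid_down)^2))
  spread <- function(cc, ctr) median(sqrt(rowSums(sweep(cc, 2, ctr)^2)))
  expect_gt(between, spread(coords[up, , drop = FALSE], centroid_up))
  expect_gt(between, spread(coords[!up, , drop = FALSE], centroid_down))
})

test_that("portraits expose one sample's meta-feature landscape", {
  toy <- toy_profiles()
  m <- suppressWarnings(train_som(toy$x, som_params(rows = 5, cols = 5, epochs = 10,
                                                    radius_init = 2.5, seed = 1)))
  pt <- render_portrait(m, 1)
  expect_equal(nrow(pt), 25)
  expect_equal(pt$value, unname(m$codes[, 1]))
  expect_error(render_portrait(m, 99), "out of range")
  # constant-zero data gives a flat mid-scale portrait
  z <- matrix(0, 30, 4, dimnames = list(sprintf("P%02d", 1:30), NULL))
  mz <- suppressWarnings(train_som(z, som_params(rows = 3, cols = 3, epochs = 5,
                                                 radius_init = 1.5, seed = 1)))
  expect_true(all(render_portrait(mz, 2)$value == 0))
  # duplicated samples give identical portraits
  x2 <- cbind(toy$x, toy$x[, 1])
  m2 <- suppressWarnings(train_som(x2, som_params(rows = 5, cols = 5, epochs = 10,
                                                  radius_init = 2.5, seed = 1)))
  expect_equal(render_portrait(m2, 1)$value,
               render_portrait(m2, ncol(x2))$value)
})

test_that("population map conserves protein counts", {
  toy <- toy_profiles()
  m <- suppressWarnings(train_som(toy$x, som_params(rows = 5, cols = 5, epochs = 10,
                                                    radius_init = 2.5, seed = 1)))
  pop <- population_map(m)
  expect_equal(sum(pop$n), nrow(toy$x))
  # single-protein dataset: one node count 1, rest 0
  one <- suppressWarnings(train_som(toy$x[1, , drop = FALSE],
                                    som_params(rows = 3, cols = 3, epochs = 5,
                                               radius_init = 1.5, seed = 1)))
  pop1 <- population_map(one)
  expect_equal(sort(pop1$n, decreasing = TRUE)[1:2], c(1L, 0L))
})

test_that("variance profiles scale quadratically and warn on centralized input", {
  toy <- toy_profiles()
  m <- suppressWarnings(train_som(toy$x, som_params(rows = 5, cols = 5, epochs = 10,
                                                    radius_init = 2.5, seed = 1)))
  vp <- variance_profile(m)
  m2 <- m; m2$codes <- m$codes * 2
  expect_equal(variance_profile(m2)$variance, 4 * vp$variance)
  # landscape constant at every time point -> all-zero profile
  mflat <- m; mflat$codes <- matrix(1, nrow(m$codes), ncol(m$codes))
  expect_true(all(variance_profile(mflat)$variance == 0))
  mc <- m; mc$centralized <- TRUE
  expect_warning(variance_profile(mc), "centralized")
})

test_that("peak detection finds separated local maxima", {
  expect_equal(detect_peaks(c(0, 1, 0, 2, 0), min_separation = 1), c(2L, 4L))
  expect_equal(detect_peaks(1:10), integer(0))      # monotone
  expect_equal(detect_peaks(10:1), integer(0))
  # greedy thinning keeps the larger of two close peaks
  expect_equal(detect_peaks(c(0, 3, 0, 2, 0, 0, 5, 0), min_separation = 3),
               c(2L, 7L))
  # peaks reported on the week axis
  expect_equal(detect_peaks(c(0, 1, 0), weeks = c(10, 20, 30)), 20L)
  expect_error(detect_peaks(c(1, 2)), "length")
})
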