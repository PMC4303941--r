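test_that("percentile selection sizes, tie handling and polarity disjointness", {
  model <- fixture_model()
  spots <- select_percentile_spots(model, mode = "averaged")
  over_nodes <- unlist(spots$nodes[spots$polarity == "over"])
  under_nodes <- unlist(spots$nodes[spots$polarity == "under"])
  # ceiling(1600 * 2 / 100) = 32 per polarity, plus any cutoff ties
  avg <- rowMeans(model$codes)
  expect_setequal(over_nodes, which(avg >= sort(avg, decreasing = TRUE)[32]))
  expect_setequal(under_nodes, which(avg <= sort(avg)[32]))
  expect_gte(length(over_nodes), 32)
  expect_length(intersect(over_nodes, under_nodes), 0)

  union_spots <- fixture_spots()
  expect_length(intersect(unlist(union_spots$nodes[union_spots$polarity == "over"]),
                          unlist(union_spots$nodes[union_spots$polarity == "under"])),
                0)
  expect_error(select_percentile_spots(model, percentile = 0), "percentile")
  expect_error(select_percentile_spots(model, percentile = 50), "percentile")

  # boundary ties are included: a landscape with 40 equal-max nodes
  m <- model
  m$codes <- matrix(0, 100, 5)
  m$codes[1:40, ] <- 1
  m$weeks <- 1:5
  m$params <- som_params(rows = 10, cols = 10, epochs = 10, radius_init = 5)
  m$assignment <- stats::setNames(rep(1L, 10), sprintf("P%d", 1:10))
  tied <- select_percentile_spots(m, mode = "averaged", percentile = 2)
  expect_equal(sum(lengths(tied$nodes[tied$polarity == "over"])), 40)
})

test_that("connected-component segmentation matches a brute-force flood fill", {
  # block mask: one 4x8 rectangle is exactly one spot
  block <- as.vector(outer(0:3, 1:8, function(r, c) r * 40 + c))
  comps <- somscape:::node_components(block, 40, 40)
  expect_length(comps, 1)
  expect_setequal(comps[[1]], block)

  # random masks against the oracle
  set.seed(11)
  for (i in 1:25) {
    rows <- sample(5:40, 1); cols <- sample(5:40, 1)
    mask <- sort(sample(rows * cols, ceiling(rows * cols * runif(1, 0.05, 0.4))))
    got <- canon_components(somscape:::node_components(mask, rows, cols))
    want <- canon_components(flood_fill_components(mask, rows, cols))
    expect_identical(got, want)
  }
})

test_that("spot members, profiles and conservation agree with the population map", {
  model <- fixture_model()
  spots <- fixture_spots()
  pop <- population_map(model)
  for (i in seq_len(nrow(spots))) {
    expect_equal(spots$n_proteins[i], sum(pop$n[spots$nodes[[i]]]))
  }
  # one-node spot profile is that node's code row
  one <- spots[which(spots$n_nodes == 1)[1], ]
  if (nrow(one) == 1 && !is.na(one$id)) {
    prof <- spot_profile(one, model)
    expect_equal(prof$value, unname(model$codes[one$nodes[[1]], ]))
  }
  # over-spot profiles have positive maxima
  over <- spots[spots$polarity == "over", ]
  expect_true(all(vapply(over$profile, max, numeric(1)) > 0))
  # letters are assigned in decreasing node-count order
  expect_true(all(diff(spots$n_nodes) <= 0))
})

test_that("k-means spots recover planted antiphase clusters", {
  toy <- toy_profiles(n_per = 200)
  m <- suppressWarnings(train_som(toy$x, som_params(rows = 10, cols = 10,
                                                    epochs = 40, radius_init = 5,
                                                    seed = 1)))
  expect_error(select_kmeans_spots(m, k = 1), ">= 2")
  expect_error(select_kmeans_spots(m, k = 1000), "exceed")
  sp <- select_kmeans_spots(m, k = 2, seed = 1)
  expect_equal(sum(sp$n_nodes), 100)   # cluster sizes sum to K
  # protein-level agreement with planted labels; grid components of one
  # k-means cluster share a profile, so merge them back via majority label
  lab_pred <- rep(NA_character_, nrow(toy$x))
  for (i in seq_len(nrow(sp))) {
    idx <- match(sp$proteins[[i]], rownames(toy$x))
    majority <- names(which.max(table(toy$labels[idx])))
    lab_pred[idx] <- majority
  }
  expect_gte(somscape:::adjusted_rand_index(lab_pred, toy$labels), 0.9)

  corr <- select_correlation_spots(m, threshold = 0.8)
  expect_gte(nrow(corr), 1)
  # cross-method agreement on cluster counts (within +/- 2)
  expect_lte(abs(nrow(corr) - nrow(sp)), 2)
})

test_that("correlation spots group identical profiles into one map-wide spot", {
  m <- fixture_model()
  flat <- m
  flat$params <- som_params(rows = 8, cols = 8, epochs = 10, radius_init = 4)
  flat$codes <- matrix(rep(sin(1:6), each = 64), 64, 6)
  flat$weeks <- 1:6
  flat$assignment <- stats::setNames(rep(1L, 5), sprintf("P%d", 1:5))
  sp <- select_correlation_spots(flat, threshold = 0.9)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$n_nodes, 64)
  expect_error(select_correlation_spots(m, threshold = 0), "threshold")
})

test_that("spot phases map onto the reference schedule", {
  mk_spot <- function(phase) tibble::tibble(phase_hat = phase)
  expect_equal(classify_spot_phase(mk_spot(3)), "early")
  expect_equal(classify_spot_phase(mk_spot(9)), "intermediate")
  expect_equal(classify_spot_phase(mk_spot(14)), "late")
  expect_equal(classify_spot_phase(mk_spot(-2)), "early")   # pre-isolation
  expect_equal(classify_spot_phase(mk_spot(17)), "late")    # post-isolation
})

test_that("summary maps flag each node with at most one polarity", {
  model <- fixture_model()
  sm <- summary_map(fixture_spots(), model)
  expect_equal(nrow(sm), 1600)
  expect_true(all(sm$flag %in% c("over", "under", "none")))
  expect_true(all(is.na(sm$spot[sm$flag == "none"])))
})

test_that("spot tables round-trip through TSV", {
  spots <- fixture_spots()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spot_table(spots, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(spots))
  expect_equal(back$id, spots$id)
  expect_equal(back$n_proteins, spots$n_proteins)
})
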