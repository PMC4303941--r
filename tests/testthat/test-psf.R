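kgml_fixture <- function() {
  system.file("extdata", "synthetic_pathway.xml", package = "somscape")
}

test_that("KGML parsing builds signed graphs and logs preprocessing", {
  g <- parse_kgml(kgml_fixture())
  expect_equal(nrow(g$nodes), 5)
  # binding relation dropped, one back-edge of the 3<->4 cycle removed
  expect_equal(g$dropped_relations, 1L)
  expect_equal(g$removed_edges, 1L)
  expect_equal(nrow(g$edges), 3)
  expect_setequal(g$sinks, c("4", "5"))
  expect_true("1" %in% g$sources)
  expect_equal(g$nodes$members[[1]], c("SYN0001", "SYN0002"))
  # malformed XML is an error
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<pathway><entry id='1'", bad)
  expect_error(parse_kgml(bad), "malformed XML")
})

test_that("edge-list pathways build and reject unknown interaction types", {
  chain <- pathway_from_edges(
    data.frame(src = c("a", "b"), dst = c("b", "c"), type = "activation")
  )
  expect_equal(chain$sources, "a")
  expect_equal(chain$sinks, "c")
  expect_error(
    pathway_from_edges(data.frame(src = "a", dst = "b", type = "binds")),
    "activation or inhibition"
  )
  # a 2-cycle loses its back edge
  loop <- pathway_from_edges(
    data.frame(src = c("a", "b", "b"), dst = c("b", "a", "c"), type = "activation")
  )
  expect_equal(loop$removed_edges, 1L)
})

test_that("node fold changes average measured members and default to neutral", {
  g <- pathway_from_edges(
    data.frame(src = "n1", dst = "n2", type = "activation"),
    members = list(n1 = c("P1", "P2"), n2 = "P9")
  )
  fc <- node_fold_change(g, c(P1 = 2, P2 = 4))
  expect_equal(unname(fc["n1"]), 3)
  expect_equal(unname(fc["n2"]), 1)  # unmeasured -> neutral
  expect_error(node_fold_change(g, c(P1 = -1)), "positive")
})

test_that("PSF propagation follows the stated activation/inhibition rules", {
  chain <- pathway_from_edges(
    data.frame(src = "A", dst = "B", type = "activation")
  )
  # all FC = 1 -> neutral sink
  res <- compute_psf(chain, c(A = 1, B = 1))
  expect_equal(res$signal[res$node == "B"], 1)
  # activation multiplies: FC_A = 2, FC_B = 3 -> 6
  res2 <- compute_psf(chain, c(A = 2, B = 3))
  expect_equal(res2$signal[res2$node == "B"], 6)
  # inhibition divides: FC_A = 2, FC_B = 4 -> 0.5
  inhib <- pathway_from_edges(
    data.frame(src = "A", dst = "B", type = "inhibition")
  )
  res3 <- compute_psf(inhib, c(A = 2, B = 4))
  expect_equal(res3$signal[res3$node == "B"], 0.5)
})

test_that("linear chains obey the closed-form product oracle", {
  set.seed(51)
  for (rep in 1:40) {
    len <- sample(2:10, 1)
    ids <- sprintf("n%02d", seq_len(len))
    types <- sample(c("activation", "inhibition"), len - 1, replace = TRUE)
    g <- pathway_from_edges(
      data.frame(src = ids[-len], dst = ids[-1], type = types)
    )
    fc <- stats::setNames(runif(len, 0.2, 5), ids)
    res <- compute_psf(g, fc)
    # closed form: source FC, then multiply or divide by each downstream FC
    want <- fc[[1]]
    for (i in 2:len) {
      want <- if (types[i - 1] == "activation") want * fc[[i]] else want / fc[[i]]
    }
    expect_equal(res$signal[res$node == ids[len]], want, tolerance = 1e-12)
  }
})

random_dag <- function(n, p = 0.3, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) {
      edges <- rbind(edges, data.frame(
        src = ids[i], dst = ids[j],
        type = sample(c("activation", "inhibition"), 1)
      ))
    }
  }
  if (is.null(edges)) edges <- data.frame(src = ids[1], dst = ids[2],
                                          type = "activation")
  pathway_from_edges(edges)
}

test_that("neutral fold changes give unit signals on random DAGs", {
  for (s in 1:15) {
    g <- random_dag(sample(4:12, 1), seed = 60 + s)
    fc <- stats::setNames(rep(1, nrow(g$nodes)), g$nodes$id)
    res <- compute_psf(g, fc)
    expect_true(all(res$signal == 1))
  }
})

test_that("signals are invariant to the topological order used", {
  # an alternative valid topological order (Kahn with reversed tie-break)
  topo_alt <- function(graph) {
    ids <- graph$nodes$id
    indeg <- stats::setNames(rep(0L, length(ids)), ids)
    for (t in graph$edges$to) indeg[[t]] <- indeg[[t]] + 1L
    out <- character(0)
    ready <- ids[indeg == 0]
    while (length(ready)) {
      v <- sort(ready, decreasing = TRUE)[1]
      ready <- setdiff(ready, v)
      out <- c(out, v)
      for (u in graph$edges$to[graph$edges$from == v]) {
        indeg[[u]] <- indeg[[u]] - 1L
        if (indeg[[u]] == 0) ready <- c(ready, u)
      }
    }
    out
  }
  for (s in 1:10) {
    g <- random_dag(sample(5:10, 1), seed = 80 + s)
    set.seed(s)
    fc <- stats::setNames(runif(nrow(g$nodes), 0.3, 4), g$nodes$id)
    res1 <- compute_psf(g, fc)
    g2 <- g
    g2$topo <- topo_alt(g)
    res2 <- compute_psf(g2, fc)
    expect_equal(res1$signal, res2$signal, tolerance = 1e-12)
  }
})

test_that("PSF time profiles track fold changes over the week grid", {
  co <- fixture_cohort()
  mm <- build_mean_volunteer(co$volunteers)
  pw <- demo_pathways(co$truth)
  prof <- psf_time_profiles(pw$demo_activation_chain, mm)
  expect_equal(sort(unique(prof$week)), mm$weeks)
  expect_true(all(prof$signal > 0))
  # constant series give constant profiles
  const <- somscape:::new_abundance_matrix(
    matrix(0.5, 20, 5, dimnames = list(sprintf("SYN%04d", 1:20), 1:5)), 1:5
  )
  g <- pathway_from_edges(
    data.frame(src = "a", dst = "b", type = "activation"),
    members = list(a = "SYN0001", b = "SYN0002")
  )
  pc <- psf_time_profiles(g, const)
  expect_equal(length(unique(round(pc$signal, 12))), 1)
  expect_error(psf_time_profiles(g, fixture_delta()), "non-centralized")
})

test_that("PSF profiles match the spots they were built from", {
  co <- fixture_cohort()
  spots <- fixture_spots()
  mm <- build_mean_volunteer(co$volunteers)
  pw <- demo_pathways(co$truth)
  prof <- psf_time_profiles(pw$demo_activation_chain, mm)
  matches <- match_profiles(prof, spots)
  expect_true(all(abs(matches$r[!matches$flagged]) <= 1 + 1e-12))
  expect_true(any(matches$best))
  # a PSF profile equal to a spot profile correlates perfectly with it
  fake <- tibble::tibble(sink = "fake", week = spots$profile[[1]] |> names() |>
                           as.integer(), signal = spots$profile[[1]])
  m2 <- match_profiles(fake, spots)
  expect_equal(m2$r[m2$spot == spots$id[1]], 1)
  # permuting the time order destroys the match
  set.seed(71)
  fake_perm <- fake
  fake_perm$signal <- sample(fake_perm$signal)
  m3 <- match_profiles(fake_perm, spots)
  expect_lt(m3$r[m3$spot == spots$id[1]], 0.9)
})
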