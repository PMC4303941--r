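test_that("Fisher enrichment matches the closed-form hypergeometric", {
  # universe 10, set 5, spot 5, overlap 5 -> 1 / C(10,5)
  u <- sprintf("P%02d", 1:10)
  res <- fisher_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$p_fisher, 1 / choose(10, 5))
  expect_equal(res$overlap, 5)
  # empty set degenerates to p = 1
  expect_equal(fisher_enrichment(u[1:5], character(0), u)$p_fisher, 1)
  # out-of-universe members are dropped before testing
  res2 <- fisher_enrichment(u[1:5], c(u[1:3], "QQQ"), u)
  expect_equal(res2$n_set, 3)
  expect_error(fisher_enrichment(u[1:2], u[1:2], character(0)), "universe")
})

test_that("Fisher p equals exhaustive enumeration on universes up to 20", {
  set.seed(41)
  for (rep in 1:60) {
    n_u <- sample(5:20, 1)
    u <- sprintf("P%02d", seq_len(n_u))
    set <- sample(u, sample(0:n_u, 1))
    spot <- sample(u, sample(1:n_u, 1))
    res <- fisher_enrichment(spot, set, u)
    want <- if (length(set) == 0) 1 else {
      hyper_brute(res$overlap, res$n_set, res$n_spot, res$n_universe)
    }
    expect_equal(res$p_fisher, want, tolerance = 1e-12)
  }
  # overlap at the independence expectation is never significant
  u <- sprintf("P%02d", 1:20)
  res <- fisher_enrichment(u[1:10], u[c(1:5, 11:15)], u)  # overlap 5 = 10*10/20
  expect_gte(res$p_fisher, 0.5)
})

test_that("GSZ rewards overlap and overexpression and is centered under resampling", {
  u <- sprintf("P%03d", 1:200)
  scores <- stats::setNames(rep(0, 200), u)
  scores[1:20] <- 0.4                      # the "spot" with delta-E 0.4
  # the spot itself scores highest among candidate sets
  competitors <- lapply(seq(30, 180, by = 30), function(s) u[s + 1:20])
  gsz_all <- vapply(c(list(u[1:20]), competitors), function(s) gsz_score(scores, s),
                    numeric(1))
  expect_equal(which.max(gsz_all), 1L)
  # random same-size sets center near 0
  set.seed(42)
  null <- vapply(1:1000, function(i) gsz_score(scores, sample(u, 20)), numeric(1))
  expect_lt(abs(mean(null)), 0.15)
  # monotone in the members' delta-E at fixed overlap
  grades <- seq(0.1, 1, by = 0.1)
  gsz_grad <- vapply(grades, function(g) {
    s <- scores; s[1:20] <- g
    gsz_score(s, u[1:20])
  }, numeric(1))
  expect_true(all(diff(gsz_grad) > 0))
  # set disjoint from the universe is flagged
  expect_true(is.na(gsz_score(scores, c("X1", "X2"))))
})

test_that("spot enrichment tables combine Fisher, GSZ and BH per spot", {
  co <- fixture_cohort()
  delta <- fixture_delta()
  spots <- fixture_spots()
  gsc <- truth_gene_sets(co$truth)
  res <- enrich_spots(head(spots, 4), gsc, delta)
  expect_true(all(res$overlap <= pmin(res$n_set, res$n_spot)))
  expect_true(all(res$p_fisher > 0 & res$p_fisher <= 1))
  # BH is monotone within each spot: adjusted p never reorders raw p
  for (sid in unique(res$id)) {
    sub <- res[res$id == sid, ]
    expect_true(all(diff(sub$p_adjusted[order(sub$p_fisher)]) >= -1e-15))
  }
  # each large spot's best set is a planted module set
  big <- res[res$id %in% spots$id[spots$n_proteins > 50], ]
  for (sid in unique(big$id)) {
    sub <- big[big$id == sid, ]
    expect_match(sub$set[which.min(sub$p_fisher)], "^set_M")
  }
})

test_that("density maps integrate to set size and localize planted modules", {
  model <- fixture_model()
  co <- fixture_cohort()
  # all proteins: density integrates to N
  dm <- tissue_density_map(co$truth$protein, model, bandwidth = 2)
  expect_equal(sum(dm$density), length(co$truth$protein), tolerance = 1e-6)
  expect_true(all(dm$density >= 0))
  # empty overlap: flat zero map
  dm0 <- tissue_density_map(c("NOPE1", "NOPE2"), model)
  expect_true(all(dm0$density == 0))
  # a planted module's set is densest on the nodes that host its proteins
  m01 <- co$truth$protein[co$truth$label == "M01"]
  dmm <- tissue_density_map(m01, model, bandwidth = 1.5)
  host_nodes <- unique(model$assignment[m01])
  # density concentrates on the module's blob: host nodes carry far more
  # density than the rest of the map, and the global density peak lies on or
  # next to a host node (smoothing can move it into a hole of the blob)
  expect_gt(mean(dmm$density[host_nodes]),
            5 * mean(dmm$density[-host_nodes]))
  peak <- dmm[which.max(dmm$density), ]
  host_xy <- dmm[dmm$node %in% host_nodes, ]
  cheb <- pmax(abs(host_xy$row - peak$row), abs(host_xy$col - peak$col))
  expect_lte(min(cheb), 1)
})

test_that("set profiles average member rows", {
  delta <- fixture_delta()
  co <- fixture_cohort()
  # whole-universe set on centralized data: the profile is the column mean
  # of delta-E, whose time average is exactly zero (row centering)
  sp_all <- set_profile(co$truth$protein, delta)
  expect_equal(sp_all$value, unname(colMeans(delta$values)))
  expect_equal(mean(sp_all$value), 0, tolerance = 1e-9)
  # singleton set returns that row
  p1 <- co$truth$protein[1]
  expect_equal(set_profile(p1, delta)$value, unname(delta$values[p1, ]))
  # planted early module peaks in the early phase
  m01 <- co$truth$protein[co$truth$label == "M01"]
  prof <- set_profile(m01, delta)
  expect_lte(prof$week[which.max(prof$value)], 6)
  expect_error(set_profile("NOPE", delta), "overlap")
})

test_that("enrichment heatmaps cluster sets and round-trip", {
  co <- fixture_cohort()
  spots <- head(fixture_spots(), 6)
  res <- enrich_spots(spots, truth_gene_sets(co$truth), fixture_delta())
  hm <- enrichment_heatmap(res, spots)
  expect_setequal(colnames(hm$matrix), spots$id)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_heatmap(hm, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), hm$matrix, ignore_attr = TRUE)
  expect_error(enrichment_heatmap(res[res$id == res$id[1], ], spots), "at least 2")
})
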