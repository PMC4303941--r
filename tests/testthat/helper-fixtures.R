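# Shared, lazily built fixtures. The default cohort + full 40x40 SOM cost
# ~15 s; they are trained once and reused across test files.
.fixtures <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- generate_cohort(cohort_design(), seed = 1)
  }
  .fixtures$cohort
}

fixture_delta <- function() {
  if (is.null(.fixtures$delta)) {
    .fixtures$delta <- centralize(build_mean_volunteer(fixture_cohort()$volunteers))
  }
  .fixtures$delta
}

fixture_model <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$model <- train_som(fixture_delta(), som_params(seed = 1))
  }
  .fixtures$model
}

fixture_spots <- function() {
  if (is.null(.fixtures$spots)) {
    .fixtures$spots <- select_percentile_spots(fixture_model())
  }
  .fixtures$spots
}

# Planted module phases/periods of default_module_specs(), used by recovery
# and phase checks.
fixture_module_truth <- function() {
  specs <- default_module_specs()
  data.frame(
    label = vapply(specs, `[[`, character(1), "name"),
    phase = vapply(specs, `[[`, numeric(1), "phase"),
    period = vapply(specs, function(s) if (s$shape == "cosine") s$period else NA_real_,
                    numeric(1))
  )
}

# Small matrix of distinguishable profiles for cheap SOM tests.
toy_profiles <- function(n_per = 60, m = 12, seed = 42) {
  set.seed(seed)
  t <- seq_len(m)
  a <- cos(2 * pi * t / m)
  base <- rbind(
    matrix(rep(a, n_per), ncol = m, byrow = TRUE),
    matrix(rep(-a, n_per), ncol = m, byrow = TRUE)
  )
  x <- base + matrix(rnorm(2 * n_per * m, sd = 0.1), ncol = m)
  rownames(x) <- sprintf("P%03d", seq_len(2 * n_per))
  list(x = x, labels = rep(c("up", "down"), each = n_per))
}

# Brute-force flood fill (4/8-neighborhood) used as the independent oracle
# for connected-component segmentation.
flood_fill_components <- function(nodes, rows, cols) {
  if (!length(nodes)) return(list())
  grid_row <- function(n) (n - 1) %/% cols + 1
  grid_col <- function(n) (n - 1) %% cols + 1
  in_mask <- logical(rows * cols)
  in_mask[nodes] <- TRUE
  seen <- logical(rows * cols)
  comps <- list()
  for (start in sort(nodes)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      r <- grid_row(v); c <- grid_col(v)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > rows || cc < 1 || cc > cols) next
        u <- (rr - 1) * cols + cc
        if (in_mask[u] && !seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
      }
    }
    comps <- c(comps, list(sort(comp)))
  }
  comps
}

# Canonical form for comparing component lists.
canon_components <- function(comps) {
  comps <- lapply(comps, function(x) as.integer(sort(x)))
  comps[order(vapply(comps, min, numeric(1)))]
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Direct evaluation of the weighted-topological-overlap formula by explicit
# summation (independent oracle for wto_scores()).
wto_brute <- function(a) {
  n <- nrow(a)
  w <- matrix(0, n, n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    mediated <- 0
    for (u in seq_len(n)) if (u != i && u != j) mediated <- mediated + a[i, u] * a[u, j]
    w[i, j] <- (mediated + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  w
}

# Exhaustive hypergeometric upper tail (independent oracle for Fisher p).
hyper_brute <- function(overlap, n_set, n_spot, n_universe) {
  js <- 0:min(n_set, n_spot)
  mass <- choose(n_set, js) * choose(n_universe - n_set, n_spot - js) /
    choose(n_universe, n_spot)
  sum(mass[js >= overlap])
}
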