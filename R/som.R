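#' SOM training parameters
#'
#' Parameters for the batch self-organizing map. The default 40x40 grid gives
#' K = 1600 meta-features. Training is batch-style with a Gaussian
#' neighborhood whose radius decays linearly from `radius_init` to
#' `radius_final` over `epochs` sweeps; batch updates remove any dependence
#' on presentation order, so a learning-rate schedule is not needed.
#'
#' @param rows,cols Grid dimensions (K = rows * cols).
#' @param epochs Number of batch sweeps.
#' @param radius_init,radius_final Neighborhood radius schedule (strictly
#'   decreasing).
#' @param init `"pca"` (linear initialization on the first two principal
#'   components; deterministic) or `"random"` (seeded).
#' @param seed Seed for random initialization.
#' @return A `som_params` object.
#' @export
som_params <- function(rows = 40, cols = 40, epochs = 100,
                       radius_init = max(rows, cols) / 2, radius_final = 1,
                       init = c("pca", "random"), seed = 1) {
  init <- match.arg(init)
  if (rows < 2 || cols < 2) abort("grid must be at least 2x2")
  if (radius_final >= radius_init) abort("radius schedule must be strictly decreasing")
  if (epochs < 1) abort("at least one epoch required")
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         epochs = as.integer(epochs), radius_init = radius_init,
         radius_final = radius_final, init = init, seed = as.integer(seed)),
    class = "som_params"
  )
}

# Row-major node index (1-based) <-> grid coordinates.
node_grid <- function(rows, cols) {
  tibble(node = seq_len(rows * cols),
         row = rep(seq_len(rows), each = cols),
         col = rep(seq_len(cols), times = rows))
}

# Squared grid distances between all node pairs (K x K).
grid_dist2 <- function(rows, cols) {
  g <- node_grid(rows, cols)
  outer(g$row, g$row, `-`)^2 + outer(g$col, g$col, `-`)^2
}

# Best-matching unit per data row; ties broken by lowest node index.
bmu_assign <- function(x, codes) {
  scores <- tcrossprod(x, codes) - rep(rowSums(codes^2) / 2, each = nrow(x))
  max.col(scores, ties.method = "first")
}

quantization_error <- function(x, codes, assignment) {
  mean(sqrt(rowSums((x - codes[assignment, , drop = FALSE])^2)))
}

init_codes <- function(x, params) {
  k <- params$rows * params$cols
  g <- node_grid(params$rows, params$cols)
  if (params$init == "random") {
    # random codes around the data mean (not data samples, so the initial
    # quantization error genuinely upper-bounds the trained one)
    set.seed(params$seed)
    mu <- colMeans(x)
    sds <- pmax(apply(x, 2, stats::sd), 1e-8)
    return(matrix(mu, k, ncol(x), byrow = TRUE) +
             matrix(stats::rnorm(k * ncol(x)), k, ncol(x)) *
             rep(sds, each = k))
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = 2)
  # fixed sign convention so initialization is permutation-invariant
  v <- sv$v
  for (j in seq_len(ncol(v))) {
    piv <- which.max(abs(v[, j]))
    if (v[piv, j] < 0) v[, j] <- -v[, j]
  }
  sd1 <- sv$d[1] / sqrt(max(1, nrow(x) - 1))
  sd2 <- if (length(sv$d) > 1) sv$d[2] / sqrt(max(1, nrow(x) - 1)) else 0
  c1 <- if (params$cols > 1) 2 * (g$col - 1) / (params$cols - 1) - 1 else 0
  c2 <- if (params$rows > 1) 2 * (g$row - 1) / (params$rows - 1) - 1 else 0
  codes <- matrix(mu, nrow = k, ncol = ncol(x), byrow = TRUE) +
    outer(c1 * sd1, v[, 1]) +
    (if (ncol(v) > 1) outer(c2 * sd2, v[, 2]) else 0)
  codes
}

#' Train a batch self-organizing map on protein profiles
#'
#' Distributes N protein profiles over a rows x cols grid of meta-feature
#' profiles ("codes"). Each batch sweep assigns every protein to its nearest
#' meta-feature (Euclidean distance, ties to the lowest node index) and then
#' replaces every code by the neighborhood-weighted mean of the assigned
#' profiles, with a Gaussian neighborhood of linearly decaying radius.
#' Training is deterministic for a fixed seed; proteins with identical
#' profiles always land on the same node.
#'
#' @param data An `abundance_matrix` / `differential_matrix`, or a plain
#'   numeric matrix (proteins x time points).
#' @param params A [som_params()].
#' @return A `som_model` with fields `codes` (K x M meta-feature matrix),
#'   `assignment` (protein -> node, 1-based row-major), `weeks`, `params`,
#'   `qe_initial`, `qe_final`, and `centralized`.
#' @export
train_som <- function(data, params = som_params()) {
  centralized <- inherits(data, "differential_matrix")
  weeks <- NULL
  if (inherits(data, "abundance_matrix")) {
    weeks <- data$weeks
    x <- data$values
  } else {
    x <- as.matrix(data)
    weeks <- suppressWarnings(as.integer(colnames(x) %||% character(0)))
    if (length(weeks) != ncol(x) || anyNA(weeks)) weeks <- seq_len(ncol(x))
  }
  if (ncol(x) < 2) abort("at least two time points are required")
  if (anyNA(x)) abort("profiles must not contain NA")
  k <- params$rows * params$cols
  if (nrow(x) < k) {
    warn(sprintf("fewer proteins (%d) than meta-features (%d)", nrow(x), k))
  }

  codes <- init_codes(x, params)
  assignment <- bmu_assign(x, codes)
  qe_initial <- quantization_error(x, codes, assignment)
  d2 <- grid_dist2(params$rows, params$cols)
  radii <- seq(params$radius_init, params$radius_final, length.out = params$epochs)

  for (e in seq_len(params$epochs)) {
    assignment <- bmu_assign(x, codes)
    sums <- rowsum(x, assignment, reorder = FALSE)
    s <- matrix(0, k, ncol(x))
    s[as.integer(rownames(sums)), ] <- sums
    counts <- tabulate(assignment, nbins = k)
    h <- exp(-d2 / (2 * radii[e]^2))
    denom <- as.vector(h %*% counts)
    codes <- (h %*% s) / denom
  }
  assignment <- bmu_assign(x, codes)
  qe_final <- quantization_error(x, codes, assignment)

  structure(
    list(codes = codes, assignment = stats::setNames(assignment, rownames(x)),
         weeks = weeks, params = params, qe_initial = qe_initial,
         qe_final = qe_final, centralized = centralized,
         protein_ids = rownames(x)),
    class = "som_model"
  )
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf(
    "<som_model> %dx%d grid (K = %d), %d proteins, %d time points; QE %.4f -> %.4f\n",
    x$params$rows, x$params$cols, nrow(x$codes), length(x$assignment),
    ncol(x$codes), x$qe_initial, x$qe_final
  ))
  invisible(x)
}

#' @export
glance.som_model <- function(x, ...) {
  tibble(
    k = nrow(x$codes), rows = x$params$rows, cols = x$params$cols,
    n_proteins = length(x$assignment), n_timepoints = ncol(x$codes),
    qe_initial = x$qe_initial, qe_final = x$qe_final,
    centralized = x$centralized
  )
}

#' @export
tidy.som_model <- function(x, ...) {
  g <- node_grid(x$params$rows, x$params$cols)
  tibble(protein = names(x$assignment), node = unname(x$assignment)) |>
    dplyr::left_join(g, by = "node")
}

#' Extract the portrait of one sample
#'
#' The portrait is the vector of all K meta-feature values at one time point,
#' laid out on the grid. Rendered with a symmetric red (high) / blue (low)
#' scale for centralized data.
#'
#' @param model A [train_som()] model.
#' @param sample Sample index (column of the training matrix) or week via
#'   `week =`.
#' @param week Alternative to `sample`: the week index.
#' @return A `som_portrait` tibble (`node`, `row`, `col`, `value`) with the
#'   sample's week as an attribute.
#' @export
render_portrait <- function(model, sample = NULL, week = NULL) {
  stopifnot(inherits(model, "som_model"))
  if (is.null(sample)) {
    if (is.null(week)) abort("give `sample` or `week`")
    sample <- match(week, model$weeks)
    if (is.na(sample)) abort(sprintf("week %s not in model", week))
  }
  if (sample < 1 || sample > ncol(model$codes)) abort("sample index out of range")
  g <- node_grid(model$params$rows, model$params$cols)
  out <- dplyr::mutate(g, value = model$codes[, sample])
  structure(out, class = c("som_portrait", class(out)),
            week = model$weeks[sample], centralized = model$centralized)
}

#' Population map: proteins per meta-feature
#'
#' @param model A `som_model`.
#' @return Tibble (`node`, `row`, `col`, `n`); counts sum to N.
#' @export
population_map <- function(model) {
  stopifnot(inherits(model, "som_model"))
  g <- node_grid(model$params$rows, model$params$cols)
  dplyr::mutate(g, n = tabulate(model$assignment, nbins = nrow(model$codes)))
}

#' Total-abundance variance profile
#'
#' For a model trained on absolute (non-centralized) detection fractions, the
#' variance over the K meta-feature values at each time point estimates the
#' mean squared amplitude of overall abundance as a function of time.
#'
#' @param model A `som_model` trained on non-centralized data (a warning is
#'   issued, and the profile still computed, for centralized input).
#' @return Tibble (`week`, `variance`).
#' @export
variance_profile <- function(model) {
  stopifnot(inherits(model, "som_model"))
  if (model$centralized) {
    warn("variance profile is meant for models trained on non-centralized data")
  }
  tibble(week = model$weeks, variance = apply(model$codes, 2, stats::var))
}

#' Detect local peaks in a time profile
#'
#' Local maxima strictly exceeding both neighbors, greedily thinned (largest
#' first) so that retained peaks are at least `min_separation` weeks apart.
#'
#' @param profile Numeric values, or a tibble with `week` and a value column.
#' @param weeks Week positions (defaults to the tibble's `week` column or
#'   1..length).
#' @param min_separation Minimum spacing between reported peaks, in weeks.
#' @return Integer vector of peak weeks (possibly empty).
#' @export
detect_peaks <- function(profile, weeks = NULL, min_separation = 2) {
  if (is.data.frame(profile)) {
    weeks <- weeks %||% profile$week
    value_col <- setdiff(names(profile), "week")[1]
    profile <- profile[[value_col]]
  }
  weeks <- weeks %||% seq_along(profile)
  if (length(profile) < 3) abort("profile must have length >= 3")
  n <- length(profile)
  cand <- which(profile[2:(n - 1)] > profile[1:(n - 2)] &
                  profile[2:(n - 1)] > profile[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(-profile[cand], cand)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(weeks[i] - weeks[kept]) >= min_separation)) {
      kept <- c(kept, i)
    }
  }
  sort(as.integer(weeks[kept]))
}
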