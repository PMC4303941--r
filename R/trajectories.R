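# Sample state vectors: one row per sample (time point), the K meta-feature
# values of its portrait. These, rather than raw protein vectors, feed the
# similarity projections.
sample_states <- function(model) {
  t(model$codes)
}

new_trajectory <- function(df, method) {
  structure(df, class = c("trajectory", class(df)), method = method)
}

#' Project samples with a second-level SOM
#'
#' Trains a small SOM over the sample state vectors (the K-dimensional
#' portraits) and places every sample on its best-matching node, giving a
#' 2D similarity space in which successive time points trace a trajectory.
#' Samples with identical portraits land on identical coordinates.
#'
#' @param states Sample-by-feature matrix (e.g. `t(model$codes)`), or a
#'   `som_model` whose portraits should be used.
#' @param weeks Week index per sample (defaults to the model's weeks or
#'   row names).
#' @param rows,cols Grid of the second-level SOM (default 10x10).
#' @param epochs,seed Training schedule and seed (see [som_params()]).
#' @return A `trajectory` tibble (`sample`, `week`, `x`, `y`, `method`).
#' @export
second_level_som <- function(states, weeks = NULL, rows = 10, cols = 10,
                             epochs = 50, seed = 1) {
  if (inherits(states, "som_model")) {
    weeks <- weeks %||% states$weeks
    states <- sample_states(states)
  }
  states <- as.matrix(states)
  if (nrow(states) < 3) abort("at least three samples are required")
  weeks <- weeks %||% suppressWarnings(as.integer(rownames(states))) %||%
    seq_len(nrow(states))
  if (anyNA(weeks)) weeks <- seq_len(nrow(states))
  params <- som_params(rows = rows, cols = cols, epochs = epochs,
                       radius_init = max(rows, cols) / 2, radius_final = 0.5,
                       seed = seed)
  model <- suppressWarnings(train_som(states, params))
  g <- node_grid(rows, cols)
  bmu <- model$assignment
  new_trajectory(
    tibble(sample = seq_len(nrow(states)), week = as.integer(weeks),
           x = g$col[bmu], y = g$row[bmu], method = "som2"),
    "som2"
  )
}

# Symmetric fixed-point fast ICA with logcosh contrast on whitened data.
# z: n x c whitened matrix (unit-variance uncorrelated columns).
fastica_symmetric <- function(z, seed = 1, max_iter = 200, tol = 1e-6) {
  c_dim <- ncol(z)
  n <- nrow(z)
  set.seed(derive_seed(seed, "ica"))
  w <- matrix(stats::rnorm(c_dim^2), c_dim)
  orthonormalize <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  w <- orthonormalize(w)
  for (it in seq_len(max_iter)) {
    s <- z %*% t(w)                    # n x c source estimates
    g <- tanh(s)
    g_prime <- 1 - g^2
    w_new <- crossprod(g, z) / n - diag(colMeans(g_prime)) %*% w
    w_new <- orthonormalize(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) return(list(w = w, iterations = it, converged = TRUE))
  }
  list(w = w, iterations = max_iter, converged = FALSE)
}

#' Project samples by independent component analysis
#'
#' Whitens the sample state vectors and runs a symmetric fixed-point ICA
#' (logcosh contrast) to find the directions of minimal mutual statistical
#' dependence; the first two independent components are the trajectory
#' coordinates. Sign convention: each component's first nonzero value is
#' positive.
#'
#' @param states Sample-by-feature matrix or a `som_model`.
#' @param weeks Week per sample.
#' @param n_components Number of components (default 2).
#' @param seed,max_iter,tol Fixed-point settings; non-convergence is an error
#'   reporting the iteration count.
#' @return A `trajectory` tibble (`sample`, `week`, `x`, `y`, `method`) with
#'   the full component matrix in attribute `components`.
#' @export
ica_projection <- function(states, weeks = NULL, n_components = 2, seed = 1,
                           max_iter = 200, tol = 1e-6) {
  if (inherits(states, "som_model")) {
    weeks <- weeks %||% states$weeks
    states <- sample_states(states)
  }
  states <- as.matrix(states)
  n <- nrow(states)
  weeks <- weeks %||% suppressWarnings(as.integer(rownames(states))) %||% seq_len(n)
  if (anyNA(weeks)) weeks <- seq_len(n)
  if (n_components > min(n, ncol(states))) {
    abort("`n_components` must not exceed min(n_samples, n_features)")
  }
  xc <- sweep(states, 2, colMeans(states))
  sv <- svd(xc, nu = n_components, nv = 0)
  if (sv$d[n_components] < 1e-10) {
    abort("degenerate input: fewer than `n_components` directions of variance")
  }
  z <- sv$u[, seq_len(n_components), drop = FALSE] * sqrt(n - 1)
  fit <- fastica_symmetric(z, seed = seed, max_iter = max_iter, tol = tol)
  if (!fit$converged) {
    abort(sprintf("ICA did not converge after %d iterations", fit$iterations))
  }
  s <- z %*% t(fit$w)
  for (j in seq_len(ncol(s))) {
    first <- which(abs(s[, j]) > 1e-8)[1]
    if (!is.na(first) && s[first, j] < 0) s[, j] <- -s[, j]
  }
  out <- new_trajectory(
    tibble(sample = seq_len(n), week = as.integer(weeks),
           x = s[, 1], y = if (ncol(s) > 1) s[, 2] else 0, method = "ica"),
    "ica"
  )
  attr(out, "components") <- s
  attr(out, "iterations") <- fit$iterations
  out
}

#' Segment a trajectory into time phases
#'
#' K-means (fixed seed) on the 2D sample coordinates; clusters are labelled
#' early / intermediate / late (for k = 3) by ascending median sample week,
#' and agreement with the reference phase labels of the study design is
#' reported as an adjusted Rand index.
#'
#' @param traj A `trajectory`.
#' @param k Number of segments (default 3; 4 separates the pre-isolation
#'   cluster from the early-isolation one).
#' @param design A [study_design()] supplying reference phase labels.
#' @param seed K-means seed.
#' @param aggregate_early With `k = 4`, merge the two earliest segments (the
#'   pre-isolation and early-isolation windows) into one `early` phase, the
#'   way the four observed windows collapse onto the three reference phases.
#'   Default TRUE for `k = 4`.
#' @return The trajectory with a `segment` column; attributes `ari`
#'   (agreement with reference phases) and `reference` (the reference
#'   labels).
#' @export
segment_trajectory <- function(traj, k = 3, design = study_design(), seed = 1,
                               aggregate_early = (k == 4)) {
  stopifnot(inherits(traj, "trajectory"))
  if (k < 2) abort("`k` must be >= 2")
  if (k > nrow(traj)) abort("`k` must not exceed the number of samples")
  set.seed(derive_seed(seed, "segment"))
  km <- stats::kmeans(cbind(traj$x, traj$y), centers = k, nstart = 10,
                      iter.max = 50)
  med_week <- vapply(split(traj$week, km$cluster), stats::median, numeric(1))
  rank_by_week <- rank(med_week, ties.method = "first")
  labels <- if (k == 3) c("early", "intermediate", "late")
  else if (k == 4 && aggregate_early) c("early", "early", "intermediate", "late")
  else paste0("segment_", seq_len(k))
  seg <- labels[rank_by_week[as.character(km$cluster)]]
  reference <- phase_of_week(traj$week)
  out <- dplyr::mutate(traj, segment = seg)
  out <- new_trajectory(out, attr(traj, "method"))
  attr(out, "ari") <- adjusted_rand_index(seg, reference)
  attr(out, "reference") <- reference
  out
}

#' Write a trajectory as TSV
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
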