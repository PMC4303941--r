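#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Pearson correlation that treats zero-variance vectors as uncorrelated (r = 0)
# instead of propagating NA. Used throughout wTO / beta / matching.
safe_cor <- function(x, y = NULL) {
  if (is.null(y)) {
    sds <- apply(x, 2, stats::sd)
    r <- suppressWarnings(stats::cor(x))
    r[!is.finite(r)] <- 0
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
    diag(r) <- 1
    return(r)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Adjusted Rand index between two label vectors (permutation-invariant
# agreement; 1 = identical partitions, ~0 = random).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Deterministic fan-out of one global seed into per-stage seeds: a stable
# string hash combined with the global seed, kept below 2^31.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Spot letters in detection order: A..Z, then AA, AB, ...
spot_letters <- function(n) {
  single <- LETTERS
  if (n <= 26) return(single[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(single, extra)[seq_len(n)]
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
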