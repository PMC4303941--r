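#' Weighted topological overlap between meta-feature profiles
#'
#' Builds a signed-channel adjacency from Pearson correlations between node
#' profiles — `a_ij = max(r_ij, 0)` in the positive channel, `max(-r_ij, 0)`
#' in the negative channel, diagonal zero — and scores every node pair by the
#' topological overlap
#' `w_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
#' where `k_i = sum_u a_iu`. The score combines the direct association with
#' associations mediated by all third nodes of the map. Zero-variance
#' profiles have all correlations defined as 0.
#'
#' @param profiles Matrix of profiles in rows (e.g. `model$codes`), or a
#'   `som_model`.
#' @param sign `"positive"` or `"negative"` channel.
#' @return Symmetric matrix of wTO scores in `[0, 1]`, zero diagonal.
#' @export
wto_scores <- function(profiles, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (inherits(profiles, "som_model")) profiles <- profiles$codes
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3) {
    warn("fewer than 3 profiles: mediated overlap has no third nodes")
  }
  r <- safe_cor(t(profiles))
  a <- if (sign == "positive") pmax(r, 0) else pmax(-r, 0)
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  denom <- outer(k, k, pmin) + 1 - a
  w <- num / denom
  diag(w) <- 0
  w
}

#' Spot-spot wTO network edges
#'
#' Aggregates node-pair wTO scores to the spot level: the score of a spot
#' pair is the mean wTO over all cross-spot node pairs; pairs at or above
#' `threshold` are flagged as edges. Spots of one polarity must not share
#' nodes.
#'
#' @param spots A `spot_set`.
#' @param scores Node-pair wTO matrix from [wto_scores()].
#' @param channel Label recorded on the edges (`"positive"`/`"negative"`).
#' @param threshold Edge threshold on the aggregated score.
#' @return Tibble (`spot_i`, `spot_j`, `channel`, `score`, `edge`).
#' @export
spot_wto_network <- function(spots, scores, channel = "positive",
                             threshold = 0.1) {
  stopifnot(inherits(spots, "spot_set"))
  for (pol in unique(spots$polarity)) {
    nodes <- unlist(spots$nodes[spots$polarity == pol])
    if (anyDuplicated(nodes)) abort("overlapping spots within one polarity")
  }
  n <- nrow(spots)
  if (n < 2) return(tibble(spot_i = character(), spot_j = character(),
                           channel = character(), score = numeric(),
                           edge = logical()))
  pairs <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    sc <- mean(scores[spots$nodes[[i]], spots$nodes[[j]]])
    tibble(spot_i = spots$id[i], spot_j = spots$id[j], channel = channel,
           score = sc, edge = sc >= threshold)
  })
  dplyr::bind_rows(rows)
}

# Row-standardize: (x - mean) / sd with zero-variance rows mapped to zero
# (their correlations are defined as 0).
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowSums(xc^2) / (ncol(x) - 1))
  z <- xc / ifelse(sd > 0, sd, Inf)
  z
}

# Beta coherence statistic of a set of profiles: the squared ratio of the
# sum correlation between the mean module profile (the raw-profile mean, so
# member amplitudes weight the centroid) and the members, and the all-pairs
# sum correlation (ordered pairs, diagonal included, so a perfectly coherent
# module has beta = 1). With Z the row-standardized profiles and
# s = colSums(Z), the all-pairs sum is s.s/(M-1) and the centroid sum is
# zc.s/(M-1) with zc the standardized raw centroid, keeping the permutation
# null cheap.
beta_statistic <- function(profiles) {
  profiles <- as.matrix(profiles)
  m <- nrow(profiles)
  if (m == 0) abort("beta statistic needs at least one member profile")
  if (m == 1) return(1)
  beta_from_parts(colSums(standardize_rows(profiles)), colMeans(profiles),
                  ncol(profiles))
}

beta_from_parts <- function(s, centroid, n_time) {
  zc <- centroid - mean(centroid)
  sdc <- sqrt(sum(zc^2) / (n_time - 1))
  if (sdc > 0) zc <- zc / sdc else zc <- zc * 0
  denom <- sum(s^2) / (n_time - 1)
  if (denom <= 0) return(NA_real_)
  (sum(zc * s) / (n_time - 1))^2 / denom
}

#' Beta co-expression significance test for spot modules
#'
#' For each spot, computes the beta statistic over the spot's meta-feature
#' profiles (the single-protein profiles are substituted by their
#' meta-features to keep the cost linear in map size) and estimates a
#' p-value from a permutation null: `n_perm` random same-size node sets drawn
#' from the whole map. With `method = "analytic"` a Beta distribution is
#' moment-matched to the permutation sample and used as the null.
#' P-values are Benjamini-Hochberg adjusted across spots.
#'
#' @param spots A `spot_set`.
#' @param model The `som_model` the spots came from (or a profile matrix).
#' @param n_perm Number of permutations (>= 100).
#' @param method `"permutation"` (default) or `"analytic"`.
#' @param seed Seed for the permutation draw.
#' @return Tibble (`id`, `m`, `beta`, `p_value`, `p_adjusted`, `method`).
#' @export
beta_test <- function(spots, model, n_perm = 1000,
                      method = c("permutation", "analytic"), seed = 1) {
  method <- match.arg(method)
  if (n_perm < 100) abort("`n_perm` must be >= 100")
  profiles <- if (inherits(model, "som_model")) model$codes else as.matrix(model)
  k <- nrow(profiles)
  n_time <- ncol(profiles)
  z <- standardize_rows(profiles)
  set.seed(derive_seed(seed, "beta"))
  res <- lapply(seq_len(nrow(spots)), function(i) {
    nodes <- spots$nodes[[i]]
    m <- length(nodes)
    if (m == 0) abort(sprintf("spot %s has no member meta-features", spots$id[i]))
    beta_obs <- beta_statistic(profiles[nodes, , drop = FALSE])
    null <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(k, m)
      if (m == 1) return(1)
      beta_from_parts(colSums(z[idx, , drop = FALSE]),
                      colMeans(profiles[idx, , drop = FALSE]), n_time)
    }, numeric(1))
    null <- null[is.finite(null)]
    p <- if (method == "permutation") {
      (1 + sum(null >= beta_obs)) / (length(null) + 1)
    } else {
      mu <- mean(null); v <- stats::var(null)
      # moment-matched Beta(a,b) on [0,1]
      common <- mu * (1 - mu) / v - 1
      a <- max(mu * common, 1e-3); b <- max((1 - mu) * common, 1e-3)
      stats::pbeta(min(beta_obs, 1), a, b, lower.tail = FALSE)
    }
    tibble(id = spots$id[i], m = m, beta = beta_obs, p_value = p)
  })
  out <- dplyr::bind_rows(res)
  dplyr::mutate(out, p_adjusted = stats::p.adjust(.data$p_value, "BH"),
                method = method)
}
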