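#' Fisher (hypergeometric) enrichment of a protein set in a spot
#'
#' Upper-tail hypergeometric probability of seeing at least the observed
#' overlap between the spot members and the set, given the universe of all
#' proteins studied. The set is intersected with the universe first.
#'
#' @param members Spot member accessions.
#' @param set Gene-set member accessions.
#' @param universe All proteins input to the SOM.
#' @return Tibble (`n_universe`, `n_set`, `n_spot`, `overlap`, `p_fisher`).
#' @export
fisher_enrichment <- function(members, set, universe) {
  if (!length(universe)) abort("empty universe")
  universe <- unique(universe)
  members <- intersect(unique(members), universe)
  set <- intersect(unique(set), universe)
  ov <- length(intersect(members, set))
  p <- if (length(set) == 0 || length(members) == 0) 1 else {
    stats::phyper(ov - 1, length(set), length(universe) - length(set),
                  length(members), lower.tail = FALSE)
  }
  tibble(n_universe = length(universe), n_set = length(set),
         n_spot = length(members), overlap = ov, p_fisher = p)
}

#' Gene-set enrichment Z-score (GSZ)
#'
#' Standardized set statistic that combines overlap with the degree of
#' overexpression: each universe protein carries a score (its delta-E in the
#' spot, 0 outside), and the sum of scores over the set members is z-scored
#' against the simple-random-sampling-without-replacement null of a random
#' same-size set from the universe, with a small variance regularizer
#' `lambda`. Higher = more enriched and more overexpressed.
#'
#' @param scores Named numeric vector over the universe: per-protein delta-E
#'   contribution (0 for proteins outside the spot).
#' @param set Gene-set member accessions.
#' @param lambda Variance regularizer (default 0.1).
#' @return The GSZ score (scalar). A set disjoint from the universe is
#'   flagged with `NA`.
#' @export
gsz_score <- function(scores, set, lambda = 0.1) {
  if (is.null(names(scores))) abort("`scores` must be named by protein accession")
  set <- intersect(unique(set), names(scores))
  m <- length(set)
  if (m == 0) return(NA_real_)
  n <- length(scores)
  t_obs <- sum(scores[set])
  mu <- mean(scores)
  v <- stats::var(scores)
  var_t <- m * v * (n - m) / max(n - 1, 1)
  (t_obs - m * mu) / sqrt(var_t + lambda)
}

#' Enrichment of every gene set in every spot
#'
#' Runs [fisher_enrichment()] and [gsz_score()] for all (spot, set) pairs.
#' The universe is the set of all proteins input to the SOM; gene-set members
#' outside it are dropped. For GSZ, a spot member's score is its delta-E at
#' the spot's argmax week; non-members score 0. P-values are
#' Benjamini-Hochberg adjusted across sets within each spot.
#'
#' @param spots A `spot_set`.
#' @param gene_sets A `gene_set_collection`.
#' @param matrix A `differential_matrix` (delta-E values) over the universe.
#' @param accession_map Optional tibble (`accession`, `gene`) translating
#'   gene-symbol sets onto the protein universe.
#' @return Tibble (`id`, `set`, `category`, `n_universe`, `n_set`, `n_spot`,
#'   `overlap`, `p_fisher`, `gsz`, `p_adjusted`).
#' @export
enrich_spots <- function(spots, gene_sets, matrix, accession_map = NULL) {
  stopifnot(inherits(spots, "spot_set"), inherits(gene_sets, "gene_set_collection"),
            inherits(matrix, "abundance_matrix"))
  universe <- rownames(matrix$values)
  sets <- gene_sets$sets
  if (!is.null(accession_map)) {
    sets <- lapply(sets, function(s) {
      unique(accession_map$accession[accession_map$gene %in% s |
                                       accession_map$accession %in% s])
    })
    sets <- sets[lengths(sets) > 0]
  }
  out <- purrr::map_dfr(seq_len(nrow(spots)), function(i) {
    members <- spots$proteins[[i]]
    peak_col <- which(matrix$weeks == spots$phase_hat[i])[1]
    scores <- stats::setNames(rep(0, length(universe)), universe)
    present <- intersect(members, universe)
    scores[present] <- matrix$values[present, peak_col]
    res <- purrr::map_dfr(names(sets), function(nm) {
      fe <- fisher_enrichment(members, sets[[nm]], universe)
      dplyr::mutate(fe, id = spots$id[i], set = nm,
                    category = unname(gene_sets$categories[nm] %||% "custom"),
                    gsz = gsz_score(scores, sets[[nm]]), .before = 1)
    })
    dplyr::mutate(res, p_adjusted = stats::p.adjust(.data$p_fisher, "BH"))
  })
  dplyr::select(out, "id", "set", "category", "n_universe", "n_set", "n_spot",
                "overlap", "p_fisher", "gsz", "p_adjusted")
}

#' Smoothed density map of a gene set on the SOM grid
#'
#' Counts the set's member proteins per node and smooths the counts with a
#' Gaussian kernel of the given grid bandwidth; the kernel columns are
#' normalized so the density still integrates to the set size on the map.
#' High-density regions are the connected nodes above the 90th density
#' percentile.
#'
#' @param set Member accessions.
#' @param model A `som_model`.
#' @param bandwidth Gaussian kernel bandwidth in grid units (default 2).
#' @return Tibble (`node`, `row`, `col`, `count`, `density`, `region`);
#'   `region` is an integer component id or `NA`.
#' @export
tissue_density_map <- function(set, model, bandwidth = 2) {
  stopifnot(inherits(model, "som_model"))
  members <- intersect(unique(set), names(model$assignment))
  counts <- tabulate(model$assignment[members], nbins = nrow(model$codes))
  d2 <- grid_dist2(model$params$rows, model$params$cols)
  kern <- exp(-d2 / (2 * bandwidth^2))
  kern <- sweep(kern, 2, colSums(kern), "/")  # mass-preserving smoothing
  density <- as.vector(kern %*% counts)
  g <- node_grid(model$params$rows, model$params$cols)
  out <- dplyr::mutate(g, count = counts, density = density)
  region <- rep(NA_integer_, nrow(out))
  if (any(density > 0)) {
    cut <- stats::quantile(density, 0.9)
    high <- which(density > cut)
    comps <- node_components(high, model$params$rows, model$params$cols)
    for (ci in seq_along(comps)) region[comps[[ci]]] <- ci
  }
  out <- dplyr::mutate(out, region = region)
  structure(out, class = c("density_map", class(out)), set_size = length(members))
}

#' Mean abundance profile of a protein set
#'
#' Unweighted mean over the member rows of the matrix.
#'
#' @param set Member accessions.
#' @param matrix An `abundance_matrix` or `differential_matrix`.
#' @return Tibble (`week`, `value`, `n_members`).
#' @export
set_profile <- function(set, matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  members <- intersect(unique(set), rownames(matrix$values))
  if (!length(members)) abort("set has no overlap with the matrix universe")
  prof <- colMeans(matrix$values[members, , drop = FALSE])
  tibble(week = matrix$weeks, value = unname(prof), n_members = length(members))
}

#' Cluster enrichment results into a heatmap matrix
#'
#' Spots are ordered by phase (argmax week); sets are hierarchically
#' clustered (complete linkage on Euclidean distance) over their score
#' profiles across spots.
#'
#' @param results Tibble from [enrich_spots()].
#' @param spots The `spot_set` (supplies the phase ordering).
#' @param value `"gsz"` (default) or `"log_p"` (-log10 Fisher p).
#' @return An `enrichment_heatmap`: list with `matrix` (sets x spots, row
#'   order clustered), `spot_order` and `set_order`.
#' @export
enrichment_heatmap <- function(results, spots, value = c("gsz", "log_p")) {
  value <- match.arg(value)
  if (length(unique(results$id)) < 2 || length(unique(results$set)) < 2) {
    abort("need at least 2 spots and 2 sets")
  }
  score <- if (value == "gsz") results$gsz else -log10(pmax(results$p_fisher, 1e-300))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(results, score = score)[, c("set", "id", "score")],
    names_from = "id", values_from = "score"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$set
  m[!is.finite(m)] <- 0
  spot_order <- spots$id[order(spots$phase_hat)]
  spot_order <- intersect(spot_order, colnames(m))
  m <- m[, spot_order, drop = FALSE]
  set_order <- if (nrow(m) > 2) {
    stats::hclust(stats::dist(m), method = "complete")$order
  } else seq_len(nrow(m))
  m <- m[set_order, , drop = FALSE]
  structure(list(matrix = m, spot_order = spot_order,
                 set_order = rownames(m), value = value),
            class = "enrichment_heatmap")
}

#' Write an enrichment heatmap matrix as TSV (round-trips via read.table)
#'
#' @param hm An `enrichment_heatmap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_heatmap <- function(hm, path) {
  df <- data.frame(set = rownames(hm$matrix), hm$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
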