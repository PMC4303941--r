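# Connected components of a set of selected nodes under 8-neighborhood grid
# adjacency (diagonal contact merges spots, matching how adjacent spots read
# visually on the map). Returns a list of integer node vectors.
node_components <- function(nodes, rows, cols) {
  if (!length(nodes)) return(list())
  g <- node_grid(rows, cols)[nodes, , drop = FALSE]
  pairs <- which(
    outer(g$row, g$row, function(a, b) abs(a - b) <= 1) &
      outer(g$col, g$col, function(a, b) abs(a - b) <= 1),
    arr.ind = TRUE
  )
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  gr <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(nodes))
  )
  comp <- igraph::components(gr)$membership
  unname(lapply(split(nodes, comp), sort))
}

# Top/bottom percentile node masks with boundary ties included.
percentile_mask <- function(values, k_sel, top = TRUE) {
  if (top) which(values >= sort(values, decreasing = TRUE)[k_sel])
  else which(values <= sort(values)[k_sel])
}

build_spots <- function(components, polarity, method, model) {
  pop <- tabulate(model$assignment, nbins = nrow(model$codes))
  rows <- purrr::map2(components, polarity, function(nodes, pol) {
    members <- names(model$assignment)[model$assignment %in% nodes]
    prof <- colMeans(model$codes[nodes, , drop = FALSE])
    n_nd <- length(nodes)
    n_pr <- length(members)
    tibble(
      polarity = pol, nodes = list(nodes), n_nodes = n_nd,
      proteins = list(members), n_proteins = n_pr,
      profile = list(stats::setNames(prof, model$weeks)),
      phase_hat = model$weeks[which.max(prof)],
      lag_max_min = model$weeks[which.max(prof)] - model$weeks[which.min(prof)]
    )
  })
  out <- dplyr::bind_rows(rows)
  # letters in decreasing spot size (node count), ties by lowest node index
  ord <- order(-out$n_nodes, vapply(out$nodes, min, integer(1)))
  out <- out[ord, ]
  out <- dplyr::mutate(out, id = spot_letters(dplyr::n()), method = method,
                       .before = 1)
  structure(out, class = c("spot_set", class(out)), model_k = nrow(model$codes))
}

#' Select over/under-expression spot modules by percentile
#'
#' In `averaged` mode each meta-feature value is averaged over all expression
#' states and the maximum and minimum `percentile`-percent of nodes are
#' selected (boundary ties included). In `union` mode (default) the top and
#' bottom percentile nodes are selected per sample and the per-sample masks
#' are unioned, which collects the spots observed in the individual
#' portraits. Spots are the connected components of the selected nodes under
#' 8-neighborhood adjacency. A node claimed by both polarities (possible in
#' union mode) is kept in the channel with the larger absolute state-averaged
#' value.
#'
#' @param model A [train_som()] model.
#' @param mode `"union"` or `"averaged"`.
#' @param percentile Percent of nodes per polarity (default 2; must be in
#'   (0, 50)).
#' @return A `spot_set` tibble: one row per spot with id (capital letters in
#'   decreasing size order), polarity, node set, member proteins, mean
#'   delta-E profile, estimated phase `phase_hat` and max-min lag.
#' @export
select_percentile_spots <- function(model, mode = c("union", "averaged"),
                                    percentile = 2) {
  stopifnot(inherits(model, "som_model"))
  mode <- match.arg(mode)
  if (percentile <= 0 || percentile >= 50) abort("`percentile` must be in (0, 50)")
  k <- nrow(model$codes)
  k_sel <- ceiling(k * percentile / 100)
  avg <- rowMeans(model$codes)
  if (mode == "averaged") {
    over <- percentile_mask(avg, k_sel, top = TRUE)
    under <- percentile_mask(avg, k_sel, top = FALSE)
  } else {
    over <- sort(unique(unlist(lapply(seq_len(ncol(model$codes)), function(s) {
      percentile_mask(model$codes[, s], k_sel, top = TRUE)
    }))))
    under <- sort(unique(unlist(lapply(seq_len(ncol(model$codes)), function(s) {
      percentile_mask(model$codes[, s], k_sel, top = FALSE)
    }))))
  }
  both <- intersect(over, under)
  if (length(both)) {
    to_over <- both[avg[both] >= 0]
    under <- setdiff(under, to_over)
    over <- setdiff(over, setdiff(both, to_over))
  }
  comps_over <- node_components(over, model$params$rows, model$params$cols)
  comps_under <- node_components(under, model$params$rows, model$params$cols)
  build_spots(
    c(comps_over, comps_under),
    c(rep("over", length(comps_over)), rep("under", length(comps_under))),
    paste0("percentile-", mode), model
  )
}

#' Select spot modules by correlation to seed nodes
#'
#' Seed nodes are the local maxima (8-neighborhood) of the per-node profile
#' variance; in decreasing seed strength, every still-unassigned node whose
#' meta profile has Pearson correlation >= `threshold` with the seed joins
#' that seed's group. Groups are then split into grid-connected components.
#'
#' @param model A `som_model`.
#' @param threshold Correlation threshold in (0, 1].
#' @return A `spot_set` (polarity `"none"`).
#' @export
select_correlation_spots <- function(model, threshold = 0.9) {
  stopifnot(inherits(model, "som_model"))
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1]")
  v <- apply(model$codes, 1, stats::var)
  g <- node_grid(model$params$rows, model$params$cols)
  vm <- matrix(v[order(g$node)], nrow = model$params$rows,
               ncol = model$params$cols, byrow = TRUE)
  is_max <- vapply(seq_len(nrow(g)), function(i) {
    r <- g$row[i]; c <- g$col[i]
    nb <- vm[max(1, r - 1):min(nrow(vm), r + 1),
             max(1, c - 1):min(ncol(vm), c + 1)]
    vm[r, c] >= max(nb)
  }, logical(1))
  seeds <- g$node[is_max][order(-v[g$node[is_max]])]
  assigned <- rep(NA_integer_, nrow(model$codes))
  cc <- safe_cor(t(model$codes))
  for (s in seeds) {
    if (!is.na(assigned[s])) next
    grab <- which(is.na(assigned) & cc[s, ] >= threshold)
    assigned[grab] <- s
  }
  groups <- split(which(!is.na(assigned)), assigned[!is.na(assigned)])
  comps <- unlist(lapply(groups, node_components,
                         rows = model$params$rows, cols = model$params$cols),
                  recursive = FALSE)
  build_spots(comps, rep("none", length(comps)), "correlation", model)
}

#' Select spot modules by k-means on meta profiles
#'
#' K-means (fixed seed) on the K meta-feature profiles; each cluster is then
#' split into grid-connected components.
#'
#' @param model A `som_model`.
#' @param k Number of clusters (2..K).
#' @param seed Seed for k-means.
#' @return A `spot_set` (polarity `"none"`).
#' @export
select_kmeans_spots <- function(model, k, seed = 1) {
  stopifnot(inherits(model, "som_model"))
  if (k < 2) abort("`k` must be >= 2")
  if (k > nrow(model$codes)) abort("`k` must not exceed the number of meta-features")
  set.seed(derive_seed(seed, "kmeans-spots"))
  km <- stats::kmeans(model$codes, centers = k, nstart = 5, iter.max = 50)
  groups <- split(seq_len(nrow(model$codes)), km$cluster)
  comps <- unlist(lapply(groups, node_components,
                         rows = model$params$rows, cols = model$params$cols),
                  recursive = FALSE)
  build_spots(comps, rep("none", length(comps)), "kmeans", model)
}

#' Mean time profile of a spot
#'
#' Average of the member meta-feature profiles, with the estimated phase
#' (argmax week) and the max-min lag.
#'
#' @param spot One row of a `spot_set` (or a spot id together with `spots =`).
#' @param model The `som_model` the spots came from.
#' @param spots Optional `spot_set` to look `spot` up in by id.
#' @return Tibble (`week`, `value`) with attributes `phase_hat` and
#'   `lag_max_min`.
#' @export
spot_profile <- function(spot, model, spots = NULL) {
  if (is.character(spot)) {
    stopifnot(!is.null(spots))
    spot <- spots[spots$id == spot, ]
    if (!nrow(spot)) abort("spot id not found")
  }
  nodes <- spot$nodes[[1]]
  if (!length(nodes)) abort("empty spot")
  profile <- colMeans(model$codes[nodes, , drop = FALSE])
  structure(tibble(week = model$weeks, value = unname(profile)),
            phase_hat = model$weeks[which.max(profile)],
            lag_max_min = model$weeks[which.max(profile)] -
              model$weeks[which.min(profile)])
}

#' Classify a spot into the early / intermediate / late reference phase
#'
#' The phase containing the argmax week of the spot profile; pre-isolation
#' maxima map to early and post-isolation maxima to late.
#'
#' @param spot A `spot_set` row (or the whole set, vectorized).
#' @param design A [study_design()] (only phase boundaries are used).
#' @return Character vector of phases.
#' @export
classify_spot_phase <- function(spot, design = study_design()) {
  phase_of_week(spot$phase_hat)
}

#' Spot summary map: per-node over/under/none flags
#'
#' Collects the spots of both polarities into one master map.
#'
#' @param spots A `spot_set` from [select_percentile_spots()].
#' @param model The underlying `som_model`.
#' @return Tibble (`node`, `row`, `col`, `flag`, `spot`).
#' @export
summary_map <- function(spots, model) {
  g <- node_grid(model$params$rows, model$params$cols)
  flag <- rep("none", nrow(g))
  spot_id <- rep(NA_character_, nrow(g))
  for (i in seq_len(nrow(spots))) {
    nodes <- spots$nodes[[i]]
    flag[nodes] <- spots$polarity[i]
    spot_id[nodes] <- spots$id[i]
  }
  dplyr::mutate(g, flag = flag, spot = spot_id)
}

#' @export
tidy.spot_set <- function(x, ...) {
  dplyr::select(as_tibble(x), "id", "method", "polarity", "n_nodes",
                "n_proteins", "phase_hat", "lag_max_min")
}

#' Write a spot table as TSV (nodes and members as comma-joined lists)
#'
#' @param spots A `spot_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  df <- dplyr::mutate(
    as_tibble(spots),
    nodes = vapply(.data$nodes, paste, character(1), collapse = ","),
    proteins = vapply(.data$proteins, paste, character(1), collapse = ","),
    profile = vapply(.data$profile, function(p) paste(signif(p, 6), collapse = ","),
                     character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
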