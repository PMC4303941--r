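new_pathway_graph <- function(name, nodes, edges, dropped_relations = 0L,
                              removed_edges = 0L) {
  if (!nrow(nodes)) abort("pathway has no nodes")
  missing <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing)) abort(sprintf("edge endpoint not in nodes: %s", missing[[1]]))
  g <- structure(
    list(name = name, nodes = nodes, edges = edges,
         dropped_relations = dropped_relations, removed_edges = removed_edges),
    class = "pathway_graph"
  )
  ord <- topo_order(g)  # errors on residual cycles
  indeg <- table(factor(edges$to, levels = nodes$id))
  outdeg <- table(factor(edges$from, levels = nodes$id))
  g$sources <- nodes$id[indeg == 0]
  g$sinks <- nodes$id[outdeg == 0]
  if (!length(g$sinks)) abort("pathway has no sink nodes after preprocessing")
  g$topo <- ord
  g
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf(
    "<pathway_graph> %s: %d nodes, %d edges (%d sources, %d sinks; %d relations dropped, %d back-edges removed)\n",
    x$name, nrow(x$nodes), nrow(x$edges), length(x$sources), length(x$sinks),
    x$dropped_relations, x$removed_edges
  ))
  invisible(x)
}

# Kahn topological order over node ids, deterministic (lowest id first);
# errors if a cycle remains.
topo_order <- function(graph) {
  ids <- sort(graph$nodes$id)
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  for (t in graph$edges$to) indeg[[as.character(t)]] <- indeg[[as.character(t)]] + 1L
  out <- character(0)
  ready <- ids[indeg[as.character(ids)] == 0]
  indeg_left <- indeg
  edges <- graph$edges
  while (length(ready)) {
    v <- sort(ready)[1]
    ready <- setdiff(ready, v)
    out <- c(out, v)
    child <- edges$to[edges$from == v]
    for (u in child) {
      indeg_left[[as.character(u)]] <- indeg_left[[as.character(u)]] - 1L
      if (indeg_left[[as.character(u)]] == 0) ready <- c(ready, as.character(u))
    }
  }
  if (length(out) != length(ids)) abort("pathway graph contains a cycle")
  out
}

# Remove back edges found by depth-first search from every root in
# deterministic node order, so the remaining graph is acyclic.
break_cycles <- function(nodes, edges) {
  ids <- sort(nodes$id)
  adj <- split(seq_len(nrow(edges)), factor(edges$from, levels = ids))
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 on stack, 2 done
  drop <- logical(nrow(edges))
  visit <- function(v) {
    state[[v]] <<- 1L
    for (ei in adj[[v]]) {
      u <- as.character(edges$to[ei])
      if (state[[u]] == 1L) drop[ei] <<- TRUE
      else if (state[[u]] == 0L) visit(u)
    }
    state[[v]] <<- 2L
  }
  for (v in ids) if (state[[v]] == 0L) visit(v)
  list(edges = edges[!drop, , drop = FALSE], removed = sum(drop))
}

#' Parse a KGML-subset pathway file
#'
#' Reads KEGG KGML: `entry` elements (id + space-separated accession list)
#' become nodes and `relation` elements become signed edges — subtypes
#' activation/expression map to activation, inhibition/repression to
#' inhibition, all other subtypes are dropped and counted. Cycles are broken
#' by removing back edges found by depth-first search in deterministic node
#' order; the removed-edge count is recorded on the graph.
#'
#' @param path KGML (XML) file path.
#' @return A `pathway_graph` with `nodes` (tibble `id`, `members`), signed
#'   `edges`, derived `sources` and `sinks`, and preprocessing counters.
#' @export
parse_kgml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(sprintf("malformed XML: %s", conditionMessage(e))))
  name <- xml2::xml_attr(doc, "title")
  if (is.na(name)) name <- xml2::xml_attr(doc, "name")
  if (is.na(name)) name <- basename(path)
  entries <- xml2::xml_find_all(doc, ".//entry")
  if (!length(entries)) abort("KGML has no entry elements")
  nodes <- tibble(
    id = xml2::xml_attr(entries, "id"),
    members = lapply(strsplit(xml2::xml_attr(entries, "name"), " +"),
                     function(x) x[nzchar(x)])
  )
  if (anyDuplicated(nodes$id)) abort("duplicate entry ids in KGML")
  relations <- xml2::xml_find_all(doc, ".//relation")
  from <- character(0); to <- character(0); type <- character(0); dropped <- 0L
  for (rel in relations) {
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, ".//subtype"), "name")
    sgn <- if (any(subtypes %in% c("activation", "expression"))) "activation"
    else if (any(subtypes %in% c("inhibition", "repression"))) "inhibition"
    else NA_character_
    if (is.na(sgn)) { dropped <- dropped + 1L; next }
    from <- c(from, xml2::xml_attr(rel, "entry1"))
    to <- c(to, xml2::xml_attr(rel, "entry2"))
    type <- c(type, sgn)
  }
  edges <- tibble(from = from, to = to, type = type)
  edges <- edges[edges$from %in% nodes$id & edges$to %in% nodes$id, ]
  broken <- break_cycles(nodes, edges)
  new_pathway_graph(name, nodes, broken$edges, dropped_relations = dropped,
                    removed_edges = broken$removed)
}

#' Build a pathway graph from an edge-list table
#'
#' Toy pathways can be given as TSV with columns `src`, `dst`, `type`
#' (activation/inhibition) and optionally `members` (comma-joined
#' accessions per node, attached to whichever column first mentions the
#' node), or constructed directly from data frames.
#'
#' @param edges Data frame (`src`, `dst`, `type`) or a TSV path.
#' @param members Optional named list: node id -> member accessions.
#' @param name Pathway name.
#' @return A `pathway_graph`.
#' @export
pathway_from_edges <- function(edges, members = NULL, name = "pathway") {
  if (is.character(edges) && length(edges) == 1) {
    edges <- utils::read.table(edges, sep = "\t", header = TRUE,
                               colClasses = "character")
  }
  edges <- as_tibble(edges)
  if (!all(c("src", "dst", "type") %in% names(edges))) {
    abort("edge table needs columns src, dst, type")
  }
  if (!all(edges$type %in% c("activation", "inhibition"))) {
    abort("edge type must be activation or inhibition")
  }
  ids <- sort(unique(c(edges$src, edges$dst)))
  nodes <- tibble(
    id = ids,
    members = lapply(ids, function(i) members[[i]] %||% i)
  )
  e <- tibble(from = edges$src, to = edges$dst, type = edges$type)
  broken <- break_cycles(nodes, e)
  new_pathway_graph(name, nodes, broken$edges, removed_edges = broken$removed)
}

#' Per-node fold change from protein fold changes
#'
#' A node's fold change is the arithmetic mean of the fold changes of its
#' measured members; nodes with no measured member are neutral (FC = 1).
#'
#' @param graph A `pathway_graph`.
#' @param fold_changes Named numeric vector of positive protein fold changes.
#' @return Named numeric vector of node fold changes.
#' @export
node_fold_change <- function(graph, fold_changes) {
  if (any(fold_changes <= 0)) abort("fold changes must be positive")
  vapply(seq_len(nrow(graph$nodes)), function(i) {
    hit <- intersect(graph$nodes$members[[i]], names(fold_changes))
    if (!length(hit)) 1 else mean(fold_changes[hit])
  }, numeric(1)) |>
    stats::setNames(graph$nodes$id)
}

#' Propagate pathway signal flow
#'
#' Processes nodes in topological order. A source node's signal is its own
#' fold change. For any other node, each parent contributes its signal
#' multiplied by the node's fold change over an activation edge and divided
#' by it over an inhibition edge; the contributions are averaged over the
#' incoming edges (a normalized sum, which keeps signals finite on
#' converging branches and neutral at fold change 1). Sink signals are the
#' pathway outputs. With all fold changes 1, every signal is 1.
#'
#' @param graph A `pathway_graph`.
#' @param node_fc Named node fold changes from [node_fold_change()].
#' @return A `psf_result` tibble (`node`, `signal`, `is_source`, `is_sink`).
#' @export
compute_psf <- function(graph, node_fc) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (any(node_fc <= 0)) abort("node fold changes must be positive")
  signal <- stats::setNames(rep(NA_real_, nrow(graph$nodes)), graph$nodes$id)
  for (v in graph$topo) {
    inc <- graph$edges[graph$edges$to == v, ]
    if (!nrow(inc)) {
      signal[[v]] <- node_fc[[v]]
    } else {
      contrib <- vapply(seq_len(nrow(inc)), function(e) {
        s_parent <- signal[[inc$from[e]]]
        if (inc$type[e] == "activation") s_parent * node_fc[[v]]
        else s_parent / node_fc[[v]]
      }, numeric(1))
      signal[[v]] <- mean(contrib)
    }
  }
  out <- tibble(node = graph$nodes$id,
                signal = unname(signal[graph$nodes$id]),
                is_source = graph$nodes$id %in% graph$sources,
                is_sink = graph$nodes$id %in% graph$sinks)
  structure(out, class = c("psf_result", class(out)))
}

#' Pathway signal flow over a time course
#'
#' At each time point, protein fold changes are `(abundance + eps) /
#' (mean abundance + eps)` with the row mean taken over all time points; the
#' pseudocount `eps` keeps binary-derived abundances positive. PSF is then
#' computed per time point and the per-sink signals assembled into profiles.
#'
#' @param graph A `pathway_graph`.
#' @param matrix An `abundance_matrix` (non-centralized detection fractions).
#' @param eps Pseudocount (default 0.01).
#' @return Tibble (`sink`, `week`, `signal`).
#' @export
psf_time_profiles <- function(graph, matrix, eps = 0.01) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (matrix$centralized) abort("use non-centralized abundances for fold changes")
  base <- rowMeans(matrix$values) + eps
  purrr::map_dfr(seq_along(matrix$weeks), function(t) {
    fc <- (matrix$values[, t] + eps) / base
    res <- compute_psf(graph, node_fold_change(graph, fc))
    sinks <- res[res$is_sink, ]
    tibble(sink = sinks$node, week = matrix$weeks[t], signal = sinks$signal)
  })
}

#' Match PSF sink profiles to spot profiles
#'
#' Pearson correlation of every (sink, spot) profile pair on the shared week
#' grid; the best-matching spot per sink is flagged. Zero-variance profiles
#' are skipped and flagged.
#'
#' @param psf_profiles Tibble from [psf_time_profiles()].
#' @param spots A `spot_set`.
#' @return Tibble (`sink`, `spot`, `r`, `best`, `flagged`).
#' @export
match_profiles <- function(psf_profiles, spots) {
  stopifnot(inherits(spots, "spot_set"))
  out <- purrr::map_dfr(unique(psf_profiles$sink), function(s) {
    prof <- psf_profiles[psf_profiles$sink == s, ]
    prof <- prof[order(prof$week), ]
    purrr::map_dfr(seq_len(nrow(spots)), function(i) {
      sp <- spots$profile[[i]]
      weeks <- as.numeric(names(sp))
      shared <- intersect(prof$week, weeks)
      if (length(shared) != length(weeks) || length(shared) != nrow(prof)) {
        abort("PSF and spot profiles must share the same week grid")
      }
      x <- prof$signal[match(shared, prof$week)]
      y <- sp[match(shared, weeks)]
      degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
      tibble(sink = s, spot = spots$id[i],
             r = if (degenerate) NA_real_ else stats::cor(x, y),
             flagged = degenerate)
    })
  })
  out |>
    dplyr::group_by(.data$sink) |>
    dplyr::mutate(best = !is.na(.data$r) & .data$r == max(.data$r, na.rm = TRUE)) |>
    dplyr::ungroup()
}
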