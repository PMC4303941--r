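#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_tile geom_path
#'   geom_point geom_line geom_text scale_fill_gradient2 scale_fill_viridis_c
#'   scale_y_reverse labs theme_minimal theme element_blank coord_equal
NULL

#' Plot a SOM portrait
#'
#' Red encodes over-expression and blue under-expression; for centralized
#' (delta-E) data the color scale is symmetric about zero.
#'
#' @param object A `som_portrait` from [render_portrait()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.som_portrait <- function(object, ...) {
  lim <- max(abs(object$value))
  p <- ggplot(object, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    coord_equal() +
    scale_y_reverse() +
    labs(title = sprintf("week %s", attr(object, "week")), x = NULL, y = NULL,
         fill = if (isTRUE(attr(object, "centralized"))) "ΔE" else "abundance") +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
  if (isTRUE(attr(object, "centralized"))) {
    p + scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                             limits = c(-lim, lim))
  } else {
    p + scale_fill_gradient2(low = "blue", mid = "yellow", high = "red",
                             midpoint = mean(range(object$value)))
  }
}

#' Plot a sample trajectory in similarity space
#'
#' Samples are connected in temporal order; points are labelled by week and
#' colored by segment when present.
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory <- function(object, ...) {
  df <- as_tibble(object)[order(object$week), ]
  p <- ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_path(arrow = grid::arrow(length = grid::unit(2, "mm"), type = "closed"),
              color = "grey60")
  p <- if ("segment" %in% names(df)) {
    p + geom_point(aes(color = .data$segment), size = 2)
  } else {
    p + geom_point(aes(color = .data$week), size = 2)
  }
  p + geom_text(aes(label = .data$week), vjust = -0.8, size = 2.6) +
    labs(x = "component 1", y = "component 2",
         title = sprintf("sample trajectory (%s)", attr(object, "method"))) +
    theme_minimal()
}

#' Plot a spot summary map
#'
#' @param object Tibble from [summary_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_summary_map <- function(object, ...) {
  ggplot(object, aes(x = .data$col, y = .data$row, fill = .data$flag)) +
    geom_tile() +
    coord_equal() +
    scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(over = "red", under = "blue",
                                          none = "grey95")) +
    labs(x = NULL, y = NULL, fill = NULL) +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
}

#' Plot a total-abundance variance profile
#'
#' @param object Tibble from [variance_profile()].
#' @param peaks Optional peak weeks from [detect_peaks()], marked with
#'   asterisks.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_variance_profile <- function(object, peaks = NULL, ...) {
  p <- ggplot(object, aes(x = .data$week, y = .data$variance)) +
    geom_line() + geom_point() +
    labs(x = "week", y = "landscape variance",
         title = "total protein abundance over time") +
    theme_minimal()
  if (length(peaks)) {
    marks <- object[object$week %in% peaks, ]
    p <- p + geom_text(data = marks, label = "*", vjust = -0.4, size = 6,
                       color = "red3")
  }
  p
}

#' Plot a gene-set density map
#'
#' @param object Tibble from [tissue_density_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.density_map <- function(object, ...) {
  ggplot(object, aes(x = .data$col, y = .data$row, fill = .data$density)) +
    geom_raster() +
    coord_equal() +
    scale_y_reverse() +
    scale_fill_viridis_c() +
    labs(x = NULL, y = NULL, fill = "density") +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
}

#' Plot a clustered enrichment heatmap
#'
#' @param object An `enrichment_heatmap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_heatmap <- function(object, ...) {
  df <- as_tibble(object$matrix, rownames = "set") |>
    tidyr::pivot_longer(-"set", names_to = "spot", values_to = "score")
  df$set <- factor(df$set, levels = rev(object$set_order))
  df$spot <- factor(df$spot, levels = object$spot_order)
  ggplot(df, aes(x = .data$spot, y = .data$set, fill = .data$score)) +
    geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "brown") +
    labs(x = "spot (ordered by phase)", y = NULL, fill = object$value) +
    theme_minimal()
}
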