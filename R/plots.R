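#' Triangle plot of heterozygosity versus ancestry
#'
#' Localities (or individuals) in the (S, H) triangle: parental species at
#' the lower corners, F1 hybrids at the apex (0.5, 1).
#'
#' @param x a `triangle_stats` tibble or a locality summary from
#'   [locality_triangle_summary()].
#' @param labels optional core/edge labels from [classify_core_edge()] to
#'   colour points.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
plot_triangle <- function(x, labels = NULL, ...) {
  df <- tibble::as_tibble(x)
  if (!is.null(labels) && "locality" %in% names(df)) {
    df <- dplyr::left_join(df, labels, by = "locality")
  }
  edge <- tibble::tibble(S = c(0, 0.5, 1, 0), H = c(0, 1, 0, 0))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$S, y = .data$H)) +
    ggplot2::geom_path(data = edge, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "ancestry S (fraction focal alleles)",
                  y = "interclass heterozygosity H") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(labels) && all(c("dominant", "label") %in% names(df))) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$dominant,
                                         shape = .data$label), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2, colour = "steelblue")
  }
}

#' @method autoplot triangle_stats
#' @export
autoplot.triangle_stats <- function(object, ...) plot_triangle(object, ...)

#' @method autoplot cline_fit
#' @export
autoplot.cline_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(x = seq(min(d$x), max(d$x), length.out = 400))
  grid$p <- cline_frequency(grid$x, object$par, object$variant)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$h)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p), colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "signed distance to 0.5 contour (km)", y = "hybrid index",
                  size = "n genotypes",
                  title = sprintf("cline fit, variant '%s'", object$variant)) +
    ggplot2::theme_minimal()
}

#' @method autoplot cline_selection
#' @export
autoplot.cline_selection <- function(object, ...) {
  d <- object$best$data
  curves <- purrr::map_dfr(object$fits, function(f) {
    g <- tibble::tibble(x = seq(min(d$x), max(d$x), length.out = 400),
                        variant = f$variant)
    g$p <- cline_frequency(g$x, f$par, f$variant)
    g
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$h)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.5) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(y = .data$p, colour = .data$variant)) +
    ggplot2::labs(x = "signed distance to 0.5 contour (km)", y = "hybrid index",
                  colour = "model", size = "n genotypes") +
    ggplot2::theme_minimal()
}

#' @method autoplot thiessen_map
#' @export
autoplot.thiessen_map <- function(object, fill = NULL, ...) {
  polys <- object$polygons
  if (!is.null(fill)) {
    if (is.data.frame(fill)) fill <- setNames(fill[[2]], fill[[1]])
    polys$fill <- fill[polys$locality]
  }
  p <- ggplot2::ggplot(polys, ggplot2::aes(x = .data$x, y = .data$y,
                                           group = .data$locality))
  p <- if (!is.null(fill)) {
    p + ggplot2::geom_polygon(ggplot2::aes(fill = .data$fill), colour = "grey30")
  } else {
    p + ggplot2::geom_polygon(fill = "grey90", colour = "grey30")
  }
  p + ggplot2::geom_point(data = object$points, ggplot2::aes(group = NULL),
                          size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = "value") +
    ggplot2::theme_minimal()
}

#' @method autoplot k_selection
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "k (genepools)", y = expression(Delta * k)) +
    ggplot2::theme_minimal()
}
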