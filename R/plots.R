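#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a binned size distribution
#'
#' Relative-frequency histogram in the field's convention: 2-nm bins
#' labelled by their lower limit, frequencies as percent of particles.
#'
#' @param object a `size_summary` from [summarize_sizes()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot size_summary
#' @export
autoplot.size_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_lower, y = .data$rel_freq_pct)) +
    ggplot2::geom_col(width = object$bin_width * 0.9,
                      just = 0, fill = "grey35") +
    ggplot2::labs(x = sprintf("Particle size (lower limit of %g-nm bins)",
                              object$bin_width),
                  y = "Relative frequency (%)") +
    ggplot2::theme_classic()
}

#' Bland-Altman agreement plot
#'
#' Per-pair differences against means, with the bias and the 95% limits
#' of agreement drawn as horizontal lines.
#'
#' @param object a `bland_altman` from [bland_altman()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of paired sizes", y = "Difference (a - b)") +
    ggplot2::theme_classic()
}

#' Plot an antibody saturation curve
#'
#' Labelled fraction against antibody concentration; plateau points are
#' highlighted and the plateau estimate drawn as a dashed line.
#'
#' @param object a `saturation_curve` from [saturation_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot saturation_curve
#' @export
autoplot.saturation_curve <- function(object, ...) {
  g <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$concentration,
                                    y = .data$fraction)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_plateau), size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "Antibody concentration",
                  y = "Labelled particles (%)") +
    ggplot2::theme_classic()
  if (isTRUE(attr(object, "has_plateau"))) {
    g <- g + ggplot2::geom_hline(yintercept = attr(object, "plateau"),
                                 linetype = 2)
  }
  g
}

#' Plot the SEC fraction size trend
#'
#' Mean particle size per gel filtration fraction with the fitted OLS
#' line.
#'
#' @param object a `sec_trend` from [sec_trend_fit()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sec_trend
#' @export
autoplot.sec_trend <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "Fraction", y = "Mean particle size (nm)") +
    ggplot2::theme_classic()
}

#' Plot an aggregate census
#'
#' Event counts per aggregate-size category.
#'
#' @param object an `aggregate_census`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot aggregate_census
#' @export
autoplot.aggregate_census <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$category, y = .data$n_events)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Particles per event", y = "Events") +
    ggplot2::theme_classic()
}

#' Display a micrograph with optional mask outlines
#'
#' Renders the intensity grid in image orientation (origin top-left) and
#' overlays instance mask boundary pixels.
#'
#' @param mg a [micrograph()].
#' @param instances optional [instance_set()] to outline.
#' @param colour outline colour.
#' @return a ggplot.
#' @export
plot_micrograph <- function(mg, instances = NULL, colour = "red") {
  stopifnot(inherits(mg, "micrograph"))
  nr <- nrow(mg$image)
  df <- tibble::tibble(
    x = as.vector(col(mg$image)) - 1,
    y = as.vector(row(mg$image)) - 1,
    intensity = as.vector(mg$image)
  )
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(instances) && length(instances$masks) > 0) {
    bidx <- unlist(lapply(instances$masks, mask_boundary,
                          dims = instances$dim))
    g <- g + ggplot2::geom_point(
      data = tibble::tibble(x = idx_cols(bidx, nr) - 1,
                            y = idx_rows(bidx, nr) - 1),
      colour = colour, size = 0.1)
  }
  g
}
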