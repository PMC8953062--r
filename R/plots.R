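#' Stacked-bar plot of one or more taxonomic profiles
#'
#' @param object A `tax_profile` tibble, or a long tibble with `sample_id`,
#'   `taxon`, `fraction` covering several samples.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tax_profile <- function(object, ...) {
  df <- as_tibble(object)
  if (!"sample_id" %in% names(df)) {
    df$sample_id <- attr(object, "sample_id") %||% "sample"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                   fill = .data$taxon)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "Relative abundance", fill = "Taxon") +
    ggplot2::theme_minimal()
}

#' Compare profiles across samples as stacked bars
#'
#' @param profiles Long tibble with `sample_id`, `taxon`, `fraction` (e.g.
#'   the `profiles` element of [run_cohort()]).
#' @return A ggplot object.
#' @export
plot_composition <- function(profiles) {
  cls <- class(profiles)
  if (!"tax_profile" %in% cls) class(profiles) <- c("tax_profile", cls)
  autoplot(profiles)
}

#' Ordination scatter plot of a PCoA result
#'
#' @param object A `vagitax_pcoa` object.
#' @param colour Optional vector (one value per sample) used as point colour,
#'   e.g. a sampling-method or subject label.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vagitax_pcoa <- function(object, colour = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3L) abort("Need at least 2 axes to plot an ordination.")
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$proportion_explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$proportion_explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour), size = 2) +
      ggplot2::labs(colour = NULL)
  }
}
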