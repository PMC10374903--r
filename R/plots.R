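# ggplot2 visualisations of fitted objects and feature tables.

#' @exportS3Method ggplot2::autoplot
autoplot.rescore_calibration <- function(object, ...) {
  knots <- tidy(object)
  ggplot2::ggplot(knots, ggplot2::aes(x = .data$experimental, y = .data$calibrated)) +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "experimental value", y = "calibrated (predicted scale)",
      title = sprintf("%s calibration (n = %d, charge %s)",
                      object$kind, object$n_train, as.character(object$charge))
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.kde_binset <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin * object$bin_width, y = .data$E)) +
    ggplot2::geom_col(fill = "#41b6c4") +
    ggplot2::geom_hline(yintercept = object$U, linetype = "dashed") +
    ggplot2::labs(
      x = "experimental bin", y = "weighted PSM count E",
      title = sprintf("KDE bins (charge %s); dashed line: prior pseudo-count U = %g",
                      as.character(object$charge), object$U)
    ) +
    ggplot2::theme_minimal()
}

#' Target/decoy feature distributions
#'
#' Density plot of one computed feature, split by PSM label — the visual
#' check that a feature separates correct from incorrect matches.
#'
#' @param features Feature tibble from [compute_features()].
#' @param feature Feature column to plot.
#' @return A ggplot object.
#' @export
plot_feature_separation <- function(features, feature = "unweighted_spectral_entropy") {
  if (!feature %in% names(features)) abort(sprintf("no feature column '%s'", feature))
  d <- mutate(features, class = ifelse(.data$label == 1L, "target", "decoy"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[feature]], fill = .data$class)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::scale_fill_manual(values = c(target = "#1b9e77", decoy = "#d95f02")) +
    ggplot2::labs(x = feature, y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
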