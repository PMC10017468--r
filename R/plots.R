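# ggplot2 displays for the main result types.

#' Plot lobar involvement frequencies with bootstrap spread
#'
#' Bar chart of the lobar involvement frequencies among focal-type
#' participants, ordered by frequency, with approximate 95% bootstrap
#' intervals (point frequency +/- 1.96 bootstrap SD).
#'
#' @param object A `freq_boot` from [involvement_frequency_bootstrap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.freq_boot <- function(object, ...) {
  f <- dplyr::arrange(object$frequencies, dplyr::desc(.data$frequency))
  f$lobe <- factor(f$lobe, levels = f$lobe)
  ggplot2::ggplot(f, ggplot2::aes(x = .data$lobe, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$frequency - 1.96 * .data$boot_sd, 0),
                   ymax = .data$frequency + 1.96 * .data$boot_sd),
      width = 0.2) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(
      x = NULL, y = "involvement frequency",
      title = "Lobar amyloid involvement among focal-type participants",
      subtitle = sprintf("n = %d participants, %d bootstrap resamples",
                         object$n_included, object$n_resamples)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the pairwise -log10 p matrix of lobar frequency comparisons
#'
#' Tile display of the bootstrap pairwise p-values on the -log10 scale.
#'
#' @param x A `freq_boot` object.
#' @return A ggplot object.
#' @export
plot_frequency_pvalues <- function(x) {
  stopifnot(inherits(x, "freq_boot"))
  pw <- dplyr::bind_rows(
    x$pairwise,
    dplyr::rename(x$pairwise, lobe_a = "lobe_b", lobe_b = "lobe_a")
  )
  ord <- x$frequencies$lobe[order(-x$frequencies$frequency)]
  pw$lobe_a <- factor(pw$lobe_a, levels = ord)
  pw$lobe_b <- factor(pw$lobe_b, levels = ord)
  ggplot2::ggplot(pw, ggplot2::aes(.data$lobe_a, .data$lobe_b,
                                   fill = .data$neg_log10_p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise lobar frequency comparisons") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot Centiloid against the number of involved regions
#'
#' Box plots of global Centiloid by involved-region count, colored by group
#' label — the staging analogue of the burden-versus-extent relation.
#'
#' @param object A staging tibble from [stage_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amyloid_staging <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$n_involved <- factor(d$n_involved, levels = 0:10)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_involved, y = .data$global_cl,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "number of involved regions",
                  y = "global amyloid burden (Centiloid)",
                  fill = "group") +
    ggplot2::theme_minimal()
}

#' Plot regional cutoffs
#'
#' Dot plot of the derived per-region SUVR cutoffs with the retained maxima
#' they were raised from.
#'
#' @param object A `regional_cutoffs` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regional_cutoffs <- function(object, ...) {
  d <- tidy(object)
  d$region <- factor(d$region, levels = rev(region_names()))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$region)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$final_max,
                                     color = "retained max")) +
    ggplot2::geom_point(ggplot2::aes(x = .data$cutoff, color = "cutoff")) +
    ggplot2::labs(x = "SUVR", y = NULL, color = NULL,
                  title = sprintf("Regional positivity cutoffs [%s]",
                                  object$ligand)) +
    ggplot2::theme_minimal()
}
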