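# ggplot2 views of the main result types.

#' @describeIn accuracy_vs_depth_curve Concordance against mean read
#'   depth, one series per calling mode (mean over replicates, with
#'   per-replicate points).
#' @param object A `depth_curve`.
#' @export
autoplot.depth_curve <- function(object, ...) {
  summ <- glance(object)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$depth,
                                     y = 100 * .data$mean_concordance,
                                     colour = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = object,
      ggplot2::aes(y = 100 * .data$concordance),
      alpha = 0.3, size = 1
    ) +
    ggplot2::labs(x = "Mean read depth (X)",
                  y = "Genotype concordance (%)",
                  colour = "Calling mode") +
    ggplot2::theme_minimal()
}

#' @describeIn sliding_window_scan Tajima's D along the genome with
#'   outlier cutoffs marked.
#' @param object A `window_scan`.
#' @param cutoffs Horizontal reference lines (default -2, +2).
#' @param ... Unused.
#' @export
autoplot.window_scan <- function(object, cutoffs = c(-2, 2), ...) {
  mid <- (object$start + object$end) / 2
  df <- tibble(chromosome = object$chromosome, mid = mid, D = object$D)
  ggplot2::ggplot(df[!is.na(df$D), ],
                  ggplot2::aes(x = .data$mid / 1e6, y = .data$D)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = cutoffs, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::facet_wrap(~chromosome, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Tajima's D") +
    ggplot2::theme_minimal()
}

#' @describeIn paralog_age_comparison Gene-level D by duplication-age
#'   class, with the background median marked.
#' @param object A `paralog_comparison`.
#' @export
autoplot.paralog_comparison <- function(object, ...) {
  bg_median <- object$class_summary$median_D[
    object$class_summary$age_class == "background"
  ]
  ggplot2::ggplot(object$member_d,
                  ggplot2::aes(x = .data$age_class, y = .data$D)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = bg_median, linetype = "dotted") +
    ggplot2::labs(x = "Duplication age class",
                  y = "Mean Tajima's D per gene") +
    ggplot2::theme_minimal()
}
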