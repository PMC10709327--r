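# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_tile scale_x_log10 labs theme_minimal scale_fill_gradient2
#'   position_dodge geom_errorbar facet_wrap element_text theme
#' @export
ggplot2::autoplot

#' Plot an amino-acid composition comparison
#'
#' Side-by-side residue frequencies of the capped-peptide set and the
#' reference set, from [compare_composition()] output.
#'
#' @param comparison Tibble from [compare_composition()].
#' @return A ggplot object.
#' @export
plot_composition <- function(comparison) {
  long <- comparison %>%
    select("residue", capped = "mean_capped", reference = "mean_ref") %>%
    tidyr::pivot_longer(c("capped", "reference"), names_to = "set",
                        values_to = "frequency")
  ggplot(long, aes(x = .data$residue, y = .data$frequency,
                   fill = .data$set)) +
    geom_col(position = position_dodge()) +
    labs(x = "Amino acid", y = "Mean per-peptide frequency", fill = NULL) +
    theme_minimal()
}

#' Plot a flanking-residue frequency heatmap
#'
#' @param profile Tibble from [flanking_profile()].
#' @return A ggplot object.
#' @export
plot_flanking <- function(profile) {
  ggplot(profile, aes(x = factor(.data$offset), y = .data$residue,
                      fill = .data$freq)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "firebrick",
                         midpoint = 0, mid = "white") +
    labs(x = "Offset from capped residue", y = "Residue",
         fill = "Frequency") +
    theme_minimal()
}

#' @describeIn expression_zscore Clustered heatmap of the z-score matrix.
#' @param object An `expression_zscore` object.
#' @param ... Unused.
#' @method autoplot expression_zscore
#' @export
autoplot.expression_zscore <- function(object, ...) {
  long <- tidy(object) %>%
    mutate(
      gene = factor(.data$gene, levels = rownames(object$zscore)),
      tissue = factor(.data$tissue, levels = colnames(object$zscore))
    )
  ggplot(long, aes(x = .data$tissue, y = .data$gene, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "z") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @describeIn fit_4pl Dose-response curve with the fitted 4PL overlaid.
#' @param object A fitted object.
#' @method autoplot fit_4pl
#' @export
autoplot.fit_4pl <- function(object, ...) {
  grid <- tibble(dose = 10^seq(log10(min(object$data$dose)),
                               log10(max(object$data$dose)),
                               length.out = 200))
  grid$response <- predict(object, newdata = grid)
  ggplot(object$data, aes(x = .data$dose, y = .data$y)) +
    geom_point() +
    geom_line(data = grid, aes(y = .data$response)) +
    scale_x_log10() +
    labs(x = "Dose (M)", y = "Response") +
    theme_minimal()
}

#' @describeIn fit_decay Decay series with the fitted exponential overlaid.
#' @param object A fitted object.
#' @method autoplot fit_decay
#' @export
autoplot.fit_decay <- function(object, ...) {
  grid <- tibble(t = seq(min(object$data$t), max(object$data$t),
                         length.out = 200))
  grid$level <- predict(object, newdata = grid)
  ggplot(object$data, aes(x = .data$t, y = .data$y)) +
    geom_point() +
    geom_line(data = grid, aes(y = .data$level)) +
    labs(x = "Time (min)", y = "Level") +
    theme_minimal()
}

#' Plot an MRM transition trace
#'
#' @param trace Tibble with `time`, `intensity` (and optionally
#'   `expected_rt`) columns for one compound.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  p <- ggplot(trace, aes(x = .data$time, y = .data$intensity)) +
    geom_line() +
    labs(x = "Retention time (min)", y = "Intensity") +
    theme_minimal()
  if ("expected_rt" %in% names(trace)) {
    p <- p + ggplot2::geom_vline(xintercept = unique(trace$expected_rt),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}
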