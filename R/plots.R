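#' Frequency plot of somatic gains and losses along the genome
#'
#' Gains plotted upward and losses downward per clone, in genome order,
#' with chromosome boundaries marked — the standard cohort aberration
#' summary.
#'
#' @param freq Output of [aberration_frequency()].
#' @return A ggplot object.
#' @export
plot_aberration_frequency <- function(freq) {
  assert_cols(freq, c("clone_id", "chrom", "position", "gain_frac",
                      "loss_frac"), "`freq`")
  freq <- freq |>
    arrange(.data$chrom, .data$position) |>
    mutate(index = row_number())
  bounds <- freq |>
    group_by(.data$chrom) |>
    summarise(start = min(.data$index), .groups = "drop")
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$gain_frac), fill = "#D55E00",
                      width = 1) +
    ggplot2::geom_col(ggplot2::aes(y = -.data$loss_frac), fill = "#0072B2",
                      width = 1) +
    ggplot2::geom_vline(xintercept = bounds$start - 0.5, linewidth = 0.2,
                        colour = "grey70") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = bounds$start, labels = bounds$chrom,
                                expand = c(0.01, 0)) +
    ggplot2::labs(x = "chromosome", y = "aberration frequency (gain up, loss down)") +
    ggplot2::theme_minimal()
}

#' Plot one sample's segmented profile
#'
#' Clone log2 ratios in genome order with segment means overlaid.
#'
#' @param segmented Output of [segment_profiles()].
#' @param sample A `sample_id` present in `segmented`.
#' @return A ggplot object.
#' @export
plot_profile <- function(segmented, sample) {
  df <- segmented |>
    filter(.data$sample_id == sample) |>
    arrange(.data$chrom, .data$position) |>
    mutate(index = row_number())
  if (nrow(df) == 0) abort(sprintf("sample %s not found", sample))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$log2ratio), size = 0.4,
                        alpha = 0.5) +
    ggplot2::geom_step(ggplot2::aes(y = .data$seg_mean), colour = "#D55E00",
                       linewidth = 0.6) +
    ggplot2::labs(title = sample, x = "clone index", y = "log2 ratio") +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.concordance_fit Boxplots of intra- vs inter-patient
#'   correlations per analysis scope.
#' @export
autoplot.concordance_fit <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$scope, y = .data$r,
                               fill = .data$type)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(intra = "#D55E00",
                                          inter = "#0072B2")) +
    ggplot2::labs(x = "chromosome arm", y = "pairwise Pearson r",
                  fill = "pair type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @describeIn tidy.preferential_fit Observed patient log-odds per marker
#'   with the preferential-flag threshold.
#' @export
autoplot.preferential_fit <- function(object, ...) {
  ggplot2::ggplot(object$patients,
                  ggplot2::aes(x = .data$marker_id, y = .data$ln_odds)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$preferential),
                         width = 0.15, height = 0, size = 1.5) +
    ggplot2::geom_hline(yintercept = object$params$threshold,
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "marker", y = "patient ln O (odds of random loss)",
                  colour = "preferential") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
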