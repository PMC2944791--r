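#' Per-sample noise estimate: scaled MAD of segmentation residuals
#'
#' The experimental noise of each array is estimated as the scaled median
#' absolute deviation of the difference between observed log2 ratios and
#' the fitted segment means: `median(|observed - segmented|) * 1.4826`.
#' The 1.4826 factor makes the estimate consistent with the Gaussian sd.
#'
#' @param segmented Output of [segment_profiles()].
#' @return Tibble with one row per sample: `sample_id`, `mad`, and
#'   `patient_id` if present in the input.
#' @export
compute_mads <- function(segmented) {
  assert_cols(segmented, c("sample_id", "log2ratio", "seg_mean"), "`segmented`")
  keep <- intersect(c("sample_id", "patient_id"), names(segmented))
  out <- segmented |>
    filter(!is.na(.data$log2ratio), !is.na(.data$seg_mean)) |>
    group_by(across(dplyr::all_of(keep))) |>
    summarise(mad = scaled_mad(.data$log2ratio - .data$seg_mean),
              .groups = "drop")
  missing <- setdiff(unique(segmented$sample_id), out$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("no residuals available for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out
}

scaled_mad <- function(r) {
  r <- r[!is.na(r)]
  if (length(r) == 0) abort("cannot compute MAD of zero residuals")
  stats::median(abs(r)) * 1.4826
}

#' Quality-control filter on sample MAD
#'
#' Splits a segmented cohort into samples retained and excluded by the
#' noise criterion: a sample is excluded when its residual MAD exceeds the
#' threshold (strictly greater; a sample at exactly the threshold is
#' kept). Default threshold 0.2 log2-ratio units.
#'
#' @param segmented Output of [segment_profiles()].
#' @param threshold MAD threshold in log2-ratio units.
#' @param mads Optional precomputed [compute_mads()] table.
#' @return List with elements `kept` and `excluded` (clone-level tibbles,
#'   original sample order preserved) and `mads` (the per-sample MAD table
#'   with an `excluded` flag).
#' @export
qc_filter <- function(segmented, threshold = 0.2, mads = NULL) {
  assert_nonneg(threshold, "threshold")
  if (nrow(segmented) == 0) {
    return(list(kept = segmented, excluded = segmented,
                mads = tibble(sample_id = character(), mad = double(),
                              excluded = logical())))
  }
  if (is.null(mads)) mads <- compute_mads(segmented)
  mads <- mutate(mads, excluded = .data$mad > threshold)
  bad <- mads$sample_id[mads$excluded]
  list(
    kept = filter(segmented, !(.data$sample_id %in% bad)),
    excluded = filter(segmented, .data$sample_id %in% bad),
    mads = mads
  )
}
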