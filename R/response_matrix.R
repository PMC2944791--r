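#' Build the response matrix for concordance and ICC analyses
#'
#' The response value for each clone in each sample is the fitted segment
#' mean, except where the clone is an outlier within its segment — further
#' than `outlier_k` sample-MADs from the segment mean — in which case the
#' original log2 ratio is kept. Using segment means suppresses clone-level
#' noise; keeping raw values for outliers preserves genuine single-clone
#' signal. The same response values feed the pairwise-correlation tests
#' and the per-clone intraclass-correlation model.
#'
#' @param segmented Output of [segment_profiles()] (or
#'   [call_gains_losses()]).
#' @param outlier_k Outlier threshold in sample-MAD units; `Inf` gives pure
#'   segment means.
#' @param mads Optional precomputed [compute_mads()] table.
#' @return Tibble with `sample_id`, `patient_id` (if present), `clone_id`,
#'   `chrom`, `arm`, `position`, `mad` and the response value `y`.
#' @export
build_response_matrix <- function(segmented, outlier_k = 3, mads = NULL) {
  assert_cols(segmented, c("sample_id", "clone_id", "chrom", "log2ratio",
                           "seg_mean"), "`segmented`")
  assert_nonneg(outlier_k, "outlier_k")
  if (any(is.na(segmented$seg_mean) & !is.na(segmented$log2ratio))) {
    abort("`segmented` contains unsegmented non-missing clones; run segment_profiles() first.")
  }
  if (is.null(mads)) mads <- compute_mads(segmented)
  keep <- intersect(c("sample_id", "patient_id", "tumor_type", "clone_id",
                      "chrom", "arm", "position"), names(segmented))
  segmented |>
    left_join(select(mads, "sample_id", "mad"), by = "sample_id") |>
    mutate(
      .outlier = !is.na(.data$log2ratio) &
        abs(.data$log2ratio - .data$seg_mean) > outlier_k * .data$mad,
      y = ifelse(.data$.outlier, .data$log2ratio, .data$seg_mean)
    ) |>
    select(dplyr::all_of(keep), "mad", "y")
}
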