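#' Normalize aCGH profiles against array covariates
#'
#' Removes systematic trends in the log2 ratios attributable to probe GC
#' content and geometric position on the array. Each sample's values are
#' regressed on the supplied per-clone covariates with a robust linear fit
#' (Huber M-estimation via iteratively reweighted least squares) and
#' replaced by the residuals, re-centered to median zero. With no
#' covariates the values are median-centered only.
#'
#' @param acgh Clone-level tibble (see [segment_profiles()] for columns).
#' @param covariates Optional tibble with `clone_id` plus any numeric
#'   covariate columns (e.g. `gc`, `array_row`, `array_col`). Must cover
#'   every clone present in `acgh`.
#' @return `acgh` with `log2ratio` replaced by normalized values.
#' @export
normalize_profiles <- function(acgh, covariates = NULL) {
  assert_cols(acgh, c("sample_id", "clone_id", "log2ratio"), "`acgh`")
  if (is.null(covariates)) {
    return(acgh |>
             group_by(.data$sample_id) |>
             mutate(log2ratio = .data$log2ratio -
                      stats::median(.data$log2ratio, na.rm = TRUE)) |>
             ungroup())
  }
  covariates <- as_tibble(covariates)
  assert_cols(covariates, "clone_id", "`covariates`")
  cov_cols <- setdiff(names(covariates), "clone_id")
  if (length(cov_cols) == 0) abort("`covariates` has no covariate columns.")
  if (!all(acgh$clone_id %in% covariates$clone_id)) {
    abort("`covariates` does not cover every clone in `acgh`.")
  }
  if (anyDuplicated(covariates$clone_id)) {
    abort("`covariates$clone_id` must be unique.")
  }

  acgh |>
    left_join(covariates, by = "clone_id") |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      ok <- !is.na(df$log2ratio) &
        complete.cases(df[cov_cols])
      if (sum(ok) > length(cov_cols) + 2L) {
        dat <- df[ok, cov_cols, drop = FALSE]
        dat$.y <- df$log2ratio[ok]
        fit <- tryCatch(MASS::rlm(.y ~ ., data = dat, maxit = 50),
                        error = function(e) stats::lm(.y ~ ., data = dat))
        df$log2ratio[ok] <- as.numeric(fit$residuals)
      }
      df$log2ratio <- df$log2ratio - stats::median(df$log2ratio, na.rm = TRUE)
      df[setdiff(names(df), cov_cols)]
    }) |>
    ungroup()
}
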