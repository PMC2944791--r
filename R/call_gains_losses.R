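#' Call per-clone gains and losses by merging segment levels
#'
#' Converts segment means into discrete copy-number states. Within each
#' sample, segments across the whole genome start as separate "levels";
#' the procedure repeatedly takes the pair of levels with the closest
#' means whose clone-value distributions are not distinguishable by a
#' Wilcoxon rank-sum test at `merge_p`, merges them, and re-estimates the
#' merged level's mean, until every remaining pair of levels differs. The
#' level whose mean is nearest 0 is declared neutral (ties broken toward
#' the level with more clones: the reference channel defines diploid);
#' levels above it are gains, below it losses, and every clone inherits
#' its level's call.
#'
#' @param segmented Output of [segment_profiles()].
#' @param merge_p Significance level below which two levels are considered
#'   distinct (and therefore not merged).
#' @return `segmented` with added columns `level_mean` (the merged level's
#'   mean) and `call` (factor: `gain`, `loss`, `neutral`, `missing`).
#' @examples
#' sim <- simulate_acgh_cohort(sim_config(n_patients = 1, n_clones = 88,
#'                                        seed = 3))
#' set.seed(1)
#' calls <- segment_profiles(sim$acgh, n_perm = 100) |> call_gains_losses()
#' table(calls$call)
#' @export
call_gains_losses <- function(segmented, merge_p = 1e-4) {
  assert_cols(segmented, c("sample_id", "log2ratio", "seg_id", "seg_mean"),
              "`segmented`")
  assert_prob(merge_p, "merge_p")

  segmented |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) call_one_sample(df, merge_p)) |>
    ungroup()
}

call_one_sample <- function(df, merge_p) {
  ok <- !is.na(df$log2ratio) & !is.na(df$seg_id)
  df$level_mean <- NA_real_
  df$call <- factor(rep("missing", nrow(df)),
                    levels = c("gain", "loss", "neutral", "missing"))
  if (!any(ok)) return(df)

  values <- split(df$log2ratio[ok], df$seg_id[ok])
  level_of <- setNames(seq_along(values), names(values))  # seg_id -> level
  active <- rep(TRUE, length(values))

  level_values <- function(l) unlist(values[names(level_of)[level_of == l]],
                                     use.names = FALSE)
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    means <- purrr::map_dbl(act, function(l) mean(level_values(l)))
    ord <- order(means)
    # Candidate merges: adjacent levels in mean order, nearest gap first.
    gaps <- diff(means[ord])
    merged <- FALSE
    for (g in order(gaps)) {
      l1 <- act[ord[g]]
      l2 <- act[ord[g + 1L]]
      if (levels_distinguishable(level_values(l1), level_values(l2), merge_p)) next
      level_of[level_of == l2] <- l1
      active[l2] <- FALSE
      merged <- TRUE
      break
    }
    if (!merged) break
  }

  level_means <- tapply(df$log2ratio[ok], level_of[df$seg_id[ok]], mean)
  level_sizes <- tapply(df$log2ratio[ok], level_of[df$seg_id[ok]], length)
  lm_num <- as.numeric(level_means)
  # Neutral: mean closest to 0, ties to the larger level.
  neutral <- which.min(abs(lm_num) - as.numeric(level_sizes) * 1e-12)
  call_of_level <- ifelse(lm_num > lm_num[neutral], "gain",
                          ifelse(lm_num < lm_num[neutral], "loss", "neutral"))
  names(call_of_level) <- names(level_means)

  lev <- as.character(level_of[df$seg_id[ok]])
  df$level_mean[ok] <- lm_num[match(lev, names(level_means))]
  df$call[ok] <- call_of_level[lev]
  df
}

# Rank-sum comparison of two levels' clone values; indistinguishable when
# p > merge_p. Constant identical values are indistinguishable by fiat.
levels_distinguishable <- function(v1, v2, merge_p) {
  if (stats::var(c(v1, v2)) <= .Machine$double.eps) return(FALSE)
  p <- suppressWarnings(wilcox.test(v1, v2, exact = FALSE)$p.value)
  if (is.na(p)) return(FALSE)
  p <= merge_p
}

#' Cohort aberration frequencies per clone
#'
#' Fraction of samples called gain and called loss at each clone, ignoring
#' missing calls — the summary behind cohort-level frequency plots.
#'
#' @param calls Output of [call_gains_losses()].
#' @return Tibble with one row per clone: `clone_id`, `chrom`, `arm`,
#'   `position`, `n_samples` (non-missing), `gain_frac`, `loss_frac`.
#' @export
aberration_frequency <- function(calls) {
  assert_cols(calls, c("clone_id", "chrom", "call"), "`calls`")
  if (nrow(calls) == 0) abort("`calls` is empty.")
  keep <- intersect(c("clone_id", "chrom", "arm", "position"), names(calls))
  calls |>
    filter(.data$call != "missing") |>
    group_by(across(dplyr::all_of(keep))) |>
    summarise(
      n_samples = n(),
      gain_frac = mean(.data$call == "gain"),
      loss_frac = mean(.data$call == "loss"),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$position)
}
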