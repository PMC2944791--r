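#' Is a sample's profile informative over a set of clones?
#'
#' A sample can only contribute a meaningful correlation if its profile is
#' neither flat nor saturated over the analysis scope: at least 20% of its
#' non-missing clone values must exceed 2 sample-MADs in absolute value
#' (real signal present) and at least 20% must lie at or below 2 MADs
#' (a baseline present). Pairs where neither member is informative are
#' excluded so correlations are not driven by flat profiles.
#'
#' @param values Numeric response values for one sample over the scope
#'   (arm or genome); `NA` allowed.
#' @param mad The sample's MAD.
#' @param frac Required fraction on each side (default 0.2).
#' @return Logical flag; `FALSE` when no non-missing values exist.
#' @export
informative_profile <- function(values, mad, frac = 0.2) {
  v <- abs(values[!is.na(values)])
  if (length(v) == 0) return(FALSE)
  mean(v > 2 * mad) >= frac && mean(v <= 2 * mad) >= frac
}

#' Pairwise Pearson correlations between tumor profiles
#'
#' Computes the Pearson correlation of response values over the scoped
#' clones for every eligible pair of samples, labelled `intra` (same
#' patient) or `inter` (different patients). Intra pairs are drawn only
#' from patients contributing at least `min_tumors` samples; a pair is
#' eligible only if at least one member is informative over the scope
#' (see [informative_profile()]). Pairs with fewer than 2 complete clone
#' pairs or a constant member are skipped.
#'
#' @param resp Response tibble from [build_response_matrix()].
#' @param arm Scope: an arm label as `"17q"`, or `NULL` for genome-wide
#'   (all autosomal clones).
#' @param min_tumors Minimum samples per patient for intra-pair
#'   eligibility.
#' @return Tibble of pairs: `sample_1`, `sample_2`, `patient_1`,
#'   `patient_2`, `type` (`intra`/`inter`), `r`.
#' @export
pairwise_correlations <- function(resp, arm = NULL, min_tumors = 3) {
  assert_cols(resp, c("sample_id", "patient_id", "clone_id", "chrom", "arm",
                      "mad", "y"), "`resp`")
  scoped <- scope_clones(resp, arm)
  wide <- scoped |>
    select("sample_id", "clone_id", "y") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "y") |>
    arrange(.data$clone_id)
  Y <- as.matrix(wide[-1])
  samples <- colnames(Y)
  meta <- distinct(resp, .data$sample_id, .data$patient_id, .data$mad)
  meta <- meta[match(samples, meta$sample_id), ]

  informative <- vapply(seq_along(samples), function(s) {
    informative_profile(Y[, s], meta$mad[s])
  }, logical(1))

  suppressWarnings(R <- stats::cor(Y, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(R), arr.ind = TRUE)
  pairs <- tibble(
    sample_1 = samples[idx[, 1]],
    sample_2 = samples[idx[, 2]],
    patient_1 = meta$patient_id[idx[, 1]],
    patient_2 = meta$patient_id[idx[, 2]],
    r = R[idx],
    eligible = informative[idx[, 1]] | informative[idx[, 2]]
  )

  tumor_counts <- dplyr::count(meta, .data$patient_id)
  multi <- tumor_counts$patient_id[tumor_counts$n >= min_tumors]
  pairs <- pairs |>
    mutate(type = ifelse(.data$patient_1 == .data$patient_2, "intra", "inter")) |>
    filter(.data$type == "inter" | .data$patient_1 %in% multi)

  n_bad <- sum(is.na(pairs$r))
  if (n_bad > 0) {
    message(sprintf("%d pair(s) skipped (constant profile or <2 shared clones)",
                    n_bad))
  }
  pairs |>
    filter(.data$eligible, !is.na(.data$r)) |>
    select("sample_1", "sample_2", "patient_1", "patient_2", "type", "r")
}

scope_clones <- function(resp, arm) {
  if (is.null(arm)) return(resp)
  if (!grepl("^[0-9]+[pq]$", arm)) abort("`arm` must look like \"17q\".")
  ch <- as.integer(sub("[pq]$", "", arm))
  a <- sub("^[0-9]+", "", arm)
  out <- filter(resp, .data$chrom == ch, .data$arm == a)
  if (nrow(out) == 0) abort(sprintf("no clones on arm %s", arm))
  out
}

#' Eligibility of an analysis scope for the concordance test
#'
#' A chromosome arm (or the genome) enters the concordance comparison only
#' when it has at least `min_clones` clones with non-missing values and at
#' least `min_pairs` sample pairs in each of the intra- and inter-patient
#' groups.
#'
#' @param n_clones Number of scoped clones with non-missing values.
#' @param n_intra,n_inter Eligible pair counts per group.
#' @param min_clones,min_pairs Thresholds (defaults 40 and 20).
#' @return Logical flag.
#' @export
scope_eligible <- function(n_clones, n_intra, n_inter,
                           min_clones = 40, min_pairs = 20) {
  n_clones >= min_clones && n_intra >= min_pairs && n_inter >= min_pairs
}

#' Compare intra- and inter-patient correlation groups
#'
#' Tests whether within-patient correlations exceed between-patient
#' correlations. Group variances are first compared with the
#' Brown–Forsythe (median-centered Levene) test; a pooled-variance
#' two-sided t-test is reported only when the variances are not
#' significantly unequal (`levene_p >= levene_gate`), and a Welch
#' two-sided t-test is always reported. `p` is the pooled p-value when
#' available, otherwise the Welch p-value.
#'
#' @param intra,inter Numeric vectors of correlation coefficients (each of
#'   length >= 2).
#' @param levene_gate Variance-equality gate for presenting the pooled t.
#' @return One-row tibble: `n_intra`, `n_inter`, `mean_intra`,
#'   `mean_inter`, `levene_p`, `t_p_pooled` (`NA` when suppressed),
#'   `t_p_welch`, `p`.
#' @export
compare_groups <- function(intra, inter, levene_gate = 0.05) {
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (length(intra) < 2 || length(inter) < 2) {
    abort("both groups need at least 2 correlation values.")
  }
  vals <- c(intra, inter)
  grp <- factor(rep(c("intra", "inter"), c(length(intra), length(inter))))
  levene_p <- car::leveneTest(vals, grp, center = median)[["Pr(>F)"]][1]
  welch <- t.test(intra, inter, var.equal = FALSE)$p.value
  pooled <- if (!is.na(levene_p) && levene_p >= levene_gate) {
    t.test(intra, inter, var.equal = TRUE)$p.value
  } else {
    NA_real_
  }
  tibble(
    n_intra = length(intra), n_inter = length(inter),
    mean_intra = mean(intra), mean_inter = mean(inter),
    levene_p = levene_p, t_p_pooled = pooled, t_p_welch = welch,
    p = ifelse(is.na(pooled), welch, pooled)
  )
}

#' Holm step-down adjustment for multiple testing
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(pvals) {
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "holm")
}

#' Genome-wide within- vs between-patient concordance test
#'
#' Applies the pair filters and group comparison of
#' [pairwise_correlations()] and [compare_groups()] to correlations over
#' all autosomal clones.
#'
#' @inheritParams pairwise_correlations
#' @inheritParams scope_eligible
#' @inheritParams compare_groups
#' @return One-row tibble as [compare_groups()], plus `n_clones` and
#'   `eligible`.
#' @export
genome_wide_test <- function(resp, min_tumors = 3, min_clones = 40,
                             min_pairs = 20, levene_gate = 0.05) {
  pairs <- pairwise_correlations(resp, arm = NULL, min_tumors = min_tumors)
  test_scope(resp, pairs, arm = NA_character_, min_clones, min_pairs,
             levene_gate, strict = TRUE)
}

test_scope <- function(scoped_resp, pairs, arm, min_clones, min_pairs,
                       levene_gate, strict = FALSE) {
  n_clones <- scoped_resp |>
    filter(!is.na(.data$y)) |>
    distinct(.data$clone_id) |>
    nrow()
  intra <- pairs$r[pairs$type == "intra"]
  inter <- pairs$r[pairs$type == "inter"]
  eligible <- scope_eligible(n_clones, length(intra), length(inter),
                             min_clones, min_pairs)
  if (!eligible) {
    if (strict) {
      abort(sprintf(
        "scope not eligible: %d clones, %d intra / %d inter pairs (need >= %d clones, %d pairs each)",
        n_clones, length(intra), length(inter), min_clones, min_pairs))
    }
    return(tibble(
      arm = arm, n_clones = n_clones, eligible = FALSE,
      n_intra = length(intra), n_inter = length(inter),
      mean_intra = NA_real_, mean_inter = NA_real_,
      levene_p = NA_real_, t_p_pooled = NA_real_, t_p_welch = NA_real_,
      p = NA_real_
    ))
  }
  res <- compare_groups(intra, inter, levene_gate)
  dplyr::bind_cols(tibble(arm = arm, n_clones = n_clones, eligible = TRUE), res)
}

#' Fit the full concordance analysis: per-arm and genome-wide
#'
#' Runs the pairwise-correlation comparison on every chromosome arm
#' present in the response matrix and genome-wide, applies the arm
#' eligibility rule, and Holm-adjusts the per-arm p-values across eligible
#' arms (pooled and Welch columns adjusted separately).
#'
#' @inheritParams genome_wide_test
#' @return An object of class `concordance_fit` with components `arms`
#'   (per-arm results tibble with `holm_p_pooled`, `holm_p_welch`),
#'   `genome` (one-row genome-wide result, `NULL` if the genome scope is
#'   ineligible), `pairs` (all pair correlations with scope labels) and
#'   `params`. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' sim <- simulate_acgh_cohort(sim_config(n_patients = 8, n_clones = 110,
#'                                        tumors_min = 3, tumors_max = 3,
#'                                        seed = 11))
#' set.seed(1)
#' seg <- segment_profiles(sim$acgh, n_perm = 200)
#' fit <- fit_concordance(build_response_matrix(seg), min_clones = 5,
#'                        min_pairs = 5)
#' tidy(fit)
#' }
#' @export
fit_concordance <- function(resp, min_tumors = 3, min_clones = 40,
                            min_pairs = 20, levene_gate = 0.05) {
  arms <- resp |>
    distinct(.data$chrom, .data$arm) |>
    arrange(.data$chrom, .data$arm) |>
    mutate(label = paste0(.data$chrom, .data$arm)) |>
    pull("label")

  pair_tbls <- purrr::map(arms, function(a) {
    pairwise_correlations(resp, arm = a, min_tumors = min_tumors)
  })
  arm_results <- purrr::map2(arms, pair_tbls, function(a, pr) {
    test_scope(scope_clones(resp, a), pr, a, min_clones, min_pairs, levene_gate)
  }) |> bind_rows()
  arm_results <- arm_results |>
    mutate(
      holm_p_pooled = holm_with_na(.data$t_p_pooled, .data$eligible),
      holm_p_welch = holm_with_na(.data$t_p_welch, .data$eligible)
    )

  genome <- tryCatch(
    genome_wide_test(resp, min_tumors, min_clones, min_pairs, levene_gate),
    error = function(e) {
      warn(paste("genome-wide test not run:", conditionMessage(e)))
      NULL
    }
  )

  pairs <- purrr::map2(arms, pair_tbls, function(a, pr) {
    mutate(pr, scope = a)
  }) |> bind_rows()

  structure(
    list(arms = arm_results, genome = genome, pairs = pairs,
         params = list(min_tumors = min_tumors, min_clones = min_clones,
                       min_pairs = min_pairs, levene_gate = levene_gate)),
    class = "concordance_fit"
  )
}

# Holm-adjust only across the eligible arms; ineligible stay NA.
holm_with_na <- function(p, eligible) {
  out <- rep(NA_real_, length(p))
  sel <- eligible & !is.na(p)
  out[sel] <- holm_adjust(p[sel])
  out
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat("<concordance_fit>\n")
  cat(sprintf("  arms tested: %d eligible of %d\n",
              sum(x$arms$eligible), nrow(x$arms)))
  if (!is.null(x$genome)) {
    cat(sprintf("  genome-wide: mean intra r = %.3f, mean inter r = %.3f, p = %.3g\n",
                x$genome$mean_intra, x$genome$mean_inter, x$genome$p))
  } else {
    cat("  genome-wide: not eligible\n")
  }
  invisible(x)
}
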