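#' Patient-specific log-odds of random (non-preferential) allele loss
#'
#' For a patient with `n` imbalanced tumors of which `k` retain the A
#' allele, computes the Bayes factor of the random-loss point null
#' (each tumor retains A independently with probability 1/2) against a
#' preferential alternative in which the retention probability is drawn
#' from a Beta prior (uniform by default):
#' \deqn{O_j = \frac{C(n,k)\, 2^{-n}}{\int_0^1 C(n,k) p^k (1-p)^{n-k}\,
#'   dBeta(p; a, b)}}
#' which at the uniform prior reduces to the closed form
#' `O_j = C(n,k) 2^(-n) (n+1)`. Small `ln O_j` (strongly negative) means
#' the split of retained alleles is too lopsided for random loss —
#' evidence of preferential imbalance. Symmetric in `k` and `n - k`.
#'
#' @param k Number of imbalanced tumors retaining allele A (vectorized).
#' @param n Number of imbalanced tumors (each >= 2).
#' @param prior Beta prior shape parameters `c(a, b)` of the preferential
#'   alternative; `c(1, 1)` is uniform.
#' @return `ln O_j`, same length as `k`.
#' @examples
#' patient_log_odds(4, 4)  # all four tumors lose the same allele
#' patient_log_odds(1, 2)  # an even split: evidence for randomness
#' @export
patient_log_odds <- function(k, n, prior = c(1, 1)) {
  stopifnot(length(prior) == 2, all(prior > 0))
  if (any(n < 2)) abort("`n` must be >= 2: patients need two or more imbalanced tumors.")
  if (any(k < 0 | k > n)) abort("`k` must satisfy 0 <= k <= n.")
  log_null <- lchoose(n, k) - n * log(2)
  log_alt <- lchoose(n, k) + lbeta(k + prior[1], n - k + prior[2]) -
    lbeta(prior[1], prior[2])
  log_null - log_alt
}

#' Flag a patient as showing preferential imbalance
#'
#' @param ln_odds Log-odds from [patient_log_odds()].
#' @param threshold Flag when `ln_odds` is strictly below this (default
#'   -1.5).
#' @return Logical vector.
#' @export
flag_preferential <- function(ln_odds, threshold = -1.5) {
  if (any(!is.finite(ln_odds))) abort("`ln_odds` must be finite.")
  ln_odds < threshold
}

#' Simulate the null distribution of patient log-odds
#'
#' Draws, for each replicate and each patient tumor-count `n` in `n_list`,
#' `k ~ Binomial(n, 1/2)` (random allele loss) and records the resulting
#' `ln O_j`. This is the reference sample the locus-level Wilcoxon test
#' compares observed log-odds against; matching `n_list` to the observed
#' patients' counts makes the comparison exact for the cohort at hand.
#'
#' @param n_list Integer vector of per-patient imbalanced-tumor counts
#'   (each >= 2).
#' @param reps Number of replicates (>= 100).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric vector of `reps * length(n_list)` null log-odds.
#' @export
simulate_null_odds <- function(n_list, reps = 1000L, seed = NULL) {
  if (length(n_list) == 0) abort("`n_list` must be non-empty.")
  if (any(n_list < 2)) abort("all tumor counts in `n_list` must be >= 2.")
  reps <- assert_count(reps, "reps", min = 100L)
  draw <- function() {
    n <- rep(n_list, reps)
    k <- rbinom(length(n), n, 0.5)
    patient_log_odds(k, n)
  }
  if (is.null(seed)) draw() else with_child_seed(seed, draw())
}

#' Locus-level test for preferential allelic imbalance
#'
#' Compares the observed patients' log-odds at one locus against a
#' simulated null sample with a one-sided Wilcoxon rank-sum test
#' (alternative: observed log-odds stochastically smaller, as preferential
#' imbalance can only shrink them). Midranks with the normal
#' approximation and tie correction, no continuity correction.
#'
#' @param ln_odds Observed patient log-odds (>= 2 patients).
#' @param null_odds Null sample from [simulate_null_odds()].
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `n_patients`, `wilcoxon_p`, `significant`.
#' @export
locus_preferential_test <- function(ln_odds, null_odds, alpha = 0.05) {
  if (length(null_odds) == 0) abort("`null_odds` must be non-empty.")
  if (length(ln_odds) < 2) abort("need >= 2 observed patients.")
  p <- suppressWarnings(
    wilcox.test(ln_odds, null_odds, alternative = "less",
                exact = FALSE, correct = FALSE)$p.value
  )
  tibble(n_patients = length(ln_odds), wilcoxon_p = p,
         significant = p < alpha)
}

#' Preferential-imbalance analysis across loci
#'
#' The full locus-level procedure over a cohort's patient x marker
#' summaries: restrict to informative patients (two or more imbalanced
#' tumors), compute each patient's `ln O_j`, flag strongly preferential
#' patients (`ln O_j < threshold`), and for each marker with at least two
#' informative patients run [locus_preferential_test()] against a
#' simulated null matched to that marker's patient tumor counts.
#'
#' @param summaries Output of [summarize_patient_marker()].
#' @param reps Null-simulation replicates per locus.
#' @param threshold Patient-flag threshold on `ln O_j`.
#' @param alpha Locus significance level.
#' @param prior Beta prior of the alternative, see [patient_log_odds()].
#' @param holm If `TRUE`, additionally Holm-adjust the locus p-values
#'   (off by default; loci are reported at raw `alpha`).
#' @return An object of class `preferential_fit`: list with `loci`
#'   (per-marker tibble: `marker_id`, `n_heterozygous`, `n_multi_loh`,
#'   `n_tumors_loh`, `n_preferential`, `wilcoxon_p`, `significant`),
#'   `patients` (per informative patient x marker: `ln_odds`,
#'   `preferential`), and `params`. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' sim <- simulate_allelotype_cohort(
#'   sim_config(n_patients = 15, pref_loss_prob = 0.95, imbalance_prob = 0.8,
#'              seed = 5), n_markers = 2)
#' fit <- call_allelic_imbalance(sim$peaks) |>
#'   summarize_patient_marker() |>
#'   test_preferential(reps = 200)
#' tidy(fit)
#' @export
test_preferential <- function(summaries, reps = 1000L, threshold = -1.5,
                              alpha = 0.05, prior = c(1, 1), holm = FALSE) {
  assert_cols(summaries, c("patient_id", "marker_id", "n_imbalanced",
                           "k_favoring_a"), "`summaries`")
  informative <- summaries |>
    filter(.data$n_imbalanced >= 2) |>
    mutate(
      ln_odds = patient_log_odds(.data$k_favoring_a, .data$n_imbalanced,
                                 prior = prior),
      preferential = flag_preferential(.data$ln_odds, threshold)
    )

  loci <- summaries |>
    group_by(.data$marker_id) |>
    summarise(n_heterozygous = n(), .groups = "drop")

  locus_rows <- informative |>
    group_by(.data$marker_id) |>
    dplyr::group_modify(function(df, key) {
      row <- tibble(
        n_multi_loh = nrow(df),
        n_tumors_loh = sum(df$n_imbalanced),
        n_preferential = sum(df$preferential),
        wilcoxon_p = NA_real_, significant = NA
      )
      if (nrow(df) >= 2) {
        null_odds <- simulate_null_odds(df$n_imbalanced, reps = reps)
        res <- locus_preferential_test(df$ln_odds, null_odds, alpha)
        row$wilcoxon_p <- res$wilcoxon_p
        row$significant <- res$significant
      }
      row
    }) |>
    ungroup()

  loci <- left_join(loci, locus_rows, by = "marker_id") |>
    mutate(
      n_multi_loh = dplyr::coalesce(.data$n_multi_loh, 0L),
      n_tumors_loh = dplyr::coalesce(.data$n_tumors_loh, 0L),
      n_preferential = dplyr::coalesce(.data$n_preferential, 0L)
    )
  if (holm) {
    loci <- mutate(loci, holm_p = holm_with_na(.data$wilcoxon_p,
                                               !is.na(.data$wilcoxon_p)))
  }

  structure(
    list(loci = loci, patients = informative,
         params = list(reps = reps, threshold = threshold, alpha = alpha,
                       prior = prior, holm = holm)),
    class = "preferential_fit"
  )
}

#' @export
print.preferential_fit <- function(x, ...) {
  cat("<preferential_fit>\n")
  tested <- sum(!is.na(x$loci$wilcoxon_p))
  cat(sprintf("  loci: %d (%d tested, %d significant at %.2g)\n",
              nrow(x$loci), tested,
              sum(x$loci$significant, na.rm = TRUE), x$params$alpha))
  invisible(x)
}

#' Chi-square test of allelic skew at a SNP
#'
#' Among heterozygous imbalanced tumors at a SNP, tests whether the counts
#' retaining each allele depart from the 50:50 split expected under random
#' imbalance: a two-cell goodness-of-fit chi-square
#' `X^2 = (a - b)^2 / (a + b)` on 1 degree of freedom, no continuity
#' correction.
#'
#' @param retained,lost Counts of tumors favoring each allele (vectorized;
#'   `retained + lost >= 1`).
#' @return Tibble: `retained`, `lost`, `chi_sq`, `p_value`.
#' @examples
#' snp_chisquare_test(28, 7)
#' snp_chisquare_test(3, 3)   # perfectly balanced: p = 1
#' @export
snp_chisquare_test <- function(retained, lost) {
  if (any(retained < 0 | lost < 0)) abort("counts must be non-negative.")
  if (any(retained + lost < 1)) abort("`retained` + `lost` must be >= 1.")
  chi_sq <- (retained - lost)^2 / (retained + lost)
  tibble(retained = retained, lost = lost, chi_sq = chi_sq,
         p_value = pchisq(chi_sq, df = 1, lower.tail = FALSE))
}

#' SNP-level allelic-skew analysis from imbalance calls
#'
#' Counts, per SNP, the heterozygous imbalanced tumors retaining allele 1
#' versus allele 2 and applies [snp_chisquare_test()].
#'
#' @param calls Output of [call_snp_imbalance()].
#' @return Tibble: `snp_id`, `n_imbalanced`, `retained`, `lost`, `chi_sq`,
#'   `p_value` (SNPs with zero imbalanced tumors get `NA` test columns).
#' @export
test_snp_imbalance <- function(calls) {
  assert_cols(calls, c("snp_id", "status", "favored_allele"), "`calls`")
  counts <- calls |>
    filter(.data$status == "imbalance") |>
    group_by(.data$snp_id) |>
    summarise(
      n_imbalanced = n(),
      retained = sum(.data$favored_allele == "A"),
      lost = sum(.data$favored_allele == "B"),
      .groups = "drop"
    )
  all_snps <- distinct(calls, .data$snp_id)
  out <- left_join(all_snps, counts, by = "snp_id") |>
    mutate(across(c("n_imbalanced", "retained", "lost"),
                  ~ dplyr::coalesce(.x, 0L)))
  test <- snp_chisquare_test(pmax(out$retained, 0), pmax(out$lost, 0) +
                               ifelse(out$n_imbalanced == 0, 1L, 0L))
  out |>
    mutate(
      chi_sq = ifelse(.data$n_imbalanced == 0, NA_real_, test$chi_sq),
      p_value = ifelse(.data$n_imbalanced == 0, NA_real_, test$p_value)
    )
}
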