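#' Per-clone intraclass correlation from a one-way random-effects model
#'
#' For each clone, fits `Y_ij = mu + alpha_i + eps_ij` where `i` indexes
#' patients and `j` tumors, by the one-way ANOVA method of moments with
#' the unbalanced-design group-size correction
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)`. The between-patient variance
#' `sigma_alpha^2 = max(0, (MSB - MSW)/n0)` is clamped at zero, the
#' residual variance is `MSW`, and
#' `ICC = sigma_alpha^2 / (sigma_alpha^2 + sigma_eps^2)` — the fraction of
#' a clone's copy-number variance attributable to patient identity.
#'
#' Clones are only fitted when at least two patients contribute two or
#' more tumors each; other clones are dropped with a warning.
#'
#' @param resp Response tibble from [build_response_matrix()] (needs
#'   `clone_id`, `patient_id`, `y`).
#' @param clones Optional character vector restricting to specific clones.
#' @return Tibble with one row per fitted clone: `clone_id`, `n_patients`,
#'   `n_tumors`, `mu_hat`, `sigma_alpha_sq`, `sigma_eps_sq`, `icc`.
#' @examples
#' resp <- tibble::tibble(
#'   clone_id = "c1",
#'   patient_id = rep(c("P1", "P2", "P3"), each = 4),
#'   y = rep(c(-0.5, 0, 0.5), each = 4) + rnorm(12, 0, 0.1)
#' )
#' estimate_icc(resp)
#' @export
estimate_icc <- function(resp, clones = NULL) {
  assert_cols(resp, c("clone_id", "patient_id", "y"), "`resp`")
  if (!is.null(clones)) resp <- filter(resp, .data$clone_id %in% clones)
  resp <- filter(resp, !is.na(.data$y))
  if (nrow(resp) == 0) abort("no non-missing response values.")

  out <- resp |>
    group_by(.data$clone_id) |>
    dplyr::group_modify(function(df, key) icc_one_clone(df$y, df$patient_id)) |>
    ungroup()

  n_dropped <- sum(is.na(out$icc))
  if (n_dropped == nrow(out)) {
    abort("no clone has >= 2 patients with >= 2 tumors each; cannot estimate ICC.")
  }
  if (n_dropped > 0) {
    warn(sprintf("%d clone(s) dropped: fewer than 2 patients with 2+ tumors",
                 n_dropped))
  }
  filter(out, !is.na(.data$icc))
}

icc_one_clone <- function(y, patient) {
  n_i <- table(patient)
  a <- length(n_i)
  N <- length(y)
  if (sum(n_i >= 2) < 2 || a < 2 || N - a < 1) {
    return(tibble(n_patients = a, n_tumors = N, mu_hat = mean(y),
                  sigma_alpha_sq = NA_real_, sigma_eps_sq = NA_real_,
                  icc = NA_real_))
  }
  means <- tapply(y, patient, mean)
  grand <- mean(y)
  msb <- sum(n_i * (means - grand)^2) / (a - 1)
  msw <- sum((y - means[patient])^2) / (N - a)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  sigma_alpha <- max(0, (msb - msw) / n0)
  icc <- if (sigma_alpha + msw <= 0) 0 else sigma_alpha / (sigma_alpha + msw)
  tibble(n_patients = a, n_tumors = N, mu_hat = grand,
         sigma_alpha_sq = sigma_alpha, sigma_eps_sq = msw, icc = icc)
}
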