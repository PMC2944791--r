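#' Simulate an aCGH cohort with patient-shared whole-arm aberrations
#'
#' Generates clone-level log2-ratio profiles for a multi-tumor cohort. Each
#' patient draws one propensity shift per chromosome arm; each of the
#' patient's tumors then independently realises whole-arm gains or losses
#' (log2-ratio offsets of `+/- aberration_shift`) from those propensities,
#' plus clone-level Gaussian noise. A configurable fraction of samples gets
#' inflated noise so that MAD-based quality control has something to catch.
#' All randomness runs on per-patient streams derived from `config$seed`:
#' the same seed reproduces the cohort exactly, and adding patients leaves
#' earlier patients' profiles unchanged.
#'
#' @param config A [sim_config()].
#' @param map A [genome_map()]; defaults to `genome_map(config$n_clones)`.
#' @return A list with elements
#'   * `acgh`: tibble of clone-level measurements (`sample_id`,
#'     `patient_id`, `tumor_type`, `clone_id`, `chrom`, `arm`, `position`,
#'     `log2ratio`);
#'   * `truth`: list of ground-truth tibbles (`arms`: per patient x arm
#'     propensity and realised per-tumor states; `samples`: true per-sample
#'     noise sd). Truth is for evaluation only and is never consumed by
#'     analysis stages.
#' @examples
#' sim <- simulate_acgh_cohort(sim_config(n_patients = 2, seed = 7))
#' head(sim$acgh)
#' @export
simulate_acgh_cohort <- function(config, map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(map)) map <- genome_map(config$n_clones)
  assert_cols(map, c("clone_id", "chrom", "arm", "position"), "`map`")

  arms <- distinct(map, .data$chrom, .data$arm)
  per_patient <- purrr::map(seq_len(config$n_patients), function(i) {
    with_child_seed(child_seed(config$seed, paste0("acgh/patient/", i)), {
      simulate_patient_profiles(config, map, arms, i)
    })
  })

  list(
    acgh = bind_rows(purrr::map(per_patient, "acgh")),
    truth = list(
      arms = bind_rows(purrr::map(per_patient, "arm_truth")),
      samples = bind_rows(purrr::map(per_patient, "sample_truth"))
    )
  )
}

simulate_patient_profiles <- function(config, map, arms, i) {
  patient_id <- sprintf("P%03d", i)
  n_tumors <- if (config$tumors_min == config$tumors_max) config$tumors_min else
    sample(config$tumors_min:config$tumors_max, 1L)
  n_arms <- nrow(arms)

  delta <- rnorm(n_arms, 0, config$patient_effect_sd)
  p_gain <- plogis(qlogis(config$gain_rate) + delta)
  p_loss <- plogis(qlogis(config$loss_rate) - delta)
  # Degenerate base rates (0 or 1) stay degenerate regardless of delta.
  p_gain[config$gain_rate == 0] <- 0
  p_loss[config$loss_rate == 0] <- 0
  # Cap so gain + loss never exceeds 1 for a tumor.
  tot <- p_gain + p_loss
  over <- tot > 1
  p_gain[over] <- p_gain[over] / tot[over]
  p_loss[over] <- p_loss[over] / tot[over]

  # Per tumor x arm state in {-1, 0, +1}.
  u <- matrix(runif(n_tumors * n_arms), n_tumors, n_arms)
  state <- matrix(0L, n_tumors, n_arms)
  state[sweep(u, 2, p_gain, `<`)] <- 1L
  state[sweep(u, 2, p_gain, `>=`) & sweep(u, 2, p_gain + p_loss, `<`)] <- -1L

  noisy <- runif(n_tumors) < config$frac_noisy_samples
  noise_sd <- ifelse(noisy, config$noise_sd * config$noisy_factor, config$noise_sd)

  arm_key <- paste(map$chrom, map$arm)
  arm_index <- match(arm_key, paste(arms$chrom, arms$arm))

  acgh <- purrr::map(seq_len(n_tumors), function(j) {
    shift <- config$aberration_shift * state[j, arm_index]
    tibble(
      sample_id = sprintf("%s_T%d", patient_id, j),
      patient_id = patient_id,
      tumor_type = "SCC",
      clone_id = map$clone_id,
      chrom = map$chrom,
      arm = map$arm,
      position = map$position,
      log2ratio = shift + rnorm(nrow(map), 0, noise_sd[j])
    )
  }) |> bind_rows()

  list(
    acgh = acgh,
    arm_truth = tibble(
      patient_id = patient_id,
      chrom = rep(arms$chrom, each = n_tumors),
      arm = rep(arms$arm, each = n_tumors),
      sample_id = sprintf("%s_T%d", patient_id, rep(seq_len(n_tumors), n_arms)),
      propensity = rep(delta, each = n_tumors),
      p_gain = rep(p_gain, each = n_tumors),
      p_loss = rep(p_loss, each = n_tumors),
      state = as.integer(state)  # column-major: tumors fastest within arm
    ),
    sample_truth = tibble(
      sample_id = sprintf("%s_T%d", patient_id, seq_len(n_tumors)),
      patient_id = patient_id,
      noise_sd = noise_sd
    )
  )
}
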