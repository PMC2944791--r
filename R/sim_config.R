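#' Simulation configuration for synthetic multi-tumor cohorts
#'
#' Collects and validates all parameters of the cohort simulator. Defaults
#' describe a cohort of organ-transplant-recipient-like patients with
#' several independently arisen squamous cell carcinomas each: whole-arm
#' copy-number events whose propensity is partly patient-specific, clone
#' noise spanning the MAD = 0.2 quality cut, and heterozygous markers whose
#' imbalance events may preferentially lose one allele.
#'
#' Arm aberration events are modelled on the liability (logit) scale: each
#' patient draws one propensity shift per arm, `delta ~ N(0,
#' patient_effect_sd)`, and each tumor then gains the arm with probability
#' `plogis(qlogis(gain_rate) + delta)` and loses it with probability
#' `plogis(qlogis(loss_rate) - delta)`. `patient_effect_sd = 0` makes arm
#' events independent across a patient's tumors (the null regime for
#' concordance tests); large values make a patient's tumors share the same
#' whole-arm gains and losses. `pref_loss_prob = 0.5` is the null regime for
#' the preferential-imbalance test.
#'
#' @param n_patients Number of patients.
#' @param tumors_min,tumors_max Tumors per patient drawn uniformly on this
#'   range.
#' @param n_clones Number of clones in the genome map.
#' @param gain_rate,loss_rate Per-arm, per-tumor baseline gain/loss
#'   probabilities.
#' @param patient_effect_sd Sd of the patient-specific per-arm propensity
#'   shift on the logit scale; drives intra-patient concordance.
#' @param aberration_shift Absolute log2-ratio offset of an aberrant arm.
#' @param noise_sd Per-clone Gaussian noise sd (log2-ratio units).
#' @param frac_noisy_samples Fraction of samples given inflated noise
#'   (`noisy_factor` times `noise_sd`) to exercise MAD-based QC.
#' @param noisy_factor Noise-sd multiplier for the noisy samples.
#' @param het_prob Probability a patient is heterozygous at a marker.
#' @param imbalance_prob Per-tumor probability an informative locus shows
#'   allelic imbalance.
#' @param pref_loss_prob Probability that an imbalance event loses the
#'   designated (non-retained) allele; 0.5 = random loss.
#' @param peak_cv Multiplicative (log-normal) coefficient of variation of
#'   peak heights/areas.
#' @param seed Master integer seed; per-patient streams are derived from it.
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_patients = 5, seed = 1)
#' cfg$pref_loss_prob
#' @export
sim_config <- function(n_patients = 25,
                       tumors_min = 3,
                       tumors_max = 6,
                       n_clones = 440,
                       gain_rate = 0.08,
                       loss_rate = 0.15,
                       patient_effect_sd = 1.5,
                       aberration_shift = 0.5,
                       noise_sd = 0.1,
                       frac_noisy_samples = 0.1,
                       noisy_factor = 3,
                       het_prob = 0.7,
                       imbalance_prob = 0.5,
                       pref_loss_prob = 0.5,
                       peak_cv = 0.1,
                       seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients")
  tumors_min <- assert_count(tumors_min, "tumors_min")
  tumors_max <- assert_count(tumors_max, "tumors_max", min = tumors_min)
  n_clones <- assert_count(n_clones, "n_clones", min = 2L)
  assert_prob(gain_rate, "gain_rate")
  assert_prob(loss_rate, "loss_rate")
  if (gain_rate + loss_rate > 1) abort("`gain_rate` + `loss_rate` must be <= 1.")
  assert_nonneg(patient_effect_sd, "patient_effect_sd")
  assert_nonneg(aberration_shift, "aberration_shift")
  assert_nonneg(noise_sd, "noise_sd")
  assert_prob(frac_noisy_samples, "frac_noisy_samples")
  assert_nonneg(noisy_factor, "noisy_factor")
  assert_prob(het_prob, "het_prob")
  assert_prob(imbalance_prob, "imbalance_prob")
  assert_prob(pref_loss_prob, "pref_loss_prob")
  assert_nonneg(peak_cv, "peak_cv")
  seed <- assert_count(seed, "seed", min = 0L)

  structure(
    list(
      n_patients = n_patients, tumors_min = tumors_min, tumors_max = tumors_max,
      n_clones = n_clones, gain_rate = gain_rate, loss_rate = loss_rate,
      patient_effect_sd = patient_effect_sd, aberration_shift = aberration_shift,
      noise_sd = noise_sd, frac_noisy_samples = frac_noisy_samples,
      noisy_factor = noisy_factor, het_prob = het_prob,
      imbalance_prob = imbalance_prob, pref_loss_prob = pref_loss_prob,
      peak_cv = peak_cv, seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Draw tumors-per-patient counts for a cohort, one value per patient.
draw_tumor_counts <- function(config) {
  if (config$tumors_min == config$tumors_max) {
    rep(config$tumors_min, config$n_patients)
  } else {
    sample(config$tumors_min:config$tumors_max, config$n_patients, replace = TRUE)
  }
}
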