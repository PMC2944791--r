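test_that("identical configs give byte-identical cohorts", {
  cfg <- sim_config(n_patients = 3, n_clones = 88, seed = 42)
  a <- simulate_acgh_cohort(cfg)
  b <- simulate_acgh_cohort(cfg)
  expect_identical(a$acgh, b$acgh)
  expect_identical(a$truth, b$truth)

  ms1 <- simulate_allelotype_cohort(cfg, n_markers = 3)
  ms2 <- simulate_allelotype_cohort(cfg, n_markers = 3)
  expect_identical(ms1$peaks, ms2$peaks)

  sn1 <- simulate_snp_cohort(cfg, n_snps = 2)
  sn2 <- simulate_snp_cohort(cfg, n_snps = 2)
  expect_identical(sn1$peaks, sn2$peaks)
})

test_that("adding patients leaves earlier patients' draws unchanged", {
  small <- simulate_acgh_cohort(sim_config(n_patients = 3, n_clones = 88, seed = 7))
  large <- simulate_acgh_cohort(sim_config(n_patients = 5, n_clones = 88, seed = 7))
  first3 <- dplyr::filter(large$acgh, patient_id %in% c("P001", "P002", "P003"))
  expect_identical(small$acgh, first3)
})

test_that("zero aberration rates and patient effects give pure noise", {
  cfg <- sim_config(n_patients = 4, n_clones = 88, gain_rate = 0, loss_rate = 0,
                    patient_effect_sd = 0, frac_noisy_samples = 0,
                    noise_sd = 0.05, seed = 3)
  sim <- simulate_acgh_cohort(cfg)
  expect_true(all(sim$truth$arms$state == 0L))
  expect_lt(max(abs(sim$acgh$log2ratio)), 0.05 * 6)
})

test_that("a forced whole-arm loss shifts every tumor of the patient", {
  cfg <- sim_config(n_patients = 2, tumors_min = 3, tumors_max = 3,
                    n_clones = 88, gain_rate = 0, loss_rate = 1,
                    patient_effect_sd = 0, frac_noisy_samples = 0,
                    aberration_shift = 0.5, noise_sd = 0.05, seed = 11)
  sim <- simulate_acgh_cohort(cfg)
  arm_means <- sim$acgh |>
    dplyr::group_by(sample_id, chrom, arm) |>
    dplyr::summarise(m = mean(log2ratio), .groups = "drop")
  # arm means have sd noise_sd/sqrt(2 clones); allow a wide safety margin
  expect_true(all(abs(arm_means$m + 0.5) < 0.2))
  expect_equal(mean(arm_means$m), -0.5, tolerance = 0.02)
})

test_that("degenerate preferential loss makes every event retain allele A", {
  cfg <- sim_config(n_patients = 6, tumors_min = 4, tumors_max = 4,
                    het_prob = 1, imbalance_prob = 1, pref_loss_prob = 1,
                    seed = 5)
  sim <- simulate_allelotype_cohort(cfg, n_markers = 2)
  expect_true(all(sim$truth$imbalanced))
  expect_true(all(sim$truth$retained_allele == "A"))
  summ <- call_allelic_imbalance(sim$peaks) |> summarize_patient_marker()
  expect_equal(summ$k_favoring_a, summ$n_imbalanced)
})

test_that("random loss splits retained alleles evenly across many events", {
  cfg <- sim_config(n_patients = 40, tumors_min = 5, tumors_max = 5,
                    het_prob = 1, imbalance_prob = 1, pref_loss_prob = 0.5,
                    seed = 8)
  sim <- simulate_allelotype_cohort(cfg, n_markers = 3)
  frac_a <- mean(sim$truth$retained_allele == "A")
  n <- nrow(sim$truth)
  expect_lt(abs(frac_a - 0.5), 3 * sqrt(0.25 / n))
})

test_that("homozygous-only SNP cohorts yield no informative tumors", {
  cfg <- sim_config(n_patients = 5, het_prob = 0, seed = 4)
  sim <- simulate_snp_cohort(cfg, n_snps = 2)
  calls <- call_snp_imbalance(sim$peaks)
  expect_equal(nrow(calls), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(pref_loss_prob = 1.2), "pref_loss_prob")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(simulate_allelotype_cohort(sim_config(), n_markers = 0),
               "n_markers")
  expect_error(simulate_snp_cohort(sim_config(), n_snps = 0), "n_snps")
})

test_that("imbalance events push R outside the classification bands", {
  cfg <- sim_config(n_patients = 10, tumors_min = 3, tumors_max = 3,
                    het_prob = 1, imbalance_prob = 1, peak_cv = 0.05,
                    seed = 9)
  sim <- simulate_allelotype_cohort(cfg, n_markers = 2)
  calls <- call_allelic_imbalance(sim$peaks)
  expect_gt(mean(calls$status == "imbalance"), 0.95)
})
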