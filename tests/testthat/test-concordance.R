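test_that("response matrix substitutes raw values only for outliers", {
  seg <- make_segmented(list(S1 = c(rep(0.1, 9), 2)))
  seg$seg_mean <- 0.1
  mads <- tibble::tibble(sample_id = "S1", mad = 0.1)
  resp <- build_response_matrix(seg, outlier_k = 3, mads = mads)
  expect_equal(resp$y[1:9], rep(0.1, 9))
  expect_equal(resp$y[10], 2)                        # 19 MADs out: raw kept
  resp_inf <- build_response_matrix(seg, outlier_k = Inf, mads = mads)
  expect_equal(resp_inf$y, rep(0.1, 10))             # limit: pure segment means
})

test_that("informativeness needs both high- and low-amplitude clones", {
  expect_false(informative_profile(rep(0.01, 50), mad = 0.1))     # flat
  expect_true(informative_profile(c(rep(0.5, 15), rep(0.01, 35)), mad = 0.1))
  expect_false(informative_profile(rep(0.5, 50), mad = 0.1))      # saturated
  expect_false(informative_profile(rep(NA_real_, 5), mad = 0.1))
})

test_that("pairwise correlations hit the exact limits", {
  v <- c(0.5, -0.2, 0.1, 0.4, -0.5, 0, 0.3, -0.1, 0.2, -0.3)
  seg <- make_segmented(
    list(A1 = v, A2 = v, B1 = -v, B2 = v + 0.01),
    patient_of = list(A1 = "PA", A2 = "PA", B1 = "PB", B2 = "PB")
  )
  resp <- build_response_matrix(seg, mads = tibble::tibble(
    sample_id = c("A1", "A2", "B1", "B2"), mad = 0.05))
  # raw values survive as responses (every clone is its own outlier here)
  pairs <- pairwise_correlations(resp, min_tumors = 2)
  r12 <- pairs$r[pairs$sample_1 == "A1" & pairs$sample_2 == "A2"]
  rneg <- pairs$r[pairs$sample_1 == "A1" & pairs$sample_2 == "B1"]
  expect_equal(r12, 1)
  expect_equal(rneg, -1)
  expect_setequal(unique(pairs$type), c("intra", "inter"))
})

test_that("intra pairs come only from patients with enough tumors", {
  v <- rnorm(10)
  seg <- make_segmented(
    list(A1 = v, A2 = v + rnorm(10, 0, 0.1), B1 = rnorm(10)),
    patient_of = list(A1 = "PA", A2 = "PA", B1 = "PB")
  )
  resp <- build_response_matrix(seg, mads = tibble::tibble(
    sample_id = c("A1", "A2", "B1"), mad = 0.2))
  pairs3 <- pairwise_correlations(resp, min_tumors = 3)
  expect_equal(sum(pairs3$type == "intra"), 0)   # PA has only 2 tumors
  pairs2 <- pairwise_correlations(resp, min_tumors = 2)
  expect_equal(sum(pairs2$type == "intra"), 1)
})

test_that("scope eligibility applies the clone and pair minimums inclusively", {
  expect_false(scope_eligible(39, 20, 20))
  expect_true(scope_eligible(40, 20, 20))
  expect_false(scope_eligible(100, 19, 20))
  expect_false(scope_eligible(100, 20, 19))
})

test_that("group comparison gates the pooled t on variance equality", {
  set.seed(51)
  same <- rnorm(30, 0.2, 0.05)
  res_ident <- compare_groups(same, same)
  expect_equal(res_ident$t_p_welch, 1, tolerance = 1e-8)

  a <- rnorm(30, 0.4, 0.05)
  b <- rnorm(30, 0.1, 0.05)
  res_sep <- compare_groups(a, b)
  expect_lt(res_sep$t_p_welch, 1e-6)
  expect_false(is.na(res_sep$t_p_pooled))  # equal variances: pooled reported

  set.seed(52)
  wide <- rnorm(30, 0.2, 0.5)
  narrow <- rnorm(30, 0.2, 0.05)
  res_var <- compare_groups(wide, narrow)
  expect_lt(res_var$levene_p, 0.05)
  expect_true(is.na(res_var$t_p_pooled))   # pooled suppressed
  expect_equal(res_var$p, res_var$t_p_welch)

  expect_error(compare_groups(1, c(0.1, 0.2)), "at least 2")
})

test_that("group swap flips the comparison symmetrically", {
  set.seed(53)
  a <- rnorm(25, 0.3, 0.1)
  b <- rnorm(25, 0.1, 0.1)
  expect_equal(compare_groups(a, b)$t_p_welch, compare_groups(b, a)$t_p_welch)
})

test_that("Holm adjustment follows the step-down rule", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(54)
  p <- runif(20)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))                      # dominance
  expect_true(all(diff(adj[order(p)]) >= -1e-12)) # monotone in rank order
})

test_that("a single-patient cohort cannot run the genome-wide test", {
  v <- replicate(3, c(rnorm(25, 0, 0.05), rnorm(25, 0.6, 0.05)), simplify = FALSE)
  seg <- make_segmented(setNames(v, c("T1", "T2", "T3")),
                        patient_of = list(T1 = "P1", T2 = "P1", T3 = "P1"))
  seg$seg_mean <- rep(rep(c(0, 0.6), each = 25), 3)
  resp <- build_response_matrix(seg, mads = tibble::tibble(
    sample_id = c("T1", "T2", "T3"), mad = 0.05))
  expect_error(genome_wide_test(resp, min_clones = 10, min_pairs = 2),
               "not eligible")
})

test_that("patient-shared events give higher intra than inter correlation", {
  hits <- vapply(1:5, function(r) {
    sim <- simulate_acgh_cohort(sim_config(
      n_patients = 8, tumors_min = 3, tumors_max = 3, n_clones = 352,
      patient_effect_sd = 1.5, frac_noisy_samples = 0, seed = 600 + r))
    set.seed(700 + r)
    seg <- segment_profiles(sim$acgh, n_perm = 100)
    g <- genome_wide_test(build_response_matrix(seg))
    g$mean_intra > g$mean_inter
  }, TRUE)
  expect_true(all(hits))
})

test_that("concordance fit returns tidy per-arm and glance genome rows", {
  sim <- simulate_acgh_cohort(sim_config(
    n_patients = 8, tumors_min = 3, tumors_max = 3, n_clones = 352,
    patient_effect_sd = 1.5, frac_noisy_samples = 0, seed = 61))
  set.seed(62)
  seg <- segment_profiles(sim$acgh, n_perm = 100)
  fit <- fit_concordance(build_response_matrix(seg), min_clones = 8,
                         min_pairs = 5)
  arms <- tidy(fit)
  expect_equal(nrow(arms), 44)
  expect_true(all(c("levene_p", "t_p_welch", "holm_p_welch", "eligible")
                  %in% names(arms)))
  eligible <- arms[arms$eligible, ]
  expect_true(all(eligible$holm_p_welch >= eligible$t_p_welch - 1e-12,
                  na.rm = TRUE))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_true(is.finite(g$p))
  expect_s3_class(autoplot(fit), "ggplot")
})
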