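test_that("patient log-odds match the closed form and enumeration", {
  expect_equal(patient_log_odds(4, 4), log(0.3125))
  expect_equal(patient_log_odds(5, 5), log(0.1875))
  expect_equal(patient_log_odds(1, 2), log(1.5))   # C(2,1) * 2^-2 * 3
  expect_error(patient_log_odds(1, 1), ">= 2")
  expect_error(patient_log_odds(5, 4), "0 <= k <= n")
})

test_that("log-odds agree with numerical integration of the Beta marginal", {
  for (n in 2:12) {
    for (k in 0:n) {
      marginal <- stats::integrate(function(p) dbinom(k, n, p), 0, 1,
                                   rel.tol = 1e-12)$value
      oracle <- (dbinom(k, n, 0.5)) / marginal
      expect_equal(patient_log_odds(k, n), log(oracle), tolerance = 1e-10)
    }
  }
  # non-uniform prior against direct quadrature
  marg <- stats::integrate(function(p) dbinom(3, 5, p) * dbeta(p, 2, 3), 0, 1,
                           rel.tol = 1e-12)$value
  expect_equal(patient_log_odds(3, 5, prior = c(2, 3)),
               log(dbinom(3, 5, 0.5) / marg), tolerance = 1e-10)
})

test_that("log-odds are symmetric and maximal at balanced counts", {
  for (n in 2:10) {
    k <- 0:n
    lo <- patient_log_odds(k, rep(n, n + 1))
    expect_equal(lo, rev(lo))                       # k <-> n - k symmetry
    expect_equal(which.max(lo), floor(n / 2) + 1)   # peak at the middle
    half <- lo[seq_len(floor(n / 2) + 1)]
    expect_true(all(diff(half) > 0))                # strictly toward extremes
  }
})

test_that("the preferential flag is strict at the threshold", {
  expect_true(flag_preferential(-1.6740))
  expect_false(flag_preferential(-1.5))
  expect_false(flag_preferential(0))
  expect_error(flag_preferential(Inf), "finite")
})

test_that("null odds simulation reproduces the exact binomial distribution", {
  null <- simulate_null_odds(n_list = 2, reps = 20000, seed = 91)
  vals <- sort(unique(round(null, 10)))
  expect_equal(vals, sort(unique(round(patient_log_odds(0:1, c(2, 2)), 10))))
  # k in {0,2} share the lower value with mass 1/2; k = 1 has mass 1/2
  p_low <- mean(null == min(null))
  expect_equal(p_low, 0.5, tolerance = 3 * sqrt(0.25 / 20000) / 0.5)

  expect_error(simulate_null_odds(integer(0)), "non-empty")
  expect_error(simulate_null_odds(3, reps = 50), "reps")
})

test_that("null flag rates match exact binomial tail mass", {
  for (n in c(4, 6, 10)) {
    exact <- sum(dbinom(0:n, n, 0.5)[flag_preferential(patient_log_odds(0:n, rep(n, n + 1)))])
    null <- simulate_null_odds(n_list = n, reps = 20000, seed = 92 + n)
    mc <- mean(flag_preferential(null))
    se <- sqrt(exact * (1 - exact) / 20000)
    expect_lt(abs(mc - exact), 3 * se + 1e-12)
  }
})

test_that("the locus test behaves at its fixed points", {
  null <- simulate_null_odds(rep(4, 10), reps = 1000, seed = 93)
  res <- locus_preferential_test(null[1:40], null)
  expect_gt(res$wilcoxon_p, 0.01)     # drawn from the null itself
  obs <- patient_log_odds(c(4, 4, 0, 4, 4, 0, 4, 4, 4, 4), rep(4, 10))
  res2 <- locus_preferential_test(obs, null)
  expect_lt(res2$wilcoxon_p, 0.05)
  expect_error(locus_preferential_test(obs, numeric(0)), "non-empty")
  expect_error(locus_preferential_test(obs[1], null), ">= 2")
})

test_that("power rises with the preferential-loss probability", {
  reject_rate <- function(p_loss, reps = 60) {
    mean(vapply(seq_len(reps), function(r) {
      set.seed(3000 + round(1000 * p_loss) + r)
      k <- rbinom(10, 4, p_loss)
      null <- simulate_null_odds(rep(4, 10), reps = 300)
      locus_preferential_test(patient_log_odds(k, rep(4, 10)), null)$wilcoxon_p < 0.05
    }, TRUE))
  }
  rates <- vapply(c(0.6, 0.75, 0.9), reject_rate, 0)
  expect_true(all(diff(rates) >= -0.05))  # monotone (non-strict, MC noise)
  expect_gt(rates[3], rates[1])
})

test_that("the chi-square skew test matches closed form and chisq.test", {
  res <- snp_chisquare_test(c(3, 28, 0), c(3, 7, 1))
  expect_equal(res$chi_sq, c(0, 12.6, 1))
  expect_equal(res$p_value[1], 1)
  expect_equal(res$p_value[3], 0.3173, tolerance = 1e-4)
  # independent route: Pearson goodness-of-fit on the two cells
  ref <- suppressWarnings(chisq.test(c(28, 7), p = c(0.5, 0.5)))
  expect_equal(res$chi_sq[2], unname(ref$statistic))
  expect_equal(res$p_value[2], ref$p.value)
  # symmetry in the two counts
  expect_equal(snp_chisquare_test(7, 28)$p_value, res$p_value[2])
  expect_error(snp_chisquare_test(0, 0), ">= 1")
})

test_that("test_preferential assembles the locus table from summaries", {
  summ <- dplyr::bind_rows(
    make_summaries(k = c(4, 4, 4, 0, 4, 4, 4, 4, 0, 4), n = 4, marker_id = "SKEWED"),
    make_summaries(k = c(2, 2, 1, 3, 2, 2, 2, 1, 2, 3), n = 4, marker_id = "RANDOM"),
    tibble::tibble(patient_id = "P99", marker_id = "RARE", n_tumors = 4,
                   n_imbalanced = 1, k_favoring_a = 1)
  )
  set.seed(94)
  fit <- test_preferential(summ, reps = 500)
  loci <- tidy(fit)
  expect_equal(sort(loci$marker_id), c("RANDOM", "RARE", "SKEWED"))
  skew <- loci[loci$marker_id == "SKEWED", ]
  rand <- loci[loci$marker_id == "RANDOM", ]
  rare <- loci[loci$marker_id == "RARE", ]
  expect_lt(skew$wilcoxon_p, 0.05)
  expect_gt(rand$wilcoxon_p, 0.05)
  expect_true(is.na(rare$wilcoxon_p))     # <2 informative patients: untested
  expect_equal(rare$n_multi_loh, 0)
  expect_equal(skew$n_multi_loh, 10)
  expect_equal(skew$n_tumors_loh, 40)
  g <- glance(fit)
  expect_equal(g$n_loci, 3)
  expect_s3_class(autoplot(fit), "ggplot")
})
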