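test_that("the imbalance ratio is the tumor/normal allelic ratio quotient", {
  expect_equal(ai_ratio(100, 50, 50, 50), 2)
  expect_equal(ai_ratio(50, 100, 50, 50), 0.5)
  expect_equal(ai_ratio(123, 456, 123, 456), 1)
  expect_error(ai_ratio(100, 0, 50, 50), "tumor_b")
  expect_error(ai_ratio(100, 50, -1, 50), "normal_a")
})

test_that("classification bands match the published thresholds", {
  out <- classify_ai(c(2, 1.4, 1, 0.5))
  expect_equal(as.character(out$status),
               c("imbalance", "uncertain", "no_imbalance", "imbalance"))
  expect_equal(as.character(out$favored_allele), c("A", "none", "none", "B"))
  # boundary behavior: thresholds themselves are not imbalance
  edge <- classify_ai(c(1.5, 0.66, 1.25, 0.85, 1.26, 0.84))
  expect_equal(as.character(edge$status),
               c("uncertain", "uncertain", "no_imbalance", "no_imbalance",
                 "uncertain", "uncertain"))
  expect_error(classify_ai(-1), "positive")
})

test_that("R is invariant to common peak scaling", {
  set.seed(81)
  q <- abs(rnorm(4, 1000, 200)) + 1
  for (c_scale in c(0.01, 1, 37)) {
    expect_equal(ai_ratio(q[1] * c_scale, q[2] * c_scale,
                          q[3] * c_scale, q[4] * c_scale),
                 ai_ratio(q[1], q[2], q[3], q[4]))
  }
})

test_that("swapping allele labels inverts R and the favored allele", {
  bands <- ai_bands(upper = 1.5, lower = 1 / 1.5)  # symmetric bands
  set.seed(82)
  for (r in 1:20) {
    q <- abs(rnorm(4, 1000, 300)) + 1
    R <- ai_ratio(q[1], q[2], q[3], q[4])
    R_swap <- ai_ratio(q[2], q[1], q[4], q[3])
    expect_equal(R_swap, 1 / R)
    s <- classify_ai(R, bands)
    s_swap <- classify_ai(R_swap, bands)
    expect_equal(as.character(s$status), as.character(s_swap$status))
    if (s$status == "imbalance") {
      expect_setequal(c(as.character(s$favored_allele),
                        as.character(s_swap$favored_allele)), c("A", "B"))
    }
  }
})

test_that("patient-marker summaries count imbalanced tumors and A-retention", {
  calls <- tibble::tibble(
    patient_id = "P1", marker_id = "M1",
    sample_id = paste0("T", 1:6),
    R = c(2, 2, 2, 2, 1, 1.4),
    status = factor(c(rep("imbalance", 4), "no_imbalance", "uncertain"),
                    levels = c("imbalance", "no_imbalance", "uncertain")),
    favored_allele = factor(c(rep("A", 4), "none", "none"),
                            levels = c("A", "B", "none"))
  )
  s <- summarize_patient_marker(calls)
  expect_equal(s$n_imbalanced, 4)
  expect_equal(s$k_favoring_a, 4)
  expect_equal(s$n_tumors, 6)   # conservation: imbalance + no_imbalance + uncertain

  calls$favored_allele[2:3] <- "B"
  s2 <- summarize_patient_marker(calls)
  expect_equal(s2$k_favoring_a, 2)
  expect_equal(s2$n_imbalanced, 4)
})

test_that("homozygous patients are dropped from imbalance calling", {
  peaks <- tibble::tibble(
    patient_id = "P1",
    sample_id = c("P1_N", "P1_T1"),
    sample_type = c("normal", "tumor"),
    marker_id = "M1",
    allele_a_bp = "150", allele_b_bp = "150",   # homozygous
    peak_a = c(1000, 2000), peak_b = c(1000, 1000)
  )
  expect_equal(nrow(call_allelic_imbalance(peaks)), 0)
})

test_that("tumors missing one member of the matched pair are excluded", {
  peaks <- tibble::tibble(
    patient_id = rep(c("P1", "P2"), each = 2),
    sample_id = c("P1_N", "P1_T1", "P2_N", "P2_T1"),
    sample_type = rep(c("normal", "tumor"), 2),
    snp_id = "rs1",
    allele_1 = "A", allele_2 = "G",
    area_1 = c(1000, 2000, NA, 1500),
    area_2 = c(1000, 1000, 1000, 1000)
  )
  calls <- call_snp_imbalance(peaks)
  expect_equal(calls$patient_id, "P1")   # P2's normal failed: tumor dropped
  expect_equal(calls$R, 2)
  expect_equal(as.character(calls$status), "imbalance")
})

test_that("SNP alleles are ordered lexicographically before the ratio", {
  # same physical data entered with swapped allele columns
  a <- tibble::tibble(
    patient_id = "P1", sample_id = c("P1_N", "P1_T1"),
    sample_type = c("normal", "tumor"), snp_id = "rs1",
    allele_1 = "A", allele_2 = "G",
    area_1 = c(1000, 2000), area_2 = c(1000, 1000)
  )
  b <- a
  b$allele_1 <- "G"; b$allele_2 <- "A"
  b$area_1 <- a$area_2; b$area_2 <- a$area_1
  expect_equal(call_snp_imbalance(a)$R, call_snp_imbalance(b)$R)
})
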