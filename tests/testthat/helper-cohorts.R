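# Shared fixture builders. Everything is generated in code; no data files.

# A small segmented cohort built directly (no CBS), for tests that target
# downstream stages only.
make_segmented <- function(values_by_sample, patient_of = NULL,
                           chrom = 1L, arm = "q") {
  out <- lapply(names(values_by_sample), function(s) {
    v <- values_by_sample[[s]]
    tibble::tibble(
      sample_id = s,
      patient_id = if (is.null(patient_of)) s else patient_of[[s]],
      tumor_type = "SCC",
      clone_id = sprintf("c%03d", seq_along(v)),
      chrom = chrom,
      arm = arm,
      position = seq_along(v) * 1e5,
      log2ratio = v,
      seg_id = paste0(chrom, "_seg01"),
      seg_mean = mean(v, na.rm = TRUE)
    )
  })
  dplyr::bind_rows(out)
}

# A one-chromosome aCGH tibble from a raw value vector.
make_profile <- function(values, sample_id = "S1", patient_id = "P1",
                         chrom = 1L) {
  n <- length(values)
  tibble::tibble(
    sample_id = sample_id,
    patient_id = patient_id,
    tumor_type = "SCC",
    clone_id = sprintf("c%03d", seq_len(n)),
    chrom = chrom,
    arm = rep(c("p", "q"), c(floor(n / 2), ceiling(n / 2))),
    position = seq_len(n) * 1e5,
    log2ratio = values
  )
}

# Exhaustive-enumeration oracle for the best circular split: scans every
# arc (i, j) directly with mean/var arithmetic, independent of the
# package's scan kernel.
oracle_best_split <- function(y, min_width = 2L) {
  n <- length(y)
  best <- list(i = 0L, j = 0L, t = 0)
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      arc <- y[(i + 1):j]
      comp <- y[-((i + 1):j)]
      ss <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
      pooled <- ss / (n - 2)
      if (pooled <= 0) next
      t <- abs(mean(arc) - mean(comp)) /
        sqrt(pooled * (1 / length(arc) + 1 / length(comp)))
      if (t > best$t) best <- list(i = i, j = j, t = t)
    }
  }
  best
}

# Direct construction of patient x marker summaries for preferential-test
# fixtures.
make_summaries <- function(k, n, marker_id = "M1") {
  tibble::tibble(
    patient_id = sprintf("P%02d", seq_along(k)),
    marker_id = marker_id,
    n_tumors = n,
    n_imbalanced = n,
    k_favoring_a = k
  )
}
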