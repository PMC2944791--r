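#' Simulate a microsatellite allelotype cohort
#'
#' Generates matched normal/tumor peak-height data for fluorescent
#' microsatellite genotyping. Each patient is heterozygous at a marker with
#' probability `het_prob`; heterozygotes carry two alleles of distinct
#' fragment sizes (allele A = larger). Normal peaks are equal up to
#' multiplicative log-normal noise (`peak_cv`). Each tumor shows allelic
#' imbalance at an informative locus with probability `imbalance_prob`; an
#' imbalance event multiplies the retained allele's tumor peak by a dosage
#' factor drawn log-uniformly in \[1.8, 3\], which pushes the imbalance
#' ratio R past the 1.5 / 0.66 classification bands. The smaller (B) allele
#' is the designated lost allele with probability `pref_loss_prob`
#' (equivalently, A is retained with that probability); 0.5 is the null of
#' random allele loss.
#'
#' @inheritParams simulate_acgh_cohort
#' @param n_markers Number of microsatellite markers.
#' @return A list with
#'   * `genotypes`: per patient x marker normal genotype tibble
#'     (`patient_id`, `marker_id`, `allele_a_bp`, `allele_b_bp`,
#'     `heterozygous`);
#'   * `peaks`: tibble of peak heights, one row per sample x marker
#'     (`patient_id`, `sample_id`, `sample_type`, `marker_id`,
#'     `allele_a_bp`, `allele_b_bp`, `peak_a`, `peak_b`);
#'   * `truth`: tibble of ground truth per patient x marker and per tumor
#'     (imbalance indicator and which allele was lost).
#' @examples
#' sim <- simulate_allelotype_cohort(sim_config(n_patients = 3, seed = 2),
#'                                   n_markers = 2)
#' head(sim$peaks)
#' @export
simulate_allelotype_cohort <- function(config, n_markers) {
  stopifnot(inherits(config, "sim_config"))
  n_markers <- assert_count(n_markers, "n_markers")
  marker_ids <- sprintf("MS%03d", seq_len(n_markers))

  per_patient <- purrr::map(seq_len(config$n_patients), function(i) {
    with_child_seed(child_seed(config$seed, paste0("allelotype/patient/", i)), {
      simulate_patient_allelotype(config, marker_ids, i,
                                  alleles_fun = draw_ms_alleles,
                                  id_prefix = "MS")
    })
  })
  assemble_peak_cohort(per_patient, marker_col = "marker_id")
}

#' Simulate a quantitative SNP genotyping cohort
#'
#' Same generative model as [simulate_allelotype_cohort()] but for
#' biallelic SNPs measured as per-allele peak areas (mass-spectrometric
#' quantitative genotyping style). Each SNP has two fixed bases; allele
#' ordering is lexicographic (allele 1 < allele 2 alphabetically). The
#' designated retained allele for a preferential event is allele 1.
#'
#' @inheritParams simulate_allelotype_cohort
#' @param n_snps Number of SNPs.
#' @return A list with `genotypes`, `peaks` (`patient_id`, `sample_id`,
#'   `sample_type`, `snp_id`, `allele_1`, `allele_2`, `area_1`, `area_2`)
#'   and `truth`, as in [simulate_allelotype_cohort()].
#' @export
simulate_snp_cohort <- function(config, n_snps) {
  stopifnot(inherits(config, "sim_config"))
  n_snps <- assert_count(n_snps, "n_snps")
  snp_ids <- sprintf("rs%05d", seq_len(n_snps))

  # SNP allele pairs are a property of the locus, not the patient.
  snp_alleles <- with_child_seed(child_seed(config$seed, "snp/loci"), {
    purrr::map(snp_ids, function(id) sort(sample(c("A", "C", "G", "T"), 2L)))
  })
  names(snp_alleles) <- snp_ids

  per_patient <- purrr::map(seq_len(config$n_patients), function(i) {
    with_child_seed(child_seed(config$seed, paste0("snp/patient/", i)), {
      simulate_patient_allelotype(config, snp_ids, i,
                                  alleles_fun = function(id) snp_alleles[[id]],
                                  id_prefix = "SNP")
    })
  })
  out <- assemble_peak_cohort(per_patient, marker_col = "marker_id")
  # Rename to the SNP dialect: alleles are bases, measurements are areas.
  out$genotypes <- rename(out$genotypes, snp_id = "marker_id",
                          allele_1 = "allele_a_bp", allele_2 = "allele_b_bp")
  out$peaks <- rename(out$peaks, snp_id = "marker_id",
                      allele_1 = "allele_a_bp", allele_2 = "allele_b_bp",
                      area_1 = "peak_a", area_2 = "peak_b")
  out$truth <- rename(out$truth, snp_id = "marker_id")
  out
}

# Two distinct fragment sizes under 200 bp; A is the larger.
draw_ms_alleles <- function(marker_id) {
  sizes <- sort(sample(seq(100L, 198L, by = 2L), 2L), decreasing = TRUE)
  as.character(sizes)
}

# One patient's genotypes + peaks across markers. Allele "a" is the
# designated retained allele (larger fragment for microsatellites, first
# base for SNPs); an imbalance event retains it with prob pref_loss_prob.
simulate_patient_allelotype <- function(config, marker_ids, i, alleles_fun,
                                        id_prefix) {
  patient_id <- sprintf("P%03d", i)
  n_tumors <- if (config$tumors_min == config$tumors_max) config$tumors_min else
    sample(config$tumors_min:config$tumors_max, 1L)
  base_peak <- 1000
  # log-normal multiplicative noise with coefficient of variation peak_cv
  sdlog <- sqrt(log(1 + config$peak_cv^2))
  noise <- function(n) exp(rnorm(n, -sdlog^2 / 2, sdlog))

  rows <- purrr::map(marker_ids, function(mk) {
    al <- alleles_fun(mk)
    het <- runif(1) < config$het_prob
    if (!het) al <- c(al[1], al[1])

    normal <- tibble(
      patient_id = patient_id,
      sample_id = sprintf("%s_N", patient_id),
      sample_type = "normal",
      marker_id = mk,
      allele_a_bp = al[1], allele_b_bp = al[2],
      peak_a = base_peak * noise(1),
      peak_b = base_peak * noise(1)
    )

    imbalanced <- het & (runif(n_tumors) < config$imbalance_prob)
    retain_a <- runif(n_tumors) < config$pref_loss_prob
    dosage <- exp(runif(n_tumors, log(1.8), log(3)))
    peak_a <- base_peak * ifelse(imbalanced & retain_a, dosage, 1) * noise(n_tumors)
    peak_b <- base_peak * ifelse(imbalanced & !retain_a, dosage, 1) * noise(n_tumors)

    tumors <- tibble(
      patient_id = patient_id,
      sample_id = sprintf("%s_T%d", patient_id, seq_len(n_tumors)),
      sample_type = "tumor",
      marker_id = mk,
      allele_a_bp = al[1], allele_b_bp = al[2],
      peak_a = peak_a, peak_b = peak_b
    )

    list(
      genotype = tibble(patient_id = patient_id, marker_id = mk,
                        allele_a_bp = al[1], allele_b_bp = al[2],
                        heterozygous = het),
      peaks = bind_rows(normal, tumors),
      truth = tibble(
        patient_id = patient_id, marker_id = mk,
        sample_id = tumors$sample_id,
        heterozygous = het,
        retained_allele_prob = if (het) config$pref_loss_prob else NA_real_,
        imbalanced = imbalanced,
        retained_allele = dplyr::case_when(
          !imbalanced ~ NA_character_,
          retain_a ~ "A",
          TRUE ~ "B"
        )
      )
    )
  })

  list(
    genotypes = bind_rows(purrr::map(rows, "genotype")),
    peaks = bind_rows(purrr::map(rows, "peaks")),
    truth = bind_rows(purrr::map(rows, "truth"))
  )
}

assemble_peak_cohort <- function(per_patient, marker_col) {
  list(
    genotypes = bind_rows(purrr::map(per_patient, "genotypes")),
    peaks = bind_rows(purrr::map(per_patient, "peaks")),
    truth = bind_rows(purrr::map(per_patient, "truth"))
  )
}
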