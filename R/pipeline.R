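#' Run the simulate / segment / concordance / imbalance pipeline
#'
#' Orchestrates the package's stages over files: `simulate` writes the
#' synthetic cohort tables, `acgh-call` segments and calls the aCGH
#' profiles (with MAD-based QC), `concord` and `icc` run the
#' within-vs-between-patient analyses, `ai` and `preferential` the
#' microsatellite imbalance analyses, and `snp-ai` the SNP skew test.
#' `all` runs everything in dependency order. Every stage logs its
#' parameters and row counts to standard error and writes its outputs
#' atomically under `out_dir`.
#'
#' @param config Named list or path to a flat `key = value` file. Keys are
#'   the [sim_config()] fields plus: `out_dir` (required), `n_markers`,
#'   `n_snps`, `acgh_tsv`/`allelotype_tsv`/`snp_tsv` (inputs for analysis
#'   stages; default: the simulate outputs under `out_dir`),
#'   `mad_threshold` (0.2), `alpha` (0.01), `n_perm` (1000), `min_width`
#'   (2), `merge_p` (1e-4), `outlier_k` (3), `min_tumors` (3),
#'   `min_clones` (40), `min_pairs` (20), `ai_upper` (1.5), `ai_lower`
#'   (0.66), `ai_no_hi` (1.25), `ai_no_lo` (0.85), `pref_threshold`
#'   (-1.5), `pref_reps` (1000), `significance` (0.05). Unknown keys are
#'   rejected.
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- read_run_config(config)
  }
  cfg <- resolve_run_config(config)
  all_stages <- c("simulate", "acgh-call", "concord", "icc", "ai",
                  "preferential", "snp-ai")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown) > 0) {
    abort(sprintf("unknown stage(s): %s", paste(unknown, collapse = ", ")))
  }
  stages <- all_stages[all_stages %in% stages]  # dependency order
  log_msg("resolved config: %s",
          paste(sprintf("%s=%s", names(cfg), vapply(cfg, format, "")),
                collapse = " "))

  out <- list()
  for (st in stages) {
    log_msg("stage %s: start", st)
    out[[st]] <- switch(
      st,
      "simulate" = stage_simulate(cfg),
      "acgh-call" = stage_acgh_call(cfg),
      "concord" = stage_concord(cfg),
      "icc" = stage_icc(cfg),
      "ai" = stage_ai(cfg),
      "preferential" = stage_preferential(cfg),
      "snp-ai" = stage_snp_ai(cfg)
    )
    log_msg("stage %s: done", st)
  }
  invisible(out)
}

log_msg <- function(fmt, ...) message(sprintf(paste0("[germsoma] ", fmt), ...))

resolve_run_config <- function(config) {
  defaults <- c(
    as.list(formals(sim_config)),
    list(out_dir = NULL, n_markers = 10, n_snps = 3,
         acgh_tsv = NULL, allelotype_tsv = NULL, snp_tsv = NULL,
         mad_threshold = 0.2, alpha = 0.01, n_perm = 1000, min_width = 2,
         merge_p = 1e-4, outlier_k = 3, min_tumors = 3, min_clones = 40,
         min_pairs = 20, ai_upper = 1.5, ai_lower = 0.66, ai_no_hi = 1.25,
         ai_no_lo = 0.85, pref_threshold = -1.5, pref_reps = 1000,
         significance = 0.05)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) abort("config must set `out_dir`.")
  cfg$acgh_tsv <- cfg$acgh_tsv %||% file.path(cfg$out_dir, "acgh.tsv")
  cfg$allelotype_tsv <- cfg$allelotype_tsv %||%
    file.path(cfg$out_dir, "allelotype_peaks.tsv")
  cfg$snp_tsv <- cfg$snp_tsv %||% file.path(cfg$out_dir, "snp_peaks.tsv")
  cfg
}

sim_config_from_run <- function(cfg) {
  do.call(sim_config, cfg[names(formals(sim_config))])
}

require_input <- function(path, stage) {
  if (!file.exists(path)) {
    abort(sprintf("stage %s: input file not found: %s", stage, path))
  }
  path
}

stage_simulate <- function(cfg) {
  sc <- sim_config_from_run(cfg)
  acgh <- simulate_acgh_cohort(sc)
  ms <- simulate_allelotype_cohort(sc, n_markers = cfg$n_markers)
  snp <- simulate_snp_cohort(sc, n_snps = cfg$n_snps)
  paths <- list(
    acgh = write_tsv_atomic(acgh$acgh, file.path(cfg$out_dir, "acgh.tsv")),
    acgh_truth_arms = write_tsv_atomic(acgh$truth$arms,
                                       file.path(cfg$out_dir, "truth_acgh_arms.tsv")),
    acgh_truth_samples = write_tsv_atomic(acgh$truth$samples,
                                          file.path(cfg$out_dir, "truth_acgh_samples.tsv")),
    allelotype_genotypes = write_tsv_atomic(ms$genotypes,
                                            file.path(cfg$out_dir, "allelotype_genotypes.tsv")),
    allelotype_peaks = write_tsv_atomic(ms$peaks,
                                        file.path(cfg$out_dir, "allelotype_peaks.tsv")),
    allelotype_truth = write_tsv_atomic(ms$truth,
                                        file.path(cfg$out_dir, "truth_allelotype.tsv")),
    snp_peaks = write_tsv_atomic(snp$peaks,
                                 file.path(cfg$out_dir, "snp_peaks.tsv")),
    snp_truth = write_tsv_atomic(snp$truth,
                                 file.path(cfg$out_dir, "truth_snp.tsv"))
  )
  log_msg("simulate: %d aCGH rows, %d peak rows, %d SNP rows",
          nrow(acgh$acgh), nrow(ms$peaks), nrow(snp$peaks))
  paths
}

stage_acgh_call <- function(cfg) {
  acgh <- read_acgh_tsv(require_input(cfg$acgh_tsv, "acgh-call"))
  set.seed(child_seed(cfg$seed, "pipeline/segment"))
  seg <- segment_profiles(acgh, alpha = cfg$alpha, n_perm = cfg$n_perm,
                          min_width = cfg$min_width)
  qc <- qc_filter(seg, threshold = cfg$mad_threshold)
  for (s in qc$mads$sample_id[qc$mads$excluded]) {
    log_msg("QC: sample %s excluded (MAD %.3f > %.3f)", s,
            qc$mads$mad[qc$mads$sample_id == s], cfg$mad_threshold)
  }
  calls <- call_gains_losses(qc$kept, merge_p = cfg$merge_p)
  freq <- aberration_frequency(calls)
  list(
    calls = write_tsv_atomic(calls, file.path(cfg$out_dir, "acgh_calls.tsv")),
    mads = write_tsv_atomic(qc$mads, file.path(cfg$out_dir, "acgh_mads.tsv")),
    segments_bed = write_segments_bed(calls,
                                      file.path(cfg$out_dir, "segments.bed")),
    frequency = write_tsv_atomic(freq,
                                 file.path(cfg$out_dir, "aberration_frequency.tsv"))
  )
}

read_calls <- function(cfg, stage) {
  path <- require_input(file.path(cfg$out_dir, "acgh_calls.tsv"), stage)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_integer(),
                    position = readr::col_double(),
                    log2ratio = readr::col_double(),
                    seg_mean = readr::col_double(),
                    level_mean = readr::col_double(),
                    .default = readr::col_character()
                  ))
}

stage_concord <- function(cfg) {
  calls <- read_calls(cfg, "concord")
  resp <- build_response_matrix(calls, outlier_k = cfg$outlier_k)
  if (dplyr::n_distinct(resp$patient_id) < 2) {
    abort("concord: need >= 2 patients to form the inter-patient group.")
  }
  fit <- fit_concordance(resp, min_tumors = cfg$min_tumors,
                         min_clones = cfg$min_clones,
                         min_pairs = cfg$min_pairs)
  for (a in fit$arms$arm[!fit$arms$eligible]) {
    log_msg("concord: arm %s ineligible (clone or pair minimum not met)", a)
  }
  list(
    arms = write_tsv_atomic(tidy(fit), file.path(cfg$out_dir, "concordance_arms.tsv")),
    genome = write_tsv_atomic(glance(fit),
                              file.path(cfg$out_dir, "concordance_genome.tsv"))
  )
}

stage_icc <- function(cfg) {
  calls <- read_calls(cfg, "icc")
  resp <- build_response_matrix(calls, outlier_k = cfg$outlier_k)
  icc <- estimate_icc(resp)
  list(icc = write_tsv_atomic(icc, file.path(cfg$out_dir, "icc.tsv")))
}

ai_bands_from_run <- function(cfg) {
  ai_bands(upper = cfg$ai_upper, lower = cfg$ai_lower,
           no_hi = cfg$ai_no_hi, no_lo = cfg$ai_no_lo)
}

stage_ai <- function(cfg) {
  peaks <- read_allelotype_tsv(require_input(cfg$allelotype_tsv, "ai"))
  calls <- call_allelic_imbalance(peaks, bands = ai_bands_from_run(cfg))
  summaries <- summarize_patient_marker(calls)
  list(
    calls = write_tsv_atomic(calls, file.path(cfg$out_dir, "ai_calls.tsv")),
    summaries = write_tsv_atomic(summaries,
                                 file.path(cfg$out_dir, "ai_patient_summaries.tsv"))
  )
}

stage_preferential <- function(cfg) {
  path <- require_input(file.path(cfg$out_dir, "ai_patient_summaries.tsv"),
                        "preferential")
  summaries <- readr::read_tsv(path, show_col_types = FALSE,
                               col_types = readr::cols(
                                 n_tumors = readr::col_integer(),
                                 n_imbalanced = readr::col_integer(),
                                 k_favoring_a = readr::col_integer(),
                                 .default = readr::col_character()
                               ))
  set.seed(child_seed(cfg$seed, "pipeline/preferential"))
  fit <- test_preferential(summaries, reps = cfg$pref_reps,
                           threshold = cfg$pref_threshold,
                           alpha = cfg$significance)
  list(
    loci = write_tsv_atomic(tidy(fit), file.path(cfg$out_dir, "preferential_loci.tsv")),
    patients = write_tsv_atomic(fit$patients,
                                file.path(cfg$out_dir, "preferential_patients.tsv"))
  )
}

stage_snp_ai <- function(cfg) {
  peaks <- read_snp_tsv(require_input(cfg$snp_tsv, "snp-ai"))
  calls <- call_snp_imbalance(peaks, bands = ai_bands_from_run(cfg))
  res <- test_snp_imbalance(calls)
  list(
    calls = write_tsv_atomic(calls, file.path(cfg$out_dir, "snp_ai_calls.tsv")),
    tests = write_tsv_atomic(res, file.path(cfg$out_dir, "snp_ai_tests.tsv"))
  )
}
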