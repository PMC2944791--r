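#' Tidy a concordance fit into the per-arm results table
#'
#' One row per chromosome arm with gain/loss context left to
#' [aberration_frequency()]; columns mirror the standard per-arm report:
#' mean within- and between-patient correlation, Brown–Forsythe p, pooled
#' and Welch t p-values and their Holm adjustments, and the eligibility
#' flag.
#'
#' @param x A `concordance_fit`.
#' @param ... Unused.
#' @return Tibble, one row per arm.
#' @export
tidy.concordance_fit <- function(x, ...) {
  x$arms
}

#' One-row genome-wide summary of a concordance fit
#'
#' @param x A `concordance_fit`.
#' @param ... Unused.
#' @return One-row tibble (genome-wide test), or a one-row tibble of `NA`s
#'   when the genome scope was ineligible.
#' @export
glance.concordance_fit <- function(x, ...) {
  if (is.null(x$genome)) {
    return(tibble(arm = NA_character_, n_clones = NA_integer_,
                  eligible = FALSE, n_intra = NA_integer_,
                  n_inter = NA_integer_, mean_intra = NA_real_,
                  mean_inter = NA_real_, levene_p = NA_real_,
                  t_p_pooled = NA_real_, t_p_welch = NA_real_, p = NA_real_))
  }
  x$genome
}

#' Tidy a preferential-imbalance fit into the per-locus table
#'
#' @param x A `preferential_fit`.
#' @param ... Unused.
#' @return Tibble, one row per marker: heterozygous patient count,
#'   informative (multi-LOH) patients and their tumor total, preferential
#'   flags, Wilcoxon p.
#' @export
tidy.preferential_fit <- function(x, ...) {
  x$loci
}

#' Cohort-level summary of a preferential-imbalance fit
#'
#' @param x A `preferential_fit`.
#' @param ... Unused.
#' @return One-row tibble: loci counts, tested loci, significant loci.
#' @export
glance.preferential_fit <- function(x, ...) {
  tibble(
    n_loci = nrow(x$loci),
    n_tested = sum(!is.na(x$loci$wilcoxon_p)),
    n_significant = sum(x$loci$significant, na.rm = TRUE),
    n_informative_patients = nrow(x$patients),
    n_preferential_patients = sum(x$patients$preferential)
  )
}
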