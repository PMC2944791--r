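#' Allelic-imbalance ratio from tumor/normal peak heights
#'
#' `R = (TA/TB) / (NA/NB)`: the tumor's allele-peak ratio normalized by
#' the matched normal's. `R = 1` means the tumor preserves the germline
#' allele balance; `R > 1` means the larger (A) allele is relatively
#' over-represented in the tumor, `R < 1` the smaller (B) allele.
#' Vectorized; all four peaks must be strictly positive.
#'
#' @param tumor_a,tumor_b Tumor peak heights of the larger (A) and smaller
#'   (B) allele.
#' @param normal_a,normal_b Matched normal peak heights.
#' @return Numeric vector of ratios.
#' @examples
#' ai_ratio(100, 50, 50, 50)  # 2: A allele doubled in the tumor
#' @export
ai_ratio <- function(tumor_a, tumor_b, normal_a, normal_b) {
  peaks <- list(tumor_a = tumor_a, tumor_b = tumor_b,
                normal_a = normal_a, normal_b = normal_b)
  for (nm in names(peaks)) {
    bad <- !is.na(peaks[[nm]]) & peaks[[nm]] <= 0
    if (any(bad)) {
      abort(sprintf("`%s` must be strictly positive (offending value at position %d)",
                    nm, which(bad)[1]))
    }
  }
  (tumor_a / tumor_b) / (normal_a / normal_b)
}

#' Classification bands for the allelic-imbalance ratio
#'
#' A tumor shows imbalance when `R > upper` (A allele relatively retained)
#' or `R < lower` (B retained); no imbalance when
#' `no_lo <= R <= no_hi`; anything else is uncertain. The published
#' convention is asymmetric (`lower = 0.66`, not `1/1.5`), and is kept as
#' printed; all bands are configurable.
#'
#' @param upper,lower Imbalance thresholds.
#' @param no_hi,no_lo Bounds of the no-imbalance band.
#' @return A named list of class `ai_bands`.
#' @export
ai_bands <- function(upper = 1.5, lower = 0.66, no_hi = 1.25, no_lo = 0.85) {
  stopifnot(lower < no_lo, no_lo <= no_hi, no_hi < upper)
  structure(list(upper = upper, lower = lower, no_hi = no_hi, no_lo = no_lo),
            class = "ai_bands")
}

#' Classify allelic-imbalance ratios
#'
#' @param R Numeric vector of ratios (> 0).
#' @param bands An [ai_bands()] object.
#' @return Tibble with `R`, `status` (factor `imbalance` / `no_imbalance` /
#'   `uncertain`) and `favored_allele` (factor `A` / `B` / `none`; the
#'   relatively retained allele, `none` unless imbalance).
#' @examples
#' classify_ai(c(2, 1.4, 1, 0.5))
#' @export
classify_ai <- function(R, bands = ai_bands()) {
  stopifnot(inherits(bands, "ai_bands"))
  if (any(!is.na(R) & R <= 0)) abort("`R` must be strictly positive.")
  status <- dplyr::case_when(
    is.na(R) ~ NA_character_,
    R > bands$upper | R < bands$lower ~ "imbalance",
    R >= bands$no_lo & R <= bands$no_hi ~ "no_imbalance",
    TRUE ~ "uncertain"
  )
  favored <- dplyr::case_when(
    is.na(R) ~ NA_character_,
    R > bands$upper ~ "A",
    R < bands$lower ~ "B",
    TRUE ~ "none"
  )
  tibble(
    R = R,
    status = factor(status, levels = c("imbalance", "no_imbalance", "uncertain")),
    favored_allele = factor(favored, levels = c("A", "B", "none"))
  )
}

#' Per-tumor allelic-imbalance calls for a microsatellite cohort
#'
#' Joins each tumor's peak record to its patient's matched normal, applies
#' [ai_ratio()] and [classify_ai()] at heterozygous markers, and drops
#' non-informative records: homozygous patients (normal alleles of equal
#' size) and tumors missing either member of the normal/tumor pair.
#'
#' @param peaks Peak tibble in the allelotype dialect (`patient_id`,
#'   `sample_id`, `sample_type`, `marker_id`, `allele_a_bp`, `allele_b_bp`,
#'   `peak_a`, `peak_b`).
#' @param bands An [ai_bands()] object.
#' @return Tibble with one row per heterozygous tumor x marker:
#'   `patient_id`, `sample_id`, `marker_id`, `R`, `status`,
#'   `favored_allele`.
#' @export
call_allelic_imbalance <- function(peaks, bands = ai_bands()) {
  assert_cols(peaks, c("patient_id", "sample_id", "sample_type", "marker_id",
                       "allele_a_bp", "allele_b_bp", "peak_a", "peak_b"),
              "`peaks`")
  normals <- peaks |>
    filter(.data$sample_type == "normal",
           !is.na(.data$peak_a), !is.na(.data$peak_b)) |>
    select("patient_id", "marker_id",
           n_allele_a = "allele_a_bp", n_allele_b = "allele_b_bp",
           normal_a = "peak_a", normal_b = "peak_b")
  tumors <- peaks |>
    filter(.data$sample_type == "tumor",
           !is.na(.data$peak_a), !is.na(.data$peak_b))

  calls <- tumors |>
    inner_join(normals, by = c("patient_id", "marker_id")) |>
    filter(.data$n_allele_a != .data$n_allele_b)  # heterozygous normals only
  ai <- classify_ai(
    ai_ratio(calls$peak_a, calls$peak_b, calls$normal_a, calls$normal_b),
    bands
  )
  dplyr::bind_cols(
    select(calls, "patient_id", "sample_id", "marker_id"),
    ai
  )
}

#' Per-tumor allelic-imbalance calls for quantitative SNP data
#'
#' Identical ratio and bands as the microsatellite analysis, with SNP
#' alleles ordered lexicographically by base (allele 1 plays the "A" role
#' of the larger microsatellite allele). Homozygous normals and tumors
#' missing either member of the matched pair are excluded.
#'
#' @param peaks SNP peak tibble (`patient_id`, `sample_id`, `sample_type`,
#'   `snp_id`, `allele_1`, `allele_2`, `area_1`, `area_2`).
#' @param bands An [ai_bands()] object.
#' @return Tibble as [call_allelic_imbalance()] with `snp_id` in place of
#'   `marker_id`.
#' @export
call_snp_imbalance <- function(peaks, bands = ai_bands()) {
  assert_cols(peaks, c("patient_id", "sample_id", "sample_type", "snp_id",
                       "allele_1", "allele_2", "area_1", "area_2"), "`peaks`")
  # Enforce lexicographic allele order, swapping areas along with labels.
  swap <- !is.na(peaks$allele_1) & !is.na(peaks$allele_2) &
    peaks$allele_1 > peaks$allele_2
  peaks[swap, c("allele_1", "allele_2")] <- peaks[swap, c("allele_2", "allele_1")]
  peaks[swap, c("area_1", "area_2")] <- peaks[swap, c("area_2", "area_1")]

  renamed <- rename(peaks, marker_id = "snp_id",
                    allele_a_bp = "allele_1", allele_b_bp = "allele_2",
                    peak_a = "area_1", peak_b = "area_2")
  call_allelic_imbalance(renamed, bands) |>
    rename(snp_id = "marker_id")
}

#' Summarise imbalance calls per patient and marker
#'
#' For each heterozygous patient x marker, counts `n_imbalanced` (tumors
#' with an imbalance call) and `k_favoring_a` (those whose retained allele
#' is A) — the sufficient statistics of the preferential-imbalance test.
#' Uncertain and no-imbalance calls contribute to neither count.
#'
#' @param calls Output of [call_allelic_imbalance()] (or
#'   [call_snp_imbalance()] after renaming `snp_id` to `marker_id`).
#' @return Tibble: `patient_id`, `marker_id`, `n_tumors` (classified),
#'   `n_imbalanced`, `k_favoring_a`.
#' @export
summarize_patient_marker <- function(calls) {
  if ("snp_id" %in% names(calls) && !"marker_id" %in% names(calls)) {
    calls <- rename(calls, marker_id = "snp_id")
  }
  assert_cols(calls, c("patient_id", "marker_id", "status", "favored_allele"),
              "`calls`")
  calls |>
    filter(!is.na(.data$status)) |>
    group_by(.data$patient_id, .data$marker_id) |>
    summarise(
      n_tumors = n(),
      n_imbalanced = sum(.data$status == "imbalance"),
      k_favoring_a = sum(.data$status == "imbalance" & .data$favored_allele == "A"),
      .groups = "drop"
    )
}
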