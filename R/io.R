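# Readers/writers for the package's tab-delimited dialects.

#' Read and write the package's tab-delimited tables
#'
#' Thin wrappers over readr with the column types of each dialect pinned
#' down: aCGH clone tables, allelotype and SNP peak tables, and generic
#' result tables. Writing is atomic (write to a temp file in the target
#' directory, then rename).
#'
#' @param path File path.
#' @return A tibble (readers) or `path`, invisibly (writer).
#' @name germsoma_io
NULL

#' @rdname germsoma_io
#' @export
read_acgh_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_integer(),
                           position = readr::col_double(),
                           log2ratio = readr::col_double(),
                           .default = readr::col_character()
                         ))
  assert_cols(out, c("sample_id", "patient_id", "clone_id", "chrom", "arm",
                     "position", "log2ratio"), path)
  out
}

#' @rdname germsoma_io
#' @export
read_allelotype_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           peak_a = readr::col_double(),
                           peak_b = readr::col_double(),
                           .default = readr::col_character()
                         ))
  assert_cols(out, c("patient_id", "sample_id", "sample_type", "marker_id",
                     "allele_a_bp", "allele_b_bp", "peak_a", "peak_b"), path)
  out
}

#' @rdname germsoma_io
#' @export
read_snp_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           area_1 = readr::col_double(),
                           area_2 = readr::col_double(),
                           .default = readr::col_character()
                         ))
  assert_cols(out, c("patient_id", "sample_id", "sample_type", "snp_id",
                     "allele_1", "allele_2", "area_1", "area_2"), path)
  out
}

#' @rdname germsoma_io
#' @param x Tibble to write.
#' @export
write_tsv_atomic <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  readr::write_tsv(x, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Export segments as a BED-style table
#'
#' Six BED columns (chrom, 0-based half-open start/end, name = sample id,
#' score 0, strand ".") plus `seg_mean` and, when calls are present, the
#' segment's `call`.
#'
#' @param segmented Output of [segment_profiles()] or
#'   [call_gains_losses()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segmented, path) {
  segs <- segments_table(segmented)
  if ("call" %in% names(segmented)) {
    seg_calls <- segmented |>
      filter(!is.na(.data$seg_id)) |>
      distinct(.data$sample_id, .data$chrom, .data$seg_id, .data$call)
    segs <- left_join(segs, seg_calls, by = c("sample_id", "chrom", "seg_id"))
  }
  bed <- segs |>
    mutate(name = .data$sample_id, score = 0L, strand = ".") |>
    select("chrom", "start", "end", "name", "score", "strand", "seg_mean",
           dplyr::any_of("call"))
  write_tsv_atomic(bed, path)
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are parsed as numbers where possible.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) abort(sprintf("malformed config line: '%s'", lines[bad][1]))
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(parsed, keys)
}
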