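#' Segment aCGH profiles by circular binary segmentation
#'
#' Partitions each sample's per-chromosome log2-ratio sequence into regions
#' of equal copy number. The change-point search is circular binary
#' segmentation: for the current stretch, the circular two-arc split
#' maximising the pooled two-sample t statistic is located by exhaustive
#' scan, its significance is assessed by permuting the clone values within
#' the stretch, and the split is accepted when the permutation p-value
#' falls below `alpha`; accepted splits are refined recursively. Results
#' are deterministic for a fixed RNG seed (`set.seed()` before calling).
#'
#' @param acgh Clone-level tibble with columns `sample_id`, `clone_id`,
#'   `chrom`, `position`, `log2ratio` (plus any metadata columns, carried
#'   through). Missing log2 ratios are allowed and are excluded from
#'   segmentation.
#' @param alpha Permutation significance level required to accept a split.
#' @param n_perm Number of permutations per candidate split.
#' @param min_width Minimum number of clones in a segment.
#' @return The input tibble (row order preserved within sample/chromosome)
#'   with two added columns: `seg_id` (segment label, unique within a
#'   sample) and `seg_mean` (that segment's mean log2 ratio). Missing
#'   clones get `NA` in both.
#' @examples
#' sim <- simulate_acgh_cohort(sim_config(n_patients = 1, n_clones = 88,
#'                                        seed = 3))
#' set.seed(1)
#' seg <- segment_profiles(sim$acgh, n_perm = 100)
#' dplyr::count(seg, sample_id, seg_id)
#' @export
segment_profiles <- function(acgh, alpha = 0.01, n_perm = 1000L, min_width = 2L) {
  assert_cols(acgh, c("sample_id", "clone_id", "chrom", "position", "log2ratio"),
              "`acgh`")
  assert_prob(alpha, "alpha")
  n_perm <- assert_count(n_perm, "n_perm")
  min_width <- assert_count(min_width, "min_width")

  acgh <- arrange(acgh, .data$sample_id, .data$chrom, .data$position)
  val <- acgh$log2ratio
  seg_id <- rep(NA_character_, nrow(acgh))
  seg_mean <- rep(NA_real_, nrow(acgh))
  groups <- split(seq_len(nrow(acgh)),
                  list(acgh$sample_id, acgh$chrom), drop = TRUE)
  for (nm in names(groups)) {
    rows <- groups[[nm]]
    ok <- !is.na(val[rows])
    if (!any(ok)) {
      warn(sprintf("%s: all values missing; no segments", nm))
      next
    }
    idx <- rows[ok]
    y <- val[idx]
    cuts <- cbs_breakpoints(y, alpha, n_perm, min_width)
    seg_of <- findInterval(seq_along(y) - 1L, cuts) + 1L  # cuts are 0-based
    means <- vapply(split(y, seg_of), mean, 0)
    seg_id[idx] <- sprintf("%d_seg%02d", acgh$chrom[idx][1], seg_of)
    seg_mean[idx] <- means[seg_of]
  }
  acgh$seg_id <- seg_id
  acgh$seg_mean <- seg_mean
  acgh
}

# Recursive CBS on a complete (non-missing) vector. Returns sorted 0-based
# cut positions: a cut at c separates y[1..c] from y[c+1..].
cbs_breakpoints <- function(y, alpha, n_perm, min_width) {
  n <- length(y)
  recurse <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L * min_width) return(integer(0))
    best <- .cbs_max_t(y[lo:hi], min_width)
    if (best$t <= 0) return(integer(0))
    p <- .cbs_perm_p(y[lo:hi], best$t, n_perm, min_width, alpha)
    if (p >= alpha) return(integer(0))
    i <- best$i  # arc is [i, j) 0-based within this stretch
    j <- best$j
    cuts <- integer(0)
    if (i > 0L) cuts <- c(cuts, lo - 1L + i)
    if (j < m) cuts <- c(cuts, lo - 1L + j)
    bounds <- c(lo - 1L, cuts, hi)
    kids <- purrr::map(seq_len(length(bounds) - 1L), function(k) {
      recurse(bounds[k] + 1L, bounds[k + 1L])
    })
    sort(c(cuts, unlist(kids)))
  }
  recurse(1L, n)
}

#' Summarise segments of a segmented cohort
#'
#' Collapses the per-clone output of [segment_profiles()] to one row per
#' segment, with clone index bounds, genomic bounds (0-based half-open,
#' BED-style) and the segment mean.
#'
#' @param segmented Output of [segment_profiles()].
#' @return Tibble with `sample_id`, `chrom`, `seg_id`, `start_index`,
#'   `end_index` (1-based inclusive clone indices within the chromosome),
#'   `start`, `end` (positions, 0-based half-open), `n_clones`, `seg_mean`.
#' @export
segments_table <- function(segmented) {
  assert_cols(segmented, c("sample_id", "chrom", "position", "seg_id", "seg_mean"),
              "`segmented`")
  segmented |>
    filter(!is.na(.data$seg_id)) |>
    group_by(.data$sample_id, .data$chrom) |>
    mutate(.clone_index = row_number()) |>
    group_by(.data$sample_id, .data$chrom, .data$seg_id) |>
    summarise(
      start_index = min(.data$.clone_index),
      end_index = max(.data$.clone_index),
      start = min(.data$position) - 1L,
      end = max(.data$position),
      n_clones = n(),
      seg_mean = .data$seg_mean[1],
      .groups = "drop"
    ) |>
    arrange(.data$sample_id, .data$chrom, .data$start_index)
}
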