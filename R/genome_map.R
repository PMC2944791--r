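#' Build a clone-level genome map
#'
#' Lays out BAC-clone style probes across the 22 autosomes, split into p and
#' q arms. The map is the coordinate system every aCGH profile aligns to:
#' one row per clone with a chromosome, an arm and a basepair position.
#' Clones are evenly spaced within each arm and positions are strictly
#' increasing within a chromosome.
#'
#' @param n_clones Total number of clones to place (>= 2 per declared arm).
#' @param arm_fractions Optional tibble/data frame with columns `chrom`
#'   (1-22), `arm` (`"p"`/`"q"`) and `fraction` giving each arm's share of
#'   clones; fractions must sum to 1. Default: all 44 autosomal arms with
#'   equal shares.
#' @return A tibble with columns `clone_id`, `chrom`, `arm`, `position`,
#'   ordered by chromosome then position.
#' @examples
#' gm <- genome_map(440)
#' dplyr::count(gm, chrom, arm)
#' @export
genome_map <- function(n_clones, arm_fractions = NULL) {
  n_clones <- assert_count(n_clones, "n_clones", min = 2L)
  if (is.null(arm_fractions)) {
    arm_fractions <- tibble(
      chrom = rep(1:22, each = 2L),
      arm = rep(c("p", "q"), times = 22L),
      fraction = 1 / 44
    )
  }
  arm_fractions <- as_tibble(arm_fractions)
  assert_cols(arm_fractions, c("chrom", "arm", "fraction"), "`arm_fractions`")
  if (!all(arm_fractions$chrom %in% 1:22)) {
    abort("`arm_fractions$chrom` must be autosomes 1..22.")
  }
  if (!all(arm_fractions$arm %in% c("p", "q"))) {
    abort("`arm_fractions$arm` must be \"p\" or \"q\".")
  }
  if (anyDuplicated(arm_fractions[c("chrom", "arm")])) {
    abort("`arm_fractions` has duplicated chrom/arm rows.")
  }
  if (abs(sum(arm_fractions$fraction) - 1) > 1e-8) {
    abort("`arm_fractions$fraction` must sum to 1.")
  }
  n_arms <- nrow(arm_fractions)
  if (n_clones < n_arms) {
    abort(sprintf("`n_clones` (%d) must be at least 1 per arm (%d arms).",
                  n_clones, n_arms))
  }

  # Largest-remainder apportionment so clone counts hit n_clones exactly
  # while every arm keeps at least one clone.
  quota <- arm_fractions$fraction * n_clones
  counts <- pmax(1L, floor(quota))
  short <- n_clones - sum(counts)
  if (short > 0) {
    idx <- order(quota - floor(quota), decreasing = TRUE)
    take <- rep_len(idx, short)
    for (i in take) counts[i] <- counts[i] + 1L
  } else if (short < 0) {
    idx <- order(quota - floor(quota))
    for (i in rep_len(idx[counts[idx] > 1L], -short)) counts[i] <- counts[i] - 1L
  }

  arm_len <- 5e7  # nominal 50 Mb per arm; spacing, not physical truth
  arm_fractions |>
    mutate(n = counts) |>
    arrange(.data$chrom, .data$arm) |>
    purrr::pmap(function(chrom, arm, fraction, n) {
      offset <- if (arm == "p") 0 else arm_len
      tibble(
        chrom = chrom,
        arm = arm,
        position = offset + as.integer(round(seq(1, arm_len, length.out = n)))
      )
    }) |>
    bind_rows() |>
    arrange(.data$chrom, .data$position) |>
    mutate(clone_id = sprintf("clone_%04d", row_number())) |>
    select("clone_id", "chrom", "arm", "position")
}
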