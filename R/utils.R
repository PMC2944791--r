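# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a stream label
#'
#' Streams (per patient, per cohort type) get independent, deterministic
#' seeds so that, e.g., adding patients to a simulated cohort does not
#' perturb the draws of earlier patients.
#'
#' @param seed Master integer seed.
#' @param label Character stream label, e.g. `"acgh/patient/3"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring
# the caller's RNG afterwards. Base-R equivalent of withr::with_seed, kept
# internal so the package has no runtime withr dependency.
with_child_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
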