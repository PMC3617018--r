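# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) stopf("`%s` must be a number in %s%g, %g%s", name,
                 if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]")
  as.numeric(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` must be a single integer")
  as.integer(seed %% .Machine$integer.max)
}

#' Derive a per-stage seed from a master seed
#'
#' Each pipeline stage draws from its own RNG stream, seeded deterministically
#' from the master seed and the stage name, so that changing the number of
#' random draws in one stage cannot perturb any other stage.
#'
#' @param master_seed single integer master seed.
#' @param stage character stage name.
#' @return a single integer seed, always in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(master_seed, stage) {
  master_seed <- check_seed(master_seed)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 7919 + h) %% (.Machine$integer.max - 1))
}
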