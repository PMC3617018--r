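#' Quantile normalise a structure matrix across all datasets
#'
#' Imposes a common empirical distribution on every column: the reference is
#' the across-column mean of order statistics, each column's values are
#' replaced by the reference value at their rank, and tied values within a
#' column receive the mean of the reference entries their rank span covers.
#' Normalisation is applied jointly across both species' columns, so a single
#' reference distribution describes every dataset regardless of platform.
#'
#' @param x a raw `StructureMatrix` (complete-case, >= 2 rows and columns).
#' @return the matrix with stage `"normalised"`; the reference distribution is
#'   stored in the `reference` element.
#' @export
quantile_normalise <- function(x) {
  stopifnot(inherits(x, "StructureMatrix"))
  v <- x$values
  if (anyNA(v)) stopf("missing cells: quantile normalisation expects a complete-case matrix")
  if (nrow(v) < 2 || ncol(v) < 2)
    stopf("need at least 2 rows and 2 columns")

  ref <- rowMeans(apply(v, 2, sort))
  cs <- c(0, cumsum(ref))
  out <- apply(v, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(v)
  x$values <- out
  x$stage <- "normalised"
  x$reference <- ref
  x
}

#' Per-region mean normalised structure for one species
#'
#' The arithmetic mean over that species' dataset columns, one value per
#' orthologous region — the per-species structure summary used for polarity
#' interpretation and chromosome-scale trend plots.
#'
#' @param x a `StructureMatrix` (normalised stage expected).
#' @param species species label present in `x$datasets$species`.
#' @return named numeric vector (names = region ids).
#' @export
mean_structure <- function(x, species) {
  stopifnot(inherits(x, "StructureMatrix"))
  cols <- x$datasets$id[x$datasets$species == species]
  if (!length(cols)) stopf("unknown species label: %s", species)
  m <- rowMeans(x$values[, cols, drop = FALSE])
  names(m) <- x$regions$region_id
  m
}
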