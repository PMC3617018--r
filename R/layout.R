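#' Genome layout
#'
#' A `GenomeLayout` records the coordinate universe of one species: ordered
#' chromosome names and lengths, with optional centromere coordinates and
#' acrocentric flags. It is the backbone for binning, subtelomere/centromere
#' window construction and circular permutation.
#'
#' @param species short species tag (e.g. `"human"`, `"mouse"`).
#' @param chromosomes data.frame with columns `name` (unique character),
#'   `length` (positive integer bp), and optionally `centromere` (bp strictly
#'   inside the chromosome, `NA` allowed) and `acrocentric` (logical).
#' @return an object of class `GenomeLayout`.
#' @export
genome_layout <- function(species, chromosomes) {
  stopifnot(is.character(species), length(species) == 1L, is.data.frame(chromosomes))
  req <- c("name", "length")
  if (!all(req %in% names(chromosomes)))
    stopf("`chromosomes` needs columns: %s", paste(req, collapse = ", "))
  if (anyDuplicated(chromosomes$name))
    stopf("chromosome names must be unique")
  if (any(chromosomes$length <= 0))
    stopf("chromosome lengths must be positive")
  if (is.null(chromosomes$centromere)) chromosomes$centromere <- NA_real_
  if (is.null(chromosomes$acrocentric)) chromosomes$acrocentric <- FALSE
  bad <- !is.na(chromosomes$centromere) &
    (chromosomes$centromere <= 0 | chromosomes$centromere >= chromosomes$length)
  if (any(bad))
    stopf("centromere coordinates must lie strictly inside the chromosome: %s",
          paste(chromosomes$name[bad], collapse = ", "))
  chromosomes$name <- as.character(chromosomes$name)
  structure(list(species = species,
                 chromosomes = chromosomes[, c("name", "length", "centromere", "acrocentric")]),
            class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout <%s>: %d chromosomes, %.1f Mb total\n",
              x$species, nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$name)
  if (anyNA(i)) stopf("unknown chromosome(s): %s",
                      paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$chromosomes$length[i]
}

#' Enumerate whole bins tiling a layout
#'
#' Bins tile each chromosome in order from coordinate 0 using 0-based
#' half-open intervals. Terminal remnants shorter than `bin_size` are not
#' binned, so every emitted bin has exactly `bin_size` bp.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp (default 100 Kb).
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
layout_bins <- function(layout, bin_size = 1e5) {
  stopifnot(inherits(layout, "GenomeLayout"))
  bin_size <- check_count(bin_size, "bin_size")
  out <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    n <- layout$chromosomes$length[i] %/% bin_size
    if (n == 0L) return(NULL)
    data.frame(chrom = layout$chromosomes$name[i],
               start = as.numeric(seq_len(n) - 1L) * bin_size,
               end = as.numeric(seq_len(n)) * bin_size)
  })
  do.call(rbind, out)
}
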