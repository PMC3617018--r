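#' Average probe records into fixed-width bins
#'
#' Probes are assigned to consecutive non-overlapping bins by their midpoint
#' (0-based half-open intervals, integer division by `bin_size`); each
#' retained (bin, dataset) cell holds the arithmetic mean of its probe values.
#' Cells with fewer than `min_probes` probes are discarded as unreliable, and
#' terminal chromosome remnants shorter than one bin are never binned.
#'
#' @param probes data.frame with columns `chrom`, `pos`, `dataset`, `value`.
#' @param layout a [genome_layout()] naming the valid chromosomes.
#' @param bin_size bin width in bp (default 100 Kb).
#' @param min_probes minimum probes per retained cell (default 10).
#' @return a `BinTrack`: data.frame with `dataset`, `chrom`, `start`, `end`,
#'   `value`, `n_probes`, sorted by dataset then coordinate, with the bin size
#'   stored as an attribute.
#' @export
bin_probes <- function(probes, layout, bin_size = 1e5, min_probes = 10) {
  stopifnot(is.data.frame(probes), inherits(layout, "GenomeLayout"))
  if (!all(c("chrom", "pos", "dataset", "value") %in% names(probes)))
    stopf("`probes` needs columns chrom, pos, dataset, value")
  bin_size <- check_count(bin_size, "bin_size")
  min_probes <- check_count(min_probes, "min_probes")

  unknown <- setdiff(unique(probes$chrom), layout$chromosomes$name)
  if (length(unknown)) {
    bad <- which(probes$chrom %in% unknown)[1]
    stopf("probe on unknown chromosome: %s:%s (dataset %s)",
          probes$chrom[bad], format(probes$pos[bad], scientific = FALSE),
          probes$dataset[bad])
  }
  len <- chrom_length(layout, probes$chrom)
  if (any(probes$pos < 0 | probes$pos >= len)) {
    bad <- which(probes$pos < 0 | probes$pos >= len)[1]
    stopf("probe outside chromosome bounds: %s:%s (dataset %s)",
          probes$chrom[bad], format(probes$pos[bad], scientific = FALSE),
          probes$dataset[bad])
  }

  dt <- data.table::as.data.table(probes)
  dt[, bin_start := (pos %/% bin_size) * bin_size]
  # drop probes falling in a terminal sub-bin remnant
  dt <- dt[bin_start + bin_size <= chrom_length(layout, chrom)]
  agg <- dt[, .(value = mean(value), n_probes = .N),
            by = .(dataset, chrom, bin_start)]
  agg <- agg[n_probes >= min_probes]
  out <- data.frame(dataset = agg$dataset, chrom = agg$chrom,
                    start = as.numeric(agg$bin_start),
                    end = as.numeric(agg$bin_start) + bin_size,
                    value = agg$value, n_probes = agg$n_probes)
  out <- out[order(out$dataset,
                   match(out$chrom, layout$chromosomes$name), out$start), ]
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  class(out) <- c("BinTrack", "data.frame")
  out
}

#' Convert a synthetic binned structure track to `BinTrack` form
#'
#' Natively binned data (e.g. Hi-C eigenvalue tracks, or simulated bin
#' values) carry no probe counts; the `n_probes` column is `NA`.
#'
#' @param structure a [gen_structure()] result.
#' @return a `BinTrack` data.frame (see [bin_probes()]).
#' @export
as_bin_track <- function(structure) {
  stopifnot(inherits(structure, "StructureTrack"))
  k <- ncol(structure$values)
  out <- data.frame(
    dataset = rep(structure$datasets$id, each = nrow(structure$bins)),
    chrom = rep(structure$bins$chrom, k),
    start = rep(structure$bins$start, k),
    end = rep(structure$bins$end, k),
    value = as.vector(structure$values),
    n_probes = NA_integer_)
  attr(out, "bin_size") <- structure$bin_size
  class(out) <- c("BinTrack", "data.frame")
  out
}

# best-overlap match of each anchor bin [s, s+w) against another grid's bins;
# returns value + overlap fraction (of the anchor bin length), NA if below
# threshold or absent
match_bins_one_chrom <- function(anchor_start, anchor_end, other_start,
                                 other_end, other_value, min_frac) {
  o <- order(other_start)
  os <- other_start[o]; oe <- other_end[o]; ov <- other_value[o]
  n <- length(anchor_start)
  val <- rep(NA_real_, n); frac <- rep(NA_real_, n)
  idx <- findInterval(anchor_start, os)
  for (k in 0:1) {
    j <- idx + k
    okj <- j >= 1 & j <= length(os)
    ovl <- rep(-Inf, n)
    ovl[okj] <- pmin(anchor_end[okj], oe[j[okj]]) - pmax(anchor_start[okj], os[j[okj]])
    f <- ovl / (anchor_end - anchor_start)
    better <- !is.na(f) & f >= min_frac & (is.na(frac) | f > frac)
    val[better] <- ov[j[better]]
    frac[better] <- f[better]
  }
  list(value = val, frac = frac)
}

#' Collate binned datasets of one species into a region-by-dataset table
#'
#' Regions survive only if present, post probe-count filtering, in every
#' dataset with pairwise coordinate overlap of at least
#' `min_collate_overlap` (fraction of the bin length). With identical binning
#' grids this reduces to exact coordinate match plus the complete-case rule.
#' The first track's grid is the anchor: output coordinates are its bins.
#'
#' @param tracks list of `BinTrack` data.frames (see [bin_probes()],
#'   [as_bin_track()]), all from one species.
#' @param min_collate_overlap pairwise overlap threshold in (0, 1].
#' @param species species label attached to the result.
#' @return data.frame `chrom`, `start`, `end` plus one value column per
#'   dataset; complete cases only. Attribute `datasets` lists the column ids.
#' @export
collate_species <- function(tracks, min_collate_overlap = 0.5, species = "A") {
  if (inherits(tracks, "BinTrack")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L)
  min_collate_overlap <- check_fraction(min_collate_overlap, "min_collate_overlap",
                                        open_lo = TRUE)
  all_ds <- unique(unlist(lapply(tracks, function(t) unique(t$dataset))))
  flat <- do.call(rbind, lapply(tracks, as.data.frame))
  sp_attr <- unique(unlist(lapply(tracks, function(t) attr(t, "species"))))
  if (length(sp_attr) > 1)
    stopf("mixed species labels in `tracks`: %s", paste(sp_attr, collapse = ", "))

  anchor <- unique(as.data.frame(tracks[[1]])[, c("chrom", "start", "end")])
  anchor <- anchor[order(anchor$chrom, anchor$start), ]
  out <- anchor
  for (ds in all_ds) {
    sub <- flat[flat$dataset == ds, ]
    v <- rep(NA_real_, nrow(anchor))
    for (ch in unique(anchor$chrom)) {
      ai <- which(anchor$chrom == ch)
      si <- which(sub$chrom == ch)
      if (!length(si)) next
      m <- match_bins_one_chrom(anchor$start[ai], anchor$end[ai],
                                sub$start[si], sub$end[si], sub$value[si],
                                min_collate_overlap)
      v[ai] <- m$value
    }
    out[[ds]] <- v
  }
  keep <- complete.cases(out[, all_ds, drop = FALSE])
  out <- out[keep, ]
  rownames(out) <- NULL
  attr(out, "datasets") <- all_ds
  attr(out, "species") <- species
  out
}
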