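# Circular-permutation tests for positional enrichment of interval sets.
#
# The null preserves the observed degree of clustering: each permuted dataset
# rigidly rotates all regions on a chromosome by one random offset, treating
# the chromosome as circular, so interval lengths and pairwise spacings
# (mod chromosome length) are conserved.

#' Subtelomeric windows of a layout
#'
#' For a non-acrocentric chromosome of length L the subtelomeric intervals at
#' window `w` are `[0, w)` and `[L - w, L)`; acrocentric chromosomes (whose
#' proximal end is the centromere) contribute only the distal interval
#' `[L - w, L)`. Windows longer than the chromosome are clipped to the whole
#' chromosome with a warning.
#'
#' @param layout a [genome_layout()].
#' @param window window size in bp (e.g. 1e6, 5e6, 1e7).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
subtelomere_intervals <- function(layout, window) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!is.numeric(window) || window <= 0) stopf("`window` must be positive")
  ch <- layout$chromosomes
  clipped <- window >= ch$length
  if (any(clipped))
    warnf("window >= chromosome length for %s; clipped to whole chromosome",
          paste(ch$name[clipped], collapse = ", "))
  w <- pmin(window, ch$length)
  distal <- data.frame(chrom = ch$name, start = ch$length - w, end = ch$length)
  proximal <- data.frame(chrom = ch$name[!ch$acrocentric],
                         start = 0, end = w[!ch$acrocentric])
  out <- rbind(proximal, distal)
  out <- out[order(match(out$chrom, ch$name), out$start), ]
  rownames(out) <- NULL
  out
}

#' Centromeric windows of a layout
#'
#' Window-sized intervals flanking the centromere coordinate: `[c, c + w)` on
#' the q-arm side and, for non-acrocentric chromosomes, `[c - w, c)` on the
#' p-arm side, clipped to the chromosome. Chromosomes without a centromere
#' coordinate are skipped with a warning.
#'
#' @inheritParams subtelomere_intervals
#' @return data.frame `chrom`, `start`, `end`.
#' @export
centromere_intervals <- function(layout, window) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!is.numeric(window) || window <= 0) stopf("`window` must be positive")
  ch <- layout$chromosomes
  missing <- is.na(ch$centromere)
  if (any(missing))
    warnf("no centromere coordinate for %s; skipped",
          paste(ch$name[missing], collapse = ", "))
  ch <- ch[!missing, , drop = FALSE]
  if (!nrow(ch)) return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  s <- ifelse(ch$acrocentric, ch$centromere, pmax(0, ch$centromere - window))
  e <- pmin(ch$length, ch$centromere + window)
  out <- data.frame(chrom = ch$name, start = s, end = e)
  rownames(out) <- NULL
  out
}

#' Circularly shift an interval set
#'
#' All intervals on a chromosome move by the same offset, wrapping modulo the
#' chromosome length; intervals that wrap past the end are split into two
#' sub-intervals carrying the same interval id, equivalent to reassigning the
#' overhang to the chromosome start.
#'
#' @param regions data.frame `chrom`, `start`, `end` (0-based half-open); an
#'   `id` column is added if absent.
#' @param layout a [genome_layout()].
#' @param offsets named numeric vector of per-chromosome offsets in
#'   `[0, length)`; chromosomes without an entry shift by 0.
#' @return data.frame `chrom`, `start`, `end`, `id` (wrapped intervals appear
#'   as two rows with one id).
#' @export
circular_shift <- function(regions, layout, offsets) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (is.null(regions$id)) regions$id <- seq_len(nrow(regions))
  L <- chrom_length(layout, regions$chrom)
  if (any(regions$start < 0 | regions$end > L | regions$start >= regions$end))
    stopf("interval outside chromosome bounds")
  off <- offsets[regions$chrom]
  off[is.na(off)] <- 0
  if (any(off < 0 | off >= L)) stopf("offsets must lie in [0, chromosome length)")
  s <- (regions$start + off) %% L
  e <- s + (regions$end - regions$start)
  wrap <- e > L
  out <- data.frame(chrom = regions$chrom, start = s, end = pmin(e, L),
                    id = regions$id)
  if (any(wrap)) {
    out <- rbind(out, data.frame(chrom = regions$chrom[wrap], start = 0,
                                 end = e[wrap] - L[wrap], id = regions$id[wrap]))
  }
  rownames(out) <- NULL
  out
}

# merged, sorted feature intervals and boundary positions per chromosome
prep_features <- function(features) {
  lapply(split(features[, c("start", "end")], features$chrom), function(f) {
    o <- order(f$start)
    s <- f$start[o]; e <- f$end[o]
    # merge overlapping/adjacent intervals
    keep_s <- numeric(0); keep_e <- numeric(0)
    for (i in seq_along(s)) {
      if (length(keep_e) && s[i] <= keep_e[length(keep_e)]) {
        keep_e[length(keep_e)] <- max(keep_e[length(keep_e)], e[i])
      } else {
        keep_s <- c(keep_s, s[i]); keep_e <- c(keep_e, e[i])
      }
    }
    list(start = keep_s, end = keep_e,
         boundaries = sort(unique(c(f$start, f$end))))
  })
}

# number of distinct region ids with >= 1 bp intersection with the features
overlap_count_stat <- function(pieces, feat) {
  hit_ids <- character(0)
  for (ch in intersect(unique(pieces$chrom), names(feat))) {
    p <- pieces[pieces$chrom == ch, ]
    f <- feat[[ch]]
    idx <- findInterval(p$start, f$start)
    hit <- (idx >= 1 & p$start < f$end[pmax(idx, 1L)]) |
           (idx < length(f$start) & f$start[pmin(idx + 1L, length(f$start))] < p$end)
    hit_ids <- c(hit_ids, as.character(p$id[hit]))
  }
  length(unique(hit_ids))
}

# median distance from region boundaries to the nearest feature boundary on
# the same chromosome; boundaries on chromosomes without features are skipped
boundary_distance_stat <- function(boundaries, feat) {
  d <- numeric(0)
  for (ch in intersect(unique(boundaries$chrom), names(feat))) {
    b <- boundaries$pos[boundaries$chrom == ch]
    fb <- feat[[ch]]$boundaries
    i <- findInterval(b, fb)
    lo <- abs(b - fb[pmax(i, 1L)])
    hi <- abs(fb[pmin(i + 1L, length(fb))] - b)
    lo[i < 1] <- Inf; hi[i >= length(fb)] <- abs(b - fb[length(fb)])[i >= length(fb)]
    d <- c(d, pmin(lo, hi))
  }
  if (!length(d)) stopf("no region boundary shares a chromosome with a feature")
  median(d)
}

#' Circular-permutation enrichment / depletion test
#'
#' Compares an observed statistic — the number of regions intersecting a
#' feature set (`"overlap_count"`), or the median distance from region
#' boundaries to the nearest feature boundary (`"boundary_distance"`) —
#' against its distribution over `n_perm` circularly permuted datasets
#' ([circular_shift()] with independent uniform offsets per chromosome per
#' permutation). For counts, enrichment means permuted values `>=` the
#' observed; for distances, association means permuted medians `<=` the
#' observed. Default p-values follow the raw `n / n_perm` convention; set
#' `add_one = TRUE` for the observed-inclusive `(1 + n) / (1 + n_perm)` form.
#'
#' @param regions interval data.frame `chrom`, `start`, `end` (the divergent
#'   regions or clusters).
#' @param features interval data.frame `chrom`, `start`, `end` (annotation).
#' @param layout a [genome_layout()].
#' @param statistic `"overlap_count"` or `"boundary_distance"`.
#' @param n_perm permutation count (default 10000).
#' @param seed integer seed.
#' @param add_one use the observed-inclusive add-one p-value convention.
#' @return object of class `EnrichmentResult`: `statistic`, `observed`,
#'   `null_mean`, `null_quantiles`, `null` (full vector), `p_enrich`,
#'   `p_deplete`, `n_perm`, `seed`.
#' @export
permutation_test <- function(regions, features, layout,
                             statistic = c("overlap_count", "boundary_distance"),
                             n_perm = 10000, seed = 1L, add_one = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(layout, "GenomeLayout"))
  n_perm <- check_count(n_perm, "n_perm")
  seed <- check_seed(seed)
  if (statistic == "boundary_distance" && nrow(features) == 0)
    stopf("boundary_distance requires a non-empty feature set")
  if (nrow(regions) == 0 && statistic == "boundary_distance")
    stopf("boundary_distance undefined for an empty region set")
  regions$id <- seq_len(max(nrow(regions), 1L))[seq_len(nrow(regions))]
  feat <- prep_features(features)
  chroms <- unique(regions$chrom)
  L <- setNames(chrom_length(layout, chroms), chroms)

  stat_of <- function(shifted, bnd) {
    if (statistic == "overlap_count") overlap_count_stat(shifted, feat)
    else boundary_distance_stat(bnd, feat)
  }
  boundaries_of <- function(r, off) {
    # boundaries of the rotated original intervals (mod L), not of the
    # wrap-split pieces
    o <- off[r$chrom]; o[is.na(o)] <- 0
    ll <- L[r$chrom]
    data.frame(chrom = rep(r$chrom, 2),
               pos = c((r$start + o) %% ll, (r$end + o - 1) %% ll + 1))
  }

  zero_off <- setNames(rep(0, length(chroms)), chroms)
  observed <- stat_of(circular_shift(regions, layout, zero_off),
                      boundaries_of(regions, zero_off))

  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      off <- setNames(floor(runif(length(chroms)) * L), chroms)
      stat_of(circular_shift(regions, layout, off), boundaries_of(regions, off))
    }, numeric(1))
  })

  ge <- sum(null >= observed); le <- sum(null <= observed)
  pv <- function(k) if (add_one) (1 + k) / (1 + n_perm) else k / n_perm
  if (statistic == "overlap_count") {
    p_enrich <- pv(ge); p_deplete <- pv(le)
  } else {
    p_enrich <- pv(le); p_deplete <- pv(ge)
  }
  structure(list(statistic = statistic, observed = observed,
                 null_mean = mean(null),
                 null_quantiles = quantile(null, c(0.025, 0.5, 0.975)),
                 null = null, p_enrich = p_enrich, p_deplete = p_deplete,
                 n_perm = n_perm, seed = seed,
                 convention = if (add_one) "add_one" else "raw"),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult [%s]: observed %.4g vs null mean %.4g (%d perms)\n  p_enrich = %.4g, p_deplete = %.4g\n",
              x$statistic, x$observed, x$null_mean, x$n_perm,
              x$p_enrich, x$p_deplete))
  invisible(x)
}
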