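# Runs of adjacent same-polarity divergent bins and their permutation null.

# per-bin frame extraction from a DivergenceResult: coordinates in the chosen
# species' genome plus the polarity labels, sorted by coordinate
frame_bins <- function(result, frame = c("A", "B")) {
  stopifnot(inherits(result, "DivergenceResult"))
  frame <- match.arg(frame)
  r <- result$regions
  out <- data.frame(region_id = r$region_id,
                    chrom = r[[paste0("chrom_", frame)]],
                    start = r[[paste0("start_", frame)]],
                    end = r[[paste0("end_", frame)]],
                    polarity = r$polarity)
  out[order(out$chrom, out$start), ]
}

#' Find maximal same-polarity runs of divergent bins
#'
#' A run is a maximal stretch of called bins that share polarity and are
#' exactly adjacent in the chosen species' coordinates (each bin's start
#' equals the previous bin's end). Orthology coverage gaps, polarity changes
#' and non-divergent bins all break runs; no gap tolerance is applied.
#'
#' @param x a `DivergenceResult`, or a data.frame with columns `chrom`,
#'   `start`, `end`, `polarity` (0 = not divergent).
#' @param frame species frame, `"A"` or `"B"` (used when `x` is a
#'   `DivergenceResult`).
#' @return data.frame `chrom`, `start`, `end`, `length_bins`, `polarity`,
#'   `run_id`; the attribute `bins` maps every divergent bin (and its
#'   `region_id` if available) to its run.
#' @export
find_runs <- function(x, frame = "A") {
  bins <- if (inherits(x, "DivergenceResult")) frame_bins(x, frame)
          else x[order(x$chrom, x$start), , drop = FALSE]
  stopifnot(all(c("chrom", "start", "end", "polarity") %in% names(bins)))
  n <- nrow(bins)
  if (n == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length_bins = integer(), polarity = integer(),
                      run_id = integer()))
  new_block <- c(TRUE, bins$chrom[-1] != bins$chrom[-n] |
                       bins$start[-1] != bins$end[-n] |
                       bins$polarity[-1] != bins$polarity[-n])
  block <- cumsum(new_block)
  div <- bins$polarity != 0L
  first <- !duplicated(block)
  agg <- data.frame(
    chrom = bins$chrom[first],
    start = bins$start[first],
    end = as.numeric(tapply(bins$end, block, max)),
    length_bins = as.integer(tapply(div, block, length)),
    polarity = bins$polarity[first])
  agg <- agg[agg$polarity != 0L, , drop = FALSE]
  agg$run_id <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  bins$run_id <- NA_integer_
  bins$run_id[div] <- match(block[div], unique(block[div]))
  attr(agg, "bins") <- bins[div, , drop = FALSE]
  agg
}

#' Within-chromosome permutation null for run lengths
#'
#' Shuffles the per-bin divergence labels (polarity-bearing: the observed mix
#' of +1, -1 and 0 travels with the shuffle) uniformly among each
#' chromosome's orthologous bins, keeping bin coordinates fixed, and records
#' the longest same-polarity adjacent run in each permuted genome.
#' `p(n)` is the fraction of permuted genomes containing at least one run of
#' length `>= n`, and is monotone non-increasing in `n`.
#'
#' @param bins data.frame `chrom`, `start`, `end`, `polarity` for every
#'   orthologous bin (typically `frame_bins` of a result; pass a
#'   `DivergenceResult` directly to use frame A).
#' @param n_perm number of permuted genomes (default 10000).
#' @param seed integer seed.
#' @param frame species frame when `bins` is a `DivergenceResult`.
#' @return object of class `RunLengthNull`: data.frame `length`, `count`
#'   (permutations containing a run at least that long), `p`; attributes
#'   `max_lengths`, `n_perm`, `seed`.
#' @export
run_length_null <- function(bins, n_perm = 10000, seed = 1L, frame = "A") {
  if (inherits(bins, "DivergenceResult")) bins <- frame_bins(bins, frame)
  n_perm <- check_count(n_perm, "n_perm")
  seed <- check_seed(seed)
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]

  by_chrom <- split(seq_len(nrow(bins)), bins$chrom)
  prep <- lapply(by_chrom, function(idx) {
    n <- length(idx)
    adj_break <- c(TRUE, bins$start[idx][-1] != bins$end[idx][-n])
    list(pol = bins$polarity[idx], group = cumsum(adj_break), n = n)
  })

  max_run_of <- function(pol, group) {
    key <- group * 4 + (pol + 2L)
    r <- rle(key)
    lens <- r$lengths[(r$values %% 4) != 2]   # drop polarity-0 runs
    if (length(lens)) max(lens) else 0L
  }

  max_lengths <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      best <- 0L
      for (ch in prep) {
        pol <- ch$pol[sample.int(ch$n)]
        best <- max(best, max_run_of(pol, ch$group))
      }
      best
    }, numeric(1))
  })

  obs_max <- max(vapply(prep, function(ch) max_run_of(ch$pol, ch$group), numeric(1)))
  max_len <- max(obs_max, max_lengths, 1)
  len <- seq_len(max_len)
  count <- vapply(len, function(l) sum(max_lengths >= l), numeric(1))
  out <- data.frame(length = len, count = count, p = count / n_perm)
  attr(out, "max_lengths") <- max_lengths
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  class(out) <- c("RunLengthNull", "data.frame")
  out
}

#' Call significant divergence clusters from runs and a run-length null
#'
#' A run becomes a divergence cluster when its length is improbable under the
#' within-chromosome permutation null. With `alpha = NULL` (default) the
#' operational rule is the conservative "never seen in the permuted data":
#' significant means no permuted genome contained a run that long, with the
#' p-value reported as the bound `1 / n_perm`. With a numeric `alpha`, runs
#' are significant when `p < alpha` (never-seen runs qualify when
#' `1 / n_perm <= alpha`).
#'
#' @param runs a [find_runs()] result.
#' @param null a [run_length_null()] result.
#' @param alpha significance level, or `NULL` for the never-seen rule.
#' @return data.frame of clusters: runs plus `p_value`, `p_is_bound`
#'   (TRUE when the run length was never seen and the value is an upper
#'   bound), `significant`; rows for all runs are retained so the run/cluster
#'   relationship stays inspectable. The `bins` attribute is carried over.
#' @export
call_clusters <- function(runs, null, alpha = NULL) {
  stopifnot(inherits(null, "RunLengthNull"))
  n_perm <- attr(null, "n_perm")
  if (!is.null(alpha)) alpha <- check_fraction(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  cnt <- null$count[pmin(runs$length_bins, max(null$length))]
  cnt[runs$length_bins > max(null$length)] <- 0
  out <- runs
  out$p_value <- ifelse(cnt == 0, 1 / n_perm, cnt / n_perm)
  out$p_is_bound <- cnt == 0
  out$significant <- if (is.null(alpha)) cnt == 0 else
    (cnt == 0 & 1 / n_perm <= alpha) | (cnt / n_perm < alpha)
  attr(out, "bins") <- attr(runs, "bins")
  out
}

#' Reconcile clusters detected in the two species frames
#'
#' Clusters are called separately in each species' coordinates; this lists
#' the pairs of significant clusters that share member orthologous regions —
#' the headline "same cluster detected in both genomes" output.
#'
#' @param clusters_A,clusters_B [call_clusters()] results for frames A and B
#'   (with their `bins` attributes carrying `region_id`).
#' @return data.frame `run_id_A`, `run_id_B`, `shared_bins`.
#' @export
reconcile_clusters <- function(clusters_A, clusters_B) {
  ba <- attr(clusters_A, "bins"); bb <- attr(clusters_B, "bins")
  if (is.null(ba) || is.null(bb) || is.null(ba$region_id))
    stopf("cluster inputs must carry their `bins` attribute with region ids")
  sig_A <- clusters_A$run_id[clusters_A$significant]
  sig_B <- clusters_B$run_id[clusters_B$significant]
  ba <- ba[ba$run_id %in% sig_A, ]
  bb <- bb[bb$run_id %in% sig_B, ]
  m <- merge(ba[, c("region_id", "run_id")], bb[, c("region_id", "run_id")],
             by = "region_id", suffixes = c("_A", "_B"))
  if (!nrow(m))
    return(data.frame(run_id_A = integer(), run_id_B = integer(),
                      shared_bins = integer()))
  agg <- aggregate(region_id ~ run_id_A + run_id_B, data = m, FUN = length)
  names(agg)[3] <- "shared_bins"
  agg[order(agg$run_id_A, agg$run_id_B), ]
}
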