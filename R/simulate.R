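# Synthetic two-species chromatin landscape generators.
#
# The generators emulate the statistical structure the downstream analysis
# assumes: contiguous open/closed compartment domains, bimodal per-dataset
# signal distributions, strong positive inter-dataset rank correlations,
# probe-level sampling, an interval orthology map with controlled overlap
# fractions and rearrangements, GC content correlated with structure, and
# expression divergence linked to implanted divergent tracts.

#' Generate a synthetic genome layout
#'
#' Chromosome lengths are deterministic given the parameters: they decline
#' linearly from 1.4x to 0.6x the mean (mimicking a real karyotype's size
#' spread) and are rounded down to whole bins. A single chromosome gets
#' exactly `mean_len`. Centromere positions (and acrocentric status) are the
#' only random quantities.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param mean_len mean chromosome length in bp; must be >= 10 bins.
#' @param seed integer seed; the call is deterministic given a seed.
#' @param bin_size bin width in bp (default 100 Kb).
#' @param p_acrocentric probability a chromosome is acrocentric (centromere at
#'   the proximal end, as in the mouse karyotype).
#' @param species species tag attached to the layout.
#' @return a [genome_layout()].
#' @export
gen_layout <- function(n_chrom, mean_len, seed, bin_size = 1e5,
                       p_acrocentric = 0, species = "A") {
  n_chrom <- check_count(n_chrom, "n_chrom")
  bin_size <- check_count(bin_size, "bin_size")
  if (!is.numeric(mean_len) || mean_len < 10 * bin_size)
    stopf("`mean_len` must be >= 10 * bin_size")
  p_acrocentric <- check_fraction(p_acrocentric, "p_acrocentric")
  seed <- check_seed(seed)

  scale <- if (n_chrom == 1L) 1 else seq(1.4, 0.6, length.out = n_chrom)
  len <- pmax(10, (mean_len * scale) %/% bin_size) * bin_size

  withr::with_seed(seed, {
    acro <- runif(n_chrom) < p_acrocentric
    cen <- numeric(n_chrom)
    frac <- runif(n_chrom, 0.3, 0.7)
    cen <- ifelse(acro,
                  pmin(3 * bin_size, len / 2),
                  round(len * frac / bin_size) * bin_size)
    cen <- pmin(pmax(cen, bin_size), len - bin_size)
  })
  genome_layout(species, data.frame(
    name = paste0("chr", species, seq_len(n_chrom)),
    length = as.numeric(len), centromere = as.numeric(cen), acrocentric = acro))
}

#' Generate a latent open/closed compartment track
#'
#' States follow a first-order two-state Markov chain along each chromosome,
#' parametrised so that the stationary open fraction equals `p_open` and the
#' mean run (domain) length, averaged over all runs, equals
#' `mean_domain_bins`. Run lengths of the open state are geometric with mean
#' `2 * mean_domain_bins * p_open`, closed runs with mean
#' `2 * mean_domain_bins * (1 - p_open)`.
#'
#' @param layout a [genome_layout()].
#' @param mean_domain_bins target mean run length in bins; must satisfy
#'   `2 * mean_domain_bins * min(p_open, 1 - p_open) >= 1`.
#' @param p_open stationary open fraction in `[0, 1]`; the degenerate values 0
#'   and 1 give constant tracks.
#' @param seed integer seed.
#' @param bin_size bin width in bp.
#' @return an object of class `CompartmentTrack`: a list with the layout,
#'   `bin_size`, and `bins` (data.frame `chrom`, `start`, `end`, logical
#'   `open`).
#' @export
gen_compartments <- function(layout, mean_domain_bins, p_open, seed, bin_size = 1e5) {
  stopifnot(inherits(layout, "GenomeLayout"))
  if (!is.numeric(mean_domain_bins) || mean_domain_bins < 1)
    stopf("`mean_domain_bins` must be >= 1")
  p_open <- check_fraction(p_open, "p_open")
  seed <- check_seed(seed)
  bins <- layout_bins(layout, bin_size)

  if (p_open %in% c(0, 1)) {
    bins$open <- p_open == 1
  } else {
    q_open <- 1 / (2 * mean_domain_bins * p_open)
    q_closed <- 1 / (2 * mean_domain_bins * (1 - p_open))
    if (q_open > 1 || q_closed > 1)
      stopf("mean_domain_bins too small for p_open = %g: need 2*m*min(p, 1-p) >= 1", p_open)
    withr::with_seed(seed, {
      open <- logical(nrow(bins))
      for (ch in unique(bins$chrom)) {
        idx <- which(bins$chrom == ch)
        n <- length(idx)
        s <- logical(n)
        s[1] <- runif(1) < p_open
        if (n > 1) {
          u <- runif(n - 1)
          for (i in 2:n) {
            s[i] <- if (s[i - 1]) u[i - 1] >= q_open else u[i - 1] < q_closed
          }
        }
        open[idx] <- s
      }
      bins$open <- open
    })
  }
  structure(list(layout = layout, bin_size = bin_size, bins = bins),
            class = "CompartmentTrack")
}

#' @export
print.CompartmentTrack <- function(x, ...) {
  cat(sprintf("CompartmentTrack <%s>: %d bins of %g Kb, %.1f%% open\n",
              x$layout$species, nrow(x$bins), x$bin_size / 1e3,
              100 * mean(x$bins$open)))
  invisible(x)
}

# maximal constant-state runs of a track, as data.frame of bin-index ranges
track_runs <- function(track) {
  b <- track$bins
  out <- lapply(unique(b$chrom), function(ch) {
    idx <- which(b$chrom == ch)
    r <- rle(b$open[idx])
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    data.frame(chrom = ch, first = idx[s], last = idx[e], open = r$values)
  })
  do.call(rbind, out)
}

#' Implant divergent tracts into a second species' track
#'
#' Species A is the reference: within each chosen tract the species-B latent
#' state is flipped to the opposite of A, and nothing outside tracts is
#' touched. Tracts are placed inside maximal constant-state runs of the A
#' track so that each tract carries a single, well defined polarity:
#' +1 where A is open (B becomes closed), -1 where A is closed. Tracts are
#' pairwise disjoint and separated by at least one bin so implanted runs
#' cannot merge.
#'
#' @param track_A reference species track ([gen_compartments()]).
#' @param track_B species-B track on the same bin index (typically a copy of
#'   `track_A`, i.e. a conserved baseline).
#' @param n_tracts number of tracts to implant (0 allowed).
#' @param tract_len_bins integer vector of candidate tract lengths in bins;
#'   lengths are drawn uniformly from this set.
#' @param seed integer seed.
#' @param end_bias_frac fraction of tracts whose placement is restricted to
#'   within `end_bias_window_bins` of a chromosome end (used to emulate
#'   subtelomeric enrichment of divergence); default 0 = uniform placement.
#' @param end_bias_window_bins window, in bins, defining "near a chromosome
#'   end" for `end_bias_frac`.
#' @return list with `track_B` (modified) and `truth`, an object of class
#'   `TruthTable`: `tracts` (chrom, start, end, polarity) and `bins`
#'   (per-bin ground-truth polarity for implanted bins).
#' @export
implant_divergence <- function(track_A, track_B, n_tracts, tract_len_bins,
                               seed, end_bias_frac = 0, end_bias_window_bins = 0) {
  stopifnot(inherits(track_A, "CompartmentTrack"), inherits(track_B, "CompartmentTrack"))
  if (!identical(track_A$bins[, c("chrom", "start", "end")],
                 track_B$bins[, c("chrom", "start", "end")]))
    stopf("track_A and track_B must share the same bin index")
  n_tracts <- check_count(n_tracts, "n_tracts", min = 0L)
  if (!is.numeric(tract_len_bins) || any(tract_len_bins < 1))
    stopf("`tract_len_bins` must be positive integers")
  end_bias_frac <- check_fraction(end_bias_frac, "end_bias_frac")
  seed <- check_seed(seed)

  b <- track_A$bins
  empty_truth <- structure(
    list(tracts = data.frame(chrom = character(), start = numeric(),
                             end = numeric(), polarity = integer()),
         bins = data.frame(chrom = character(), start = numeric(),
                           end = numeric(), polarity = integer())),
    class = "TruthTable")
  if (n_tracts == 0L)
    return(list(track_B = track_B, truth = empty_truth))

  # per-chromosome bin counts, used for the end-bias restriction
  chrom_nbins <- table(b$chrom)
  bin_rank <- stats::ave(seq_len(nrow(b)), b$chrom, FUN = seq_along)
  near_end <- rep(TRUE, nrow(b))
  if (end_bias_window_bins > 0) {
    n_of <- as.numeric(chrom_nbins[b$chrom])
    near_end <- bin_rank <= end_bias_window_bins | bin_rank > n_of - end_bias_window_bins
  }

  runs <- track_runs(track_A)
  run_of_bin <- integer(nrow(b))
  for (i in seq_len(nrow(runs))) run_of_bin[runs$first[i]:runs$last[i]] <- i
  tracts <- vector("list", n_tracts)
  withr::with_seed(seed, {
    available <- rep(TRUE, nrow(b))
    placed <- 0L
    tries <- 0L
    max_tries <- 200L * n_tracts
    while (placed < n_tracts && tries < max_tries) {
      tries <- tries + 1L
      len <- tract_len_bins[sample.int(length(tract_len_bins), 1L)]
      biased <- end_bias_frac > 0 && runif(1) < end_bias_frac
      # all start bins whose whole tract fits inside one constant-state run
      cand <- runs[runs$last - runs$first + 1L >= len, , drop = FALSE]
      if (nrow(cand) == 0L) next
      starts <- unlist(mapply(seq, cand$first, cand$last - len + 1L,
                              SIMPLIFY = FALSE))
      if (biased)
        starts <- starts[near_end[starts] & near_end[starts + len - 1L]]
      if (!length(starts)) next
      # availability over the tract plus a one-bin spacer on each side,
      # via a prefix sum of blocked bins
      cs <- c(0, cumsum(!available))
      lo <- pmax(starts - 1L, 1L)
      hi <- pmin(starts + len, nrow(b))
      starts <- starts[cs[hi + 1L] - cs[lo] == 0]
      if (!length(starts)) next
      s <- starts[sample.int(length(starts), 1L)]
      available[max(1L, s - 1L):min(nrow(b), s + len)] <- FALSE
      placed <- placed + 1L
      tracts[[placed]] <- data.frame(
        chrom = b$chrom[s], start = b$start[s], end = b$end[s + len - 1L],
        polarity = if (runs$open[run_of_bin[s]]) 1L else -1L,
        first = s, last = s + len - 1L)
    }
  })
  if (placed < n_tracts)
    stopf("could not place %d non-overlapping tracts (placed %d); genome too small or domains too short",
          n_tracts, placed)

  tr <- do.call(rbind, tracts[seq_len(placed)])
  flip <- unlist(mapply(seq, tr$first, tr$last, SIMPLIFY = FALSE))
  track_B$bins$open[flip] <- !track_A$bins$open[flip]
  flip <- sort(flip)
  truth_bins <- data.frame(chrom = b$chrom[flip], start = b$start[flip],
                           end = b$end[flip],
                           polarity = ifelse(track_A$bins$open[flip], 1L, -1L))
  ord <- order(match(tr$chrom, track_A$layout$chromosomes$name), tr$start)
  truth <- structure(list(tracts = tr[ord, c("chrom", "start", "end", "polarity")],
                          bins = truth_bins),
                     class = "TruthTable")
  rownames(truth$tracts) <- NULL
  list(track_B = track_B, truth = truth)
}

#' Generate per-dataset binned structure values from a latent track
#'
#' Each dataset's value in a bin is the state mean (`mu_open` or `mu_closed`)
#' plus a dataset-specific offset (Normal, sd `sigma_dataset`, constant across
#' bins) plus independent bin-level noise (Normal, sd `sigma_noise`). With
#' noise small relative to `mu_open - mu_closed` the per-dataset marginals are
#' bimodal and all pairwise inter-dataset rank correlations are strongly
#' positive, as observed for real replication-timing / lamina / Hi-C tracks.
#'
#' @param track a [gen_compartments()] track.
#' @param datasets data.frame with columns `id`, `assay`, `cell_type` (and
#'   optionally `species`), one row per dataset.
#' @param mu_open,mu_closed state means; `mu_open > mu_closed` (larger = more
#'   open throughout the package).
#' @param sigma_dataset sd of the dataset-specific offsets (>= 0).
#' @param sigma_noise sd of the per-bin noise (>= 0).
#' @param seed integer seed.
#' @return list of class `StructureTrack` with `bins` (coordinates), `values`
#'   (bins x datasets numeric matrix) and `datasets`.
#' @export
gen_structure <- function(track, datasets, mu_open = 1, mu_closed = -1,
                          sigma_dataset = 0.15, sigma_noise = 0.5, seed = 1L) {
  stopifnot(inherits(track, "CompartmentTrack"))
  if (!is.data.frame(datasets) || nrow(datasets) == 0L)
    stopf("`datasets` must be a non-empty data.frame")
  if (!all(c("id", "assay", "cell_type") %in% names(datasets)))
    stopf("`datasets` needs columns id, assay, cell_type")
  if (anyDuplicated(datasets$id)) stopf("dataset ids must be unique")
  if (!(mu_open > mu_closed)) stopf("`mu_open` must exceed `mu_closed`")
  if (sigma_dataset < 0 || sigma_noise < 0) stopf("sigmas must be >= 0")
  seed <- check_seed(seed)

  n <- nrow(track$bins); k <- nrow(datasets)
  state_mu <- ifelse(track$bins$open, mu_open, mu_closed)
  withr::with_seed(seed, {
    offset <- rnorm(k, 0, sigma_dataset)
    noise <- matrix(rnorm(n * k, 0, sigma_noise), n, k)
  })
  values <- state_mu + matrix(offset, n, k, byrow = TRUE) + noise
  colnames(values) <- datasets$id
  structure(list(bins = track$bins[, c("chrom", "start", "end")],
                 values = values, datasets = datasets,
                 bin_size = track$bin_size),
            class = "StructureTrack")
}

#' Scatter probe-level records from binned values
#'
#' The inverse of binning: for each (bin, dataset) cell a number of probes is
#' drawn (Poisson with mean `probes_per_bin`, or exactly `probes_per_bin` if
#' `poisson = FALSE`), probe midpoints are uniform within the bin, and probe
#' values are the bin value plus Normal noise (sd `probe_sigma`), so the
#' per-bin probe mean recovers the bin value as `probe_sigma -> 0`.
#'
#' @param structure a [gen_structure()] result.
#' @param probes_per_bin mean (or exact) probe count per bin.
#' @param probe_sigma sd of probe-level noise.
#' @param seed integer seed.
#' @param poisson draw probe counts from a Poisson distribution? If `FALSE`
#'   every cell gets exactly `probes_per_bin` probes.
#' @return data.frame of probe records: `chrom`, `pos` (midpoint bp),
#'   `dataset`, `value`.
#' @export
gen_probes <- function(structure, probes_per_bin = 25, probe_sigma = 0.2,
                       seed = 1L, poisson = TRUE) {
  stopifnot(inherits(structure, "StructureTrack"))
  if (probes_per_bin < 0) stopf("`probes_per_bin` must be >= 0")
  if (probe_sigma < 0) stopf("`probe_sigma` must be >= 0")
  seed <- check_seed(seed)

  n <- nrow(structure$bins); k <- ncol(structure$values)
  withr::with_seed(seed, {
    counts <- if (poisson) rpois(n * k, probes_per_bin)
              else rep(as.integer(probes_per_bin), n * k)
    tot <- sum(counts)
    bin_i <- rep(rep(seq_len(n), k), counts)
    ds_i <- rep(rep(seq_len(k), each = n), counts)
    pos <- floor(structure$bins$start[bin_i] +
                 runif(tot) * structure$bin_size)
    val <- structure$values[cbind(bin_i, ds_i)] + rnorm(tot, 0, probe_sigma)
  })
  data.frame(chrom = structure$bins$chrom[bin_i], pos = pos,
             dataset = structure$datasets$id[ds_i], value = val)
}

#' Generate an interval orthology map between two species
#'
#' Emulates the output of reciprocal whole-genome alignment lift-over: paired
#' 100 Kb intervals annotated with both overlap fractions. The species-B
#' genome is a block-rearranged copy of species A (same chromosome sizes,
#' `n_rearrangements` segment permutations), a fraction of bins is unmappable,
#' a fraction of retained pairs is emitted as sub-threshold decoys, and a
#' further fraction of A bins gains a second, lower-overlap (non-reciprocal)
#' candidate partner. Each emitted pair carries a ground-truth `keep` flag:
#' both fractions `>= min_overlap` and the pair is its own reciprocal best.
#'
#' @param layout_A species-A layout.
#' @param n_rearrangements number of genome-order segment breakpoints.
#' @param min_overlap keep threshold on both overlap fractions (inclusive).
#' @param frac_unmappable fraction of A bins with no emitted partner.
#' @param decoy_frac fraction of mapped pairs whose A-side overlap fraction is
#'   drawn below `min_overlap` (lift-over failures).
#' @param nonreciprocal_frac fraction of mapped A bins that also gain a
#'   secondary, lower-overlap partner pair.
#' @param seed integer seed.
#' @param bin_size bin width in bp.
#' @param species_b species tag for the derived B layout.
#' @param p_acrocentric_b probability a B chromosome is acrocentric.
#' @return list with `layout_B`, `pairs` (data.frame `chrom_A`, `start_A`,
#'   `end_A`, `chrom_B`, `start_B`, `end_B`, `overlap_A`, `overlap_B`,
#'   `keep`), and `bin_map` (A bin -> B bin index for mapped primary pairs).
#' @export
gen_orthology <- function(layout_A, n_rearrangements = 5, min_overlap = 0.5,
                          frac_unmappable = 0.05, decoy_frac = 0.05,
                          nonreciprocal_frac = 0.02, seed = 1L, bin_size = 1e5,
                          species_b = "B", p_acrocentric_b = 1) {
  stopifnot(inherits(layout_A, "GenomeLayout"))
  n_rearrangements <- check_count(n_rearrangements, "n_rearrangements", min = 0L)
  min_overlap <- check_fraction(min_overlap, "min_overlap", open_lo = TRUE)
  frac_unmappable <- check_fraction(frac_unmappable, "frac_unmappable", open_hi = TRUE)
  seed <- check_seed(seed)

  bins_A <- layout_bins(layout_A, bin_size)
  n <- nrow(bins_A)

  withr::with_seed(seed, {
    # segment-permute genome bin order to build the B genome
    n_cuts <- min(n_rearrangements, n - 1L)
    cuts <- if (n_cuts > 0) sort(sample(seq_len(n - 1L), n_cuts)) else integer()
    seg_id <- findInterval(seq_len(n) - 1L, cuts) + 1L
    seg_order <- sample(max(seg_id))
    perm <- unlist(lapply(seg_order, function(s) which(seg_id == s)))

    layout_B <- genome_layout(species_b, data.frame(
      name = sub(paste0("^chr", layout_A$species),
                 paste0("chr", species_b), layout_A$chromosomes$name),
      length = layout_A$chromosomes$length,
      centromere = ifelse(runif(nrow(layout_A$chromosomes)) < p_acrocentric_b,
                          pmin(3 * bin_size, layout_A$chromosomes$length / 2),
                          layout_A$chromosomes$centromere),
      acrocentric = runif(nrow(layout_A$chromosomes)) < p_acrocentric_b))
    bins_B <- layout_bins(layout_B, bin_size)
    stopifnot(nrow(bins_B) == n)

    # B bin j holds A bin perm[j]
    a_of_b <- perm
    b_of_a <- order(perm)

    mapped <- runif(n) >= frac_unmappable
    idx_A <- which(mapped)
    pairs <- data.frame(
      chrom_A = bins_A$chrom[idx_A], start_A = bins_A$start[idx_A],
      end_A = bins_A$end[idx_A],
      chrom_B = bins_B$chrom[b_of_a[idx_A]],
      start_B = bins_B$start[b_of_a[idx_A]],
      end_B = bins_B$end[b_of_a[idx_A]],
      overlap_A = runif(length(idx_A), min_overlap, 1),
      overlap_B = runif(length(idx_A), min_overlap, 1))

    is_decoy <- runif(nrow(pairs)) < decoy_frac
    pairs$overlap_A[is_decoy] <- runif(sum(is_decoy), 0.15, min_overlap - 0.01)

    # secondary, non-reciprocal candidates: always weaker than the primary
    n2 <- round(nonreciprocal_frac * nrow(pairs))
    if (n2 > 0) {
      pick <- sample(which(!is_decoy), min(n2, sum(!is_decoy)))
      alt_b <- sample(n, length(pick))
      sec <- pairs[pick, ]
      sec$chrom_B <- bins_B$chrom[alt_b]
      sec$start_B <- bins_B$start[alt_b]
      sec$end_B <- bins_B$end[alt_b]
      sec$overlap_A <- pairs$overlap_A[pick] * runif(length(pick), 0.5, 0.9)
      sec$overlap_B <- pairs$overlap_B[pick] * runif(length(pick), 0.5, 0.9)
      pairs <- rbind(pairs, sec)
    }
  })

  pairs$keep <- orthology_keep_flags(pairs, min_overlap)
  bin_map <- data.frame(a_index = which(mapped), b_index = b_of_a[mapped])
  list(layout_B = layout_B, pairs = pairs, bin_map = bin_map)
}

#' Generate GC content and gene annotations tied to a compartment track
#'
#' GC fractions are state-dependent (open bins GC-richer) with Normal noise
#' calibrated numerically so that the realised Spearman correlation between GC
#' and mean structure approaches `rho_target`. Gene counts per bin are Poisson
#' with a state-dependent rate; gene starts are uniform within bins.
#'
#' @param track a [gen_compartments()] track.
#' @param rho_target target Spearman correlation between GC and structure, in
#'   (0, 1).
#' @param gene_density_open,gene_density_closed mean genes per bin by state.
#' @param seed integer seed.
#' @param gc_open,gc_closed state mean GC fractions.
#' @param gene_class class label attached to the emitted genes.
#' @param truth optional [implant_divergence()] `TruthTable`; with
#'   `tract_rate_multiplier != 1` the gene rate is multiplied inside implanted
#'   tracts (used to emulate, e.g., elevated lincRNA density in divergent
#'   regions).
#' @param tract_rate_multiplier rate multiplier inside truth tracts.
#' @return list with `gc` (data.frame `chrom`, `start`, `end`, `gc`) and
#'   `genes` (data.frame `chrom`, `start`, `end`, `class`).
#' @export
gen_gc_and_genes <- function(track, rho_target = 0.6, gene_density_open = 2.3,
                             gene_density_closed = 1.8, seed = 1L,
                             gc_open = 0.41, gc_closed = 0.355,
                             gene_class = "protein_coding", truth = NULL,
                             tract_rate_multiplier = 1) {
  stopifnot(inherits(track, "CompartmentTrack"))
  rho_target <- check_fraction(rho_target, "rho_target", open_lo = TRUE, open_hi = TRUE)
  if (gene_density_open < 0 || gene_density_closed < 0) stopf("gene densities must be >= 0")
  seed <- check_seed(seed)

  b <- track$bins
  n <- nrow(b)
  s <- as.numeric(b$open)
  delta <- gc_open - gc_closed

  # calibrate the GC noise sd against a structure proxy (state + mild noise,
  # matching the default mean-structure noise scale relative to the state gap)
  p_hat <- mean(s)
  sd_gc <- withr::with_seed(1902L, {
    m <- 4000L
    s0 <- as.numeric(runif(m) < p_hat)
    z1 <- rnorm(m); z2 <- rnorm(m)
    f <- function(sig) {
      cor(delta * s0 + sig * z1, s0 + 0.1 * z2, method = "spearman") - rho_target
    }
    lo <- delta * 1e-3; hi <- delta * 20
    if (f(lo) < 0) lo else uniroot(f, c(lo, hi))$root
  })

  in_tract <- rep(FALSE, n)
  if (!is.null(truth) && nrow(truth$bins) > 0) {
    key <- paste(b$chrom, b$start)
    in_tract <- key %in% paste(truth$bins$chrom, truth$bins$start)
  }
  rate <- ifelse(b$open, gene_density_open, gene_density_closed)
  rate <- rate * ifelse(in_tract, tract_rate_multiplier, 1)

  withr::with_seed(seed, {
    gc <- gc_closed + delta * s + rnorm(n, 0, sd_gc)
    gc <- pmin(pmax(gc, 0.02), 0.98)
    counts <- rpois(n, rate)
    bin_i <- rep(seq_len(n), counts)
    gstart <- floor(b$start[bin_i] + runif(length(bin_i)) * (track$bin_size - 1000))
  })
  genes <- data.frame(chrom = b$chrom[bin_i], start = gstart,
                      end = gstart + 1000, class = gene_class)
  list(gc = data.frame(chrom = b$chrom, start = b$start, end = b$end, gc = gc),
       genes = genes)
}

#' Generate an orthologous expression table linked to implanted divergence
#'
#' Each gene's log2 expression fold change (species A over species B) is drawn
#' Normal around `baseline_shift + polarity * effect_log2`, where polarity is
#' the ground-truth divergence of the gene's bin (0 outside tracts). RPKM
#' values are positive by construction.
#'
#' @param truth a `TruthTable` from [implant_divergence()].
#' @param genes gene annotation data.frame (`chrom`, `start`, ...).
#' @param effect_log2 shift of the mean log2 fold change inside +1 tracts
#'   (mirrored in -1 tracts).
#' @param sd_log2 sd of the per-gene log2 fold change.
#' @param baseline_shift global mean log2 fold change (default 0; any overall
#'   offset observed in real data is a dataset property, not a model constant).
#' @param seed integer seed.
#' @param base_mean_log2,base_sd_log2 distribution of species-B log2 RPKM.
#' @return data.frame `gene_id`, `chrom`, `start`, `rpkm_A`, `rpkm_B`,
#'   `truth_polarity`.
#' @export
gen_expression <- function(truth, genes, effect_log2 = 1, sd_log2 = 1.5,
                           baseline_shift = 0, seed = 1L,
                           base_mean_log2 = 3, base_sd_log2 = 1.5) {
  if (sd_log2 < 0) stopf("`sd_log2` must be >= 0")
  seed <- check_seed(seed)
  pol <- truth_polarity_at(truth, genes$chrom, genes$start)
  n <- nrow(genes)
  withr::with_seed(seed, {
    lfc <- baseline_shift + pol * effect_log2 + rnorm(n, 0, sd_log2)
    rpkm_B <- 2^rnorm(n, base_mean_log2, base_sd_log2)
  })
  data.frame(gene_id = sprintf("g%05d", seq_len(n)), chrom = genes$chrom,
             start = genes$start, rpkm_A = rpkm_B * 2^lfc, rpkm_B = rpkm_B,
             truth_polarity = pol)
}

#' Flag genes as divergently or conservedly regulated, linked to ground truth
#'
#' Assigns each gene a binary regulatory-divergence flag whose odds are
#' `odds_ratio` times higher inside implanted divergent tracts than outside,
#' for testing the Fisher-exact association between chromatin divergence and
#' regulatory divergence at a known effect size.
#'
#' @param genes gene annotation data.frame (`chrom`, `start`).
#' @param truth a `TruthTable`.
#' @param odds_ratio target odds ratio (>= 0).
#' @param base_rate divergent-regulation probability outside tracts.
#' @param seed integer seed.
#' @return character vector (`"divergent"` / `"conserved"`), one per gene.
#' @export
gen_regulatory_flags <- function(genes, truth, odds_ratio = 2, base_rate = 0.2,
                                 seed = 1L) {
  base_rate <- check_fraction(base_rate, "base_rate", open_lo = TRUE, open_hi = TRUE)
  seed <- check_seed(seed)
  pol <- truth_polarity_at(truth, genes$chrom, genes$start)
  odds <- base_rate / (1 - base_rate) * ifelse(pol != 0, odds_ratio, 1)
  p <- odds / (1 + odds)
  withr::with_seed(seed, flag <- runif(nrow(genes)) < p)
  ifelse(flag, "divergent", "conserved")
}

# Generator-side ground-truth keep flags for emitted orthology pairs:
# a pair is kept iff both overlap fractions clear the threshold (inclusive)
# and the pair is the best-overlap partner of both of its sides. Written as a
# plain per-side scan; the analysis-side reciprocal-best search in
# map_orthologs() is implemented independently.
orthology_keep_flags <- function(pairs, min_overlap) {
  key_A <- paste(pairs$chrom_A, pairs$start_A)
  key_B <- paste(pairs$chrom_B, pairs$start_B)
  rank_key <- function(frac, len, chrom, start) {
    # lexicographic (larger frac, larger bp, chrom, lower start) as one score
    order(order(-frac, -(frac * len), chrom, start))
  }
  best_of <- function(key, ord_rank) {
    best <- tapply(ord_rank, key, min)
    ord_rank == as.numeric(best[key])
  }
  rA <- rank_key(pairs$overlap_A, pairs$end_A - pairs$start_A,
                 pairs$chrom_B, pairs$start_B)
  rB <- rank_key(pairs$overlap_B, pairs$end_B - pairs$start_B,
                 pairs$chrom_A, pairs$start_A)
  best_of(key_A, rA) & best_of(key_B, rB) &
    pairs$overlap_A >= min_overlap & pairs$overlap_B >= min_overlap
}

# ground-truth polarity of the truth bin containing each (chrom, pos)
truth_polarity_at <- function(truth, chrom, pos) {
  stopifnot(inherits(truth, "TruthTable"))
  pol <- integer(length(chrom))
  tb <- truth$bins
  if (nrow(tb) == 0) return(pol)
  for (ch in unique(tb$chrom)) {
    ti <- which(tb$chrom == ch)
    qi <- which(chrom == ch)
    if (!length(qi)) next
    o <- order(tb$start[ti]); ti <- ti[o]
    j <- findInterval(pos[qi], tb$start[ti])
    hit <- j > 0 & pos[qi] < tb$end[ti][pmax(j, 1L)]
    pol[qi[hit]] <- tb$polarity[ti][j[hit]]
  }
  pol
}
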