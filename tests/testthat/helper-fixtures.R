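# Shared in-code fixtures for the test suite.

# single-chromosome layout with n whole bins
toy_layout <- function(n_bins = 10, bin_size = 1e5, species = "A",
                       acrocentric = FALSE, centromere = NA) {
  genome_layout(species, data.frame(
    name = paste0("chr", species, "1"), length = n_bins * bin_size,
    centromere = centromere, acrocentric = acrocentric))
}

# a CompartmentTrack with explicitly given states
toy_track <- function(open, layout = NULL, bin_size = 1e5) {
  if (is.null(layout)) layout <- toy_layout(length(open), bin_size)
  bins <- layout_bins(layout, bin_size)
  stopifnot(nrow(bins) == length(open))
  bins$open <- open
  structure(list(layout = layout, bin_size = bin_size, bins = bins),
            class = "CompartmentTrack")
}

# a small normalised StructureMatrix built directly from a value matrix;
# regions are laid out on one chromosome per species, consecutively
toy_matrix <- function(values, n_A = ncol(values) / 2, stage = "normalised",
                       bin_size = 1e5) {
  n <- nrow(values)
  k <- ncol(values)
  ids <- colnames(values)
  if (is.null(ids)) ids <- sprintf("ds%02d", seq_len(k))
  colnames(values) <- ids
  regions <- data.frame(
    region_id = sprintf("chrA1:%d", (seq_len(n) - 1)) ,
    chrom_A = "chrA1", start_A = (seq_len(n) - 1) * bin_size,
    end_A = seq_len(n) * bin_size,
    chrom_B = "chrB1", start_B = (seq_len(n) - 1) * bin_size,
    end_B = seq_len(n) * bin_size)
  regions$region_id <- paste0("chrA1:", regions$start_A)
  datasets <- data.frame(id = ids,
                         species = rep(c("A", "B"), c(n_A, k - n_A)),
                         assay = "RT", cell_type = "ESC")
  sm <- structure_matrix(regions, values, datasets, stage = "raw")
  sm$stage <- stage
  sm
}

# two-species matrix drawn from the generative model, with implanted
# divergent bins (polarity +1 in the first n_div bins); returns matrix plus
# truth polarity vector
sim_matrix <- function(n = 300, k_per_species = 4, n_div = 30,
                       mu = 1, sigma_noise = 0.5, sigma_dataset = 0.1,
                       seed = 1) {
  withr::with_seed(seed, {
    state_A <- sample(c(-mu, mu), n, replace = TRUE)
    state_B <- state_A
    pol <- integer(n)
    if (n_div > 0) {
      idx <- seq_len(n_div)
      state_B[idx] <- -state_A[idx]
      pol[idx] <- ifelse(state_A[idx] > 0, 1L, -1L)
    }
    offs <- rnorm(2 * k_per_species, 0, sigma_dataset)
    vals <- cbind(
      vapply(seq_len(k_per_species), function(j)
        state_A + offs[j] + rnorm(n, 0, sigma_noise), numeric(n)),
      vapply(seq_len(k_per_species), function(j)
        state_B + offs[k_per_species + j] + rnorm(n, 0, sigma_noise),
        numeric(n)))
  })
  colnames(vals) <- sprintf("ds%02d", seq_len(2 * k_per_species))
  list(matrix = toy_matrix(vals, n_A = k_per_species), truth_polarity = pol)
}

# study conditions of the parameter-recovery acceptance criterion:
# ~5000 orthologous bins, 6 datasets per species, implant effect 4x bin
# noise, ~10% divergent in 4-8-bin tracts, complete orthologous coverage
recovery_config <- function(seed, end_bias_frac = 0.5,
                            n_perm_div = 10000L, n_perm_cluster = 2000L,
                            n_perm_enrich = 2000L) {
  pipeline_config(
    seed = seed,
    simulate = list(end_bias_frac = end_bias_frac, frac_unmappable = 0,
                    decoy_frac = 0, nonreciprocal_frac = 0),
    divergence = list(n_perm = n_perm_div),
    cluster = list(n_perm = n_perm_cluster),
    enrichment = list(n_perm = n_perm_enrich, windows = 5e6))
}

# naive interval-set utilities used as oracles
naive_overlap_count <- function(regions, features) {
  hit <- logical(length(unique(regions$id)))
  names(hit) <- as.character(unique(regions$id))
  for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(features))) {
    if (regions$chrom[i] == features$chrom[j] &&
        regions$start[i] < features$end[j] &&
        features$start[j] < regions$end[i])
      hit[as.character(regions$id[i])] <- TRUE
  }
  sum(hit)
}

naive_union_length <- function(df) {
  tot <- 0
  for (ch in unique(df$chrom)) {
    x <- df[df$chrom == ch, ]
    covered <- rep(FALSE, max(x$end))
    for (i in seq_len(nrow(x)))
      covered[(x$start[i] + 1):x$end[i]] <- TRUE
    tot <- tot + sum(covered)
  }
  tot
}
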