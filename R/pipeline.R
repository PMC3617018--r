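# End-to-end orchestration: simulate -> bin -> collate -> map -> normalise ->
# call -> cluster -> enrich -> associate, from a single config with
# deterministic per-stage seeding.

#' Default pipeline configuration
#'
#' Analysis constants default to the canonical comparative-chromatin setup:
#' 100 Kb bins, a 10-probe retention floor, 50% collation and reciprocal
#' orthology overlap thresholds, FDR target 2e-4, and subtelomere windows of
#' 1/5/10 Mb. Permutation counts default to 100000 (divergence; superseded by
#' exhaustive enumeration whenever the label space is small enough) and 10000
#' (cluster and enrichment nulls). Simulation defaults describe the reference
#' synthetic genome: 8 chromosomes averaging 62.5 Mb (about 5000 orthologous
#' bins), 6 datasets per species, compartment domains of mean 8 bins, state
#' means +/-1 with bin noise sd 0.5 (so an implanted state flip is a 4-sigma
#' effect), and roughly 10% of bins inside implanted divergent tracts of 4-8
#' bins.
#'
#' @param ... named overrides of any default (nested lists are replaced
#'   wholesale).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    bin_size = 1e5,
    min_probes = 10L,
    collate_overlap = 0.5,
    orthology_threshold = 0.5,
    simulate = list(
      n_chrom = 8L, mean_len = 6.25e7, p_open = 0.5, mean_domain_bins = 8,
      n_datasets = 6L, mu_open = 1, mu_closed = -1,
      sigma_dataset = 0.15, sigma_noise = 0.5,
      n_tracts = 84L, tract_len_bins = 4:8,
      end_bias_frac = 0, end_bias_window_bins = 50L,
      probes_per_bin = 25, probe_sigma = 0.2,
      n_rearrangements = 5L, frac_unmappable = 0.05, decoy_frac = 0.05,
      nonreciprocal_frac = 0.02,
      rho_gc = 0.6, gene_density_open = 2.3, gene_density_closed = 1.8,
      lincRNA_density = 0.03, lincRNA_tract_multiplier = 2,
      expr_effect_log2 = 1, expr_sd_log2 = 1.5, expr_baseline = 0,
      regulatory_odds_ratio = 2, regulatory_base_rate = 0.2),
    divergence = list(fdr_target = 2e-4, n_perm = 1e5, s0_method = "median",
                      cut_method = "delta"),
    cluster = list(n_perm = 10000L, alpha = NULL),
    enrichment = list(n_perm = 10000L, windows = c(1e6, 5e6, 1e7)))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  class(cfg) <- c("PipelineConfig", "list")
  cfg
}

sim_datasets <- function(species, n) {
  assays <- rep(c("RT", "LA", "HiC"), length.out = n)
  data.frame(id = sprintf("%s_%s_%d", species, assays, seq_len(n)),
             species = species, assay = assays,
             cell_type = rep(c("ESC", "iPSC", "fibroblast"), length.out = n))
}

#' Simulate a full two-species study
#'
#' Generates the species-A genome and compartment landscape, a conserved
#' species-B copy with implanted divergent tracts, per-dataset structure
#' values and probe-level records for both species, the orthology map, GC
#' and gene annotations, an orthologous expression table, and per-gene
#' regulatory-divergence flags.
#'
#' @param config a [pipeline_config()].
#' @return list of simulation artefacts including the ground-truth
#'   `TruthTable`.
#' @export
simulate_study <- function(config = pipeline_config()) {
  s <- config$simulate
  seed <- config$seed
  layout_A <- gen_layout(s$n_chrom, s$mean_len, seed = stage_seed(seed, "layout"),
                         bin_size = config$bin_size, species = "A")
  track_A <- gen_compartments(layout_A, s$mean_domain_bins, s$p_open,
                              seed = stage_seed(seed, "compartments"),
                              bin_size = config$bin_size)
  imp <- implant_divergence(track_A, track_A, s$n_tracts, s$tract_len_bins,
                            seed = stage_seed(seed, "implant"),
                            end_bias_frac = s$end_bias_frac,
                            end_bias_window_bins = s$end_bias_window_bins)
  orth <- gen_orthology(layout_A, s$n_rearrangements,
                        min_overlap = config$orthology_threshold,
                        frac_unmappable = s$frac_unmappable,
                        decoy_frac = s$decoy_frac,
                        nonreciprocal_frac = s$nonreciprocal_frac,
                        seed = stage_seed(seed, "orthology"),
                        bin_size = config$bin_size)

  # species-B latent track on the rearranged B genome
  bins_B <- layout_bins(orth$layout_B, config$bin_size)
  state_B <- rep(NA, nrow(bins_B))
  state_B[orth$bin_map$b_index] <- imp$track_B$bins$open[orth$bin_map$a_index]
  state_B[is.na(state_B)] <- withr::with_seed(
    stage_seed(seed, "b_fill"),
    runif(sum(is.na(state_B))) < s$p_open)
  bins_B$open <- as.logical(state_B)
  track_B <- structure(list(layout = orth$layout_B, bin_size = config$bin_size,
                            bins = bins_B), class = "CompartmentTrack")

  ds_A <- sim_datasets("A", s$n_datasets)
  ds_B <- sim_datasets("B", s$n_datasets)
  str_A <- gen_structure(track_A, ds_A, s$mu_open, s$mu_closed,
                         s$sigma_dataset, s$sigma_noise,
                         seed = stage_seed(seed, "structure_A"))
  str_B <- gen_structure(track_B, ds_B, s$mu_open, s$mu_closed,
                         s$sigma_dataset, s$sigma_noise,
                         seed = stage_seed(seed, "structure_B"))
  probes_A <- gen_probes(str_A, s$probes_per_bin, s$probe_sigma,
                         seed = stage_seed(seed, "probes_A"))
  probes_B <- gen_probes(str_B, s$probes_per_bin, s$probe_sigma,
                         seed = stage_seed(seed, "probes_B"))

  gcg <- gen_gc_and_genes(track_A, s$rho_gc, s$gene_density_open,
                          s$gene_density_closed,
                          seed = stage_seed(seed, "gc_genes"))
  linc <- gen_gc_and_genes(track_A, s$rho_gc, s$lincRNA_density,
                           s$lincRNA_density,
                           seed = stage_seed(seed, "lincRNA"),
                           gene_class = "lincRNA", truth = imp$truth,
                           tract_rate_multiplier = s$lincRNA_tract_multiplier)
  genes <- rbind(gcg$genes, linc$genes)
  expr <- gen_expression(imp$truth, gcg$genes, s$expr_effect_log2,
                         s$expr_sd_log2, s$expr_baseline,
                         seed = stage_seed(seed, "expression"))
  reg_flags <- gen_regulatory_flags(gcg$genes, imp$truth,
                                    s$regulatory_odds_ratio,
                                    s$regulatory_base_rate,
                                    seed = stage_seed(seed, "regulatory"))

  list(layout_A = layout_A, layout_B = orth$layout_B,
       track_A = track_A, track_B = track_B, truth = imp$truth,
       orthology = orth, datasets = rbind(ds_A, ds_B),
       structure_A = str_A, structure_B = str_B,
       probes_A = probes_A, probes_B = probes_B,
       gc = gcg$gc, genes = genes, expression = expr,
       regulatory_flags = reg_flags)
}

#' Run the full divergence pipeline
#'
#' Executes every stage from a single config: simulation (or supplied
#' simulated study), probe binning, within-species collation, cross-species
#' orthology mapping, joint quantile normalisation, divergence calling,
#' run/cluster detection in both frames, subtelomeric and centromeric
#' circular-permutation enrichment, and the association statistics. When the
#' ground truth is available a recovery report (sensitivity, realised false
#' discovery proportion, cluster boundary accuracy) is attached.
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-generated [simulate_study()] output.
#' @param outdir optional directory; when given, the main artefacts are
#'   written as TSV/BED/bedGraph/JSON with a provenance manifest.
#' @return a result bundle (named list).
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         outdir = NULL) {
  if (is.null(study)) study <- simulate_study(config)

  bt_A <- bin_probes(study$probes_A, study$layout_A, config$bin_size,
                     config$min_probes)
  bt_B <- bin_probes(study$probes_B, study$layout_B, config$bin_size,
                     config$min_probes)
  tab_A <- collate_species(list(bt_A), config$collate_overlap, species = "A")
  tab_B <- collate_species(list(bt_B), config$collate_overlap, species = "B")
  mapped <- map_orthologs(tab_A, tab_B, study$orthology$pairs,
                          config$orthology_threshold,
                          datasets = study$datasets)
  norm <- quantile_normalise(mapped$matrix)

  div <- call_divergence(norm,
                         fdr_target = config$divergence$fdr_target,
                         n_perm = config$divergence$n_perm,
                         seed = stage_seed(config$seed, "divergence"),
                         s0_method = config$divergence$s0_method,
                         cut_method = config$divergence$cut_method)
  labels <- classify_regions(div)

  runs_A <- find_runs(div, frame = "A")
  runs_B <- find_runs(div, frame = "B")
  null_A <- run_length_null(div, n_perm = config$cluster$n_perm,
                            seed = stage_seed(config$seed, "cluster_null_A"),
                            frame = "A")
  null_B <- run_length_null(div, n_perm = config$cluster$n_perm,
                            seed = stage_seed(config$seed, "cluster_null_B"),
                            frame = "B")
  clus_A <- call_clusters(runs_A, null_A, config$cluster$alpha)
  clus_B <- call_clusters(runs_B, null_B, config$cluster$alpha)
  reconciled <- reconcile_clusters(clus_A, clus_B)

  div_bins_A <- frame_bins(div, "A")
  div_bins_A <- div_bins_A[div_bins_A$polarity != 0L, ]
  enrich <- list()
  for (w in config$enrichment$windows) {
    wlab <- sprintf("%gMb", w / 1e6)
    enrich[[paste0("subtelomere_", wlab)]] <- permutation_test(
      div_bins_A, subtelomere_intervals(study$layout_A, w), study$layout_A,
      "overlap_count", config$enrichment$n_perm,
      seed = stage_seed(config$seed, paste0("enrich_subtel_", wlab)))
    enrich[[paste0("centromere_", wlab)]] <- permutation_test(
      div_bins_A, centromere_intervals(study$layout_A, w), study$layout_A,
      "overlap_count", config$enrichment$n_perm,
      seed = stage_seed(config$seed, paste0("enrich_centro_", wlab)))
  }

  regions_A <- data.frame(chrom = div$regions$chrom_A,
                          start = div$regions$start_A,
                          end = div$regions$end_A)
  gc_vec <- study$gc$gc[match(paste(regions_A$chrom, regions_A$start),
                              paste(study$gc$chrom, study$gc$start))]
  assoc <- list(
    correlations = correlation_matrix(norm),
    chrom_distribution = chrom_distribution_test(
      div$regions$chrom_A[div$regions$polarity != 0L],
      table(div$regions$chrom_A)),
    gc = gc_by_class(gc_vec, labels, div$regions$mean_A),
    density = density_compare(study$genes, labels, regions_A),
    expression_relative = expression_divergence(study$expression, labels,
                                                regions_A, "relative"),
    expression_absolute = expression_divergence(study$expression, labels,
                                                regions_A, "absolute"),
    overlap_qc = overlap_qc(div$regions, labels))

  ridx <- assign_to_regions(study$expression$chrom, study$expression$start,
                            regions_A)
  gene_in_div <- !is.na(ridx) & labels$class[pmax(ridx, 1L)] != "nondivergent"
  keep <- !is.na(ridx)
  assoc$regulatory_fisher <- class_enrichment_fisher(
    study$regulatory_flags[keep], gene_in_div[keep])

  recovery <- if (nrow(study$truth$bins)) {
    evaluate_recovery(div, clus_A, study$truth, null = null_A)
  } else NULL

  bundle <- list(config = config, study = study, matrix_raw = mapped$matrix,
                 lineage_specific_A = mapped$lineage_specific_A,
                 lineage_specific_B = mapped$lineage_specific_B,
                 matrix = norm, divergence = div, labels = labels,
                 runs_A = runs_A, runs_B = runs_B,
                 null_A = null_A, null_B = null_B,
                 clusters_A = clus_A, clusters_B = clus_B,
                 reconciled_clusters = reconciled,
                 enrichment = enrich, associations = assoc,
                 recovery = recovery)
  if (!is.null(outdir)) write_bundle(bundle, outdir)
  bundle
}

#' Compare divergence calls and clusters against the implanted ground truth
#'
#' @param div a [call_divergence()] result.
#' @param clusters_A a frame-A [call_clusters()] result.
#' @param truth the `TruthTable` of the simulation.
#' @param null optional frame-A [run_length_null()]; when supplied, cluster
#'   recovery is reported over the detectable tracts — those long enough that
#'   a run of that length is itself significant under the null (short tracts
#'   cannot, by construction of the cluster test, yield significant clusters).
#' @return list: per-bin `sensitivity` (fraction of truth bins in the region
#'   universe called with the right polarity), `fdp` (fraction of calls
#'   outside truth bins), call counts, and per-tract cluster recovery
#'   (significant cluster with both boundaries within one bin).
#' @export
evaluate_recovery <- function(div, clusters_A, truth, null = NULL) {
  r <- div$regions
  key <- paste(r$chrom_A, r$start_A)
  tkey <- paste(truth$bins$chrom, truth$bins$start)
  truth_pol <- truth$bins$polarity[match(key, tkey)]
  truth_pol[is.na(truth_pol)] <- 0L
  called <- r$polarity != 0L
  tp <- sum(called & r$polarity == truth_pol & truth_pol != 0L)
  fp <- sum(called & truth_pol == 0L)
  n_truth <- sum(truth_pol != 0L)

  bin_size <- r$end_A[1] - r$start_A[1]
  sig <- clusters_A[clusters_A$significant, , drop = FALSE]
  tr <- truth$tracts
  # restrict to tracts present (by >= 1 bin) in the orthologous universe
  tr$in_universe <- vapply(seq_len(nrow(tr)), function(i) {
    any(r$chrom_A == tr$chrom[i] & r$start_A >= tr$start[i] &
          r$start_A < tr$end[i])
  }, logical(1))
  tr$recovered <- vapply(seq_len(nrow(tr)), function(i) {
    any(sig$chrom == tr$chrom[i] &
          abs(sig$start - tr$start[i]) <= bin_size &
          abs(sig$end - tr$end[i]) <= bin_size &
          sig$polarity == tr$polarity[i])
  }, logical(1))
  tr$length_bins <- as.integer((tr$end - tr$start) / bin_size)
  tr$detectable <- tr$in_universe
  if (!is.null(null)) {
    never_seen <- null$length[null$count == 0]
    min_sig <- if (length(never_seen)) min(never_seen) else Inf
    tr$detectable <- tr$in_universe & tr$length_bins >= min_sig
  }
  list(sensitivity = if (n_truth) tp / n_truth else NA_real_,
       fdp = if (sum(called)) fp / sum(called) else 0,
       n_called = sum(called), n_truth_bins = n_truth,
       true_positives = tp, false_positives = fp,
       tracts = tr,
       cluster_recovery = if (any(tr$detectable))
         mean(tr$recovered[tr$detectable]) else NA_real_)
}
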