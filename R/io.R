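# Readers and writers for the package's standard formats. Genomic interval
# formats (BED, bedGraph) go through rtracklayer; tabular artefacts are plain
# TSV with explicit headers; all coordinates 0-based half-open on disk in
# BED-family files.

df_to_granges <- function(df, score = NULL, name = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
  if (!is.null(score)) gr$score <- score
  if (!is.null(name)) gr$name <- name
  gr
}

#' Write an interval set as BED
#'
#' @param df data.frame `chrom`, `start`, `end` (0-based half-open).
#' @param path output file.
#' @param name,score optional name / score vectors.
#' @export
write_bed <- function(df, path, name = NULL, score = NULL) {
  rtracklayer::export(df_to_granges(df, score = score, name = name), path,
                      format = "BED")
  invisible(path)
}

#' Read a BED file as a 0-based half-open data.frame
#'
#' @param path BED file.
#' @return data.frame `chrom`, `start`, `end` plus `name`/`score` if present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' Write one dataset's probe records as bedGraph
#'
#' Probes are written as 1 bp intervals at their midpoints.
#'
#' @param probes data.frame `chrom`, `pos`, `value` (one dataset).
#' @param path output file.
#' @export
write_probes_bedgraph <- function(probes, path) {
  df <- data.frame(chrom = probes$chrom, start = probes$pos,
                   end = probes$pos + 1)
  rtracklayer::export(df_to_granges(df, score = probes$value), path,
                      format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph track
#'
#' @param path bedGraph file.
#' @return data.frame `chrom`, `start`, `end`, `value` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), value = gr$score)
}

#' Write / read a StructureMatrix as TSV
#'
#' Region ids, both coordinate frames and one value column per dataset.
#'
#' @param x a `StructureMatrix`.
#' @param path TSV file.
#' @export
write_structure_matrix <- function(x, path) {
  stopifnot(inherits(x, "StructureMatrix"))
  df <- cbind(x$regions[, c("region_id", "chrom_A", "start_A", "end_A",
                            "chrom_B", "start_B", "end_B")],
              as.data.frame(x$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- x$datasets
  meta$stage <- x$stage
  write.table(meta, paste0(path, ".datasets"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure_matrix
#' @export
read_structure_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  meta <- read.table(paste0(path, ".datasets"), sep = "\t", header = TRUE)
  coords <- c("region_id", "chrom_A", "start_A", "end_A",
              "chrom_B", "start_B", "end_B")
  values <- as.matrix(df[, meta$id, drop = FALSE])
  rownames(values) <- df$region_id
  structure_matrix(df[, coords], values,
                   meta[, c("id", "species", "assay", "cell_type")],
                   stage = unique(meta$stage))
}

#' Write a genome layout as TSV
#'
#' @param layout a [genome_layout()].
#' @param path TSV file.
#' @export
write_layout <- function(layout, path) {
  df <- layout$chromosomes
  df$species <- layout$species
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  genome_layout(unique(df$species),
                df[, c("name", "length", "centromere", "acrocentric")])
}

#' Write the main pipeline artefacts with a provenance manifest
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  write_structure_matrix(bundle$matrix, p("structure_matrix.tsv"))
  div <- bundle$divergence$regions
  write.table(div[, c("region_id", "chrom_A", "start_A", "end_A", "chrom_B",
                      "start_B", "end_B", "d", "polarity", "mean_A", "mean_B")],
              p("divergence.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- div[div$polarity != 0L, ]
  if (nrow(calls))
    write_bed(data.frame(chrom = calls$chrom_A, start = calls$start_A,
                         end = calls$end_A),
              p("divergent_regions_A.bed"),
              name = as.character(calls$polarity))
  for (fr in c("A", "B")) {
    cl <- bundle[[paste0("clusters_", fr)]]
    sig <- cl[cl$significant, , drop = FALSE]
    if (nrow(sig))
      write_bed(sig[, c("chrom", "start", "end")],
                p(sprintf("clusters_%s.bed", fr)),
                name = as.character(sig$polarity),
                score = pmin(1000, round(-10 * log10(sig$p_value))))
    write.table(as.data.frame(bundle[[paste0("null_", fr)]]),
                p(sprintf("run_length_null_%s.tsv", fr)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  enr <- lapply(bundle$enrichment, function(e)
    e[c("statistic", "observed", "null_mean", "p_enrich", "p_deplete",
        "n_perm", "seed")])
  jsonlite::write_json(enr, p("enrichment.json"), auto_unbox = TRUE,
                       digits = NA)

  d <- bundle$divergence
  manifest <- list(
    package = "chromdiverge",
    version = as.character(packageVersion("chromdiverge")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(bundle$config),
    divergence = list(s0 = d$s0, cut_low = d$cut_low, cut_up = d$cut_up,
                      fdr_target = d$fdr_target, fdr_achieved = d$fdr_achieved,
                      n_perm_used = d$n_perm_used, exhaustive = d$exhaustive,
                      n_calls = d$n_calls, seed = d$seed))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(outdir)
}
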