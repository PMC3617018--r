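# Cross-species pairing of binned regions by reciprocal best overlap.

#' Construct a StructureMatrix
#'
#' The central container of the analysis: rows are orthologous region pairs,
#' columns are datasets labelled with species / assay / cell type, cells are
#' structure values (complete-case by construction).
#'
#' @param regions data.frame with `region_id`, `chrom_A`, `start_A`, `end_A`,
#'   `chrom_B`, `start_B`, `end_B` (plus optional `overlap_A`, `overlap_B`).
#' @param values numeric matrix, rows matching `regions`, named columns.
#' @param datasets data.frame `id`, `species`, `assay`, `cell_type`, one row
#'   per value column.
#' @param stage `"raw"` or `"normalised"`.
#' @return an object of class `StructureMatrix`.
#' @export
structure_matrix <- function(regions, values, datasets, stage = "raw") {
  stopifnot(is.data.frame(regions), is.matrix(values), is.data.frame(datasets))
  if (nrow(regions) != nrow(values))
    stopf("regions and values disagree on row count")
  if (ncol(values) != nrow(datasets) || !identical(colnames(values), datasets$id))
    stopf("value columns must match datasets$id in order")
  if (anyDuplicated(datasets$id)) stopf("dataset ids must be unique")
  if (anyNA(values)) stopf("StructureMatrix must be complete-case")
  stage <- match.arg(stage, c("raw", "normalised"))
  rownames(values) <- regions$region_id
  structure(list(regions = regions, values = values, datasets = datasets,
                 stage = stage),
            class = "StructureMatrix")
}

#' @export
print.StructureMatrix <- function(x, ...) {
  cat(sprintf("StructureMatrix [%s]: %d orthologous regions x %d datasets (%s)\n",
              x$stage, nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", unique(x$datasets$species),
                            table(x$datasets$species)[unique(x$datasets$species)]),
                    collapse = ", ")))
  invisible(x)
}

# analysis-side reciprocal-best search over candidate pairs.
# score per side: overlap fraction; ties broken by larger overlap bp, then
# lexicographic partner chromosome, then lower partner start.
reciprocal_best <- function(pairs) {
  key_A <- paste(pairs$chrom_A, pairs$start_A)
  key_B <- paste(pairs$chrom_B, pairs$start_B)
  pick_best <- function(key, frac, bp, p_chrom, p_start) {
    ord <- order(key, -frac, -bp, p_chrom, p_start)
    first <- !duplicated(key[ord])
    best <- logical(length(key))
    best[ord[first]] <- TRUE
    best
  }
  best_A <- pick_best(key_A, pairs$overlap_A,
                      pairs$overlap_A * (pairs$end_A - pairs$start_A),
                      pairs$chrom_B, pairs$start_B)
  best_B <- pick_best(key_B, pairs$overlap_B,
                      pairs$overlap_B * (pairs$end_B - pairs$start_B),
                      pairs$chrom_A, pairs$start_A)
  best_A & best_B
}

#' Pair collated species tables into an orthologous StructureMatrix
#'
#' Candidate pairs (with their two overlap fractions, as produced by the
#' upstream alignment lift-over or by [gen_orthology()]) are retained when
#' each side's best-overlap partner is the other and both overlap fractions
#' are at least `threshold` (inclusive). Retained pairs are then joined with
#' the per-species region tables; only regions represented in every dataset
#' of both species enter the matrix. All unpaired regions are returned as
#' putatively lineage specific.
#'
#' @param table_A,table_B collated per-species tables ([collate_species()]).
#' @param pairs candidate pair data.frame: `chrom_A`, `start_A`, `end_A`,
#'   `chrom_B`, `start_B`, `end_B`, `overlap_A`, `overlap_B`.
#' @param threshold reciprocal overlap threshold in (0, 1] (default 0.5).
#' @param datasets optional data.frame `id`, `species`, `assay`, `cell_type`
#'   describing the value columns of both tables; reconstructed minimally if
#'   omitted.
#' @return list: `matrix` (a raw `StructureMatrix`), `lineage_specific_A` and
#'   `lineage_specific_B` (region data.frames), and `retained_pairs`.
#' @export
map_orthologs <- function(table_A, table_B, pairs, threshold = 0.5,
                          datasets = NULL) {
  threshold <- check_fraction(threshold, "threshold", open_lo = TRUE)
  need <- c("chrom_A", "start_A", "end_A", "chrom_B", "start_B", "end_B",
            "overlap_A", "overlap_B")
  if (!all(need %in% names(pairs)))
    stopf("`pairs` needs columns: %s", paste(need, collapse = ", "))
  pkey <- paste(pairs$chrom_A, pairs$start_A, pairs$chrom_B, pairs$start_B)
  if (anyDuplicated(pkey)) stopf("duplicate interval pairs in orthology map")

  ok <- pairs$overlap_A >= threshold & pairs$overlap_B >= threshold &
    reciprocal_best(pairs)
  kept <- pairs[ok, , drop = FALSE]

  ds_A <- attr(table_A, "datasets"); ds_B <- attr(table_B, "datasets")
  sp_A <- attr(table_A, "species") %||% "A"
  sp_B <- attr(table_B, "species") %||% "B"
  if (length(intersect(ds_A, ds_B)))
    stopf("dataset ids shared between species: %s",
          paste(intersect(ds_A, ds_B), collapse = ", "))

  ia <- match(paste(kept$chrom_A, kept$start_A),
              paste(table_A$chrom, table_A$start))
  ib <- match(paste(kept$chrom_B, kept$start_B),
              paste(table_B$chrom, table_B$start))
  present <- !is.na(ia) & !is.na(ib)
  kept <- kept[present, , drop = FALSE]
  ia <- ia[present]; ib <- ib[present]

  region_id <- if (nrow(kept)) {
    paste0(kept$chrom_A, ":",
           format(kept$start_A, scientific = FALSE, trim = TRUE))
  } else character(0)
  regions <- data.frame(region_id = region_id, kept[, need], row.names = NULL)
  values <- cbind(as.matrix(table_A[ia, ds_A, drop = FALSE]),
                  as.matrix(table_B[ib, ds_B, drop = FALSE]))
  rownames(values) <- regions$region_id

  if (is.null(datasets)) {
    datasets <- data.frame(id = c(ds_A, ds_B),
                           species = c(rep(sp_A, length(ds_A)), rep(sp_B, length(ds_B))),
                           assay = NA_character_, cell_type = NA_character_)
  } else {
    datasets <- datasets[match(c(ds_A, ds_B), datasets$id), ]
  }

  ord <- order(regions$chrom_A, regions$start_A)
  sm <- structure_matrix(regions[ord, ], values[ord, , drop = FALSE], datasets,
                         stage = "raw")
  lin_A <- table_A[-ia, c("chrom", "start", "end"), drop = FALSE]
  lin_B <- table_B[-ib, c("chrom", "start", "end"), drop = FALSE]
  if (!length(ia)) lin_A <- table_A[, c("chrom", "start", "end")]
  if (!length(ib)) lin_B <- table_B[, c("chrom", "start", "end")]
  rownames(lin_A) <- rownames(lin_B) <- NULL
  list(matrix = sm, lineage_specific_A = lin_A, lineage_specific_B = lin_B,
       retained_pairs = kept)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
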