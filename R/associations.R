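# Downstream statistics relating divergence calls to inter-dataset
# correlation structure, chromosome distribution, GC content, gene density,
# expression divergence, regulatory-class enrichment and alignment-overlap QC.

#' Inter-dataset rank correlation matrix with clustering order
#'
#' Pairwise Spearman correlations between all dataset columns, plus an
#' average-linkage hierarchical clustering order on `1 - rho` distance for
#' heatmap reproduction. Constant columns yield undefined correlations and
#' are flagged.
#'
#' @param x a `StructureMatrix` with >= 3 regions.
#' @param method correlation method (default `"spearman"`).
#' @return list `rho` (symmetric matrix, unit diagonal), `order` (dataset ids
#'   in dendrogram order), `hclust`, `flagged` (constant column ids),
#'   `p` (matrix of per-pair correlation-test p-values).
#' @export
correlation_matrix <- function(x, method = "spearman") {
  stopifnot(inherits(x, "StructureMatrix"))
  v <- x$values
  if (nrow(v) < 3) stopf("need >= 3 regions")
  flagged <- colnames(v)[apply(v, 2, function(col) sd(col) == 0)]
  rho <- cor(v, method = method)
  diag(rho) <- 1
  p <- matrix(NA_real_, ncol(v), ncol(v), dimnames = dimnames(rho))
  for (i in seq_len(ncol(v))) for (j in seq_len(ncol(v))) {
    if (i < j && !colnames(v)[i] %in% flagged && !colnames(v)[j] %in% flagged) {
      p[i, j] <- p[j, i] <-
        suppressWarnings(stats::cor.test(v[, i], v[, j], method = method))$p.value
    }
  }
  usable <- !colnames(v) %in% flagged
  hc <- if (sum(usable) >= 2)
    hclust(as.dist(1 - rho[usable, usable, drop = FALSE]), method = "average")
  else NULL
  ord <- if (is.null(hc)) colnames(v) else colnames(v)[usable][hc$order]
  list(rho = rho, order = ord, hclust = hc, flagged = flagged, p = p)
}

#' Chi-squared test of divergent-call distribution across chromosomes
#'
#' Expected counts follow the proportion of orthologous bins per chromosome;
#' chromosomes of interest are those with standardized residuals
#' `(obs - exp) / sqrt(exp)` beyond +/-1.96.
#'
#' @param calls character/factor vector of chromosomes of the called regions.
#' @param bins_per_chrom named vector: orthologous bin count per chromosome.
#' @return list `statistic`, `df`, `p_value`, `table` (per-chromosome
#'   observed, expected, residual, flagged).
#' @export
chrom_distribution_test <- function(calls, bins_per_chrom) {
  zero <- bins_per_chrom == 0
  if (any(zero)) {
    warnf("chromosome(s) with zero orthologous bins excluded: %s",
          paste(names(bins_per_chrom)[zero], collapse = ", "))
    bins_per_chrom <- bins_per_chrom[!zero]
  }
  if (length(bins_per_chrom) < 2) stopf("need >= 2 chromosomes")
  obs <- table(factor(calls, levels = names(bins_per_chrom)))
  total <- sum(obs)
  expd <- total * bins_per_chrom / sum(bins_per_chrom)
  resid <- (as.numeric(obs) - expd) / sqrt(expd)
  stat <- sum(resid^2)
  df <- length(bins_per_chrom) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(chrom = names(bins_per_chrom),
                          observed = as.numeric(obs), expected = as.numeric(expd),
                          residual = as.numeric(resid),
                          flagged = abs(resid) > 1.96, row.names = NULL))
}

#' GC content versus divergence class
#'
#' Rank-sum contrasts of GC between each divergent class and the
#' nondivergent background, per-class least-squares regressions of GC on
#' mean structure, and the binned-category contrast: the structure axis is
#' cut into equal-width categories and the divergent-vs-nondivergent GC
#' difference (with a rank-sum p) reported per category.
#'
#' @param gc numeric GC fraction per region (aligned with `labels`).
#' @param labels a [classify_regions()] data.frame.
#' @param structure numeric mean structure per region (same order).
#' @param n_categories number of equal-width structure categories.
#' @return list `tests` (class, n, median GC, p vs nondivergent),
#'   `regressions` (class, slope, intercept, n, skipped flag),
#'   `categories` (category bounds, per-class mean GC difference and p).
#' @export
gc_by_class <- function(gc, labels, structure, n_categories = 10L) {
  stopifnot(length(gc) == nrow(labels), length(structure) == nrow(labels))
  cls <- labels$class
  bg <- gc[cls == "nondivergent"]
  test_one <- function(cl) {
    g <- gc[cls == cl]
    if (!length(g) || !length(bg)) stopf("class `%s` or background empty", cl)
    data.frame(class = cl, n = length(g), median_gc = median(g),
               p_vs_nondivergent = if (cl == "nondivergent") NA_real_ else
                 wilcox.test(g, bg)$p.value)
  }
  tests <- do.call(rbind, lapply(unique(cls), test_one))

  reg_one <- function(cl) {
    i <- cls == cl
    if (sum(i) < 2)
      return(data.frame(class = cl, slope = NA_real_, intercept = NA_real_,
                        n = sum(i), skipped = TRUE))
    fit <- lm(gc[i] ~ structure[i])
    data.frame(class = cl, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), n = sum(i), skipped = FALSE)
  }
  regressions <- do.call(rbind, lapply(unique(cls), reg_one))

  br <- seq(min(structure), max(structure), length.out = n_categories + 1)
  cat_i <- cut(structure, br, include.lowest = TRUE)
  cats <- do.call(rbind, lapply(levels(cat_i), function(lv) {
    i <- cat_i == lv
    gdiv <- gc[i & cls != "nondivergent"]; gnon <- gc[i & cls == "nondivergent"]
    data.frame(category = lv,
               n_divergent = length(gdiv), n_nondivergent = length(gnon),
               gc_difference = if (length(gdiv) && length(gnon))
                 mean(gdiv) - mean(gnon) else NA_real_,
               p = if (length(gdiv) >= 2 && length(gnon) >= 2)
                 wilcox.test(gdiv, gnon)$p.value else NA_real_)
  }))
  list(tests = tests, regressions = regressions, categories = cats)
}

# assign point annotations (by start coordinate) to fixed regions; returns
# region row index or NA. Regions must be non-overlapping.
assign_to_regions <- function(chrom, pos, regions) {
  idx <- rep(NA_integer_, length(chrom))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    qi <- which(chrom == ch)
    if (!length(qi)) next
    o <- order(regions$start[ri]); ri <- ri[o]
    j <- findInterval(pos[qi], regions$start[ri])
    hit <- j > 0 & pos[qi] < regions$end[ri][pmax(j, 1L)]
    idx[qi[hit]] <- ri[j[hit]]
  }
  idx
}

#' Gene density by divergence class
#'
#' Counts annotation starts per region (gene-to-region assignment by start
#' coordinate; strand-agnostic), aggregates densities per class in both
#' per-100 Kb and per-Mb units, and reports two-sided rank-sum tests of each
#' divergent class, and all divergent regions pooled, against nondivergent.
#'
#' @param annotations data.frame `chrom`, `start`, `class` (annotation class,
#'   e.g. `protein_coding`, `lincRNA`).
#' @param labels a [classify_regions()] data.frame.
#' @param regions region coordinate data.frame (`chrom`, `start`, `end`)
#'   aligned with `labels` (frame-A coordinates of the matrix regions).
#' @return data.frame: annotation class, region class, n regions, mean
#'   density per 100 Kb and per Mb, rank-sum p vs nondivergent (NA where
#'   degenerate, flagged).
#' @export
density_compare <- function(annotations, labels, regions) {
  stopifnot(nrow(labels) == nrow(regions))
  out <- list()
  for (acl in unique(annotations$class)) {
    a <- annotations[annotations$class == acl, ]
    ridx <- assign_to_regions(a$chrom, a$start, regions)
    counts <- tabulate(ridx[!is.na(ridx)], nbins = nrow(regions))
    width_mb <- (regions$end - regions$start) / 1e6
    bg <- counts[labels$class == "nondivergent"]
    groups <- list(nondivergent = "nondivergent",
                   divergent_open_A = "divergent_open_A",
                   divergent_closed_A = "divergent_closed_A",
                   divergent_all = c("divergent_open_A", "divergent_closed_A"))
    for (g in names(groups)) {
      i <- labels$class %in% groups[[g]]
      cnt <- counts[i]
      degenerate <- g == "nondivergent" || !length(cnt) || !length(bg) ||
        (all(cnt == 0) && all(bg == 0))
      out[[length(out) + 1L]] <- data.frame(
        annotation_class = acl, region_class = g, n_regions = sum(i),
        density_per_100kb = if (length(cnt)) mean(cnt) else NA_real_,
        density_per_mb = if (length(cnt)) sum(cnt) / sum(width_mb[i]) else NA_real_,
        p_vs_nondivergent = if (degenerate) NA_real_ else
          wilcox.test(cnt, bg)$p.value,
        degenerate = degenerate)
    }
  }
  do.call(rbind, out)
}

#' Expression divergence by divergence class
#'
#' Computes `log2((RPKM_A + c) / (RPKM_B + c))` per orthologous gene pair
#' (pseudocount `c` recorded in the output), assigns genes to regions by
#' start coordinate, and contrasts each divergent class against the
#' nondivergent background with two-sided rank-sum tests. In `"absolute"`
#' mode the divergent classes are restricted to their
#' absolute-value-restricted subclasses (see [classify_regions()]).
#'
#' @param expr data.frame `gene_id`, `chrom`, `start`, `rpkm_A`, `rpkm_B`.
#' @param labels a [classify_regions()] data.frame.
#' @param regions region coordinates aligned with `labels`.
#' @param mode `"relative"` or `"absolute"`.
#' @param pseudocount RPKM pseudocount (default 0.01).
#' @return list `table` (class, n genes, median log2FC, p vs nondivergent,
#'   testable), `log2fc` (per-gene values with region class), `pseudocount`.
#' @export
expression_divergence <- function(expr, labels, regions,
                                  mode = c("relative", "absolute"),
                                  pseudocount = 0.01) {
  mode <- match.arg(mode)
  stopifnot(nrow(labels) == nrow(regions))
  lfc <- log2((expr$rpkm_A + pseudocount) / (expr$rpkm_B + pseudocount))
  ridx <- assign_to_regions(expr$chrom, expr$start, regions)
  keep <- !is.na(ridx)
  lfc <- lfc[keep]; ridx <- ridx[keep]
  cls <- labels$class[ridx]
  if (mode == "absolute") {
    ok_abs <- labels$absolute[ridx]
    cls[cls != "nondivergent" & !ok_abs] <- "divergent_excluded"
  }
  per_gene <- data.frame(gene_id = expr$gene_id[keep], log2fc = lfc, class = cls)
  bg <- lfc[cls == "nondivergent"]
  rows <- lapply(c("nondivergent", "divergent_open_A", "divergent_closed_A"),
                 function(cl) {
    v <- lfc[cls == cl]
    testable <- cl == "nondivergent" || (length(v) >= 2 && length(bg) >= 2)
    data.frame(class = cl, n_genes = length(v),
               median_log2fc = if (length(v)) median(v) else NA_real_,
               p_vs_nondivergent = if (cl != "nondivergent" && testable)
                 wilcox.test(v, bg)$p.value else NA_real_,
               testable = testable)
  })
  list(table = do.call(rbind, rows), log2fc = per_gene,
       pseudocount = pseudocount, mode = mode)
}

#' Fisher's exact test of regulatory-class enrichment in divergent chromatin
#'
#' Builds the 2x2 table of gene regulatory class (divergently vs conservedly
#' regulated) against residence in divergent vs nondivergent chromatin, and
#' reports the cross-product odds ratio with a two-sided exact p-value. With
#' a zero margin the raw OR is undefined; the Haldane-corrected OR (+0.5 to
#' every cell) is reported alongside in all cases.
#'
#' @param regulation character vector per gene: `"divergent"`/`"conserved"`.
#' @param in_divergent_region logical vector per gene.
#' @return list `table`, `odds_ratio`, `odds_ratio_haldane`, `p_value`.
#' @export
class_enrichment_fisher <- function(regulation, in_divergent_region) {
  stopifnot(length(regulation) == length(in_divergent_region))
  tab <- table(factor(regulation, levels = c("divergent", "conserved")),
               factor(in_divergent_region, levels = c(TRUE, FALSE)))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * cc)
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  list(table = tab, odds_ratio = as.numeric(or),
       odds_ratio_haldane = as.numeric(or_h),
       p_value = fisher.test(tab)$p.value)
}

#' Alignment-overlap QC by divergence class
#'
#' Summarises the orthology-map overlap fractions per divergence class with
#' rank-sum tests of divergent against nondivergent regions — the control
#' that called structural divergence is not an artefact of poor alignment.
#'
#' @param pairs retained orthology pairs with `overlap_A`, `overlap_B`,
#'   aligned with `labels` (row order of the matrix regions).
#' @param labels a [classify_regions()] data.frame.
#' @return data.frame per (side, class): n, mean, median overlap, p vs
#'   nondivergent.
#' @export
overlap_qc <- function(pairs, labels) {
  stopifnot(nrow(pairs) == nrow(labels))
  div <- labels$class != "nondivergent"
  out <- list()
  for (side in c("overlap_A", "overlap_B")) {
    v <- pairs[[side]]
    for (g in list(c("nondivergent", FALSE), c("divergent", TRUE))) {
      i <- div == as.logical(g[2])
      out[[length(out) + 1L]] <- data.frame(
        side = side, class = g[1], n = sum(i),
        mean_overlap = mean(v[i]), median_overlap = median(v[i]),
        p_vs_nondivergent = if (as.logical(g[2]) && sum(i) >= 2 && sum(!i) >= 2)
          wilcox.test(v[i], v[!i])$p.value else NA_real_)
    }
  }
  do.call(rbind, out)
}
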