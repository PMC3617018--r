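# Correlation structure, chromosome distribution, GC, density, expression,
# Fisher enrichment, alignment QC.

test_that("correlation matrix is symmetric with a clustering order", {
  sim <- sim_matrix(n = 500, k_per_species = 3, n_div = 0,
                    sigma_noise = 0.4, seed = 6)
  cm <- correlation_matrix(sim$matrix)
  expect_equal(diag(cm$rho), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cm$rho, t(cm$rho))
  # the generator's latent-state model forces positive pairwise rho
  expect_true(all(cm$rho[upper.tri(cm$rho)] > 0.3))
  expect_length(cm$order, 6)
  expect_true(all(cm$p[upper.tri(cm$p)] < 1e-10))

  # reversed ranks give exactly -1
  v <- cbind(a1 = c(1, 2, 3, 4), b1 = c(4, 3, 2, 1))
  cm2 <- correlation_matrix(toy_matrix(v, n_A = 1))
  expect_equal(cm2$rho[1, 2], -1)

  # constant columns are flagged, not propagated as errors
  v3 <- cbind(a1 = c(1, 2, 3), a2 = c(2, 2, 2), b1 = c(3, 1, 2))
  cm3 <- suppressWarnings(correlation_matrix(toy_matrix(v3, n_A = 2)))
  expect_equal(cm3$flagged, "a2")
})

test_that("chromosome distribution test matches hand arithmetic and chisq.test", {
  # proportional observed counts: statistic 0, nothing flagged
  r0 <- chrom_distribution_test(rep(c("c1", "c2"), c(10, 10)),
                                c(c1 = 50, c2 = 50))
  expect_equal(r0$statistic, 0)
  expect_false(any(r0$table$flagged))

  # two chromosomes, bins (100,100), calls (30,10): expected (20,20),
  # chi-squared = 5 + 5 = 10, residuals +/-sqrt(5) ~ 2.236 -> both flagged
  r1 <- chrom_distribution_test(rep(c("c1", "c2"), c(30, 10)),
                                c(c1 = 100, c2 = 100))
  expect_equal(r1$statistic, 10)
  expect_equal(r1$table$residual, c(sqrt(5), -sqrt(5)))
  expect_true(all(r1$table$flagged))
  # independent route: stats::chisq.test with the same expected proportions
  ct <- chisq.test(c(30, 10), p = c(0.5, 0.5))
  expect_equal(r1$statistic, unname(ct$statistic))
  expect_equal(r1$p_value, ct$p.value)

  # residual sum-of-squares identity on arbitrary data
  withr::with_seed(2, {
    calls <- sample(paste0("c", 1:5), 200, replace = TRUE)
    bins <- setNames(sample(50:150, 5), paste0("c", 1:5))
  })
  r2 <- chrom_distribution_test(calls, bins)
  expect_equal(sum(r2$table$residual^2), r2$statistic)

  expect_warning(chrom_distribution_test("c1", c(c1 = 10, c2 = 0, c3 = 5)),
                 "zero orthologous bins")
})

test_that("a chromosome with doubled call density is flagged consistently", {
  flagged <- 0L
  for (s in 1:20) {
    withr::with_seed(s, {
      bins <- setNames(rep(200, 5), paste0("c", 1:5))
      rate <- c(2, 1, 1, 1, 1) / 6
      calls <- sample(paste0("c", 1:5), 180, TRUE, prob = rate)
    })
    r <- chrom_distribution_test(calls, bins)
    flagged <- flagged + (r$table$flagged[1] && r$table$residual[1] > 0)
  }
  expect_gte(flagged, 19L)
})

test_that("gc_by_class reproduces collinear regressions and null contrasts", {
  # perfectly collinear class: the least-squares line is exact
  n <- 60
  structure_v <- seq(-1, 1, length.out = n)
  gc <- 0.37 + 0.05 * structure_v
  labels <- data.frame(region_id = as.character(seq_len(n)),
                       class = rep(c("nondivergent", "divergent_open_A"),
                                   c(40, 20)),
                       polarity = rep(c(0L, 1L), c(40, 20)),
                       absolute = FALSE)
  res <- gc_by_class(gc, labels, structure_v, n_categories = 4)
  reg <- res$regressions
  expect_equal(reg$slope[reg$class == "nondivergent"], 0.05)
  expect_equal(reg$intercept[reg$class == "divergent_open_A"], 0.37)

  # identical GC distributions: no significant class contrast in most seeds
  nonsig <- 0L
  for (s in 1:20) {
    withr::with_seed(s, gcs <- rnorm(n, 0.37, 0.02))
    p <- gc_by_class(gcs, labels, structure_v)$tests
    nonsig <- nonsig + (p$p_vs_nondivergent[p$class == "divergent_open_A"] > 0.05)
  }
  expect_gte(nonsig, 15L)

  # an implanted downward GC shift in the divergent-open class puts its
  # regression line below the nondivergent line over the shared range
  withr::with_seed(5, {
    gcd <- 0.37 + 0.05 * structure_v + rnorm(n, 0, 0.005)
    gcd[labels$class == "divergent_open_A"] <-
      gcd[labels$class == "divergent_open_A"] - 0.03
  })
  res2 <- gc_by_class(gcd, labels, structure_v)
  r2 <- res2$regressions
  mid <- mean(structure_v)
  line <- function(cl) r2$intercept[r2$class == cl] +
    r2$slope[r2$class == cl] * mid
  expect_lt(line("divergent_open_A"), line("nondivergent"))
  expect_lt(res2$tests$p_vs_nondivergent[
    res2$tests$class == "divergent_open_A"], 0.01)
})

test_that("density_compare recovers implanted annotation-rate contrasts", {
  regions <- data.frame(chrom = "chrA1", start = (0:199) * 1e5,
                        end = (1:200) * 1e5)
  labels <- data.frame(region_id = as.character(1:200),
                       class = rep(c("nondivergent", "divergent_open_A"),
                                   c(160, 40)),
                       polarity = rep(c(0L, 1L), c(160, 40)),
                       absolute = FALSE)

  # no genes at all: densities zero and the test degenerate, flagged
  empty <- data.frame(chrom = character(), start = numeric(),
                      class = character())
  d0 <- density_compare(empty, labels, regions)
  expect_null(d0)   # no annotation classes, nothing to tabulate

  # a class whose genes all fall outside the region universe: densities 0,
  # rank test degenerate and flagged
  stray <- data.frame(chrom = "chrZ9", start = c(5, 10), class = "miRNA")
  dz <- density_compare(stray, labels, regions)
  expect_true(all(dz$density_per_100kb[dz$n_regions > 0] == 0))
  expect_true(all(dz$degenerate))
  expect_true(all(is.na(dz$p_vs_nondivergent)))

  # equal Poisson rates: mostly non-significant across seeds
  nonsig <- 0L
  for (s in 1:10) {
    withr::with_seed(s, cnt <- rpois(200, 2))
    genes <- data.frame(
      chrom = "chrA1",
      start = rep(regions$start, cnt) + 10,
      class = "protein_coding")
    d <- density_compare(genes, labels, regions)
    p <- d$p_vs_nondivergent[d$region_class == "divergent_open_A"]
    nonsig <- nonsig + (p > 0.05)
  }
  expect_gte(nonsig, 9L)

  # doubled rate inside the divergent class: detected, both unit scales
  withr::with_seed(3, cnt2 <- rpois(200, ifelse(labels$polarity != 0, 2, 1)))
  genes2 <- data.frame(chrom = "chrA1", start = rep(regions$start, cnt2) + 10,
                       class = "lincRNA")
  d2 <- density_compare(genes2, labels, regions)
  row <- d2[d2$region_class == "divergent_open_A", ]
  expect_lt(row$p_vs_nondivergent, 0.01)
  expect_equal(row$density_per_mb, row$density_per_100kb * 10)
})

test_that("expression divergence recovers medians, signs and the absolute-mode ordering", {
  # two genes with RPKM (8,2) and (2,8) in opposite classes
  regions <- data.frame(chrom = "chrA1", start = c(0, 1e5, 2e5),
                        end = c(1e5, 2e5, 3e5))
  labels <- data.frame(region_id = c("r1", "r2", "r3"),
                       class = c("divergent_open_A", "divergent_closed_A",
                                 "nondivergent"),
                       polarity = c(1L, -1L, 0L), absolute = TRUE)
  expr <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     chrom = "chrA1", start = c(10, 1e5 + 10, 2e5 + 10, 2e5 + 20),
                     rpkm_A = c(8, 2, 4, 4), rpkm_B = c(2, 8, 4, 4))
  res <- expression_divergence(expr, labels, regions, pseudocount = 0)
  tab <- res$table
  expect_equal(tab$median_log2fc[tab$class == "divergent_open_A"], 2)
  expect_equal(tab$median_log2fc[tab$class == "divergent_closed_A"], -2)
  expect_equal(tab$median_log2fc[tab$class == "nondivergent"], 0)

  # simulated effect recovery plus the absolute-mode separation ordering
  cfg <- pipeline_config(seed = 5L,
                         simulate = list(n_chrom = 4L, mean_len = 4e7,
                                         n_tracts = 30L, frac_unmappable = 0,
                                         decoy_frac = 0, nonreciprocal_frac = 0),
                         divergence = list(n_perm = 2000L),
                         cluster = list(n_perm = 500L),
                         enrichment = list(n_perm = 200L, windows = 5e6))
  b <- run_pipeline(cfg)
  rel <- b$associations$expression_relative$table
  ab <- b$associations$expression_absolute$table
  med_bg <- rel$median_log2fc[rel$class == "nondivergent"]
  med_plus <- rel$median_log2fc[rel$class == "divergent_open_A"]
  expect_lt(abs((med_plus - med_bg) - 1), 0.5)   # implanted effect ~ 1
  expect_lt(rel$p_vs_nondivergent[rel$class == "divergent_open_A"], 0.01)
  # absolute restriction sharpens the separation
  expect_gte(ab$median_log2fc[ab$class == "divergent_open_A"], med_plus - 0.1)
})

test_that("fisher enrichment follows the cross-product formula", {
  # table [[10,20],[30,40]] -> OR = (10*40)/(20*30) = 2/3
  reg <- rep(c("divergent", "conserved"), c(30, 70))
  in_div <- c(rep(c(TRUE, FALSE), c(10, 20)), rep(c(TRUE, FALSE), c(30, 40)))
  fe <- class_enrichment_fisher(reg, in_div)
  expect_equal(fe$odds_ratio, 2 / 3, tolerance = 1e-12)
  expect_equal(fe$p_value, fisher.test(matrix(c(10, 30, 20, 40), 2))$p.value)

  # independence: OR near 1 on average across seeds
  ors <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      rg <- sample(c("divergent", "conserved"), 400, TRUE)
      dv <- sample(c(TRUE, FALSE), 400, TRUE)
    })
    class_enrichment_fisher(rg, dv)$odds_ratio
  }, numeric(1))
  expect_lt(abs(mean(log(ors))), 0.15)

  # zero margin: raw OR degenerate, Haldane version finite
  fe0 <- class_enrichment_fisher(rep("divergent", 10), rep(TRUE, 10))
  expect_true(is.nan(fe0$odds_ratio))
  expect_true(is.finite(fe0$odds_ratio_haldane))
})

test_that("overlap QC summarises alignment fractions per class", {
  withr::with_seed(9, {
    pairs <- data.frame(overlap_A = runif(100, 0.5, 1),
                        overlap_B = runif(100, 0.5, 1))
  })
  labels <- data.frame(region_id = as.character(1:100),
                       class = rep(c("nondivergent", "divergent_open_A"),
                                   c(70, 30)),
                       polarity = rep(c(0L, 1L), c(70, 30)), absolute = FALSE)
  qc <- overlap_qc(pairs, labels)
  expect_equal(nrow(qc), 4L)
  # identical distributions: the QC contrast is non-significant
  expect_true(all(qc$p_vs_nondivergent[!is.na(qc$p_vs_nondivergent)] > 0.001))
  # an implanted overlap deficit in divergent regions is detected
  pairs2 <- pairs
  pairs2$overlap_A[labels$class != "nondivergent"] <-
    pairs2$overlap_A[labels$class != "nondivergent"] - 0.15
  qc2 <- overlap_qc(pairs2, labels)
  expect_lt(qc2$p_vs_nondivergent[qc2$side == "overlap_A" &
                                  qc2$class == "divergent"], 0.01)
})
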