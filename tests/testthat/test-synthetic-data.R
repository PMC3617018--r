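# Generators: determinism, layout geometry, compartment run statistics,
# implanting, structure values, probes, orthology, GC/genes, expression.

test_that("gen_layout produces whole-bin chromosomes deterministically", {
  l1 <- gen_layout(1, 1e7, seed = 7)
  expect_equal(nrow(layout_bins(l1)), 100L)          # exactly 100 bins
  expect_identical(l1, gen_layout(1, 1e7, seed = 7)) # seed determinism

  l4 <- gen_layout(4, 5e6, seed = 1)
  # brute-force recount of bins from the emitted chromosome lengths
  expect_equal(nrow(layout_bins(l4)),
               sum(l4$chromosomes$length %/% 1e5))
  expect_true(all(l4$chromosomes$length %% 1e5 == 0))
  expect_true(all(l4$chromosomes$centromere > 0 &
                  l4$chromosomes$centromere < l4$chromosomes$length))

  expect_error(gen_layout(0, 1e7, seed = 1), "n_chrom")
  expect_error(gen_layout(2, 5e5, seed = 1), "mean_len")
})

test_that("compartment tracks match the target open fraction and run length", {
  lay <- gen_layout(1, 1e9, seed = 2)  # 10,000 bins
  tr <- gen_compartments(lay, mean_domain_bins = 8, p_open = 0.5, seed = 3)
  expect_equal(nrow(tr$bins), 10000L)
  expect_false(anyNA(tr$bins$open))

  # oracle: tally run lengths directly from the emitted track
  r <- rle(tr$bins$open)
  m_obs <- mean(r$lengths)
  se <- sd(r$lengths) / sqrt(length(r$lengths))
  expect_lt(abs(m_obs - 8), 3 * se + 1e-9)
  expect_lt(abs(mean(tr$bins$open) - 0.5), 0.05)

  # degenerate boundary: everything open
  tr1 <- gen_compartments(lay, 8, p_open = 1, seed = 3)
  expect_true(all(tr1$bins$open))

  expect_error(gen_compartments(lay, 1, p_open = 0.1, seed = 1),
               "mean_domain_bins too small")
  expect_identical(gen_compartments(lay, 8, 0.5, seed = 3),
                   gen_compartments(lay, 8, 0.5, seed = 3))
})

test_that("compartment run lengths are geometric with the specified mean", {
  lay <- gen_layout(1, 5e9, seed = 4)  # 50,000 bins
  tr <- gen_compartments(lay, mean_domain_bins = 8, p_open = 0.5, seed = 5)
  lens <- rle(tr$bins$open)$lengths
  # goodness of fit against Geometric(mean 8): chi-squared on binned counts
  p_geo <- 1 / 8
  br <- c(1:15, Inf)
  obs <- table(cut(lens, c(0, br)))
  probs <- diff(c(0, 1 - (1 - p_geo)^br[-length(br)], 1))
  expect_gt(suppressWarnings(
    stats::chisq.test(as.numeric(obs), p = probs)$p.value), 0.01)
})

test_that("implant_divergence flips only species B inside disjoint tracts", {
  lay <- toy_layout(200)
  tr_A <- gen_compartments(lay, 8, 0.5, seed = 6)

  # no tracts: identity
  out0 <- implant_divergence(tr_A, tr_A, 0, 4, seed = 1)
  expect_identical(out0$track_B$bins, tr_A$bins)
  expect_equal(nrow(out0$truth$tracts), 0L)

  # one 8-bin tract over an all-open reference
  tr_open <- toy_track(rep(TRUE, 20))
  out1 <- implant_divergence(tr_open, tr_open, 1, 8, seed = 2)
  expect_equal(nrow(out1$truth$bins), 8L)
  expect_true(all(out1$truth$bins$polarity == 1L))
  expect_equal(sum(out1$track_B$bins$open == FALSE), 8L)

  # 5 tracts of 4 bins: 20 truth bins, pairwise disjoint (brute force)
  out5 <- implant_divergence(tr_A, tr_A, 5, 4, seed = 11)
  expect_equal(nrow(out5$truth$bins), 20L)
  t5 <- out5$truth$tracts
  for (i in seq_len(4)) for (j in (i + 1):5) {
    expect_true(t5$end[i] <= t5$start[j] || t5$end[j] <= t5$start[i])
  }
  # outside tracts, B equals its input; inside, B is flipped A
  key <- paste(tr_A$bins$chrom, tr_A$bins$start)
  inside <- key %in% paste(out5$truth$bins$chrom, out5$truth$bins$start)
  expect_identical(out5$track_B$bins$open[!inside], tr_A$bins$open[!inside])
  expect_identical(out5$track_B$bins$open[inside], !tr_A$bins$open[inside])
  # polarity consistent with the reference state
  expect_identical(out5$truth$bins$polarity,
                   ifelse(tr_A$bins$open[inside], 1L, -1L))

  # infeasible request errors
  expect_error(implant_divergence(tr_open, tr_open, 10, 8, seed = 1),
               "non-overlapping")
})

test_that("structure values are bimodal and rank-correlated across datasets", {
  ds <- data.frame(id = c("a", "b"), assay = "RT", cell_type = "ESC")
  tr <- toy_track(c(TRUE, FALSE, TRUE, FALSE))
  s0 <- gen_structure(tr, ds, mu_open = 1, mu_closed = -1,
                      sigma_dataset = 0, sigma_noise = 0, seed = 1)
  expect_equal(unname(s0$values[, 1]), c(1, -1, 1, -1))
  expect_equal(s0$values[, 1], s0$values[, 2])

  # sigma_noise = 0: identical ranks, Spearman rho exactly 1
  s1 <- gen_structure(tr, ds, sigma_dataset = 0.3, sigma_noise = 0, seed = 2)
  expect_equal(cor(s1$values[, 1], s1$values[, 2], method = "spearman"), 1)

  # 10,000 bins, 6 datasets: all pairwise rho positive and substantial
  lay <- gen_layout(1, 1e9, seed = 2)
  trk <- gen_compartments(lay, 8, 0.5, seed = 3)
  ds6 <- data.frame(id = letters[1:6], assay = "RT", cell_type = "ESC")
  s6 <- gen_structure(trk, ds6, sigma_noise = 0.4, seed = 5)
  rho <- cor(s6$values, method = "spearman")
  expect_true(all(rho[upper.tri(rho)] > 0.3))

  expect_error(gen_structure(tr, ds[0, ], seed = 1), "non-empty")
  expect_error(gen_structure(tr, ds, mu_open = -1, mu_closed = 1, seed = 1),
               "mu_open")
})

test_that("probe scattering recovers bin values and stays inside bins", {
  tr <- toy_track(c(TRUE, FALSE, TRUE))
  ds <- data.frame(id = "x", assay = "RT", cell_type = "ESC")
  st <- gen_structure(tr, ds, sigma_dataset = 0, sigma_noise = 0, seed = 1)

  # zero probe noise: per-bin probe mean equals the bin value exactly
  p0 <- gen_probes(st, probes_per_bin = 10, probe_sigma = 0, seed = 2,
                   poisson = FALSE)
  m <- tapply(p0$value, p0$pos %/% 1e5, mean)
  expect_equal(as.numeric(m), unname(st$values[, 1]))
  expect_true(all(p0$pos >= 0 & p0$pos < 3e5))
  expect_true(all(p0$pos %/% 1e5 %in% 0:2))

  # standard-error bound: 1 bin, value 0.7, 50 probes, sd 0.1
  tr1 <- toy_track(TRUE)
  st1 <- gen_structure(tr1, ds, mu_open = 0.7, mu_closed = -1,
                       sigma_dataset = 0, sigma_noise = 0, seed = 1)
  p1 <- gen_probes(st1, 50, probe_sigma = 0.1, seed = 2, poisson = FALSE)
  expect_equal(nrow(p1), 50L)
  expect_lt(abs(mean(p1$value) - 0.7), 3 * 0.1 / sqrt(50))

  expect_identical(gen_probes(st, 10, 0.1, seed = 3),
                   gen_probes(st, 10, 0.1, seed = 3))
})

test_that("orthology maps carry controlled overlap fractions and keep flags", {
  lay <- gen_layout(4, 1e7, seed = 1)

  # clean map: everything kept
  o0 <- gen_orthology(lay, n_rearrangements = 3, frac_unmappable = 0,
                      decoy_frac = 0, nonreciprocal_frac = 0, seed = 9)
  expect_true(all(o0$pairs$keep))
  expect_equal(nrow(o0$pairs), nrow(layout_bins(lay)))
  expect_true(all(o0$pairs$overlap_A >= 0.5 & o0$pairs$overlap_B >= 0.5))

  # decoys drop below the threshold
  o1 <- gen_orthology(lay, 3, frac_unmappable = 0.1, decoy_frac = 0.1,
                      nonreciprocal_frac = 0.05, seed = 9)
  expect_true(any(!o1$pairs$keep))
  expect_true(all(o1$pairs$overlap_A[o1$pairs$keep] >= 0.5))
  # a sub-threshold fraction always flags drop
  low <- o1$pairs$overlap_A < 0.5 | o1$pairs$overlap_B < 0.5
  expect_true(all(!o1$pairs$keep[low]))
  expect_identical(o1$pairs,
                   gen_orthology(lay, 3, frac_unmappable = 0.1,
                                 decoy_frac = 0.1, nonreciprocal_frac = 0.05,
                                 seed = 9)$pairs)
})

test_that("GC tracks hit the target structure correlation; gene rates follow state", {
  lay <- gen_layout(1, 5e8, seed = 2)  # 5,000 bins
  trk <- gen_compartments(lay, 8, 0.5, seed = 3)
  gg <- gen_gc_and_genes(trk, rho_target = 0.6, seed = 4)
  # realised Spearman against a mean-structure proxy built from the track
  ds6 <- data.frame(id = letters[1:6], assay = "RT", cell_type = "ESC")
  ms <- rowMeans(gen_structure(trk, ds6, seed = 5)$values)
  rho <- cor(gg$gc$gc, ms, method = "spearman")
  expect_gt(rho, 0.5); expect_lt(rho, 0.7)

  # open bins carry more genes when the rates differ
  cnt <- tabulate(match(paste(gg$genes$chrom, gg$genes$start %/% 1e5),
                        paste(trk$bins$chrom, trk$bins$start %/% 1e5)),
                  nbins = nrow(trk$bins))
  expect_gt(mean(cnt[trk$bins$open]), mean(cnt[!trk$bins$open]))

  # equal densities: state difference non-significant in most seeds
  nonsig <- 0L
  for (s in 1:10) {
    g2 <- gen_gc_and_genes(trk, 0.6, gene_density_open = 2,
                           gene_density_closed = 2, seed = s)
    c2 <- tabulate(match(paste(g2$genes$chrom, g2$genes$start %/% 1e5),
                         paste(trk$bins$chrom, trk$bins$start %/% 1e5)),
                   nbins = nrow(trk$bins))
    p <- wilcox.test(c2[trk$bins$open], c2[!trk$bins$open])$p.value
    nonsig <- nonsig + (p > 0.05)
  }
  expect_gte(nonsig, 9L)
})

test_that("expression tables encode the implanted divergence effect", {
  lay <- toy_layout(300)
  trk <- gen_compartments(lay, 8, 0.5, seed = 1)
  imp <- implant_divergence(trk, trk, 6, 5, seed = 2)
  gg <- gen_gc_and_genes(trk, 0.6, 2, 2, seed = 3)

  # zero effect and zero sd: log2 fold change is exactly the baseline
  e0 <- gen_expression(imp$truth, gg$genes, effect_log2 = 0, sd_log2 = 0,
                       baseline_shift = 0.25, seed = 4)
  expect_equal(log2(e0$rpkm_A / e0$rpkm_B), rep(0.25, nrow(e0)),
               tolerance = 1e-12)
  expect_true(all(e0$rpkm_A > 0 & e0$rpkm_B > 0))

  # implanted effect: genes in +1 tracts shift up; rank test rejects
  lay2 <- gen_layout(1, 3e8, seed = 5)
  trk2 <- gen_compartments(lay2, 8, 0.5, seed = 5)
  imp2 <- implant_divergence(trk2, trk2, 25, 6, seed = 6)
  gg2 <- gen_gc_and_genes(trk2, 0.6, 3, 3, seed = 7)
  e2 <- gen_expression(imp2$truth, gg2$genes, effect_log2 = 1, sd_log2 = 1.5,
                       seed = 6)
  lfc <- log2(e2$rpkm_A / e2$rpkm_B)
  plus <- e2$truth_polarity == 1L; bg <- e2$truth_polarity == 0L
  expect_gte(sum(plus), 20L)
  expect_lt(wilcox.test(lfc[plus], lfc[bg])$p.value, 0.01)
})

test_that("regulatory flags reproduce the target odds ratio at scale", {
  lay <- gen_layout(1, 1e9, seed = 1)
  trk <- gen_compartments(lay, 8, 0.5, seed = 1)
  imp <- implant_divergence(trk, trk, 150, 6, seed = 2)
  gg <- gen_gc_and_genes(trk, 0.6, 3, 3, seed = 3)
  fl <- gen_regulatory_flags(gg$genes, imp$truth, odds_ratio = 2,
                             base_rate = 0.2, seed = 4)
  pol <- chromdiverge:::truth_polarity_at(imp$truth, gg$genes$chrom,
                                          gg$genes$start)
  tab <- table(fl == "divergent", pol != 0)
  or <- (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
        (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  ft <- fisher.test(tab)
  expect_true(ft$conf.int[1] < 2 && 2 < ft$conf.int[2])
  expect_gt(or, 1.4); expect_lt(or, 2.8)
})
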