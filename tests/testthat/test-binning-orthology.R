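# Probe binning, within-species collation, cross-species orthology pairing.

test_that("bin_probes averages by midpoint and applies the probe floor", {
  lay <- toy_layout(3)
  probes <- data.frame(chrom = "chrA1",
                       pos = seq(5000, 95000, length.out = 10),
                       dataset = "d1", value = 1:10)
  bt <- bin_probes(probes, lay, min_probes = 10)
  expect_equal(nrow(bt), 1L)
  expect_equal(bt$value, 5.5)        # arithmetic mean of 1..10
  expect_equal(bt$n_probes, 10L)

  # nine probes: cell absent under the 10-probe floor
  bt9 <- bin_probes(probes[1:9, ], lay, min_probes = 10)
  expect_equal(nrow(bt9), 0L)

  # boundary midpoints: 99,999 -> bin 0; 100,000 -> bin 1 (brute-force
  # integer division oracle)
  pb <- data.frame(chrom = "chrA1", pos = c(99999, 100000),
                   dataset = "d1", value = c(1, 2))
  btb <- bin_probes(pb, lay, min_probes = 1)
  expect_equal(btb$start, c(0, 1e5))
  expect_equal(btb$start, (pb$pos %/% 1e5) * 1e5)

  # probe order is irrelevant
  shuffled <- probes[sample(nrow(probes)), ]
  expect_equal(bin_probes(shuffled, lay, min_probes = 10), bt)

  # unknown chromosome names the offending record
  badp <- data.frame(chrom = "chrZZ", pos = 1, dataset = "d9", value = 0)
  expect_error(bin_probes(badp, lay), "chrZZ")
  expect_error(bin_probes(data.frame(chrom = "chrA1", pos = 4e5,
                                     dataset = "d1", value = 0), lay),
               "bounds")
})

test_that("collate_species keeps complete cases and honours overlap thresholds", {
  lay <- toy_layout(4)
  mk <- function(ds, starts, values, offset = 0) {
    out <- data.frame(dataset = ds, chrom = "chrA1", start = starts + offset,
                      end = starts + offset + 1e5, value = values,
                      n_probes = 20L)
    attr(out, "bin_size") <- 1e5
    class(out) <- c("BinTrack", "data.frame")
    out
  }
  s <- c(0, 1e5, 2e5, 3e5)
  t1 <- mk("d1", s, 1:4)
  t2 <- mk("d2", s, 5:8)
  tab <- collate_species(list(t1, t2))
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$d1, 1:4); expect_equal(tab$d2, 5:8)

  # one dataset missing a bin: that region is dropped everywhere
  tab3 <- collate_species(list(t1, mk("d2", s[-2], 5:7)))
  expect_equal(nrow(tab3), 3L)
  expect_false(1e5 %in% tab3$start)

  # single candidate bin offset by 40 Kb (overlap 60 Kb / 100 Kb = 0.6):
  # paired; offset 60 Kb (overlap 0.4): not paired
  a1 <- mk("d1", 0, 1)
  off40 <- collate_species(list(a1, mk("d2", 0, 9, offset = 4e4)))
  expect_equal(nrow(off40), 1L)
  expect_equal(off40$d2, 9)
  expect_equal((1e5 - 4e4) / 1e5, 0.6)   # oracle overlap arithmetic
  off60 <- collate_species(list(a1, mk("d2", 0, 9, offset = 6e4)))
  expect_equal(nrow(off60), 0L)
})

test_that("map_orthologs applies inclusive reciprocal-best thresholds", {
  mk_tab <- function(sp, ds, n = 3) {
    out <- data.frame(chrom = paste0("chr", sp, "1"),
                      start = (seq_len(n) - 1) * 1e5, end = seq_len(n) * 1e5)
    for (d in ds) out[[d]] <- seq_len(n) + 0.1
    attr(out, "datasets") <- ds
    attr(out, "species") <- sp
    out
  }
  tab_A <- mk_tab("A", c("a1", "a2"))
  tab_B <- mk_tab("B", c("b1", "b2"))
  base_pair <- function(i, j, oa, ob) data.frame(
    chrom_A = "chrA1", start_A = (i - 1) * 1e5, end_A = i * 1e5,
    chrom_B = "chrB1", start_B = (j - 1) * 1e5, end_B = j * 1e5,
    overlap_A = oa, overlap_B = ob)

  # exactly 50% both sides is retained (inclusive threshold)
  m1 <- map_orthologs(tab_A, tab_B, base_pair(1, 1, 0.5, 0.5), 0.5)
  expect_equal(nrow(m1$matrix$regions), 1L)

  # (0.49, 0.80) is dropped; both regions become lineage specific
  m2 <- map_orthologs(tab_A, tab_B, base_pair(1, 1, 0.49, 0.80), 0.5)
  expect_equal(nrow(m2$matrix$regions), 0L)
  expect_equal(nrow(m2$lineage_specific_A), 3L)
  expect_equal(nrow(m2$lineage_specific_B), 3L)

  # reciprocal best: A1 overlaps B1 at 0.6 and B2 at 0.55; keep only the
  # 0.6 pair (oracle: brute-force best search over the two candidates)
  pairs <- rbind(base_pair(1, 1, 0.6, 0.6), base_pair(1, 2, 0.55, 0.55))
  m3 <- map_orthologs(tab_A, tab_B, pairs, 0.5)
  expect_equal(nrow(m3$matrix$regions), 1L)
  expect_equal(m3$matrix$regions$start_B, 0)

  # duplicate pairs rejected
  expect_error(map_orthologs(tab_A, tab_B,
                             rbind(base_pair(1, 1, 0.6, 0.6),
                                   base_pair(1, 1, 0.6, 0.6)), 0.5),
               "duplicate")

  # region conservation: matrix rows + lineage-specific rows account for
  # every region of each input table
  expect_equal(nrow(m3$matrix$regions) + nrow(m3$lineage_specific_A),
               nrow(tab_A))
  expect_equal(nrow(m3$matrix$regions) + nrow(m3$lineage_specific_B),
               nrow(tab_B))
})

test_that("map_orthologs recovers the generator's keep/drop flags exactly", {
  cfg <- pipeline_config(seed = 31L,
                         simulate = list(n_chrom = 3L, mean_len = 1e7,
                                         n_tracts = 4L, frac_unmappable = 0.1,
                                         decoy_frac = 0.1,
                                         nonreciprocal_frac = 0.05))
  study <- simulate_study(cfg)
  tab_A <- collate_species(list(as_bin_track(study$structure_A)), species = "A")
  tab_B <- collate_species(list(as_bin_track(study$structure_B)), species = "B")
  m <- map_orthologs(tab_A, tab_B, study$orthology$pairs, 0.5,
                     datasets = study$datasets)
  got <- paste(m$retained_pairs$chrom_A, m$retained_pairs$start_A,
               m$retained_pairs$chrom_B, m$retained_pairs$start_B)
  p <- study$orthology$pairs
  want <- paste(p$chrom_A, p$start_A, p$chrom_B, p$start_B)[p$keep]
  expect_setequal(got, want)
})

test_that("interval and matrix writers round-trip through standard formats", {
  tmp <- withr::local_tempdir()
  df <- data.frame(chrom = c("chr1", "chr2"), start = c(0, 5e5),
                   end = c(1e5, 7e5))
  write_bed(df, file.path(tmp, "x.bed"), name = c("+1", "-1"))
  back <- read_bed(file.path(tmp, "x.bed"))
  expect_equal(back[, c("chrom", "start", "end")], df)
  expect_equal(back$name, c("+1", "-1"))

  probes <- data.frame(chrom = "chr1", pos = c(100, 250), value = c(0.5, -1.25))
  write_probes_bedgraph(probes, file.path(tmp, "p.bedGraph"))
  bg <- read_bedgraph(file.path(tmp, "p.bedGraph"))
  expect_equal(bg$start, probes$pos)
  expect_equal(bg$value, probes$value)

  sm <- toy_matrix(matrix(rnorm(20), 5, 4,
                          dimnames = list(NULL, c("a1", "a2", "b1", "b2"))))
  write_structure_matrix(sm, file.path(tmp, "m.tsv"))
  sm2 <- read_structure_matrix(file.path(tmp, "m.tsv"))
  expect_equal(sm2$values, sm$values, tolerance = 1e-12)
  expect_equal(sm2$datasets$species, sm$datasets$species)

  lay <- toy_layout(5, centromere = 2e5)
  write_layout(lay, file.path(tmp, "l.tsv"))
  expect_equal(read_layout(file.path(tmp, "l.tsv")), lay)
})
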