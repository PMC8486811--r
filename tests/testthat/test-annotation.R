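test_that("DHS-model bead classification follows the precedence rule", {
  # chromosome of 5 beads (15 kb); DHS in bin 2, H3K27ac in bins 2-3, none in 4-5
  dhs <- data.frame(chrom = "chrT", start = 3500, end = 3600)
  ac <- data.frame(chrom = "chrT", start = c(3000, 6100), end = c(3800, 8000))
  cls <- classify_beads_dhs(dhs, ac, "chrT", 15000)
  expect_equal(cls, c("heterochromatin", "TU", "euchromatin",
                      "heterochromatin", "heterochromatin"))
  # empty tracks: everything non-binding
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  expect_equal(unique(classify_beads_dhs(empty, empty, "chrT", 15000)),
               "heterochromatin")
  # a 1-bp overlap at a bin boundary counts
  dhs2 <- data.frame(chrom = "chrT", start = 2999, end = 3000)
  cls2 <- classify_beads_dhs(dhs2, empty, "chrT", 15000)
  expect_equal(cls2[1], "TU")
  expect_equal(cls2[2], "heterochromatin")
})

test_that("chromatin-state classification: majority overlap with tie-break", {
  map <- c(Tss = "TU", Enh = "euchromatin", Quies = "heterochromatin")
  track <- data.frame(chrom = "chrT",
                      start = c(0, 2000, 3000, 4400, 6000),
                      end = c(2000, 3000, 4400, 6000, 9000),
                      state = c("Tss", "Enh", "Quies", "Enh", "Quies"))
  cls <- classify_beads_hmm(track, map, "chrT", 9000)
  # bin 1: Tss 2000 bp vs Enh 1000 bp -> TU
  # bin 2: Quies 1400 vs Enh 1600 -> euchromatin
  # bin 3: Quies 3000 -> heterochromatin
  expect_equal(cls, c("TU", "euchromatin", "heterochromatin"))
  # exact tie: the interval with the lower start coordinate wins
  tie <- data.frame(chrom = "chrT", start = c(0, 1500), end = c(1500, 3000),
                    state = c("Tss", "Quies"))
  expect_equal(classify_beads_hmm(tie, map, "chrT", 3000), "TU")
  # unmapped state label is an error naming the label
  bad <- data.frame(chrom = "chrT", start = 0, end = 100, state = "Mystery")
  expect_error(classify_beads_hmm(bad, map, "chrT", 3000), "Mystery")
})

test_that("synthetic fixture: classification round-trip and density", {
  fx <- synthetic_annotation_fixture(chrom_length = 1.5e6, tu_density = 0.039,
                                     seed = 42)
  cls <- classify_beads_dhs(fx$dhs, fx$h3k27ac, fx$chrom, fx$length)
  expect_identical(cls, fx$classes)        # generator inversion, exact
  expect_equal(mean(fx$classes == "TU"), 0.039, tolerance = 0.5)
  # files round-trip through the BED/bedGraph readers
  dir <- tempfile()
  paths <- write_fixture_tracks(fx, dir)
  dhs_back <- read_bed_track(paths["dhs"])
  expect_equal(dhs_back$start, fx$dhs$start)
  expect_equal(dhs_back$end, fx$dhs$end)
  sig_back <- read_bedgraph_track(paths["signal"])
  expect_equal(sig_back$score, fx$signal$score, tolerance = 1e-6)
})

test_that("territory ellipsoid: volume algebra, scaling law, round trip", {
  ax <- ellipsoid_for_territory(35784, 0.14, c(2, 1, 1))
  expect_equal(ax[1], 50.4, tolerance = 0.01)
  expect_equal(ax[3], 25.2, tolerance = 0.01)
  # doubling the bead count scales each axis by 2^(1/3)
  ax2 <- ellipsoid_for_territory(2 * 35784, 0.14, c(2, 1, 1))
  expect_equal(ax2 / ax, rep(2^(1 / 3), 3), tolerance = 1e-12)
  # recomputing the volume fraction from the output recovers the input
  phi <- (35784 * pi / 6) / (4 / 3 * pi * prod(ax))
  expect_equal(phi, 0.14, tolerance = 1e-12)
})

test_that("bead counts for real chromosome sizes match 3-kbp binning", {
  expect_equal(n_beads_for_chromosome(107349540), 35784L)  # HSA14, hg19
  expect_equal(n_beads_for_chromosome(51304566), 17102L)   # HSA22, hg19
})

test_that("rank/quintile comparison: diagonal, reversal, marginals", {
  x <- 1:100
  same <- rank_quintile_compare(x, x + 0.0)
  expect_equal(same$spearman, 1)
  expect_true(all(same$quintile_counts[upper.tri(same$quintile_counts)] == 0))
  expect_true(all(same$quintile_counts[lower.tri(same$quintile_counts)] == 0))
  rev <- rank_quintile_compare(x, -x)
  expect_equal(rev$spearman, -1)
  expect_equal(sum(rev$quintile_counts), 100)
  expect_true(all(rowSums(rev$quintile_counts) == 20))
  # patch mode averages contiguous binding runs
  cls <- c("TU", "TU", "heterochromatin", "euchromatin", "euchromatin")
  pm <- rank_quintile_compare(c(1, 3, 9, 4, 6), c(2, 4, 9, 3, 7),
                              mode = "patch", bead_classes = cls)
  expect_equal(pm$n, 2)                    # two binding patches
  expect_error(rank_quintile_compare(1:5, 1:4), "different lengths")
})

test_that("copula-calibrated signal recovers the target rank correlation", {
  withr::with_seed(7, {
    act <- runif(35784)
  })
  fx <- synthetic_annotation_fixture(chrom_length = 35784 * 3000,
                                     target_rank_corr = 0.4, activity = act,
                                     seed = 7)
  sp <- rank_quintile_compare(act, fx$signal$score)
  expect_equal(sp$spearman, 0.4, tolerance = 0.025)
  # perfect correlation passes through the whole comparison pipeline
  fx1 <- synthetic_annotation_fixture(chrom_length = 3e5,
                                      target_rank_corr = 1,
                                      activity = seq_len(100), seed = 8)
  expect_equal(rank_quintile_compare(seq_len(100),
                                     fx1$signal$score)$spearman, 1)
})

test_that("nearest-TU distance anticorrelation utility", {
  # activity that decreases exactly with isolation gives r = -1
  tus <- c(10L, 12L, 30L, 60L, 61L)
  d <- c(2, 2, 18, 1, 1)
  act <- 1 / (1 + d) + c(0, 1e-6, 0, 2e-6, 3e-6)
  r <- nearest_tu_distance_correlation(act, tus)
  expect_equal(r$distances, d)
  expect_lt(r$spearman, -0.9)
  # equally spaced TUs: distance is constant, correlation undefined
  rdeg <- nearest_tu_distance_correlation(c(1, 2, 3), c(10L, 20L, 30L))
  expect_true(rdeg$degenerate)
  expect_true(is.na(rdeg$spearman))
  expect_error(nearest_tu_distance_correlation(1:2, c(1L, 5L)), "at least 3")
})

test_that("fibre construction from classes carries the genomic map", {
  cls <- c("TU", "euchromatin", "heterochromatin", "TU")
  fib <- fibre_from_classes(cls, "chrT")
  expect_equal(fib$n_beads, 4)
  expect_equal(fib$genomic_map$start, c(0, 3000, 6000, 9000))
  expect_equal(tu_indices(fib), c(1L, 4L))
})
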