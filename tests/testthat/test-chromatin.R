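test_that("toy fibre construction: seeded placement, classes, density", {
  a <- build_toy_fibre(M = 1000, n_tu = 39, seed = 5)
  b <- build_toy_fibre(M = 1000, n_tu = 39, seed = 5)
  expect_identical(tu_indices(a), tu_indices(b))
  expect_length(tu_indices(a), 39)
  expect_equal(sum(a$bead_class == "euchromatin"), 961)
  c <- build_toy_fibre(M = 1000, n_tu = 39, seed = 6)
  expect_false(identical(tu_indices(a), tu_indices(c)))
  # no TUs at all
  none <- build_toy_fibre(M = 50, n_tu = 0)
  expect_length(tu_indices(none), 0)
  expect_error(build_toy_fibre(M = 10, n_tu = 10), "smaller")
  # the frozen reference fibre has its anchor TUs
  ref <- toy_reference_fibre()
  expect_true(all(c(33, 396, 404, 886, 905, 907, 930, 931) %in%
                    tu_indices(ref)))
  expect_length(tu_indices(ref), 39)
  expect_identical(tu_indices(ref), tu_indices(toy_reference_fibre()))
})

test_that("loops: bond conversion, cycles, presets", {
  fib <- build_toy_fibre(M = 100, n_tu = 5, seed = 1)
  # no anchors: unchanged (FENE backbone kept)
  expect_identical(add_loops(fib, data.frame(i = integer(), j = integer())),
                   fib)
  one <- add_loops(fib, cbind(10L, 60L))
  expect_equal(nrow(one$bonds), 100)           # 99 backbone + 1 loop
  expect_true(all(one$bonds$kind[1:99] == "harmonic_backbone"))
  g <- igraph::graph_from_data_frame(one$bonds[, 1:2], directed = FALSE)
  expect_equal(igraph::ecount(g) - igraph::vcount(g) + 1, 1)  # one cycle
  # eight non-overlapping reference loops
  loops <- toy_reference_loops()
  expect_equal(nrow(loops), 8)
  o <- order(loops[, 1])
  expect_true(all(loops[o, 2][-8] < loops[o, 1][-1]))
  looped <- add_loops(toy_reference_fibre(), loops)
  expect_equal(sum(looped$bonds$kind == "harmonic_loop"), 8)
  # all-loops preset tiles the chain
  all_loops <- add_all_loops(build_toy_fibre(M = 500, n_tu = 10, seed = 2),
                             loop_size = 50L)
  expect_equal(sum(all_loops$bonds$kind == "harmonic_loop"), 9)
  expect_error(add_loops(fib, cbind(1L, 200L)), "out of range")
})

test_that("region relabelling: involution and TU bookkeeping", {
  fib <- toy_reference_fibre()
  het <- set_region_class(fib, 901, 940, "heterochromatin")
  expect_true(all(het$bead_class[901:940] == "heterochromatin"))
  # relabelled TUs leave the recorded TU list
  expect_false(any(c(905, 907, 930, 931) %in% tu_indices(het)))
  # relabel back: the original fibre returns
  back <- het
  for (i in 901:940) back$bead_class[i] <- fib$bead_class[i]
  expect_identical(validate_fibre(back)$bead_class, fib$bead_class)
  # the island preset keeps its four embedded TUs
  island <- toy_het_island_fibre()
  expect_true(all(c(905, 907, 930, 931) %in% tu_indices(island)))
  expect_equal(sum(island$bead_class[901:940] == "heterochromatin"), 36)
  expect_error(set_region_class(fib, 0, 10), "invalid")
})

test_that("knockout: reclassifies, reports, and is idempotent", {
  fib <- toy_reference_fibre()
  ko <- knockout_tu(fib, 930)
  expect_equal(ko$bead_class[930], "heterochromatin")
  # identity retained for reporting
  expect_true(930 %in% tu_indices(ko))
  expect_false(930 %in% tu_indices(ko, include_knockouts = FALSE))
  expect_identical(knockout_tu(ko, 930), ko)
  expect_error(knockout_tu(fib, 2), "not a TU")
  # a full sweep yields one mutant per TU
  mutants <- lapply(tu_indices(fib), knockout_tu, fibre = fib)
  expect_length(mutants, 39)
})

test_that("region deletion: re-joining, re-indexing, genomic gap", {
  M <- 17102
  cls <- rep("euchromatin", M)
  cls[seq(5, M, by = 400)] <- "TU"
  gm <- data.frame(chrom = "chr22", start = (seq_len(M) - 1) * 3000,
                   end = seq_len(M) * 3000)
  fib <- chromatin_fibre(cls, genomic_map = gm)
  del <- delete_region(fib, 6305, 7156)
  expect_equal(del$n_beads, 16250)             # 17102 - 852
  # the junction is bonded and the chain is still a single path
  expect_equal(nrow(del$bonds), 16249)
  # genomic coordinates of surviving beads are preserved (gap visible)
  expect_equal(del$genomic_map$start[6304], 6303 * 3000)
  expect_equal(del$genomic_map$start[6305], 7156 * 3000)
  # the deleted range maps to the expected hg19 coordinates
  expect_lte(fib$genomic_map$start[6305] + 1, 18912231)
  expect_gte(fib$genomic_map$end[6305], 18912231 - 3000)
  expect_gte(fib$genomic_map$end[7156], 21465672)
  # empty deletion is the identity
  expect_identical(delete_region(fib, 10, 9), fib)
  expect_error(delete_region(fib, 1, M), "whole chain")
  # loops crossing the cut are dropped; others are re-indexed
  small <- add_loops(build_toy_fibre(M = 100, n_tu = 4, seed = 2),
                     rbind(c(10L, 40L), c(60L, 90L)))
  dsmall <- delete_region(small, 30, 50)
  expect_equal(nrow(dsmall$loops), 1)
  expect_equal(unlist(dsmall$loops), c(i = 39L, j = 69L))
})

test_that("fibre validator catches broken structures", {
  fib <- build_toy_fibre(M = 20, n_tu = 2, seed = 1)
  broken <- fib
  broken$bonds <- broken$bonds[-5, ]
  expect_error(validate_fibre(broken), "backbone")
  dup <- fib
  dup$bonds <- rbind(dup$bonds, data.frame(i = 3L, j = 4L,
                                           kind = "harmonic_loop"))
  expect_error(validate_fibre(dup), "duplicate")
  badclass <- fib
  badclass$bead_class[3] <- "exotic"
  expect_error(validate_fibre(badclass))
})

test_that("fibre serialisation round-trips including knockouts and loops", {
  fib <- add_loops(toy_het_island_fibre(), toy_reference_loops())
  fib <- knockout_tu(fib, 33)
  path <- tempfile(fileext = ".tsv")
  write_fibre_tsv(fib, path)
  back <- read_fibre_tsv(path)
  expect_identical(back$bead_class, fib$bead_class)
  expect_equal(back$loops, fib$loops, ignore_attr = TRUE)
  expect_equal(back$knocked_out, fib$knocked_out)
})
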