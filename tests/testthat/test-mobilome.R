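test_that("TE-merged reference masks repeats and appends the library", {
  g <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 100)))
  expect_equal(length(build_te_merged_reference(g)), 1)
  ann <- data.frame(chrom = "s1", start = 51, end = 150)
  lib <- Biostrings::DNAStringSet(c(TE1 = "ACGTACGT", TE2 = "GGGGCCCC",
                                    TE3 = "TTTTAAAA"))
  hier <- data.table::data.table(id = c("TE1", "TE2", "TE3"),
                                 family = "f", order = "o")
  mr <- build_te_merged_reference(g, ann, lib, hier)
  expect_equal(Biostrings::vcountPattern("N", mr)[[1]], 100)
  expect_equal(length(mr), 4)
  expect_equal(nrow(attr(mr, "provenance")), 3)
  expect_error(build_te_merged_reference(g, NULL, lib, hier[1:2]), "missing")
})

test_that("caller returns nothing without TE evidence and errors unsorted", {
  ev <- data.table::data.table(chrom = "c", pos = c(100L, 500L),
                               strand = "+", mate_class = "reference",
                               mapq = 60L)
  expect_equal(nrow(detect_te_insertions(ev, rng_seed = 1)), 0)
  bad <- data.table::data.table(chrom = "c", pos = c(500L, 100L),
                                strand = "+", mate_class = "famA", mapq = 60L)
  expect_error(detect_te_insertions(bad, rng_seed = 1), "sorted")
})

test_that("signatures too far apart stay unpaired", {
  ## a short pair span keeps signature centers at the anchor clusters:
  ## forward signature ~1000, reverse ~1400, separation 400 > 300
  prm <- signature_params(span = 10L)
  mk <- function(pos, sd) data.table::data.table(
    chrom = "c", pos = pos, strand = sd, mate_class = "famA", mapq = 60L)
  ev <- rbind(mk(c(995L, 1000L, 1005L), "+"), mk(c(1395L, 1400L, 1405L), "-"))
  data.table::setorder(ev, pos)
  out <- detect_te_insertions(ev, prm, rng_seed = 1)
  expect_equal(nrow(out), 2)
  expect_true(all(out$n_signatures == 1L))
  ## bring them within range: one paired insertion near the midpoint
  ev2 <- rbind(mk(c(895L, 900L, 905L), "+"), mk(c(1095L, 1100L, 1105L), "-"))
  data.table::setorder(ev2, pos)
  out2 <- detect_te_insertions(ev2, prm, rng_seed = 1)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$n_signatures, 2L)
  expect_lt(abs(out2$pos - 1000), 60)
})

test_that("subsampling is seed-reproducible and never upsamples", {
  ins <- data.table::data.table(chrom = "simTE", pos = 5000L,
                                family = "famA", frequency = 0.8)
  sim <- simulate_te_evidence(ins, physical_coverage = 30,
                              chrom_length = 10000L, rng_seed = 3)
  a <- detect_te_insertions(sim$evidence, rng_seed = 11)
  b <- detect_te_insertions(sim$evidence, rng_seed = 11)
  expect_identical(a, b)
  ## per-position support is bounded by the target after subsampling
  ## (30x generated, so the bound is active on both signature sides)
  expect_true(all(a$support <= 2 * signature_params()$target_coverage))
  ## no upsampling: a single pair per side stays a single pair and can
  ## never reach the min count of 2
  one <- data.table::data.table(
    chrom = "c", pos = c(4900L, 5100L), strand = c("+", "-"),
    mate_class = "famA", mapq = 60L)
  expect_equal(nrow(detect_te_insertions(one, rng_seed = 1)), 0)
})

test_that("caller recovers synthetic insertions and their frequencies", {
  truth <- te_world(n_per_freq = 10)
  sim <- simulate_te_evidence(truth, physical_coverage = 10,
                              chrom_length = max(truth$pos) + 2000L,
                              rng_seed = 21)
  calls <- detect_te_insertions(sim$evidence, signature_params(),
                                rng_seed = 22)
  m <- match_calls(calls, truth)
  ## spec invariant: frequency MAE < 0.1 at 10x physical coverage
  expect_lt(mean(m$freq_err, na.rm = TRUE), 0.1)
  ## common and fixed insertions are essentially always found
  expect_gt(mean(m$detected[truth$frequency >= 0.4]), 0.95)
})

test_that("unique_insertions applies tolerant cross-population matching", {
  a <- data.table::data.table(chrom = "c", pos = c(100L, 900L),
                              family = "famA", order = "o",
                              frequency = 0.5, support = 10L,
                              n_signatures = 2L)
  b <- data.table::data.table(chrom = "c", pos = 110L, family = "famA",
                              order = "o", frequency = 0.6, support = 10L,
                              n_signatures = 2L)
  u <- unique_insertions(list(A = a, B = b), tolerance = 25L)
  expect_equal(u$A$pos, 900L)   # the 100/110 event is shared
  expect_equal(nrow(u$B), 0)
  u2 <- unique_insertions(list(A = a, B = b), tolerance = 5L)
  expect_equal(nrow(u2$B), 1)   # outside tolerance -> unique to B
  uo <- unique_insertions(list(A = a), tolerance = 25L)
  expect_equal(nrow(uo$A), 2)   # single population: everything unique
  expect_error(unique_insertions(list(A = a), tolerance = -1), "tolerance")
})

test_that("frequency spectrum bookkeeping is exact", {
  fs <- frequency_spectrum(c(0.1, 0.2, 0.6, 1.0), n_bins = 10)
  expect_equal(fs$low_fraction, 0.5)
  expect_equal(fs$high_fraction, 0.5)
  expect_equal(fs$fixed_fraction, 0.25)
  expect_equal(sum(fs$histogram$count), 4)
  all1 <- frequency_spectrum(rep(1, 5))
  expect_equal(all1$fixed_fraction, 1)
  expect_equal(all1$high_fraction, 1)
  empty <- frequency_spectrum(numeric(0))
  expect_true(all(is.na(c(empty$low_fraction, empty$high_fraction,
                          empty$fixed_fraction))))
  expect_error(frequency_spectrum(0.5, n_bins = 1), "n_bins")
})

test_that("landscape puts verbatim reads in bin 0, unmatched reads nowhere", {
  withr::with_seed(8, {
    cons <- random_dna(500)
    junk <- Biostrings::DNAStringSet(vapply(1:5, function(i) random_dna(100),
                                            ""))
  })
  hier <- data.table::data.table(id = "TE1", family = "LINE/R1",
                                 order = "LINE")
  lib <- Biostrings::DNAStringSet(c(TE1 = cons))
  sim <- simulate_te_copies(cons, n_copies = 3, divergence_levels = 0,
                            rng_seed = 2)
  land <- repeat_landscape(sim$reads, lib, hier, sample_coverage = 1,
                           rng_seed = 3)
  expect_equal(land$bin, 0L)
  expect_equal(land$proportion, 1)
  ## junk reads contribute to no bin; proportions sum <= 1
  both <- repeat_landscape(c(sim$reads, junk), lib, hier, sample_coverage = 1,
                           rng_seed = 3)
  expect_lte(sum(both$proportion), 1)
  expect_error(repeat_landscape(sim$reads, Biostrings::DNAStringSet(),
                                hier, 1, rng_seed = 1), "empty")
})

test_that("window composition merges intervals and truncates windows", {
  w <- window_spec(1000, 1000, 1e-4)
  fx <- data.frame(chrom = "s1", start = c(100, 150), end = c(200, 250),
                   class = "exon")
  res <- window_composition(fx, w, c(s1 = 1000))
  expect_equal(res$fraction, 0.151)
  ## invariance to feature order and to splitting into abutting pieces
  fx2 <- data.frame(chrom = "s1", start = c(150, 100, 201),
                    end = c(200, 200, 250), class = "exon")
  expect_equal(window_composition(fx2[sample(3), ], w, c(s1 = 1000))$fraction,
               0.151)
  ## full-repeat window and truncation denominator
  fx3 <- data.frame(chrom = "s1", start = 1, end = 1500, class = "DNA")
  res3 <- window_composition(fx3, w, c(s1 = 1500))
  expect_equal(res3$fraction, c(1, 1))
  expect_equal(res3$end[2] - res3$start[2] + 1, 500)
  ## empty annotation -> zeros
  res4 <- window_composition(fx3[0, ], w, c(s1 = 1000))
  expect_true(nrow(res4) == 0 || all(res4$fraction == 0))
})

test_that("telomere scan counts tandem motifs and flags capped ends", {
  ## a scaffold that is exactly 100 tandem AACCT copies
  ts <- telomere_scan(c(s = strrep("AACCT", 100)), motifs = "AACCT",
                      window = 1000)
  expect_equal(sum(ts$counts$count), 100)
  ## telomere-capped scaffold: both ends flagged, interior not
  withr::with_seed(10, mid <- random_dna(60000))
  capped <- paste0(strrep("AACCT", 2000), mid, strrep("AGGTT", 2000))
  res <- telomere_scan(c(sc1 = capped), motifs = "AACCT", window = 10000)
  expect_true(all(res$ends$enriched))
  interior <- res$counts[res$counts$start > 20000 &
                           res$counts$end < nchar(capped) - 20000, ]
  expect_true(all(interior$count < 25))
  ## motif-free random scaffold: nothing enriched
  res2 <- telomere_scan(c(sc2 = mid), motifs = "AACAGACCCG", window = 10000)
  expect_false(any(res2$ends$enriched))
  expect_error(telomere_scan(c(s = "ACGT"), motifs = "ACGU"), "ACGT")
})
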