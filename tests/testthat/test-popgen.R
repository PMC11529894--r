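pool40 <- pool_spec("p", n_pool = 40, min_count = 1, min_coverage = 2,
                    max_coverage = 1e6)

test_that("site_pi matches hand values and the min-count rule", {
  expect_equal(site_pi(count_row(A = 5, T = 5), pool40), (10 / 9) * 0.5)
  expect_equal(site_pi(count_row(A = 50), pool40), 0)
  p2 <- pool_spec("p", 40, min_count = 2)
  expect_equal(site_pi(count_row(A = 9, T = 1), p2), 0)
  expect_true(is.na(site_pi(count_row(A = 1), pool40)))
})

test_that("site_pi with b=1 equals the brute-force read-pair oracle", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      cv <- sample(2:30, 1)
      k <- as.vector(stats::rmultinom(1, cv, runif(4)))
      est <- site_pi(count_row(k[1], k[2], k[3], k[4]), pool40)
      expect_equal(est, brute_pi(k), tolerance = 1e-12)
    }
  })
})

test_that("pi and theta_w are invariant under nucleotide relabeling", {
  m <- count_row(A = 12, T = 5, C = 2, G = 0)
  perm <- count_row(A = 2, T = 12, C = 0, G = 5)
  p <- pool_spec("p", 40, 2)
  w1 <- window_stats(sites_from(m), p, window_spec(1000, 1000, 1e-4))
  w2 <- window_stats(sites_from(perm), p, window_spec(1000, 1000, 1e-4))
  expect_equal(w1$pi, w2$pi)
  expect_equal(w1$theta_w, w2$theta_w)
})

test_that("window_stats handles empty windows, sorting, and NA masking", {
  m <- rbind(count_row(A = 30), count_row(A = 15, T = 15))
  s <- site_counts("c1", c(10, 20), "A", list(m))
  p <- pool_spec("p", 40, 1)
  w <- window_stats(s, p, window_spec(100, 100, 1e-4))
  expect_equal(w$n_snps, 1L)
  expect_gt(w$pi, 0)
  ## zero-SNP window: pi = theta = 0, D and delta-theta NA
  s0 <- site_counts("c1", c(10, 20), "A",
                    list(rbind(count_row(A = 30), count_row(A = 30))))
  w0 <- window_stats(s0, p, window_spec(100, 100, 1e-4))
  expect_equal(c(w0$pi, w0$theta_w), c(0, 0))
  expect_true(is.na(w0$tajima_d) && is.na(w0$delta_theta))
  ## coverage fraction below threshold -> all NA
  wlow <- window_stats(s, p, window_spec(100, 100, 0.9))
  expect_true(all(is.na(c(wlow$pi, wlow$theta_w, wlow$tajima_d))))
  sbad <- site_counts("c1", c(20, 10), "A", list(m))
  expect_error(window_stats(sbad, p, window_spec(100, 100, 0.5)), "sorted")
})

test_that("delta_theta closed forms and monotonicity", {
  expect_equal(delta_theta(1e-4, 1e-4), 0)
  expect_equal(delta_theta(0, 1e-4), 1)
  expect_equal(round(delta_theta(1.3e-4, 2.2807e-4), 2), 0.43)
  expect_true(is.na(delta_theta(0.1, 0)))
  expect_error(delta_theta(-1e-4, 1e-4), "non-negative")
  ## antitone in pi at fixed theta; isotone in theta at fixed pi
  pis <- seq(0, 5e-4, length.out = 7)
  expect_true(all(diff(delta_theta(pis, 3e-4)) < 0))
  ths <- seq(1e-4, 8e-4, length.out = 7)
  expect_true(all(diff(delta_theta(2e-4, ths)) > 0))
})

test_that("coding-site classification enumerates the genetic code", {
  genome <- c(chr1 = "ATGGGATTTAAACCC")
  feats <- data.table::data.table(chrom = "chr1", start = 1L, end = 12L,
                                  strand = "+", type = "CDS", frame = "0",
                                  attr = "Parent=t1")
  ctx <- classify_coding_sites(feats, genome)
  expect_equal(ctx[ctx$pos == 6, ]$syn_len, 1)          # GGN 3rd pos
  expect_equal(ctx[ctx$pos == 9, ]$syn_len, 1 / 3)      # TTT 3rd pos
  expect_equal(ctx[ctx$pos == 2, ]$syn_len, 0)          # 2nd positions
  expect_equal(ctx[ctx$pos == 5, ]$syn_len, 0)
  ## minus strand: same codons when the segment is reverse-complemented
  genome2 <- c(chr2 = paste0("GG", revcomp("ATGGGATTTAAA"), "AA"))
  feats2 <- data.table::data.table(chrom = "chr2", start = 3L, end = 14L,
                                   strand = "-", type = "CDS", frame = "0",
                                   attr = "Parent=t2")
  ctx2 <- classify_coding_sites(feats2, genome2)
  expect_setequal(unique(ctx2$codon), unique(ctx$codon))
  ## non-multiple-of-3 CDS errors unless flagged incomplete
  bad <- data.table::data.table(chrom = "chr1", start = 1L, end = 11L,
                                strand = "+", type = "CDS", frame = "0",
                                attr = "Parent=t3")
  expect_error(classify_coding_sites(bad, genome), "divisible")
  flagged <- data.table::copy(bad)[, attr := "Parent=t3;note=incomplete"]
  expect_silent(classify_coding_sites(flagged, genome))
})

test_that("windowed piS/piNS use site-length denominators", {
  genome <- c(chr1 = "ATGGGATTTAAACCCCCCCC")
  feats <- data.table::data.table(chrom = "chr1", start = 1L, end = 12L,
                                  strand = "+", type = "CDS", frame = "0",
                                  attr = "Parent=t1")
  ctx <- classify_coding_sites(feats, genome)
  ref <- strsplit(genome[[1]], "")[[1]]
  cnt <- matrix(0L, 20, 6, dimnames = list(NULL, c("A","T","C","G","N","del")))
  for (i in 1:20) cnt[i, ref[i]] <- 30L
  cnt[6, ] <- c(5L, 5L, 0L, 0L, 0L, 0L)   # GGA <-> GGT, synonymous
  s <- site_counts("chr1", 1:20, ref, list(cnt))
  res <- window_pi_syn_nonsyn(s, ctx, pool_spec("p", 40, 1, 2),
                              window_spec(1000, 1000, 1e-3))
  expect_equal(res$pi_syn, (10 / 9) * 0.5 / sum(ctx$syn_len))
  expect_equal(res$pi_nonsyn, 0)
  ## no CDS -> empty/NA
  res2 <- window_pi_syn_nonsyn(s, ctx[0], pool_spec("p", 40, 1, 2),
                               window_spec(1000, 1000, 1e-3))
  expect_equal(nrow(res2), 0)
})
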