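test_that("mu = 0 yields no true variants and errors stay sub-threshold", {
  dem <- demography_model(mu = 0)
  sim <- simulate_pool_seq(dem, seq_params(L = 20000L, mean_coverage = 60,
                                           error_rate = 0.001,
                                           pool_sizes = c(p = 40L)),
                           rng_seed = 1)
  expect_equal(length(sim$truth$variant_pos), 0)
  w <- window_stats(sim$sites, pool_spec("p", 40, 2, 4, 1e4),
                    window_spec(20000, 20000, 0.5))
  ## same-base error doubletons slip past min-count 2 at a rate of
  ## ~C(60,2) e^2 / 3 ~ 6e-4 per site; the resulting theta must stay an
  ## order of magnitude below a real signal of 0.005
  expect_lt(w$theta_w, 1e-3)
})

test_that("same seed gives byte-identical outputs", {
  dem <- demography_model()
  sq <- seq_params(L = 5000L, pool_sizes = c(a = 10L, b = 12L))
  s1 <- simulate_pool_seq(dem, sq, rng_seed = 42)
  s2 <- simulate_pool_seq(dem, sq, rng_seed = 42)
  expect_identical(write_sync(s1$sites), write_sync(s2$sites))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_pool_seq(dem, sq, rng_seed = 43)
  expect_false(identical(write_sync(s1$sites), write_sync(s3$sites)))
  ## TE evidence and TE copies are deterministic too
  ins <- data.table::data.table(chrom = "t", pos = 5000L, family = "famA",
                                frequency = 0.5)
  e1 <- simulate_te_evidence(ins, 10, 10000L, rng_seed = 9)
  e2 <- simulate_te_evidence(ins, 10, 10000L, rng_seed = 9)
  expect_identical(e1$evidence, e2$evidence)
  r1 <- simulate_te_copies("ACGTACGTACGTACGTACGT", 2, 0.1, 10, rng_seed = 3)
  r2 <- simulate_te_copies("ACGTACGTACGTACGTACGT", 2, 0.1, 10, rng_seed = 3)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
})

test_that("every emitted variant has a truth twin (truth coverage)", {
  sim <- simulate_pool_seq(demography_model(),
                           seq_params(L = 50000L, error_rate = 0,
                                      pool_sizes = c(a = 30L, b = 30L)),
                           rng_seed = 7)
  st <- poolscape:::site_state(sim$sites$counts[[1]],
                               pool_spec("a", 30, 2, 4, 1e4))
  snp_pos <- sim$sites$pos[st$snp]
  ## with zero sequencing error every read-level SNP is a true variant
  expect_true(all(snp_pos %in% sim$truth$variant_pos))
  expect_equal(ncol(sim$truth$pool_freqs), 2)
  expect_true(all(sim$truth$pool_freqs >= 0 & sim$truth$pool_freqs <= 1))
})

test_that("two-stage sampling collapses to binomial for huge pools", {
  p <- rep(0.3, 4000)
  big <- sample_pool_reads(p, n_pool = 10000, coverage = 50, rng_seed = 1)
  ## read counts should match Binomial(50, 0.3) quantiles closely
  qs <- stats::quantile(big$derived_reads, c(0.1, 0.25, 0.5, 0.75, 0.9))
  qb <- stats::qbinom(c(0.1, 0.25, 0.5, 0.75, 0.9), 50, 0.3)
  expect_true(all(abs(qs - qb) <= 1))
  ## and the variance must NOT carry the extra pool-stage term
  v <- stats::var(big$derived_reads)
  vbin <- 50 * 0.3 * 0.7
  expect_lt(abs(v - vbin) / vbin, 0.15)
  ## small pools are overdispersed relative to binomial
  small <- sample_pool_reads(p, n_pool = 10, coverage = 50, rng_seed = 2)
  expect_gt(stats::var(small$derived_reads), 1.5 * vbin)
})

test_that("founder worlds show the introduction signature at desk scale", {
  sim <- simulate_pool_seq(demography_model(),
                           seq_params(L = 200000L, pool_sizes = c(p = 40L)),
                           rng_seed = 31)
  w <- window_stats(sim$sites, pool_spec("p", 40, 2, 4, 1e4),
                    window_spec(50000, 50000, 0.5))
  expect_lt(mean(w$tajima_d), 0)
  expect_gt(mean(w$delta_theta), 0.25)
})

test_that("TE evidence generator respects the frequency contract", {
  ## f = 0 everywhere -> no TE-classed pairs -> caller returns nothing
  ins0 <- data.table::data.table(chrom = "t", pos = c(3000L, 6000L),
                                 family = "famA", frequency = 0)
  sim0 <- simulate_te_evidence(ins0, 10, 10000L, rng_seed = 5)
  expect_equal(nrow(detect_te_insertions(sim0$evidence, rng_seed = 1)), 0)
  ## f = 1 -> frequency estimate exactly 1
  ins1 <- data.table::data.table(chrom = "t", pos = 5000L, family = "famA",
                                 frequency = 1)
  sim1 <- simulate_te_evidence(ins1, 10, 10000L, rng_seed = 6)
  call1 <- detect_te_insertions(sim1$evidence, rng_seed = 2)
  expect_equal(nrow(call1), 1)
  expect_equal(call1$frequency, 1)
})

test_that("mpileup writer round-trips through the reader", {
  withr::with_seed(13, m <- random_counts(50))
  s <- site_counts("sc1", 1:50, sample(NUC4, 50, TRUE), list(m))
  back <- read_mpileup(write_mpileup(s), n_pools = 1)
  expect_identical(unname(back$counts[[1]][, 1:4]), unname(m[, 1:4]))
})
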