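mkpools <- function() list(pool_spec("a", 40, 2, 2), pool_spec("b", 40, 2, 2))
w1k <- window_spec(1000, 1000, 1e-4)

two_pool_sites <- function(m1, m2, pos = seq_len(nrow(m1))) {
  site_counts("c1", pos, "A", list(m1, m2))
}

test_that("FST analytic cases", {
  ## identical 50:50 pools -> 0
  m <- count_row(A = 50, T = 50)
  f0 <- window_fst(two_pool_sites(m, m), mkpools(), w1k)
  expect_equal(f0$fst, 0)
  ## fixed difference at c=100 -> exactly 1 (pi_within = 0)
  f1 <- window_fst(two_pool_sites(count_row(A = 100), count_row(T = 100)),
                   mkpools(), w1k)
  expect_equal(f1$fst, 1)
  ## hand-computed heterozygosities: 75:25 vs 25:75 at c=100
  f2 <- window_fst(two_pool_sites(count_row(A = 75, T = 25),
                                  count_row(A = 25, T = 75)),
                   mkpools(), w1k)
  piw <- (100 / 99) * (1 - 0.75^2 - 0.25^2)    # 0.378788 per pool
  pit <- (100 / 99) * 0.5                      # 0.505051 pooled
  expect_equal(piw, 0.3787879, tolerance = 1e-6)
  expect_equal(pit, 0.5050505, tolerance = 1e-6)
  expect_equal(f2$fst, (pit - piw) / pit, tolerance = 1e-9)
  ## symmetric in pool order; no-SNP window is NA
  f2r <- window_fst(two_pool_sites(count_row(A = 25, T = 75),
                                   count_row(A = 75, T = 25)),
                    rev(mkpools()), w1k, pool_indices = c(2L, 1L))
  expect_equal(f2$fst, f2r$fst)
  fna <- window_fst(two_pool_sites(count_row(A = 40), count_row(A = 40)),
                    mkpools(), w1k)
  expect_true(is.na(fna$fst))
  expect_error(window_fst(two_pool_sites(m, m),
                          list(pool_spec("a", 40), pool_spec("a", 40)), w1k),
               "distinct")
})

test_that("dXY counts differing major alleles and is deterministic", {
  m1 <- do.call(rbind, rep(list(count_row(A = 10)), 10))
  m2 <- rbind(do.call(rbind, rep(list(count_row(T = 10)), 3)),
              do.call(rbind, rep(list(count_row(A = 10)), 7)))
  d <- window_dxy(two_pool_sites(m1, m2), mkpools(), w1k)
  expect_equal(d$dxy, 0.3)
  expect_equal(d$n_joint_sites, 10L)
  ## identical pools -> 0 for any seed
  for (sd in c(1, 99)) {
    d0 <- window_dxy(two_pool_sites(m2, m2), mkpools(), w1k, rng_seed = sd)
    expect_equal(d0$dxy, 0)
  }
})

test_that("dXY tie handling: seeded, reproducible, fair", {
  tied <- two_pool_sites(count_row(A = 50, T = 50), count_row(T = 100))
  expect_error(window_dxy(tied, mkpools(), w1k), "rng_seed")
  r1 <- window_dxy(tied, mkpools(), w1k, rng_seed = 7)
  r2 <- window_dxy(tied, mkpools(), w1k, rng_seed = 7)
  expect_identical(r1, r2)
  ## brute force over both tie outcomes: expected contribution 0.5
  draws <- vapply(1:400, function(sd)
    window_dxy(tied, mkpools(), w1k, rng_seed = sd)$dxy, numeric(1))
  expect_setequal(unique(draws), c(0, 1))
  expect_equal(mean(draws), 0.5, tolerance = 0.08)
})

test_that("dXY increases with divergence time (rank correlation)", {
  ## grid spans well past 2N generations so drift + new mutations separate
  ## the points beyond sampling noise
  tgrid <- c(100, 400, 1600, 6400, 25600)
  dxy <- vapply(seq_along(tgrid), function(i) {
    dem <- demography_model(N0 = 500, Nb = 500, Nc = 500,
                            T_found = tgrid[i], mu = 2.5e-6)
    sim <- simulate_pool_seq(dem, seq_params(
      L = 100000L, mean_coverage = 40, error_rate = 0,
      pool_sizes = c(p1 = 30L, p2 = 30L)), rng_seed = 100 + i)
    d <- window_dxy(sim$sites, list(pool_spec("p1", 30, 2, 2, 1e3),
                                    pool_spec("p2", 30, 2, 2, 1e3)),
                    window_spec(100000, 100000, 0.5),
                    pool_indices = c(1L, 2L), rng_seed = 5)
    d$dxy
  }, numeric(1))
  expect_gt(stats::cor(tgrid, dxy, method = "spearman"), 0.9)
})
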