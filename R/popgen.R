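## Pooling-corrected diversity estimators.
##
## Pool-seq read counts are a two-stage sample: n_pool genomes drawn from the
## population, then c reads drawn (with error) from the pool. A minimum allele
## count b suppresses sequencing errors but also hides genuine rare variants.
## The correction factors below are expectations, under the neutral site
## frequency spectrum, over the allele-count configurations that remain
## detectable at threshold b given coverage c and pool size n. They are
## memoized per (b, c, n).

.corr_cache <- new.env(parent = emptyenv())

## Detectability-weighted heterozygosity mass: for pool allele count k
## (prior 1/k), reads m ~ Binom(c, k/n) restricted to b <= m <= c-b,
## weighted by the read-level heterozygosity 2m(c-m)/(c(c-1)).
pidiv_raw <- function(b, c, n) {
  if (c < 2L || n < 2L) return(NA_real_)
  if (c - b < b) return(0)
  m <- b:(c - b)
  k <- seq_len(n - 1L)
  wm <- 2 * m * (c - m) / (c * (c - 1))
  acc <- 0
  for (kk in k) {
    acc <- acc + sum(stats::dbinom(m, c, kk / n) * wm) / kk
  }
  acc
}

## Expected detectable segregating-site mass per unit theta (the pooled
## analogue of Watterson's harmonic-number denominator a1).
thetadiv <- function(b, c, n) {
  key <- paste0("t", b, ".", c, ".", n)
  hit <- .corr_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (c < 2L || n < 2L || c - b < b) NA_real_ else {
    m <- b:(c - b)
    k <- seq_len(n - 1L)
    acc <- 0
    for (kk in k) acc <- acc + sum(stats::dbinom(m, c, kk / n)) / kk
    acc
  }
  assign(key, val, envir = .corr_cache)
  val
}

## Fraction of read-level heterozygosity that survives the min-count filter:
## pidiv(b)/pidiv(1). pidiv(1, c, n) == (n-1)/n analytically (the boundary
## terms m = 0 and m = c carry zero heterozygosity weight), so b <= 1
## short-circuits to exactly 1 and site_pi at b = 1 is the raw mean pairwise
## difference among reads.
pi_correction <- function(b, c, n) {
  if (b <= 1L) return(1)
  key <- paste0("p", b, ".", c, ".", n)
  hit <- .corr_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- pidiv_raw(b, c, n) / ((n - 1) / n)
  assign(key, val, envir = .corr_cache)
  val
}

#' Pool metadata
#'
#' @param name pool/population label.
#' @param n_pool number of haploid genomes in the pool (the value handed to
#'   the estimator; the run manifest records it verbatim).
#' @param min_count minimum allele count b for a variant to be believed.
#' @param min_coverage,max_coverage per-site coverage bounds; sites outside
#'   are invalid and excluded from window denominators.
#' @export
pool_spec <- function(name, n_pool, min_count = 2L, min_coverage = 4L,
                      max_coverage = .Machine$integer.max) {
  stopifnot(n_pool >= 2L, min_count >= 1L, min_coverage <= max_coverage)
  structure(list(name = as.character(name), n_pool = as.integer(n_pool),
                 min_count = as.integer(min_count),
                 min_coverage = as.integer(min_coverage),
                 max_coverage = as.integer(max_coverage)),
            class = "pool_spec")
}

#' Window specification
#' @param size window size in bp (default 100 kb, nonoverlapping).
#' @param step step size; must equal `size` (nonoverlapping windows).
#' @param min_covered_fraction windows with fewer valid sites than this
#'   fraction of the window length get NA statistics; default 0.6.
#' @export
window_spec <- function(size = 100000L, step = size,
                        min_covered_fraction = 0.6) {
  stopifnot(size >= 1L, step == size,
            min_covered_fraction > 0, min_covered_fraction <= 1)
  structure(list(size = as.integer(size), step = as.integer(step),
                 min_covered_fraction = min_covered_fraction),
            class = "window_spec")
}

## Per-site state for one pool: coverage, validity, SNP flag, effective
## counts, corrected site pi and per-SNP Watterson mass. Vectorized.
site_state <- function(counts, pool) {
  m <- counts[, NUCS, drop = FALSE]
  cov <- rowSums(m)
  valid <- cov >= pool$min_coverage & cov <= pool$max_coverage & cov >= 2L
  eff <- m * (m >= pool$min_count)
  ceff <- rowSums(eff)
  nall <- rowSums(eff > 0L)
  snp <- valid & nall >= 2L
  h <- numeric(nrow(m))
  if (any(snp)) {
    cs <- ceff[snp]
    sq <- rowSums((eff[snp, , drop = FALSE] / cs)^2)
    h[snp] <- (cs / (cs - 1)) * (1 - sq)
  }
  ## corrections per unique coverage
  pi_corr <- rep(1, nrow(m))
  th <- rep(NA_real_, nrow(m))
  if (any(snp)) {
    for (cv in unique(cov[snp])) {
      idx <- snp & cov == cv
      pi_corr[idx] <- pi_correction(pool$min_count, cv, pool$n_pool)
      th[idx] <- 1 / thetadiv(pool$min_count, cv, pool$n_pool)
    }
  }
  pi <- h / pi_corr
  pi[!valid] <- NA_real_
  th[!snp] <- 0
  th[!valid] <- NA_real_
  list(coverage = cov, valid = valid, snp = snp, pi = pi, theta = th,
       eff = eff)
}

#' Corrected per-site heterozygosity for pooled reads
#'
#' With effective counts `c_a` (alleles below `min_count` removed) over
#' coverage `c`, returns the read-sampling-unbiased heterozygosity
#' `(c/(c-1)) (1 - sum((c_a/c)^2))` divided by the min-count detection
#' correction (the expected fraction of heterozygosity observable at
#' threshold b given c and n_pool). At `min_count = 1` this equals the mean
#' pairwise difference over all read pairs exactly.
#'
#' @param counts a 6-vector (A,T,C,G,N,del) or a sites x 6 matrix.
#' @param pool a [pool_spec()]. Coverage bounds in the spec are ignored here;
#'   only `min_count` and `n_pool` matter.
#' @return numeric vector of per-site pi; NA where coverage < 2.
#' @export
site_pi <- function(counts, pool) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, COUNT_COLS))
  p2 <- pool
  p2$min_coverage <- 2L
  p2$max_coverage <- .Machine$integer.max
  site_state(counts, p2)$pi
}

#' The bottleneck statistic delta-theta = 1 - pi/theta
#'
#' Approaches 1 immediately after a strong bottleneck (rare variants dominate,
#' pi << theta) and decays toward 0 as variants rise in frequency.
#'
#' @param pi,theta non-negative per-site diversity estimates (vectorized).
#' @return `1 - pi/theta`; NA where theta is 0 or either input is NA.
#' @export
delta_theta <- function(pi, theta) {
  if (any(pi < 0, na.rm = TRUE) || any(theta < 0, na.rm = TRUE))
    stop("pi and theta must be non-negative")
  out <- 1 - pi / theta
  out[!is.na(theta) & theta == 0] <- NA_real_
  out
}

tajima_constants <- function(n) {
  ## real-valued n via digamma/trigamma so a coverage-weighted effective
  ## sample size can be plugged in directly
  a1 <- digamma(n) - digamma(1)
  a2 <- trigamma(1) - trigamma(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed pool-seq diversity statistics
#'
#' Per nonoverlapping window: per-site pi (mean corrected site heterozygosity
#' over valid sites), per-site Watterson's theta (detection-corrected
#' segregating-site mass over valid sites), Tajima's D, and
#' delta-theta = 1 - pi/theta_w. Windows whose covered fraction falls below
#' `window$min_covered_fraction` are reported with NA statistics.
#'
#' Tajima's D convention under pooling: the variance constants use an
#' effective sample size `n_eff = min(n_pool, c)` aggregated per window by the
#' coverage-weighted mean, and the theta term of the numerator is scaled by
#' `(n_pool-1)/n_pool` so both numerator terms estimate the same quantity and
#' E[D] is ~0 at neutral equilibrium (see the methods vignette).
#'
#' @param sites a `site_counts` object sorted by (chrom, pos).
#' @param pool a [pool_spec()].
#' @param window a [window_spec()].
#' @param pool_index which pool column of `sites` to use; default 1.
#' @param mask optional `mask_intervals` applied before estimation.
#' @param chrom_lengths optional named vector of scaffold lengths used to
#'   truncate the final window's denominator.
#' @return `data.table` with one row per window: chrom, start, end,
#'   n_valid_sites, n_snps, covered_fraction, pi, theta_w, tajima_d,
#'   delta_theta.
#' @export
window_stats <- function(sites, pool, window = window_spec(),
                         pool_index = 1L, mask = NULL, chrom_lengths = NULL) {
  if (!is.null(mask)) sites <- apply_mask(sites, mask)
  check_sorted(sites)
  st <- site_state(sites$counts[[pool_index]], pool)
  dt <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos,
    valid = st$valid, snp = st$snp, pi = st$pi, theta = st$theta,
    cov = st$coverage)
  dt[, win := (pos - 1L) %/% window$size]
  agg <- dt[, {
    v <- valid
    list(n_valid_sites = sum(v),
         n_snps = sum(snp),
         pi_sum = sum(pi[v]),
         theta_sum = sum(theta[v]),
         cov_sum = sum(cov[v]),
         neff_wsum = sum(pmin(pool$n_pool, cov[v]) * cov[v]))
  }, by = .(chrom, win)]
  agg[, start := win * window$size + 1L]
  agg[, end := (win + 1L) * window$size]
  agg[, wlen := as.numeric(window$size)]
  if (!is.null(chrom_lengths)) {
    agg[chrom %in% names(chrom_lengths),
        wlen := pmin(wlen, chrom_lengths[chrom] - start + 1)]
    agg[, end := as.integer(start + wlen - 1)]
  }
  agg[, covered_fraction := n_valid_sites / wlen]
  agg[, `:=`(pi = pi_sum / n_valid_sites, theta_w = theta_sum / n_valid_sites)]
  agg[n_valid_sites == 0L, `:=`(pi = NA_real_, theta_w = NA_real_)]
  ## Tajima's D
  agg[, tajima_d := {
    D <- rep(NA_real_, .N)
    ok <- n_snps > 0L & cov_sum > 0
    if (any(ok)) {
      neff <- neff_wsum[ok] / cov_sum[ok]
      neff <- pmax(neff, 2.000001)
      k <- tajima_constants(neff)
      S <- as.numeric(n_snps[ok])
      num <- pi_sum[ok] - theta_sum[ok] * (pool$n_pool - 1) / pool$n_pool
      den <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
      D[ok] <- ifelse(den > 0, num / den, NA_real_)
    }
    D
  }]
  agg[, delta_theta := delta_theta(pmax(pi, 0), pmax(theta_w, 0))]
  agg[n_snps == 0L & n_valid_sites > 0L, delta_theta := NA_real_]
  low <- agg$covered_fraction < window$min_covered_fraction
  for (col in c("pi", "theta_w", "tajima_d", "delta_theta"))
    agg[low, (col) := NA_real_]
  out <- agg[, .(chrom, start, end, n_valid_sites, n_snps, covered_fraction,
                 pi, theta_w, tajima_d, delta_theta)]
  data.table::setorder(out, chrom, start)
  out[]
}

check_sorted <- function(sites) {
  if (length(sites$pos) < 2L) return(invisible(TRUE))
  o <- order(sites$chrom, sites$pos, method = "radix")
  if (!identical(o, seq_along(sites$pos)))
    stop("sites must be sorted by (chrom, pos)")
  invisible(TRUE)
}
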