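## Between-population statistics: windowed pairwise FST and major-allele
## absolute divergence dXY. Joint sites must satisfy each pool's own coverage
## bounds; no rescaling to a common coverage is attempted.

joint_site_state <- function(sites, pools, pool_indices) {
  m1 <- sites$counts[[pool_indices[1L]]][, NUCS, drop = FALSE]
  m2 <- sites$counts[[pool_indices[2L]]][, NUCS, drop = FALSE]
  c1 <- rowSums(m1); c2 <- rowSums(m2)
  valid <- c1 >= pools[[1L]]$min_coverage & c1 <= pools[[1L]]$max_coverage &
    c2 >= pools[[2L]]$min_coverage & c2 <= pools[[2L]]$max_coverage &
    c1 >= 2L & c2 >= 2L
  list(m1 = m1, m2 = m2, c1 = c1, c2 = c2, valid = valid)
}

#' Windowed pairwise FST between two pools
#'
#' Per SNP (called from the combined pools at `min_count`),
#' `FST = (pi_total - mean(pi_within)) / pi_total` with read-frequency
#' heterozygosities carrying the small-sample factor `c/(c-1)` per pool, and
#' `min(c1, c2)/(min(c1, c2)-1)` on the heterozygosity of the pooled counts.
#' Negative per-SNP estimates are clamped to 0 before window averaging.
#'
#' @param sites `site_counts` sorted by (chrom, pos).
#' @param pools list of two [pool_spec()]s with distinct names.
#' @param window a [window_spec()].
#' @param pool_indices columns of `sites` holding the two pools.
#' @param min_count combined min count for the SNP call; default 2.
#' @return `data.table` (chrom, start, end, pop_a, pop_b, fst, n_snps,
#'   n_joint_sites); `fst` NA where a window holds no SNPs.
#' @export
window_fst <- function(sites, pools, window = window_spec(),
                       pool_indices = c(1L, 2L), min_count = 2L) {
  if (pools[[1L]]$name == pools[[2L]]$name)
    stop("pool pair must have distinct names")
  check_sorted(sites)
  ## canonical orientation so the statistic is symmetric by construction
  if (pools[[1L]]$name > pools[[2L]]$name) {
    pools <- pools[c(2L, 1L)]; pool_indices <- pool_indices[c(2L, 1L)]
  }
  js <- joint_site_state(sites, pools, pool_indices)
  comb <- js$m1 + js$m2
  keep <- comb * (comb >= min_count)
  snp <- js$valid & rowSums(keep > 0L) >= 2L
  fst_site <- rep(NA_real_, length(snp))
  if (any(snp)) {
    k1 <- js$m1[snp, , drop = FALSE] * (keep[snp, , drop = FALSE] > 0L)
    k2 <- js$m2[snp, , drop = FALSE] * (keep[snp, , drop = FALSE] > 0L)
    e1 <- rowSums(k1); e2 <- rowSums(k2)
    h1 <- (e1 / (e1 - 1)) * (1 - rowSums((k1 / e1)^2))
    h2 <- (e2 / (e2 - 1)) * (1 - rowSums((k2 / e2)^2))
    cmin <- pmin(e1, e2)
    et <- e1 + e2
    ht <- (cmin / (cmin - 1)) * (1 - rowSums(((k1 + k2) / et)^2))
    f <- (ht - (h1 + h2) / 2) / ht
    f[ht <= 0] <- 0
    fst_site[snp] <- pmin(1, pmax(0, f))
  }
  dt <- data.table::data.table(chrom = sites$chrom, pos = sites$pos,
                               valid = js$valid, snp = snp, fst = fst_site)
  dt[, win := (pos - 1L) %/% window$size]
  agg <- dt[, .(n_joint_sites = sum(valid), n_snps = sum(snp),
                fst = if (sum(snp)) mean(fst[snp]) else NA_real_),
            by = .(chrom, win)]
  finish_pair_table(agg, window, pools)
}

#' Windowed major-allele absolute divergence (dXY)
#'
#' At each jointly valid site the most abundant allele of each pool is
#' selected (ties broken uniformly at random with the seeded generator);
#' dXY is the fraction of sites whose selected alleles differ. By default all
#' jointly valid sites enter the denominator (monomorphic sites contribute 0
#' unless the major alleles differ); `snps_only` restricts to SNPs.
#'
#' @inheritParams window_fst
#' @param rng_seed integer seed used for tie-breaking; required whenever ties
#'   exist (reproducibility contract).
#' @param snps_only restrict to sites that are SNPs in the combined pools.
#' @return `data.table` (chrom, start, end, pop_a, pop_b, dxy, n_joint_sites).
#' @export
window_dxy <- function(sites, pools, window = window_spec(),
                       pool_indices = c(1L, 2L), rng_seed = NULL,
                       snps_only = FALSE, min_count = 2L) {
  if (pools[[1L]]$name == pools[[2L]]$name)
    stop("pool pair must have distinct names")
  check_sorted(sites)
  if (pools[[1L]]$name > pools[[2L]]$name) {
    pools <- pools[c(2L, 1L)]; pool_indices <- pool_indices[c(2L, 1L)]
  }
  js <- joint_site_state(sites, pools, pool_indices)
  use <- js$valid
  if (snps_only) {
    comb <- js$m1 + js$m2
    keep <- comb * (comb >= min_count)
    use <- use & rowSums(keep > 0L) >= 2L
  }
  maj1 <- major_allele(js$m1, use, rng_seed)
  maj2 <- major_allele(js$m2, use, rng_seed)
  dt <- data.table::data.table(chrom = sites$chrom, pos = sites$pos,
                               use = use, diff = maj1 != maj2)
  dt[, win := (pos - 1L) %/% window$size]
  agg <- dt[, .(n_joint_sites = sum(use),
                dxy = if (sum(use)) sum(diff[use]) / sum(use) else NA_real_),
            by = .(chrom, win)]
  finish_pair_table(agg, window, pools)
}

## index of the most abundant nucleotide per row; ties resolved uniformly
## with the seeded generator (error if ties exist but no seed was given)
major_allele <- function(m, use, rng_seed) {
  mx <- pmax(m[, 1L], m[, 2L], m[, 3L], m[, 4L])
  n_top <- rowSums(m == mx)
  out <- max.col(m, ties.method = "first")
  tied <- use & n_top > 1L & mx > 0L
  if (any(tied)) {
    if (is.null(rng_seed))
      stop("rng_seed is required: major-allele ties present")
    picks <- with_seed(rng_seed, {
      vapply(which(tied), function(i) {
        cand <- which(m[i, ] == mx[i])
        cand[sample.int(length(cand), 1L)]
      }, integer(1L))
    })
    out[tied] <- picks
  }
  out
}

finish_pair_table <- function(agg, window, pools) {
  agg[, start := win * window$size + 1L]
  agg[, end := (win + 1L) * window$size]
  agg[, pop_a := pools[[1L]]$name]
  agg[, pop_b := pools[[2L]]$name]
  agg[, win := NULL]
  data.table::setcolorder(agg, c("chrom", "start", "end", "pop_a", "pop_b"))
  data.table::setorder(agg, chrom, start)
  agg[]
}
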