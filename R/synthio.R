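## Synthetic pool-seq and TE evidence with complete ground truth.
##
## The generator states a world resembling the study system: a handful of
## pooled populations founded recently from a common source through a severe
## propagule bottleneck, resequenced as pools to >60x with a small sequencing
## error rate. Population samples come from a per-block coalescent with
## piecewise demography (exponential recovery since founding, constant
## ancestral size before); pooled reads are the second sampling stage.

#' Demography model for the synthetic generator
#'
#' Sizes are diploid population sizes; pairwise coalescence rate is
#' `1/(2N(t))` per generation for haploid lineages. Backward in time each
#' population shrinks exponentially from `Nc` (present) to `Nb` at the
#' founding time `T_found`, at which point all populations merge into a
#' panmictic ancestral population of size `N0`.
#'
#' Defaults state a severe insect introduction: a propagule of ~5 founders
#' 180 generations ago (the study system's introduction history at ~5
#' generations/year), an outbreak recovery overshooting the small source
#' population (Nc = 4*N0), ancestral theta = 4*N0*mu = 0.005. The founding
#' phase must prune the sampled genealogy to ~1 surviving lineage for the
#' introduction signature (excess rare alleles, strongly negative Tajima's
#' D, high delta-theta) to emerge; the cumulative pairwise founding hazard
#' `T/(2*Nb*log(Nc/Nb))` is ~3 under these defaults, so deep ancestral
#' variation survives in only a few percent of blocks and the world's true
#' delta-theta sits near 0.5 (a pool of 40 caps delta-theta at
#' `1 - 2*a1/n` ~ 0.79 even for a pure star genealogy). `T_found = 0` (with
#' `Nb = Nc = N0`) gives the neutral equilibrium world.
#'
#' @param N0 ancestral diploid size.
#' @param Nb founder (bottleneck) size.
#' @param T_found founding time in generations before present.
#' @param Nc present diploid size (exponential recovery target).
#' @param mu per-site per-generation mutation rate.
#' @param F optional inbreeding coefficient; implemented as a reduction of
#'   the number of distinct lineages drawn per pool to
#'   `round(n_pool*(1-F)) + 1`.
#' @export
demography_model <- function(N0 = 500, Nb = 5, T_found = 180, Nc = 2000,
                             mu = 2.5e-6, F = 0) {
  stopifnot(N0 >= 2, Nb >= 2, Nc >= 2, T_found >= 0, mu >= 0, F >= 0, F <= 1)
  structure(list(N0 = N0, Nb = Nb, T_found = T_found, Nc = Nc, mu = mu,
                 F = F), class = "demography_model")
}

#' @rdname demography_model
#' @param theta ancestral scaled mutation rate 4*N0*mu.
#' @export
demography_equilibrium <- function(theta = 0.005, N0 = 1000) {
  demography_model(N0 = N0, Nb = N0, T_found = 0, Nc = N0,
                   mu = theta / (4 * N0))
}

#' Sequencing parameters for the synthetic generator
#' @param L region length in bp.
#' @param mean_coverage mean per-pool Poisson coverage (study design: >60x).
#' @param error_rate per-read-base error probability, redistributed uniformly
#'   to the other three bases; default 0.001 (~Q30).
#' @param pool_sizes named integer vector of haploid genomes per pool;
#'   defaults mirror the four study pools.
#' @export
seq_params <- function(L = 500000L, mean_coverage = 60,
                       error_rate = 0.001,
                       pool_sizes = c(BH = 40L, KP = 21L, MO = 33L, RH = 40L)) {
  stopifnot(L >= 1, error_rate >= 0, error_rate <= 0.05, mean_coverage > 0,
            all(pool_sizes >= 2))
  if (is.null(names(pool_sizes)))
    names(pool_sizes) <- paste0("pool", seq_along(pool_sizes))
  structure(list(L = as.integer(L), mean_coverage = mean_coverage,
                 error_rate = error_rate,
                 pool_sizes = as.integer(stats::setNames(pool_sizes,
                                                         names(pool_sizes)))),
            class = "seq_params")
}

## --------------------------------------------------------------- genealogy --

## Coalescent genealogy for one non-recombining block: K demes, each with
## n_by_pop lineages, exponential recovery on [0, T_found) backward, then a
## panmictic ancestral deme of size N0. Returns branch lengths (generations)
## and the per-deme descendant-count matrix of each branch.
simulate_genealogy <- function(n_by_pop, model) {
  K <- length(n_by_pop)
  blen <- numeric(0)
  bdesc <- matrix(0L, nrow = K, ncol = 0L)
  demes <- vector("list", K)
  for (j in seq_len(K)) {
    D <- matrix(0L, nrow = K, ncol = n_by_pop[j])
    D[j, ] <- 1L
    demes[[j]] <- list(D = D, birth = numeric(n_by_pop[j]))
  }
  Tf <- model$T_found
  if (Tf > 0) {
    r <- log(model$Nc / model$Nb) / Tf
    for (j in seq_len(K)) {
      st <- demes[[j]]
      t <- 0
      while (ncol(st$D) > 1L) {
        k <- ncol(st$D)
        pairs <- k * (k - 1) / 2
        E <- stats::rexp(1)
        tnew <- if (abs(r) < 1e-12) {
          t + E * 2 * model$Nc / pairs
        } else {
          arg <- exp(r * t) + 2 * model$Nc * r * E / pairs
          if (arg <= 0) Inf else log(arg) / r
        }
        if (is.na(tnew) || tnew >= Tf) break
        t <- tnew
        ij <- sample.int(k, 2L)
        merged <- merge_lineages(st, ij, t)
        blen <- c(blen, merged$lens)
        bdesc <- cbind(bdesc, merged$desc)
        st <- merged$state
      }
      demes[[j]] <- st
    }
  }
  ## pool survivors into the ancestral deme
  D <- do.call(cbind, lapply(demes, `[[`, "D"))
  birth <- unlist(lapply(demes, `[[`, "birth"))
  st <- list(D = D, birth = birth)
  t <- Tf
  while (ncol(st$D) > 1L) {
    k <- ncol(st$D)
    t <- t + stats::rexp(1) * 2 * model$N0 / (k * (k - 1) / 2)
    ij <- sample.int(k, 2L)
    merged <- merge_lineages(st, ij, t)
    blen <- c(blen, merged$lens)
    bdesc <- cbind(bdesc, merged$desc)
    st <- merged$state
  }
  list(len = blen, desc = bdesc)
}

merge_lineages <- function(st, ij, t) {
  lens <- t - st$birth[ij]
  desc <- st$D[, ij, drop = FALSE]
  newD <- st$D[, ij[1L], drop = FALSE] + st$D[, ij[2L], drop = FALSE]
  keep <- setdiff(seq_len(ncol(st$D)), ij)
  list(lens = lens, desc = desc,
       state = list(D = cbind(st$D[, keep, drop = FALSE], newD),
                    birth = c(st$birth[keep], t)))
}

## --------------------------------------------------------- pool-seq reads --

#' Simulate a pool-seq dataset with ground truth
#'
#' Stage 1 draws, per block of `block_len` bp, a coalescent genealogy of the
#' pooled lineages under the demography and drops infinite-sites mutations on
#' it; the coalescent sample of `n_pool` lineages per pool *is* the draw of
#' pool genomes from the population. Stage 2 draws Poisson coverage per site
#' and pool, samples reads binomially from pool allele frequencies, and
#' applies sequencing error by redistributing erroneous reads uniformly over
#' the other three bases.
#'
#' @param model a [demography_model()].
#' @param seq a [seq_params()].
#' @param rng_seed integer seed; identical seeds give byte-identical output.
#' @param block_len length of independently simulated blocks (bp); sites
#'   within a block share one genealogy, blocks are unlinked.
#' @param chrom scaffold name used in the emitted tables.
#' @return list with `sites` (a `site_counts` over all L positions) and
#'   `truth` (demography, parameters, seeds, per-site true pool frequencies
#'   and true theta = 4*N0*mu).
#' @export
simulate_pool_seq <- function(model, seq = seq_params(), rng_seed,
                              block_len = 10000L, chrom = "sim1") {
  stopifnot(inherits(model, "demography_model"), inherits(seq, "seq_params"))
  with_seed(rng_seed, {
    K <- length(seq$pool_sizes)
    n_lin <- pmax(2L, as.integer(round(seq$pool_sizes * (1 - model$F))) +
                    as.integer(model$F > 0))
    L <- seq$L
    n_blocks <- ceiling(L / block_len)
    mut_pos <- integer(0)
    mut_counts <- matrix(0L, nrow = 0L, ncol = K)
    for (bl in seq_len(n_blocks)) {
      b0 <- (bl - 1L) * block_len
      blen_bp <- min(block_len, L - b0)
      g <- simulate_genealogy(n_lin, model)
      tot <- sum(g$len)
      S <- stats::rpois(1L, model$mu * blen_bp * tot)
      if (S == 0L) next
      br <- sample.int(length(g$len), S, replace = TRUE, prob = g$len)
      pos <- b0 + sample.int(blen_bp, S, replace = TRUE)
      dup <- duplicated(pos)
      mut_pos <- c(mut_pos, pos[!dup])
      mut_counts <- rbind(mut_counts, t(g$desc[, br[!dup], drop = FALSE]))
    }
    ## collisions across blocks impossible (disjoint ranges); sort by pos
    o <- order(mut_pos)
    mut_pos <- mut_pos[o]
    mut_counts <- mut_counts[o, , drop = FALSE]
    ## drop mutations fixed in every pool's sample (invisible at read level
    ## they would just flip ref; keep them as fixed derived sites instead)
    ref_idx <- sample.int(4L, L, replace = TRUE)
    alt_shift <- sample.int(3L, length(mut_pos), replace = TRUE)
    alt_idx <- ((ref_idx[mut_pos] - 1L + alt_shift) %% 4L) + 1L
    pools <- vector("list", K)
    for (p in seq_len(K)) {
      cov <- stats::rpois(L, seq$mean_coverage)
      m <- matrix(0L, nrow = L, ncol = 6L,
                  dimnames = list(NULL, COUNT_COLS))
      q <- rep(0, L)
      q[mut_pos] <- mut_counts[, p] / n_lin[p]
      der <- integer(L)
      has <- q > 0
      der[has] <- stats::rbinom(sum(has), cov[has], q[has])
      refn <- cov - der
      ## sequencing error: each read errs with prob e to one of the other 3
      e <- seq$error_rate
      if (e > 0) {
        err_r <- stats::rbinom(L, refn, e)
        err_d <- stats::rbinom(L, der, e)
        refn <- refn - err_r
        der <- der - err_d
      } else {
        err_r <- err_d <- integer(L)
      }
      m[cbind(seq_len(L), ref_idx)] <- refn
      idx_alt <- cbind(mut_pos, alt_idx)
      m[idx_alt] <- m[idx_alt] + der[mut_pos]
      if (e > 0) {
        m <- scatter_errors(m, err_r, ref_idx)
        if (length(mut_pos))
          m <- scatter_errors(m, err_d, ref_idx, only = mut_pos,
                              from_idx = alt_idx)
      }
      pools[[p]] <- m
    }
    sites <- site_counts(rep(chrom, L), seq_len(L), NUCS[ref_idx], pools)
    freqs <- matrix(0, nrow = length(mut_pos), ncol = K,
                    dimnames = list(NULL, names(seq$pool_sizes)))
    if (length(mut_pos)) freqs[] <- sweep(mut_counts, 2L, n_lin, "/")
    truth <- list(
      kind = "pool_seq",
      model = unclass(model), seq = unclass(seq), rng_seed = rng_seed,
      block_len = block_len, chrom = chrom,
      theta_true = 4 * model$N0 * model$mu,
      n_lineages = stats::setNames(n_lin, names(seq$pool_sizes)),
      variant_pos = mut_pos,
      variant_ref = NUCS[ref_idx[mut_pos]],
      variant_alt = NUCS[alt_idx],
      pool_freqs = freqs)
    list(sites = sites, truth = truth)
  })
}

## distribute err counts (per site) from base from_idx uniformly over the
## other three bases; `only` restricts to a subset of rows
scatter_errors <- function(m, err, ref_idx, only = NULL, from_idx = NULL) {
  rows <- if (is.null(only)) which(err > 0L) else only[err[only] > 0L]
  if (!length(rows)) return(m)
  n <- err[rows]
  src <- if (is.null(from_idx)) ref_idx[rows] else from_idx[err[only] > 0L]
  e1 <- stats::rbinom(length(n), n, 1 / 3)
  e2 <- stats::rbinom(length(n), n - e1, 1 / 2)
  e3 <- n - e1 - e2
  oth <- t(vapply(src, function(s) setdiff(1:4, s), integer(3L)))
  for (k in 1:3) {
    ek <- list(e1, e2, e3)[[k]]
    idx <- cbind(rows, oth[, k])
    m[idx] <- m[idx] + ek
  }
  m
}

#' Two-stage pooled read sampling from known population frequencies
#'
#' Exposes the sampling stages directly: pool allele counts are binomial
#' draws of `n_pool` genomes at the true population frequency, then `coverage`
#' reads are drawn binomially from the pool frequency with error
#' `error_rate`. As `n_pool` grows this collapses to single-stage binomial
#' read sampling at the population frequency.
#'
#' @param p true population derived-allele frequencies (vector, one per site).
#' @param n_pool number of haploid genomes in the pool.
#' @param coverage read coverage per site (scalar or vector).
#' @param error_rate per-read error probability (errors flip the allele).
#' @param rng_seed integer seed.
#' @return list with `pool_counts` (derived genomes in the pool) and
#'   `derived_reads` per site.
#' @export
sample_pool_reads <- function(p, n_pool, coverage, error_rate = 0,
                              rng_seed = 1L) {
  stopifnot(all(p >= 0 & p <= 1))
  with_seed(rng_seed, {
    kp <- stats::rbinom(length(p), n_pool, p)
    q <- kp / n_pool
    cov <- rep_len(coverage, length(p))
    m <- stats::rbinom(length(p), cov, q)
    if (error_rate > 0) {
      flip_d <- stats::rbinom(length(p), m, error_rate)
      flip_r <- stats::rbinom(length(p), cov - m, error_rate)
      m <- m - flip_d + flip_r
    }
    list(pool_counts = kp, derived_reads = m, coverage = cov)
  })
}

## ------------------------------------------------------------ TE evidence --

#' Simulate read-pair evidence for TE insertions with known truth
#'
#' For each insertion at frequency f, forward- and reverse-strand anchor
#' pairs are generated at `physical_coverage` per side; each pair's mate is
#' TE-classed with probability f and reference-classed otherwise. Anchor
#' positions are jittered within the insert-size model (anchors 80-220 bp
#' from the breakpoint, physical span `frag` bp). Background reference-only
#' pairs cover the rest of the chromosome.
#'
#' @param insertions `data.frame` with columns chrom, pos, family and
#'   frequency in `[0,1]`.
#' @param physical_coverage expected read pairs per side of each insertion.
#' @param chrom_length length of the simulated scaffold.
#' @param background_coverage expected physical coverage of reference-only
#'   pairs away from insertions.
#' @param frag physical span of one pair beyond its anchor (bp).
#' @param rng_seed integer seed.
#' @return list with `evidence` (data.table chrom, pos, strand, mate_class,
#'   mapq sorted by position) and `truth`.
#' @export
simulate_te_evidence <- function(insertions, physical_coverage = 10,
                                 chrom_length = 1000000L,
                                 background_coverage = physical_coverage,
                                 frag = 150L, rng_seed = 1L) {
  ins <- data.table::as.data.table(insertions)
  stopifnot(all(c("chrom", "pos", "family", "frequency") %in% names(ins)),
            all(ins$frequency >= 0 & ins$frequency <= 1))
  with_seed(rng_seed, {
    ev <- vector("list", nrow(ins) + 1L)
    for (i in seq_len(nrow(ins))) {
      P <- ins$pos[i]
      rows <- list()
      for (sd in c("+", "-")) {
        n <- stats::rpois(1L, physical_coverage)
        if (n == 0L) next
        off <- sample(80:220, n, replace = TRUE)
        pos <- if (sd == "+") P - off else P + off
        te <- stats::runif(n) < ins$frequency[i]
        rows[[sd]] <- data.table::data.table(
          chrom = ins$chrom[i], pos = as.integer(pos), strand = sd,
          mate_class = ifelse(te, ins$family[i], "reference"),
          mapq = sample(20:60, n, replace = TRUE))
      }
      ev[[i]] <- data.table::rbindlist(rows)
    }
    n_bg <- stats::rpois(1L, background_coverage * chrom_length / frag)
    if (n_bg > 0L) {
      bg <- data.table::data.table(
        chrom = ins$chrom[1L] %||% "simTE",
        pos = sample.int(chrom_length, n_bg, replace = TRUE),
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        mate_class = "reference",
        mapq = sample(20:60, n_bg, replace = TRUE))
      ## background stays clear of insertion neighbourhoods
      if (nrow(ins)) {
        near <- rep(FALSE, n_bg)
        for (P in ins$pos) near <- near | abs(bg$pos - P) <= 400L
        bg <- bg[!near]
      }
      ev[[nrow(ins) + 1L]] <- bg
    }
    evidence <- data.table::rbindlist(ev)
    data.table::setorder(evidence, chrom, pos)
    truth <- list(kind = "te_evidence", insertions = ins,
                  physical_coverage = physical_coverage,
                  chrom_length = chrom_length, frag = frag,
                  rng_seed = rng_seed)
    list(evidence = evidence[], truth = truth)
  })
}

## ------------------------------------------------------------- TE copies --

#' Simulate diverged TE copies and reads tiled from them
#'
#' Each copy of the consensus is mutated independently per base at one of the
#' given divergence levels; reads are tiled from the mutated copies with a
#' half-read-length step. Truth records each read's copy and divergence.
#'
#' @param consensus a single consensus sequence (character).
#' @param n_copies copies per divergence level.
#' @param divergence_levels per-base substitution probabilities in `[0, 0.5]`.
#' @param read_length read length in bp.
#' @param rng_seed integer seed.
#' @return list with `reads` (named `DNAStringSet`) and `truth`.
#' @export
simulate_te_copies <- function(consensus, n_copies = 5L,
                               divergence_levels = c(0, 0.05, 0.2),
                               read_length = 100L, rng_seed = 1L) {
  stopifnot(all(divergence_levels >= 0 & divergence_levels <= 0.5))
  cons <- toupper(as.character(consensus))
  bases <- strsplit(cons, "")[[1L]]
  with_seed(rng_seed, {
    reads <- character(0); rdiv <- numeric(0); rcopy <- character(0)
    for (d in divergence_levels) {
      for (ci in seq_len(n_copies)) {
        b <- bases
        mut <- stats::runif(length(b)) < d
        if (any(mut)) {
          b[mut] <- vapply(b[mut], function(x)
            sample(setdiff(NUCS, x), 1L), character(1L))
        }
        copy <- paste(b, collapse = "")
        starts <- seq(1L, max(1L, nchar(copy) - read_length + 1L),
                      by = max(1L, read_length %/% 2L))
        rd <- substring(copy, starts, pmin(nchar(copy),
                                           starts + read_length - 1L))
        rd <- rd[nchar(rd) >= min(read_length, nchar(copy))]
        nm <- sprintf("d%g_c%d_r%d", d, ci, seq_along(rd))
        reads <- c(reads, rd); rdiv <- c(rdiv, rep(d, length(rd)))
        rcopy <- c(rcopy, nm)
      }
    }
    rs <- Biostrings::DNAStringSet(reads)
    names(rs) <- rcopy
    list(reads = rs,
         truth = list(kind = "te_copies", read_divergence = rdiv,
                      divergence_levels = divergence_levels,
                      n_copies = n_copies, read_length = read_length,
                      rng_seed = rng_seed))
  })
}

#' Write a truth record as JSON
#' @param truth a truth list from one of the simulators.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write site counts as samtools-style mpileup text
#'
#' Reference-matching reads are emitted as `.`, others as explicit bases,
#' deletions as `*`; all qualities are written as the single character
#' `qual_char`. Indel evidence recorded on the object is appended as
#' `+1A`-style insertion strings so the masking stage can round-trip.
#'
#' @param sites a `site_counts` object.
#' @param path output path; if NULL, lines are returned.
#' @param qual_char quality character (default "I" = Q40).
#' @export
write_mpileup <- function(sites, path = NULL, qual_char = "I") {
  np <- n_pools(sites)
  n <- length(sites$pos)
  cols <- vector("list", np)
  for (p in seq_len(np)) {
    m <- sites$counts[[p]]
    bases <- character(n); depth <- integer(n)
    for (i in seq_len(n)) {
      ref <- sites$ref[i]
      parts <- character(0)
      for (b in NUCS) {
        k <- m[i, b]
        if (k > 0L)
          parts <- c(parts, strrep(if (b == ref) "." else b, k))
      }
      if (m[i, "N"] > 0L) parts <- c(parts, strrep("N", m[i, "N"]))
      if (m[i, "del"] > 0L) parts <- c(parts, strrep("*", m[i, "del"]))
      bs <- paste(parts, collapse = "")
      depth[i] <- sum(m[i, ])
      if (sites$indels[i, p] > 0L && depth[i] > 0L)
        bs <- paste0(bs, strrep("+1A", sites$indels[i, p]))
      bases[i] <- if (depth[i] > 0L) bs else "*"
      if (depth[i] == 0L) bases[i] <- "*"
    }
    qual <- strrep(qual_char, pmax(depth, 0L))
    qual[depth == 0L] <- "*"
    bases[depth == 0L] <- "*"
    cols[[p]] <- paste(depth, bases, qual, sep = "\t")
  }
  lines <- do.call(paste, c(list(sites$chrom, sites$pos, sites$ref), cols,
                            list(sep = "\t")))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}
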