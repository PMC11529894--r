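## TE insertion calling from paired-end signatures, insertion frequency
## analysis, divergence landscapes, window composition, telomere scans.

#' Parameters of the signature-based TE insertion caller
#'
#' Defaults are the seven printed parameters of the signature pipeline:
#' mapping-quality floor 15, physical target coverage 10, signature min
#' count 2, other-TE and structural-variant tolerance 2, pairing window
#' [-200, 300] bp.
#'
#' @param map_qual minimum mapping quality of evidence rows.
#' @param target_coverage physical coverage to which positions are
#'   subsampled (never upsampled).
#' @param min_count minimum per-position family support inside a signature.
#' @param max_otherte_count,max_structvar_count tolerated support of other
#'   TE families / structural variants at a signature.
#' @param min_distance,max_distance separation window (reverse minus forward
#'   signature position) for pairing two signatures into one insertion.
#' @param span physical span of one read pair beyond its anchor, bp.
#' @export
signature_params <- function(map_qual = 15L, target_coverage = 10L,
                             min_count = 2L, max_otherte_count = 2L,
                             max_structvar_count = 2L, min_distance = -200L,
                             max_distance = 300L, span = 150L) {
  stopifnot(min_distance <= max_distance, target_coverage >= 1L,
            min_count >= 1L, max_otherte_count >= 0L,
            max_structvar_count >= 0L, span >= 1L)
  structure(list(map_qual = as.integer(map_qual),
                 target_coverage = as.integer(target_coverage),
                 min_count = as.integer(min_count),
                 max_otherte_count = as.integer(max_otherte_count),
                 max_structvar_count = as.integer(max_structvar_count),
                 min_distance = as.integer(min_distance),
                 max_distance = as.integer(max_distance),
                 span = as.integer(span)),
            class = "signature_params")
}

#' Hard-mask annotated repeats and append the TE library
#'
#' Repeat intervals are replaced by N; library sequences are appended as
#' extra records. The returned object carries a provenance table mapping
#' each appended record to its family and order.
#'
#' @param genome named `DNAStringSet`.
#' @param repeat_annotation interval table (chrom, start, end), 1-based
#'   inclusive; `NULL` or empty for no masking.
#' @param te_library `DNAStringSet` of TE consensus sequences.
#' @param hierarchy TE hierarchy table (id, family, order); every library id
#'   must be present.
#' @return `DNAStringSet` with attribute `provenance`.
#' @export
build_te_merged_reference <- function(genome, repeat_annotation = NULL,
                                      te_library = NULL, hierarchy = NULL) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  out <- genome
  if (!is.null(repeat_annotation) && nrow(repeat_annotation) > 0L) {
    ann <- data.table::as.data.table(repeat_annotation)
    for (ch in unique(ann$chrom)) {
      if (!ch %in% names(out)) stop(sprintf("unknown scaffold '%s'", ch))
      a <- ann[chrom == ch]
      if (any(a$start < 1L) || any(a$end > Biostrings::width(out[ch])))
        stop("repeat annotation outside genome bounds")
      ir <- IRanges::reduce(IRanges::IRanges(a$start, a$end))
      out[[ch]] <- Biostrings::replaceAt(
        out[[ch]], ir,
        Biostrings::DNAStringSet(strrep("N", IRanges::width(ir))))
    }
  }
  prov <- data.table::data.table(record = character(), family = character(),
                                 order = character())
  if (!is.null(te_library) && length(te_library) > 0L) {
    if (is.character(te_library))
      te_library <- Biostrings::DNAStringSet(te_library)
    if (is.null(hierarchy)) stop("a TE hierarchy is required with a library")
    miss <- setdiff(names(te_library), hierarchy$id)
    if (length(miss))
      stop(sprintf("library id(s) missing from hierarchy: %s",
                   paste(miss, collapse = ", ")))
    out <- c(out, te_library)
    idx <- match(names(te_library), hierarchy$id)
    prov <- data.table::data.table(record = names(te_library),
                                   family = hierarchy$family[idx],
                                   order = hierarchy$order[idx])
  }
  attr(out, "provenance") <- prov
  out
}

## ------------------------------------------------------- insertion caller --

#' Call TE insertions from paired-end signature evidence
#'
#' Implements the four-step signature pipeline on a physical pileup:
#' (1) per-position counts of TE-supporting (per family), reference- and
#' structural-variant-supporting pairs spanning it; (2) positions with total
#' physical coverage above `target_coverage` subsampled without replacement
#' (seeded; positions below target untouched); (3) per family and strand,
#' maximal runs with support >= `min_count` become candidate signatures at
#' their support-weighted center; (4) signatures with other-family or
#' structural-variant support above tolerance are discarded; (5) forward and
#' reverse signatures of one family whose separation lies in
#' `[min_distance, max_distance]` merge into one insertion at the midpoint,
#' unmatched signatures are kept as single-signature insertions;
#' (6) frequency = TE / (TE + reference) physical coverage at the signature
#' center, averaged over paired signatures.
#'
#' @param evidence `data.frame` (chrom, pos, strand, mate_class, mapq)
#'   sorted by (chrom, pos); `mate_class` is a TE family id, `"reference"`,
#'   or `"structvar"`.
#' @param params a [signature_params()].
#' @param rng_seed integer seed for the subsampling stage.
#' @param hierarchy optional TE hierarchy used to attach the order column.
#' @return `data.table` (chrom, pos, family, order, frequency, support,
#'   n_signatures).
#' @export
detect_te_insertions <- function(evidence, params = signature_params(),
                                 rng_seed = 1L, hierarchy = NULL) {
  ev <- data.table::as.data.table(evidence)
  stopifnot(all(c("chrom", "pos", "strand", "mate_class", "mapq") %in%
                  names(ev)))
  if (is.unsorted(ev$pos) &&
      any(ev[, is.unsorted(pos), by = chrom]$V1))
    stop("evidence must be sorted by (chrom, pos)")
  ev <- ev[mapq >= params$map_qual]
  fams <- sort(setdiff(unique(ev$mate_class), c("reference", "structvar")))
  if (!length(fams) || nrow(ev) == 0L)
    return(empty_insertions())
  sigs <- with_seed(rng_seed, {
    out <- list()
    for (ch in sort(unique(ev$chrom))) {
      e <- ev[chrom == ch]
      out[[ch]] <- chrom_signatures(e, fams, params)
    }
    data.table::rbindlist(out)
  })
  if (nrow(sigs) == 0L) return(empty_insertions())
  ins <- pair_signatures(sigs, params)
  if (!is.null(hierarchy)) {
    idx <- match(ins$family, hierarchy$id)
    ins[, order := hierarchy$order[idx]]
  } else ins[, order := NA_character_]
  data.table::setcolorder(ins, c("chrom", "pos", "family", "order",
                                 "frequency", "support", "n_signatures"))
  data.table::setorder(ins, chrom, pos)
  ins[]
}

empty_insertions <- function() {
  data.table::data.table(chrom = character(), pos = integer(),
                         family = character(), order = character(),
                         frequency = numeric(), support = integer(),
                         n_signatures = integer())
}

## per-chromosome physical pileup + subsampling + run detection
chrom_signatures <- function(e, fams, params) {
  span <- params$span
  e[, start := ifelse(strand == "+", pos, pmax(1L, pos - span))]
  e[, end := ifelse(strand == "+", pos + span, pos)]
  maxend <- max(e$end) + 1L
  keys <- c(paste0(rep(fams, each = 2L), "|", c("+", "-")),
            "reference", "structvar")
  rles <- vector("list", length(keys)); names(rles) <- keys
  for (f in fams) for (sd in c("+", "-")) {
    sub <- e[mate_class == f & strand == sd]
    rles[[paste0(f, "|", sd)]] <- IRanges::coverage(
      IRanges::IRanges(sub$start, sub$end), width = maxend)
  }
  for (cl in c("reference", "structvar")) {
    sub <- e[mate_class == cl]
    rles[[cl]] <- IRanges::coverage(IRanges::IRanges(sub$start, sub$end),
                                    width = maxend)
  }
  famtot <- Reduce(`+`, rles[seq_len(2L * length(fams))])
  if (all(S4Vectors::runValue(famtot) == 0L)) return(NULL)
  sl <- IRanges::slice(famtot, lower = 1L)
  regions <- IRanges::reduce(IRanges::ranges(sl))
  sig <- list()
  for (ri in seq_along(regions)) {
    rs <- IRanges::start(regions)[ri]; re <- IRanges::end(regions)[ri]
    X <- vapply(rles, function(r)
      as.integer(S4Vectors::window(r, rs, re)), integer(re - rs + 1L))
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L,
                                     dimnames = list(NULL, keys))
    X <- subsample_pileup(X, params$target_coverage)
    pos <- rs:re
    for (f in fams) for (sd in c("+", "-")) {
      v <- X[, paste0(f, "|", sd)]
      hits <- v >= params$min_count
      if (!any(hits)) next
      r <- rle(hits)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      rs_idx <- starts[r$values]; re_idx <- ends[r$values]
      ## threshold crossings fragment one physical cluster into several
      ## runs; runs separated by less than the pair span belong to the same
      ## signature (one per strand and family per cluster)
      if (length(rs_idx) > 1L) {
        gap <- rs_idx[-1L] - re_idx[-length(re_idx)] - 1L
        grpid <- cumsum(c(1L, as.integer(gap > params$span)))
        rs_idx <- tapply(rs_idx, grpid, min)
        re_idx <- tapply(re_idx, grpid, max)
      }
      for (k in seq_along(rs_idx)) {
        ii <- rs_idx[k]:re_idx[k]
        ii <- ii[v[ii] >= params$min_count]
        w <- v[ii]
        center <- ii[which.min(abs(ii - sum(ii * w) / sum(w)))]
        other <- sum(X[center, seq_len(2L * length(fams))]) -
          X[center, paste0(f, "|+")] - X[center, paste0(f, "|-")]
        if (other > params$max_otherte_count) next
        if (X[center, "structvar"] > params$max_structvar_count) next
        te <- v[center]
        refc <- X[center, "reference"]
        sig[[length(sig) + 1L]] <- data.table::data.table(
          chrom = e$chrom[1L], pos = pos[center], family = f, strand = sd,
          support = max(w),
          frequency = if (te + refc > 0) te / (te + refc) else NA_real_)
      }
    }
  }
  data.table::rbindlist(sig)
}

## per-position multivariate hypergeometric downsampling of class counts to
## the target total; positions at or below target are untouched
subsample_pileup <- function(X, target) {
  tot <- rowSums(X)
  over <- which(tot > target)
  if (!length(over)) return(X)
  rem_pop <- tot[over]
  rem_draw <- rep(as.integer(target), length(over))
  for (j in seq_len(ncol(X))) {
    m <- X[over, j]
    drawn <- stats::rhyper(length(over), m, rem_pop - m, rem_draw)
    X[over, j] <- drawn
    rem_pop <- rem_pop - m
    rem_draw <- rem_draw - drawn
  }
  X
}

## greedy nearest-separation pairing of forward/reverse signatures
pair_signatures <- function(sigs, params) {
  out <- list()
  for (grp in split(sigs, by = c("chrom", "family"), sorted = TRUE)) {
    fwd <- grp[strand == "+"][order(pos)]
    rev <- grp[strand == "-"][order(pos)]
    used_r <- rep(FALSE, nrow(rev))
    for (i in seq_len(nrow(fwd))) {
      sep <- rev$pos - fwd$pos[i]
      cand <- which(!used_r & sep >= params$min_distance &
                      sep <= params$max_distance)
      if (length(cand)) {
        j <- cand[which.min(abs(sep[cand]))]
        used_r[j] <- TRUE
        out[[length(out) + 1L]] <- data.table::data.table(
          chrom = fwd$chrom[i],
          pos = as.integer(round((fwd$pos[i] + rev$pos[j]) / 2)),
          family = fwd$family[i],
          frequency = mean(c(fwd$frequency[i], rev$frequency[j]),
                           na.rm = TRUE),
          support = fwd$support[i] + rev$support[j],
          n_signatures = 2L)
      } else {
        ## unpaired: the breakpoint lies ~half a pair span inward of the
        ## signature center (a forward signature sits upstream of it)
        out[[length(out) + 1L]] <- fwd[i, .(chrom,
                                            pos = pos + params$span %/% 2L,
                                            family, frequency,
                                            support, n_signatures = 1L)]
      }
    }
    if (any(!used_r)) {
      out[[length(out) + 1L]] <- rev[!used_r, .(chrom,
                                                pos = pos - params$span %/% 2L,
                                                family,
                                                frequency, support,
                                                n_signatures = 1L)]
    }
  }
  data.table::rbindlist(out)
}

## ----------------------------------------------------- population overlap --

#' Population-unique TE insertions
#'
#' Insertions of the same family whose positions differ by at most
#' `tolerance` bp are treated as the same event across populations; per
#' population, the events present in that population only are returned.
#'
#' @param per_population named list of insertion tables (as returned by
#'   [detect_te_insertions()]).
#' @param tolerance positional matching tolerance in bp; default 25.
#' @return named list of insertion tables restricted to unique events.
#' @export
unique_insertions <- function(per_population, tolerance = 25L) {
  if (tolerance < 0L) stop("tolerance must be >= 0")
  stopifnot(!is.null(names(per_population)))
  all <- data.table::rbindlist(per_population, idcol = "population",
                               fill = TRUE)
  if (nrow(all) == 0L) return(lapply(per_population, function(x) x))
  data.table::setorder(all, chrom, family, pos)
  all[, cluster := cumsum(
    c(1L, (diff(pos) > tolerance) |
        (chrom[-1L] != chrom[-.N]) | (family[-1L] != family[-.N]))),
    ]
  npop <- all[, .(n_pops = data.table::uniqueN(population)), by = cluster]
  all <- merge(all, npop, by = "cluster")
  uniq <- all[n_pops == 1L]
  lapply(stats::setNames(names(per_population), names(per_population)),
         function(p) {
           u <- uniq[population == p]
           u[, c("cluster", "n_pops", "population") := NULL]
           u[]
         })
}

#' TE insertion frequency spectrum
#'
#' Equal-width histogram on `[0, 1]` plus the summary fractions used to read
#' the spectrum: low (< 0.5), high (> 0.5) and fixed (= 1 within 1e-9).
#'
#' @param insertions insertion table with a `frequency` column (or a numeric
#'   vector of frequencies).
#' @param n_bins number of equal-width bins; must be >= 2.
#' @return list with `histogram` (data.table bin_lo, bin_hi, count) and
#'   `low_fraction`, `high_fraction`, `fixed_fraction` (all NA when empty).
#' @export
frequency_spectrum <- function(insertions, n_bins = 20L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  f <- if (is.numeric(insertions)) insertions else insertions$frequency
  f <- f[!is.na(f)]
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1]")
  br <- seq(0, 1, length.out = n_bins + 1L)
  if (!length(f)) {
    return(list(histogram = data.table::data.table(
      bin_lo = br[-length(br)], bin_hi = br[-1L], count = 0L),
      low_fraction = NA_real_, high_fraction = NA_real_,
      fixed_fraction = NA_real_))
  }
  bin <- pmin(n_bins, findInterval(f, br, rightmost.closed = TRUE))
  list(histogram = data.table::data.table(
    bin_lo = br[-length(br)], bin_hi = br[-1L],
    count = tabulate(bin, nbins = n_bins)),
    low_fraction = mean(f < 0.5),
    high_fraction = mean(f > 0.5),
    fixed_fraction = mean(abs(f - 1) <= 1e-9))
}

## -------------------------------------------------------------- landscape --

#' Read-versus-library TE divergence landscape
#'
#' A seeded read sample totalling `sample_coverage * genome_size` bases is
#' locally aligned (both orientations) against every library sequence; each
#' read keeps its best-scoring hit. Hits below the floor (>= `min_match`
#' matching columns or >= `min_read_frac` of the read aligned) are dropped.
#' Divergence = (mismatches + gap columns) / aligned columns, binned at 1%;
#' the genome proportion of a (label, bin) cell is its aligned read bases
#' over the total sampled bases.
#'
#' @param reads `DNAStringSet` (or character vector) of reads.
#' @param te_library `DNAStringSet` of repeat consensus sequences.
#' @param hierarchy TE hierarchy (id, family, order) covering the library.
#' @param sample_coverage fraction of `genome_size` to sample, e.g. 0.1.
#' @param genome_size genome size in bp the coverage refers to.
#' @param rng_seed integer seed for read sampling.
#' @param label_by `"family"` or `"order"` column of the hierarchy.
#' @param min_match,min_read_frac alignment floor.
#' @return `data.table` (label, bin, proportion); `bin` i covers [i, i+1)%.
#' @export
repeat_landscape <- function(reads, te_library, hierarchy,
                             sample_coverage = 0.1, genome_size = NULL,
                             rng_seed = 1L, label_by = c("family", "order"),
                             min_match = 80L, min_read_frac = 0.5) {
  label_by <- match.arg(label_by)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (is.character(te_library))
    te_library <- Biostrings::DNAStringSet(te_library)
  if (length(te_library) == 0L) stop("TE library is empty")
  if (is.null(genome_size)) genome_size <- sum(Biostrings::width(reads))
  target <- sample_coverage * genome_size
  reads <- with_seed(rng_seed, {
    idx <- sample.int(length(reads))
    keep <- idx[cumsum(as.numeric(Biostrings::width(reads)[idx])) <=
                  max(target, min(Biostrings::width(reads)))]
    if (!length(keep)) keep <- idx[1L]
    reads[sort(keep)]
  })
  total_bases <- sum(Biostrings::width(reads))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  nr <- length(reads)
  best <- list(score = rep(-Inf, nr), lib = rep(NA_integer_, nr),
               mism = rep(NA_real_, nr), gaps = rep(NA_real_, nr),
               cols = rep(NA_real_, nr), nmatch = rep(NA_real_, nr),
               abases = rep(NA_real_, nr))
  for (orient in 1:2) {
    rds <- if (orient == 1L) reads else Biostrings::reverseComplement(reads)
    for (li in seq_along(te_library)) {
      pa <- Biostrings::pairwiseAlignment(
        rds, te_library[[li]], type = "local",
        substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
      sc <- Biostrings::score(pa)
      upd <- which(sc > best$score)
      if (!length(upd)) next
      ps <- as.character(Biostrings::alignedPattern(pa[upd]))
      ss <- as.character(Biostrings::alignedSubject(pa[upd]))
      pgap <- vapply(gregexpr("-", ps, fixed = TRUE), function(x)
        sum(x > 0), numeric(1L))
      sgap <- vapply(gregexpr("-", ss, fixed = TRUE), function(x)
        sum(x > 0), numeric(1L))
      best$score[upd] <- sc[upd]
      best$lib[upd] <- li
      best$mism[upd] <- Biostrings::nmismatch(pa[upd])
      best$gaps[upd] <- pgap + sgap
      best$cols[upd] <- nchar(ps)
      best$nmatch[upd] <- Biostrings::nmatch(pa[upd])
      best$abases[upd] <- nchar(ps) - pgap
    }
  }
  best <- data.table::as.data.table(best)
  rl <- Biostrings::width(reads)
  keep <- is.finite(best$score) &
    (best$nmatch >= min_match | best$abases >= min_read_frac * rl)
  if (!any(keep))
    return(data.table::data.table(label = character(), bin = integer(),
                                  proportion = numeric()))
  hit <- best[keep]
  idx <- match(names(te_library)[hit$lib], hierarchy$id)
  hit[, label := hierarchy[[label_by]][idx]]
  hit[, divergence := 100 * (mism + gaps) / cols]
  hit[, bin := pmin(99L, as.integer(floor(divergence)))]
  out <- hit[, .(proportion = sum(abases) / total_bases),
             by = .(label, bin)]
  data.table::setorder(out, label, bin)
  out[]
}

## ------------------------------------------------------------ composition --

#' Windowed TE / exon composition of the genome
#'
#' Per window and feature class, the fraction of bases covered by the merged
#' intervals of that class. Windows beyond the scaffold end are truncated and
#' the truncated length is the denominator.
#'
#' @param features interval table with columns chrom, start, end, class.
#' @param window a [window_spec()].
#' @param genome_lengths named vector of scaffold lengths.
#' @return `data.table` (chrom, start, end, class, fraction), all windows x
#'   all classes (fraction 0 where a class is absent).
#' @export
window_composition <- function(features, window, genome_lengths) {
  fx <- data.table::as.data.table(features)
  classes <- sort(unique(fx$class))
  empty <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), class = character(),
                                  fraction = numeric())
  if (!length(classes)) return(empty)
  out <- list()
  for (ch in names(genome_lengths)) {
    len <- as.integer(genome_lengths[[ch]])
    starts <- seq(1L, len, by = window$size)
    ends <- pmin(starts + window$size - 1L, len)
    base <- data.table::data.table(chrom = ch, start = starts, end = ends)
    for (cl in classes) {
      f <- fx[chrom == ch & class == cl]
      covbp <- integer(length(starts))
      if (nrow(f) > 0L) {
        ir <- IRanges::reduce(IRanges::IRanges(pmax(1L, f$start),
                                               pmin(len, f$end)))
        cov <- IRanges::coverage(ir, width = len)
        v <- IRanges::Views(cov, starts, ends)
        covbp <- IRanges::viewSums(v)
      }
      out[[length(out) + 1L]] <- data.table::data.table(
        base, class = cl, fraction = covbp / (ends - starts + 1L))
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, start, class)
  res[]
}

## ---------------------------------------------------------------- telomere --

#' Telomeric-motif window scan with end-enrichment flags
#'
#' Counts non-overlapping occurrences of each motif and its reverse
#' complement per window. A scaffold end is flagged enriched for a motif when
#' the maximum count among its terminal `end_windows` windows is at least
#' `min_count` and at least `enrich_factor` times the scaffold's median
#' window count.
#'
#' @param genome named `DNAStringSet` or named character vector.
#' @param motifs uppercase DNA motifs; defaults are four Coleopteran
#'   telomeric repeats.
#' @param window window size in bp.
#' @param end_windows number of terminal windows forming each "end".
#' @param enrich_factor,min_count enrichment thresholds.
#' @return list with `counts` (chrom, start, end, motif, count) and `ends`
#'   (chrom, motif, end, count, median_count, enriched).
#' @export
telomere_scan <- function(genome,
                          motifs = c("AACAGACCCG", "AACCC", "AACCT", "ACCTG"),
                          window = 10000L, end_windows = 3L,
                          enrich_factor = 10, min_count = 25L) {
  if (!length(motifs)) stop("motifs must be non-empty")
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must be uppercase ACGT strings")
  seqs <- if (is.character(genome)) genome else
    stats::setNames(as.character(genome), names(genome))
  counts <- list(); ends <- list()
  for (ch in names(seqs)) {
    s <- toupper(seqs[[ch]])
    len <- nchar(s)
    starts <- seq(1L, len, by = window)
    stops <- pmin(starts + window - 1L, len)
    wins <- substring(s, starts, stops)
    for (mo in motifs) {
      rc <- revcomp(mo)
      cnt <- count_nonoverlap(wins, mo)
      if (rc != mo) cnt <- cnt + count_nonoverlap(wins, rc)
      counts[[length(counts) + 1L]] <- data.table::data.table(
        chrom = ch, start = starts, end = stops, motif = mo, count = cnt)
      med <- stats::median(cnt)
      nw <- length(cnt)
      for (side in c("left", "right")) {
        idx <- if (side == "left") seq_len(min(end_windows, nw)) else
          seq(max(1L, nw - end_windows + 1L), nw)
        mx <- max(cnt[idx])
        ends[[length(ends) + 1L]] <- data.table::data.table(
          chrom = ch, motif = mo, end = side, count = mx,
          median_count = med,
          enriched = mx >= min_count & mx >= enrich_factor * max(med, 1e-9))
      }
    }
  }
  list(counts = data.table::rbindlist(counts),
       ends = data.table::rbindlist(ends))
}

count_nonoverlap <- function(strings, motif) {
  vapply(gregexpr(motif, strings, fixed = TRUE), function(x)
    sum(x > 0L), numeric(1L))
}
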