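## Synonymous / nonsynonymous site classification and windowed piS / piNS.

#' Classify CDS positions by codon context
#'
#' Each CDS position is annotated with its codon, position-in-codon and a
#' synonymous site length: the fraction of the 3 possible substitutions at
#' that position that leave the amino acid unchanged (standard genetic code).
#' The nonsynonymous length is its complement. Positions covered by
#' overlapping CDS annotations with conflicting frames are excluded.
#'
#' @param features interval table from [read_features()] (rows with
#'   `type == "CDS"` are used); the `attr` column must carry `Parent=` (or
#'   `ID=`) transcript identifiers, and `frame` the GFF3 phase.
#' @param genome a named `DNAStringSet` (or named character vector).
#' @return `data.table` (chrom, pos, strand, codon, codon_pos, syn_len,
#'   nonsyn_len). `codon` and `codon_pos` are given on the coding strand.
#' @export
classify_coding_sites <- function(features, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  cds <- data.table::as.data.table(features)[type == "CDS"]
  if (nrow(cds) == 0L)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(), codon = character(),
                                  codon_pos = integer(), syn_len = numeric(),
                                  nonsyn_len = numeric()))
  tx <- gff_attr(cds$attr, "Parent")
  tx[is.na(tx)] <- gff_attr(cds$attr[is.na(tx)], "ID")
  if (anyNA(tx)) stop("CDS rows need Parent= or ID= attributes")
  cds[, transcript := tx]
  out <- vector("list", length(unique(tx)))
  names(out) <- unique(tx)
  for (t in unique(tx)) {
    seg <- cds[transcript == t]
    strand <- seg$strand[1L]
    data.table::setorder(seg, start)
    if (strand == "-") seg <- seg[rev(seq_len(nrow(seg)))]
    ## genomic positions in translation order
    gpos <- unlist(lapply(seq_len(nrow(seg)), function(i) {
      p <- seg$start[i]:seg$end[i]
      if (strand == "-") rev(p) else p
    }))
    phase <- suppressWarnings(as.integer(seg$frame[1L]))
    if (is.na(phase)) phase <- 0L
    if (phase > 0L) gpos <- gpos[-seq_len(phase)]
    incomplete <- grepl("incomplete", seg$attr[1L], ignore.case = TRUE)
    if (length(gpos) %% 3L != 0L) {
      if (!incomplete)
        stop(sprintf("CDS of transcript '%s' not divisible by 3", t))
      gpos <- gpos[seq_len(3L * (length(gpos) %/% 3L))]
    }
    if (!length(gpos)) next
    chrom <- seg$chrom[1L]
    sq <- as.character(Biostrings::subseq(
      genome[[chrom]], min(gpos), max(gpos)))
    base_at <- function(p) substring(sq, p - min(gpos) + 1L, p - min(gpos) + 1L)
    bases <- toupper(base_at(gpos))
    if (strand == "-") bases <- chartr("ACGT", "TGCA", bases)
    ncod <- length(gpos) %/% 3L
    codon <- paste0(bases[seq(1, by = 3, length.out = ncod)],
                    bases[seq(2, by = 3, length.out = ncod)],
                    bases[seq(3, by = 3, length.out = ncod)])
    res <- data.table::data.table(
      chrom = chrom, pos = gpos, strand = strand,
      codon = rep(codon, each = 3L),
      codon_pos = rep(1:3, ncod))
    sl <- syn_site_length(res$codon, res$codon_pos)
    res[, syn_len := sl]
    res[, nonsyn_len := 1 - sl]
    out[[t]] <- res
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) return(res)
  ## drop positions with conflicting overlapping annotations
  res <- unique(res)
  dup <- res[, .N, by = .(chrom, pos)][N > 1L]
  if (nrow(dup) > 0L)
    res <- res[!dup, on = c("chrom", "pos")]
  data.table::setorder(res, chrom, pos)
  res[]
}

## fraction of the 3 possible substitutions at codon_pos that are synonymous
syn_site_length <- function(codon, codon_pos) {
  gc <- Biostrings::GENETIC_CODE
  key <- paste0(codon, codon_pos)
  ukey <- !duplicated(key)
  lut <- vapply(which(ukey), function(i) {
    cd <- strsplit(codon[i], "")[[1L]]
    if (any(!cd %in% NUCS)) return(NA_real_)
    aa <- gc[[codon[i]]]
    alts <- setdiff(NUCS, cd[codon_pos[i]])
    nsyn <- sum(vapply(alts, function(a) {
      cd2 <- cd; cd2[codon_pos[i]] <- a
      gc[[paste(cd2, collapse = "")]] == aa
    }, logical(1L)))
    nsyn / 3
  }, numeric(1L))
  names(lut) <- key[ukey]
  unname(lut[key])
}

## is the substitution ref_allele -> alt_allele at this codon context
## synonymous? alleles are given on the genome's forward strand.
is_synonymous <- function(codon, codon_pos, strand, allele_a, allele_b) {
  gc <- Biostrings::GENETIC_CODE
  mapply(function(cd, cp, st, a, b) {
    if (st == "-") { a <- chartr("ACGT", "TGCA", a); b <- chartr("ACGT", "TGCA", b) }
    c1 <- strsplit(cd, "")[[1L]]; c2 <- c1
    c1[cp] <- a; c2[cp] <- b
    k1 <- paste(c1, collapse = ""); k2 <- paste(c2, collapse = "")
    if (!k1 %in% names(gc) || !k2 %in% names(gc)) return(NA)
    gc[[k1]] == gc[[k2]]
  }, codon, codon_pos, strand, allele_a, allele_b, USE.NAMES = FALSE)
}

#' Windowed synonymous and nonsynonymous diversity
#'
#' piS per window is the summed corrected site pi of synonymous SNPs divided
#' by the total synonymous site length of all valid CDS sites in the window;
#' piNS analogously. A SNP whose two (top) alleles change the amino acid is
#' assigned to the nonsynonymous class, otherwise to the synonymous class.
#'
#' @param sites `site_counts` (masked/filtered as for pi).
#' @param contexts output of [classify_coding_sites()].
#' @param pool a [pool_spec()].
#' @param window a [window_spec()].
#' @param pool_index pool column to use.
#' @return `data.table` (chrom, start, end, syn_len, nonsyn_len, pi_syn,
#'   pi_nonsyn); NA where the corresponding length denominator is 0.
#' @export
window_pi_syn_nonsyn <- function(sites, contexts, pool,
                                 window = window_spec(), pool_index = 1L) {
  check_sorted(sites)
  st <- site_state(sites$counts[[pool_index]], pool)
  dt <- data.table::data.table(chrom = sites$chrom, pos = sites$pos,
                               valid = st$valid, snp = st$snp, pi = st$pi)
  eff <- st$eff
  dt <- merge(dt, contexts, by = c("chrom", "pos"), sort = FALSE)
  if (nrow(dt) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), syn_len = numeric(),
                                  nonsyn_len = numeric(), pi_syn = numeric(),
                                  pi_nonsyn = numeric()))
  idx <- match(paste(dt$chrom, dt$pos), paste(sites$chrom, sites$pos))
  dt[, is_syn := NA]
  sn <- which(dt$snp)
  if (length(sn)) {
    top2 <- t(apply(eff[idx[sn], , drop = FALSE], 1L, function(v)
      NUCS[order(v[NUCS], decreasing = TRUE)[1:2]]))
    dt$is_syn[sn] <- is_synonymous(dt$codon[sn], dt$codon_pos[sn],
                                   dt$strand[sn], top2[, 1L], top2[, 2L])
  }
  dt[, win := (pos - 1L) %/% window$size]
  agg <- dt[valid == TRUE, .(
    syn_len = sum(syn_len),
    nonsyn_len = sum(nonsyn_len),
    pi_syn_sum = sum(pi[snp & is_syn %in% TRUE]),
    pi_nonsyn_sum = sum(pi[snp & is_syn %in% FALSE])
  ), by = .(chrom, win)]
  agg[, start := win * window$size + 1L]
  agg[, end := (win + 1L) * window$size]
  agg[, pi_syn := ifelse(syn_len > 0, pi_syn_sum / syn_len, NA_real_)]
  agg[, pi_nonsyn := ifelse(nonsyn_len > 0, pi_nonsyn_sum / nonsyn_len,
                            NA_real_)]
  out <- agg[, .(chrom, start, end, syn_len, nonsyn_len, pi_syn, pi_nonsyn)]
  data.table::setorder(out, chrom, start)
  out[]
}
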