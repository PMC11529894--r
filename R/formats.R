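## Text-format plumbing: per-site allele counts, mpileup decoding, sync IO,
## indel-region masking. Coordinates are 1-based inclusive throughout; BED
## conversion happens only at the BED boundary.

NUCS <- c("A", "T", "C", "G")
COUNT_COLS <- c("A", "T", "C", "G", "N", "del")

#' Per-site, per-pool nucleotide counts
#'
#' The atom of every estimator in the package: for each genomic site, one
#' 6-vector of counts (A, T, C, G, N, deletion) per pool. Coverage is defined
#' as A+T+C+G; N and deletions never count toward coverage.
#'
#' @param chrom character vector of scaffold names.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases (A/T/C/G/N).
#' @param counts list with one integer matrix per pool; each matrix has one
#'   row per site and columns `A,T,C,G,N,del`.
#' @param indels optional integer matrix (sites x pools) of per-site indel
#'   evidence (insertion events + deleted bases seen in reads), used by
#'   [identify_indel_regions()].
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(chrom, pos, ref, counts, indels = NULL) {
  stopifnot(is.list(counts), length(counts) >= 1L)
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be >= 1")
  n <- length(pos)
  counts <- lapply(counts, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (ncol(m) != 6L) stop("each pool count matrix needs 6 columns (A,T,C,G,N,del)")
    if (nrow(m) != n) stop("count matrix rows must match number of sites")
    if (any(m < 0L)) stop("counts must be non-negative")
    colnames(m) <- COUNT_COLS
    m
  })
  if (is.null(indels)) {
    indels <- matrix(0L, nrow = n, ncol = length(counts))
  } else {
    indels <- as.matrix(indels)
    storage.mode(indels) <- "integer"
  }
  structure(list(chrom = rep_len(as.character(chrom), n), pos = pos,
                 ref = rep_len(toupper(as.character(ref)), n),
                 counts = counts, indels = indels),
            class = "site_counts")
}

#' @export
length.site_counts <- function(x) length(x$pos)

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("<site_counts> %d sites, %d pool(s)\n", length(x$pos),
              length(x$counts)))
  invisible(x)
}

#' Number of pools in a `site_counts` object
#' @param x a `site_counts` object.
#' @export
n_pools <- function(x) length(x$counts)

#' Coverage matrix (sites x pools); coverage = A+T+C+G
#' @param x a `site_counts` object.
#' @export
coverage_matrix <- function(x) {
  vapply(x$counts, function(m) as.integer(rowSums(m[, NUCS, drop = FALSE])),
         integer(length(x$pos)))
}

subset_sites <- function(x, keep) {
  site_counts(x$chrom[keep], x$pos[keep], x$ref[keep],
              lapply(x$counts, function(m) m[keep, , drop = FALSE]),
              x$indels[keep, , drop = FALSE])
}

## ---------------------------------------------------------------- mpileup --

#' Decode samtools mpileup text into per-site counts
#'
#' Fully decodes the mpileup base-string grammar: `.`/`,` match the reference,
#' explicit bases count as themselves, `^X` read-start markers are skipped
#' together with their mapping-quality byte, `$` is skipped, `+n`/`-n` indel
#' strings are consumed (and tallied as indel evidence for masking), and `*`
#' counts as a deletion. Bases whose quality is below `min_base_quality`
#' (Phred+33) are discarded.
#'
#' @param stream path to an mpileup file, or a character vector of lines.
#' @param n_pools number of pools (one base/quality column pair each).
#' @param min_base_quality Phred quality floor; default 20.
#' @return a `site_counts` object with indel evidence attached.
#' @export
read_mpileup <- function(stream, n_pools, min_base_quality = 20L) {
  lines <- if (length(stream) == 1L && file.exists(stream)) readLines(stream) else stream
  lines <- lines[nzchar(lines)]
  nl <- length(lines)
  if (nl == 0L) {
    return(site_counts(character(), integer(), character(),
                       rep(list(matrix(integer(), 0, 6)), n_pools)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- 3L + 3L * n_pools
  counts <- rep(list(matrix(0L, nl, 6L, dimnames = list(NULL, COUNT_COLS))), n_pools)
  indels <- matrix(0L, nl, n_pools)
  chrom <- character(nl); pos <- integer(nl); ref <- character(nl)
  for (i in seq_len(nl)) {
    f <- fields[[i]]
    if (length(f) < need)
      stop(sprintf("mpileup line %d: expected %d fields, got %d", i, need, length(f)))
    chrom[i] <- f[1L]
    pos[i] <- as.integer(f[2L])
    ref[i] <- toupper(f[3L])
    for (p in seq_len(n_pools)) {
      depth <- as.integer(f[3L + 3L * (p - 1L) + 1L])
      bases <- f[3L + 3L * (p - 1L) + 2L]
      quals <- f[3L + 3L * (p - 1L) + 3L]
      dec <- tryCatch(
        decode_pileup_bases(bases, quals, ref[i], min_base_quality),
        error = function(e) stop(sprintf("mpileup line %d, pool %d: %s",
                                         i, p, conditionMessage(e))))
      if (dec$n_events != depth && depth > 0L)
        stop(sprintf("mpileup line %d, pool %d: decoded %d events but depth is %d",
                     i, p, dec$n_events, depth))
      counts[[p]][i, ] <- dec$counts
      indels[i, p] <- dec$indels
    }
  }
  site_counts(chrom, pos, ref, counts, indels)
}

## Decode one pileup base string. Returns counts (A,T,C,G,N,del), number of
## indel events (insertions + deletion-run starts) and the total event count
## that must equal the printed depth.
decode_pileup_bases <- function(bases, quals, ref, min_q) {
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  qv <- utf8ToInt(quals) - 33L
  counts <- stats::setNames(integer(6L), COUNT_COLS)
  i <- 1L; qi <- 1L; n_events <- 0L; n_indel <- 0L
  nch <- length(ch)
  while (i <= nch) {
    c0 <- ch[i]
    if (c0 == "^") {           # read start: skip marker + mapq byte
      i <- i + 2L
      next
    }
    if (c0 == "$") { i <- i + 1L; next }
    if (c0 == "+" || c0 == "-") {   # indel string attached to previous base
      j <- i + 1L
      while (j <= nch && grepl("^[0-9]$", ch[j])) j <- j + 1L
      if (j == i + 1L) stop("malformed indel length")
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > nch) stop("malformed indel: sequence truncated")
      n_indel <- n_indel + 1L
      i <- j + len
      next
    }
    ## an actual base-call event consuming one quality byte
    if (qi > length(qv)) stop("base/quality string length mismatch")
    q <- qv[qi]; qi <- qi + 1L
    n_events <- n_events + 1L
    base <- if (c0 == "." || c0 == ",") ref else toupper(c0)
    if (c0 == "*") {
      if (q >= min_q) counts["del"] <- counts["del"] + 1L
    } else if (q >= min_q) {
      if (base %in% NUCS) counts[base] <- counts[base] + 1L
      else counts["N"] <- counts["N"] + 1L
    }
    i <- i + 1L
  }
  if (qi != length(qv) + 1L) stop("base/quality string length mismatch")
  list(counts = counts, indels = n_indel, n_events = n_events)
}

## ------------------------------------------------------------------- sync --

#' Write / read PoPoolation2-style sync tables
#'
#' Tab-separated `chrom pos ref` followed by one `A:T:C:G:N:del` column per
#' pool. `read_sync(write_sync(x))` is the identity.
#'
#' @param sites a `site_counts` object.
#' @param path output path; if `NULL` the lines are returned.
#' @export
write_sync <- function(sites, path = NULL) {
  cols <- lapply(sites$counts, function(m)
    paste(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L], m[, 6L], sep = ":"))
  lines <- do.call(paste, c(list(sites$chrom, sites$pos, sites$ref), cols,
                            list(sep = "\t")))
  if (is.null(path)) return(lines)
  data.table::fwrite(list(lines), path, quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sync
#' @param text path to a sync file, or a character vector of sync lines.
#' @export
read_sync <- function(text) {
  dt <- if (length(text) == 1L && file.exists(text)) {
    data.table::fread(text, header = FALSE, sep = "\t", colClasses = "character")
  } else {
    data.table::fread(text = text, header = FALSE, sep = "\t",
                      colClasses = "character")
  }
  if (ncol(dt) < 4L) stop("sync input needs >= 4 columns")
  np <- ncol(dt) - 3L
  counts <- vector("list", np)
  for (p in seq_len(np)) {
    parts <- data.table::tstrsplit(dt[[3L + p]], ":", fixed = TRUE)
    if (length(parts) != 6L)
      stop(sprintf("sync pool column %d: expected 6 ':'-separated fields", p))
    m <- matrix(0L, nrow(dt), 6L, dimnames = list(NULL, COUNT_COLS))
    for (k in 1:6) {
      v <- suppressWarnings(as.integer(parts[[k]]))
      if (anyNA(v)) stop(sprintf("sync pool column %d: non-integer count", p))
      m[, k] <- v
    }
    counts[[p]] <- m
  }
  site_counts(dt[[1L]], as.integer(dt[[2L]]), dt[[3L]], counts)
}

## ---------------------------------------------------------------- masking --

#' Identify indel-contaminated regions
#'
#' Every site whose summed indel evidence across pools reaches `min_count`
#' contributes a closed interval `[pos - flank, pos + flank]`; overlapping
#' intervals are merged. Mirrors the usual practice of excluding windows
#' around indels before diversity estimation.
#'
#' @param sites a `site_counts` object carrying indel evidence.
#' @param min_count minimum summed indel evidence; default 2.
#' @param flank flank in bp added on both sides; default 5.
#' @return a `data.table` (chrom, start, end) of merged 1-based closed
#'   intervals, class `mask_intervals`.
#' @export
identify_indel_regions <- function(sites, min_count = 2L, flank = 5L) {
  if (flank < 0L) stop("flank must be >= 0")
  tot <- rowSums(sites$indels)
  hit <- which(tot >= min_count)
  if (!length(hit)) {
    return(empty_mask())
  }
  dt <- data.table::data.table(chrom = sites$chrom[hit],
                               start = pmax(1L, sites$pos[hit] - as.integer(flank)),
                               end = sites$pos[hit] + as.integer(flank))
  merge_mask(dt)
}

empty_mask <- function() {
  m <- data.table::data.table(chrom = character(), start = integer(),
                              end = integer())
  data.table::setattr(m, "class", c("mask_intervals", class(m)))
  m[]
}

#' Merge overlapping 1-based closed intervals into a mask
#' @param dt data.table/data.frame with chrom, start, end.
#' @export
merge_mask <- function(dt) {
  dt <- data.table::as.data.table(dt)[order(chrom, start, end)]
  if (nrow(dt) == 0L) return(empty_mask())
  if (any(dt$start > dt$end)) stop("mask interval with start > end")
  out <- dt[, {
    ir <- IRanges::reduce(IRanges::IRanges(start, end))
    list(start = IRanges::start(ir), end = IRanges::end(ir))
  }, by = chrom]
  data.table::setattr(out, "class", c("mask_intervals", class(out)))
  out[]
}

#' Drop sites falling inside mask intervals
#' @param sites a `site_counts` object.
#' @param mask a `mask_intervals` table (merged, 1-based closed).
#' @export
apply_mask <- function(sites, mask) {
  if (is.null(mask) || nrow(mask) == 0L) return(sites)
  drop <- rep(FALSE, length(sites$pos))
  for (ch in unique(mask$chrom)) {
    m <- mask[mask$chrom == ch, ]
    idx <- which(sites$chrom == ch)
    if (!length(idx)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$pos[idx], width = 1L),
      IRanges::IRanges(m$start, m$end))
    drop[idx[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  subset_sites(sites, !drop)
}

## --------------------------------------------------------------- features --

#' Read a TE hierarchy table (id, family, order)
#' @param path tab-separated file with header columns id, family, order.
#' @export
read_te_hierarchy <- function(path) {
  h <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  data.table::setnames(h, tolower(names(h)))
  if (!all(c("id", "family", "order") %in% names(h)))
    stop("TE hierarchy needs columns: id, family, order")
  if (anyDuplicated(h$id)) stop("TE hierarchy ids must be unique")
  h[]
}

#' Read genomic features (GFF3 or BED) into a flat interval table
#'
#' Returns a `data.table` with 1-based inclusive `chrom,start,end,strand,
#' type,attr` columns. BED input (detected from the extension or forced with
#' `format = "bed"`) is converted from 0-based half-open coordinates.
#'
#' @param path file path.
#' @param format `"gff3"` or `"bed"`; guessed from the extension by default.
#' @export
read_features <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (format == "bed") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
    out <- data.table::data.table(
      chrom = as.character(dt[[1L]]),
      start = as.integer(dt[[2L]]) + 1L,  # BED is 0-based half-open
      end = as.integer(dt[[3L]]),
      strand = if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "*",
      type = "region",
      attr = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NA_character_)
    return(out[])
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          quote = "", colClasses = "character")
  if (ncol(dt) < 9L) stop("GFF3 input needs 9 columns")
  data.table::data.table(
    chrom = dt[[1L]], start = as.integer(dt[[4L]]), end = as.integer(dt[[5L]]),
    strand = dt[[7L]], type = dt[[3L]], frame = dt[[8L]], attr = dt[[9L]])[]
}

gff_attr <- function(attr, key) {
  out <- rep(NA_character_, length(attr))
  pat <- paste0(".*(?:^|;)\\s*", key, "=([^;]*).*")
  idx <- grepl(paste0(key, "="), attr)
  out[idx] <- sub(pat, "\\1", attr[idx])
  out
}
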