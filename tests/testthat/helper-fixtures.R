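## Fixture builders shared across test files. Everything is generated in
## code; no binary fixtures.

NUC4 <- c("A", "T", "C", "G")

count_row <- function(A = 0, T = 0, C = 0, G = 0, N = 0, del = 0) {
  matrix(c(A, T, C, G, N, del), 1, 6,
         dimnames = list(NULL, c("A", "T", "C", "G", "N", "del")))
}

## one-pool site_counts from a matrix of nucleotide counts
sites_from <- function(mat, chrom = "c1", pos = seq_len(nrow(mat)),
                       ref = "A") {
  site_counts(chrom, pos, ref, list(mat))
}

random_counts <- function(n, max_cov = 60) {
  m <- matrix(0L, n, 6, dimnames = list(NULL, c("A","T","C","G","N","del")))
  for (i in seq_len(n)) {
    cv <- sample(2:max_cov, 1)
    p <- as.vector(stats::rmultinom(1, cv, prob = c(runif(2), 0.02, 0.02)))
    m[i, 1:4] <- p
  }
  m
}

## brute-force mean pairwise difference among reads at one site
brute_pi <- function(counts4) {
  reads <- rep(NUC4, counts4)
  if (length(reads) < 2) return(NA_real_)
  pr <- utils::combn(length(reads), 2)
  mean(reads[pr[1, ]] != reads[pr[2, ]])
}

random_dna <- function(n) paste(sample(NUC4, n, replace = TRUE), collapse = "")

## small two-family TE world for caller tests
te_world <- function(n_per_freq = 10, freqs = seq(0.1, 1, by = 0.1),
                     spacing = 2000L, seed = 99) {
  withr::with_seed(seed, {
    n <- n_per_freq * length(freqs)
    data.table::data.table(
      chrom = "simTE",
      pos = sort(sample(seq(2000L, n * spacing + 2000L, by = spacing %/% 2L), n)),
      family = sample(c("famA", "famB"), n, TRUE),
      frequency = rep(freqs, each = n_per_freq))
  })
}

match_calls <- function(calls, truth, tol = 50L) {
  det <- logical(nrow(truth)); ferr <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- calls[calls$family == truth$family[i] &
                    abs(calls$pos - truth$pos[i]) <= tol, ]
    if (nrow(cand)) {
      det[i] <- TRUE
      j <- which.min(abs(cand$pos - truth$pos[i]))
      ferr[i] <- abs(cand$frequency[j] - truth$frequency[i])
    }
  }
  list(detected = det, freq_err = ferr)
}

## verify the two compact-letter-display axioms exhaustively
cld_ok <- function(letters, sig) {
  g <- names(letters)
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i >= j) next
    share <- length(intersect(strsplit(letters[[i]], "")[[1]],
                              strsplit(letters[[j]], "")[[1]])) > 0
    if (sig[g[i], g[j]] && share) return(FALSE)
    if (!sig[g[i], g[j]] && !share) return(FALSE)
  }
  all(nzchar(letters))
}
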