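## Small shared helpers.

## Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
## state afterwards. All stochastic operations in the package route through
## this so a recorded seed reproduces outputs bit-for-bit.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## derive a child seed < 2^31 from a parent seed and a stream label
child_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + s) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1L]]),
          collapse = ""), character(1L), USE.NAMES = FALSE)
}
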