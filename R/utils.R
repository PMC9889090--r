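# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All seeded operations in the package go through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Validate a DNA string; returns it uppercased. `allow_n` admits N.
check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) stop(what, " must be non-empty", call. = FALSE)
  x <- toupper(x)
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% alphabet)
  if (length(bad)) {
    stop(sprintf("%s contains non-%s character '%s' at position %d",
                 what, if (allow_n) "ACGTN" else "ACGT",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  x
}

# Start positions (1-based) of all, possibly overlapping, occurrences of
# `motif` in `x`. Motifs never match across N.
motif_starts <- function(x, motif) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                   Biostrings::DNAString(x), fixed = TRUE)
  BiocGenerics::start(hits)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
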