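#' Alignment scoring parameters
#'
#' Defaults mirror the EMBOSS Water DNA scoring scheme: match +5,
#' mismatch -4, gap open 10, gap extend 0.5, where a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. Half-unit scores are handled exactly
#' (scores are doubled to integers internally).
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (typically negative).
#' @param gap_open Penalty charged for the first residue of a gap.
#' @param gap_extend Penalty for each additional gap residue;
#'   `gap_open >= gap_extend >= 0`.
#' @return An `AlignmentParams`.
#' @export
alignment_params <- function(match = 5, mismatch = -4,
                             gap_open = 10, gap_extend = 0.5) {
  stopifnot(match > 0, gap_open >= gap_extend, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "AlignmentParams")
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Returns the single best-scoring local alignment, as Water reports.
#' Matching is case-insensitive; `N` scores as a mismatch against
#' everything. Ties are broken deterministically: the traceback prefers a
#' diagonal step, then a gap in `b`, then a gap in `a`, and starts from the
#' highest-scoring cell with the smallest `(i, j)` lexicographically.
#'
#' @param a,b DNA strings (non-empty).
#' @param params An [alignment_params()].
#' @return A `LocalAlignment`: `score`; `a_pos`, `b_pos` (1-based position
#'   per alignment column, `NA` at gaps); `a_start`/`a_end`,
#'   `b_start`/`b_end` (1-based inclusive; 0s when the alignment is empty);
#'   and the input sequences.
#' @examples
#' local_align("ACGTACGT", "ACGTTCGT")
#' @export
local_align <- function(a, b, params = alignment_params()) {
  stopifnot(inherits(params, "AlignmentParams"))
  a <- check_dna(a, "sequence a")
  b <- check_dna(b, "sequence b")
  r <- .sw_align_cpp(a, b, params$match, params$mismatch,
                     params$gap_open, params$gap_extend)
  apos <- r$a_pos; bpos <- r$b_pos
  structure(list(score = r$score, a_pos = apos, b_pos = bpos,
                 a_start = if (length(apos)) min(apos, na.rm = TRUE) else 0L,
                 a_end = if (length(apos)) max(apos, na.rm = TRUE) else 0L,
                 b_start = if (length(bpos)) min(bpos, na.rm = TRUE) else 0L,
                 b_end = if (length(bpos)) max(bpos, na.rm = TRUE) else 0L,
                 a = a, b = b, params = params),
            class = "LocalAlignment")
}

#' @export
print.LocalAlignment <- function(x, ...) {
  cat(sprintf("<LocalAlignment> score %.1f, %d columns, a:%d-%d b:%d-%d\n",
              x$score, length(x$a_pos), x$a_start, x$a_end,
              x$b_start, x$b_end))
  invisible(x)
}

# brute-force oracle: exhaustive enumeration of gapped local alignments
# (exported for verification work; exponential, keep sequences short)
#' Brute-force local alignment score by exhaustive enumeration
#'
#' Enumerates every gapped local alignment as an increasing chain of
#' matched column pairs and returns the maximum score. Independent of the
#' dynamic-programming path in [local_align()]; exponential, intended for
#' sequences of roughly 12 nt or fewer.
#'
#' @inheritParams local_align
#' @return The optimal local alignment score (numeric).
#' @export
enumerate_local_score <- function(a, b, params = alignment_params()) {
  stopifnot(inherits(params, "AlignmentParams"))
  .sw_enumerate_cpp(toupper(a), toupper(b), params$match, params$mismatch,
                    params$gap_open, params$gap_extend)
}

#' Extract gapless conserved stretches from a local alignment
#'
#' Splits the alignment into maximal runs of gap-free columns and emits
#' every run of at least `min_len` columns, with paired coordinates in both
#' sequences and per-stretch identity. Substitutions are allowed inside a
#' stretch; indels terminate it.
#'
#' @param aln A `LocalAlignment`.
#' @param min_len Minimum stretch length in bp (default 20).
#' @return data.frame `a_start`, `a_end`, `b_start`, `b_end` (0-based
#'   half-open), `length`, `identity`; zero rows when nothing qualifies.
#' @export
conserved_stretches <- function(aln, min_len = 20L) {
  stopifnot(inherits(aln, "LocalAlignment"), min_len >= 1)
  gapfree <- !is.na(aln$a_pos) & !is.na(aln$b_pos)
  out <- data.frame(a_start = integer(0), a_end = integer(0),
                    b_start = integer(0), b_end = integer(0),
                    length = integer(0), identity = numeric(0))
  if (!length(gapfree)) return(out)
  r <- rle(gapfree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ach <- strsplit(aln$a, "", fixed = TRUE)[[1L]]
  bch <- strsplit(aln$b, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (k in which(r$values & r$lengths >= min_len)) {
    cols <- starts[k]:ends[k]
    ap <- aln$a_pos[cols]; bp <- aln$b_pos[cols]
    ident <- mean(ach[ap] == bch[bp] & ach[ap] != "N")
    rows[[length(rows) + 1L]] <- data.frame(
      a_start = ap[1L] - 1L, a_end = ap[length(ap)],
      b_start = bp[1L] - 1L, b_end = bp[length(bp)],
      length = length(cols), identity = ident)
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize conserved stretches
#'
#' Coverage of each sequence by conserved stretches, plus the paired
#' segment-endpoint table used to draw connecting lines between the two
#' sequence boxes.
#'
#' @param stretches data.frame from [conserved_stretches()].
#' @param a_len,b_len Full lengths of the two input sequences.
#' @return list: `n_stretches`, `covered_a`, `covered_b`, `coverage_a`,
#'   `coverage_b`, `mean_identity`, and `segments` (the stretch table).
#' @export
conservation_summary <- function(stretches, a_len, b_len) {
  stopifnot(a_len >= 1, b_len >= 1)
  cov_a <- sum(stretches$length)
  cov_b <- sum(stretches$length)
  list(n_stretches = nrow(stretches),
       covered_a = cov_a, covered_b = cov_b,
       coverage_a = cov_a / a_len, coverage_b = cov_b / b_len,
       mean_identity = if (nrow(stretches)) mean(stretches$identity) else NA_real_,
       segments = stretches)
}

#' Conservation analysis of two sequences
#'
#' Convenience wrapper: locally aligns `a` to `b`, extracts gapless
#' stretches of at least `min_len` bp, and summarizes coverage. Sub-region
#' analyses (individual exons, an enhancer) are run by calling this on the
#' extracted subsequences.
#'
#' @inheritParams local_align
#' @param min_len Minimum conserved-stretch length (default 20).
#' @return list: `alignment`, `stretches`, `summary`.
#' @export
conservation_analysis <- function(a, b, params = alignment_params(),
                                  min_len = 20L) {
  aln <- local_align(a, b, params)
  st <- conserved_stretches(aln, min_len = min_len)
  list(alignment = aln, stretches = st,
       summary = conservation_summary(st, nchar(a), nchar(b)))
}
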