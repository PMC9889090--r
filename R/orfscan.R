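STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Enumerate open reading frames in a transcript
#'
#' Finds every ATG-initiated ORF in the three forward frames of the given
#' (stranded) transcript, extending each start to the first in-frame stop
#' codon. Nested ORFs from internal ATGs are all reported. Starts with no
#' downstream in-frame stop run to the transcript end and are flagged
#' `open_ended`; these are excluded by default.
#'
#' @param transcript DNA/RNA string (U is treated as T).
#' @param transcript_id Label carried into the output.
#' @param min_aa Minimum ORF length in codons, stop codon excluded
#'   (default 0 = no filter).
#' @param include_open_ended Keep stop-less ORFs (default `FALSE`).
#' @return data.frame: `transcript_id`, `frame` (0/1/2), `start`, `end`
#'   (0-based half-open in transcript coordinates; `end` includes the stop
#'   codon when present), `aa_length` (codons excluding the stop),
#'   `open_ended`, `seq`.
#' @examples
#' enumerate_orfs("AAATGAAACCCTAAGG")
#' @export
enumerate_orfs <- function(transcript, transcript_id = "tx",
                           min_aa = 0L, include_open_ended = FALSE) {
  transcript <- gsub("U", "T", toupper(transcript), fixed = TRUE)
  transcript <- check_dna(transcript, "transcript")
  n <- nchar(transcript)
  rows <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    cstart <- frame + 3L * (seq_len(ncod) - 1L) + 1L # 1-based codon starts
    codons <- substring(transcript, cstart, cstart + 2L)
    starts <- which(codons == "ATG")
    if (!length(starts)) next
    stops <- which(codons %in% STOP_CODONS)
    # first stop at or after each start
    nxt <- if (length(stops))
      stops[findInterval(starts - 1L, stops) + 1L] else
      rep(NA_integer_, length(starts))
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- nxt[k]
      open_ended <- is.na(e)
      if (open_ended && !include_open_ended) next
      aa_len <- if (open_ended) ncod - s + 1L else e - s
      if (aa_len < min_aa || aa_len < 1L) next
      start0 <- cstart[s] - 1L
      end0 <- if (open_ended) cstart[ncod] + 2L else cstart[e] + 2L
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = transcript_id, frame = frame,
        start = start0, end = end0, aa_length = aa_len,
        open_ended = open_ended,
        seq = substring(transcript, start0 + 1L, end0),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_length = integer(0), open_ended = logical(0),
                      seq = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Codon-frequency log-odds scorer
#'
#' A deterministic toy coding-potential scorer satisfying the scorer
#' contract (ORF record in, one real score out): the mean per-codon
#' log-odds of the ORF's codon usage against a uniform background, using a
#' fixed human-like codon-frequency table. It exists so the distribution
#' machinery can be exercised end to end; it is not a phylogenetic
#' codon-substitution model and makes no claim of comparability with one.
#'
#' @return A scorer function `(orf_seq) -> numeric`.
#' @export
codon_logodds_scorer <- function() {
  # fixed pseudo-frequency table: rank codons by GC content as a crude
  # proxy for coding bias; normalized within the 61 sense codons
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, STOP_CODONS)
  gc <- vapply(strsplit(sense, ""), function(x) sum(x %in% c("G", "C")),
               numeric(1L))
  w <- (1 + gc)^2
  freq <- setNames(w / sum(w), sense)
  bg <- 1 / length(sense)
  function(orf_seq) {
    orf_seq <- toupper(orf_seq)
    ncod <- nchar(orf_seq) %/% 3L
    cs <- 3L * (seq_len(ncod) - 1L) + 1L
    cods <- substring(orf_seq, cs, cs + 2L)
    cods <- cods[!cods %in% STOP_CODONS]
    if (!length(cods)) return(0)
    mean(log2(freq[cods] / bg))
  }
}

#' Score a table of ORFs
#'
#' @param orfs data.frame from [enumerate_orfs()].
#' @param scorer A function `(orf_seq) -> numeric`; defaults to
#'   [codon_logodds_scorer()].
#' @return `orfs` with a numeric `score` column appended.
#' @export
score_orfs <- function(orfs, scorer = codon_logodds_scorer()) {
  orfs$score <- vapply(orfs$seq, scorer, numeric(1L), USE.NAMES = FALSE)
  orfs
}

#' Reproducible subsample of ORF scores
#'
#' Uniform sampling without replacement under a fixed seed, leaving the
#' caller's RNG stream untouched.
#'
#' @param scores Numeric vector (the score population).
#' @param n Sample size; must not exceed the population.
#' @param seed Integer seed.
#' @return Numeric vector of `n` sampled scores.
#' @export
sample_orf_scores <- function(scores, n, seed) {
  if (n > length(scores))
    stop("sample size ", n, " exceeds population size ", length(scores))
  with_seed(seed, scores[sample.int(length(scores), n)])
}

#' Trim a score set to its central percentile window
#'
#' Retains the scores inside the closed interval between the `lo` and `hi`
#' empirical percentiles. Percentiles use linear interpolation between
#' order statistics (`stats::quantile` type 7), so for large continuous
#' samples the retained fraction approaches `(hi - lo) / 100`.
#'
#' @param scores Numeric vector (at least 2 values).
#' @param lo,hi Percentile bounds (defaults 2.5 and 97.5).
#' @return A `ScoreDistribution`: `scores`, `trimmed`, `n_total`,
#'   `n_trimmed`, `bounds`.
#' @export
percentile_window <- function(scores, lo = 2.5, hi = 97.5) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  stopifnot(lo >= 0, hi <= 100, lo < hi)
  q <- quantile(scores, probs = c(lo, hi) / 100, type = 7, names = FALSE)
  keep <- scores >= q[1L] & scores <= q[2L]
  structure(list(scores = scores, trimmed = scores[keep],
                 n_total = length(scores), n_trimmed = sum(keep),
                 bounds = q),
            class = "ScoreDistribution")
}

#' @export
print.ScoreDistribution <- function(x, ...) {
  cat(sprintf("<ScoreDistribution> %d of %d scores in [%.4g, %.4g] (%.1f%%)\n",
              x$n_trimmed, x$n_total, x$bounds[1L], x$bounds[2L],
              100 * x$n_trimmed / x$n_total))
  invisible(x)
}

#' Equal-area density comparison of two score sets
#'
#' Kernel densities of both sets on a shared grid, each rescaled so its
#' trapezoid integral over the grid is exactly 1 — the two curves enclose
#' equal areas regardless of sample sizes. Also reports the ratio of
#' medians.
#'
#' @param set_a,set_b Non-empty numeric vectors.
#' @param n_grid Grid resolution (default 512).
#' @param bw Bandwidth passed to [stats::density()] (default "nrd0").
#' @return list: `table` (data.frame `score`, `density_a`, `density_b`),
#'   `median_a`, `median_b`, `median_ratio`.
#' @export
compare_distributions <- function(set_a, set_b, n_grid = 512L, bw = "nrd0") {
  stopifnot(length(set_a) >= 1L, length(set_b) >= 1L)
  rng <- range(c(set_a, set_b))
  pad <- diff(rng) * 0.1 + 1e-9
  from <- rng[1L] - pad; to <- rng[2L] + pad
  dens <- function(x) {
    if (length(x) == 1L || diff(range(x)) == 0) {
      # degenerate: a narrow gaussian around the single value
      d <- density(x, bw = 0.01 * max(1, abs(x[1L])), from = from, to = to,
                   n = n_grid)
    } else {
      d <- density(x, bw = bw, from = from, to = to, n = n_grid)
    }
    y <- d$y
    area <- sum(diff(d$x) * (y[-1L] + y[-length(y)]) / 2)
    list(x = d$x, y = y / area)
  }
  da <- dens(set_a); db <- dens(set_b)
  list(table = data.frame(score = da$x, density_a = da$y, density_b = db$y),
       median_a = median(set_a), median_b = median(set_b),
       median_ratio = median(set_a) / median(set_b))
}
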