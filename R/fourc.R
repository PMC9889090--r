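#' Primer trimming specification
#'
#' Mirrors the contract of adapter trimming with `--discard-untrimmed
#' -e 0.05 -m 25`: a read is kept only when its 5' end matches the
#' viewpoint primer within the error rate, the primer is removed, and reads
#' falling below the minimum length are dropped.
#'
#' @param primer Primer sequence expected at the 5' end of every read.
#' @param max_error_rate Maximum fraction of mismatches in the primer match
#'   (mismatch-only, indel-free). Allowed errors =
#'   `floor(nchar(primer) * max_error_rate)`. Default 0.05.
#' @param min_len_after_trim Minimum read length after primer removal;
#'   shorter reads are dropped. Default 25.
#' @param discard_untrimmed Drop reads without a primer match (default
#'   `TRUE`, matching the published filtering).
#' @return An object of class `TrimSpec`.
#' @export
trim_spec <- function(primer, max_error_rate = 0.05,
                      min_len_after_trim = 25L, discard_untrimmed = TRUE) {
  primer <- check_dna(primer, "primer", allow_n = FALSE)
  stopifnot(max_error_rate >= 0, max_error_rate < 1, min_len_after_trim >= 1)
  structure(list(primer = primer,
                 max_error_rate = max_error_rate,
                 min_len_after_trim = as.integer(min_len_after_trim),
                 discard_untrimmed = isTRUE(discard_untrimmed)),
            class = "TrimSpec")
}

#' Trim the viewpoint primer off 4C reads
#'
#' @param reads A data.frame with columns `id` and `seq` (see
#'   [read_reads()]).
#' @param spec A [trim_spec()].
#' @return The surviving reads with primers removed; attribute `tally`
#'   records reads in, primer-matched, and kept.
#' @export
trim_reads <- function(reads, spec) {
  stopifnot(inherits(spec, "TrimSpec"),
            is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  seq <- toupper(reads$seq)
  np <- nchar(spec$primer)
  allowed <- floor(np * spec$max_error_rate)
  pb <- strsplit(spec$primer, "", fixed = TRUE)[[1L]]
  mism <- integer(nrow(reads))
  for (i in seq_len(np)) mism <- mism + (substr(seq, i, i) != pb[i])
  matched <- nchar(seq) >= np & mism <= allowed
  out_seq <- ifelse(matched, substring(seq, np + 1L), seq)
  keep <- if (spec$discard_untrimmed) matched else rep(TRUE, length(seq))
  keep <- keep & nchar(out_seq) >= spec$min_len_after_trim
  out <- reads[keep, , drop = FALSE]
  out$seq <- out_seq[keep]
  rownames(out) <- NULL
  attr(out, "tally") <- c(input = nrow(reads),
                          primer_matched = sum(matched),
                          kept = sum(keep))
  out
}

#' Exact-match reference aligner
#'
#' Builds the mapping contract used by [iterative_map()]: a function taking
#' a character vector of read sequences and returning one row per read with
#' `mapped`, `chrom`, `pos` (0-based leftmost), `strand`. A read maps only
#' when it occurs exactly once in the genome across both strands;
#' multi-mapping or absent sequences are reported unmapped. Sufficient for
#' synthetic genomes; any function honouring the same contract (e.g. an
#' adapter around an external short-read aligner) can stand in.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @return A function `(seqs) -> data.frame(mapped, chrom, pos, strand)`.
#' @export
exact_aligner <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome <- toupper(genome)
  rc <- vapply(genome, reverse_complement, character(1L))
  # lazy per-(chrom, length) tables of fixed-width substrings; R's string
  # hash makes match() against these effectively O(1) per read
  cache <- new.env(parent = emptyenv())
  tables_for <- function(chr, len) {
    key <- paste0(chr, ":", len)
    if (!is.null(cache[[key]])) return(cache[[key]])
    g <- genome[[chr]]
    n <- nchar(g)
    if (len > n) {
      t <- list(fwd = character(0), rev = character(0),
                dup = character(0), n = n)
    } else {
      starts <- seq_len(n - len + 1L)
      fwd <- substring(g, starts, starts + len - 1L)
      rev <- substring(rc[[chr]], starts, starts + len - 1L)
      dup <- unique(c(fwd[duplicated(fwd)], rev[duplicated(rev)],
                      intersect(fwd, rev)))
      t <- list(fwd = fwd, rev = rev, dup = dup, n = n)
    }
    cache[[key]] <- t
    t
  }

  function(seqs) {
    n <- length(seqs)
    res <- data.frame(mapped = logical(n), chrom = NA_character_,
                      pos = NA_integer_, strand = NA_character_,
                      stringsAsFactors = FALSE)
    if (n == 0L) return(res)
    seqs <- toupper(seqs)
    clean <- !grepl("[^ACGT]", seqs)
    hits_n <- integer(n)
    for (len in unique(nchar(seqs[clean]))) {
      sel <- which(clean & nchar(seqs) == len)
      ss <- seqs[sel]
      for (chr in names(genome)) {
        t <- tables_for(chr, len)
        if (!length(t$fwd)) next
        iF <- match(ss, t$fwd)
        iR <- match(ss, t$rev)
        multi <- ss %in% t$dup
        hit <- (!is.na(iF) | !is.na(iR))
        hits_n[sel] <- hits_n[sel] + hit + multi # >1 marks ambiguity
        one_f <- hit & !multi & !is.na(iF)
        one_r <- hit & !multi & is.na(iF)
        if (any(one_f)) {
          idx <- sel[one_f]
          fill <- is.na(res$pos[idx])
          res$chrom[idx][fill] <- chr
          res$pos[idx][fill] <- iF[one_f][fill] - 1L
          res$strand[idx][fill] <- "+"
        }
        if (any(one_r)) {
          idx <- sel[one_r]
          fill <- is.na(res$pos[idx])
          # position j in the reverse-complement strand corresponds to
          # leftmost genomic coordinate n - j - len + 2 (1-based)
          res$chrom[idx][fill] <- chr
          res$pos[idx][fill] <- (t$n - iR[one_r][fill] - len + 2L) - 1L
          res$strand[idx][fill] <- "-"
        }
      }
    }
    res$mapped <- hits_n == 1L
    res$chrom[!res$mapped] <- NA_character_
    res$pos[!res$mapped] <- NA_integer_
    res$strand[!res$mapped] <- NA_character_
    res
  }
}

#' Iterative 3'-end trimming and mapping
#'
#' The 4C mapping loop: each read is first mapped at full length; while it
#' stays unmapped, exactly 5 nt are removed from its 3' end and mapping is
#' retried, until it maps or the remaining length drops below 25 bp.
#'
#' @param reads A data.frame with columns `id` and `seq`.
#' @param genome Named character vector / `DNAStringSet`; used to build the
#'   default [exact_aligner()] when `aligner` is `NULL`.
#' @param aligner Optional mapping function honouring the
#'   [exact_aligner()] contract.
#' @param min_len Minimum mappable length (default 25). Reads already
#'   shorter than this are reported unmapped without a mapping attempt.
#' @param trim_step Bases removed from the 3' end per round (default 5).
#' @return data.frame: `read_id`, `mapped`, `chrom`, `pos` (0-based
#'   leftmost), `strand`, `final_length` (length at which mapping succeeded,
#'   or the sub-threshold length at termination), `n_trims`.
#' @export
iterative_map <- function(reads, genome = NULL, aligner = NULL,
                          min_len = 25L, trim_step = 5L) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (is.null(aligner)) {
    if (is.null(genome)) stop("provide either `genome` or `aligner`")
    aligner <- exact_aligner(genome)
  }
  n <- nrow(reads)
  out <- data.frame(read_id = reads$id, mapped = FALSE,
                    chrom = NA_character_, pos = NA_integer_,
                    strand = NA_character_,
                    final_length = nchar(reads$seq), n_trims = 0L,
                    stringsAsFactors = FALSE)
  seqs <- toupper(reads$seq)
  active <- which(nchar(seqs) >= min_len)
  while (length(active)) {
    res <- tryCatch(aligner(seqs[active]), error = function(e) {
      stop("aligner failed on reads starting at '", reads$id[active[1L]],
           "': ", conditionMessage(e), call. = FALSE)
    })
    hit <- which(res$mapped)
    if (length(hit)) {
      idx <- active[hit]
      out$mapped[idx] <- TRUE
      out$chrom[idx] <- res$chrom[hit]
      out$pos[idx] <- res$pos[hit]
      out$strand[idx] <- res$strand[hit]
      out$final_length[idx] <- nchar(seqs[idx])
    }
    active <- active[!res$mapped]
    if (!length(active)) break
    seqs[active] <- substr(seqs[active], 1L,
                           nchar(seqs[active]) - trim_step)
    out$n_trims[active] <- out$n_trims[active] + 1L
    out$final_length[active] <- nchar(seqs[active])
    active <- active[nchar(seqs[active]) >= min_len]
  }
  out
}

#' Assign mapped reads to restriction fragments
#'
#' Each mapped read increments the fragment containing its 5'-most genomic
#' coordinate (leftmost position for + reads, rightmost for - reads, since
#' 4C reads start at the restriction site). Reads landing in invalid
#' fragments are dropped when `exclude_invalid`.
#'
#' @param mappings Output of [iterative_map()].
#' @param fragmap A `FragmentMap` over the same genome.
#' @param exclude_invalid Drop reads in invalid (blind or too-short)
#'   fragments (default `TRUE`).
#' @return list with `counts` (integer vector parallel to
#'   `fragmap$fragments`) and `tally` (input / mapped / counted /
#'   dropped_invalid / unmapped).
#' @export
assign_to_fragments <- function(mappings, fragmap, exclude_invalid = TRUE) {
  stopifnot(inherits(fragmap, "FragmentMap"))
  f <- fragmap$fragments
  counts <- integer(nrow(f))
  m <- mappings[mappings$mapped, , drop = FALSE]
  dropped <- 0L
  if (nrow(m)) {
    coord5 <- ifelse(m$strand == "+", m$pos, m$pos + m$final_length - 1L)
    for (chr in unique(m$chrom)) {
      rows <- which(f$chrom == chr)
      if (!length(rows))
        stop("mapped read on '", chr, "' not covered by the fragment map")
      sel <- which(m$chrom == chr)
      x <- coord5[sel]
      if (any(x < f$start[rows[1L]] | x >= f$end[rows[length(rows)]]))
        stop("mapped coordinate outside the fragment map on ", chr,
             " (genome/fragment-map mismatch)")
      k <- findInterval(x, f$start[rows])
      hit <- rows[k]
      if (exclude_invalid) {
        ok <- f$valid[hit]
        dropped <- dropped + sum(!ok)
        hit <- hit[ok]
      }
      tb <- tabulate(hit, nbins = nrow(f))
      counts <- counts + tb
    }
  }
  list(counts = counts,
       tally = c(input = nrow(mappings), mapped = nrow(m),
                 counted = sum(counts), dropped_invalid = dropped,
                 unmapped = nrow(mappings) - nrow(m)))
}

#' Reads-per-million normalization
#'
#' `rpm_i = counts_i / sum(counts) * 1e6`; an all-zero library stays zero.
#'
#' @param counts Non-negative numeric vector.
#' @return Numeric vector summing to 1e6 (or all zeros).
#' @export
rpm_normalize <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  tot <- sum(counts)
  if (tot == 0) return(numeric(length(counts)))
  counts / tot * 1e6
}

#' Closest-five-fragment smoothing
#'
#' Replaces each fragment's value by the mean over the closest five
#' fragments. The default reading is the centered index window
#' `i-2 .. i+2`, truncated at chromosome ends; fragments on other
#' chromosomes never enter a window. `method = "distance"` instead picks
#' the five fragments nearest by genomic midpoint distance (self included).
#'
#' @param values Numeric vector, one value per fragment.
#' @param chrom Optional chromosome of each fragment (same length); when
#'   `NULL`, all values are treated as one chromosome.
#' @param k Window size (odd, default 5).
#' @param method `"index"` (default) or `"distance"`.
#' @param midpoints Fragment midpoints, required for `method = "distance"`.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_profile <- function(values, chrom = NULL, k = 5L,
                           method = c("index", "distance"),
                           midpoints = NULL) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("empty profile")
  stopifnot(k >= 1L, k %% 2L == 1L)
  if (is.null(chrom)) chrom <- rep("*", length(values))
  stopifnot(length(chrom) == length(values))
  out <- numeric(length(values))
  half <- (k - 1L) %/% 2L
  for (chr in unique(chrom)) {
    sel <- which(chrom == chr)
    x <- values[sel]
    n <- length(x)
    if (method == "index") {
      cs <- c(0, cumsum(x))
      i <- seq_len(n)
      lo <- pmax(1L, i - half)
      hi <- pmin(n, i + half)
      out[sel] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    } else {
      stopifnot(!is.null(midpoints), length(midpoints) == length(values))
      mp <- midpoints[sel]
      kk <- min(k, n)
      out[sel] <- vapply(seq_len(n), function(i) {
        nb <- order(abs(mp - mp[i]), seq_len(n))[seq_len(kk)]
        mean(x[nb])
      }, numeric(1L))
    }
  }
  out
}

parse_region <- function(x) {
  if (is.list(x)) return(x)
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1L]]
  if (length(m) != 4L) stop("cannot parse region '", x,
                            "' (expected chrom:start-end)")
  list(chrom = m[2L],
       start = as.integer(gsub(",", "", m[3L])),
       end = as.integer(gsub(",", "", m[4L])))
}

#' Run the full 4C viewpoint pipeline
#'
#' trim -> iterative map -> fragment assignment -> RPM -> smoothing, with
#' per-stage read tallies. Smoothing is applied to the RPM track by default
#' (`smooth_raw = TRUE` smooths raw counts instead).
#'
#' @inheritParams iterative_map
#' @param fragmap A `FragmentMap` for the same genome.
#' @param trimspec A [trim_spec()]; `NULL` skips trimming (reads already
#'   primer-free).
#' @param viewpoint Viewpoint region, `"chrom:start-end"` (1-based) or a
#'   list `(chrom, start, end)`; annotation only.
#' @param exclude_invalid Drop reads in invalid fragments (default `TRUE`).
#' @param smooth_raw Smooth raw counts instead of RPM.
#' @return A `FourCProfile`: fragments, `counts`, `rpm`, `smoothed`,
#'   stage `tally`, `viewpoint`.
#' @export
run_fourc <- function(reads, genome, fragmap, trimspec = NULL,
                      viewpoint = NULL, aligner = NULL,
                      exclude_invalid = TRUE, smooth_raw = FALSE,
                      min_len = 25L, trim_step = 5L) {
  stopifnot(inherits(fragmap, "FragmentMap"))
  tally <- list(input = nrow(reads))
  if (!is.null(trimspec)) {
    reads <- trim_reads(reads, trimspec)
    tally$after_trim <- nrow(reads)
  }
  f <- fragmap$fragments
  if (nrow(reads) == 0L) {
    warning("no reads survived trimming; returning an empty profile")
    return(structure(list(viewpoint = if (!is.null(viewpoint))
                            parse_region(viewpoint) else NULL,
                          fragments = f,
                          counts = integer(nrow(f)),
                          rpm = numeric(nrow(f)),
                          smoothed = numeric(nrow(f)),
                          tally = unlist(tally)),
                     class = "FourCProfile"))
  }
  mp <- iterative_map(reads, genome = genome, aligner = aligner,
                      min_len = min_len, trim_step = trim_step)
  asg <- assign_to_fragments(mp, fragmap, exclude_invalid = exclude_invalid)
  rpm <- rpm_normalize(asg$counts)
  sm <- smooth_profile(if (smooth_raw) asg$counts else rpm, chrom = f$chrom)
  structure(list(viewpoint = if (!is.null(viewpoint))
                   parse_region(viewpoint) else NULL,
                 fragments = f,
                 counts = asg$counts, rpm = rpm, smoothed = sm,
                 tally = c(unlist(tally), asg$tally[-1L])),
            class = "FourCProfile")
}

#' @export
print.FourCProfile <- function(x, ...) {
  cat(sprintf("<FourCProfile> %d fragments, %d reads counted\n",
              nrow(x$fragments), sum(x$counts)))
  if (!is.null(x$viewpoint))
    cat(sprintf("  viewpoint %s:%d-%d\n", x$viewpoint$chrom,
                x$viewpoint$start, x$viewpoint$end))
  cat("  tallies:", paste(names(x$tally), x$tally, sep = "=",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Write the three 4C tracks as bedGraph
#'
#' One line per fragment interval (0-based half-open), values rounded to 6
#' significant digits for byte-stable output.
#'
#' @param profile A `FourCProfile`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_fourc_tracks <- function(profile, dir, prefix = "fourc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- profile$fragments
  gr <- GenomicRanges::GRanges(f$chrom,
                               IRanges::IRanges(f$start + 1L, f$end))
  paths <- character(0)
  for (track in c("counts", "rpm", "smoothed")) {
    S4Vectors::mcols(gr)$score <- signif(profile[[track]], 6)
    p <- file.path(dir, paste0(prefix, ".", track, ".bedGraph"))
    rtracklayer::export(gr, p, format = "bedGraph")
    paths <- c(paths, p)
  }
  invisible(paths)
}
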