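# Shared fixtures, all generated in code.

nlaiii <- enzyme_spec("NlaIII", "CATG")
dpnii <- enzyme_spec("DpnII", "GATC")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent oracle: positions of all (overlapping) motif occurrences by a
# position-by-position substring comparison
naive_motif_starts <- function(x, motif) {
  x <- toupper(x); motif <- toupper(motif)
  w <- nchar(motif)
  n <- nchar(x)
  if (w > n) return(integer(0))
  which(vapply(seq_len(n - w + 1L), function(i)
    substr(x, i, i + w - 1L) == motif, logical(1L)))
}

# independent oracle for ORF enumeration: per-frame walk over codons with
# explicit state, no vectorized index arithmetic
naive_orf_scan <- function(tx, include_open_ended = FALSE) {
  tx <- gsub("U", "T", toupper(tx), fixed = TRUE)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (frame in 0:2) {
    i <- frame + 1L
    while (i + 2L <= nchar(tx)) {
      if (substr(tx, i, i + 2L) == "ATG") {
        j <- i
        found_stop <- FALSE
        while (j + 2L <= nchar(tx)) {
          if (substr(tx, j, j + 2L) %in% stops) { found_stop <- TRUE; break }
          j <- j + 3L
        }
        if (found_stop) {
          out[[length(out) + 1L]] <- data.frame(
            frame = frame, start = i - 1L, end = j + 2L,
            aa_length = (j - i) %/% 3L, open_ended = FALSE)
        } else if (include_open_ended) {
          last <- j - 1L # j overshot; last full codon ended at j - 1
          out[[length(out) + 1L]] <- data.frame(
            frame = frame, start = i - 1L, end = last,
            aa_length = (last - (i - 1L)) %/% 3L, open_ended = TRUE)
        }
      }
      i <- i + 3L
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), aa_length = integer(0),
                      open_ended = logical(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$frame), , drop = FALSE]
}

# a small spliced-read table covering both defined isoforms and sloppy reads
tiny_spliced_tbl <- function() {
  data.frame(
    read_id = c("r1", "r2", "r3", "r4"),
    chrom = "chr8",
    strand = "+",
    blocks = c("55125402-55125601,55140806-55141005",  # Ex1+2 junction
               "55123055-55123254,55140806-55141005",  # Ex1+3 junction
               "55125402-55125601,55130000-55130199",  # sloppy
               "55120000-55120399"),                   # unspliced
    stringsAsFactors = FALSE)
}
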