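#' Restriction enzyme specification
#'
#' A minimal description of a restriction enzyme: a label and its
#' unambiguous recognition motif. The 4C workflow uses two of these, a
#' primary cutter defining the fragment map (NlaIII, `CATG`) and a secondary
#' cutter whose sites determine fragment validity (DpnII, `GATC`).
#'
#' @param name Text label, e.g. `"NlaIII"`.
#' @param site Recognition motif; unambiguous DNA bases (A/C/G/T) only.
#' @return An object of class `EnzymeSpec`.
#' @examples
#' enzyme_spec("NlaIII", "CATG")
#' @export
enzyme_spec <- function(name, site) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  site <- check_dna(site, "recognition site", allow_n = FALSE)
  structure(list(name = name, site = site), class = "EnzymeSpec")
}

#' @export
print.EnzymeSpec <- function(x, ...) {
  cat(sprintf("<EnzymeSpec> %s (%s)\n", x$name, x$site))
  invisible(x)
}

#' In-silico digestion of a sequence by a restriction enzyme
#'
#' Scans the sequence left to right for every (possibly overlapping)
#' occurrence of the primary recognition motif and places a fragment
#' boundary at the start coordinate of each occurrence, so every fragment
#' except possibly the first begins with the recognition sequence. The
#' fragments tile `[0, nchar(sequence))` in 0-based half-open coordinates.
#' Motifs never match across an `N`.
#'
#' @param sequence DNA string (A/C/G/T/N; case-insensitive).
#' @param chrom Sequence (chromosome) name.
#' @param primary An [enzyme_spec()] for the primary cutter.
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `index` (0-based ordinal along the chromosome).
#' @examples
#' digest("TTTCATGAAACATGGG", "chrA", enzyme_spec("NlaIII", "CATG"))
#' @export
digest <- function(sequence, chrom, primary) {
  stopifnot(inherits(primary, "EnzymeSpec"))
  sequence <- check_dna(sequence, "sequence")
  starts1 <- motif_starts(sequence, primary$site) # 1-based
  bounds0 <- unique(c(0L, starts1 - 1L, nchar(sequence)))
  bounds0 <- sort(bounds0)
  n <- length(bounds0) - 1L
  data.frame(chrom = rep(chrom, n),
             start = bounds0[-length(bounds0)],
             end = bounds0[-1L],
             index = seq_len(n) - 1L,
             stringsAsFactors = FALSE)
}

#' Annotate restriction fragments with secondary-site content and validity
#'
#' A fragment is *blind* when no secondary-cutter site lies fully within it;
#' blind fragments cannot be re-digested in the 4C library preparation and
#' are excluded from counting by default. A fragment is *valid* when it is
#' not blind and at least `min_len` bp long.
#'
#' @param fragments Fragment table from [digest()] (one chromosome).
#' @param sequence The same sequence that produced `fragments`.
#' @param secondary An [enzyme_spec()] for the secondary cutter.
#' @param primary An [enzyme_spec()]; carried into the map for provenance.
#' @param min_len Minimum fragment length (bp) for validity. Default 40;
#'   set to 1 to keep every non-blind fragment.
#' @return A `FragmentMap`: list with `enzymes` and a `fragments`
#'   data.frame gaining logical columns `has_secondary_site`, `blind`,
#'   `valid`.
#' @export
annotate_validity <- function(fragments, sequence, secondary,
                              primary = NULL, min_len = 40L) {
  stopifnot(inherits(secondary, "EnzymeSpec"),
            is.numeric(min_len), min_len >= 1)
  sequence <- check_dna(sequence, "sequence")
  check_tiling(fragments, nchar(sequence))
  s1 <- motif_starts(sequence, secondary$site) # 1-based starts
  w <- nchar(secondary$site)
  # full occurrence within [start, end): 0-based start s0 = s1 - 1
  s0 <- s1 - 1L
  has <- vapply(seq_len(nrow(fragments)), function(k) {
    any(s0 >= fragments$start[k] & (s0 + w) <= fragments$end[k])
  }, logical(1L))
  fragments$has_secondary_site <- has
  fragments$blind <- !has
  fragments$valid <- has & (fragments$end - fragments$start) >= min_len
  structure(list(enzymes = list(primary = primary, secondary = secondary),
                 min_len = as.integer(min_len),
                 fragments = fragments),
            class = "FragmentMap")
}

check_tiling <- function(fragments, seq_len) {
  need <- c("chrom", "start", "end", "index")
  if (!all(need %in% names(fragments)))
    stop("fragment table lacks columns: ",
         paste(setdiff(need, names(fragments)), collapse = ", "))
  for (chr in unique(fragments$chrom)) {
    f <- fragments[fragments$chrom == chr, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    ok <- f$start[1L] == 0L && all(f$end > f$start) &&
      all(f$start[-1L] == f$end[-nrow(f)])
    if (!is.null(seq_len)) ok <- ok && f$end[nrow(f)] == seq_len
    if (!ok) stop("fragments do not tile the sequence on ", chr)
  }
  invisible(TRUE)
}

#' Build a fragment map for a genome
#'
#' Convenience wrapper: digests every sequence of a genome with the primary
#' cutter and annotates validity with the secondary cutter. Chromosomes keep
#' the order of the input; fragments are sorted by start within each.
#'
#' @param genome Named character vector or `DNAStringSet` of sequences.
#' @inheritParams annotate_validity
#' @return A `FragmentMap` over all chromosomes.
#' @examples
#' fm <- build_fragment_map(c(chrA = "TTTCATGAAGATCACATGGG"),
#'                          enzyme_spec("NlaIII", "CATG"),
#'                          enzyme_spec("DpnII", "GATC"), min_len = 1)
#' fm$fragments
#' @export
build_fragment_map <- function(genome, primary, secondary, min_len = 40L) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  stopifnot(is.character(genome), length(genome) >= 1L,
            !is.null(names(genome)))
  maps <- lapply(names(genome), function(chr) {
    fr <- digest(genome[[chr]], chr, primary)
    annotate_validity(fr, genome[[chr]], secondary,
                      primary = primary, min_len = min_len)$fragments
  })
  structure(list(enzymes = list(primary = primary, secondary = secondary),
                 min_len = as.integer(min_len),
                 fragments = do.call(rbind, maps)),
            class = "FragmentMap")
}

#' @export
print.FragmentMap <- function(x, ...) {
  f <- x$fragments
  cat(sprintf("<FragmentMap> %d fragments on %d sequence(s); %d valid, %d blind\n",
              nrow(f), length(unique(f$chrom)), sum(f$valid), sum(f$blind)))
  cat(sprintf("  primary %s (%s), secondary %s (%s), min_len %d\n",
              x$enzymes$primary$name %||% "?", x$enzymes$primary$site %||% "?",
              x$enzymes$secondary$name, x$enzymes$secondary$site, x$min_len))
  invisible(x)
}

#' Convert a fragment map to GRanges
#'
#' @param fragmap A `FragmentMap`.
#' @return A [GenomicRanges::GRanges] (1-based internally, as usual for
#'   Bioconductor) with fragment metadata columns.
#' @export
fragment_granges <- function(fragmap) {
  f <- fragmap$fragments
  GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    index = f$index, has_secondary_site = f$has_secondary_site,
    blind = f$blind, valid = f$valid,
    name = paste0(f$chrom, ".", f$index))
}

#' Write a fragment map as BED6 and a flag TSV
#'
#' BED output is 0-based half-open per the BED standard; name is
#' `chrom.index`, score 0, strand ".". The TSV carries the blind/valid
#' flags. Rows are ordered by input chromosome order, then start.
#'
#' @param fragmap A `FragmentMap`.
#' @param bed,tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_fragment_map <- function(fragmap, bed = NULL, tsv = NULL) {
  f <- fragmap$fragments
  if (!is.null(bed)) {
    gr <- fragment_granges(fragmap)
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, bed, format = "BED")
  }
  if (!is.null(tsv)) {
    write.table(f, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed, tsv = tsv))
}
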