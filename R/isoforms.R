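#' Splice junction from block coordinates
#'
#' Junctions are stored 1-based and canonicalized: `left` is the last
#' aligned base before the intron on the lower-coordinate side, `right` the
#' first aligned base after it. Coordinates given in either order are
#' normalized so `left < right`, matching how genome-browser coordinates of
#' a junction are quoted irrespective of transcript orientation.
#'
#' @param left,right 1-based genomic coordinates flanking the gap.
#' @return list with `left` and `right`, `left < right`.
#' @export
junction <- function(left, right) {
  stopifnot(is.numeric(left), is.numeric(right), left != right)
  list(left = as.integer(min(left, right)),
       right = as.integer(max(left, right)))
}

# blocks: data.frame(start, end) 1-based inclusive, sorted -> junction df
junctions_from_blocks <- function(blocks) {
  nb <- nrow(blocks)
  if (nb < 2L) return(data.frame(left = integer(0), right = integer(0)))
  data.frame(left = blocks$end[-nb], right = blocks$start[-1L])
}

#' Read spliced long-read alignments from a TSV
#'
#' Documented tabular alternative to BAM input: columns `read_id`, `chrom`,
#' `strand`, `blocks`, where `blocks` is a comma-separated list of 1-based
#' inclusive intervals `start-end` in genomic order.
#'
#' @param path TSV path.
#' @return data.frame as read, one row per read.
#' @export
read_spliced_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "chrom", "strand", "blocks")
  if (!all(need %in% names(df)))
    stop("spliced-read TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Read spliced long-read alignments from SAM/BAM
#'
#' Gapped alignment records become block structures; N (and D) cigar
#' operations separate blocks. SAM input is converted on the fly.
#'
#' @param path SAM or BAM file.
#' @param window Optional region restriction, `"chrom:start-end"`.
#' @return data.frame in the same shape as [read_spliced_tsv()].
#' @export
read_spliced_bam <- function(path, window = NULL) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = TRUE)
  }
  param <- Rsamtools::ScanBamParam(what = "qname")
  if (!is.null(window)) {
    w <- parse_region(window)
    param <- Rsamtools::ScanBamParam(
      what = "qname",
      which = GenomicRanges::GRanges(w$chrom,
                                     IRanges::IRanges(w$start, w$end)))
  }
  ga <- GenomicAlignments::readGAlignments(path, param = param)
  blocks <- GenomicAlignments::grglist(ga)
  data.frame(
    read_id = S4Vectors::mcols(ga)$qname,
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    strand = as.character(BiocGenerics::strand(ga)),
    blocks = vapply(as.list(blocks), function(g) {
      paste(paste0(BiocGenerics::start(g), "-", BiocGenerics::end(g)),
            collapse = ",")
    }, character(1L)),
    stringsAsFactors = FALSE)
}

parse_blocks <- function(x) {
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  if (any(lengths(m) != 3L)) stop("malformed block string: ", x)
  df <- data.frame(start = as.integer(vapply(m, `[`, "", 2L)),
                   end = as.integer(vapply(m, `[`, "", 3L)))
  if (any(df$end < df$start)) stop("block end before start in: ", x)
  df
}

#' Extract split reads overlapping a window
#'
#' Keeps reads whose alignment overlaps the window, merges inter-block gaps
#' shorter than `min_intron` (treated as alignment deletions, not introns),
#' and derives splice junctions from the remaining gaps. Reads with
#' malformed block structure are skipped with a warning and tallied.
#'
#' @param alignments data.frame from [read_spliced_tsv()] /
#'   [read_spliced_bam()].
#' @param window Genomic interval `"chrom:start-end"` (1-based) or list.
#' @param min_intron Minimum gap length to count as an intron (default 20).
#' @return A `SplicedReadSet`: list with `reads` (read_id, chrom, strand,
#'   n_junctions, spliced), `junctions` (read_id, chrom, left, right) and a
#'   `tally` (input / in_window / spliced / unspliced / rejected).
#' @export
extract_spliced_reads <- function(alignments, window, min_intron = 20L) {
  w <- parse_region(window)
  keep_reads <- list(); keep_jx <- list(); rejected <- 0L; in_window <- 0L
  for (i in seq_len(nrow(alignments))) {
    blocks <- tryCatch(parse_blocks(alignments$blocks[i]), error = function(e) {
      warning("skipping read '", alignments$read_id[i], "': ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(blocks)) { rejected <- rejected + 1L; next }
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    if (alignments$chrom[i] != w$chrom ||
        max(blocks$end) < w$start || min(blocks$start) > w$end) next
    in_window <- in_window + 1L
    # merge gaps below the intron threshold
    if (nrow(blocks) > 1L) {
      gap <- blocks$start[-1L] - blocks$end[-nrow(blocks)] - 1L
      grp <- cumsum(c(0L, gap >= min_intron))
      blocks <- data.frame(
        start = tapply(blocks$start, grp, min),
        end = tapply(blocks$end, grp, max))
    }
    jx <- junctions_from_blocks(blocks)
    keep_reads[[length(keep_reads) + 1L]] <- data.frame(
      read_id = alignments$read_id[i], chrom = alignments$chrom[i],
      strand = alignments$strand[i], n_junctions = nrow(jx),
      spliced = nrow(jx) > 0L, stringsAsFactors = FALSE)
    if (nrow(jx)) {
      jx$read_id <- alignments$read_id[i]
      jx$chrom <- alignments$chrom[i]
      keep_jx[[length(keep_jx) + 1L]] <- jx[, c("read_id", "chrom",
                                                "left", "right")]
    }
  }
  reads <- if (length(keep_reads)) do.call(rbind, keep_reads) else
    data.frame(read_id = character(0), chrom = character(0),
               strand = character(0), n_junctions = integer(0),
               spliced = logical(0))
  jx <- if (length(keep_jx)) do.call(rbind, keep_jx) else
    data.frame(read_id = character(0), chrom = character(0),
               left = integer(0), right = integer(0))
  rownames(reads) <- rownames(jx) <- NULL
  structure(list(window = w, reads = reads, junctions = jx,
                 tally = c(input = nrow(alignments), in_window = in_window,
                           spliced = sum(reads$spliced),
                           unspliced = sum(!reads$spliced),
                           rejected = rejected)),
            class = "SplicedReadSet")
}

#' @export
print.SplicedReadSet <- function(x, ...) {
  cat(sprintf("<SplicedReadSet> %d reads in %s:%d-%d (%d spliced, %d unspliced)\n",
              nrow(x$reads), x$window$chrom, x$window$start, x$window$end,
              x$tally[["spliced"]], x$tally[["unspliced"]]))
  invisible(x)
}

#' Isoform definition
#'
#' @param name Isoform label, e.g. `"Ex1+2"`.
#' @param junctions List of [junction()]s all of which a read must carry.
#' @param tolerance Maximum absolute deviation (nt) allowed on each side of
#'   each junction (default 0, exact coordinates).
#' @return An `IsoformDef`.
#' @export
isoform_def <- function(name, junctions, tolerance = 0L) {
  stopifnot(is.character(name), length(junctions) >= 1L, tolerance >= 0)
  junctions <- lapply(junctions, function(j) junction(j$left, j$right))
  structure(list(name = name, junctions = junctions,
                 tolerance = as.integer(tolerance)), class = "IsoformDef")
}

#' Packaged T-REX17 isoform definitions
#'
#' The two defined isoforms of the human lncRNA T-REX17 (hg19 browser
#' coordinates): Ex1+2 joins chr8:55,125,601 to chr8:55,140,806 and Ex1+3
#' joins chr8:55,123,254 to chr8:55,140,806. Reads carrying any other
#' junction combination are classified "sloppy". Note the source labels
#' the 55,125,601 coordinate "3'-sequence of Exon 3" for isoform Ex1+2,
#' which sits oddly with the exon naming; the definitions here follow the
#' coordinates literally.
#'
#' @param tolerance Junction tolerance in nt (default 0; a ±5 preset is
#'   common for nanopore junction wobble).
#' @return list of [isoform_def()]s, in classification priority order.
#' @export
trex17_isoform_defs <- function(tolerance = 0L) {
  path <- system.file("extdata", "trex17_isoforms.yaml", package = "lnckit")
  read_isoform_defs(path, tolerance = tolerance)
}

#' Read isoform definitions from YAML
#'
#' Expected layout: a top-level `isoforms` list, each entry with `name` and
#' `junctions` (list of `left`/`right` pairs).
#'
#' @param path YAML file.
#' @param tolerance Overrides the per-definition tolerance when not `NULL`.
#' @return list of [isoform_def()]s in file order (= priority order).
#' @export
read_isoform_defs <- function(path, tolerance = NULL) {
  y <- yaml::read_yaml(path)
  lapply(y$isoforms, function(e) {
    isoform_def(e$name,
                lapply(e$junctions, function(j) junction(j$left, j$right)),
                tolerance = tolerance %||% (e$tolerance %||% 0L))
  })
}

#' Classify split reads against isoform definitions
#'
#' A read is assigned to the first definition (list order = priority) whose
#' required junctions are all present among the read's junctions within the
#' definition's tolerance; otherwise it is "sloppy". Classification is
#' strand-agnostic: the junction coordinates suffice.
#'
#' @param sreads A `SplicedReadSet` from [extract_spliced_reads()].
#' @param defs list of [isoform_def()]s.
#' @return data.frame `read_id`, `category` for every split read.
#' @export
classify_reads <- function(sreads, defs) {
  stopifnot(inherits(sreads, "SplicedReadSet"))
  split_ids <- sreads$reads$read_id[sreads$reads$spliced]
  if (!length(split_ids)) stop("no split reads to classify")
  jx <- sreads$junctions
  cat_of <- vapply(split_ids, function(id) {
    rj <- jx[jx$read_id == id, , drop = FALSE]
    for (d in defs) {
      ok <- all(vapply(d$junctions, function(q) {
        any(abs(rj$left - q$left) <= d$tolerance &
              abs(rj$right - q$right) <= d$tolerance)
      }, logical(1L)))
      if (ok) return(d$name)
    }
    "sloppy"
  }, character(1L))
  data.frame(read_id = split_ids, category = unname(cat_of),
             stringsAsFactors = FALSE)
}

#' Relative isoform quantification
#'
#' Per-category split-read counts and percentages of total split reads
#' (1 decimal), plus the combined percentage of all defined isoforms.
#'
#' @param classified data.frame from [classify_reads()], or a named count
#'   vector (category -> count).
#' @param defs The definitions used (names fix the category order).
#' @return An `IsoformQuantification`: `counts`, `total_split_reads`,
#'   `fractions` (percent, 1 decimal), `defined_pct`, `sloppy_pct`.
#' @export
quantify_isoforms <- function(classified, defs = NULL) {
  counts <- if (is.data.frame(classified)) {
    tab <- table(classified$category)
    setNames(as.integer(tab), names(tab))
  } else {
    stopifnot(is.numeric(classified), !is.null(names(classified)))
    classified
  }
  def_names <- if (!is.null(defs)) vapply(defs, `[[`, "", "name") else
    setdiff(names(counts), "sloppy")
  all_names <- c(def_names, "sloppy")
  counts <- setNames(as.integer(ifelse(all_names %in% names(counts),
                                       counts[all_names], 0L)), all_names)
  total <- sum(counts)
  if (total == 0L) stop("zero split reads")
  pct <- round(counts / total * 100, 1L)
  defined_pct <- round(sum(counts[def_names]) / total * 100, 1L)
  sloppy_pct <- round(counts[["sloppy"]] / total * 100, 1L)
  structure(list(counts = counts, total_split_reads = total,
                 fractions = pct, defined_pct = defined_pct,
                 sloppy_pct = sloppy_pct),
            class = "IsoformQuantification")
}

#' @export
print.IsoformQuantification <- function(x, ...) {
  cat(sprintf("<IsoformQuantification> %d split reads\n",
              x$total_split_reads))
  for (nm in names(x$counts))
    cat(sprintf("  %-10s %5d  (%.1f%%)\n", nm, x$counts[[nm]],
                x$fractions[[nm]]))
  cat(sprintf("  defined isoforms combined: %.1f%%\n", x$defined_pct))
  invisible(x)
}

#' Write isoform models as BED12
#'
#' One BED12 line per isoform definition, with blocks inferred from the
#' junction chain inside the given window.
#'
#' @param defs list of [isoform_def()]s.
#' @param window `"chrom:start-end"` bounding the transcript models.
#' @param path Output BED file.
#' @return Invisibly, `path`.
#' @export
write_isoform_bed <- function(defs, window, path) {
  w <- parse_region(window)
  lines <- vapply(defs, function(d) {
    lefts <- vapply(d$junctions, `[[`, integer(1L), "left")
    rights <- vapply(d$junctions, `[[`, integer(1L), "right")
    ord <- order(lefts)
    lefts <- lefts[ord]; rights <- rights[ord]
    starts1 <- c(w$start, rights)       # 1-based block starts
    ends1 <- c(lefts, w$end)            # 1-based block ends
    chrom_start <- w$start - 1L         # BED 0-based
    sizes <- ends1 - starts1 + 1L
    offs <- starts1 - w$start
    paste(w$chrom, chrom_start, w$end, d$name, 0L, ".",
          chrom_start, w$end, "0", length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","), sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
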