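# Shared format I/O: FASTA/FASTQ via Biostrings, tables via base utils,
# manifests via jsonlite, configs via yaml. BED/bedGraph writers live next
# to the structures they serialize (restriction.R, fourc.R).

#' Read a (multi-record) FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              format = "fasta")
  invisible(path)
}

#' Read sequencing reads from FASTQ or FASTA
#'
#' @param path Reads file; format inferred from the extension
#'   (`.fastq`/`.fq` vs anything else).
#' @return data.frame with columns `id`, `seq` (the shape every
#'   read-consuming function of the package takes).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (constant quality)
#'
#' @param reads data.frame with `id`, `seq`.
#' @param path Output path.
#' @param qual_char Constant per-base quality character (default `"I"`).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$id))
  q <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(n)
    paste(rep(qual_char, n), collapse = ""), character(1L)))
  writeLines(as.vector(rbind(paste0("@", reads$id),
                             reads$seq,
                             "+",
                             as.character(q))), path)
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Validate a configuration list against allowed keys
#'
#' Unknown keys are rejected with the offending field named; listed
#' required keys must be present.
#'
#' @param config Named list (e.g. from [yaml::read_yaml()]).
#' @param allowed Character vector of permitted keys.
#' @param required Keys that must be present (subset of `allowed`).
#' @return The config, invisibly, when valid.
#' @export
validate_config <- function(config, allowed, required = character(0)) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config field: ", unknown[1L], call. = FALSE)
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing config field: ", missing[1L], call. = FALSE)
  invisible(config)
}

#' Write a machine-readable run manifest
#'
#' Records inputs, parameter values, package version, seed and stage
#' tallies of an analysis step as JSON, so a run is reproducible from its
#' output directory alone.
#'
#' @param path Output JSON path.
#' @param step Step name.
#' @param params Named list of parameter values.
#' @param inputs,outputs Character vectors of file paths.
#' @param seed Seed used (or `NULL`).
#' @param tally Named numeric stage tallies (or `NULL`).
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(path, step, params = list(), inputs = character(0),
                           outputs = character(0), seed = NULL,
                           tally = NULL) {
  manifest <- list(step = step,
                   package = "lnckit",
                   version = as.character(utils::packageVersion("lnckit")),
                   seed = seed, params = params,
                   inputs = inputs, outputs = outputs,
                   tally = as.list(tally))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
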