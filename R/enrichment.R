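#' Rank RNA-pulldown proteins by LFQ enrichment
#'
#' Scores each protein by `log2(((Even + Odd)/2 + pc) / (LacZ + pc))` —
#' the mean label-free quantification of the two targeting probe pools
#' (Even/Odd split-probe design) over the non-targeting LacZ control — and
#' ranks descending. Ties are broken by protein id so the ranking is a
#' deterministic permutation.
#'
#' @param table data.frame with columns `protein_id`, `Even_LFQ`,
#'   `Odd_LFQ`, `LacZ_LFQ` (non-negative; `protein_id` unique).
#' @param pseudocount Added to both ratio terms; must be positive whenever
#'   any `LacZ_LFQ` is 0 (default 0: fail rather than fabricate
#'   enrichment).
#' @return data.frame `protein_id`, `score`, `rank` (1-based), sorted by
#'   rank.
#' @examples
#' rank_pulldown(data.frame(protein_id = c("a", "b"),
#'                          Even_LFQ = c(8, 2), Odd_LFQ = c(8, 2),
#'                          LacZ_LFQ = c(2, 2)))
#' @export
rank_pulldown <- function(table, pseudocount = 0) {
  need <- c("protein_id", "Even_LFQ", "Odd_LFQ", "LacZ_LFQ")
  stopifnot(all(need %in% names(table)), pseudocount >= 0)
  if (anyDuplicated(table$protein_id))
    stop("protein_id values must be unique")
  with(table, stopifnot(all(Even_LFQ >= 0), all(Odd_LFQ >= 0),
                        all(LacZ_LFQ >= 0)))
  denom <- table$LacZ_LFQ + pseudocount
  if (any(denom == 0)) {
    bad <- table$protein_id[denom == 0]
    stop("zero LacZ_LFQ with zero pseudocount for: ",
         paste(head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ..." else "",
         " (set pseudocount > 0)")
  }
  score <- log2(((table$Even_LFQ + table$Odd_LFQ) / 2 + pseudocount) / denom)
  ord <- order(-score, table$protein_id)
  out <- data.frame(protein_id = table$protein_id[ord],
                    score = score[ord],
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Subcellular fractionation percentages
#'
#' Band intensities of each fraction are first normalized on the
#' cytoplasmic fraction (`rel = I / I_Cyt`, so Cyt's relative value is 1 by
#' construction), then the relative fractions of each replicate are scaled
#' to sum to 100%.
#'
#' @param intensities data.frame with columns `replicate`, `fraction`,
#'   `intensity`; each replicate must include a `Cyt` fraction with
#'   intensity > 0.
#' @param cyt_label Name of the cytoplasmic fraction (default `"Cyt"`).
#' @return data.frame with added `relative` and `percent` columns;
#'   per-replicate percents sum to 100.
#' @examples
#' fractionation_percent(data.frame(replicate = 1,
#'                                  fraction = c("Cyt", "Nuc", "Chr"),
#'                                  intensity = c(10, 20, 10)))
#' @export
fractionation_percent <- function(intensities, cyt_label = "Cyt") {
  need <- c("replicate", "fraction", "intensity")
  stopifnot(all(need %in% names(intensities)))
  out <- list()
  for (rep_id in unique(intensities$replicate)) {
    d <- intensities[intensities$replicate == rep_id, , drop = FALSE]
    if (anyDuplicated(d$fraction))
      stop("duplicate fractions in replicate ", rep_id)
    cyt <- d$intensity[d$fraction == cyt_label]
    if (length(cyt) != 1L)
      stop("replicate ", rep_id, " lacks a '", cyt_label, "' fraction")
    if (cyt <= 0)
      stop("replicate ", rep_id, ": '", cyt_label, "' intensity must be > 0")
    d$relative <- d$intensity / cyt
    d$percent <- d$relative / sum(d$relative) * 100
    out[[length(out) + 1L]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
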