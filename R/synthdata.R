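#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators with the defaults
#' the analyses assume. All generators are pure functions of this
#' configuration: the same config yields byte-identical output.
#'
#' @param seed Master seed.
#' @param genome_length Genome size in bp (default 50000).
#' @param primary,secondary [enzyme_spec()]s (defaults NlaIII `CATG` and
#'   DpnII `GATC`).
#' @param primary_density,secondary_density Target motif occurrence rates
#'   per bp (defaults 1/500 and 1/250).
#' @param read_length Genomic portion of each simulated 4C read after the
#'   primer (default 30).
#' @param primer Viewpoint primer prepended to every 4C read.
#' @param n_reads Number of simulated 4C reads (default 10000).
#' @param contamination Fraction of reads carrying non-genomic 3' junk of
#'   5, 10 or 15 nt, forcing 1-3 iterative trims (default 0.3).
#' @param background Additive uniform-ligation floor of the interaction
#'   profile, relative to the decay peak of 1 (default 0.05).
#' @param decay_exponent Power-law viewpoint-distance decay exponent
#'   `(1 + d)^-alpha` in fragment units (default 1).
#' @param planted_fold Fold-enrichment of the planted interacting fragment
#'   (default 10).
#' @param viewpoint_index Valid-fragment ordinal used as viewpoint;
#'   `NULL` = the middle valid fragment.
#' @param planted_index Fragment row of the planted interaction; `NULL` =
#'   drawn uniformly among valid fragments at least 20 fragments from the
#'   viewpoint (seeded).
#' @param isoform_composition Named split-read counts per category for the
#'   spliced-read generator; defaults to the T-REX17 long-read composition
#'   (Ex1+2 16, Ex1+3 11, sloppy 89).
#' @param n_proteins,n_enriched,lfq_fold,lfq_cv LFQ table generator:
#'   proteins total, planted enriched, fold applied to Even/Odd, and
#'   log-normal noise coefficient of variation (defaults 1000, 20, 8, 0.1).
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       primary = enzyme_spec("NlaIII", "CATG"),
                       secondary = enzyme_spec("DpnII", "GATC"),
                       primary_density = 1 / 500,
                       secondary_density = 1 / 250,
                       read_length = 30L,
                       primer = "ACGTCGATTGCAGTCCAGTT",
                       n_reads = 10000L,
                       contamination = 0.3,
                       background = 0.05,
                       decay_exponent = 1,
                       planted_fold = 10,
                       viewpoint_index = NULL,
                       planted_index = NULL,
                       isoform_composition = c("Ex1+2" = 16L, "Ex1+3" = 11L,
                                               sloppy = 89L),
                       n_proteins = 1000L, n_enriched = 20L,
                       lfq_fold = 8, lfq_cv = 0.1) {
  if (genome_length < 1000) stop("genome_length must be at least 1 kb")
  stopifnot(contamination >= 0, contamination <= 1,
            n_reads >= 0, planted_fold > 0, background >= 0,
            n_enriched <= n_proteins, lfq_cv >= 0,
            all(isoform_composition >= 0))
  structure(as.list(environment()), class = "SimConfig")
}

# replace every occurrence of `motif` in `chars` (character vector of
# bases) except those starting at `keep` by mutating one base
scrub_motif <- function(chars, motif, keep = integer(0)) {
  bases <- c("A", "C", "G", "T")
  mlen <- nchar(motif)
  repeat {
    s <- motif_starts(paste(chars, collapse = ""), motif)
    s <- setdiff(s, keep)
    if (!length(s)) break
    for (p in s) {
      # mutate the middle base; re-draw deterministically within the RNG
      at <- p + mlen %/% 2L
      chars[at] <- sample(setdiff(bases, chars[at]), 1L)
    }
  }
  chars
}

#' Generate a synthetic genome with controlled restriction-site density
#'
#' A random sequence in which the primary and secondary recognition motifs
#' occur (only) at positions drawn to match the configured densities:
#' spurious occurrences in the random background are mutated away, then
#' motifs are written at sampled, non-overlapping positions. Reproducible
#' per seed.
#'
#' @param cfg A [sim_config()].
#' @return Named character vector of length 1 (chromosome `"chrS"`).
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  L <- cfg$genome_length
  if (L < 1000) stop("genome_length must be at least 1 kb")
  p_site <- cfg$primary$site; s_site <- cfg$secondary$site
  n_p <- round(L * cfg$primary_density)
  n_s <- round(L * cfg$secondary_density)
  spacing <- L / max(n_p + n_s, 1L)
  if (spacing < max(nchar(p_site), nchar(s_site)) * 2)
    stop("site density infeasible: motifs longer than the mean spacing")
  with_seed(cfg$seed, {
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    # place primary then secondary sites on a jittered regular lattice so
    # neither overlaps; scrub all other occurrences of either motif
    slots <- round(seq(1L, L - 20L, length.out = n_p + n_s))
    pick <- sample(length(slots), n_p + n_s)
    p_pos <- sort(slots[pick[seq_len(n_p)]])
    s_pos <- sort(slots[pick[n_p + seq_len(n_s)]])
    for (p in p_pos)
      chars[p:(p + nchar(p_site) - 1L)] <- strsplit(p_site, "")[[1L]]
    for (p in s_pos)
      chars[p:(p + nchar(s_site) - 1L)] <- strsplit(s_site, "")[[1L]]
    chars <- scrub_motif(chars, p_site, keep = p_pos)
    chars <- scrub_motif(chars, s_site, keep = s_pos)
    # scrubbing one motif can recreate the other; re-check both
    chars <- scrub_motif(chars, p_site, keep = p_pos)
    g <- paste(chars, collapse = "")
    setNames(g, "chrS")
  })
}

# interaction weight per fragment row (0 for invalid / unplaceable).
# The planted interaction has a small footprint: full fold at its center
# fragment, decaying into the two flanking fragments on each side, the way
# a looping contact enriches a multi-kb region rather than a point.
fourc_weights <- function(cfg, fragmap, vp_row, planted_row) {
  f <- fragmap$fragments
  d <- abs(seq_len(nrow(f)) - vp_row)
  w <- cfg$background + (1 + d)^(-cfg$decay_exponent)
  kernel <- c(0.25, 0.5, 1, 0.5, 0.25)
  off <- -2:2
  rows <- planted_row + off
  ok <- rows >= 1L & rows <= nrow(f)
  w[rows[ok]] <- w[rows[ok]] * (1 + (cfg$planted_fold - 1) * kernel[ok])
  w[!f$valid] <- 0
  # a read needs read_length bases after the fragment start
  w[f$start + cfg$read_length > cfg$genome_length] <- 0
  w
}

pick_viewpoint_row <- function(cfg, fragmap) {
  valid_rows <- which(fragmap$fragments$valid)
  if (!length(valid_rows)) stop("fragment map has no valid fragments")
  if (!is.null(cfg$viewpoint_index)) {
    row <- which(fragmap$fragments$index == cfg$viewpoint_index)
    if (!length(row)) stop("viewpoint_index not in fragment map")
    return(row)
  }
  valid_rows[ceiling(length(valid_rows) / 2)]
}

#' Simulate a 4C-seq read set with a planted interaction
#'
#' Reads are drawn from valid-fragment 5' ends with probability
#' proportional to `(background + (1 + d)^-alpha) * fold`, where `d` is the
#' fragment-index distance to the viewpoint and `fold` is 1 everywhere
#' except the planted fragment. Each read is the viewpoint primer followed
#' by `read_length` genomic bases from the fragment start; a configured
#' fraction additionally carries 5, 10 or 15 junk 3' nt whose first base
#' mismatches the genome, so mapping succeeds only after 1-3 iterative
#' trims.
#'
#' @param cfg A [sim_config()].
#' @param genome Genome from [make_genome()] (named character vector).
#' @param fragmap `FragmentMap` of that genome.
#' @return list: `reads` (data.frame `id`, `seq`), `viewpoint_row`,
#'   `planted_row` (row numbers into `fragmap$fragments`), `truth`
#'   (per-read source fragment row and junk length).
#' @export
simulate_fourc_reads <- function(cfg, genome, fragmap) {
  stopifnot(inherits(cfg, "SimConfig"), inherits(fragmap, "FragmentMap"))
  f <- fragmap$fragments
  gseq <- genome[[1L]]
  chrom <- names(genome)[1L]
  vp_row <- pick_viewpoint_row(cfg, fragmap)
  with_seed(cfg$seed + 1L, {
    planted_row <- if (!is.null(cfg$planted_index)) cfg$planted_index else {
      rows_all <- seq_len(nrow(f))
      # keep the interaction clearly outside the viewpoint zone, scaling
      # the required separation down on small fragment maps
      min_dist <- min(20L, max(3L, (nrow(f) - 9L) %/% 2L))
      cand <- which(f$valid &
                      abs(rows_all - vp_row) >= min_dist &
                      rows_all > 4L & rows_all < nrow(f) - 3L &
                      f$start + cfg$read_length <= cfg$genome_length)
      if (!length(cand)) stop("no eligible fragment to plant an interaction")
      # prefer sites whose +-2 footprint lies in valid fragments, so the
      # interaction is not truncated by blind neighbours
      full <- cand[vapply(cand, function(r)
        all(f$valid[(r - 2L):(r + 2L)]), logical(1L))]
      if (length(full)) cand <- full
      cand[sample.int(length(cand), 1L)]
    }
    if (!f$valid[planted_row]) stop("planted fragment is not valid")
    w <- fourc_weights(cfg, fragmap, vp_row, planted_row)
    if (all(w == 0)) stop("no fragment has positive sampling weight")
    src <- sample.int(nrow(f), cfg$n_reads, replace = TRUE, prob = w)
    core <- substring(gseq, f$start[src] + 1L,
                      f$start[src] + cfg$read_length)
    contaminated <- runif(cfg$n_reads) < cfg$contamination
    junk_n <- ifelse(contaminated, 5L * sample(1:3, cfg$n_reads,
                                               replace = TRUE), 0L)
    bases <- c("A", "C", "G", "T")
    junk <- vapply(seq_len(cfg$n_reads), function(i) {
      if (junk_n[i] == 0L) return("")
      # first junk base differs from the next genomic base, so the
      # contaminated read cannot map at its origin at full length
      nxt_pos <- f$start[src[i]] + cfg$read_length + 1L
      nxt <- if (nxt_pos <= nchar(gseq))
        substring(gseq, nxt_pos, nxt_pos) else "A"
      first <- sample(setdiff(bases, nxt), 1L)
      paste0(first, paste(sample(bases, junk_n[i] - 1L, replace = TRUE),
                          collapse = ""))
    }, character(1L))
    reads <- data.frame(
      id = sprintf("read%06d", seq_len(cfg$n_reads)),
      seq = paste0(cfg$primer, core, junk),
      stringsAsFactors = FALSE)
    list(reads = reads, viewpoint_row = vp_row, planted_row = planted_row,
         chrom = chrom,
         truth = data.frame(id = reads$id, fragment_row = src,
                            junk = junk_n))
  })
}

#' Locate the strongest smoothed 4C signal away from the viewpoint
#'
#' Argmax of the smoothed track with the viewpoint-proximal zone masked
#' (the self-ligation/viewpoint neighbourhood is conventionally excluded
#' from 4C interaction calling).
#'
#' @param profile A `FourCProfile`.
#' @param viewpoint_row Fragment row of the viewpoint.
#' @param exclude Half-width of the masked zone in fragments (default 15).
#' @return Row number of the maximal smoothed fragment.
#' @export
peak_fragment <- function(profile, viewpoint_row, exclude = 15L) {
  sm <- profile$smoothed
  sm[abs(seq_along(sm) - viewpoint_row) <= exclude] <- -Inf
  which.max(sm)
}

#' Simulate spliced long reads with a defined junction composition
#'
#' Emits exactly the requested number of split reads per category: reads of
#' a defined isoform carry that isoform's exact junction coordinates;
#' "sloppy" reads carry a single junction drawn uniformly within the window
#' (excluding the defined coordinate pairs). Block length is 200 nt on each
#' side of a junction, clipped to the window.
#'
#' @param cfg A [sim_config()] (uses `isoform_composition` and `seed`).
#' @param window `"chrom:start-end"` (1-based).
#' @param defs list of [isoform_def()]s supplying coordinates for the
#'   defined categories; defaults to [trex17_isoform_defs()].
#' @param jitter Uniform +-jitter (nt) applied to defined junction
#'   coordinates (default 0; use with a classification tolerance).
#' @return data.frame in [read_spliced_tsv()] layout.
#' @export
simulate_spliced_reads <- function(cfg, window = "chr8:55115873-55141447",
                                   defs = trex17_isoform_defs(),
                                   jitter = 0L) {
  stopifnot(inherits(cfg, "SimConfig"))
  w <- parse_region(window)
  comp <- cfg$isoform_composition
  def_names <- vapply(defs, `[[`, "", "name")
  unknown <- setdiff(names(comp), c(def_names, "sloppy"))
  if (length(unknown))
    stop("composition categories without a definition: ",
         paste(unknown, collapse = ", "))
  blk <- 200L
  with_seed(cfg$seed + 2L, {
    rows <- list()
    mk_read <- function(id, left, right) {
      b1s <- max(w$start, left - blk + 1L)
      b2e <- min(w$end, right + blk - 1L)
      if (left < w$start || right > w$end)
        stop("junction ", left, "/", right, " outside window")
      data.frame(read_id = id, chrom = w$chrom, strand = "+",
                 blocks = sprintf("%d-%d,%d-%d", b1s, left, right, b2e),
                 stringsAsFactors = FALSE)
    }
    rid <- 0L
    for (nm in names(comp)) {
      n_cat <- comp[[nm]]
      if (n_cat == 0L) next
      if (nm == "sloppy") {
        defined_pairs <- do.call(rbind, lapply(defs, function(d)
          t(vapply(d$junctions, function(j) c(j$left, j$right),
                   numeric(2L)))))
        made <- 0L
        while (made < n_cat) {
          left <- sample(seq(w$start + blk, w$end - 2L * blk - 50L), 1L)
          right <- left + sample(50:(w$end - blk - left), 1L)
          if (any(defined_pairs[, 1L] == left &
                    defined_pairs[, 2L] == right)) next
          rid <- rid + 1L; made <- made + 1L
          rows[[length(rows) + 1L]] <-
            mk_read(sprintf("sloppy%04d", rid), left, right)
        }
      } else {
        d <- defs[[match(nm, def_names)]]
        for (k in seq_len(n_cat)) {
          rid <- rid + 1L
          jx <- d$junctions[[1L]]
          jl <- jx$left + if (jitter > 0L) sample(-jitter:jitter, 1L) else 0L
          jr <- jx$right + if (jitter > 0L) sample(-jitter:jitter, 1L) else 0L
          rows[[length(rows) + 1L]] <-
            mk_read(sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", nm), rid),
                    jl, jr)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write simulated spliced reads as SAM
#'
#' Minimal single-end SAM (one `@SQ` line, MAPQ 60, `<M>N<M>` cigars from
#' the block structure) so the BAM reading path can be exercised without
#' external data.
#'
#' @param sim data.frame from [simulate_spliced_reads()].
#' @param path Output `.sam` path.
#' @param seq_length Declared reference length for the `@SQ` header.
#' @return Invisibly, `path`.
#' @export
write_spliced_sam <- function(sim, path, seq_length = 60000000L) {
  chrom <- sim$chrom[1L]
  recs <- vapply(seq_len(nrow(sim)), function(i) {
    b <- parse_blocks(sim$blocks[i])
    sizes <- b$end - b$start + 1L
    cigar <- paste0(sizes[1L], "M")
    if (nrow(b) > 1L) {
      for (k in 2L:nrow(b)) {
        gap <- b$start[k] - b$end[k - 1L] - 1L
        cigar <- paste0(cigar, gap, "N", sizes[k], "M")
      }
    }
    seq <- paste(rep("A", sum(sizes)), collapse = "")
    paste(sim$read_id[i], if (sim$strand[i] == "-") 16L else 0L,
          chrom, b$start[1L], 60L, cigar, "*", 0L, 0L, seq, "*",
          sep = "\t")
  }, character(1L))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, seq_length),
               recs), path)
  invisible(path)
}

#' Simulate an RNA-pulldown LFQ table
#'
#' Background proteins have `Even ~ Odd ~ LacZ` up to multiplicative
#' log-normal noise of the configured coefficient of variation; a planted
#' subset has Even and Odd scaled by the configured fold. Per-protein base
#' abundances are log-normal, spanning a realistic intensity range.
#'
#' @param cfg A [sim_config()].
#' @return list: `table` (data.frame `protein_id`, `Even_LFQ`, `Odd_LFQ`,
#'   `LacZ_LFQ`), `enriched` (planted protein ids).
#' @export
simulate_lfq <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed + 3L, {
    n <- cfg$n_proteins
    ids <- sprintf("P%04d", seq_len(n))
    base <- rlnorm(n, meanlog = log(1e7), sdlog = 1)
    sdl <- sqrt(log(1 + cfg$lfq_cv^2))
    noise <- function() rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    enriched <- sample(ids, cfg$n_enriched)
    fold <- ifelse(ids %in% enriched, cfg$lfq_fold, 1)
    tab <- data.frame(protein_id = ids,
                      Even_LFQ = base * fold * noise(),
                      Odd_LFQ = base * fold * noise(),
                      LacZ_LFQ = base * noise(),
                      stringsAsFactors = FALSE)
    list(table = tab, enriched = sort(enriched))
  })
}
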