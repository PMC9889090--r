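#!/usr/bin/env Rscript
# Cross-species conservation of a synthetic locus pair: two sequences
# sharing diverged blocks (substitutions and indels) stand in for the
# human and mouse loci; Smith-Waterman local alignment followed by
# extraction of gapless stretches of >= 20 bp.

suppressPackageStartupMessages(library(lnckit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

out <- file.path("results", "conservation")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# synthetic orthologous pair: conserved blocks of 30-120 bp at ~85%
# identity separated by unrelated spacer sequence
set.seed(seed + 40L)
rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
mutate <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}
blocks <- replicate(5, rand(sample(30:120, 1)))
human <- paste0(rand(80), paste(vapply(blocks, function(b)
  paste0(b, rand(60)), character(1)), collapse = ""), rand(40))
mouse <- paste0(rand(50), paste(vapply(blocks, function(b)
  paste0(mutate(b, 0.15), rand(90)), character(1)), collapse = ""), rand(20))
write_fasta(c(human_locus_synthetic = human,
              mouse_locus_synthetic = mouse),
            file.path(out, "locus_pair_synthetic.fa"))

res <- conservation_analysis(human, mouse, min_len = 20)
print(res$alignment)
write_tsv(res$stretches, file.path(out, "conserved_stretches.tsv"))
jsonlite::write_json(res$summary[c("n_stretches", "covered_a", "covered_b",
                                   "coverage_a", "coverage_b",
                                   "mean_identity")],
                     file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("%d conserved stretches >= 20 bp; %.1f%% of the first sequence covered; mean identity %.2f\n",
            res$summary$n_stretches, 100 * res$summary$coverage_a,
            res$summary$mean_identity))

write_manifest(file.path(out, "manifest.json"), step = "conservation",
               params = list(match = 5, mismatch = -4, gap_open = 10,
                             gap_extend = 0.5, min_len = 20),
               outputs = list.files(out), seed = seed)
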