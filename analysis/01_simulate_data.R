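#!/usr/bin/env Rscript
# Generates every synthetic input the downstream analyses consume:
# a 50 kb genome with controlled NlaIII/DpnII site densities, a 4C read
# library with a planted interaction, a spliced long-read set with the
# T-REX17 junction composition, and an RNA-pulldown LFQ table.

suppressPackageStartupMessages(library(lnckit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
g <- make_genome(cfg)
write_fasta(g, file.path(out, "genome.fa"))
cat(sprintf("genome: %d bp, %s sites at ~1/%d bp\n", nchar(g[[1]]),
            cfg$primary$name, round(1 / cfg$primary_density)))

fm <- build_fragment_map(g, cfg$primary, cfg$secondary, min_len = 40)
sim <- simulate_fourc_reads(cfg, g, fm)
write_fastq(sim$reads, file.path(out, "fourc_reads.fastq"))
write_tsv(sim$truth, file.path(out, "fourc_truth.tsv"))
cat(sprintf("4C reads: %d (%.0f%% with 3' contamination); planted fragment row %d, viewpoint row %d\n",
            nrow(sim$reads), 100 * cfg$contamination, sim$planted_row,
            sim$viewpoint_row))

sp <- simulate_spliced_reads(cfg)
write_tsv(sp, file.path(out, "spliced_reads.tsv"))
write_spliced_sam(sp, file.path(out, "spliced_reads.sam"))
cat(sprintf("spliced reads: %d (%s)\n", nrow(sp),
            paste(names(cfg$isoform_composition), cfg$isoform_composition,
                  sep = "=", collapse = ", ")))

lfq <- simulate_lfq(cfg)
write_tsv(lfq$table, file.path(out, "lfq_table.tsv"))
writeLines(lfq$enriched, file.path(out, "lfq_planted_ids.txt"))
cat(sprintf("LFQ table: %d proteins, %d planted at fold %.0f\n",
            cfg$n_proteins, cfg$n_enriched, cfg$lfq_fold))

write_manifest(file.path(out, "manifest.json"), step = "simulate",
               params = list(genome_length = cfg$genome_length,
                             n_reads = cfg$n_reads,
                             contamination = cfg$contamination,
                             planted_fold = cfg$planted_fold),
               outputs = list.files(out), seed = seed)
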