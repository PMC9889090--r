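#!/usr/bin/env Rscript
# 4C viewpoint analysis on the simulated library: in-silico digestion,
# primer trimming, iterative 5-nt 3'-end trim mapping, assignment to valid
# fragments, RPM normalization and closest-five-fragment smoothing.
# Run 01_simulate_data.R first.

suppressPackageStartupMessages(library(lnckit))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

dat <- file.path("results", "data")
out <- file.path("results", "fourc")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
g <- read_fasta(file.path(dat, "genome.fa"))
reads <- read_reads(file.path(dat, "fourc_reads.fastq"))

fm <- build_fragment_map(g, cfg$primary, cfg$secondary, min_len = 40)
write_fragment_map(fm, bed = file.path(out, "fragments.bed"),
                   tsv = file.path(out, "fragments.tsv"))
cat(sprintf("fragment map: %d fragments, %d valid\n",
            nrow(fm$fragments), sum(fm$fragments$valid)))

prof <- run_fourc(reads, g, fm, trimspec = trim_spec(cfg$primer))
print(prof)
write_fourc_tracks(prof, out)

# compare the smoothed peak with the simulation truth
sim <- simulate_fourc_reads(cfg, g, fm) # deterministic for the seed
peak <- peak_fragment(prof, sim$viewpoint_row)
cat(sprintf("smoothed peak (viewpoint zone masked): fragment row %d; planted row %d -> %s\n",
            peak, sim$planted_row,
            if (peak == sim$planted_row) "recovered" else "missed"))

write_manifest(file.path(out, "manifest.json"), step = "fourc",
               params = list(min_frag_len = 40, min_map_len = 25,
                             trim_step = 5),
               inputs = c("genome.fa", "fourc_reads.fastq"),
               outputs = list.files(out), seed = seed, tally = prof$tally)
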