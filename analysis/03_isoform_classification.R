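#!/usr/bin/env Rscript
# Splice-junction classification of the simulated nanopore reads against
# the packaged T-REX17 isoform definitions, with relative quantification.
# Run 01_simulate_data.R first.

suppressPackageStartupMessages(library(lnckit))

dat <- file.path("results", "data")
out <- file.path("results", "isoforms")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

window <- "chr8:55115873-55141447"
defs <- trex17_isoform_defs()

aln <- read_spliced_tsv(file.path(dat, "spliced_reads.tsv"))
sr <- extract_spliced_reads(aln, window)
print(sr)

cl <- classify_reads(sr, defs)
write_tsv(cl, file.path(out, "read_categories.tsv"))

q <- quantify_isoforms(cl, defs)
print(q)
jsonlite::write_json(
  list(counts = as.list(q$counts), total_split_reads = q$total_split_reads,
       fractions_pct = as.list(q$fractions), defined_pct = q$defined_pct,
       sloppy_pct = q$sloppy_pct),
  file.path(out, "quantification.json"), auto_unbox = TRUE, digits = NA)

write_isoform_bed(defs, window, file.path(out, "isoform_models.bed"))
write_manifest(file.path(out, "manifest.json"), step = "isoforms",
               params = list(window = window, tolerance = 0, min_intron = 20),
               inputs = "spliced_reads.tsv", outputs = list.files(out),
               tally = sr$tally)
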