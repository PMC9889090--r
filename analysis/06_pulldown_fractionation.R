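#!/usr/bin/env Rscript
# RNA-pulldown LFQ enrichment ranking on the simulated table, and
# subcellular fractionation percentages from band intensities.
# Run 01_simulate_data.R first.

suppressPackageStartupMessages(library(lnckit))

dat <- file.path("results", "data")
out <- file.path("results", "enrichment")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lfq <- read_tsv(file.path(dat, "lfq_table.tsv"))
planted <- readLines(file.path(dat, "lfq_planted_ids.txt"))

ranking <- rank_pulldown(lfq)
write_tsv(ranking, file.path(out, "pulldown_ranking.tsv"))
top20 <- ranking$protein_id[1:20]
cat(sprintf("top-20 ranks contain %d of %d planted proteins\n",
            length(intersect(top20, planted)), length(planted)))

# worked fractionation example: Cyt 10, Nuc 20, Chr 10 per replicate
bands <- data.frame(replicate = rep(1:3, each = 3),
                    fraction = rep(c("Cyt", "Nuc", "Chr"), 3),
                    intensity = rep(c(10, 20, 10), 3))
fr <- fractionation_percent(bands)
write_tsv(fr, file.path(out, "fractionation.tsv"))
cat("fractionation percentages (replicate 1):",
    sprintf("%s %.1f%%", fr$fraction[1:3], fr$percent[1:3]), "\n")

write_manifest(file.path(out, "manifest.json"), step = "enrichment",
               params = list(pseudocount = 0),
               inputs = c("lfq_table.tsv", "lfq_planted_ids.txt"),
               outputs = list.files(out))
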