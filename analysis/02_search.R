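#!/usr/bin/env Rscript
# Stage 2: homology search.
#
# Scans the simulated genome with each master sequence (the known-library
# route, as a RepeatMasker-style survey would) using the seed-and-extend
# local aligner at e <= 1e-10, and writes the raw hit tables in all three
# dialects under results/search/. Stage 3 rebuilds consensuses from
# single-copy seeds instead, mirroring a de novo survey.

suppressMessages(library(sidekit))

stopifnot(file.exists("results/sim/genome.fa"))
genome <- read_fasta("results/sim/genome.fa")
masters <- read_fasta("results/sim/masters.fa")
cfg <- pipeline_config()
dir.create("results/search", showWarnings = FALSE, recursive = TRUE)

all_hits <- list()
for (m in masters) {
  fam <- sub("_master$", "", m$id)
  h <- search_genome(m, genome, cfg, family = fam)
  cat(sprintf("%s: %d significant hits (median span %d bp, median identity %.1f%%)\n",
              fam, nrow(h), as.integer(median(h$end - h$start)),
              median(h$pct_identity)))
  all_hits[[fam]] <- h
}
hits <- do.call(rbind, all_hits)
write_hit_table(hits, "results/search/hits.tsv", "tsv")
write_hit_table(hits, "results/search/hits.bed", "bed")
write_hit_table(hits, "results/search/hits.gff3", "gff3")
cat("wrote results/search/hits.{tsv,bed,gff3}\n")
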