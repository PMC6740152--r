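#!/usr/bin/env Rscript
# Stage 5: copy counting, genome coverage and activity-through-age.
#
# Applies the ambiguity filter (drop fragments < 160 bp, which removes
# cross-matches between the SIDE and the LINE ends), merges collinear
# adjacent fragments into copies, compares copy numbers against the
# planted truth, computes genome coverage, and bins per-copy Jukes-Cantor
# divergences into the activity landscape.

suppressMessages(library(sidekit))

stopifnot(file.exists("results/consensus/LINE_hits.tsv"))
cfg <- pipeline_config()
genome <- read_fasta("results/sim/genome.fa")[[1]]
truth <- read.delim("results/sim/truth.tsv", comment.char = "")
hits <- rbind(read_hit_table("results/consensus/LINE_hits.tsv"),
              read_hit_table("results/consensus/SIDE_hits.tsv"))
dir.create("results/landscape", showWarnings = FALSE, recursive = TRUE)

kept <- filter_fragments(hits, cfg$min_fragment_len)
cat(sprintf("ambiguity filter: %d/%d fragments >= %d bp kept\n",
            nrow(kept), nrow(hits), cfg$min_fragment_len))
copies <- merge_adjacent(kept, cfg)
write_copies(copies, "results/landscape/copies.tsv", "tsv")
write_copies(copies, "results/landscape/copies.bed", "bed")

for (fam in c("LINE", "SIDE")) {
  n <- sum(copies$family == fam)
  n_true <- sum(grepl(paste0("^", fam), truth$name))
  cov <- genome_coverage(copies[copies$family == fam, ], nchar(genome$seq))
  cat(sprintf("%s: %d copies (truth %d, error %+.1f%%), %.3f%% of the genome\n",
              fam, n, n_true, 100 * (n - n_true) / n_true, 100 * cov))
}

ls <- activity_landscape(copies, cfg)
con <- file("results/landscape/landscape.tsv", "wb")
writeLines(paste(names(ls), collapse = "\t"), con)
writeLines(sprintf("%s\t%.2f\t%.2f\t%d\t%d", ls$family, ls$bin_start,
                   ls$bin_end, ls$n_copies, ls$bp), con)
close(con)
for (fam in c("LINE", "SIDE")) {
  m <- landscape_mode(ls, fam)
  cat(sprintf("%s activity peak: divergence bin [%.2f,%.2f) with %d copies\n",
              fam, m[1], m[2],
              max(ls$n_copies[ls$family == fam])))
}
cat("wrote results/landscape/{copies.tsv, copies.bed, landscape.tsv}\n")
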