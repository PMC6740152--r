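#!/usr/bin/env Rscript
# Stage 4: structural annotation of the SIDE against its partner LINE.
#
# Decomposes the reconstructed SIDE consensus into LINE-homologous 5'/3'
# blocks, the central variable region and the poly-A tail; infers the
# deleted LINE interval; searches the breakpoints for direct-repeat
# microhomologies; surveys target-site duplications at every recovered
# copy; and builds the breakpoint sequence logo from aligned copy windows.

suppressMessages(library(sidekit))

stopifnot(file.exists("results/consensus/consensuses.fa"))
cons <- read_fasta("results/consensus/consensuses.fa")
line <- cons[[1]]; side <- cons[[2]]
genome <- read_fasta("results/sim/genome.fa")[[1]]
cfg <- pipeline_config()
dir.create("results/annotate", showWarnings = FALSE, recursive = TRUE)

arch <- find_homologous_blocks(side, line)
cat(sprintf("5' block: SIDE [%d,%d) ~ LINE [%d,%d), %.1f%% identity\n",
            arch$five_block$side_start, arch$five_block$side_end,
            arch$five_block$line_start, arch$five_block$line_end,
            arch$five_block$pct_identity))
cat(sprintf("3' block: SIDE [%d,%d) ~ LINE [%d,%d), %.1f%% identity\n",
            arch$three_block$side_start, arch$three_block$side_end,
            arch$three_block$line_start, arch$three_block$line_end,
            arch$three_block$pct_identity))
cat(sprintf("variable region: SIDE [%d,%d); poly-A tail: %d bp\n",
            arch$variable_region[1], arch$variable_region[2], arch$polya_len))
write_architecture_gff3(arch, side$id, "results/annotate/architecture.gff3")

del <- infer_deletion_interval(arch)
mh <- find_breakpoint_microhomology(line, del)
cat(sprintf("deleted LINE interval: [%d,%d); %d breakpoint microhomolog%s",
            del[1], del[2], nrow(mh), if (nrow(mh) == 1) "y" else "ies"))
if (nrow(mh) > 0)
  cat(sprintf(" (longest: %s, %d bp)", mh$motif[1], mh$length[1]))
cat("\n")

# TSD survey over recovered SIDE copies. Alignment boundaries are trimmed
# by a few terminal mismatches, so the exact insertion edges the detector
# needs are scanned over a small slack around each recovered boundary and
# the longest duplication wins.
hits <- read_hit_table("results/consensus/SIDE_hits.tsv")
copies <- merge_adjacent(filter_fragments(hits, cfg$min_fragment_len), cfg)
tsds <- lapply(seq_len(nrow(copies)), function(i) {
  best <- NULL
  for (ds in -3:3) for (de in -3:3) {
    r <- tryCatch(detect_tsd(genome, c(copies$start[i] + ds,
                                       copies$end[i] + de),
                             window = cfg$tsd_search_window),
                  error = function(e) NULL)
    if (!is.null(r) && (is.null(best) || r$length > best$length)) best <- r
  }
  best
})
found <- !vapply(tsds, is.null, logical(1))
lens <- vapply(tsds[found], function(t) t$length, integer(1))
cat(sprintf("TSDs (boundary slack +-3 bp) at %d/%d recovered SIDE copies; %d of length >= 4 bp\n",
            sum(found), nrow(copies), sum(lens >= 4)))

# breakpoint logo over copy windows anchored on the 5' breakpoint
bp <- del[1]
win <- 15L
frags <- character(0)
line_hits <- read_hit_table("results/consensus/LINE_hits.tsv")
lh <- line_hits[line_hits$q_start + win < bp & line_hits$q_end > bp + win, ]
for (i in seq_len(min(nrow(lh), 100L))) {
  h <- lh[i, ]
  seqc <- subseq0(genome$seq, h$start, h$end, h$strand)
  off <- bp - h$q_start # approximate copy coordinate of the breakpoint
  if (off - win >= 0 && off + win <= nchar(seqc))
    frags <- c(frags, substr(seqc, off - win + 1L, off + win))
}
logo <- breakpoint_logo(frags, anchor = win)
write_logo_tsv(logo, "results/annotate/breakpoint_logo.tsv")
cat(sprintf("breakpoint logo from %d copy windows; mean information %.2f bits (max position: %.2f)\n",
            length(frags), mean(logo$info_bits), max(logo$info_bits)))
cat("wrote results/annotate/{architecture.gff3, breakpoint_logo.tsv}\n")
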