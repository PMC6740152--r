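#' Scan a genome for copies of a consensus
#'
#' Seed-and-extend local-alignment search, the desk-scale stand-in for a
#' blastn scan: exact k-mer seeds (default k = 11) are clustered by
#' diagonal, each cluster is extended with banded affine-gap
#' Smith-Waterman, and alignments are kept when their Karlin-Altschul
#' e-value is at or below `config$evalue_dna`. Both strands are searched
#' (minus strand via the reverse complement of the consensus); hits are
#' reported in forward genome coordinates with `q_start`/`q_end` on the
#' forward consensus orientation, sorted by genome position. Overlapping
#' hits (e.g. the two strands claiming the same locus) are resolved by
#' keeping the higher score; exact ties keep the plus strand.
#'
#' @param consensus a [seq_record()] query (length >= 30).
#' @param genome a `seq_record` or list of them.
#' @param config a [pipeline_config()].
#' @param scheme a [scoring_scheme()].
#' @param k seed word size.
#' @param family family label stored in the hit table (defaults to the
#'   consensus id).
#' @return a [hit_table()].
#' @export
search_genome <- function(consensus, genome, config = pipeline_config(),
                          scheme = scoring_scheme(), k = 11L,
                          family = consensus$id) {
  if (inherits(genome, "seq_record")) genome <- list(genome)
  qlen <- seq_length(consensus)
  if (qlen < 30L) stop("consensus query must be >= 30 bp (got ", qlen, ")")
  n_total <- sum(vapply(genome, seq_length, numeric(1)))
  queries <- list("+" = consensus$seq, "-" = revcomp(consensus$seq))

  rows <- list()
  for (rec in genome) {
    slen <- seq_length(rec)
    if (slen < k) {
      side_log("search_genome: record '%s' (%d bp) shorter than seed length; skipped",
               rec$id, slen, level = "warning")
      next
    }
    for (strand in c("+", "-")) {
      q <- queries[[strand]]
      seeds <- seed_hits_cpp(q, rec$seq, as.integer(k))
      if (nrow(seeds) == 0L) next
      clusters <- cluster_seeds_cpp(seeds[, "qpos"], seeds[, "spos"],
                                    max_diag_diff = 50L, max_spos_gap = 1000L)
      for (ci in seq_len(nrow(clusters))) {
        cl <- clusters[ci, ]
        wstart <- max(0L, cl[["smin"]] - 200L)
        wend <- min(slen, cl[["smax"]] + as.integer(k) + 200L)
        win <- substr(rec$seq, wstart + 1L, wend)
        aln <- local_align(q, win, scheme,
                           band_lo = cl[["dmin"]] - wstart - 60L,
                           band_hi = cl[["dmax"]] - wstart + 60L)
        if (aln$score <= 0) next
        ev <- evalue_of(aln$score, qlen, n_total, scheme)
        if (ev > config$evalue_dna) next
        gstart <- wstart + aln$b_start
        gend <- wstart + aln$b_end
        if (strand == "+") {
          qs <- aln$a_start; qe <- aln$a_end
        } else {
          qs <- qlen - aln$a_end; qe <- qlen - aln$a_start
        }
        rows[[length(rows) + 1L]] <- data.frame(
          family = family, seqid = rec$id, start = gstart, end = gend,
          strand = strand, score = aln$score, evalue = ev,
          pct_identity = 100 * aln$n_match / (aln$n_match + aln$n_mismatch),
          q_start = qs, q_end = qe,
          aligned_len = aln$n_match + aln$n_mismatch + aln$n_gapcols,
          n_match = aln$n_match, n_mismatch = aln$n_mismatch,
          n_gapcols = aln$n_gapcols, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    side_log("search_genome: family '%s': 0 significant hits", family)
    return(hit_table())
  }
  df <- do.call(rbind, rows)
  df <- resolve_overlaps(df)
  df <- df[order(df$seqid, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  side_log("search_genome: family '%s': %d significant hit(s) at e <= %g",
           family, nrow(df), config$evalue_dna)
  do.call(hit_table, df[hit_cols])
}

# Keep the better of any two hits overlapping by more than half the
# shorter one (duplicate cluster extensions, strand conflicts). Ties keep
# "+" over "-", then the earlier start.
resolve_overlaps <- function(df) {
  df <- df[order(df$seqid,
                 -df$score,
                 match(df$strand, c("+", "-")),
                 df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  acc_seqid <- character(0); acc_start <- integer(0); acc_end <- integer(0)
  for (i in seq_len(nrow(df))) {
    s <- df$start[i]; e <- df$end[i]
    ov <- acc_seqid == df$seqid[i] &
      pmin(acc_end, e) - pmax(acc_start, s) >
        0.5 * pmin(e - s, acc_end - acc_start)
    if (!any(ov)) {
      keep[i] <- TRUE
      acc_seqid <- c(acc_seqid, df$seqid[i])
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  df[keep, , drop = FALSE]
}
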