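#' Hit tables
#'
#' A hit table is a data frame with one row per local-alignment match of a
#' family consensus against a genome, mirroring RepeatMasker-style `.out`
#' semantics. Genome coordinates are 0-based half-open on the forward
#' strand; `q_start`/`q_end` always refer to the forward orientation of the
#' consensus, with `strand` recording which genome strand matched.
#'
#' Columns: `family`, `seqid`, `start`, `end`, `strand`, `score`, `evalue`,
#' `pct_identity` (over gap-free aligned columns), `q_start`, `q_end`,
#' `aligned_len` (aligned columns incl. gaps), `n_match`, `n_mismatch`,
#' `n_gapcols`.
#'
#' @param family,seqid,start,end,strand,score,evalue,pct_identity,q_start,q_end,aligned_len,n_match,n_mismatch,n_gapcols column vectors.
#' @return a `data.frame` of class `hit_table`.
#' @export
hit_table <- function(family = character(), seqid = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = integer(),
                      evalue = numeric(), pct_identity = numeric(),
                      q_start = integer(), q_end = integer(),
                      aligned_len = integer(), n_match = integer(),
                      n_mismatch = integer(), n_gapcols = integer()) {
  df <- data.frame(family = as.character(family), seqid = as.character(seqid),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), score = as.integer(score),
                   evalue = as.numeric(evalue),
                   pct_identity = as.numeric(pct_identity),
                   q_start = as.integer(q_start), q_end = as.integer(q_end),
                   aligned_len = as.integer(aligned_len),
                   n_match = as.integer(n_match),
                   n_mismatch = as.integer(n_mismatch),
                   n_gapcols = as.integer(n_gapcols),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    stopifnot(all(df$start >= 0L), all(df$end > df$start),
              all(df$strand %in% c("+", "-")))
  }
  class(df) <- c("hit_table", "data.frame")
  df
}

hit_cols <- c("family", "seqid", "start", "end", "strand", "score", "evalue",
              "pct_identity", "q_start", "q_end", "aligned_len", "n_match",
              "n_mismatch", "n_gapcols")

#' Write a hit table
#'
#' Three dialects: `"tsv"` (all columns, round-trips bit-exactly through
#' [read_hit_table()]), `"bed"` (BED6: 0-based half-open, name =
#' family, score column clamped to 0-1000) and `"gff3"` (1-based
#' inclusive, type `dispersed_repeat`). BED and GFF3 emit the same
#' intervals as the TSV.
#'
#' @param hits a hit table.
#' @param path output file.
#' @param dialect one of `"tsv"`, `"bed"`, `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, dialect = c("tsv", "bed", "gff3")) {
  if (length(dialect) != 1L || !dialect %in% c("tsv", "bed", "gff3"))
    stop("unknown dialect '", paste(dialect, collapse = ","),
         "'; use one of: tsv, bed, gff3")
  stopifnot(all(hit_cols %in% names(hits)))
  con <- file(path, "wb") # binary mode: fixed \n endings for round-trips
  on.exit(close(con))
  if (dialect == "tsv") {
    writeLines(paste(hit_cols, collapse = "\t"), con)
    if (nrow(hits) > 0L) {
      lines <- sprintf("%s\t%s\t%d\t%d\t%s\t%d\t%.6e\t%.4f\t%d\t%d\t%d\t%d\t%d\t%d",
                       hits$family, hits$seqid, hits$start, hits$end,
                       hits$strand, hits$score, hits$evalue, hits$pct_identity,
                       hits$q_start, hits$q_end, hits$aligned_len,
                       hits$n_match, hits$n_mismatch, hits$n_gapcols)
      writeLines(lines, con)
    }
  } else if (dialect == "bed") {
    if (nrow(hits) > 0L) {
      score <- pmax(0L, pmin(1000L, hits$score))
      writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", hits$seqid, hits$start,
                         hits$end, hits$family, score, hits$strand), con)
    }
  } else { # gff3: 1-based inclusive
    writeLines("##gff-version 3", con)
    if (nrow(hits) > 0L) {
      attrs <- sprintf("ID=hit%d;family=%s;pct_identity=%.2f;q_start=%d;q_end=%d",
                       seq_len(nrow(hits)), hits$family, hits$pct_identity,
                       hits$q_start, hits$q_end)
      writeLines(sprintf("%s\tsidekit\tdispersed_repeat\t%d\t%d\t%d\t%s\t.\t%s",
                         hits$seqid, hits$start + 1L, hits$end, hits$score,
                         hits$strand, attrs), con)
    }
  }
  invisible(path)
}

#' Read a TSV hit table written by [write_hit_table()]
#'
#' @param path TSV file.
#' @return a `hit_table`.
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(family = "character", seqid = "character",
                                  start = "integer", end = "integer",
                                  strand = "character", score = "integer",
                                  evalue = "numeric", pct_identity = "numeric",
                                  q_start = "integer", q_end = "integer",
                                  aligned_len = "integer", n_match = "integer",
                                  n_mismatch = "integer", n_gapcols = "integer"))
  do.call(hit_table, df[hit_cols])
}
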