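#' Sequence records
#'
#' A `seq_record` is the carrier for all sequences in the pipeline
#' (genomes, consensuses, element copies): an id, a free-text description
#' and an uppercase DNA string over the alphabet `A,C,G,T,N`.
#'
#' @param id record identifier (non-empty string).
#' @param seq DNA string; lowercase is uppercased, any character outside
#'   `A,C,G,T,N` is mapped to `N` with a logged warning.
#' @param description free-text description (may be empty).
#' @return an object of class `seq_record` with fields `id`,
#'   `description`, `seq`.
#' @export
seq_record <- function(id, seq, description = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  n_bad <- nchar(gsub("[ACGTN]", "", seq))
  if (n_bad > 0L) {
    seq <- gsub("[^ACGTN]", "N", seq)
    side_log("record '%s': %d non-ACGTN character(s) mapped to N", id, n_bad,
             level = "warning")
  }
  structure(list(id = id, description = description, seq = seq),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s%s (%d bp)\n", x$id,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              nchar(x$seq)))
  invisible(x)
}

#' @rdname seq_record
#' @param x a `seq_record`.
#' @param ... unused.
#' @export
as.character.seq_record <- function(x, ...) x$seq

seq_length <- function(rec) nchar(rec$seq)

#' Read a FASTA file
#'
#' One `seq_record` per header, in file order. Sequences are uppercased and
#' characters outside `A,C,G,T,N` are mapped to `N` with a logged warning.
#' Parsing is delegated to Biostrings; records with empty sequences are a
#' format error reported with the offending header's line number.
#'
#' @param path FASTA file.
#' @return list of [seq_record()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no records in FASTA '", path, "'")
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    bad <- names(set)[widths == 0L][1L]
    lines <- readLines(path, warn = FALSE)
    ln <- which(startsWith(trimws(lines), paste0(">", bad)))[1L]
    stop(sprintf("empty sequence for record '%s' (line %s) in '%s'",
                 bad, ifelse(is.na(ln), "?", ln), path))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(as.character(set))
  recs <- lapply(seq_along(set), function(i) seq_record(ids[i], seqs[i], desc[i]))
  side_log("read_fasta: %d record(s) from %s", length(recs), path, level = "debug")
  recs
}

#' Write records to FASTA
#'
#' @param records a `seq_record` or list of them.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  seqs <- vapply(records, function(r) r$seq, character(1))
  nm <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A,C,G,T,N).
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a genomic interval from a sequence
#'
#' Coordinates are 0-based, half-open, on the forward strand; when
#' `strand == "-"` the extracted sequence is reverse-complemented.
#'
#' @param seq DNA string.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return the substring (reverse-complemented for `"-"`).
#' @export
subseq0 <- function(seq, start, end, strand = "+") {
  stopifnot(start >= 0, end > start, end <= nchar(seq))
  s <- substr(seq, start + 1L, end)
  if (strand == "-") revcomp(s) else s
}
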