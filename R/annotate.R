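#' Decompose a SIDE against its partner LINE
#'
#' A SIDE (short internally deleted element) retains its partner LINE's 5'
#' and 3' ends around a central, non-homologous variable region. This
#' finds the two highest-scoring collinear local alignments anchored near
#' the SIDE's termini: the 5' block must start within `anchor_slack` bp of
#' the SIDE start and the 3' block must end within `anchor_slack` bp of
#' the SIDE end (the poly-A tail, if any, is allowed beyond the 3' block).
#' The stretch between the blocks is reported as the variable region.
#' Block identities are percent matches over gap-free aligned columns.
#'
#' @param side,line [seq_record()]s, both at least `min_block` bp.
#' @param scheme a [scoring_scheme()].
#' @param min_block minimum block length considered (bp).
#' @param anchor_slack tolerance for terminal anchoring (bp).
#' @return an `element_architecture`: list with `five_block`,
#'   `three_block` (each `NULL` or a list `side_start`, `side_end`,
#'   `line_start`, `line_end`, `pct_identity`, `score`), `variable_region`
#'   (`c(start, end)` on the SIDE or `NULL`), `polya_len`, `side_len`,
#'   `line_len`. A missing block yields a warning (SIDE call not
#'   confirmed).
#' @export
find_homologous_blocks <- function(side, line, scheme = scoring_scheme(),
                                   min_block = 50L, anchor_slack = 10L) {
  Ls <- seq_length(side); Ll <- seq_length(line)
  stopifnot(Ls >= min_block, Ll >= min_block)
  polya <- detect_polya(side)

  as_block <- function(aln, side_offset = 0L) {
    list(side_start = aln$a_start + side_offset,
         side_end = aln$a_end + side_offset,
         line_start = aln$b_start, line_end = aln$b_end,
         pct_identity = 100 * aln$n_match / (aln$n_match + aln$n_mismatch),
         score = aln$score)
  }

  b1 <- local_align(side$seq, line$seq, scheme)
  if (b1$score <= 0) {
    warning("no homology between SIDE and LINE; SIDE call not confirmed")
    return(structure(list(five_block = NULL, three_block = NULL,
                          variable_region = NULL, polya_len = polya,
                          side_len = Ls, line_len = Ll),
                     class = "element_architecture"))
  }
  blocks <- list(as_block(b1))
  left_len <- b1$a_start
  right_len <- Ls - b1$a_end
  if (left_len >= min_block) {
    sub <- substr(side$seq, 1L, b1$a_start)
    a <- local_align(sub, line$seq, scheme)
    if (a$score > 0 && (a$n_match + a$n_mismatch) >= min_block)
      blocks <- c(blocks, list(as_block(a)))
  }
  if (right_len >= min_block) {
    sub <- substr(side$seq, b1$a_end + 1L, Ls)
    a <- local_align(sub, line$seq, scheme)
    if (a$score > 0 && (a$n_match + a$n_mismatch) >= min_block)
      blocks <- c(blocks, list(as_block(a, side_offset = b1$a_end)))
  }

  near_start <- vapply(blocks, function(b) b$side_start <= anchor_slack,
                       logical(1))
  near_end <- vapply(blocks, function(b)
    b$side_end >= Ls - anchor_slack || b$side_end >= Ls - polya - anchor_slack,
    logical(1))
  score_of <- vapply(blocks, function(b) b$score, numeric(1))

  five <- NULL; three <- NULL
  if (any(near_start))
    five <- blocks[near_start][[which.max(score_of[near_start])]]
  remaining <- near_end & !vapply(blocks, identical, logical(1), y = five)
  if (any(remaining))
    three <- blocks[remaining][[which.max(score_of[remaining])]]
  # a single block spanning essentially everything: degenerate (SIDE = LINE)
  if (!is.null(five) && is.null(three) && five$side_end >= Ls - anchor_slack - polya &&
      five$side_start <= anchor_slack) {
    side_log("find_homologous_blocks: single block spans the whole element (no internal deletion)",
             level = "warning")
  }
  if (is.null(five))
    warning("no 5'-anchored homologous block found; SIDE call not confirmed")
  if (is.null(three) && !(is.null(five) || five$side_end >= Ls - anchor_slack - polya))
    warning("no 3'-anchored homologous block found; SIDE call not confirmed")

  variable <- NULL
  if (!is.null(five) && !is.null(three) && three$side_start > five$side_end)
    variable <- c(five$side_end, three$side_start)
  structure(list(five_block = five, three_block = three,
                 variable_region = variable, polya_len = polya,
                 side_len = Ls, line_len = Ll),
            class = "element_architecture")
}

#' Percent identity of an aligned sequence pair
#'
#' `100 * matches / aligned columns`, where columns containing a gap in
#' either sequence are excluded from both numerator and denominator.
#'
#' @param a,b aligned strings of equal length (from one alignment; `-` is
#'   the gap character).
#' @return identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av != "-" & bv != "-"
  if (!any(ok)) stop("no gap-free columns; identity undefined")
  100 * sum(av[ok] == bv[ok]) / sum(ok)
}

#' Length of a terminal homopolymer tail
#'
#' Scans backwards from the 3' terminus for a run of `base` (default
#' poly-A; set `base = "C"` for poly-C stretches), allowing at most
#' `max_mismatch_per_10` non-target bases within any 10 most recently
#' included positions. The tail must begin and end on the target base; a
#' run shorter than `min_run` reports 0.
#'
#' @param seq a [seq_record()] or DNA string.
#' @param base target base.
#' @param min_run minimum run length to report.
#' @param max_mismatch_per_10 tolerated non-target bases per 10 bp window.
#' @return tail length (0 if absent).
#' @export
detect_polya <- function(seq, base = "A", min_run = 5L,
                         max_mismatch_per_10 = 1L) {
  s <- if (inherits(seq, "seq_record")) seq$seq else seq
  L <- nchar(s)
  if (L == 0L) return(0L)
  v <- strsplit(s, "")[[1]]
  if (v[L] != base) return(0L)
  flags <- logical(0) # TRUE = mismatch, most recent last
  i <- L
  while (i >= 1L) {
    mm <- v[i] != base
    window <- c(flags, mm)
    window <- window[max(1L, length(window) - 9L):length(window)]
    if (mm && sum(window) > max_mismatch_per_10) break
    flags <- c(flags, mm)
    i <- i - 1L
  }
  # trim mismatches at the 5' edge of the tail
  while (length(flags) > 0L && flags[length(flags)]) flags <- flags[-length(flags)]
  len <- length(flags)
  if (len < min_run) 0L else len
}

#' Detect a target-site duplication flanking an insertion
#'
#' Finds the longest exact word duplicated on both sides of the insertion,
#' with its right edge at the insertion start and its left edge at the
#' insertion end (the signature of target-primed insertion). Exact
#' duplication only; length restricted to `len_range`.
#'
#' @param genome a [seq_record()] or DNA string.
#' @param insertion `c(start, end)` of the inserted element, 0-based
#'   half-open (element only, excluding the duplications).
#' @param window flank width inspected on each side (bp).
#' @param len_range `c(min, max)` motif length.
#' @return a list `motif`, `length`, `left_iv`, `right_iv` (0-based
#'   half-open), or `NULL` if no duplication (or the insertion sits at a
#'   contig edge, with a warning).
#' @export
detect_tsd <- function(genome, insertion, window = 20L, len_range = c(2L, 20L)) {
  s <- if (inherits(genome, "seq_record")) genome$seq else genome
  L <- nchar(s)
  start <- insertion[1]; end <- insertion[2]
  stopifnot(start >= 0, end > start, end <= L)
  kmin <- len_range[1]; kmax <- min(len_range[2], window)
  if (start < kmin || end + kmin > L) {
    side_log("detect_tsd: insertion at contig edge; no flank to inspect",
             level = "warning")
    return(NULL)
  }
  left <- substr(s, max(1L, start - window + 1L), start)
  right <- substr(s, end + 1L, min(L, end + window))
  kmax <- min(kmax, nchar(left), nchar(right))
  for (k in rev(seq.int(kmin, kmax))) {
    suf <- substr(left, nchar(left) - k + 1L, nchar(left))
    pre <- substr(right, 1L, k)
    if (suf == pre) {
      return(list(motif = suf, length = k,
                  left_iv = c(start - k, start),
                  right_iv = c(end, end + k)))
    }
  }
  NULL
}

#' Direct repeats (microhomologies) at deletion breakpoints
#'
#' Reports every word of length `k` in `k_range` present near both
#' breakpoints of an internal deletion: in a window straddling the
#' deletion start (`[start - window, start + k)`) and one straddling the
#' deletion end (`[end - k, end + window)`). The one-word-length overlap
#' into the deleted interval accommodates the retained-copy geometry of
#' template-jump deletions, where one repeat copy sits flush against a
#' breakpoint. Longest words first.
#'
#' @param line a [seq_record()] or DNA string (the intact element).
#' @param deleted `c(start, end)` of the deleted interval, 0-based
#'   half-open, strictly inside the element.
#' @param k_range word lengths to test.
#' @param window flank width at each breakpoint (bp).
#' @return data frame `motif`, `length`, `upstream_pos`, `downstream_pos`
#'   (0-based starts of the two occurrences), longest first; zero rows if
#'   none.
#' @export
find_breakpoint_microhomology <- function(line, deleted, k_range = 3:12,
                                          window = 15L) {
  s <- if (inherits(line, "seq_record")) line$seq else line
  L <- nchar(s)
  ds <- deleted[1]; de <- deleted[2]
  stopifnot(ds > 0, de < L, ds < de)
  out <- list()
  for (k in sort(k_range, decreasing = TRUE)) {
    up_lo <- max(0L, ds - window); up_hi <- min(ds + k, de)
    dn_lo <- max(ds, de - k); dn_hi <- min(L, de + window)
    if (up_hi - up_lo < k || dn_hi - dn_lo < k) next
    up_starts <- seq.int(up_lo, up_hi - k)
    dn_starts <- seq.int(dn_lo, dn_hi - k)
    up_words <- substring(s, up_starts + 1L, up_starts + k)
    dn_words <- substring(s, dn_starts + 1L, dn_starts + k)
    shared <- intersect(up_words, dn_words)
    for (w in shared) {
      up_at <- up_starts[match(w, up_words)]
      dn_at <- dn_starts[match(w, dn_words)]
      if (up_at == dn_at) next # same physical occurrence, not a repeat
      out[[length(out) + 1L]] <- data.frame(motif = w, length = k,
                                            upstream_pos = up_at,
                                            downstream_pos = dn_at,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(motif = character(), length = integer(),
                      upstream_pos = integer(), downstream_pos = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(-res$length, res$upstream_pos), , drop = FALSE]
}

#' Position frequency matrix and information content (sequence logo)
#'
#' Per-position base frequencies over aligned equal-length sequences and
#' the information content `2 + sum_b f_b log2 f_b` bits (0 log 0 = 0),
#' the quantity a sequence-logo letter stack displays.
#'
#' @param seqs character vector of aligned DNA strings, all one length.
#' @param anchor optional 0-based position marking the breakpoint the
#'   alignment is anchored on (metadata only).
#' @return list of class `logo_matrix`: `freqs` (L x 4 matrix, columns
#'   A,C,G,T), `info_bits` (length L), `anchor`.
#' @export
breakpoint_logo <- function(seqs, anchor = NULL) {
  if (length(seqs) == 0L) stop("no sequences")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must all have the same length")
  mat <- do.call(rbind, strsplit(seqs, ""))
  freqs <- t(apply(mat, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0L) return(rep(0.25, 4))
    tabulate(match(col, c("A", "C", "G", "T")), nbins = 4L) / length(col)
  }))
  colnames(freqs) <- c("A", "C", "G", "T")
  info <- apply(freqs, 1L, function(f) {
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  structure(list(freqs = freqs, info_bits = info, anchor = anchor),
            class = "logo_matrix")
}

#' Infer the deleted LINE interval from a SIDE architecture
#'
#' The LINE span absent from the SIDE: from the end of the 5' homologous
#' block to the start of the 3' homologous block, in LINE coordinates.
#' Feeds [find_breakpoint_microhomology()].
#'
#' @param architecture an `element_architecture` with both blocks present.
#' @param line_len LINE length (bp), for bounds checking.
#' @return `c(start, end)`, 0-based half-open on the LINE.
#' @export
infer_deletion_interval <- function(architecture, line_len = architecture$line_len) {
  five <- architecture$five_block; three <- architecture$three_block
  if (is.null(five) || is.null(three))
    stop("both homologous blocks are required to infer a deletion interval")
  if (three$line_start <= five$line_end)
    stop("homologous blocks overlap on the LINE; not an internal deletion")
  stopifnot(five$line_end >= 0, three$line_start <= line_len)
  c(five$line_end, three$line_start)
}

#' Write an element architecture as GFF3
#'
#' Features on the SIDE consensus coordinate system (1-based inclusive):
#' the homologous blocks, variable region and poly-A tail.
#'
#' @param architecture an `element_architecture`.
#' @param side_id sequence id for column 1.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_architecture_gff3 <- function(architecture, side_id, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  emit <- function(type, start, end, attrs) {
    writeLines(sprintf("%s\tsidekit\t%s\t%d\t%d\t.\t+\t.\t%s",
                       side_id, type, start + 1L, end, attrs), con)
  }
  a <- architecture
  if (!is.null(a$five_block))
    emit("five_prime_homologous_block", a$five_block$side_start,
         a$five_block$side_end,
         sprintf("line_start=%d;line_end=%d;pct_identity=%.2f",
                 a$five_block$line_start, a$five_block$line_end,
                 a$five_block$pct_identity))
  if (!is.null(a$variable_region))
    emit("variable_region", a$variable_region[1], a$variable_region[2], "-")
  if (!is.null(a$three_block))
    emit("three_prime_homologous_block", a$three_block$side_start,
         a$three_block$side_end,
         sprintf("line_start=%d;line_end=%d;pct_identity=%.2f",
                 a$three_block$line_start, a$three_block$line_end,
                 a$three_block$pct_identity))
  if (a$polya_len > 0L)
    emit("polyA_tail", a$side_len - a$polya_len, a$side_len, "-")
  invisible(path)
}

#' Write a logo matrix as TSV
#'
#' @param logo a `logo_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_logo_tsv <- function(logo, path) {
  df <- data.frame(position = seq_len(nrow(logo$freqs)) - 1L,
                   A = logo$freqs[, "A"], C = logo$freqs[, "C"],
                   G = logo$freqs[, "G"], T = logo$freqs[, "T"],
                   info_bits = logo$info_bits)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(sprintf("%d\t%.6f\t%.6f\t%.6f\t%.6f\t%.6f", df$position, df$A,
                     df$C, df$G, df$T, df$info_bits), con)
  invisible(path)
}
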