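#' Exclude short alignment fragments
#'
#' Because a SIDE and its partner LINE share their 5'/3' ends, their
#' consensuses cross-mask each other's copies; dropping fragments whose
#' genome span is below `min_len` leaves only fragments unambiguously
#' attributable to one family. The threshold is inclusive: a fragment of
#' exactly `min_len` bp is retained ("exclude fragments < min_len").
#' Counts before/after are logged.
#'
#' @param hits a [hit_table()].
#' @param min_len minimum genome span (bp); default from
#'   [pipeline_config()] is 160 (use 250 for genomes with worse
#'   cross-masking).
#' @return the retained rows.
#' @export
filter_fragments <- function(hits, min_len = 160L) {
  span <- hits$end - hits$start
  out <- hits[span >= min_len, , drop = FALSE]
  side_log("filter_fragments: %d/%d fragment(s) >= %d bp retained",
           nrow(out), nrow(hits), min_len)
  out
}

#' Merge adjacent collinear fragments into element copies
#'
#' Defragmentation: old copies are interrupted by later insertions and
#' deletions, so one copy appears as several fragments. Greedy chaining
#' along the genome joins consecutive fragments into one copy when they
#' share family and strand, the genomic gap is at most `merge_max_gap`
#' plus the consensus-coordinate gap between them, and their consensus
#' coordinates are collinear (the next fragment resumes no more than 20 bp
#' before the previous one ended, strand-appropriately). Each hit lands in
#' exactly one copy; copy count never exceeds hit count.
#'
#' @param hits a [hit_table()] (any order; sorted internally).
#' @param config a [pipeline_config()] supplying `merge_max_gap`.
#' @return data frame of class `merged_copies`: `copy_id`, `family`,
#'   `seqid`, `start`, `end` (hull), `strand`, `n_fragments`,
#'   `matched_bp` (summed fragment genome spans), `n_match`, `n_mismatch`
#'   (pooled gap-free columns), `p` (mismatch proportion), `d`
#'   (Jukes-Cantor distance), `saturated`.
#' @export
merge_adjacent <- function(hits, config = pipeline_config()) {
  if (nrow(hits) == 0L) return(empty_copies())
  fam <- split(seq_len(nrow(hits)), hits$family)
  out <- do.call(rbind, lapply(fam, function(idx)
    merge_adjacent_one(hits[idx, , drop = FALSE], config)))
  out <- out[order(out$seqid, out$start), , drop = FALSE]
  out$copy_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  side_log("merge_adjacent: %d fragment(s) -> %d copy(ies)", nrow(hits),
           nrow(out))
  class(out) <- c("merged_copies", "data.frame")
  out
}

merge_adjacent_one <- function(hits, config) {
  hits <- hits[order(hits$seqid, hits$start, hits$end), , drop = FALSE]
  n <- nrow(hits)
  copy_of <- integer(n)
  copy_of[1L] <- 1L
  for (i in seq_len(n)[-1L]) {
    prev <- i - 1L # chain only onto the immediately preceding fragment
    same <- hits$seqid[i] == hits$seqid[prev] &&
      hits$family[i] == hits$family[prev] &&
      hits$strand[i] == hits$strand[prev]
    joined <- FALSE
    if (same) {
      ggap <- hits$start[i] - hits$end[prev]
      if (hits$strand[i] == "+") {
        qgap <- hits$q_start[i] - hits$q_end[prev]
        collinear <- hits$q_start[i] >= hits$q_end[prev] - 20L
      } else { # minus strand: genome order runs 3'->5' on the consensus
        qgap <- hits$q_start[prev] - hits$q_end[i]
        collinear <- hits$q_end[i] <= hits$q_start[prev] + 20L
      }
      if (same && collinear && ggap <= config$merge_max_gap + max(0L, qgap))
        joined <- TRUE
    }
    copy_of[i] <- if (joined) copy_of[prev] else copy_of[prev] + 1L
  }
  out <- lapply(split(seq_len(n), copy_of), function(idx) {
    h <- hits[idx, , drop = FALSE]
    data.frame(family = h$family[1L], seqid = h$seqid[1L],
               start = min(h$start), end = max(h$end), strand = h$strand[1L],
               n_fragments = length(idx),
               matched_bp = sum(h$end - h$start),
               n_match = sum(h$n_match), n_mismatch = sum(h$n_mismatch),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$copy_id <- NA_integer_
  out$p <- out$n_mismatch / (out$n_match + out$n_mismatch)
  out$saturated <- out$p >= 0.75
  out$d <- ifelse(out$saturated, NA_real_, jukes_cantor(pmin(out$p, 0.749999)))
  if (any(out$saturated))
    side_log("merge_adjacent: %d copy(ies) at mismatch saturation flagged (d undefined)",
             sum(out$saturated), level = "warning")
  out[, c("copy_id", "family", "seqid", "start", "end", "strand",
          "n_fragments", "matched_bp", "n_match", "n_mismatch",
          "p", "d", "saturated")]
}

empty_copies <- function() {
  out <- data.frame(copy_id = integer(), family = character(),
                    seqid = character(), start = integer(), end = integer(),
                    strand = character(), n_fragments = integer(),
                    matched_bp = integer(), n_match = integer(),
                    n_mismatch = integer(), p = numeric(), d = numeric(),
                    saturated = logical(), stringsAsFactors = FALSE)
  class(out) <- c("merged_copies", "data.frame")
  out
}

#' Jukes-Cantor distance
#'
#' `d = -(3/4) ln(1 - 4p/3)`: the expected number of substitutions per
#' site given an observed mismatch proportion `p`, correcting for multiple
#' hits under the one-parameter substitution model. Defined for
#' `0 <= p < 0.75`; at `p >= 0.75` the correction diverges (saturation).
#'
#' @param p observed mismatch proportion(s).
#' @return corrected distance(s), `d >= p`.
#' @export
jukes_cantor <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 0.75))
    stop("jukes_cantor: p must satisfy 0 <= p < 0.75 (saturation)")
  -0.75 * log(1 - 4 * p / 3)
}

#' Divergence of one copy versus its family consensus
#'
#' Re-aligns the (possibly fragmented) copy against the consensus and
#' pools mismatches over gap-free aligned columns: `p = mismatches /
#' columns`, `d = jukes_cantor(p)`. Copies at saturation are flagged
#' (excluded from landscapes) with a warning.
#'
#' @param copy one row of a `merged_copies` frame (or any list with
#'   `seqid`, `start`, `end`, `strand`, and optionally `n_fragments`).
#' @param consensus the family [seq_record()].
#' @param genome the genome (`seq_record` or list) the copy lives in.
#' @param scheme a [scoring_scheme()].
#' @return the copy with `n_match`, `n_mismatch`, `p`, `d`, `saturated`
#'   updated.
#' @export
copy_divergence <- function(copy, consensus, genome,
                            scheme = scoring_scheme()) {
  if (inherits(genome, "seq_record")) genome <- list(genome)
  seqs <- setNames(vapply(genome, function(r) r$seq, character(1)),
                   vapply(genome, function(r) r$id, character(1)))
  frag <- subseq0(seqs[[copy$seqid]], copy$start, copy$end, copy$strand)
  aln <- local_align(frag, consensus$seq, scheme)
  if (aln$n_match + aln$n_mismatch == 0L)
    stop("copy does not align to the consensus")
  copy$n_match <- aln$n_match
  copy$n_mismatch <- aln$n_mismatch
  copy$p <- aln$n_mismatch / (aln$n_match + aln$n_mismatch)
  copy$saturated <- copy$p >= 0.75
  if (copy$saturated) {
    side_log("copy_divergence: copy at saturation (p = %.3f); excluded from landscapes",
             copy$p, level = "warning")
    copy$d <- NA_real_
  } else {
    copy$d <- jukes_cantor(copy$p)
  }
  copy
}

#' Activity-through-age landscape
#'
#' Bins per-copy Jukes-Cantor divergences into fixed-width bins (default
#' 0.01 substitutions/site) and reports copy count and summed matched bp
#' per bin and family. Low-divergence bins hold the most recently
#' transposed copies; no calendar dating is implied. Saturated copies
#' (`d = NA`) are excluded.
#'
#' @param copies a `merged_copies` frame carrying `d`.
#' @param config a [pipeline_config()] supplying `landscape_bin_width`.
#' @return data frame `family`, `bin_start`, `bin_end`, `n_copies`, `bp`.
#' @export
activity_landscape <- function(copies, config = pipeline_config()) {
  w <- config$landscape_bin_width
  ok <- !is.na(copies$d)
  copies <- copies[ok, , drop = FALSE]
  if (nrow(copies) == 0L)
    return(data.frame(family = character(), bin_start = numeric(),
                      bin_end = numeric(), n_copies = integer(),
                      bp = integer(), stringsAsFactors = FALSE))
  nbins <- max(1L, ceiling((max(copies$d) + 1e-12) / w))
  bin <- pmin(nbins - 1L, floor(copies$d / w))
  out <- do.call(rbind, lapply(split(seq_len(nrow(copies)),
                                     list(copies$family, bin), drop = TRUE),
                               function(idx) {
    data.frame(family = copies$family[idx[1L]], bin = bin[idx[1L]],
               n_copies = length(idx), bp = sum(copies$matched_bp[idx]),
               stringsAsFactors = FALSE)
  }))
  out$bin_start <- out$bin * w
  out$bin_end <- (out$bin + 1L) * w
  out <- out[order(out$family, out$bin_start),
             c("family", "bin_start", "bin_end", "n_copies", "bp")]
  rownames(out) <- NULL
  out
}

#' Modal divergence bin of a landscape
#'
#' @param landscape output of [activity_landscape()].
#' @param family family to inspect.
#' @param by rank bins by copy count (`"n_copies"`) or bp (`"bp"`).
#' @return `c(bin_start, bin_end)` of the fullest bin.
#' @export
landscape_mode <- function(landscape, family, by = c("n_copies", "bp")) {
  by <- match.arg(by)
  sub <- landscape[landscape$family == family, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no bins for family '", family, "'")
  i <- which.max(sub[[by]])
  c(sub$bin_start[i], sub$bin_end[i])
}

#' Fraction of a genome covered by element copies
#'
#' Union of copy intervals (overlaps counted once) divided by genome
#' length.
#'
#' @param copies a `merged_copies` frame (or any frame with
#'   `start`/`end`).
#' @param genome_len genome length (bp), > 0.
#' @return coverage fraction in `[0, 1]`.
#' @export
genome_coverage <- function(copies, genome_len) {
  stopifnot(genome_len > 0)
  if (nrow(copies) == 0L) return(0)
  ir <- IRanges::IRanges(start = copies$start + 1L, end = copies$end)
  sum(IRanges::width(IRanges::reduce(ir))) / genome_len
}

#' Cross-genome SIDE/LINE copy-number correlation
#'
#' Spearman rank correlation between per-genome SIDE and LINE copy
#' numbers (rank-based, robust to the orders-of-magnitude range real
#' copy-number tables span). The p-value is exact (all `n!` permutations)
#' for `n <= 8`, otherwise Monte-Carlo with `n_perm` permutations at a
#' fixed seed; two-sided: `P(|rho_perm| >= |rho_obs|)`.
#'
#' @param table data frame with columns `side` and `line` (one row per
#'   genome), `n >= 4`.
#' @param n_perm Monte-Carlo permutations when `n > 8`.
#' @param seed RNG seed for the Monte-Carlo branch.
#' @return list of class `correlation_result`: `n`, `statistic`,
#'   `p_value`, `method`.
#' @export
copy_number_correlation <- function(table, n_perm = 10000L, seed = 1L) {
  stopifnot(all(c("side", "line") %in% names(table)))
  x <- table$side; y <- table$line
  n <- length(x)
  if (n < 4L) stop("need counts from at least 4 genomes")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant ranks; correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(pr) cor(rx, ry[pr]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- sprintf("spearman, exact permutation (%d!)", n)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    rhos <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)), numeric(1))
    p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
    method <- sprintf("spearman, %d Monte-Carlo permutations", n_perm)
  }
  structure(list(n = n, statistic = rho, p_value = p, method = method),
            class = "correlation_result")
}

# all n! permutations of 1..n as a matrix (n <= 8: at most 40,320 rows)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, 1L] <- k
    rest <- seq_len(n)[-k]
    block[, -1L] <- matrix(rest[sub], nrow(sub))
    out[[k]] <- block
  }
  do.call(rbind, out)
}

#' Write merged copies as BED6 or TSV
#'
#' @param copies a `merged_copies` frame.
#' @param path output file.
#' @param dialect `"tsv"` (all columns) or `"bed"` (BED6, name =
#'   `family#copy_id`).
#' @return `path`, invisibly.
#' @export
write_copies <- function(copies, path, dialect = c("tsv", "bed")) {
  dialect <- match.arg(dialect)
  con <- file(path, "wb")
  on.exit(close(con))
  if (dialect == "tsv") {
    cols <- c("copy_id", "family", "seqid", "start", "end", "strand",
              "n_fragments", "matched_bp", "n_match", "n_mismatch", "p", "d",
              "saturated")
    writeLines(paste(cols, collapse = "\t"), con)
    if (nrow(copies) > 0L)
      writeLines(sprintf("%d\t%s\t%s\t%d\t%d\t%s\t%d\t%d\t%d\t%d\t%.6f\t%s\t%s",
                         copies$copy_id, copies$family, copies$seqid,
                         copies$start, copies$end, copies$strand,
                         copies$n_fragments, copies$matched_bp,
                         copies$n_match, copies$n_mismatch, copies$p,
                         ifelse(is.na(copies$d), "NA", sprintf("%.6f", copies$d)),
                         ifelse(copies$saturated, "TRUE", "FALSE")), con)
  } else {
    if (nrow(copies) > 0L)
      writeLines(sprintf("%s\t%d\t%d\t%s#%d\t%d\t%s", copies$seqid,
                         copies$start, copies$end, copies$family,
                         copies$copy_id,
                         pmax(0L, pmin(1000L, copies$matched_bp)),
                         copies$strand), con)
  }
  invisible(path)
}
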