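#' Select the seed set of full-length hits
#'
#' The first consensus round uses the top-scoring `n_seed_hits` hits whose
#' span on the consensus covers at least `full_length_frac` of its length
#' ("full-length" hits). "First" is read as top-scoring rather than
#' first-encountered, so the seed set does not depend on genome
#' coordinates.
#'
#' @param hits a [hit_table()].
#' @param consensus_len length of the query consensus (bp).
#' @param config a [pipeline_config()].
#' @return the selected rows, sorted by decreasing score.
#' @export
select_full_length_hits <- function(hits, consensus_len,
                                    config = pipeline_config()) {
  span <- hits$q_end - hits$q_start
  qual <- hits[span >= config$full_length_frac * consensus_len, , drop = FALSE]
  if (nrow(qual) == 0L)
    stop("no full-length hits at full_length_frac = ", config$full_length_frac,
         "; lower full_length_frac or check the query")
  qual <- qual[order(-qual$score, qual$seqid, qual$start), , drop = FALSE]
  out <- head(qual, config$n_seed_hits)
  side_log("select_full_length_hits: %d/%d hits full-length; %d selected",
           nrow(qual), nrow(hits), nrow(out))
  out
}

#' Extract hit sequences from the genome
#'
#' Returns one `seq_record` per hit row, in forward consensus orientation
#' (minus-strand hits are reverse-complemented).
#'
#' @param hits a [hit_table()].
#' @param genome a `seq_record` or list of them.
#' @return list of [seq_record()].
#' @export
extract_hit_seqs <- function(hits, genome) {
  if (inherits(genome, "seq_record")) genome <- list(genome)
  seqs <- setNames(vapply(genome, function(r) r$seq, character(1)),
                   vapply(genome, function(r) r$id, character(1)))
  lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    seq_record(sprintf("%s_%s_%d_%d%s", h$family, h$seqid, h$start, h$end,
                       if (h$strand == "-") "_rc" else ""),
               subseq0(seqs[[h$seqid]], h$start, h$end, h$strand))
  })
}

#' Anchor copies onto a reference and build a base-count profile
#'
#' Multiple alignment by pairwise anchoring: each copy is locally aligned
#' to the reference and its bases are projected onto reference columns.
#' Deletions in a copy are counted as gaps; insertions relative to the
#' reference are recorded (total bases) but excluded from the profile, so
#' consensus coordinates stay fixed within a round. Copies with no
#' significant alignment (score below `min_score`) are dropped with a
#' warning.
#'
#' @param copies list of [seq_record()].
#' @param reference a `seq_record` giving the column system.
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum alignment score for a copy to be anchored.
#' @return a `consensus_profile`: list with `counts` (5 x L matrix, rows
#'   A,C,G,T,gap), `depth`, `insertions_dropped`, `reference`.
#' @export
anchor_align <- function(copies, reference, scheme = scoring_scheme(),
                         min_score = 20L) {
  L <- seq_length(reference)
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  dropped <- 0L
  ins_dropped <- 0L
  anchored <- 0L
  cvec <- integer(5L * L) # column-major (A,C,G,T,-) x reference position
  for (cp in copies) {
    aln <- anchored_local_align(cp$seq, reference$seq, scheme)
    if (aln$score < min_score) {
      dropped <- dropped + 1L
      next
    }
    av <- strsplit(aln$a_aln, "")[[1]]
    bv <- strsplit(aln$b_aln, "")[[1]]
    ref_col <- bv != "-"
    ins_dropped <- ins_dropped + sum(!ref_col)
    pos <- aln$b_start + cumsum(ref_col) # 1-based reference column
    row <- match(av, c("A", "C", "G", "T", "-"))
    keep <- ref_col & !is.na(row)
    cvec <- cvec + tabulate((pos[keep] - 1L) * 5L + row[keep], nbins = 5L * L)
    anchored <- anchored + 1L
  }
  counts <- matrix(cvec, nrow = 5L,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  if (dropped > 0L)
    side_log("anchor_align: %d cop%s with no significant alignment dropped",
             dropped, if (dropped == 1L) "y" else "ies", level = "warning")
  side_log("anchor_align: %d/%d copies anchored; %d inserted base(s) excluded from profile",
           anchored, length(copies), ins_dropped, level = "debug")
  structure(list(counts = counts, depth = anchored,
                 insertions_dropped = ins_dropped, reference = reference),
            class = "consensus_profile")
}

# Local alignment accelerated by seeding: the copy's exact 11-mer matches
# to the reference fix a diagonal range, and the DP is banded around it.
# Falls back to the unbanded DP when seeds are absent (highly diverged
# copies) so the result is always a genuine local alignment.
anchored_local_align <- function(a, ref, scheme, pad = 80L) {
  seeds <- seed_hits_cpp(a, ref, 11L)
  if (nrow(seeds) < 3L) return(local_align(a, ref, scheme))
  diag <- seeds[, "spos"] - seeds[, "qpos"]
  local_align(a, ref, scheme,
              band_lo = min(diag) - pad, band_hi = max(diag) + pad)
}

#' Majority-rule consensus from a profile
#'
#' Per column, the most frequent base; columns where gap is the (strict)
#' majority call are removed; ties between bases are broken by the fixed
#' order A < C < G < T, and the number of tied columns is logged.
#'
#' @param profile a `consensus_profile` from [anchor_align()] with depth
#'   >= 2.
#' @param id id for the returned record.
#' @return a [seq_record()].
#' @export
majority_consensus <- function(profile, id = "consensus") {
  stopifnot(inherits(profile, "consensus_profile"))
  if (profile$depth < 2L) stop("consensus requires profile depth >= 2")
  counts <- profile$counts
  covered <- colSums(counts) > 0L
  base_counts <- counts[1:4, , drop = FALSE]
  top_base <- apply(base_counts, 2L, max)
  gap_major <- counts[5L, ] > top_base
  keep <- covered & !gap_major
  calls <- c("A", "C", "G", "T")[apply(base_counts[, keep, drop = FALSE], 2L,
                                       which.max)]
  ties <- sum(apply(base_counts[, keep, drop = FALSE], 2L,
                    function(v) sum(v == max(v)) > 1L))
  if (ties > 0L)
    side_log("majority_consensus: %d tied column(s) broken by base order A<C<G<T",
             ties)
  side_log("majority_consensus: %d columns in, %d gap-majority removed, %d uncovered removed",
           ncol(counts), sum(gap_major & covered), sum(!covered), level = "debug")
  seq_record(id, paste(calls, collapse = ""))
}

#' Two-round iterative consensus reconstruction
#'
#' The repeat-library procedure: search the genome with a seed query; build
#' a first majority-rule consensus from the top full-length
#' `config$n_seed_hits` hits; re-search the genome exhaustively with that
#' consensus; build the final consensus from all significant hits of the
#' re-search. Both rounds log their hit counts.
#'
#' @param genome a `seq_record` or list of them.
#' @param seed_query a `seq_record` (e.g. one recovered element copy).
#' @param config a [pipeline_config()].
#' @param scheme a [scoring_scheme()].
#' @param family family label for hit tables and the consensus id.
#' @return list with `consensus` (final `seq_record`), `profile` (final
#'   `consensus_profile`), `round1` (seed-round consensus), `hits_round1`,
#'   `hits_round2`.
#' @export
iterate_consensus <- function(genome, seed_query, config = pipeline_config(),
                              scheme = scoring_scheme(),
                              family = seed_query$id) {
  hits1 <- search_genome(seed_query, genome, config, scheme, family = family)
  if (nrow(hits1) == 0L) stop("seed query yielded no significant hits")
  seed_set <- select_full_length_hits(hits1, seq_length(seed_query), config)
  copies1 <- extract_hit_seqs(seed_set, genome)
  prof1 <- anchor_align(copies1, seed_query, scheme)
  cons1 <- majority_consensus(prof1, id = paste0(family, "_round1"))
  side_log("iterate_consensus: round 1: %d hits, %d seed copies, consensus %d bp",
           nrow(hits1), nrow(seed_set), seq_length(cons1))

  hits2 <- search_genome(cons1, genome, config, scheme, family = family)
  if (nrow(hits2) == 0L) stop("round-1 consensus yielded no significant hits")
  copies2 <- extract_hit_seqs(hits2, genome)
  prof2 <- anchor_align(copies2, cons1, scheme)
  cons2 <- majority_consensus(prof2, id = family)
  side_log("iterate_consensus: round 2: %d hits, final consensus %d bp",
           nrow(hits2), seq_length(cons2))

  list(consensus = cons2, profile = prof2, round1 = cons1,
       hits_round1 = hits1, hits_round2 = hits2)
}

#' Join the 5' and 3' ends of an element into one query
#'
#' The classic trick for finding internally deleted derivatives: the first
#' `five_len` and last `three_len` bases of the element are concatenated
#' and used as a search query, so that short copies retaining only the
#' element's ends still produce contiguous full-length-ish hits.
#'
#' @param element a [seq_record()].
#' @param five_len,three_len lengths (bp) of the 5' and 3' ends to join;
#'   their sum must not exceed the element length.
#' @return a `seq_record` with id suffixed `"_joined"`.
#' @export
join_ends <- function(element, five_len, three_len) {
  L <- seq_length(element)
  if (five_len < 0 || three_len < 0 || five_len + three_len > L)
    stop("five_len + three_len must be <= element length (", L, ")")
  seq_record(paste0(element$id, "_joined"),
             paste0(substr(element$seq, 1L, five_len),
                    if (three_len > 0) substr(element$seq, L - three_len + 1L, L) else ""))
}

#' Longest open reading frame across six frames
#'
#' Validation proxy for "encodes a reverse transcriptase": the longest
#' ATG-to-stop ORF over all six frames must reach `min_aa` codons
#' (default 300 aa, reflecting the ~1,000-aa ORF of an intact ~3.3 kb CR1
#' consensus; an internally deleted derivative fails). Standard genetic
#' code.
#'
#' @param consensus a [seq_record()].
#' @param min_aa minimum ORF length in amino acids (excluding the stop).
#' @return list of class `orf_report`: `best_orf_start`, `best_orf_end`
#'   (0-based half-open on the forward consensus, ATG through stop),
#'   `length_aa`, `frame` (0,1,2), `strand`, `passes`.
#' @export
validate_orf <- function(consensus, min_aa = 300L) {
  L <- seq_length(consensus)
  if (L < 3L * min_aa) stop("consensus shorter than 3*min_aa")
  best <- list(len_nt = 0L, start = NA_integer_, end = NA_integer_,
               frame = NA_integer_, strand = NA_character_)
  stops <- c("TAA", "TAG", "TGA")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") consensus$seq else revcomp(consensus$seq)
    n <- nchar(s)
    for (frame in 0:2) {
      starts <- seq.int(frame + 1L, n - 2L, by = 3L)
      codons <- substring(s, starts, starts + 2L)
      orf_start <- NA_integer_
      for (ci in seq_along(codons)) {
        cd <- codons[ci]
        if (is.na(orf_start)) {
          if (cd == "ATG") orf_start <- ci
        } else if (cd %in% stops) {
          len_nt <- 3L * (ci - orf_start + 1L) # ATG..stop inclusive
          if (len_nt > best$len_nt) {
            a <- starts[orf_start] - 1L # 0-based on s
            b <- starts[ci] + 2L
            if (strand == "-") { tmp <- a; a <- n - b; b <- n - tmp }
            best <- list(len_nt = len_nt, start = a, end = b,
                         frame = frame, strand = strand)
          }
          orf_start <- NA_integer_
        }
      }
    }
  }
  length_aa <- if (best$len_nt > 0L) best$len_nt %/% 3L - 1L else 0L
  structure(list(best_orf_start = best$start, best_orf_end = best$end,
                 length_aa = length_aa, frame = best$frame,
                 strand = best$strand, passes = length_aa >= min_aa),
            class = "orf_report")
}
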