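#' Scoring scheme for local alignment
#'
#' Match/mismatch scores, affine gap penalties (a gap of length L costs
#' `gap_open + L * gap_extend`), and the Karlin-Altschul parameters
#' `lambda` and `K` that turn a raw local-alignment score into an e-value.
#' The defaults (+1/-2, gap open -5, extend -2) are the classic
#' blastn-style DNA scores; for that matrix the ungapped Karlin-Altschul
#' solution is `lambda = ln((3 + sqrt(21))/2) ~= 1.3328` at uniform base
#' composition, with `K ~= 0.62`. [calibrate_karlin()] re-estimates both
#' from a shuffled-sequence null for other schemes.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend gap extension penalty (< 0).
#' @param lambda,K Karlin-Altschul parameters (> 0).
#' @return a list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L,
                           gap_open = -5L, gap_extend = -2L,
                           lambda = 1.3328, K = 0.62) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
            lambda > 0, K > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = as.numeric(lambda), K = as.numeric(K)),
            class = "scoring_scheme")
}

#' Optimal local alignment of two sequences
#'
#' Affine-gap Smith-Waterman with deterministic tie-breaking: among
#' equal-scoring alignments the one with the lowest start on `a`, then on
#' `b`, is returned. Coordinates are 0-based half-open. An optional
#' diagonal band (`diag = position_on_b - position_on_a`) restricts the
#' search space for seed-and-extend scans.
#'
#' @param a,b DNA strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @param band_lo,band_hi optional diagonal band limits.
#' @return list with `score`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   aligned strings `a_aln`/`b_aln`, and the column counts `n_match`,
#'   `n_mismatch`, `n_gapcols`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(),
                        band_lo = NULL, band_hi = NULL) {
  stopifnot(is.character(a), is.character(b), nzchar(a), nzchar(b))
  sw_align_cpp(a, b, scheme$match, scheme$mismatch, scheme$gap_open,
               scheme$gap_extend,
               if (is.null(band_lo)) NA_integer_ else as.integer(band_lo),
               if (is.null(band_hi)) NA_integer_ else as.integer(band_hi))
}

#' Karlin-Altschul e-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of chance
#' local alignments scoring at least `score` between a query of length `m`
#' and a subject of length `n`. Monotone decreasing in `score`, linear in
#' both lengths.
#'
#' @param score alignment score (>= 0).
#' @param m query length.
#' @param n subject length (total searched).
#' @param scheme a [scoring_scheme()] carrying `lambda` and `K`.
#' @return the e-value.
#' @export
evalue_of <- function(score, m, n, scheme = scoring_scheme()) {
  stopifnot(all(score >= 0), m > 0, n > 0)
  scheme$K * as.numeric(m) * as.numeric(n) * exp(-scheme$lambda * score)
}

#' Calibrate Karlin-Altschul parameters from a shuffled-sequence null
#'
#' Simulates `n_shuffle` pairs of i.i.d. random sequences of lengths `m`
#' and `n`, records their optimal local-alignment scores, and fits the
#' Gumbel law the Karlin-Altschul theory predicts for maxima:
#' `sd(S) = pi / (lambda * sqrt(6))` and
#' `mean(S) = (ln(K m n) + gamma) / lambda`, solved by moments.
#'
#' @param scheme a [scoring_scheme()] (its `lambda`/`K` are ignored).
#' @param m,n sequence lengths for the null.
#' @param n_shuffle number of random pairs.
#' @param gc GC content of the null sequences.
#' @param seed RNG seed (fixed for reproducibility).
#' @return a new `scoring_scheme` with calibrated `lambda` and `K`.
#' @export
calibrate_karlin <- function(scheme = scoring_scheme(), m = 200L, n = 200L,
                             n_shuffle = 1000L, gc = 0.5, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  scores <- vapply(seq_len(n_shuffle), function(i) {
    a <- rand_dna(m, gc)
    b <- rand_dna(n, gc)
    local_align(a, b, scheme)$score
  }, numeric(1))
  euler_gamma <- 0.5772156649015329
  lambda <- pi / (stats::sd(scores) * sqrt(6))
  K <- exp(lambda * mean(scores) - euler_gamma) / (as.numeric(m) * n)
  side_log("calibrate_karlin: lambda=%.4f K=%.4g from %d shuffles (m=%d n=%d)",
           lambda, K, n_shuffle, m, n)
  scoring_scheme(scheme$match, scheme$mismatch, scheme$gap_open,
                 scheme$gap_extend, lambda = lambda, K = K)
}

# save/restore global RNG state so calibrations don't perturb pipelines
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Random DNA string
#'
#' I.i.d. bases at a given GC content (the background model of the
#' simulator and of the e-value null).
#'
#' @param n length.
#' @param gc GC fraction in (0, 1).
#' @return a DNA string of length `n`.
#' @export
rand_dna <- function(n, gc = 0.5) {
  stopifnot(n > 0, gc > 0, gc < 1)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
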