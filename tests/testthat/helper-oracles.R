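# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately naive (full-matrix DP, exhaustive scans) and
# never share code with the implementation they check.

options(sidekit.log_level = "warning")

# Full-matrix affine-gap local alignment, score only. A gap of length L
# costs gap_open + L * gap_extend, as in the package's scheme.
sw_oracle_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = -5, gap_extend = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
    }
  }
  max(H)
}

# Exhaustive TSD scan: longest k with left-flank suffix == right-flank
# prefix, by direct substring comparison.
tsd_oracle <- function(genome, start, end, window = 20L, kmin = 2L, kmax = 20L) {
  L <- nchar(genome)
  for (k in rev(seq.int(kmin, min(kmax, window, start, L - end)))) {
    left <- substr(genome, start - k + 1L, start)
    right <- substr(genome, end + 1L, end + k)
    if (left == right) return(left)
  }
  NULL
}

# Exhaustive microhomology scan over all (k, offset) pairs under the same
# window contract as the package function: the upstream window straddles
# the deletion start by one word length, the downstream window straddles
# the deletion end.
mh_oracle <- function(s, ds, de, k_range = 3:12, window = 15L) {
  L <- nchar(s)
  found <- list()
  for (k in k_range) {
    up <- seq.int(max(0L, ds - window), min(ds + k, de) - k)
    dn <- seq.int(max(ds, de - k), min(L, de + window) - k)
    up <- up[up >= 0]; dn <- dn[dn >= 0]
    for (u in up) for (v in dn) {
      if (u != v &&
          substr(s, u + 1L, u + k) == substr(s, v + 1L, v + k))
        found[[length(found) + 1L]] <-
          list(motif = substr(s, u + 1L, u + k), k = k)
    }
  }
  found
}

# Recompute an alignment's score from its aligned strings (path audit).
score_from_alignment <- function(a_aln, b_aln, match = 1, mismatch = -2,
                                 gap_open = -5, gap_extend = -2) {
  av <- strsplit(a_aln, "")[[1]]; bv <- strsplit(b_aln, "")[[1]]
  s <- 0; prev_gap <- ""
  for (t in seq_along(av)) {
    g <- if (av[t] == "-") "a" else if (bv[t] == "-") "b" else ""
    if (g != "") {
      s <- s + gap_extend + if (g == prev_gap) 0 else gap_open
    } else {
      s <- s + if (av[t] == bv[t]) match else mismatch
    }
    prev_gap <- g
  }
  s
}

# A small simulation used by several unit tests (0.5 Mb, 40 LINE + 80
# SIDE copies, single burst at d = 0.05).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- plant_copies(simulation_config(
        genome_len = 5e5L, n_line = 40L, n_side = 80L, rng_seed = 101L))
    cache
  }
})
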