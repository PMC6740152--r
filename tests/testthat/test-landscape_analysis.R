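empty_copies_for_test <- function() data.frame(start = integer(), end = integer())

frag_hits <- function(spans, family = "f", strand = "+",
                      starts = cumsum(c(0L, head(spans, -1) + 1000L)),
                      q_starts = rep(0L, length(spans))) {
  n <- length(spans)
  hit_table(family = rep(family, n), seqid = rep("chr1", n),
            start = as.integer(starts), end = as.integer(starts + spans),
            strand = rep(strand, n), score = as.integer(spans),
            evalue = rep(1e-30, n), pct_identity = rep(95, n),
            q_start = as.integer(q_starts),
            q_end = as.integer(q_starts + spans),
            aligned_len = as.integer(spans), n_match = as.integer(spans),
            n_mismatch = rep(0L, n), n_gapcols = rep(0L, n))
}

test_that("the fragment filter boundary is inclusive at the published cut-offs", {
  h <- frag_hits(c(120L, 159L, 160L, 300L))
  suppressMessages({
    expect_equal(filter_fragments(h, 160L)$end - filter_fragments(h, 160L)$start,
                 c(160L, 300L))
    expect_equal(filter_fragments(h, 250L)$end - filter_fragments(h, 250L)$start,
                 300L)
    expect_equal(nrow(filter_fragments(hit_table(), 160L)), 0L)
  })
})

test_that("collinear nearby fragments merge into one copy; strands never mix", {
  # consensus [0,150) then [160,310), genomic gap 15
  h <- hit_table(family = c("f", "f"), seqid = c("chr1", "chr1"),
                 start = c(100L, 265L), end = c(250L, 415L),
                 strand = c("+", "+"), score = c(150L, 150L),
                 evalue = rep(1e-40, 2), pct_identity = rep(98, 2),
                 q_start = c(0L, 160L), q_end = c(150L, 310L),
                 aligned_len = c(150L, 150L), n_match = c(147L, 148L),
                 n_mismatch = c(3L, 2L), n_gapcols = c(0L, 0L))
  suppressMessages(copies <- merge_adjacent(h, pipeline_config()))
  expect_equal(nrow(copies), 1L)
  expect_equal(copies$n_fragments, 2L)
  expect_equal(copies$start, 100L)
  expect_equal(copies$end, 415L)
  expect_equal(copies$matched_bp, 300L)

  h$strand <- c("+", "-")
  suppressMessages(copies2 <- merge_adjacent(h, pipeline_config()))
  expect_equal(nrow(copies2), 2L)

  # non-collinear consensus coordinates never merge (two distinct copies)
  h3 <- frag_hits(c(200L, 200L), starts = c(0L, 230L),
                  q_starts = c(100L, 0L))
  suppressMessages(copies3 <- merge_adjacent(h3, pipeline_config()))
  expect_equal(nrow(copies3), 2L)
})

test_that("merging never increases copy count and a zero-gap config unmerges", {
  set.seed(41)
  spans <- sample(160:400, 20, replace = TRUE)
  h <- frag_hits(spans, starts = cumsum(c(0L, head(spans, -1) + 700L)))
  suppressMessages({
    copies <- merge_adjacent(h, pipeline_config())
    expect_lte(nrow(copies), nrow(h))
    expect_equal(nrow(merge_adjacent(h, pipeline_config(merge_max_gap = 1L))),
                 nrow(h))
  })
})

test_that("Jukes-Cantor correction follows the closed form", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(round(jukes_cantor(0.10), 6), 0.107326) # exact to 6 decimals
  p <- seq(0.01, 0.7, by = 0.01)
  expect_true(all(jukes_cantor(p) >= p)) # correction only inflates
  expect_lt(jukes_cantor(1e-6) - 1e-6, 1e-9) # and vanishes as p -> 0
  expect_error(jukes_cantor(0.75), "saturation")
  expect_error(jukes_cantor(-0.01), "saturation|must satisfy")
})

test_that("copy divergence pools gap-free columns and matches planted mismatches", {
  set.seed(42)
  cons <- seq_record("c", rand_dna(500))
  genome <- seq_record("chr1", paste0(rand_dna(300), cons$seq, rand_dna(300)))
  copy <- list(seqid = "chr1", start = 300L, end = 800L, strand = "+")
  got <- copy_divergence(copy, cons, genome)
  expect_equal(got$p, 0)
  expect_equal(got$d, 0)

  # exactly 20% planted mismatches
  v <- strsplit(cons$seq, "")[[1]]
  idx <- sample(500, 100)
  alt <- c(A = "C", C = "G", G = "T", T = "A")
  v[idx] <- alt[v[idx]]
  genome2 <- seq_record("chr1", paste0(rand_dna(300), paste(v, collapse = ""),
                                       rand_dna(300)))
  got2 <- copy_divergence(copy, cons, genome2)
  # local alignment may trim a terminal mismatch cluster, so "about 20%"
  expect_equal(got2$p, 0.20, tolerance = 0.03)
  expect_equal(got2$d, 0.2326, tolerance = 0.04)
})

test_that("observed copy divergences centre on the simulated burst age", {
  sim <- small_sim()
  cfg <- pipeline_config()
  hits <- search_genome(sim$side_master, sim$genome, cfg, family = "SIDE")
  hits <- suppressMessages(filter_fragments(hits, cfg$min_fragment_len))
  copies <- suppressMessages(merge_adjacent(hits, cfg))
  tr <- sim$truth[sim$truth$family == "SIDE", ]
  expect_equal(nrow(copies), nrow(tr), tolerance = 0.05)
  # mean observed d within 1.5 standard errors + divergence spread of the
  # burst mean 0.05
  se <- sd(copies$d) / sqrt(nrow(copies))
  expect_lt(abs(mean(copies$d) - 0.05), 3 * se + 0.01)
})

test_that("landscapes bin counts and conserve bp totals", {
  copies <- empty <- suppressMessages(merge_adjacent(frag_hits(c(200L, 300L)),
                                                     pipeline_config()))
  copies$d <- c(0, 0)
  ls0 <- activity_landscape(copies, pipeline_config())
  expect_equal(nrow(ls0), 1L)
  expect_equal(ls0$bin_start, 0)
  expect_equal(ls0$n_copies, 2L)
  expect_equal(sum(ls0$bp), sum(copies$matched_bp))

  set.seed(43)
  copies2 <- do.call(rbind, rep(list(copies), 40))
  copies2$d <- c(pmax(0, rnorm(40, 0.03, 0.008)),
                 pmax(0, rnorm(40, 0.15, 0.008)))
  copies2$family <- "f"
  ls2 <- activity_landscape(copies2, pipeline_config())
  expect_equal(sum(ls2$bp), sum(copies2$matched_bp)) # bp conserved
  expect_equal(sum(ls2$n_copies), 80L)
  # bimodal: local maxima at the two planted burst positions +- one bin
  top2 <- ls2[order(-ls2$n_copies), ][1:2, ]
  expect_lte(min(abs(sort(top2$bin_start) - 0.03)), 0.011)
  expect_lte(min(abs(sort(top2$bin_start, decreasing = TRUE) - 0.15)), 0.011)
})

test_that("genome coverage is a union fraction", {
  expect_equal(genome_coverage(empty_copies_for_test(), 1e4), 0)
  one <- data.frame(start = 0L, end = 100L)
  expect_equal(genome_coverage(one, 1e4), 0.01)
  two <- data.frame(start = c(0L, 50L), end = c(100L, 150L))
  expect_equal(genome_coverage(two, 1000), 0.15)
})

test_that("Spearman copy-number correlation has exact closed forms and an exhaustive oracle", {
  mono <- data.frame(side = c(1, 5, 20, 300, 4000), line = c(2, 7, 30, 600, 9000))
  r <- copy_number_correlation(mono)
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 2 / factorial(5))
  anti <- data.frame(side = mono$side, line = rev(mono$line))
  expect_equal(copy_number_correlation(anti)$statistic, -1)

  set.seed(44)
  for (rep in 1:5) {
    tab <- data.frame(side = sample(100, 6), line = sample(100, 6))
    got <- copy_number_correlation(tab)
    # independent brute force over all 720 permutations
    perms <- expand.grid(rep(list(1:6), 6))
    perms <- perms[apply(perms, 1, function(x) length(unique(x)) == 6), ]
    rx <- rank(tab$side); ry <- rank(tab$line)
    rho_obs <- cor(rx, ry)
    rhos <- apply(perms, 1, function(pr) cor(rx, ry[unlist(pr)]))
    expect_equal(got$statistic, rho_obs)
    expect_equal(got$p_value, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
  }
  expect_error(copy_number_correlation(data.frame(side = c(1, 1, 1, 1),
                                                  line = c(1, 2, 3, 4))),
               "constant ranks")
  expect_error(copy_number_correlation(data.frame(side = 1:3, line = 3:1)),
               "at least 4")
})

test_that("copies and landscape tables export and re-import", {
  copies <- suppressMessages(merge_adjacent(frag_hits(c(200L, 300L)),
                                            pipeline_config()))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_copies(copies, p, "tsv")
  back <- read.delim(p)
  expect_equal(back$start, copies$start)
  expect_equal(back$d, copies$d, tolerance = 1e-6)
  b <- withr::local_tempfile(fileext = ".bed")
  write_copies(copies, b, "bed")
  expect_equal(ncol(read.delim(b, header = FALSE)), 6L)
})
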