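test_that("homologous 5'/3' blocks are recovered on a constructed SIDE", {
  set.seed(31)
  line <- seq_record("LINE", rand_dna(1200))
  side <- seq_record("SIDE", paste0(substr(line$seq, 1, 120), rand_dna(100),
                                    substr(line$seq, 1061, 1200)))
  arch <- find_homologous_blocks(side, line)
  expect_false(is.null(arch$five_block))
  expect_false(is.null(arch$three_block))
  expect_lte(abs(arch$five_block$line_start - 0), 3)
  expect_lte(abs(arch$five_block$line_end - 120), 3)
  expect_lte(abs(arch$three_block$line_start - 1060), 3)
  expect_lte(abs(arch$three_block$line_end - 1200), 3)
  expect_lte(abs(arch$variable_region[1] - 120), 3)
  expect_lte(abs(arch$variable_region[2] - 220), 3)
  expect_equal(arch$five_block$pct_identity, 100)
})

test_that("a SIDE identical to the LINE degenerates to one spanning block", {
  set.seed(32)
  line <- seq_record("LINE", rand_dna(800))
  arch <- suppressMessages(find_homologous_blocks(line, line))
  expect_false(is.null(arch$five_block))
  expect_null(arch$three_block)
  expect_null(arch$variable_region)
  expect_equal(arch$five_block$side_start, 0L)
  expect_equal(arch$five_block$side_end, 800L)
  expect_error(infer_deletion_interval(arch), "both homologous blocks")
})

test_that("block identities on a diverged simulator pair track the observed mismatch", {
  sim <- small_sim()
  set.seed(33)
  side_copy <- seq_record("copy", mutate_copy(sim$side_master$seq, 0.05))
  arch <- find_homologous_blocks(side_copy, sim$line_master)
  for (b in list(arch$five_block, arch$three_block)) {
    expect_false(is.null(b))
    frag <- substr(side_copy$seq, b$side_start + 1, b$side_end)
    ref <- substr(sim$line_master$seq, b$line_start + 1, b$line_end)
    aln <- local_align(frag, ref)
    expect_lte(abs(b$pct_identity -
                     100 * aln$n_match / (aln$n_match + aln$n_mismatch)), 2)
  }
})

test_that("percent identity excludes gap columns and is symmetric", {
  expect_equal(percent_identity(strrep("A", 100), strrep("A", 100)), 100)
  a90 <- paste0(strrep("A", 90), strrep("C", 10))
  b90 <- strrep("A", 100)
  expect_equal(percent_identity(a90, b90), 90)
  expect_equal(percent_identity(b90, a90), 90)
  # 5 gap columns, 80 matches over 95 gap-free columns
  a <- paste0(strrep("A", 80), strrep("C", 15), strrep("-", 5))
  b <- paste0(strrep("A", 80), strrep("G", 15), strrep("T", 5))
  expect_equal(percent_identity(a, b), 100 * 80 / 95, tolerance = 1e-10)
  expect_equal(round(percent_identity(a, b), 2), 84.21)
  expect_error(percent_identity("---", "AAA"), "no gap-free")
})

test_that("poly-A tail detection follows the windowed-mismatch rule", {
  expect_equal(detect_polya(paste0("GCGC", strrep("A", 6))), 6L)
  expect_equal(detect_polya(paste0("GCGC", strrep("A", 5), "G")), 0L)
  expect_equal(detect_polya(paste0("GCGC", "AAAAGAAAAA")), 10L)
  expect_equal(detect_polya("GCGCGCGC"), 0L)
  expect_equal(detect_polya(paste0("GG", strrep("A", 4))), 0L) # below min_run
  expect_equal(detect_polya(paste0("TTTT", strrep("C", 8)), base = "C"), 8L)
})

test_that("TSD detection matches the exhaustive oracle and finds a planted (T)6", {
  g <- paste0("GATTACAGCGGCT", "TTTTTT", "CCGGAAGGCCTT", "TTTTTT", "AGCGTCAG")
  ins <- c(13L + 6L, 13L + 6L + 12L)
  r <- detect_tsd(g, ins)
  expect_equal(r$motif, "TTTTTT")
  expect_equal(r$length, 6L)
  expect_equal(r$left_iv, c(13L, 19L))
  expect_equal(r$right_iv, c(31L, 37L))

  set.seed(34)
  for (i in 1:100) {
    L <- sample(40:100, 1)
    g <- rand_dna(L)
    s <- sample(21:(L - 25), 1); e <- s + sample(3:8, 1)
    got <- detect_tsd(g, c(s, e))
    want <- tsd_oracle(g, s, e)
    if (is.null(want)) expect_null(got)
    else expect_equal(got$motif, want)
  }
})

test_that("TSD detection at a contig edge reports none with a warning", {
  expect_message(r <- detect_tsd("ACGTACGTAC", c(0L, 6L)), "contig edge")
  expect_null(r)
})

test_that("breakpoint microhomology matches the brute-force oracle", {
  # the documented case: a 5 bp direct repeat AGGCC surrounding the
  # deleted region
  set.seed(35)
  s <- paste0(rand_dna(40), "AGGCC", rand_dna(200), "AGGCC", rand_dna(40))
  del <- c(45L, 245L) # from just after the first copy to just after the second
  mh <- find_breakpoint_microhomology(s, del)
  expect_true("AGGCC" %in% mh$motif)
  row <- mh[mh$motif == "AGGCC", ][1, ]
  expect_equal(row$length, 5L)
  expect_equal(row$upstream_pos, 40L)
  expect_equal(row$downstream_pos, 245L)

  # no repeat planted: usually empty, always identical to the oracle
  for (i in 1:100) {
    L <- sample(60:100, 1)
    s <- rand_dna(L)
    ds <- sample(18:25, 1); de <- ds + sample(15:30, 1)
    got <- find_breakpoint_microhomology(s, c(ds, de))
    want <- mh_oracle(s, ds, de)
    want_set <- unique(vapply(want, function(w) w$motif, character(1)))
    expect_setequal(got$motif, want_set)
    if (nrow(got) > 0) {
      # longest-first ordering and recorded positions carry the motif
      expect_true(all(diff(got$length) <= 0))
      for (r in seq_len(nrow(got)))
        expect_equal(substr(s, got$upstream_pos[r] + 1,
                            got$upstream_pos[r] + got$length[r]),
                     got$motif[r])
    }
  }
})

test_that("logo frequencies and information content follow the closed form", {
  logo <- breakpoint_logo(c("AACA", "AGCA", "ATCG", "ACCT"))
  expect_equal(logo$freqs[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(logo$info_bits[1], 2)                   # conserved column
  expect_equal(logo$info_bits[2], 0)                   # uniform column
  expect_equal(logo$freqs[4, ], c(A = 0.5, C = 0, G = 0.25, T = 0.25))
  logo2 <- breakpoint_logo(c("AC", "AG"))
  expect_equal(logo2$info_bits[2], 1)                  # 50/50 column: 1 bit
  expect_true(all(abs(rowSums(logo$freqs) - 1) < 1e-9))
  expect_true(all(logo$info_bits >= 0 & logo$info_bits <= 2))
  expect_error(breakpoint_logo(character(0)), "no sequences")
  expect_error(breakpoint_logo(c("AA", "AAA")), "same length")
})

test_that("the deleted LINE interval is the span between the blocks", {
  arch <- structure(list(five_block = list(side_start = 0L, side_end = 350L,
                                           line_start = 0L, line_end = 350L,
                                           pct_identity = 95, score = 300L),
                         three_block = list(side_start = 450L, side_end = 790L,
                                            line_start = 3000L,
                                            line_end = 3340L,
                                            pct_identity = 96, score = 310L),
                         variable_region = c(350L, 450L), polya_len = 10L,
                         side_len = 790L, line_len = 3340L),
                    class = "element_architecture")
  expect_equal(infer_deletion_interval(arch), c(350L, 3000L))
  arch$three_block$line_start <- 300L # blocks overlap on the LINE
  expect_error(infer_deletion_interval(arch), "overlap")
})

test_that("simulator SIDE architecture round-trips deletion and microhomology", {
  sim <- small_sim()
  cfg <- sim$config
  arch <- find_homologous_blocks(sim$side_master, sim$line_master)
  del <- infer_deletion_interval(arch)
  true_del <- c(cfg$side_five_len,
                nchar(sim$line_master$seq) - cfg$side_three_len)
  expect_lte(abs(del[1] - true_del[1]), 5)
  expect_lte(abs(del[2] - true_del[2]), 5)
  mh <- find_breakpoint_microhomology(sim$line_master, del)
  expect_true(cfg$microhomology_motif %in% mh$motif)
  # the 5' homology block terminates with the planted poly-C stretch
  five_end_region <- substr(sim$line_master$seq, cfg$side_five_len - 14,
                            cfg$side_five_len)
  expect_true(grepl("C{8,}", five_end_region))
})
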