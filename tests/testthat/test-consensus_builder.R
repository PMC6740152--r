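make_hits <- function(spans, scores, qlen = 100L) {
  n <- length(spans)
  hit_table(family = rep("f", n), seqid = rep("chr1", n),
            start = seq(0L, by = 1000L, length.out = n),
            end = seq(0L, by = 1000L, length.out = n) + 200L,
            strand = rep("+", n), score = as.integer(scores),
            evalue = rep(1e-20, n), pct_identity = rep(95, n),
            q_start = rep(0L, n), q_end = as.integer(spans),
            aligned_len = as.integer(spans), n_match = as.integer(spans),
            n_mismatch = rep(0L, n), n_gapcols = rep(0L, n))
}

test_that("the seed set is the top-scoring 50 full-length hits", {
  h <- make_hits(spans = rep(95L, 60), scores = 1:60)
  suppressMessages(sel <- select_full_length_hits(h, 100L, pipeline_config()))
  expect_equal(nrow(sel), 50L)
  expect_equal(sort(sel$score, decreasing = TRUE), 60:11) # highest scores kept

  # 89% of the query at frac = 0.90 is excluded; zero qualifying errors out
  h2 <- make_hits(spans = c(89L, 90L, 95L), scores = c(10L, 9L, 8L))
  suppressMessages(sel2 <- select_full_length_hits(h2, 100L, pipeline_config()))
  expect_equal(sort(sel2$q_end), c(90L, 95L))
  expect_error(select_full_length_hits(make_hits(80L, 1L), 100L,
                                       pipeline_config()),
               "lower full_length_frac")
})

test_that("5'-truncated copies are excluded from the seed set", {
  # 30 near-intact copies and 70 copies missing >= 20% of their 5' end:
  # only the former qualify as full-length at frac = 0.90
  set.seed(20)
  sim <- small_sim()
  master <- sim$line_master$seq
  L <- nchar(master)
  full <- replicate(30, mutate_copy(master, 0.05))
  trunc <- replicate(70, {
    cut <- sample(seq.int(ceiling(0.2 * L), floor(0.6 * L)), 1)
    substr(mutate_copy(master, 0.05), cut + 1L, L)
  })
  els <- sample(c(full, trunc))
  genome <- seq_record("chr1", paste(c(rbind(replicate(100, rand_dna(400)),
                                             els), rand_dna(400)),
                                     collapse = ""))
  cfg <- pipeline_config()
  hits <- search_genome(sim$line_master, genome, cfg, family = "LINE")
  suppressMessages(sel <- select_full_length_hits(hits, L, cfg))
  expect_equal(nrow(sel), 30L)
  expect_true(all(sel$q_end - sel$q_start >= 0.9 * L))
})

test_that("anchoring identical copies reproduces the reference as consensus", {
  set.seed(21)
  ref <- seq_record("ref", rand_dna(300))
  copies <- lapply(1:6, function(i) seq_record(paste0("c", i), ref$seq))
  prof <- anchor_align(copies, ref)
  expect_equal(prof$depth, 6L)
  expect_equal(colSums(prof$counts), rep(6L, 300))
  cons <- majority_consensus(prof)
  expect_equal(cons$seq, ref$seq)
})

test_that("an internal deletion shows up as gap counts in the profile", {
  set.seed(22)
  ref <- seq_record("ref", rand_dna(300))
  del <- seq_record("del", paste0(substr(ref$seq, 1, 150),
                                  substr(ref$seq, 161, 300)))
  prof <- anchor_align(list(seq_record("a", ref$seq), del), ref)
  expect_equal(sum(prof$counts["-", ]), 10L)
  expect_equal(which(prof$counts["-", ] == 1L), 151:160)
})

test_that("anchored profile consensus matches a directly stacked-column oracle", {
  # copies differ from the master by substitutions only, so the true
  # multiple alignment is the trivial column stacking: the oracle takes a
  # per-column majority over the raw copy strings
  set.seed(23)
  master <- rand_dna(200)
  copies <- lapply(1:5, function(i) mutate_copy(master, 0.06))
  mat <- do.call(rbind, strsplit(unlist(copies), ""))
  oracle <- paste(apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)] # ties resolved A<C<G<T by factor order
  }), collapse = "")
  prof <- anchor_align(lapply(seq_along(copies), function(i)
    seq_record(paste0("c", i), copies[[i]])),
    seq_record("ref", master))
  got <- suppressMessages(majority_consensus(prof))
  # local anchoring may trim a diverged terminal base or two; the interior
  # must agree with the global stacking oracle exactly
  expect_equal(substr(got$seq, 4, nchar(got$seq) - 3),
               substr(oracle, 4, nchar(oracle) - 3))
  expect_gte(nchar(got$seq), nchar(oracle) - 4L)
})

test_that("majority vote follows counts, tie order A<C<G<T, and drops gap-majority columns", {
  prof <- structure(list(counts = matrix(c(3L, 1L, 0L, 0L, 0L,   # A wins
                                           2L, 2L, 0L, 0L, 0L,   # A/C tie -> A
                                           0L, 0L, 1L, 0L, 3L,   # gap majority
                                           0L, 0L, 0L, 4L, 0L),  # T wins
                                         nrow = 5L,
                                         dimnames = list(c("A", "C", "G", "T", "-"),
                                                         NULL)),
                         depth = 4L, insertions_dropped = 0L,
                         reference = NULL),
                    class = "consensus_profile")
  withr::local_options(sidekit.log_level = "info")
  expect_message(cons <- majority_consensus(prof), "tied")
  expect_equal(cons$seq, "AAT")
  expect_error(majority_consensus(structure(list(counts = prof$counts,
                                                 depth = 1L),
                                            class = "consensus_profile")),
               "depth >= 2")
})

test_that("two-round consensus is a fixed point on an exact-copy genome and idempotent after convergence", {
  set.seed(24)
  seed <- seq_record("el", rand_dna(300))
  genome <- seq_record("chr1", paste(c(rbind(replicate(8, rand_dna(700)),
                                             seed$seq), rand_dna(700)),
                                     collapse = ""))
  res <- suppressMessages(iterate_consensus(genome, seed))
  expect_equal(res$consensus$seq, seed$seq)
  expect_gte(nrow(res$hits_round2), nrow(res$hits_round1))
  # a third round reproduces the round-2 consensus (hit set stabilised)
  h3 <- search_genome(res$consensus, genome)
  expect_equal(nrow(h3), nrow(res$hits_round2))
  prof3 <- anchor_align(extract_hit_seqs(h3, genome), res$consensus)
  cons3 <- suppressMessages(majority_consensus(prof3))
  expect_equal(cons3$seq, res$consensus$seq)
})

test_that("iterating from a diverged seed converges toward the master", {
  set.seed(25)
  master <- rand_dna(350)
  genome <- seq_record("chr1",
                       paste(c(rbind(replicate(30, rand_dna(500)),
                                     replicate(30, mutate_copy(master, 0.10))),
                               rand_dna(500)), collapse = ""))
  seed <- seq_record("seed", mutate_copy(master, 0.15))
  res <- suppressMessages(iterate_consensus(genome, seed))
  id_to <- function(q) {
    a <- local_align(q, master)
    percent_identity(a$a_aln, a$b_aln)
  }
  expect_gt(id_to(res$consensus$seq), id_to(seed$seq))
  expect_gte(id_to(res$consensus$seq), 99)
})

test_that("join_ends concatenates the element termini", {
  set.seed(26)
  el <- seq_record("el", rand_dna(3300))
  j <- join_ends(el, 300L, 300L)
  expect_equal(seq_record(j$id, j$seq)$seq,
               paste0(substr(el$seq, 1, 300), substr(el$seq, 3001, 3300)))
  expect_equal(j$id, "el_joined")
  expect_equal(nchar(j$seq), 600L)
  expect_equal(join_ends(el, 3300L, 0L)$seq, el$seq) # prefix identity
  expect_error(join_ends(el, 3000L, 400L), "must be <=")
})

test_that("a joined-ends query finds SIDE copies in a SIDE-only genome", {
  sim <- small_sim()
  tr <- sim$truth
  side_rows <- tr[tr$family == "SIDE" & !tr$fragmented, ][1:10, ]
  pieces <- vapply(seq_len(nrow(side_rows)), function(i)
    subseq0(sim$genome$seq, side_rows$start[i], side_rows$end[i], "+"),
    character(1))
  set.seed(27)
  genome <- seq_record("chr1", paste(c(rbind(replicate(10, rand_dna(800)),
                                             pieces), rand_dna(800)),
                                     collapse = ""))
  cfg <- pipeline_config()
  q <- join_ends(sim$line_master, 150L, 180L)
  h_joined <- search_genome(q, genome, cfg)
  expect_gte(nrow(h_joined), 10L)
  # every SIDE copy is recovered by the joined query, each hit covering a
  # substantial fraction of it, while hits of the full-length LINE query
  # never span more than a sliver of that query: as a probe for
  # internally deleted derivatives, only the joined form can yield
  # full-length-ish matches
  spans <- (h_joined$q_end - h_joined$q_start) / nchar(q$seq)
  expect_gte(median(spans), 0.35)
  h_full <- search_genome(sim$line_master, genome, cfg)
  expect_lt(max((h_full$q_end - h_full$q_start) / nchar(sim$line_master$seq)),
            0.2)
})

test_that("ORF validation passes a real ORF and fails stop-riddled or deleted sequences", {
  set.seed(28)
  sense <- setdiff(apply(expand.grid(b1 = c("A", "C", "G", "T"),
                                     b2 = c("A", "C", "G", "T"),
                                     b3 = c("A", "C", "G", "T")),
                         1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA", "ATG"))
  orf <- paste0("ATG", paste(sample(sense, 299, replace = TRUE), collapse = ""),
                "TAA")
  expect_equal(nchar(orf), 903L)
  rep <- validate_orf(seq_record("x", paste0(rand_dna(50), orf, rand_dna(47))),
                      min_aa = 300L)
  expect_true(rep$passes)
  expect_equal(rep$length_aa, 300L)
  expect_equal((rep$best_orf_end - rep$best_orf_start) %% 3L, 0L)

  allstop <- seq_record("s", paste(rep("TAA", 400), collapse = ""))
  expect_false(validate_orf(allstop, min_aa = 100L)$passes)

  sim <- small_sim()
  expect_true(validate_orf(sim$line_master, min_aa = 300L)$passes)
  # the internal deletion destroys the ORF (SIDE master is ~360 bp)
  expect_false(validate_orf(sim$side_master, min_aa = 100L)$passes)
})
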