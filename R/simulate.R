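#' Simulation configuration
#'
#' The stated world the ground-truth generator emulates: a genome seeded
#' with a CR1-like LINE family (~3.3 kb: short 5'-UTR, one long ORF with
#' endonuclease/RT-like coding capacity, 3'-UTR, poly-A tail) and a SIDE
#' family formed from it by internal deletion between short direct
#' repeats, retaining the LINE's 5' and 3' ends around a non-homologous
#' variable region (~360 bp with the defaults, inside the 263-386 bp
#' range real SIDE families span). Copies are aged under a Jukes-Cantor
#' clock around one or more replication-burst divergences, LINE copies
#' are 5'-truncated with geometric depth (the CR1 hallmark), insertions
#' carry target-site duplications, and a fraction of copies is split by
#' an unrelated nested insertion.
#'
#' @param genome_len total genome length (bp); planted copies live inside
#'   it.
#' @param gc background GC content (lepidopteran-like default 0.375).
#' @param n_line,n_side planted copy numbers.
#' @param burst_d data frame with columns `mean`, `weight`: divergence
#'   burst mixture (weights sum to 1).
#' @param d_sd per-burst divergence standard deviation (truncated at 0).
#' @param p_truncate_5prime probability a LINE copy is 5'-truncated.
#' @param truncation_geometric_p geometric parameter of truncation depth
#'   (mean ~ 1/p bp).
#' @param p_fragment probability a copy is split by a nested unrelated
#'   insertion.
#' @param frag_insert_len length of the nested insertion (bp).
#' @param tsd_len_range `c(min, max)` target-site duplication length.
#' @param polya_len_range `c(min, max)` per-copy poly-A tail length.
#' @param side_five_len,side_three_len LINE 5'/3' end lengths retained in
#'   the SIDE (bp).
#' @param variable_region_len length of the SIDE's non-homologous central
#'   region (bp).
#' @param microhomology_motif direct repeat planted at the two deletion
#'   flanks of the LINE master.
#' @param min_copy_gap minimum background gap between planted copies (bp).
#' @param rng_seed seed; identical configs give byte-identical output.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(genome_len = 2e6L, gc = 0.375,
                              n_line = 150L, n_side = 300L,
                              burst_d = data.frame(mean = 0.05, weight = 1),
                              d_sd = 0.01,
                              p_truncate_5prime = 0.5,
                              truncation_geometric_p = 0.002,
                              p_fragment = 0.10,
                              frag_insert_len = 300L,
                              tsd_len_range = c(4L, 8L),
                              polya_len_range = c(8L, 18L),
                              side_five_len = 120L,
                              side_three_len = 140L,
                              variable_region_len = 100L,
                              microhomology_motif = "AGGCC",
                              min_copy_gap = 600L,
                              rng_seed = 1L) {
  stopifnot(n_line >= 0, n_side >= 0, genome_len > 0, gc > 0, gc < 1,
            abs(sum(burst_d$weight) - 1) < 1e-9,
            all(burst_d$mean >= 0), d_sd >= 0,
            p_truncate_5prime >= 0, p_truncate_5prime <= 1,
            truncation_geometric_p > 0, truncation_geometric_p < 1,
            p_fragment >= 0, p_fragment <= 1,
            side_five_len > nchar(microhomology_motif),
            side_three_len > 0, variable_region_len >= 0,
            grepl("^[ACGT]+$", microhomology_motif))
  structure(list(genome_len = as.integer(genome_len), gc = gc,
                 n_line = as.integer(n_line), n_side = as.integer(n_side),
                 burst_d = burst_d, d_sd = d_sd,
                 p_truncate_5prime = p_truncate_5prime,
                 truncation_geometric_p = truncation_geometric_p,
                 p_fragment = p_fragment,
                 frag_insert_len = as.integer(frag_insert_len),
                 tsd_len_range = as.integer(tsd_len_range),
                 polya_len_range = as.integer(polya_len_range),
                 side_five_len = as.integer(side_five_len),
                 side_three_len = as.integer(side_three_len),
                 variable_region_len = as.integer(variable_region_len),
                 microhomology_motif = microhomology_motif,
                 min_copy_gap = as.integer(min_copy_gap),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Build the LINE master sequence
#'
#' A ~3.3 kb CR1-like element: random 5'-UTR (100 bp), a single long ORF
#' (ATG ... stop, 1019 aa, no internal stops), random 3'-UTR (100 bp) and
#' an 18 bp poly-A tail. The microhomology motif is planted at the two
#' future deletion flanks (ending exactly at `side_five_len` and at
#' `length - side_three_len`), with a poly-C stretch terminating the
#' future 5' homology block immediately upstream of the first copy. Any
#' stop codon such planting creates inside the ORF is repaired at an
#' unprotected base. Consumes the R RNG; [plant_copies()] seeds it.
#'
#' @param config a [simulation_config()].
#' @return a [seq_record()] with id `"LINE_master"`.
#' @export
make_master_line <- function(config = simulation_config()) {
  utr5 <- 100L; n_codons <- 1018L; utr3 <- 100L; polya <- 18L
  orf_start <- utr5
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1L, paste,
                         collapse = ""),
                   c("TAA", "TAG", "TGA", "ATG"))
  orf <- paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                             collapse = ""), "TAA")
  s <- paste0(rand_dna(utr5, config$gc), orf, rand_dna(utr3, config$gc),
              strrep("A", polya))
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  motif <- strsplit(config$microhomology_motif, "")[[1]]
  k <- length(motif)
  m1 <- config$side_five_len - k      # first copy ends at side_five_len
  m2 <- L - config$side_three_len - k # second copy ends at the deletion end
  stopifnot(m1 > 9L, m2 > m1 + k, m2 + k <= L)
  protected <- logical(L)
  v[(m1 + 1L):(m1 + k)] <- motif
  v[(m2 + 1L):(m2 + k)] <- motif
  protected[c((m1 + 1L):(m1 + k), (m2 + 1L):(m2 + k))] <- TRUE
  cpos <- (m1 - 9L):m1 # 9 bp poly-C terminating the 5' homology block
  v[cpos] <- "C"
  protected[cpos] <- TRUE
  # repair any internal stop codon the planting created
  orf_end <- orf_start + 3L * (n_codons + 2L)
  for (cs in seq.int(orf_start + 3L, orf_end - 6L, by = 3L)) {
    codon <- paste(v[(cs + 1L):(cs + 3L)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) {
      free <- which(!protected[(cs + 1L):(cs + 3L)])
      stopifnot(length(free) > 0L)
      v[cs + free[1L]] <- "C"
    }
  }
  seq_record("LINE_master", paste(v, collapse = ""))
}

#' Derive the SIDE master by internal deletion
#'
#' Template-jump (copy-choice) deletion between the two planted direct
#' repeats: the product keeps the LINE's first `side_five_len` bases
#' (ending in one retained motif copy), gains a random non-homologous
#' variable region, and resumes at the deletion end (the second motif
#' copy is lost with the deleted interval), keeping the LINE's last
#' `side_three_len` bases including the poly-A tail.
#'
#' @param master the LINE master [seq_record()].
#' @param config a [simulation_config()].
#' @return a [seq_record()] with id `"SIDE_master"`.
#' @export
derive_side <- function(master, config = simulation_config()) {
  L <- seq_length(master)
  stopifnot(config$side_five_len + config$side_three_len < L)
  seq_record("SIDE_master",
             paste0(substr(master$seq, 1L, config$side_five_len),
                    if (config$variable_region_len > 0)
                      rand_dna(config$variable_region_len, config$gc) else "",
                    substr(master$seq, L - config$side_three_len + 1L, L)))
}

#' Age a copy under a Jukes-Cantor clock
#'
#' Each site is substituted independently with probability
#' `p_sub = (3/4)(1 - exp(-4 d / 3))` to a uniformly chosen different
#' base -- the generative inverse of the Jukes-Cantor correction, so the
#' expected observed mismatch fraction against the master is exactly
#' `p_sub`.
#'
#' @param seq a [seq_record()] or DNA string.
#' @param target_d target divergence (substitutions/site, >= 0).
#' @return same type as `seq`, mutated.
#' @export
mutate_copy <- function(seq, target_d) {
  stopifnot(target_d >= 0)
  s <- if (inherits(seq, "seq_record")) seq$seq else seq
  if (target_d == 0) return(seq)
  p_sub <- 0.75 * (1 - exp(-4 * target_d / 3))
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < p_sub & v %in% c("A", "C", "G", "T"))
  if (length(hit) > 0L) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    v[hit] <- vapply(v[hit], function(b)
      alt[[b]][sample.int(3L, 1L)], character(1))
  }
  out <- paste(v, collapse = "")
  if (inherits(seq, "seq_record")) seq_record(seq$id, out, seq$description)
  else out
}

#' 5'-truncate a copy
#'
#' With probability `p_truncate_5prime`, removes a geometrically
#' distributed prefix (mean ~ `1/truncation_geometric_p` bp, capped at
#' 90% of the copy length) -- the CR1-style abortive reverse
#' transcription signature.
#'
#' @param seq DNA string.
#' @param config a [simulation_config()].
#' @return list with `seq` and `truncated_bp`.
#' @export
truncate_5prime <- function(seq, config = simulation_config()) {
  L <- nchar(seq)
  if (config$p_truncate_5prime <= 0 ||
      runif(1) >= config$p_truncate_5prime)
    return(list(seq = seq, truncated_bp = 0L))
  tr <- min(stats::rgeom(1L, config$truncation_geometric_p),
            as.integer(floor(0.9 * L)))
  list(seq = if (tr > 0L) substr(seq, tr + 1L, L) else seq,
       truncated_bp = as.integer(tr))
}

#' Plant element copies into a synthetic genome
#'
#' Assembles the full scenario with a ground-truth record per copy:
#' background i.i.d. sequence at the configured GC, LINE and SIDE copies
#' in shuffled order and random strand, per-copy divergence drawn from
#' the burst mixture (normal with sd `d_sd`, floored at 0), optional 5'
#' truncation (LINE only), per-copy poly-A tail length, a target-site
#' duplication of random length duplicated at each insertion site, and
#' nested unrelated insertions splitting a fraction of copies. Copies are
#' separated by at least `min_copy_gap` bp of background and never
#' nested (except the deliberate splitting insertions). Fully
#' reproducible from `rng_seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (a `seq_record`, id `"chr1"`),
#'   `truth` (data frame: `copy_id`, `family`, `start`, `end` -- element
#'   span incl. any nested insertion, excluding the duplications --,
#'   `strand`, `true_d`, `truncated_bp`, `tsd`, `tsd_len`, `fragmented`),
#'   `line_master`, `side_master`, `config`.
#' @export
plant_copies <- function(config = simulation_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$rng_seed)

  line_master <- make_master_line(config)
  side_master <- derive_side(line_master, config)
  n <- config$n_line + config$n_side
  fams <- sample(c(rep("LINE", config$n_line), rep("SIDE", config$n_side)))

  pieces <- character(0)
  rows <- list()
  planted <- 0L
  cursor <- 0L
  specs <- vector("list", n)
  if (n > 0L) {
    for (i in seq_len(n)) {
      fam <- fams[i]
      base <- if (fam == "LINE") line_master$seq else side_master$seq
      # per-copy poly-A tail length
      tail_len <- sample(seq.int(config$polya_len_range[1],
                                 config$polya_len_range[2]), 1L)
      core <- sub("A+$", "", base)
      el <- paste0(core, strrep("A", tail_len))
      # age
      comp <- sample.int(nrow(config$burst_d), 1L,
                         prob = config$burst_d$weight)
      d_i <- max(0, rnorm(1L, config$burst_d$mean[comp], config$d_sd))
      el <- mutate_copy(el, d_i)
      # truncate (LINE only: the CR1 hallmark)
      trunc <- 0L
      if (fam == "LINE") {
        t5 <- truncate_5prime(el, config)
        el <- t5$seq; trunc <- t5$truncated_bp
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") el <- revcomp(el)
      # nested fragmentation insertion
      fragmented <- FALSE
      if (config$p_fragment > 0 && nchar(el) >= 300L &&
          runif(1) < config$p_fragment) {
        at <- sample.int(nchar(el) - 200L, 1L) + 100L
        el <- paste0(substr(el, 1L, at),
                     rand_dna(config$frag_insert_len, config$gc),
                     substr(el, at + 1L, nchar(el)))
        fragmented <- TRUE
      }
      tsd_len <- sample(seq.int(config$tsd_len_range[1],
                                config$tsd_len_range[2]), 1L)
      tsd <- rand_dna(tsd_len, config$gc)
      specs[[i]] <- list(fam = fam, el = el, tsd = tsd, tsd_len = tsd_len,
                         d = d_i, trunc = trunc, strand = strand,
                         fragmented = fragmented)
      planted <- planted + nchar(el) + 2L * tsd_len
    }
  }
  if (planted >= config$genome_len / 2)
    stop("infeasible packing: planted ", planted, " bp exceeds half of genome_len")
  background <- config$genome_len - planted
  if (background < (n + 1L) * config$min_copy_gap)
    stop("infeasible packing: not enough background for inter-copy gaps")
  extra <- background - (n + 1L) * config$min_copy_gap
  gap_extra <- as.vector(stats::rmultinom(1L, extra, rep(1, n + 1L)))
  gaps <- config$min_copy_gap + gap_extra

  for (i in seq_len(n + 1L)) {
    pieces <- c(pieces, rand_dna(gaps[i], config$gc))
    cursor <- cursor + gaps[i]
    if (i <= n) {
      sp <- specs[[i]]
      pieces <- c(pieces, sp$tsd)
      cursor <- cursor + sp$tsd_len
      el_start <- cursor
      pieces <- c(pieces, sp$el)
      cursor <- cursor + nchar(sp$el)
      pieces <- c(pieces, sp$tsd)
      cursor <- cursor + sp$tsd_len
      rows[[i]] <- data.frame(copy_id = i, family = sp$fam,
                              start = el_start, end = el_start + nchar(sp$el),
                              strand = sp$strand, true_d = sp$d,
                              truncated_bp = sp$trunc, tsd = sp$tsd,
                              tsd_len = sp$tsd_len, fragmented = sp$fragmented,
                              stringsAsFactors = FALSE)
    }
  }
  truth <- if (n > 0L) do.call(rbind, rows) else
    data.frame(copy_id = integer(), family = character(), start = integer(),
               end = integer(), strand = character(), true_d = numeric(),
               truncated_bp = integer(), tsd = character(),
               tsd_len = integer(), fragmented = logical(),
               stringsAsFactors = FALSE)
  genome <- seq_record("chr1", paste(pieces, collapse = ""))
  side_log("plant_copies: %d LINE + %d SIDE copies in %d bp (seed %d)",
           config$n_line, config$n_side, seq_length(genome), config$rng_seed)
  list(genome = genome, truth = truth, line_master = line_master,
       side_master = side_master, config = config)
}

#' Write the ground truth as a BED6+ TSV
#'
#' BED6 columns plus `true_d`, `truncated_bp`, `tsd`, `fragmented`.
#'
#' @param truth the `truth` frame from [plant_copies()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(c("#seqid", "start", "end", "name", "score", "strand",
                     "true_d", "truncated_bp", "tsd", "fragmented"),
                   collapse = "\t"), con)
  if (nrow(truth) > 0L)
    writeLines(sprintf("chr1\t%d\t%d\t%s#%d\t0\t%s\t%.6f\t%d\t%s\t%s",
                       truth$start, truth$end, truth$family, truth$copy_id,
                       truth$strand, truth$true_d, truth$truncated_bp,
                       truth$tsd, ifelse(truth$fragmented, "TRUE", "FALSE")),
               con)
  invisible(path)
}
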