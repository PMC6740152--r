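#' Pipeline configuration
#'
#' All thresholds the pipeline applies, with the field's standard defaults:
#' a `1e-10` e-value cut-off for DNA-level searches and `1e-5` for the
#' protein-level (RT-domain) search stage, seed consensus built from the
#' first 50 full-length hits, "full-length" meaning a hit spanning at least
#' 90% of the query, fragments shorter than 160 bp excluded before copy
#' counting (250 bp for genomes where SIDE/LINE cross-masking is worse),
#' and divergence landscapes binned at 0.01 substitutions/site.
#'
#' @param evalue_dna e-value cut-off for DNA searches (hits with
#'   `evalue <= evalue_dna` are significant).
#' @param evalue_protein e-value cut-off for the protein-level stage.
#' @param n_seed_hits number of top full-length hits seeding the first
#'   consensus round.
#' @param full_length_frac fraction of the query a hit must span to count
#'   as full-length, in (0, 1].
#' @param min_fragment_len fragments with genome span below this are
#'   excluded before merging/counting (bp).
#' @param merge_max_gap base genomic gap allowed when chaining collinear
#'   fragments of one copy (bp); the consensus-coordinate gap is added on
#'   top (see [merge_adjacent()]).
#' @param landscape_bin_width divergence bin width for activity-through-age
#'   tables.
#' @param tsd_search_window flank width inspected for target-site
#'   duplications (bp).
#' @param rng_seed seed for every stochastic step.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(evalue_dna = 1e-10,
                            evalue_protein = 1e-5,
                            n_seed_hits = 50L,
                            full_length_frac = 0.90,
                            min_fragment_len = 160L,
                            merge_max_gap = 500L,
                            landscape_bin_width = 0.01,
                            tsd_search_window = 20L,
                            rng_seed = 1L) {
  cfg <- list(evalue_dna = as.numeric(evalue_dna),
              evalue_protein = as.numeric(evalue_protein),
              n_seed_hits = as.integer(n_seed_hits),
              full_length_frac = as.numeric(full_length_frac),
              min_fragment_len = as.integer(min_fragment_len),
              merge_max_gap = as.integer(merge_max_gap),
              landscape_bin_width = as.numeric(landscape_bin_width),
              tsd_search_window = as.integer(tsd_search_window),
              rng_seed = as.integer(rng_seed))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("evalue_dna", "evalue_protein", "n_seed_hits", "min_fragment_len",
           "merge_max_gap", "landscape_bin_width", "tsd_search_window")
  for (k in pos) {
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config field '", k, "' must be > 0 (got ", cfg[[k]], ")")
  }
  if (!is.finite(cfg$full_length_frac) ||
      cfg$full_length_frac <= 0 || cfg$full_length_frac > 1)
    stop("config field 'full_length_frac' must lie in (0, 1]")
  invisible(cfg)
}

#' Load a key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Unset keys take the [pipeline_config()] defaults; entries in `overrides`
#' (e.g. from a command line) take precedence over the file. The resolved
#' configuration is logged at startup.
#'
#' @param path config file, or `NULL` for defaults only.
#' @param overrides named list overriding file values.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  values <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[=:]\\s*(.+)$", ln))[[1]]
      if (length(m) != 3L) stop("cannot parse config line: '", ln, "'")
      values[[m[2]]] <- m[3]
    }
  }
  for (k in names(overrides)) values[[k]] <- overrides[[k]]
  valid <- names(formals(pipeline_config))
  unknown <- setdiff(names(values), valid)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(valid, collapse = ", "))
  args <- lapply(values, function(v) if (is.character(v)) as.numeric(v) else v)
  cfg <- do.call(pipeline_config, args)
  side_log("config: %s",
           paste(sprintf("%s=%s", names(cfg), unlist(lapply(cfg, format))),
                 collapse = " "))
  cfg
}
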