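# Shared fixtures: configurations, a naive mapping oracle, and memoised
# pipeline runs so expensive simulations are computed once per session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small, fast study conditions for unit-level recovery tests
small_config <- function(seed = 42L, ...) {
  sim_config(seed = seed, n_background_reads = 3000L, cds_codons = 60L,
             n_cds = 8L, spacer_len = 60L,
             aaa_counts = c(0L, 2L, 4L, 6L, 8L, 10L, 12L, 14L),
             aag_counts = c(14L, 12L, 10L, 8L, 6L, 4L, 2L, 0L), ...)
}

# run trim -> count -> fold change for a built simulation
run_counting <- function(built, cfg) {
  tp <- trim_params(cfg$adapter, cfg$umi_len)
  ind <- simulate_reads(built$reference, built$truth, cfg, "induced")
  un <- simulate_reads(built$reference, built$truth, cfg, "uninduced")
  ti <- trim_reads(ind$reads, tp)
  tu <- trim_reads(un$reads, tp)
  idx <- build_index(built$reference)
  list(built = built, cfg = cfg, raw = list(induced = ind, uninduced = un),
       trimmed = list(induced = ti, uninduced = tu),
       fc = fold_change_track(map_and_count(idx, ti$reads, "induced"),
                              map_and_count(idx, tu$reads, "uninduced")))
}

small_pipeline <- function() {
  memo("small_pipeline", {
    cfg <- small_config()
    run_counting(build_reference(cfg), cfg)
  })
}

default_pipeline <- function() {
  memo("default_pipeline", {
    cfg <- sim_config(seed = 1L)
    run_counting(build_reference(cfg), cfg)
  })
}

# hand-built count track: the package's container, filled directly so
# threshold and pseudocount rules can be checked against hand arithmetic
make_track <- function(counts_plus, total, condition = "",
                       counts_minus = NULL, contig = "c1") {
  L <- length(counts_plus)
  if (is.null(counts_minus)) counts_minus <- integer(L)
  counts <- list(list("+" = as.integer(counts_plus),
                      "-" = as.integer(counts_minus)))
  names(counts) <- contig
  structure(list(condition = condition, counts = counts,
                 total_mapped = as.integer(total), n_multi = 0L,
                 n_unmapped = 0L,
                 contig_lengths = stats::setNames(L, contig)),
            class = "end_count_track")
}

# independent mapping oracle: all-offsets string comparison on both strands
naive_map <- function(genome, read) {
  k <- nchar(read)
  L <- nchar(genome)
  loci <- list()
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  for (i in seq_len(L - k + 1L)) {
    w <- substr(genome, i, i + k - 1L)
    if (w == read) loci[[length(loci) + 1L]] <- list(pos = i, strand = "+")
    if (w == rc) {
      loci[[length(loci) + 1L]] <- list(pos = i + k - 1L, strand = "-")
    }
  }
  loci
}

random_genome <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
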