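#' Simulation configuration
#'
#' Bundles every tunable of the forward simulator of the toxin mechanism:
#' anticodon cleavage of the two lysine tRNA isoacceptors, ribosome stalling
#' at Lys codons, secondary mRNA cleavage upstream of the stalled ribosome,
#' and codon-dependent suppression of protein synthesis. The single `seed`
#' fully determines every output (reference, read libraries, spectral
#' counts).
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_background_reads Background 5'-OH reads per condition. These
#'   emulate ordinary RNA turnover: uniform 5' starts on feature sense
#'   strands, plus a small intergenic fraction on both strands.
#' @param cleavage_depth Expected reads per planted toxin cut (Poisson mean).
#' @param stall_depth Expected reads per chosen stall-associated cut
#'   (Poisson mean; identical for AAA and AAG sites so detection is
#'   class-symmetric).
#' @param stall_weight_AAA,stall_weight_AAG Nonnegative site-selection
#'   weights: each Lys codon hosts a secondary cut with probability
#'   proportional to the weight of its codon class (scaled so the larger
#'   weight gives probability 1).
#' @param footprint_offset Nucleotides from a cut's 5'-OH base to the first
#'   base of the stalled-ribosome A-site codon, counting the 5'-OH base as
#'   position 1. Default 15: the codon begins at the 15th nucleotide of the
#'   3' fragment.
#' @param umi_len Random-nucleotide UMI length appended to the adapter.
#' @param adapter 5' adapter constant region (DNA alphabet) preceding the
#'   UMI in every read.
#' @param read_len_range Inclusive range of post-adapter read lengths
#'   (UMI + genomic insert), drawn uniformly per read.
#' @param n_cds Number of protein-coding genes.
#' @param cds_codons Codons per CDS (including start and stop).
#' @param aaa_counts,aag_counts Optional integer vectors (length `n_cds`) of
#'   planted AAA / AAG codon counts per gene. Default: values spanning 0-30,
#'   independently permuted so the two counts are uncorrelated.
#' @param aaa_effect Per-AAA-codon log2 change in simulated protein
#'   synthesis upon induction (<= 0).
#' @param n_replicates Spectral-count replicates per condition.
#' @param spacer_len Intergenic spacer length between genes.
#' @param intergenic_bg_frac Fraction of background reads drawn from random
#'   genome positions on either strand rather than from transcripts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_background_reads = 20000L,
                       cleavage_depth = 100,
                       stall_depth = 40,
                       stall_weight_AAA = 3,
                       stall_weight_AAG = 1,
                       footprint_offset = 15L,
                       umi_len = 6L,
                       adapter = "GTTCAGAGTTCTACAGTCCGACGATC",
                       read_len_range = c(25L, 45L),
                       n_cds = 40L,
                       cds_codons = 200L,
                       aaa_counts = NULL,
                       aag_counts = NULL,
                       aaa_effect = -0.2,
                       n_replicates = 3L,
                       spacer_len = 100L,
                       intergenic_bg_frac = 0.1) {
  stopifnot(footprint_offset >= 1L,
            stall_weight_AAA >= 0, stall_weight_AAG >= 0,
            umi_len >= 1L, spacer_len >= 50L,
            length(read_len_range) == 2L,
            read_len_range[1] <= read_len_range[2],
            aaa_effect <= 0, grepl("^[ACGT]+$", adapter))
  if (stall_weight_AAA == 0 && stall_weight_AAG == 0) {
    stop("stall weights must not both be 0")
  }
  structure(list(seed = as.integer(seed),
                 n_background_reads = as.integer(n_background_reads),
                 cleavage_depth = cleavage_depth,
                 stall_depth = stall_depth,
                 stall_weight_AAA = stall_weight_AAA,
                 stall_weight_AAG = stall_weight_AAG,
                 footprint_offset = as.integer(footprint_offset),
                 umi_len = as.integer(umi_len),
                 adapter = adapter,
                 read_len_range = as.integer(read_len_range),
                 n_cds = as.integer(n_cds),
                 cds_codons = as.integer(cds_codons),
                 aaa_counts = aaa_counts,
                 aag_counts = aag_counts,
                 aaa_effect = aaa_effect,
                 n_replicates = as.integer(n_replicates),
                 spacer_len = as.integer(spacer_len),
                 intergenic_bg_frac = intergenic_bg_frac),
            class = "sim_config")
}

# GC-rich random DNA (p(C)=p(G)=0.325): emulates a high-GC actinobacterial
# genome so AT-rich motifs stay rare outside planted sites.
random_dna <- function(n, alphabet = c("A", "C", "G", "T"),
                       prob = c(0.175, 0.325, 0.325, 0.175)) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# 46 standard anticodons (including exactly TTT and CTT, the two Lys
# isoacceptors) plus the selenocysteine anticodon TCA. Deterministic
# synthetic complement mirroring the size of a real 47-gene tRNA set.
anticodon_set <- function() {
  codons <- apply(expand.grid(B1 = c("T", "C", "A", "G"),
                              B2 = c("T", "C", "A", "G"),
                              B3 = c("T", "C", "A", "G")), 1L, paste,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  anti <- sort(revcomp(sense))
  others <- setdiff(anti, c("TTT", "CTT"))
  std <- c("TTT", "CTT", others[seq_len(44L)])
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val")
  aa <- unname(aa3[as.character(Biostrings::GENETIC_CODE[revcomp(std)])])
  data.frame(anticodon = c(std, "TCA"),
             aa = c(aa, "U"),
             sec = c(rep(FALSE, 46L), TRUE),
             stringsAsFactors = FALSE)
}

# Filler codons over {C,G,T} only (stop TGA excluded): no A anywhere, so
# every AAA/AAG trimer in a CDS, in or out of frame, is a planted Lys codon.
filler_codons <- function() {
  pool <- apply(expand.grid(B1 = c("C", "G", "T"),
                            B2 = c("C", "G", "T"),
                            B3 = c("C", "G", "T")), 1L, paste, collapse = "")
  pool <- setdiff(pool, "TGA")
  w <- vapply(strsplit(pool, ""), function(b) {
    prod(ifelse(b %in% c("C", "G"), 0.4, 0.2))
  }, numeric(1))
  list(pool = pool, prob = w / sum(w))
}

#' Build a synthetic reference genome with planted ground truth
#'
#' One GC-rich contig carrying 47 tRNA genes (46 standard anticodons plus
#' selenocysteine; exactly two lysine isoacceptors with anticodons TTT and
#' CTT in gene orientation, occupying mature positions 34-36) and `n_cds`
#' protein-coding genes of controlled AAA/AAG codon content, alternating
#' strands, separated by spacers. The ground-truth skeleton records the
#' toxin cut between anticodon bases 2 and 3 of each Lys tRNA and every
#' candidate secondary-cleavage site `footprint_offset` nt 5' of a planted
#' Lys codon.
#'
#' @param config A [sim_config()].
#' @return List with elements `reference` ([as_reference()] object) and
#'   `truth` (list of `sites` and `proteins` data.frames).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_cds < 4L) stop("n_cds must be at least 4")
  set.seed(config$seed)

  trna_len <- 76L
  anti <- anticodon_set()
  fill <- filler_codons()

  aaa <- config$aaa_counts
  aag <- config$aag_counts
  if (is.null(aaa)) {
    aaa <- sample(round(seq(0, 30, length.out = config$n_cds)))
  }
  if (is.null(aag)) {
    aag <- sample(round(seq(0, 30, length.out = config$n_cds)))
  }
  stopifnot(length(aaa) == config$n_cds, length(aag) == config$n_cds,
            all(aaa >= 0), all(aag >= 0))
  # Lys codons sit on alternating codon slots >= 9: cuts at any footprint
  # offset <= 24 stay strictly inside the CDS, and no AA run spans two
  # planted codons.
  slot_grid <- seq(9L, config$cds_codons - 2L, by = 2L)
  if (max(aaa + aag) > length(slot_grid)) {
    stop("cds_codons too small for the requested AAA+AAG codon counts")
  }

  parts <- character(0)
  pos <- 1L
  feats <- list()
  sites <- list()
  add_spacer <- function() {
    sp <- random_dna(config$spacer_len)
    parts[[length(parts) + 1L]] <<- sp
    pos <<- pos + config$spacer_len
  }

  add_spacer()
  for (i in seq_len(47L)) {
    gene <- random_dna(trna_len)
    substr(gene, 34L, 36L) <- anti$anticodon[i]
    strand <- if (i %% 2L == 1L) "+" else "-"
    start <- pos
    end <- pos + trna_len - 1L
    id <- if (anti$sec[i]) "tRNA-SeC-TCA" else {
      paste0("tRNA-", anti$aa[i], "-", anti$anticodon[i])
    }
    feats[[length(feats) + 1L]] <- data.frame(
      id = id, contig = "synth_chr", start = start, end = end,
      strand = strand, kind = "tRNA", stringsAsFactors = FALSE)
    parts[[length(parts) + 1L]] <- if (strand == "+") gene else revcomp(gene)
    pos <- end + 1L
    if (anti$anticodon[i] %in% c("TTT", "CTT")) {
      # cut between anticodon bases 2 and 3: 5'-OH at mature position 36
      gpos <- if (strand == "+") start + 35L else end - 35L
      sites[[length(sites) + 1L]] <- data.frame(
        contig = "synth_chr", pos = gpos, strand = strand, class = "mazf",
        feature_id = id, codon_class = NA_character_,
        codon_offset = NA_integer_, stringsAsFactors = FALSE)
    }
    add_spacer()
  }

  proteins <- data.frame(protein_id = sprintf("cds_%03d", seq_len(config$n_cds)),
                         aaa_count = as.integer(aaa),
                         aag_count = as.integer(aag),
                         stringsAsFactors = FALSE)
  for (i in seq_len(config$n_cds)) {
    n_fill <- config$cds_codons - 2L
    codons <- c("ATG",
                sample(fill$pool, n_fill, replace = TRUE, prob = fill$prob),
                "TGA")
    n_lys <- aaa[i] + aag[i]
    if (n_lys > 0L) {
      slots <- sample(slot_grid, n_lys)
      codons[slots] <- c(rep("AAA", aaa[i]), rep("AAG", aag[i]))
    } else {
      slots <- integer(0)
    }
    gene <- paste(codons, collapse = "")
    strand <- if (i %% 2L == 1L) "+" else "-"
    start <- pos
    end <- pos + nchar(gene) - 1L
    id <- proteins$protein_id[i]
    feats[[length(feats) + 1L]] <- data.frame(
      id = id, contig = "synth_chr", start = start, end = end,
      strand = strand, kind = "CDS", stringsAsFactors = FALSE)
    parts[[length(parts) + 1L]] <- if (strand == "+") gene else revcomp(gene)
    pos <- end + 1L
    if (n_lys > 0L) {
      codon_start <- (slots - 1L) * 3L + 1L         # in-gene, 1-based
      frag_pos <- codon_start - config$footprint_offset + 1L
      gpos <- if (strand == "+") start + frag_pos - 1L else end - frag_pos + 1L
      sites[[length(sites) + 1L]] <- data.frame(
        contig = "synth_chr", pos = gpos, strand = strand, class = "stall",
        feature_id = id,
        codon_class = c(rep("AAA", aaa[i]), rep("AAG", aag[i])),
        codon_offset = rep(config$footprint_offset, n_lys),
        stringsAsFactors = FALSE)
    }
    add_spacer()
  }

  genome <- paste(parts, collapse = "")
  names(genome) <- "synth_chr"
  ref <- as_reference(genome, do.call(rbind, feats))
  truth <- list(sites = do.call(rbind, sites), proteins = proteins)
  list(reference = ref, truth = truth)
}

#' Simulate a 5'-OH-selected read library
#'
#' Uninduced libraries contain background reads only. Induced libraries add
#' Poisson(`cleavage_depth`) reads at each planted toxin cut and
#' Poisson(`stall_depth`) reads at each *chosen* stall site, where a Lys
#' codon's site is chosen with probability proportional to its class weight
#' (the larger weight scaled to 1). Every read is
#' `adapter + UMI + genomic sense sequence from the cut's 5'-OH base`, with
#' post-adapter length uniform in `read_len_range` and constant quality.
#'
#' @param ref Reference from [build_reference()].
#' @param truth Ground-truth skeleton from [build_reference()].
#' @param config The [sim_config()] used to build the reference.
#' @param condition `"induced"` or `"uninduced"`.
#' @return List with `reads` (data.frame `id`, `seq`, `qual`) and `sites`
#'   (realized planted sites with read counts; empty for uninduced).
#' @export
simulate_reads <- function(ref, truth, config,
                           condition = c("induced", "uninduced")) {
  condition <- match.arg(condition)
  set.seed(config$seed + if (condition == "induced") 101L else 202L)

  genome <- ref$seq[[1]]
  contig <- names(ref$seq)[1]
  glen_total <- nchar(genome)
  rcgenome <- revcomp(genome)
  feats <- ref$features

  pos <- integer(0); strand <- character(0); cls <- character(0)

  n_bg <- config$n_background_reads
  if (n_bg > 0L) {
    inter <- stats::runif(n_bg) < config$intergenic_bg_frac
    n_tx <- sum(!inter)
    flen <- feats$end - feats$start + 1L
    fidx <- sample.int(nrow(feats), n_tx, replace = TRUE, prob = flen)
    off <- floor(stats::runif(n_tx) * flen[fidx]) + 1L
    tx_pos <- ifelse(feats$strand[fidx] == "+",
                     feats$start[fidx] + off - 1L,
                     feats$end[fidx] - off + 1L)
    tx_strand <- feats$strand[fidx]
    n_int <- sum(inter)
    int_pos <- sample.int(glen_total, n_int, replace = TRUE)
    int_strand <- sample(c("+", "-"), n_int, replace = TRUE)
    pos <- c(tx_pos, int_pos)
    strand <- c(tx_strand, int_strand)
    cls <- rep(c("background", "background"), c(n_tx, n_int))
  }

  realized <- truth$sites[0, ]
  if (condition == "induced" && nrow(truth$sites) > 0L) {
    s <- truth$sites
    wmax <- max(config$stall_weight_AAA, config$stall_weight_AAG)
    p_sel <- ifelse(s$class == "mazf", 1,
                    ifelse(s$codon_class == "AAA",
                           config$stall_weight_AAA / wmax,
                           config$stall_weight_AAG / wmax))
    chosen <- stats::runif(nrow(s)) < p_sel
    depth <- ifelse(s$class == "mazf", config$cleavage_depth,
                    config$stall_depth)
    n_reads <- ifelse(chosen, stats::rpois(nrow(s), depth), 0L)
    realized <- s
    realized$n_reads <- n_reads
    keep <- n_reads > 0L
    if (any(keep)) {
      pos <- c(pos, rep(s$pos[keep], n_reads[keep]))
      strand <- c(strand, rep(s$strand[keep], n_reads[keep]))
      cls <- c(cls, rep(s$class[keep], n_reads[keep]))
    }
  }

  n <- length(pos)
  if (n == 0L) {
    return(list(reads = data.frame(id = character(), seq = character(),
                                   qual = character(),
                                   stringsAsFactors = FALSE),
                sites = realized))
  }

  post_len <- sample(seq(config$read_len_range[1], config$read_len_range[2]),
                     n, replace = TRUE)
  gin <- post_len - config$umi_len
  fw <- strand == "+"
  insert <- character(n)
  insert[fw] <- substring(genome, pos[fw],
                          pmin(pos[fw] + gin[fw] - 1L, glen_total))
  rp <- glen_total - pos[!fw] + 1L
  insert[!fw] <- substring(rcgenome, rp, pmin(rp + gin[!fw] - 1L, glen_total))

  umi_mat <- matrix(sample(c("A", "C", "G", "T"), n * config$umi_len,
                           replace = TRUE), nrow = n)
  umi <- do.call(paste0, as.data.frame(umi_mat, stringsAsFactors = FALSE))
  seqs <- paste0(config$adapter, umi, insert)
  reads <- data.frame(
    id = sprintf("%s_%07d:%s:%s:%d", condition, seq_len(n), cls, strand, pos),
    seq = seqs,
    qual = strrep("I", nchar(seqs)),
    stringsAsFactors = FALSE)
  list(reads = reads, sites = realized)
}

#' Simulate replicate spectral counts with a planted AAA-codon effect
#'
#' Per protein g, uninduced replicate counts are Poisson(mu_g) with mu_g
#' log-uniform on 5-500; induced counts are
#' Poisson(mu_g * 2^(aaa_effect * AAA_count_g)): synthesis decays with the
#' gene's AAA codon load, AAG content plays no causal role.
#'
#' @param truth Ground truth from [build_reference()] (uses `$proteins`).
#' @param config The [sim_config()].
#' @return List with `counts` (long data.frame: `protein_id`, `condition`,
#'   `replicate`, `spectral_count`) and `proteins` (truth with `mu` and
#'   planted `log2_effect`).
#' @export
simulate_proteome <- function(truth, config) {
  if (config$n_replicates < 2L) stop("n_replicates must be at least 2")
  set.seed(config$seed + 303L)
  pr <- truth$proteins
  n <- nrow(pr)
  pr$mu <- exp(stats::runif(n, log(5), log(500)))
  pr$log2_effect <- config$aaa_effect * pr$aaa_count
  reps <- seq_len(config$n_replicates)
  grid <- expand.grid(protein_id = pr$protein_id,
                      condition = c("uninduced", "induced"),
                      replicate = reps, stringsAsFactors = FALSE)
  grid <- grid[order(grid$protein_id, grid$condition, grid$replicate), ]
  mu <- pr$mu[match(grid$protein_id, pr$protein_id)]
  eff <- ifelse(grid$condition == "induced",
                2^(pr$log2_effect[match(grid$protein_id, pr$protein_id)]), 1)
  grid$spectral_count <- stats::rpois(nrow(grid), mu * eff)
  rownames(grid) <- NULL
  list(counts = grid, proteins = pr)
}

#' Simulate a complete dataset to disk
#'
#' Writes `reference.fa`, `annotation.gff3`, `induced.fastq`,
#' `uninduced.fastq`, `spectral_counts.tsv`, `truth_sites.tsv` and
#' `truth_proteins.tsv` into `outdir`. Byte-identical across runs with the
#' same configuration.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if absent).
#' @return Named character vector of output paths, invisibly.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  built <- build_reference(config)
  ind <- simulate_reads(built$reference, built$truth, config, "induced")
  unind <- simulate_reads(built$reference, built$truth, config, "uninduced")
  prot <- simulate_proteome(built$truth, config)
  paths <- c(reference = file.path(outdir, "reference.fa"),
             annotation = file.path(outdir, "annotation.gff3"),
             induced = file.path(outdir, "induced.fastq"),
             uninduced = file.path(outdir, "uninduced.fastq"),
             spectral_counts = file.path(outdir, "spectral_counts.tsv"),
             truth_sites = file.path(outdir, "truth_sites.tsv"),
             truth_proteins = file.path(outdir, "truth_proteins.tsv"))
  write_fasta(built$reference$seq, paths["reference"])
  write_annotation(built$reference$features, paths["annotation"])
  write_fastq(ind$reads, paths["induced"])
  write_fastq(unind$reads, paths["uninduced"])
  write_tsv(prot$counts, paths["spectral_counts"])
  write_tsv(ind$sites, paths["truth_sites"])
  write_tsv(prot$proteins, paths["truth_proteins"])
  invisible(paths)
}
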