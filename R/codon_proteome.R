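#' In-frame codon counts of a CDS
#'
#' Counts codons read in frame from position 1; an out-of-frame trimer
#' spanning two codons is never counted.
#'
#' @param seq CDS sequence (length divisible by 3, nonempty).
#' @return Named integer vector of observed codon counts.
#' @export
count_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("CDS length must be a positive multiple of 3")
  }
  starts <- seq(1L, n, by = 3L)
  tab <- table(substring(seq, starts, starts + 2L))
  stats::setNames(as.integer(tab), names(tab))
}

#' AAA/AAG codon content of every CDS in a reference
#'
#' @param ref A `toxcut_reference`.
#' @return data.frame: `protein_id`, `AAA_count`, `AAG_count`.
#' @export
cds_codon_table <- function(ref) {
  cds <- ref$features[ref$features$kind == "CDS", , drop = FALSE]
  one <- function(i) {
    f <- cds[i, ]
    s <- substr(ref$seq[[f$contig]], f$start, f$end)
    if (f$strand == "-") s <- revcomp(s)
    cc <- count_codons(s)
    c(AAA = unname(cc["AAA"]), AAG = unname(cc["AAG"]))
  }
  m <- vapply(seq_len(nrow(cds)), one, numeric(2))
  m[is.na(m)] <- 0
  data.frame(protein_id = cds$id, AAA_count = as.integer(m["AAA", ]),
             AAG_count = as.integer(m["AAG", ]), stringsAsFactors = FALSE)
}

#' Differential translation from spectral counts
#'
#' Proteins with fewer than `min_total` total spectral counts (all
#' replicates, both conditions) are dropped. Replicate libraries are
#' scaled to the median library size; the log2 fold change is
#' log2((sum induced + 0.5) / (sum uninduced + 0.5)) on normalised sums.
#' The p-value is an exact conditional binomial test of the protein's raw
#' induced count against the induced share of total library size; q-values
#' are Benjamini-Hochberg over retained proteins, and a protein is classed
#' up/down by the sign of its log2 fold change when q <= `alpha`.
#'
#' @param counts Long data.frame: `protein_id`, `condition`
#'   (`induced`/`uninduced`), `replicate`, `spectral_count`.
#' @param min_total Inclusive minimum total spectral counts.
#' @param alpha Significance threshold on the q-value.
#' @param codon_table Optional [cds_codon_table()] output merged onto the
#'   result.
#' @return data.frame of per-protein quantities (`sum_induced`,
#'   `sum_uninduced`, `total_counts`, `log2_fold_change`, `p_value`,
#'   `q_value`, `class`, and codon counts if supplied).
#' @export
differential_translation <- function(counts, min_total = 15, alpha = 0.05,
                                     codon_table = NULL) {
  stopifnot(all(c("protein_id", "condition", "replicate", "spectral_count")
                %in% names(counts)),
            all(counts$condition %in% c("induced", "uninduced")))
  if (sum(counts$spectral_count) == 0) stop("all spectral counts are zero")
  if (length(unique(counts$replicate[counts$condition == "induced"])) < 2L ||
      length(unique(counts$replicate[counts$condition == "uninduced"])) < 2L) {
    stop("at least 2 replicates per condition are required")
  }
  lib <- stats::aggregate(spectral_count ~ condition + replicate, counts, sum)
  lib$factor <- stats::median(lib$spectral_count) / lib$spectral_count
  counts$norm <- counts$spectral_count *
    lib$factor[match(paste(counts$condition, counts$replicate),
                     paste(lib$condition, lib$replicate))]

  raw_i <- stats::aggregate(
    spectral_count ~ protein_id, counts[counts$condition == "induced", ], sum)
  raw_u <- stats::aggregate(
    spectral_count ~ protein_id,
    counts[counts$condition == "uninduced", ], sum)
  nrm_i <- stats::aggregate(
    norm ~ protein_id, counts[counts$condition == "induced", ], sum)
  nrm_u <- stats::aggregate(
    norm ~ protein_id, counts[counts$condition == "uninduced", ], sum)
  q <- data.frame(protein_id = raw_i$protein_id,
                  raw_induced = raw_i$spectral_count,
                  raw_uninduced = raw_u$spectral_count[
                    match(raw_i$protein_id, raw_u$protein_id)],
                  sum_induced = nrm_i$norm,
                  sum_uninduced = nrm_u$norm[
                    match(raw_i$protein_id, nrm_u$protein_id)],
                  stringsAsFactors = FALSE)
  q$total_counts <- q$raw_induced + q$raw_uninduced
  q <- q[q$total_counts >= min_total, , drop = FALSE]
  if (nrow(q) == 0L) stop("no protein passes the total-count filter")

  q$log2_fold_change <- log2((q$sum_induced + 0.5) / (q$sum_uninduced + 0.5))
  n_i <- sum(lib$spectral_count[lib$condition == "induced"])
  n_u <- sum(lib$spectral_count[lib$condition == "uninduced"])
  p0 <- n_i / (n_i + n_u)
  q$p_value <- vapply(seq_len(nrow(q)), function(j) {
    stats::binom.test(q$raw_induced[j], q$total_counts[j], p = p0)$p.value
  }, numeric(1))
  q$q_value <- stats::p.adjust(q$p_value, method = "BH")
  q$class <- ifelse(q$q_value <= alpha,
                    ifelse(q$log2_fold_change > 0, "up", "down"), "ns")
  if (!is.null(codon_table)) {
    q <- merge(q, codon_table, by = "protein_id", sort = FALSE)
  }
  rownames(q) <- NULL
  q
}

#' Codon-content shift between up- and downregulated proteins
#'
#' Emits the per-class codon-count distributions (tidy, ready for
#' boxplotting) and a two-sided Wilcoxon rank-sum comparison of the chosen
#' codon's counts between the up and down classes.
#'
#' @param quants [differential_translation()] output carrying codon counts.
#' @param codon `"AAA"` or `"AAG"`.
#' @return List: `distributions` (data.frame `class`, `protein_id`,
#'   `codon`, `codon_count`) and `rank_test_p` (NA when either class is
#'   empty).
#' @export
codon_shift_summary <- function(quants, codon = c("AAA", "AAG")) {
  codon <- match.arg(codon)
  col <- paste0(codon, "_count")
  stopifnot(col %in% names(quants))
  sel <- quants$class %in% c("up", "down")
  dist <- data.frame(class = quants$class[sel],
                     protein_id = quants$protein_id[sel],
                     codon = codon,
                     codon_count = quants[[col]][sel],
                     stringsAsFactors = FALSE)
  up <- dist$codon_count[dist$class == "up"]
  down <- dist$codon_count[dist$class == "down"]
  p <- if (length(up) >= 1L && length(down) >= 1L) {
    suppressWarnings(stats::wilcox.test(down, up)$p.value)
  } else {
    NA_real_
  }
  # all-tie comparisons have zero rank variance; no evidence of a shift
  if (is.nan(p)) p <- 1
  list(distributions = dist, rank_test_p = p)
}
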