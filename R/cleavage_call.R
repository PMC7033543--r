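#' Normalise an end-count track to reads per million
#'
#' rpm[p] = count[p] * 10^6 / total_mapped.
#'
#' @param track An `end_count_track` with `total_mapped > 0`.
#' @return Same structure with numeric rpm vectors.
#' @export
normalize_rpm <- function(track) {
  stopifnot(inherits(track, "end_count_track"))
  if (track$total_mapped == 0L) stop("cannot normalise: total_mapped is 0")
  out <- track
  out$counts <- lapply(track$counts, function(ctg) {
    lapply(ctg, function(v) v * 1e6 / track$total_mapped)
  })
  out
}

#' Induced/uninduced fold-change track with the uninduced pseudocount
#'
#' Uninduced *raw* counts of 0 are replaced by a pseudocount of 1 before
#' rpm normalisation (so the uninduced rpm floor is 10^6/total_uninduced);
#' the fold change is rpm_induced / rpm_uninduced. Positions with induced
#' raw count 0 get fold change 0 regardless of the uninduced count — they
#' can never pass a > 1 threshold.
#'
#' @param induced,uninduced `end_count_track`s over the same reference.
#' @return List of class `fc_track`: per contig and strand, numeric vectors
#'   `rpm_induced`, `rpm_uninduced` (pseudocounted) and `fold`.
#' @export
fold_change_track <- function(induced, uninduced) {
  stopifnot(inherits(induced, "end_count_track"),
            inherits(uninduced, "end_count_track"))
  if (!identical(induced$contig_lengths, uninduced$contig_lengths)) {
    stop("induced and uninduced tracks are over different references")
  }
  if (induced$total_mapped == 0L || uninduced$total_mapped == 0L) {
    stop("cannot compute fold changes: a track has total_mapped = 0")
  }
  per_contig <- lapply(names(induced$counts), function(ctg) {
    lapply(stats::setNames(c("+", "-"), c("+", "-")), function(s) {
      ind <- induced$counts[[ctg]][[s]]
      un <- uninduced$counts[[ctg]][[s]]
      rpm_ind <- ind * 1e6 / induced$total_mapped
      rpm_un <- pmax(un, 1L) * 1e6 / uninduced$total_mapped
      fold <- ifelse(ind == 0L, 0, rpm_ind / rpm_un)
      list(rpm_induced = rpm_ind, rpm_uninduced = rpm_un, fold = fold)
    })
  })
  names(per_contig) <- names(induced$counts)
  structure(list(tracks = per_contig,
                 contig_lengths = induced$contig_lengths,
                 total_induced = induced$total_mapped,
                 total_uninduced = uninduced$total_mapped),
            class = "fc_track")
}

#' Call cleavage sites under rpm and fold-change thresholds
#'
#' Retains genome positions lying within a feature, on the feature's
#' strand, whose induced rpm meets the kind-specific minimum (inclusive:
#' "at least 50 rpm / 5 rpm") and whose fold change strictly exceeds
#' `min_fold` (">10"). The in-gene coordinate `gene_position` is the
#' 1-based position, in mature gene numbering, of the first nucleotide of
#' the 3' fragment (the 5'-OH base): `pos - start + 1` on plus-strand
#' features, `end - pos + 1` on minus-strand features.
#'
#' @param fc A [fold_change_track()] object.
#' @param features Feature data.frame ([read_annotation()]).
#' @param min_rpm_trna Inclusive induced-rpm minimum for tRNA features.
#' @param min_rpm_mrna Inclusive induced-rpm minimum for CDS features.
#' @param min_fold Strict fold-change threshold.
#' @return data.frame of cleavage sites: `feature_id`, `kind`, `contig`,
#'   `pos`, `strand`, `gene_position`, `rpm_induced`, `rpm_uninduced`,
#'   `fold_change`. Sites under overlapping features are reported once per
#'   feature, with a warning.
#' @export
call_sites <- function(fc, features, min_rpm_trna = 50, min_rpm_mrna = 5,
                       min_fold = 10) {
  stopifnot(inherits(fc, "fc_track"))
  validate_features(features)
  out <- list()
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    tr <- fc$tracks[[f$contig]][[f$strand]]
    idx <- f$start:f$end
    min_rpm <- if (f$kind == "tRNA") min_rpm_trna else min_rpm_mrna
    hit <- idx[tr$rpm_induced[idx] >= min_rpm & tr$fold[idx] > min_fold]
    if (length(hit)) {
      gene_pos <- if (f$strand == "+") hit - f$start + 1L else f$end - hit + 1L
      out[[length(out) + 1L]] <- data.frame(
        feature_id = f$id, kind = f$kind, contig = f$contig, pos = hit,
        strand = f$strand, gene_position = gene_pos,
        rpm_induced = tr$rpm_induced[hit],
        rpm_uninduced = tr$rpm_uninduced[hit],
        fold_change = tr$fold[hit], stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else {
    data.frame(feature_id = character(), kind = character(),
               contig = character(), pos = integer(), strand = character(),
               gene_position = integer(), rpm_induced = numeric(),
               rpm_uninduced = numeric(), fold_change = numeric(),
               stringsAsFactors = FALSE)
  }
  key <- paste(sites$contig, sites$pos, sites$strand)
  if (anyDuplicated(key)) {
    warning("site(s) under overlapping features reported once per feature")
  }
  rownames(sites) <- NULL
  sites
}

#' Per-tRNA fold-change matrix in mature coordinates
#'
#' One row per annotated tRNA (rows with no signal included), columns
#' 1..max tRNA length, entries = fold change at that mature position
#' (0 where the position exceeds the gene length).
#'
#' @param fc A [fold_change_track()] object.
#' @param features Feature data.frame; must contain at least one tRNA.
#' @return Numeric matrix, rownames = tRNA feature ids.
#' @export
trna_matrix <- function(fc, features) {
  trnas <- features[features$kind == "tRNA", , drop = FALSE]
  if (nrow(trnas) == 0L) stop("annotation contains no tRNA features")
  maxlen <- max(trnas$end - trnas$start + 1L)
  m <- matrix(0, nrow = nrow(trnas), ncol = maxlen,
              dimnames = list(trnas$id, seq_len(maxlen)))
  for (i in seq_len(nrow(trnas))) {
    f <- trnas[i, ]
    fold <- fc$tracks[[f$contig]][[f$strand]]$fold[f$start:f$end]
    if (f$strand == "-") fold <- rev(fold)
    m[i, seq_along(fold)] <- fold
  }
  m
}
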