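#' Exclude mRNA sites resembling the toxin's tRNA cut context
#'
#' A secondary (ribosome-stall-associated) cut must not look like a direct
#' toxin cut. The toxin cleaves (U/C)U|U, so an mRNA site whose
#' sense-strand context has -2 in {T,C}, -1 = T and +1 = T (DNA alphabet;
#' the +1 base is the 5'-OH base) is excluded as toxin-like. Sites too
#' close to the feature's 5' end for a context check (`gene_position < 3`)
#' are retained but flagged.
#'
#' @param sites mRNA cleavage sites from [call_sites()] (kind `CDS`).
#' @param ref A `toxcut_reference`.
#' @return List with `retained` (with logical `edge_flag` column) and
#'   `excluded` data.frames.
#' @export
filter_toxin_like <- function(sites, ref) {
  stopifnot(all(sites$kind == "CDS"))
  n <- nrow(sites)
  if (n == 0L) {
    sites$edge_flag <- logical(0)
    return(list(retained = sites, excluded = sites))
  }
  feats <- ref$features
  gene_seq <- function(fid) {
    f <- feats[feats$id == fid, ]
    s <- substr(ref$seq[[f$contig]], f$start, f$end)
    if (f$strand == "-") revcomp(s) else s
  }
  seqs <- vapply(unique(sites$feature_id), gene_seq, character(1))
  gp <- sites$gene_position
  edge <- gp < 3L
  ctx <- rep(NA_character_, n)
  ctx[!edge] <- substr(seqs[sites$feature_id[!edge]], gp[!edge] - 2L,
                       gp[!edge])
  toxin_like <- !edge & grepl("^[TC]TT$", ctx)
  sites$edge_flag <- edge
  list(retained = sites[!toxin_like, , drop = FALSE],
       excluded = sites[toxin_like, , drop = FALSE])
}

#' Extract sense-strand windows around cleavage sites
#'
#' For each site, the 50-nt (2 * `flank`) sense-strand sequence with the
#' cut between window positions `flank` and `flank + 1`: the 5'-OH base
#' sits at window index `flank + 1` (26 by default). Windows are taken from
#' the contig (they may extend past the feature); sites within `flank` of a
#' contig edge are dropped and tallied in the `n_edge_dropped` attribute.
#'
#' @param sites Retained sites from [filter_toxin_like()].
#' @param ref A `toxcut_reference`.
#' @param flank Nucleotides on each side of the cut.
#' @return The sites data.frame with a `window` column; attribute
#'   `n_edge_dropped`.
#' @export
extract_windows <- function(sites, ref, flank = 25L) {
  n <- nrow(sites)
  win <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    g <- ref$seq[[sites$contig[j]]]
    L <- nchar(g)
    p <- sites$pos[j]
    if (sites$strand[j] == "+") {
      if (p - flank >= 1L && p + flank - 1L <= L) {
        win[j] <- substr(g, p - flank, p + flank - 1L)
      }
    } else {
      if (p - flank + 1L >= 1L && p + flank <= L) {
        win[j] <- revcomp(substr(g, p - flank + 1L, p + flank))
      }
    }
  }
  keep <- !is.na(win)
  out <- sites[keep, , drop = FALSE]
  out$window <- win[keep]
  attr(out, "n_edge_dropped") <- sum(!keep)
  rownames(out) <- NULL
  out
}

#' Positional nucleotide frequency matrix of aligned windows
#'
#' @param windows Character vector of equal-length windows.
#' @return List of class `logo_matrix`: `freq` (4 x width matrix, rows
#'   A/C/G/T, columns summing to 1) and `n_sequences`.
#' @export
build_logo <- function(windows) {
  if (length(windows) == 0L) stop("cannot build a logo from zero windows")
  w <- unique(nchar(windows))
  if (length(w) != 1L) stop("windows must have equal length")
  m <- do.call(rbind, strsplit(windows, ""))
  freq <- vapply(seq_len(w), function(j) {
    tabulate(factor(m[, j], levels = c("A", "C", "G", "T")), nbins = 4L)
  }, integer(4))
  freq <- freq / length(windows)
  dimnames(freq) <- list(c("A", "C", "G", "T"), seq_len(w))
  structure(list(freq = freq, n_sequences = length(windows)),
            class = "logo_matrix")
}

#' Classify the lysine codon at or near the ribosome footprint offset
#'
#' Offsets count nucleotides of the 3' fragment: the 5'-OH base is offset
#' +1, so a codon at offset o starts at window index `flank + o`. Offsets
#' are examined in order of distance from the canonical +15 (15, 14, 16,
#' 13, 17 by default); the first AAA or AAG codon wins.
#'
#' @param window A window from [extract_windows()].
#' @param offsets Integer vector of codon-start offsets, in preference
#'   order.
#' @param flank Flank used for window extraction.
#' @return List with `codon_offset` (NA if none) and `codon_class`
#'   (`"AAA"`, `"AAG"`, or `"none"`).
#' @export
classify_stall <- function(window, offsets = c(15L, 14L, 16L, 13L, 17L),
                           flank = 25L) {
  for (o in offsets) {
    codon <- substr(window, flank + o, flank + o + 2L)
    if (codon %in% c("AAA", "AAG")) {
      return(list(codon_offset = o, codon_class = codon))
    }
  }
  list(codon_offset = NA_integer_, codon_class = "none")
}

#' Full stall-detection stage
#'
#' Filters toxin-like mRNA sites, extracts aligned windows, and classifies
#' the Lys codon near the footprint offset for each.
#'
#' @param sites mRNA cleavage sites ([call_sites()], kind CDS).
#' @param ref A `toxcut_reference`.
#' @param flank Window half-width.
#' @param offsets Codon-offset search order (see [classify_stall()]).
#' @return List: `calls` (sites + `window`, `codon_offset`, `codon_class`),
#'   `excluded` (toxin-like sites), `n_edge_dropped`.
#' @export
detect_stalls <- function(sites, ref, flank = 25L,
                          offsets = c(15L, 14L, 16L, 13L, 17L)) {
  flt <- filter_toxin_like(sites, ref)
  win <- extract_windows(flt$retained, ref, flank)
  if (nrow(win)) {
    cl <- lapply(win$window, classify_stall, offsets = offsets,
                 flank = flank)
    win$codon_offset <- vapply(cl, `[[`, integer(1), "codon_offset")
    win$codon_class <- vapply(cl, `[[`, character(1), "codon_class")
  } else {
    win$codon_offset <- integer(0)
    win$codon_class <- character(0)
  }
  list(calls = win, excluded = flt$excluded,
       n_edge_dropped = attr(win, "n_edge_dropped"))
}

#' Transcript-level AAA vs AAG stall summary
#'
#' Restricts to calls with a classified Lys codon and induced rpm at least
#' `min_rpm`, counts each transcript once (its highest-rpm site), and
#' reports the AAA proportion.
#'
#' @param calls Classified calls from [detect_stalls()].
#' @param min_rpm Inclusive induced-rpm minimum per site.
#' @return data.frame with `n_transcripts`, `n_AAA`, `n_AAG`, `pct_AAA`
#'   (NA with `undefined = TRUE` when no transcript qualifies).
#' @export
stall_summary <- function(calls, min_rpm = 1) {
  k <- calls[calls$codon_class %in% c("AAA", "AAG") &
               calls$rpm_induced >= min_rpm, , drop = FALSE]
  if (nrow(k)) {
    k <- k[order(k$feature_id, -k$rpm_induced), , drop = FALSE]
    k <- k[!duplicated(k$feature_id), , drop = FALSE]
  }
  n_aaa <- sum(k$codon_class == "AAA")
  n_aag <- sum(k$codon_class == "AAG")
  denom <- n_aaa + n_aag
  data.frame(n_transcripts = nrow(k), n_AAA = n_aaa, n_AAG = n_aag,
             pct_AAA = if (denom > 0L) 100 * n_aaa / denom else NA_real_,
             undefined = denom == 0L)
}
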