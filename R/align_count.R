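#' Build an exact-match k-mer index of a reference
#'
#' Indexes every k-mer of both strands of every contig, emulating
#' zero-mismatch seed mapping (`bowtie -n 0 -l 20`) by exact 20-mer
#' identity. For a reverse-strand k-mer the recorded position is the
#' *highest* genome coordinate of the matched interval — the biological
#' 5' end of a minus-strand read, which is what a 5'-OH assay selects.
#' K-mers containing N are excluded.
#'
#' @param ref A `toxcut_reference` or named character vector of contigs.
#' @param k K-mer length (the pipeline's trimmed read length).
#' @return List of class `kmer_index` with a keyed data.table of
#'   (kmer, contig, pos, strand) and the contig lengths.
#' @export
build_index <- function(ref, k = 20L) {
  seqs <- if (inherits(ref, "toxcut_reference")) ref$seq else ref
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  k <- as.integer(k)
  tabs <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[[i]])
    if (L < k) {
      warning("contig ", names(seqs)[i], " shorter than k = ", k,
              "; contributes nothing to the index")
      next
    }
    starts <- seq_len(L - k + 1L)
    fwd <- substring(seqs[[i]], starts, starts + k - 1L)
    rev <- revcomp(fwd)
    tabs[[i]] <- data.table::data.table(
      kmer = c(fwd, rev),
      contig = names(seqs)[i],
      pos = c(starts, starts + k - 1L),
      strand = rep(c("+", "-"), each = length(starts)))
  }
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (length(tabs) == 0L) stop("no contig long enough to index")
  dt <- data.table::rbindlist(tabs)
  dt <- dt[!grepl("N", dt$kmer, fixed = TRUE)]
  data.table::setkeyv(dt, "kmer")
  structure(list(k = k, dt = dt,
                 contig_lengths = stats::setNames(nchar(seqs), names(seqs))),
            class = "kmer_index")
}

#' Map trimmed reads and count 5'-end starts per genome position
#'
#' Each read must have length exactly `k`. A read matching exactly one
#' indexed locus increments the count at its 5'-end genome position on the
#' matched strand; reads matching zero or two-plus loci are discarded and
#' tallied (`n_unmapped`, `n_multi`). Multi-mapping reads are discarded
#' rather than randomly placed so counts are deterministic.
#'
#' @param index A [build_index()] object.
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `seq` column.
#' @param condition Label stored on the track.
#' @return List of class `end_count_track`: per contig a list of `+`/`-`
#'   integer count vectors of contig length, plus `total_mapped`,
#'   `n_multi`, `n_unmapped`.
#' @export
map_and_count <- function(index, reads, condition = "") {
  stopifnot(inherits(index, "kmer_index"))
  if (is.data.frame(reads)) reads <- reads$seq
  if (length(reads) > 0L && any(nchar(reads) != index$k)) {
    stop("all reads must have length exactly k = ", index$k)
  }
  counts <- lapply(index$contig_lengths, function(L) {
    list("+" = integer(L), "-" = integer(L))
  })
  n_multi <- 0L
  n_unmapped <- 0L
  total <- 0L
  if (length(reads) > 0L) {
    rd <- data.table::data.table(kmer = unique(reads))
    m <- index$dt[rd, on = "kmer", allow.cartesian = TRUE]
    nhit <- m[, list(n = sum(!is.na(pos))), by = "kmer"]
    hits_per_read <- nhit$n[match(reads, nhit$kmer)]
    n_unmapped <- sum(hits_per_read == 0L)
    n_multi <- sum(hits_per_read > 1L)
    uniq_kmers <- nhit$kmer[nhit$n == 1L]
    uses <- table(reads[hits_per_read == 1L])
    if (length(uses) > 0L) {
      loci <- index$dt[data.table::data.table(kmer = names(uses)),
                       on = "kmer"]
      mult <- as.integer(uses[loci$kmer])
      # a locus determines its k-mer, so positions are unique per
      # (contig, strand) and plain vector assignment is collision-free
      for (ctg in unique(loci$contig)) {
        for (s in c("+", "-")) {
          sel <- loci$contig == ctg & loci$strand == s
          if (any(sel)) {
            counts[[ctg]][[s]][loci$pos[sel]] <-
              counts[[ctg]][[s]][loci$pos[sel]] + mult[sel]
          }
        }
      }
      total <- sum(mult)
    }
  }
  structure(list(condition = condition, counts = counts,
                 total_mapped = total, n_multi = n_multi,
                 n_unmapped = n_unmapped,
                 contig_lengths = index$contig_lengths),
            class = "end_count_track")
}

#' Write an end-count track as TSV
#'
#' Columns `contig`, `position` (1-based), `strand`, `count`; zero rows are
#' omitted. A `# total_mapped=` header comment preserves the normalising
#' denominator.
#'
#' @param track An `end_count_track`.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  rows <- list()
  for (ctg in names(track$counts)) {
    for (s in c("+", "-")) {
      v <- track$counts[[ctg]][[s]]
      nz <- which(v > 0L)
      if (length(nz)) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = ctg, position = nz, strand = s, count = v[nz],
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(contig = character(), position = integer(),
               strand = character(), count = integer())
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# condition=%s total_mapped=%d n_multi=%d n_unmapped=%d lengths=%s",
                     track$condition, track$total_mapped, track$n_multi,
                     track$n_unmapped,
                     paste(sprintf("%s:%d", names(track$contig_lengths),
                                   track$contig_lengths), collapse = ",")),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an end-count track written by [write_track()]
#'
#' @param path Track TSV path.
#' @return An `end_count_track`.
#' @export
read_track <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) stop("missing track header in ", path)
  get <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr)
  lens_raw <- strsplit(get("lengths"), ",")[[1]]
  lens <- stats::setNames(as.integer(sub(".*:", "", lens_raw)),
                          sub(":.*", "", lens_raw))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "integer"))
  counts <- lapply(lens, function(L) list("+" = integer(L), "-" = integer(L)))
  for (ctg in names(lens)) {
    for (s in c("+", "-")) {
      sel <- df$contig == ctg & df$strand == s
      counts[[ctg]][[s]][df$position[sel]] <- df$count[sel]
    }
  }
  structure(list(condition = get("condition"), counts = counts,
                 total_mapped = as.integer(get("total_mapped")),
                 n_multi = as.integer(get("n_multi")),
                 n_unmapped = as.integer(get("n_unmapped")),
                 contig_lengths = lens),
            class = "end_count_track")
}
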