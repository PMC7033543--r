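#' Read a FASTA reference
#'
#' Loads contig sequences, uppercased, keyed by the first
#' whitespace-delimited token of each header. The reference alphabet is
#' restricted to A/C/G/T: the pipeline maps reads by exact 20-mer identity,
#' so ambiguity codes in the genome would silently create unmappable loci.
#'
#' @param path FASTA file (gzip accepted).
#' @return Named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate contig id in FASTA: ", ids[duplicated(ids)][1L])
  }
  if (any(Biostrings::width(x) == 0L)) {
    stop("FASTA record with no sequence: ", ids[Biostrings::width(x) == 0L][1L])
  }
  seqs <- toupper(as.character(x))
  if (any(grepl("[^ACGT]", seqs))) {
    stop("reference contains non-ACGT characters")
  }
  names(seqs) <- ids
  seqs
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read tRNA/CDS features from a GFF3 file
#'
#' Retains only rows of type `tRNA` or `CDS` (column 3); everything else is
#' ignored. Coordinates are 1-based inclusive as in the file and are kept in
#' that convention throughout the package. Retained features must carry an
#' explicit strand, tRNA genes must be 70-95 nt and CDS lengths divisible
#' by 3.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `id`, `contig`, `start`, `end`,
#'   `strand`, `kind`.
#' @export
read_annotation <- function(path) {
  g <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                         col.names = c("contig", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attr"),
                         colClasses = c("character", "character", "character",
                                        "integer", "integer", "character",
                                        "character", "character", "character"),
                         stringsAsFactors = FALSE)
  g <- g[g$type %in% c("tRNA", "CDS"), , drop = FALSE]
  if (nrow(g) == 0L) stop("no tRNA or CDS features in ", path)
  id <- sub("^.*ID=([^;]+).*$", "\\1", g$attr)
  id[!grepl("ID=", g$attr)] <- sprintf("feature_%04d", which(!grepl("ID=", g$attr)))
  feats <- data.frame(id = id, contig = g$contig, start = g$start,
                      end = g$end, strand = g$strand, kind = g$type,
                      stringsAsFactors = FALSE)
  validate_features(feats)
  feats
}

#' Validate a feature table
#'
#' Enforces the structural invariants assumed downstream: `start <= end`,
#' explicit strand, tRNA length 70-95 nt, CDS length divisible by 3.
#'
#' @param feats Feature data.frame as returned by [read_annotation()].
#' @return The validated data.frame, invisibly.
#' @export
validate_features <- function(feats) {
  stopifnot(all(c("id", "contig", "start", "end", "strand", "kind") %in%
                  names(feats)))
  if (any(feats$start > feats$end)) {
    stop("feature with start > end: ", feats$id[feats$start > feats$end][1L])
  }
  if (!all(feats$strand %in% c("+", "-"))) {
    stop("retained feature without explicit strand: ",
         feats$id[!feats$strand %in% c("+", "-")][1L])
  }
  len <- feats$end - feats$start + 1L
  bad_trna <- feats$kind == "tRNA" & (len < 70L | len > 95L)
  if (any(bad_trna)) {
    stop("tRNA feature outside 70-95 nt: ", feats$id[bad_trna][1L])
  }
  bad_cds <- feats$kind == "CDS" & (len %% 3L != 0L)
  if (any(bad_cds)) {
    stop("CDS length not divisible by 3: ", feats$id[bad_cds][1L])
  }
  invisible(feats)
}

#' Write a feature table as GFF3
#'
#' @param feats Feature data.frame.
#' @param path Output path.
#' @export
write_annotation <- function(feats, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttoxcut\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     feats$contig, feats$kind, feats$start, feats$end,
                     feats$strand, feats$id))
  writeLines(lines, path)
  invisible(path)
}

#' Bundle sequences and features into a reference object
#'
#' @param seqs Named character vector of contig sequences.
#' @param feats Feature data.frame.
#' @return A list with elements `seq` and `features`, class
#'   `toxcut_reference`.
#' @export
as_reference <- function(seqs, feats) {
  validate_features(feats)
  if (!all(feats$contig %in% names(seqs))) {
    stop("feature on unknown contig: ",
         feats$contig[!feats$contig %in% names(seqs)][1L])
  }
  clen <- nchar(seqs)[feats$contig]
  if (any(feats$end > clen)) {
    stop("feature extends past contig end: ", feats$id[feats$end > clen][1L])
  }
  structure(list(seq = seqs, features = feats), class = "toxcut_reference")
}

#' Read a FASTQ file into a read table
#'
#' Four-line records; Sanger qualities. Record ids are taken verbatim from
#' the `@` header. Errors on truncated records and on per-record
#' sequence/quality length mismatches.
#'
#' @param path FASTQ file (gzip accepted).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ record in ", path)
  id <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  seq <- lines[seq(2L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (!all(startsWith(lines[seq(1L, length(lines), by = 4L)], "@"))) {
    stop("malformed FASTQ header line in ", path)
  }
  if (any(nchar(seq) != nchar(qual))) {
    stop("FASTQ sequence/quality length mismatch for read ",
         id[nchar(seq) != nchar(qual)][1L])
  }
  if (any(grepl("[^ACGTN]", seq))) {
    stop("FASTQ sequence with characters outside {A,C,G,T,N}")
  }
  data.frame(id = id, seq = seq, qual = qual, stringsAsFactors = FALSE)
}

#' Write a read table as FASTQ
#'
#' Inverse of [read_fastq()]; round trips are byte-identical (bare `+`
#' separator line).
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste(paste0("@", reads$id), reads$seq, "+", reads$qual,
                     sep = "\n"), con)
  }
  invisible(path)
}

#' Write a data.frame as a tab-delimited table
#'
#' @param x data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited table written by [write_tsv()]
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
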