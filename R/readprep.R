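#' Trimming parameters
#'
#' The preprocessing contract for 5'-OH libraries: locate the adapter
#' constant region, strip it together with the `umi_len` random nucleotides
#' that follow, truncate the genomic insert to `final_len` from its 5' end,
#' and keep only reads whose insert reaches `min_len`.
#'
#' @param adapter Adapter constant region (DNA string). Recognition uses an
#'   exact match of its 3'-most 12 nt, so a 5'-truncated (run-off) adapter
#'   prefix is still found.
#' @param umi_len Number of random nucleotides after the adapter.
#' @param final_len Length reads are truncated to.
#' @param min_len Minimum insert length; shorter reads are dropped.
#' @return List of class `trim_params`.
#' @export
trim_params <- function(adapter, umi_len = 6L, final_len = 20L,
                        min_len = 20L) {
  stopifnot(grepl("^[ACGT]+$", adapter), final_len >= min_len, min_len >= 1L,
            umi_len >= 0L)
  structure(list(adapter = adapter, umi_len = as.integer(umi_len),
                 final_len = as.integer(final_len),
                 min_len = as.integer(min_len),
                 key = substr(adapter, max(1L, nchar(adapter) - 11L),
                              nchar(adapter))),
            class = "trim_params")
}

#' Trim a table of reads
#'
#' Vectorised implementation of the stated preprocessing: adapter removal
#' (exact match on the adapter's terminal 12 nt; reads without a match are
#' dropped, since the UMI boundary cannot be located), UMI strip, truncation
#' to `final_len`, and exclusion of inserts shorter than `min_len`.
#' Qualities are trimmed in lockstep.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param params A [trim_params()].
#' @return List with `reads` (emitted reads, all of length `final_len`) and
#'   `stats` (data.frame: `input`, `emitted`, `dropped_short`,
#'   `dropped_no_adapter`).
#' @export
trim_reads <- function(reads, params) {
  stopifnot(inherits(params, "trim_params"))
  n <- nrow(reads)
  if (n == 0L) {
    return(list(reads = reads,
                stats = data.frame(input = 0L, emitted = 0L,
                                   dropped_short = 0L,
                                   dropped_no_adapter = 0L)))
  }
  hit <- regexpr(params$key, reads$seq, fixed = TRUE)
  has_adapter <- hit > 0L
  ins_start <- hit + nchar(params$key) + params$umi_len
  insert <- ifelse(has_adapter, substring(reads$seq, ins_start), "")
  long_enough <- has_adapter & nchar(insert) >= params$min_len
  out <- data.frame(
    id = reads$id[long_enough],
    seq = substring(insert[long_enough], 1L, params$final_len),
    qual = substring(reads$qual[long_enough], ins_start[long_enough],
                     ins_start[long_enough] + params$final_len - 1L),
    stringsAsFactors = FALSE)
  stats <- data.frame(input = n,
                      emitted = sum(long_enough),
                      dropped_short = sum(has_adapter & !long_enough),
                      dropped_no_adapter = sum(!has_adapter))
  list(reads = out, stats = stats)
}

#' Trim a FASTQ library file
#'
#' File-level wrapper around [trim_reads()].
#'
#' @param in_path Input FASTQ.
#' @param out_path Output FASTQ of trimmed reads.
#' @param params A [trim_params()].
#' @param stats_path Optional path for the stats TSV.
#' @return The stats data.frame, invisibly.
#' @export
trim_library <- function(in_path, out_path, params, stats_path = NULL) {
  reads <- read_fastq(in_path)
  res <- trim_reads(reads, params)
  write_fastq(res$reads, out_path)
  if (!is.null(stats_path)) write_tsv(res$stats, stats_path)
  invisible(res$stats)
}
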