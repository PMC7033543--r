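#' End-to-end pipeline configuration
#'
#' @param reference Path to the genome FASTA.
#' @param annotation Path to the tRNA/CDS GFF3.
#' @param induced,uninduced Paths to the raw FASTQ libraries.
#' @param spectral_counts Optional path to the long spectral-count TSV
#'   (`protein_id`, `condition`, `replicate`, `spectral_count`); the
#'   proteome stage is skipped when NULL.
#' @param adapter,umi_len,final_len Trimming parameters ([trim_params()]).
#' @param min_rpm_trna,min_rpm_mrna,min_fold Cleavage-calling thresholds.
#' @param min_rpm_stall Induced-rpm minimum for the stall summary.
#' @param min_total_spectra,alpha Proteome filtering and significance.
#' @return List of class `run_config`.
#' @export
run_config <- function(reference, annotation, induced, uninduced,
                       spectral_counts = NULL,
                       adapter = "GTTCAGAGTTCTACAGTCCGACGATC",
                       umi_len = 6L, final_len = 20L,
                       min_rpm_trna = 50, min_rpm_mrna = 5, min_fold = 10,
                       min_rpm_stall = 1, min_total_spectra = 15,
                       alpha = 0.05) {
  stopifnot(min_rpm_trna > 0, min_rpm_mrna > 0, min_fold > 0,
            min_rpm_stall > 0, min_total_spectra > 0, alpha > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Stages in order: trim both libraries, map and count 5' starts, compute
#' pseudocounted fold changes, call cleavage sites, detect ribosome stalls
#' on the mRNA sites, and (if spectral counts are given) run the
#' codon-stratified differential-translation analysis. All stage outputs,
#' the resolved configuration and a conservation log are written to
#' `outdir`. Reruns with identical inputs and configuration are
#' byte-identical.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if absent).
#' @return Named list of result objects, invisibly; files are the primary
#'   product.
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  in_paths <- c(config$reference, config$annotation, config$induced,
                config$uninduced, config$spectral_counts)
  missing <- in_paths[!file.exists(in_paths)]
  if (length(missing)) {
    stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ref <- stage("load", {
    as_reference(read_fasta(config$reference),
                 read_annotation(config$annotation))
  })
  tp <- trim_params(config$adapter, config$umi_len, config$final_len,
                    config$final_len)
  trims <- stage("trim", {
    lapply(c(induced = config$induced, uninduced = config$uninduced),
           function(p) trim_reads(read_fastq(p), tp))
  })
  for (cond in names(trims)) {
    s <- trims[[cond]]$stats
    say("trim %s: input=%d emitted=%d dropped_short=%d dropped_no_adapter=%d",
        cond, s$input, s$emitted, s$dropped_short, s$dropped_no_adapter)
  }
  idx <- stage("index", build_index(ref, k = config$final_len))
  tracks <- stage("count", {
    lapply(names(trims), function(cond) {
      map_and_count(idx, trims[[cond]]$reads, condition = cond)
    })
  })
  names(tracks) <- names(trims)
  for (cond in names(tracks)) {
    t <- tracks[[cond]]
    say("count %s: mapped=%d multi=%d unmapped=%d", cond, t$total_mapped,
        t$n_multi, t$n_unmapped)
  }
  fc <- stage("fold", fold_change_track(tracks$induced, tracks$uninduced))
  sites <- stage("call", {
    call_sites(fc, ref$features, config$min_rpm_trna, config$min_rpm_mrna,
               config$min_fold)
  })
  say("call: %d sites (%d tRNA, %d mRNA)", nrow(sites),
      sum(sites$kind == "tRNA"), sum(sites$kind == "CDS"))
  tmat <- stage("call", trna_matrix(fc, ref$features))
  stalls <- stage("stalls", {
    detect_stalls(sites[sites$kind == "CDS", , drop = FALSE], ref)
  })
  say("stalls: %d calls, %d toxin-like excluded, %d edge-dropped",
      nrow(stalls$calls), nrow(stalls$excluded), stalls$n_edge_dropped)
  summ <- stall_summary(stalls$calls, config$min_rpm_stall)
  logo <- if (nrow(stalls$calls)) build_logo(stalls$calls$window) else NULL

  write_tsv(sites, file.path(outdir, "sites.tsv"))
  tm <- data.frame(trna = rownames(tmat), tmat, check.names = FALSE)
  write_tsv(tm, file.path(outdir, "trna_matrix.tsv"))
  stall_out <- stalls$calls
  write_tsv(stall_out, file.path(outdir, "stalls.tsv"))
  if (!is.null(logo)) {
    write_tsv(data.frame(base = rownames(logo$freq), logo$freq,
                         check.names = FALSE),
              file.path(outdir, "logo.tsv"))
  }
  write_tsv(summ, file.path(outdir, "stall_summary.tsv"))

  quants <- NULL
  shift <- NULL
  if (!is.null(config$spectral_counts)) {
    quants <- stage("proteome", {
      differential_translation(read_tsv(config$spectral_counts),
                               config$min_total_spectra, config$alpha,
                               codon_table = cds_codon_table(ref))
    })
    say("proteome: %d proteins retained, %d up, %d down", nrow(quants),
        sum(quants$class == "up"), sum(quants$class == "down"))
    write_tsv(quants, file.path(outdir, "quants.tsv"))
    shift <- lapply(c(AAA = "AAA", AAG = "AAG"), function(cd) {
      codon_shift_summary(quants, cd)
    })
    sh <- do.call(rbind, lapply(shift, `[[`, "distributions"))
    write_tsv(sh, file.path(outdir, "codon_shift.tsv"))
    say("codon shift rank-test p: AAA=%.3g AAG=%.3g",
        shift$AAA$rank_test_p, shift$AAG$rank_test_p)
  }

  resolved <- config
  class(resolved) <- NULL
  resolved$toxcut_version <-
    as.character(utils::packageVersion("toxcut"))
  yaml::write_yaml(resolved, file.path(outdir, "resolved_config.yaml"))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))

  invisible(list(reference = ref, trims = trims, tracks = tracks, fc = fc,
                 sites = sites, trna_matrix = tmat, stalls = stalls,
                 stall_summary = summ, logo = logo, quants = quants,
                 codon_shift = shift, log = log_lines))
}
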