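# toy reference: one plus-strand and one minus-strand CDS carrying the same
# transcript sequence, so strand handling can be checked by symmetry
toy_ref <- function(tx) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  pad <- strrep("G", 40)
  g <- paste0(pad, tx, pad, rc, pad)
  n <- nchar(tx)
  feats <- data.frame(id = c("plus", "minus"), contig = "c1",
                      start = c(41L, 41L + n + 40L),
                      end = c(40L + n, 40L + 2L * n + 40L),
                      strand = c("+", "-"), kind = "CDS",
                      stringsAsFactors = FALSE)
  as_reference(c(c1 = g), feats)
}

site_row <- function(ref, fid, gene_position, rpm = 100) {
  f <- ref$features[ref$features$id == fid, ]
  pos <- if (f$strand == "+") f$start + gene_position - 1L else
    f$end - gene_position + 1L
  data.frame(feature_id = fid, kind = "CDS", contig = f$contig, pos = pos,
             strand = f$strand, gene_position = gene_position,
             rpm_induced = rpm, rpm_uninduced = 1, fold_change = rpm,
             stringsAsFactors = FALSE)
}

# 90-nt transcript: for a cut at gene position 31 (5'-OH base = fragment
# position 1) the AAA codon sits at fragment position 15 (gene position 45)
tx_aaa <- paste0(strrep("GGC", 10), "CTGGTCGGCGGCTC", "AAA", strrep("G", 43))

test_that("toxin-like cut contexts are excluded, others retained", {
  for (ctx in list(c("TTT", TRUE), c("CTT", TRUE), c("GAA", FALSE),
                   c("ATT", FALSE), c("TCT", FALSE))) {
    tx <- paste0(strrep("GGC", 10), substr(ctx[1], 1, 2), "|",
                 substr(ctx[1], 3, 3), strrep("GCC", 19))
    tx <- sub("\\|", "", tx)
    ref <- toy_ref(tx)
    s <- site_row(ref, "plus", 33L)  # cut before the context's third base
    res <- filter_toxin_like(s, ref)
    if (as.logical(ctx[2])) {
      expect_equal(nrow(res$excluded), 1L, label = ctx[1])
    } else {
      expect_equal(nrow(res$retained), 1L, label = ctx[1])
    }
  }
  # site too close to the gene 5' end for a context check: kept, flagged
  ref <- toy_ref(tx_aaa)
  s <- site_row(ref, "plus", 2L)
  res <- filter_toxin_like(s, ref)
  expect_equal(nrow(res$retained), 1L)
  expect_true(res$retained$edge_flag)
})

test_that("windows are sense-strand, cut-centred, and strand-symmetric", {
  ref <- toy_ref(tx_aaa)
  sp <- site_row(ref, "plus", 31L)
  sm <- site_row(ref, "minus", 31L)
  wp <- extract_windows(sp, ref)
  wm <- extract_windows(sm, ref)
  expect_equal(nchar(wp$window), 50L)
  # the 5'-OH base sits at window index 26
  expect_identical(substr(wp$window, 26, 50),
                   substr(tx_aaa, 31, 55))
  expect_identical(wp$window, wm$window)

  # brute-force check of the plus-strand window interval
  g <- ref$seq[["c1"]]
  expect_identical(wp$window, substr(g, sp$pos - 25L, sp$pos + 24L))

  edge <- site_row(ref, "plus", 31L)
  edge$pos <- 10L  # within flank of the contig start
  we <- extract_windows(edge, ref)
  expect_equal(nrow(we), 0L)
  expect_equal(attr(we, "n_edge_dropped"), 1L)
})

test_that("logo columns are frequencies that sum to one", {
  w <- c("ACGT", "ACGT", "ACGT")
  lg <- build_logo(w)
  expect_equal(lg$n_sequences, 3L)
  expect_true(all(colSums(lg$freq) == 1))
  expect_equal(unname(lg$freq["A", 1]), 1)  # identical windows: unit columns

  lg2 <- build_logo(c("AAAA", "CAAA"))
  expect_equal(unname(lg2$freq[c("A", "C"), 1]), c(0.5, 0.5))
  expect_error(build_logo(character(0)), "zero windows")
  expect_error(build_logo(c("AC", "ACGT")), "equal length")
})

test_that("codon classification prefers +15 and searches nearby offsets", {
  pad25 <- strrep("G", 25)
  win <- function(downstream) paste0(pad25, substr(downstream, 1, 25))
  # AAA exactly at offset 15 (fragment position 15)
  d15 <- paste0(strrep("C", 14), "AAA", strrep("C", 8))
  expect_equal(classify_stall(win(d15)),
               list(codon_offset = 15L, codon_class = "AAA"))
  # AAG at 14, nothing at 15
  d14 <- paste0(strrep("C", 13), "AAG", strrep("C", 9))
  expect_equal(classify_stall(win(d14)),
               list(codon_offset = 14L, codon_class = "AAG"))
  d17 <- paste0(strrep("C", 16), "AAA", strrep("C", 6))
  expect_equal(classify_stall(win(d17))$codon_offset, 17L)
  # no Lys codon near +15
  expect_equal(classify_stall(win(strrep("C", 25)))$codon_class, "none")
  # an AAAA run is classifiable at 14 and 15; the preferred +15 wins
  d_both <- paste0(strrep("C", 13), "AAAA", strrep("C", 8))
  expect_equal(classify_stall(win(d_both))$codon_offset, 15L)
})

test_that("stall summary counts each transcript once at its best site", {
  calls <- data.frame(
    feature_id = c("a", "a", "b", "c"),
    codon_class = c("AAA", "AAG", "AAG", "none"),
    rpm_induced = c(50, 500, 20, 90),
    stringsAsFactors = FALSE)
  s <- stall_summary(calls)
  expect_equal(s$n_transcripts, 2L)
  expect_equal(s$n_AAG, 2L)  # transcript a keeps its higher-rpm AAG site
  expect_equal(s$pct_AAA, 0)

  # duplicating sites within a transcript changes nothing
  s2 <- stall_summary(rbind(calls, calls[2, ]))
  expect_equal(s2[, 1:4], s[, 1:4])

  empty <- stall_summary(calls[calls$codon_class == "none", ])
  expect_true(empty$undefined)
  expect_true(is.na(empty$pct_AAA))

  below <- stall_summary(calls, min_rpm = 1000)
  expect_equal(below$n_transcripts, 0L)
})

test_that("simulated stalls are recovered with the planted geometry", {
  p <- small_pipeline()
  sites <- call_sites(p$fc, p$built$reference$features)
  st <- detect_stalls(sites[sites$kind == "CDS", , drop = FALSE],
                      p$built$reference)
  off <- st$calls$codon_offset
  expect_equal(as.integer(names(which.max(table(off)))),
               p$cfg$footprint_offset)
  lg <- build_logo(st$calls$window)
  top <- rownames(lg$freq)[apply(lg$freq[, 40:42], 2, which.max)]
  expect_equal(top, c("A", "A", "A"))
})
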