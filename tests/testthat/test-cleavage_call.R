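feat1 <- data.frame(id = "g1", contig = "c1", start = 1L, end = 99L,
                    strand = "+", kind = "CDS", stringsAsFactors = FALSE)

test_that("rpm normalisation conserves mass and rejects empty tracks", {
  tr <- make_track(c(50L, 0L, rep(0L, 97L)), total = 1e6)
  rpm <- normalize_rpm(tr)
  expect_equal(rpm$counts$c1[["+"]][1], 50)
  expect_equal(rpm$counts$c1[["+"]][2], 0)
  tr2 <- make_track(c(10L, 30L, 60L, rep(0L, 96L)), total = 100L)
  rpm2 <- normalize_rpm(tr2)
  expect_equal(sum(rpm2$counts$c1[["+"]]), 1e6)
  expect_error(normalize_rpm(make_track(integer(99), total = 0L)), "total_mapped")
})

test_that("pseudocount rule gives the hand-computed fold changes", {
  ind <- make_track(c(100L, 100L, 0L, rep(0L, 96L)), total = 1e6)
  un <- make_track(c(0L, 100L, 0L, rep(0L, 96L)), total = 1e6)
  fc <- fold_change_track(ind, un)
  tr <- fc$tracks$c1[["+"]]
  expect_equal(tr$fold[1], 100)   # uninduced 0 -> pseudocount 1
  expect_equal(tr$fold[2], 1)     # equal counts, equal depth
  expect_equal(tr$fold[3], 0)     # induced 0 stays 0
  # raw-0 uninduced positions sit exactly at the pseudocount rpm floor
  expect_equal(tr$rpm_uninduced[1], 1e6 / 1e6)
  expect_true(all(tr$fold >= 0))

  # depth imbalance: same raw counts, doubled induced depth -> fold 0.5
  ind2 <- make_track(c(100L, rep(0L, 98L)), total = 2e6)
  un2 <- make_track(c(100L, rep(0L, 98L)), total = 1e6)
  expect_equal(fold_change_track(ind2, un2)$tracks$c1[["+"]]$fold[1], 0.5)

  short <- make_track(c(1L, rep(0L, 49L)), total = 10L)
  expect_error(fold_change_track(ind, short), "different references")
})

test_that("thresholds are inclusive on rpm and strict on fold change", {
  # per-million totals make raw counts equal rpm
  mk <- function(ind_counts, un_counts) {
    fold_change_track(make_track(ind_counts, total = 1e6),
                      make_track(un_counts, total = 1e6))
  }
  trna <- feat1
  trna$kind <- "tRNA"
  trna$end <- 76L

  ind <- integer(99)
  un <- integer(99)
  ind[10] <- 49L   # below the 50-rpm tRNA floor despite huge fold
  fc <- mk(ind, un)
  expect_equal(nrow(call_sites(fc, trna)), 0L)
  ind[10] <- 50L   # at the floor: "at least 50 rpm" is inclusive
  expect_equal(nrow(call_sites(mk(ind, un), trna)), 1L)

  ind10 <- integer(99)
  un10 <- integer(99)
  ind10[20] <- 60L
  un10[20] <- 6L   # fold exactly 10.0 -> excluded (strict >)
  expect_equal(nrow(call_sites(mk(ind10, un10), feat1)), 0L)
  un10[20] <- 5L   # fold 12 > 10
  sites <- call_sites(mk(ind10, un10), feat1)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$gene_position, 20L)
})

test_that("raising thresholds never adds sites", {
  fc <- small_pipeline()$fc
  feats <- small_pipeline()$built$reference$features
  base <- call_sites(fc, feats)
  stricter <- call_sites(fc, feats, min_rpm_trna = 100, min_rpm_mrna = 10,
                         min_fold = 20)
  key <- function(s) paste(s$feature_id, s$pos, s$strand)
  expect_true(all(key(stricter) %in% key(base)))
  expect_lte(nrow(stricter), nrow(base))
})

test_that("minus-strand gene positions count from the feature 3' end", {
  ind <- integer(99)
  ind[30] <- 100L
  fc <- fold_change_track(make_track(integer(99), total = 1e6,
                                     counts_minus = ind),
                          make_track(integer(99), total = 1e6))
  f <- feat1
  f$strand <- "-"
  sites <- call_sites(fc, f)
  expect_equal(sites$gene_position, 99L - 30L + 1L)
})

test_that("overlapping features duplicate a site with a warning", {
  ind <- integer(99)
  ind[30] <- 100L
  fc <- fold_change_track(make_track(ind, total = 1e6),
                          make_track(integer(99), total = 1e6))
  two <- rbind(feat1, within(feat1, id <- "g2"))
  expect_warning(sites <- call_sites(fc, two), "overlapping")
  expect_equal(nrow(sites), 2L)
})

test_that("simulated toxin cuts are recovered at mature position 36 only in Lys tRNAs", {
  p <- small_pipeline()
  feats <- p$built$reference$features
  sites <- call_sites(p$fc, feats)
  trna_sites <- sites[sites$kind == "tRNA", ]
  expect_setequal(unique(trna_sites$feature_id),
                  c("tRNA-Lys-TTT", "tRNA-Lys-CTT"))
  expect_true(all(trna_sites$gene_position == 36L))

  m <- trna_matrix(p$fc, feats)
  expect_equal(nrow(m), 47L)
  # specificity: thresholded signal anywhere in a row only for the Lys pair
  rpm_ind <- lapply(seq_len(nrow(feats)), function(i) NULL)
  passing <- rownames(m)[apply(m > 10, 1, any)]
  hot <- vapply(rownames(m), function(id) {
    f <- feats[feats$id == id, ]
    tr <- p$fc$tracks[[f$contig]][[f$strand]]
    any(tr$rpm_induced[f$start:f$end] >= 50 & tr$fold[f$start:f$end] > 10)
  }, logical(1))
  expect_setequal(names(hot)[hot], c("tRNA-Lys-TTT", "tRNA-Lys-CTT"))
})

test_that("identical libraries produce no calls", {
  p <- small_pipeline()
  idx <- build_index(p$built$reference)
  tr <- map_and_count(idx, p$trimmed$uninduced$reads, "x")
  fc <- fold_change_track(tr, tr)
  expect_equal(nrow(call_sites(fc, p$built$reference$features)), 0L)
  expect_true(max(trna_matrix(fc, p$built$reference$features)) <= 1)
})
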