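test_that("levenshtein matches the full DP oracle", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0L)
  expect_equal(levenshtein("AAAAAA", "AAATAA"), 1L)
  expect_equal(levenshtein("ACGTACGT", "AGTACGTT"), 2L)
  # property: agreement with utils::adist on random pairs
  set.seed(99)
  a <- random_dna(200, 12)
  b <- c(a[1:50],                       # identical
         random_dna(150, sample(8:16, 150, replace = TRUE)))
  oracle <- as.integer(mapply(function(x, y) utils::adist(x, y), a, b))
  expect_equal(levenshtein(a, b), oracle)
})

test_that("percent_levenshtein weights by the longer length", {
  expect_equal(percent_levenshtein("ACGT", "ACGT"), 0)
  expect_equal(percent_levenshtein("ACGT", "ACGA"), 25)
  expect_equal(percent_levenshtein("AC", "ACGT"), 50)
  expect_error(percent_levenshtein("", "ACGT"), "empty")
})

fake_reads <- function(barcode, tcr) {
  data.table::data.table(
    read_id = sprintf("r%d", seq_along(barcode)), status = "ok",
    v = 1L, j = 2L, v_deletions = 0L, j_deletions = 0L, insert = "",
    barcode = barcode, inter_tag_seq = tcr, inter_tag_qual = NA_character_,
    rev_comp = FALSE)
}

test_that("group_by_barcode groups exactly and breaks ties lexicographically", {
  r <- fake_reads(c("AAAA", "AAAA", "CCCC"),
                  c("TTTT", "TTTT", "GGGG"))
  gr <- group_by_barcode(r)
  expect_equal(sort(gr$groups$size), c(1L, 2L))
  expect_equal(nrow(gr$groups), 2L)

  # frequency tie resolved towards the lexicographically smaller TCR
  r2 <- fake_reads(rep("AAAA", 4), c("TTGG", "TTGG", "GGTT", "GGTT"))
  gr2 <- group_by_barcode(r2)
  expect_identical(gr2$tcr_levels[gr2$groups$top_tcr], "GGTT")

  # empty input
  gr0 <- group_by_barcode(fake_reads(character(0), character(0)))
  expect_equal(nrow(gr0$groups), 0L)
})

test_that("merge_groups merges within thresholds and only then", {
  tcr <- strrep("ACGT", 10)
  # barcodes one edit apart, identical dominant TCRs
  r <- fake_reads(c(rep("AAAAAA", 3), rep("AAATAA", 2)), tcr)
  cl <- merge_groups(group_by_barcode(r), collapse_config(th_bc = 2, th_tcr = 10))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 5L)
  expect_identical(cl$barcode, "AAAAAA")  # larger group keeps the barcode

  # barcodes three edits apart stay separate at th_bc = 2
  r2 <- fake_reads(c(rep("AAAAAA", 3), rep("ATTTAA", 2)), tcr)
  cl2 <- merge_groups(group_by_barcode(r2), collapse_config(th_bc = 2))
  expect_equal(nrow(cl2), 2L)

  # dominant TCRs too far apart block the merge
  r3 <- fake_reads(c(rep("AAAAAA", 3), rep("AAATAA", 2)),
                   c(rep(tcr, 3), rep(strrep("GGCC", 10), 2)))
  cl3 <- merge_groups(group_by_barcode(r3), collapse_config())
  expect_equal(nrow(cl3), 2L)

  # degenerate thresholds: clusters == groups
  cl4 <- merge_groups(group_by_barcode(r),
                      collapse_config(th_bc = 0, th_tcr = 0))
  expect_equal(nrow(cl4), 2L)
})

test_that("collapse_clusters votes one consensus per cluster", {
  cl <- data.table::data.table(
    cluster = 1:3, barcode = c("A", "B", "C"),
    size = c(4L, 6L, 3L),
    top_tcr = c("S1", "S1", "S2"), n_groups = 1L)
  reads <- data.table::data.table(
    status = "ok", v = c(1L, 1L, 2L), j = 3L, v_deletions = 0L,
    j_deletions = 0L, insert = c("", "", "AT"),
    inter_tag_seq = c("S1", "S1", "S2"))
  out <- collapse_clusters(cl, reads)
  expect_equal(nrow(out), 2L)
  s1 <- out[out$v == 1L, ]
  expect_equal(s1$tcr_count, 2L)
  expect_equal(s1$bc_count, 5)
  s2 <- out[out$v == 2L, ]
  expect_equal(s2$tcr_count, 1L)
  expect_equal(s2$bc_count, 3)
  # sorted by descending support
  expect_equal(out$tcr_count, c(2L, 1L))
})

test_that("read count is conserved through grouping and merging", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 150, seed = 55, pcr_rounds = 3L)
  truth <- simulate_repertoire(cfg, ts)
  reads <- simulate_sequencing(simulate_pcr(truth, cfg), cfg)
  ann <- annotate_reads(reads$tcr_seq, ts,
                        barcodes = extract_umi(reads$umi_seq))
  res <- collapse_reads(ann)
  expect_equal(sum(res$clusters$size), sum(ann$status == "ok"))
  expect_equal(sum(res$clusters$n_groups),
               length(unique(ann$barcode[ann$status == "ok"])))
})

test_that("cluster count is monotone non-increasing in both thresholds", {
  set.seed(404)
  base <- random_dna(30, 12)
  bcs <- c(base, vapply(base[1:15], function(b) {
    p <- sample(12, 1); substr(b, p, p) <- sample(c("A","C","G","T"), 1); b
  }, ""))
  tcrs <- random_dna(45, 60)[c(rep(1:30, length.out = 45))]
  r <- fake_reads(bcs, tcrs)
  gr <- group_by_barcode(r)
  prev_by_bc <- Inf
  for (th_bc in c(0, 1, 2, 4)) {
    n <- nrow(merge_groups(gr, collapse_config(th_bc = th_bc, th_tcr = 20)))
    expect_lte(n, prev_by_bc)
    prev_by_bc <- n
  }
  prev_by_tcr <- Inf
  for (th_tcr in c(0, 5, 20, 60)) {
    n <- nrow(merge_groups(gr, collapse_config(th_bc = 2, th_tcr = th_tcr)))
    expect_lte(n, prev_by_tcr)
    prev_by_tcr <- n
  }
})

test_that("collapse output is invariant to input read order", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 80, seed = 66, pcr_rounds = 3L)
  truth <- simulate_repertoire(cfg, ts)
  reads <- simulate_sequencing(simulate_pcr(truth, cfg), cfg)
  ann <- annotate_reads(reads$tcr_seq, ts,
                        barcodes = extract_umi(reads$umi_seq))
  res1 <- collapse_reads(ann)$collapsed
  set.seed(1)
  res2 <- collapse_reads(ann[sample(nrow(ann)), ])$collapsed
  key <- function(d) sort(paste(cls_key(d), d$tcr_count, d$bc_count))
  expect_identical(key(res1), key(res2))
})

test_that("error-free input with distinct UMIs reproduces the truth exactly", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 120, seed = 77, pcr_rounds = 3L,
                    pcr_error_rate = 0, seq_error_rate = 0)
  truth <- simulate_repertoire(cfg, ts)
  reads <- simulate_sequencing(simulate_pcr(truth, cfg), cfg)
  ann <- annotate_reads(reads$tcr_seq, ts,
                        barcodes = extract_umi(reads$umi_seq))
  res <- collapse_reads(ann)
  sc <- score_collapse(res$collapsed, truth, ts)
  expect_equal(sc$n_lost, 0L)
  expect_equal(sc$n_spurious, 0L)
  expect_equal(sc$abundance_r, 1)
  # abundances equal the ground-truth molecule counts exactly
  m <- merge(res$collapsed, truth, by = c("v", "j", "v_deletions",
                                          "j_deletions", "insert"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(m$tcr_count, m$abundance)
})

test_that("collapsed tables round-trip through the text format", {
  col <- data.table::data.table(v = c(1L, 2L), j = c(7L, 8L),
                                v_deletions = c(0L, 3L),
                                j_deletions = c(2L, 0L),
                                insert = c("", "GGC"),
                                tcr_count = c(5L, 1L),
                                bc_count = c(12.5, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_collapsed(col, path)
  expect_equal(read_collapsed(path), col)
})
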