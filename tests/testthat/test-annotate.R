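# Independent single-read oracle: straightforward character-walk
# re-implementation of tag search + deletion counting used to check the
# batch annotator.
oracle_classify <- function(read, ts) {
  g <- ts$genes; tags <- ts$tags
  hits <- naive_scan(tags$keyword, read)
  seg <- tags$segment[hits$keyword]
  vh <- hits[seg == "V", , drop = FALSE]
  jh <- hits[seg == "J", , drop = FALSE]
  if (nrow(vh) != 1L || nrow(jh) != 1L) return(NULL)
  vt <- vh$keyword; jt <- jh$keyword
  vg <- tags$gene[vt]; jg <- tags$gene[jt]
  vend_read <- vh$start + nchar(tags$keyword[vt]) - 1L
  vend_gene <- tags$offset[vt] + nchar(tags$keyword[vt]) - 1L
  i <- 0L
  while (vend_read + i + 1L <= nchar(read) &&
         vend_gene + i + 1L <= g$length[vg] &&
         substr(read, vend_read + i + 1L, vend_read + i + 1L) ==
         substr(g$sequence[vg], vend_gene + i + 1L, vend_gene + i + 1L))
    i <- i + 1L
  vdel <- g$length[vg] - vend_gene - i
  jstart <- jh$start; joff <- tags$offset[jt]
  k <- 0L
  while (jstart - k - 1L >= 1L && joff - k - 1L >= 1L &&
         substr(read, jstart - k - 1L, jstart - k - 1L) ==
         substr(g$sequence[jg], joff - k - 1L, joff - k - 1L))
    k <- k + 1L
  jdel <- joff - 1L - k
  ins_start <- vend_read + i + 1L
  ins_end <- jstart - k - 1L
  if (ins_end < ins_start - 1L) {
    over <- (ins_start - 1L) - ins_end
    k <- k - over; jdel <- jdel + over; ins_end <- jstart - k - 1L
  }
  list(v = vg, j = jg, v_deletions = vdel, j_deletions = jdel,
       insert = substr(read, ins_start, ins_end))
}

# hand-buildable mini reference with explicit tags (placement chosen so
# deletions never touch a tag)
mini_tagset <- function() {
  set.seed(77)
  v <- random_dna(1, 30)
  substr(v, 29, 30) <- "AC"
  j <- random_dna(1, 24)
  substr(j, 1, 3) <- "TTG"
  g <- data.frame(name = c("V1", "J1"), segment = c("V", "J"),
                  sequence = c(v, j), length = c(30L, 24L),
                  conserved_pos = c(22L, 4L),
                  cdr1_start = NA, cdr1_end = NA,
                  cdr2_start = NA, cdr2_end = NA,
                  stringsAsFactors = FALSE)
  class(g) <- c("germline_set", "data.frame")
  tags <- data.frame(keyword = c(substr(v, 5, 16), substr(j, 10, 21)),
                     gene = c(1L, 2L), gene_name = c("V1", "J1"),
                     segment = c("V", "J"), offset = c(5L, 10L),
                     stringsAsFactors = FALSE)
  attr(tags, "ambiguous") <- data.frame(gene = integer(0),
                                        representative = integer(0))
  tag_set(g, tags = tags)
}

test_that("constructed rearrangements yield their exact classifier", {
  ts <- mini_tagset()
  g <- ts$genes
  # no deletions, no insert
  r0 <- paste0(g$sequence[1], g$sequence[2])
  a0 <- annotate_reads(r0, ts)
  expect_identical(a0$status, "ok")
  expect_identical(cls_key(a0), "1 2 0 0 ")

  # 2 V deletions + GGC insert + 3 J deletions (boundaries mismatch
  # germline by construction, so the tuple is canonical)
  r1 <- paste0(substr(g$sequence[1], 1, 28), "GGC",
               substr(g$sequence[2], 4, 24))
  a1 <- annotate_reads(r1, ts)
  expect_identical(cls_key(a1), "1 2 2 3 GGC")
  expect_false(a1$rev_comp)

  # reverse complement recovers the same classifier, flagged
  rc1 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r1)))
  a2 <- annotate_reads(rc1, ts)
  expect_identical(cls_key(a2), "1 2 2 3 GGC")
  expect_true(a2$rev_comp)
  expect_identical(a2$inter_tag_seq, a1$inter_tag_seq)

  # a long insert is recovered verbatim
  set.seed(5)
  ins <- random_dna(1, 15)
  r3 <- paste0(substr(g$sequence[1], 1, 28), ins,
               substr(g$sequence[2], 4, 24))
  a3 <- annotate_reads(r3, ts)
  expect_identical(a3$insert, oracle_classify(r3, ts)$insert)
})

test_that("no-calls carry their reason code", {
  ts <- mini_tagset()
  g <- ts$genes
  set.seed(11)
  expect_identical(annotate_reads(random_dna(1, 80), ts)$status, "no_v")
  # V tag but no J tag
  expect_identical(annotate_reads(g$sequence[1], ts)$status, "no_j")
  # two V tag occurrences
  r <- paste0(g$sequence[1], g$sequence[1], g$sequence[2])
  expect_identical(annotate_reads(r, ts)$status, "multiple_v")
  r <- paste0(g$sequence[1], g$sequence[2], g$sequence[2])
  expect_identical(annotate_reads(r, ts)$status, "multiple_j")
  # J upstream of V
  r <- paste0(g$sequence[2], g$sequence[1])
  expect_identical(annotate_reads(r, ts)$status, "order_violation")
})

test_that("annotation round-trips error-free simulated reads exactly", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 300, seed = 303)
  truth <- simulate_repertoire(cfg, ts)
  ann <- annotate_reads(truth$sequence, ts)
  expect_true(all(ann$status == "ok"))
  # unambiguous tag set: 100% classifier recovery
  expect_identical(cls_key(ann), cls_key(truth))

  # agreement with the independent walk oracle on a subsample
  for (i in seq(1, 300, by = 12)) {
    o <- oracle_classify(truth$sequence[i], ts)
    expect_identical(cls_key(ann[i, ]), cls_key(o))
  }

  # idempotence: reconstruct from the called classifier and re-annotate
  rec <- reconstruct_sequence(ann$v, ann$j, ann$v_deletions,
                              ann$j_deletions, ann$insert, ts$genes)
  ann2 <- annotate_reads(rec, ts)
  expect_identical(cls_key(ann2), cls_key(ann))

  # strand symmetry
  idx <- seq(1, 300, by = 23)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(truth$sequence[idx])))
  arc <- annotate_reads(rc, ts)
  expect_identical(cls_key(arc), cls_key(ann[idx, ]))
  expect_true(all(arc$rev_comp))
})

test_that("extract_umi follows the configured window layout", {
  # default: two 6-mers flanking a 4-nt spacer
  read <- paste0("AAAAAA", "TTTT", "CCCCCC", "GG")
  expect_identical(extract_umi(read), "AAAAAACCCCCC")
  # too short is a no-call
  expect_true(is.na(extract_umi("AAAAAATTTTCCC")))
  # single 12-nt window at offset 0
  expect_identical(extract_umi(strrep("ACGT", 4), umi_spec(list(c(1L, 12L)))),
                   "ACGTACGTACGT")
})

test_that("process_fastq annotates record-synchronised pairs", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 100, seed = 404, pcr_rounds = 0L,
                    pcr_error_rate = 0, seq_error_rate = 0)
  truth <- simulate_repertoire(cfg, ts)
  reads <- simulate_sequencing(simulate_pcr(truth, cfg), cfg)
  fq <- write_test_fastq(reads)
  out <- process_fastq(fq["tcr"], fq["umi"], ts)
  expect_equal(unname(out$stats["total"]), nrow(reads))
  expect_equal(unname(out$stats["ok"]), nrow(reads))
  expect_identical(sort(unique(cls_key(out$reads))), sort(cls_key(truth)))
  expect_identical(out$reads$barcode[1],
                   extract_umi(reads$umi_seq[match(out$reads$read_id[1],
                                                   reads$read_id)]))

  # empty FASTQ pair
  dir <- withr::local_tempdir()
  e1 <- file.path(dir, "e1.fastq"); e2 <- file.path(dir, "e2.fastq")
  file.create(e1, e2)
  out0 <- process_fastq(e1, e2, ts)
  expect_equal(nrow(out0$reads), 0L)
  expect_equal(unname(out0$stats["total"]), 0L)

  # desynchronised pair lengths are a hard error
  fq1 <- readLines(fq["tcr"])
  writeLines(fq1[1:(length(fq1) - 4)], file.path(dir, "short.fastq"))
  expect_error(process_fastq(fq["tcr"], file.path(dir, "short.fastq"), ts),
               "desynchronised")
})
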