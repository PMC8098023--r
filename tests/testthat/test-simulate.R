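test_that("repertoire generation is deterministic and degenerate cases hold", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 200, seed = 21)
  t1 <- simulate_repertoire(cfg, ts)
  t2 <- simulate_repertoire(cfg, ts)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 200L)
  expect_equal(anyDuplicated(cls_key(t1)), 0L)
  expect_true(all(t1$abundance >= 1L))
  expect_identical(t1$sequence,
                   reconstruct_sequence(t1$v, t1$j, t1$v_deletions,
                                        t1$j_deletions, t1$insert,
                                        ts$genes))

  # zero deletion / insert means: pure V+J concatenations (only
  # n_V x n_J = 24 classifiers exist in this degenerate space)
  cfg0 <- sim_config(n_tcrs = 20, seed = 22, v_del_mean = 0,
                     j_del_mean = 0, insert_len_mean = 0)
  t0 <- simulate_repertoire(cfg0, ts)
  expect_true(all(t0$v_deletions == 0L))
  expect_true(all(t0$j_deletions == 0L))
  expect_true(all(t0$insert == ""))
  expect_identical(t0$sequence,
                   paste0(ts$genes$sequence[t0$v], ts$genes$sequence[t0$j]))
})

test_that("PCR doubling conserves copy number and propagates errors", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 40, seed = 31, pcr_rounds = 3L,
                    pcr_error_rate = 0)
  truth <- simulate_repertoire(cfg, ts)
  mol <- simulate_pcr(truth, cfg)
  expect_equal(nrow(mol), sum(truth$abundance) * 2^3)
  # error-free copies identical to their origin
  expect_identical(mol$seq, truth$sequence[match(mol$origin, truth$id)])
  # one UMI per pre-PCR molecule
  expect_equal(length(unique(paste(mol$molecule, mol$umi))),
               length(unique(mol$molecule)))

  # single molecule, 3 rounds -> 8 copies sharing one UMI
  one <- truth[1, ]; one$abundance <- 1L
  m1 <- simulate_pcr(one, cfg)
  expect_equal(nrow(m1), 8L)
  expect_equal(length(unique(m1$umi)), 1L)
})

test_that("per-copy PCR mutation load matches its closed-form expectation", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 5, seed = 41, pcr_rounds = 4L,
                    pcr_error_rate = 2e-3, abundance_lambda = 20)
  truth <- simulate_repertoire(cfg, ts)
  mol <- simulate_pcr(truth, cfg)
  len <- nchar(truth$sequence[1])
  d <- as.integer(mapply(function(x, y) utils::adist(x, y),
                         mol$seq, truth$sequence[match(mol$origin, truth$id)]))
  # expected substitutions per final copy: rate * len * rounds/2
  # (a copy made at round r accumulates r mutation opportunities;
  # averaging over the doubling tree gives rounds/2 per surviving copy)
  lambda <- cfg$pcr_error_rate * len * cfg$pcr_rounds / 2
  expect_lt(abs(mean(d) - lambda), 4 * sqrt(lambda / nrow(mol)) + 0.02)
})

test_that("sequencing preserves records and applies the error model", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 60, seed = 51, pcr_rounds = 2L,
                    seq_error_rate = 0)
  truth <- simulate_repertoire(cfg, ts)
  mol <- simulate_pcr(truth, cfg)
  reads <- simulate_sequencing(mol, cfg)
  expect_equal(nrow(reads), nrow(mol))
  expect_identical(reads$tcr_seq, mol$seq)
  expect_true(all(nchar(reads$tcr_qual) == nchar(reads$tcr_seq)))

  # UMI-read errors occur at the configured rate (binomial CI)
  cfg2 <- sim_config(n_tcrs = 60, seed = 52, pcr_rounds = 4L,
                     pcr_error_rate = 0, seq_error_rate = 5e-3,
                     abundance_lambda = 5)
  truth2 <- simulate_repertoire(cfg2, ts)
  mol2 <- simulate_pcr(truth2, cfg2)
  reads2 <- simulate_sequencing(mol2, cfg2)
  clean <- paste0(substr(mol2$umi, 1, 6), "GTCA", substr(mol2$umi, 7, 12))
  n_mut <- sum(mapply(function(x, y)
    sum(utf8ToInt(x) != utf8ToInt(y)), reads2$umi_seq, clean))
  n_bases <- sum(nchar(clean))
  p_hat <- n_mut / n_bases
  se <- sqrt(cfg2$seq_error_rate * (1 - cfg2$seq_error_rate) / n_bases)
  expect_lt(abs(p_hat - cfg2$seq_error_rate), 4 * se)
})

test_that("FASTQ output round-trips through the annotator", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 50, seed = 61, pcr_rounds = 1L,
                    pcr_error_rate = 0, seq_error_rate = 0)
  truth <- simulate_repertoire(cfg, ts)
  reads <- simulate_sequencing(simulate_pcr(truth, cfg), cfg)
  fq <- write_test_fastq(reads)
  out <- process_fastq(fq["tcr"], fq["umi"], ts)
  expect_equal(unname(out$stats["ok"]), nrow(reads))
  expect_setequal(unique(cls_key(out$reads)), cls_key(truth))
})

test_that("score_annotation counts exact classifier and junction matches", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 100, seed = 71)
  truth <- simulate_repertoire(cfg, ts)
  ann <- annotate_reads(truth$sequence, ts)
  sc <- score_annotation(ann, truth, truth$id, ts$genes)
  expect_equal(sc$classifier_accuracy, 1)   # unambiguous tags
  expect_equal(sc$junction_accuracy, 1)

  # swapping a truth V makes that read's classifier wrong
  truth2 <- data.table::copy(truth)
  truth2$v[1] <- ifelse(truth2$v[1] == 1L, 2L, 1L)
  sc2 <- score_annotation(ann, truth2, truth2$id, ts$genes)
  expect_equal(sc2$classifier_accuracy, 0.99)
})

test_that("score_collapse counts recovery, spurious and abundance fidelity", {
  ts <- make_toy_tagset()
  cfg <- sim_config(n_tcrs = 50, seed = 81)
  truth <- simulate_repertoire(cfg, ts)
  perfect <- data.table::data.table(
    v = truth$v, j = truth$j, v_deletions = truth$v_deletions,
    j_deletions = truth$j_deletions, insert = truth$insert,
    tcr_count = truth$abundance, bc_count = 10)
  sc <- score_collapse(perfect, truth, ts)
  expect_equal(sc$n_recovered, 50L)
  expect_equal(sc$n_lost, 0L)
  expect_equal(sc$n_spurious, 0L)
  expect_equal(sc$abundance_r, 1)

  # one alien classifier counts as spurious
  alien <- rbind(perfect, data.table::data.table(
    v = 1L, j = 7L, v_deletions = 12L, j_deletions = 25L,
    insert = "AATTCCGGAATTCCGG", tcr_count = 1L, bc_count = 1))
  sc2 <- score_collapse(alien, truth, ts)
  expect_equal(sc2$n_spurious, 1L)
  expect_equal(sc2$n_recovered, 50L)
})

test_that("the simulate-annotate-collapse chain is seed-deterministic", {
  ts <- make_toy_tagset()
  run <- function() {
    cfg <- sim_config(n_tcrs = 60, seed = 91, pcr_rounds = 2L)
    truth <- simulate_repertoire(cfg, ts)
    reads <- simulate_sequencing(simulate_pcr(truth, cfg), cfg)
    ann <- annotate_reads(reads$tcr_seq, ts,
                          barcodes = extract_umi(reads$umi_seq))
    collapse_reads(ann)$collapsed
  }
  expect_identical(run(), run())
})
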