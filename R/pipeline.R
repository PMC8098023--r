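#' Read and validate a dual-index sample sheet
#'
#' Tab-separated columns `sample`, `index1`, `index2`. Validation fails
#' when two samples' index pairs are within `2 * max_mismatch`
#' substitutions on both indices — such pairs could not be demultiplexed
#' unambiguously.
#'
#' @param path Sample sheet path.
#' @param max_mismatch Mismatch tolerance the sheet must support.
#' @return A data.frame with columns `sample`, `index1`, `index2`.
#' @export
read_sample_sheet <- function(path, max_mismatch = 1L) {
  s <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("sample", "index1", "index2") %in% names(s)))
    stop("sample sheet needs columns sample, index1, index2")
  if (anyDuplicated(s$sample)) stop("duplicate sample names")
  n <- nrow(s)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
      d1 <- .hamming(s$index1[i], s$index1[k])
      d2 <- .hamming(s$index2[i], s$index2[k])
      if (d1 <= 2L * max_mismatch && d2 <= 2L * max_mismatch)
        stop("index collision between samples '", s$sample[i], "' and '",
             s$sample[k], "' at mismatch tolerance ", max_mismatch)
    }
  }
  s
}

.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(.Machine$integer.max)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Index pair per record, parsed from Illumina-style description
# "... <read>:<filter>:<flags>:IDX1+IDX2".
.parse_indices <- function(headers) {
  m <- regmatches(headers,
                  regexpr("[ACGTN]+\\+[ACGTN]+$", headers))
  if (length(m) != length(headers))
    stop("record header without an INDEX1+INDEX2 field")
  parts <- strsplit(m, "+", fixed = TRUE)
  list(index1 = vapply(parts, `[`, "", 1L),
       index2 = vapply(parts, `[`, "", 2L))
}

#' Demultiplex a paired FASTQ by dual sample indices
#'
#' Assigns each record to the unique sample whose two indices are both
#' within `max_mismatch` substitutions of the record's index pair
#' (parsed from the Illumina-style `INDEX1+INDEX2` header field).
#' Records matching no sample, or more than one equally well, go to the
#' `undetermined` bin. Per-sample FASTQ pairs are written to `outdir`.
#'
#' @param fastq_tcr,fastq_umi Paired FASTQ paths.
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param outdir Output directory (created if needed).
#' @param max_mismatch Per-index substitution tolerance (default 1).
#' @return List with `files` (per-sample FASTQ pair paths) and `summary`
#'   (record counts per sample, including `undetermined`).
#' @export
demultiplex <- function(fastq_tcr, fastq_umi, sheet, outdir,
                        max_mismatch = 1L) {
  r1 <- Biostrings::readDNAStringSet(fastq_tcr, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fastq_umi, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("FASTQ pair desynchronised: ", length(r1), " vs ", length(r2))
  idx <- .parse_indices(names(r1))
  n <- length(r1)
  assign <- rep("undetermined", n)
  ns <- nrow(sheet)
  d <- matrix(0L, n, ns)
  for (s in seq_len(ns)) {
    d1 <- vapply(idx$index1, .hamming, 0L, b = sheet$index1[s])
    d2 <- vapply(idx$index2, .hamming, 0L, b = sheet$index2[s])
    d[, s] <- pmax(d1, d2)
  }
  best <- apply(d, 1L, which.min)
  bestd <- d[cbind(seq_len(n), best)]
  tied <- rowSums(d == bestd) > 1L
  hit <- bestd <= max_mismatch & !tied
  assign[hit] <- sheet$sample[best[hit]]

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bins <- c(sheet$sample, "undetermined")
  files <- list()
  for (b in bins) {
    sel <- which(assign == b)
    f1 <- file.path(outdir, paste0(b, "_tcr.fastq"))
    f2 <- file.path(outdir, paste0(b, "_umi.fastq"))
    Biostrings::writeXStringSet(
      r1[sel], f1, format = "fastq",
      qualities = Biostrings::BStringSet(
        as.character(S4Vectors::mcols(r1)$qualities)[sel]))
    Biostrings::writeXStringSet(
      r2[sel], f2, format = "fastq",
      qualities = Biostrings::BStringSet(
        as.character(S4Vectors::mcols(r2)$qualities)[sel]))
    files[[b]] <- c(tcr = f1, umi = f2)
  }
  summary <- vapply(bins, function(b) sum(assign == b), 0L)
  list(files = files, summary = summary)
}

#' Run the full annotation pipeline on one sample
#'
#' Chains annotation ([process_fastq()]), UMI collapse
#' ([collapse_reads()]) and AIRR translation ([translate_collapsed()]),
#' persisting each stage's output under `outdir` (`annotated.csv`,
#' `collapsed.csv`, `airr.tsv`, `stats.tsv`) so stages can be inspected
#' or rerun.
#'
#' @param fastq_tcr,fastq_umi Paired FASTQ paths for one sample.
#' @param tagset A [tag_set()].
#' @param outdir Output directory.
#' @param spec UMI layout.
#' @param cfg Collapse thresholds, see [collapse_config()].
#' @param min_umi_qual Optional UMI quality filter, see
#'   [process_fastq()].
#' @param drop_nonproductive Drop non-productive rows from the AIRR
#'   output (default keeps them).
#' @return List with `airr` (records data.frame), `collapsed`,
#'   `stats` (per-stage counts), `files`.
#' @export
run_pipeline <- function(fastq_tcr, fastq_umi, tagset, outdir,
                         spec = default_umi_spec(),
                         cfg = collapse_config(),
                         min_umi_qual = NULL,
                         drop_nonproductive = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- process_fastq(fastq_tcr, fastq_umi, tagset, spec = spec,
                       min_umi_qual = min_umi_qual,
                       out = file.path(outdir, "annotated.csv"))
  col <- collapse_reads(ann$reads, cfg)
  write_collapsed(col$collapsed, file.path(outdir, "collapsed.csv"))
  rec <- translate_collapsed(col$collapsed, tagset,
                             file.path(outdir, "airr.tsv"),
                             drop_nonproductive = drop_nonproductive)
  stats <- c(ann$stats,
             clusters = nrow(col$clusters),
             unique_tcrs = nrow(col$collapsed))
  utils::write.table(data.frame(stat = names(stats),
                                value = as.integer(stats)),
                     file.path(outdir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(airr = rec, collapsed = col$collapsed, stats = stats,
       files = file.path(outdir, c("annotated.csv", "collapsed.csv",
                                   "airr.tsv", "stats.tsv")))
}
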