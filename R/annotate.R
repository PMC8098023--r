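#' UMI layout specification
#'
#' Describes where the random UMI nucleotides sit on the UMI-bearing
#' read. The default layout is two 6-mers flanking a fixed 4-nt spacer
#' (12 random nt in total): positions 1-6 and 11-16.
#'
#' @param windows List of `c(start, length)` pairs (1-based) giving the
#'   random-nucleotide windows in read order.
#' @return An object of class `umi_spec`.
#' @export
umi_spec <- function(windows = list(c(1L, 6L), c(11L, 6L))) {
  stopifnot(length(windows) >= 1L,
            all(vapply(windows, length, 0L) == 2L))
  structure(list(windows = windows,
                 min_length = max(vapply(windows, function(w)
                   w[1] + w[2] - 1L, 0))),
            class = "umi_spec")
}

#' @rdname umi_spec
#' @export
default_umi_spec <- function() umi_spec()

#' Extract the UMI (barcode) from UMI-bearing reads
#'
#' Concatenates the configured random-nucleotide windows. Reads shorter
#' than the layout requires yield `NA` (a no-call).
#'
#' @param umi_reads Character vector of UMI-read sequences.
#' @param spec A [umi_spec()].
#' @return Character vector of barcodes (`NA` where the read is too
#'   short).
#' @export
extract_umi <- function(umi_reads, spec = default_umi_spec()) {
  stopifnot(inherits(spec, "umi_spec"))
  out <- rep(NA_character_, length(umi_reads))
  ok <- !is.na(umi_reads) & nchar(umi_reads) >= spec$min_length
  if (any(ok)) {
    parts <- lapply(spec$windows, function(w)
      substr(umi_reads[ok], w[1], w[1] + w[2] - 1L))
    out[ok] <- do.call(paste0, parts)
  }
  out
}

.rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Germline extension walk shared by the annotator and the simulator's
# classifier canonicalisation. All coordinates 1-based. Returns the
# five-part classifier fields for reads whose V/J tag positions are
# already known. The V-side germline match is maximised first, then the
# J side (deterministic tie-break when read nucleotides match germline on
# both sides).
.walk <- function(seqs, v_idx, j_idx, v_start_read, j_start_read,
                  v_off_gene, j_off_gene, v_kw_len, j_kw_len, genes) {
  gseq <- genes$sequence
  glen <- genes$length
  v_tag_end_read <- v_start_read + v_kw_len - 1L
  v_tag_end_gene <- v_off_gene + v_kw_len - 1L
  v_tail <- substr(gseq[v_idx], v_tag_end_gene + 1L, glen[v_idx])
  lcp <- .lcp_batch(seqs, v_tag_end_read + 1L, v_tail)
  v_del <- (glen[v_idx] - v_tag_end_gene) - lcp

  j_head <- substr(gseq[j_idx], 1L, j_off_gene - 1L)
  lcs <- .lcs_batch(seqs, j_start_read - 1L, j_head)
  j_del <- (j_off_gene - 1L) - lcs

  ins_start <- v_tag_end_read + lcp + 1L
  ins_end <- j_start_read - 1L - lcs
  overlap <- pmax(0L, (ins_start - 1L) - ins_end)
  lcs <- lcs - overlap
  j_del <- j_del + overlap
  ins_end <- j_start_read - 1L - lcs
  data.table::data.table(
    v = v_idx, j = j_idx,
    v_deletions = as.integer(v_del),
    j_deletions = as.integer(j_del),
    insert = substr(seqs, ins_start, ins_end),
    inter_start = v_start_read,
    inter_end = j_start_read + j_kw_len - 1L
  )
}

# One-orientation tag classification of a batch of sequences.
# Returns a data.table with status and, for ok reads, classifier fields.
.classify_batch <- function(seqs, tagset) {
  tags <- tagset$tags
  genes <- tagset$genes
  n <- length(seqs)
  hits <- trie_search(tagset$trie, seqs)
  seg <- tags$segment[hits$keyword]

  vc <- tabulate(hits$target[seg == "V"], nbins = n)
  jc <- tabulate(hits$target[seg == "J"], nbins = n)
  status <- rep("ok", n)
  status[vc > 1L] <- "multiple_v"
  status[jc > 1L & status == "ok"] <- "multiple_j"
  status[jc == 0L] <- "no_j"
  status[vc == 0L] <- "no_v"

  cand <- which(status == "ok")
  out <- data.table::data.table(
    idx = seq_len(n), status = status,
    v = NA_integer_, j = NA_integer_,
    v_deletions = NA_integer_, j_deletions = NA_integer_,
    insert = NA_character_,
    inter_start = NA_integer_, inter_end = NA_integer_)
  if (!length(cand)) return(out)

  vh <- hits[seg == "V" & hits$target %in% cand, , drop = FALSE]
  jh <- hits[seg == "J" & hits$target %in% cand, , drop = FALSE]
  vh <- vh[match(cand, vh$target), , drop = FALSE]
  jh <- jh[match(cand, jh$target), , drop = FALSE]
  v_tag <- vh$keyword; j_tag <- jh$keyword
  v_kw_len <- nchar(tags$keyword[v_tag])
  j_kw_len <- nchar(tags$keyword[j_tag])
  ord_ok <- (vh$start + v_kw_len - 1L) < jh$start
  out$status[cand[!ord_ok]] <- "order_violation"
  cand2 <- ord_ok
  if (!any(cand2)) return(out)

  w <- .walk(seqs[cand[cand2]],
             v_idx = tags$gene[v_tag[cand2]],
             j_idx = tags$gene[j_tag[cand2]],
             v_start_read = vh$start[cand2],
             j_start_read = jh$start[cand2],
             v_off_gene = tags$offset[v_tag[cand2]],
             j_off_gene = tags$offset[j_tag[cand2]],
             v_kw_len = v_kw_len[cand2],
             j_kw_len = j_kw_len[cand2],
             genes = genes)
  rows <- cand[cand2]
  for (col in names(w)) data.table::set(out, i = rows, j = col, value = w[[col]])
  out
}

#' Annotate reads with the five-part recombination classifier
#'
#' Searches each TCR-bearing read for exactly one V tag followed by
#' exactly one J tag (trying the reverse complement when the forward
#' orientation yields no call), counts germline V 3' / J 5' deletions by
#' maximal contiguous germline extension from the tag, and extracts the
#' non-templated insert between the trimmed segments. Failures are
#' no-calls with a reason code (`no_v`, `no_j`, `multiple_v`,
#' `multiple_j`, `order_violation`), never errors.
#'
#' @param tcr_seqs Character vector of TCR-read sequences.
#' @param tagset A [tag_set()].
#' @param barcodes Optional character vector of UMIs (recycled `NA`).
#' @param read_ids Optional read identifiers.
#' @param tcr_quals Optional per-base quality strings (same lengths as
#'   `tcr_seqs`).
#' @return A [data.table::data.table] with one row per read: `read_id`,
#'   `status`, `v`, `j` (gene indices into `tagset$genes`),
#'   `v_deletions`, `j_deletions`, `insert`, `barcode`,
#'   `inter_tag_seq`, `inter_tag_qual`, `rev_comp`.
#' @export
annotate_reads <- function(tcr_seqs, tagset, barcodes = NULL,
                           read_ids = NULL, tcr_quals = NULL) {
  stopifnot(inherits(tagset, "tcr_tagset"))
  tcr_seqs <- as.character(tcr_seqs)
  n <- length(tcr_seqs)
  if (is.null(read_ids)) read_ids <- sprintf("read%d", seq_len(n))
  if (is.null(barcodes)) barcodes <- rep(NA_character_, n)
  if (!is.null(tcr_quals) &&
      any(nchar(tcr_quals) != nchar(tcr_seqs), na.rm = TRUE))
    stop("quality strings must match sequence lengths")

  res <- .classify_batch(tcr_seqs, tagset)
  res$rev_comp <- FALSE
  fail <- which(res$status != "ok")
  if (length(fail)) {
    rcseq <- .rc(tcr_seqs[fail])
    res2 <- .classify_batch(rcseq, tagset)
    fixed <- which(res2$status == "ok")
    if (length(fixed)) {
      rows <- fail[fixed]
      for (col in c("status", "v", "j", "v_deletions", "j_deletions",
                    "insert", "inter_start", "inter_end"))
        data.table::set(res, i = rows, j = col, value = res2[[col]][fixed])
      data.table::set(res, i = rows, j = "rev_comp", value = TRUE)
      tcr_seqs[rows] <- rcseq[fixed]
      if (!is.null(tcr_quals))
        tcr_quals[rows] <- vapply(strsplit(tcr_quals[rows], ""),
                                  function(x) paste(rev(x), collapse = ""),
                                  "")
    }
  }
  res$read_id <- read_ids
  res$barcode <- barcodes
  res$inter_tag_seq <- ifelse(res$status == "ok",
                              substr(tcr_seqs, res$inter_start, res$inter_end),
                              NA_character_)
  res$inter_tag_qual <- if (is.null(tcr_quals)) NA_character_ else
    ifelse(res$status == "ok",
           substr(tcr_quals, res$inter_start, res$inter_end),
           NA_character_)
  res[, c("read_id", "status", "v", "j", "v_deletions", "j_deletions",
          "insert", "barcode", "inter_tag_seq", "inter_tag_qual",
          "rev_comp"), with = FALSE]
}

#' Annotate a single read
#'
#' Convenience wrapper around [annotate_reads()] for one read plus its
#' UMI-bearing mate.
#'
#' @param tcr_seq TCR-read sequence.
#' @param tagset A [tag_set()].
#' @param umi_read Optional UMI-read sequence.
#' @param spec UMI layout, see [umi_spec()].
#' @inheritParams annotate_reads
#' @return A one-row data.table (see [annotate_reads()]).
#' @export
annotate_read <- function(tcr_seq, tagset, umi_read = NULL,
                          spec = default_umi_spec(), read_ids = NULL) {
  bc <- if (is.null(umi_read)) NA_character_ else extract_umi(umi_read, spec)
  annotate_reads(tcr_seq, tagset, barcodes = bc, read_ids = read_ids)
}

.phred_mean <- function(quals) {
  vapply(quals, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, 0)
}

#' Annotate a paired FASTQ (TCR read + UMI read)
#'
#' Applies [extract_umi()] and [annotate_reads()] to every read pair of a
#' record-synchronised FASTQ pair and returns the annotated reads in the
#' intermediate five-part annotation format together with run statistics.
#'
#' @param fastq_tcr,fastq_umi Paths to the TCR-bearing and UMI-bearing
#'   FASTQ files (optionally gzip-compressed). Files must be
#'   record-synchronised; a length or identifier mismatch is an error.
#' @param tagset A [tag_set()].
#' @param spec UMI layout, see [umi_spec()].
#' @param min_umi_qual Optional minimum mean Phred quality over the UMI
#'   windows; pairs below it become `low_umi_quality` no-calls (default
#'   off).
#' @param out Optional path; when given, annotated (status `ok`) reads
#'   are written there with [write_annotated()].
#' @return List with `reads` (the annotation data.table, all statuses)
#'   and `stats` (named counts per status).
#' @export
process_fastq <- function(fastq_tcr, fastq_umi, tagset,
                          spec = default_umi_spec(), min_umi_qual = NULL,
                          out = NULL) {
  r1 <- Biostrings::readDNAStringSet(fastq_tcr, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fastq_umi, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("FASTQ pair desynchronised: ", length(r1), " vs ", length(r2),
         " records")
  id1 <- sub("\\s.*$", "", names(r1))
  id2 <- sub("\\s.*$", "", names(r2))
  mism <- which(id1 != id2)
  if (length(mism))
    stop("FASTQ pair desynchronised at record ", mism[1],
         ": '", id1[mism[1]], "' vs '", id2[mism[1]], "'")

  umi_seq <- as.character(r2)
  bc <- extract_umi(umi_seq, spec)
  res <- annotate_reads(as.character(r1), tagset, barcodes = bc,
                        read_ids = id1,
                        tcr_quals = as.character(S4Vectors::mcols(r1)$qualities))
  short <- which(is.na(bc))
  if (length(short))
    data.table::set(res, i = short, j = "status", value = "umi_too_short")
  if (!is.null(min_umi_qual)) {
    q2 <- as.character(S4Vectors::mcols(r2)$qualities)
    umi_q <- extract_umi(q2, spec)
    low <- which(.phred_mean(umi_q) < min_umi_qual)
    if (length(low)) data.table::set(res, i = low, j = "status",
                                     value = "low_umi_quality")
  }
  stats <- c(total = nrow(res), table(res$status))
  if (!is.null(out)) write_annotated(res[res$status == "ok"], out, tagset)
  list(reads = res, stats = stats)
}

#' Write / read the intermediate five-part annotation format
#'
#' One line per annotated read, comma-separated:
#' `v_index, j_index, v_deletions, j_deletions, insert, read_id, barcode,
#' inter_tag_seq, inter_tag_qual`. Gene indices are 1-based positions in
#' the germline file order, which is recorded in `#` header comments for
#' reproducibility.
#'
#' @param reads Annotation data.table (only status-`ok` rows are
#'   written).
#' @param path Output path.
#' @param tagset Tag set used (its gene order is written to the header).
#' @export
write_annotated <- function(reads, path, tagset = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(tagset))
    writeLines(paste0("# gene_order=",
                      paste(tagset$genes$name, collapse = "|")), con)
  ok <- reads[reads$status == "ok", ]
  df <- data.frame(ok$v, ok$j, ok$v_deletions, ok$j_deletions, ok$insert,
                   ok$read_id, ok$barcode, ok$inter_tag_seq,
                   ifelse(is.na(ok$inter_tag_qual), "", ok$inter_tag_qual))
  utils::write.table(df, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotated
#' @export
read_annotated <- function(path) {
  df <- utils::read.csv(path, header = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE,
                        colClasses = c("integer", "integer", "integer",
                                       "integer", "character", "character",
                                       "character", "character", "character"))
  names(df) <- c("v", "j", "v_deletions", "j_deletions", "insert",
                 "read_id", "barcode", "inter_tag_seq", "inter_tag_qual")
  df$insert[is.na(df$insert)] <- ""
  df$status <- "ok"
  data.table::as.data.table(df)
}
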