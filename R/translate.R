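#' Reconstruct the rearranged nucleotide sequence from a classifier
#'
#' Inverse of the annotator: germline V minus its 3' deletions, then the
#' non-templated insert, then germline J minus its 5' deletions. The
#' germline fixtures are leaderless, so the reconstruction excludes the
#' leader by construction.
#'
#' @param v,j Gene indices (into `genes`), vectorised.
#' @param v_deletions,j_deletions Deletion counts.
#' @param insert Insert sequences.
#' @param genes A `germline_set`.
#' @return Character vector of reconstructed sequences.
#' @export
reconstruct_sequence <- function(v, j, v_deletions, j_deletions, insert,
                                 genes) {
  if (any(v_deletions < 0L) || any(j_deletions < 0L))
    stop("negative deletion count")
  if (any(v_deletions > genes$length[v]) ||
      any(j_deletions > genes$length[j]))
    stop("deletions exceed gene length")
  paste0(substr(genes$sequence[v], 1L, genes$length[v] - v_deletions),
         insert,
         substr(genes$sequence[j], j_deletions + 1L, genes$length[j]))
}

#' Translate DNA with the standard genetic code
#'
#' Stop codons become `*`; a trailing partial codon is dropped.
#'
#' @param dna Character vector of DNA sequences.
#' @param frame_offset Reading-frame offset in `{0, 1, 2}`.
#' @return Character vector of protein sequences.
#' @export
translate_dna <- function(dna, frame_offset = 0L) {
  stopifnot(all(frame_offset %in% 0:2))
  dna <- substr(dna, frame_offset + 1L, nchar(dna))
  ncod <- nchar(dna) %/% 3L
  vapply(seq_along(dna), function(i) {
    n <- ncod[i]
    if (is.na(n) || n == 0L) return("")
    codons <- substring(dna[i], 3L * seq_len(n) - 2L, 3L * seq_len(n))
    paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
  }, "")
}

#' Extract the junction (CDR3 plus conserved C and F) from a
#' reconstructed sequence
#'
#' The junction spans from the conserved cysteine codon of the V gene
#' (position known from the germline annotation) through the conserved
#' phenylalanine codon of the J gene, inclusive. Positions are located
#' from the per-gene annotated conserved positions, not by motif search.
#' Returns `NA` when either conserved codon has been deleted.
#'
#' @param v,j,v_deletions,j_deletions,insert Classifier fields
#'   (vectorised).
#' @param genes A `germline_set`.
#' @return A data.frame with `junction` (nucleotide) and `junction_aa`
#'   (amino acid, translated from the cysteine codon; a trailing partial
#'   codon of an out-of-frame junction is dropped). Both `NA` when the
#'   junction is unrecoverable.
#' @export
extract_junction <- function(v, j, v_deletions, j_deletions, insert,
                             genes) {
  lv <- genes$length[v]
  cp <- genes$conserved_pos[v]
  fp <- genes$conserved_pos[j]
  ins_len <- nchar(insert)
  v_kept <- lv - v_deletions
  # C codon [cp, cp+2] must survive V trimming; F codon [fp, fp+2] must
  # survive J trimming
  ok <- (v_kept >= cp + 2L) & (j_deletions < fp)
  jun_end <- v_kept + ins_len + (fp - j_deletions) + 2L
  seqs <- reconstruct_sequence(v, j, v_deletions, j_deletions, insert, genes)
  junction <- ifelse(ok, substr(seqs, cp, jun_end), NA_character_)
  junction_aa <- rep(NA_character_, length(junction))
  junction_aa[ok] <- translate_dna(junction[ok])
  data.frame(junction = junction, junction_aa = junction_aa,
             stringsAsFactors = FALSE)
}

#' Productivity of a rearrangement
#'
#' A rearrangement is productive when its junction was found, the
#' junction length is a multiple of 3, the junction amino-acid sequence
#' starts with C and ends with F, and the V-frame translation of the full
#' sequence contains no stop codon up to the end of the junction.
#'
#' @param junction,junction_aa From [extract_junction()].
#' @param seq_aa V-frame translation of the full reconstructed sequence.
#' @param cp Conserved cysteine position (1-based, in the full
#'   sequence) of the V gene, vectorised.
#' @return Logical vector.
#' @export
is_productive <- function(junction, junction_aa, seq_aa, cp) {
  n_aa_to_jun_end <- (cp - 1L) %/% 3L + nchar(junction) %/% 3L
  ok <- !is.na(junction) &
    nchar(junction) %% 3L == 0L &
    substr(junction_aa, 1L, 1L) == "C" &
    substr(junction_aa, nchar(junction_aa), nchar(junction_aa)) == "F" &
    !grepl("*", substr(seq_aa, 1L, n_aa_to_jun_end), fixed = TRUE)
  ok & !is.na(ok)
}

.airr_required <- c(
  "sequence_id", "sequence", "rev_comp", "productive",
  "v_call", "d_call", "j_call",
  "sequence_alignment", "germline_alignment",
  "junction", "junction_aa",
  "v_cigar", "d_cigar", "j_cigar",
  "duplicate_count")

#' Build AIRR rearrangement records from collapsed TCRs
#'
#' Reconstructs each collapsed classifier's full nucleotide sequence
#' (leader excluded), extracts and translates the junction, flags
#' productivity, attaches the IMGT CDR1/CDR2 of the called V gene, and
#' fills the AIRR Rearrangement required columns plus the custom columns
#' `cdr1_aa`, `cdr2_aa`, `sequence_aa`, `vdj_classifier` (the five-part
#' classifier, comma-joined) and `bc_count` (mean cluster size).
#' `d_call` is always empty (no D-segment tags); alignment and cigar
#' columns are emitted empty. One row per unique DNA classifier; rows
#' with equal `junction_aa` from distinct DNA are kept separate.
#'
#' @param collapsed Output of [collapse_clusters()] (a `rev_comp` column
#'   is honoured when present).
#' @param genes A `germline_set`.
#' @return A data.frame of AIRR records.
#' @export
make_airr <- function(collapsed, genes) {
  n <- nrow(collapsed)
  seqs <- reconstruct_sequence(collapsed$v, collapsed$j,
                               collapsed$v_deletions,
                               collapsed$j_deletions,
                               collapsed$insert, genes)
  jun <- extract_junction(collapsed$v, collapsed$j,
                          collapsed$v_deletions, collapsed$j_deletions,
                          collapsed$insert, genes)
  seq_aa <- translate_dna(seqs)
  cp <- genes$conserved_pos[collapsed$v]
  prod <- is_productive(jun$junction, jun$junction_aa, seq_aa, cp)
  cdr_aa <- function(side) {
    s <- genes[[paste0(side, "_start")]][collapsed$v]
    e <- genes[[paste0(side, "_end")]][collapsed$v]
    out <- rep("", n)
    has <- !is.na(s)
    out[has] <- translate_dna(substr(genes$sequence[collapsed$v[has]],
                                     s[has], e[has]))
    out
  }
  rc <- if (!is.null(collapsed$rev_comp)) collapsed$rev_comp else
    rep(FALSE, n)
  bc <- if (!is.null(collapsed$bc_count)) collapsed$bc_count else
    rep(NA_real_, n)
  dup <- if (!is.null(collapsed$tcr_count)) collapsed$tcr_count else
    rep(1L, n)
  blank <- character(n)
  data.frame(
    sequence_id = sprintf("tcr_%06d", seq_len(n)),
    sequence = seqs,
    rev_comp = ifelse(rc, "T", "F"),
    productive = ifelse(prod, "T", "F"),
    v_call = genes$name[collapsed$v],
    d_call = blank,
    j_call = genes$name[collapsed$j],
    sequence_alignment = blank,
    germline_alignment = blank,
    junction = ifelse(is.na(jun$junction), "", jun$junction),
    junction_aa = ifelse(is.na(jun$junction_aa), "", jun$junction_aa),
    v_cigar = blank,
    d_cigar = blank,
    j_cigar = blank,
    duplicate_count = dup,
    cdr1_aa = cdr_aa("cdr1"),
    cdr2_aa = cdr_aa("cdr2"),
    sequence_aa = seq_aa,
    vdj_classifier = paste(collapsed$v, collapsed$j,
                            collapsed$v_deletions, collapsed$j_deletions,
                            collapsed$insert, sep = ","),
    bc_count = bc,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
}

#' Write an AIRR rearrangement TSV
#'
#' Tab-separated, one row per unique DNA rearrangement, AIRR
#' Rearrangement required columns first. Provenance (schema release,
#' germline gene order) is recorded in `#` comment lines before the
#' header; [read_airr()] skips them. Non-productive rows are included
#' unless `drop_nonproductive`.
#'
#' @param records Output of [make_airr()].
#' @param path Output path.
#' @param drop_nonproductive Drop rows with `productive == "F"`.
#' @param comments Extra provenance comment lines.
#' @export
write_airr <- function(records, path, drop_nonproductive = FALSE,
                       comments = character(0)) {
  miss <- setdiff(.airr_required, names(records))
  if (length(miss))
    stop("records lack AIRR required column(s): ",
         paste(miss, collapse = ", "))
  if (drop_nonproductive) records <- records[records$productive != "F", ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# AIRR Rearrangement TSV (schema release 1.4)",
               comments), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_airr
#' @export
read_airr <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Translate collapsed TCRs straight to an AIRR file
#'
#' @inheritParams make_airr
#' @inheritParams write_airr
#' @param tagset Tag set (gene order is recorded in the header).
#' @return The records data.frame, invisibly.
#' @export
translate_collapsed <- function(collapsed, tagset, path,
                                drop_nonproductive = FALSE) {
  rec <- make_airr(collapsed, tagset$genes)
  write_airr(rec, path, drop_nonproductive = drop_nonproductive,
             comments = paste0("# gene_order=",
                               paste(tagset$genes$name, collapse = "|")))
  invisible(rec)
}
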