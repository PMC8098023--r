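#' Load a germline V/J reference set
#'
#' Reads a FASTA file of germline V and J gene sequences together with a
#' tab-separated annotation table giving, per gene, the segment type, the
#' position of the conserved residue codon (the CDR3-bracketing cysteine
#' for V genes, the phenylalanine for J genes) and, for V genes, the
#' IMGT-defined CDR1/CDR2 intervals.
#'
#' The annotation table must contain the columns `gene`, `segment` (one of
#' `"V"`, `"J"`), `conserved_pos` (1-based start of the conserved codon),
#' and `cdr1_start`, `cdr1_end`, `cdr2_start`, `cdr2_end` (1-based
#' inclusive, codon-aligned; `NA` for J genes). Lines starting with `#`
#' are ignored.
#'
#' Parsing is strict: sequences must be non-empty uppercase ACGT, every
#' gene needs an annotation row, gene names must be unique, conserved
#' codons and CDR intervals must lie within the sequence.
#'
#' @param fasta_path Path to the germline FASTA file.
#' @param annotation_path Path to the annotation TSV.
#' @return A `germline_set`: a data.frame with one row per gene, in file
#'   order, with columns `name`, `segment`, `sequence`, `length`,
#'   `conserved_pos`, `cdr1_start`, `cdr1_end`, `cdr2_start`, `cdr2_end`.
#' @export
load_germline <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm))
    stop("duplicate gene names in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sq <- as.character(seqs)
  if (any(nchar(sq) == 0L)) stop("empty sequence in FASTA")
  bad <- grepl("[^ACGT]", sq)
  if (any(bad))
    stop("sequence for gene(s) ", paste(nm[bad], collapse = ", "),
         " contains characters outside {A,C,G,T}")

  ann <- utils::read.delim(annotation_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  req <- c("gene", "segment", "conserved_pos",
           "cdr1_start", "cdr1_end", "cdr2_start", "cdr2_end")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stop("annotation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene))
    stop("duplicate gene names in annotation table")
  no_ann <- setdiff(nm, ann$gene)
  if (length(no_ann))
    stop("missing annotation for gene(s): ", paste(no_ann, collapse = ", "))

  idx <- match(nm, ann$gene)
  g <- data.frame(
    name = nm,
    segment = ann$segment[idx],
    sequence = unname(sq),
    length = nchar(sq),
    conserved_pos = as.integer(ann$conserved_pos[idx]),
    cdr1_start = as.integer(ann$cdr1_start[idx]),
    cdr1_end = as.integer(ann$cdr1_end[idx]),
    cdr2_start = as.integer(ann$cdr2_start[idx]),
    cdr2_end = as.integer(ann$cdr2_end[idx]),
    stringsAsFactors = FALSE
  )
  if (!all(g$segment %in% c("V", "J")))
    stop("segment must be 'V' or 'J'")
  bad <- which(is.na(g$conserved_pos) | g$conserved_pos < 1L |
                 g$conserved_pos + 2L > g$length)
  if (length(bad))
    stop("conserved_pos outside sequence for gene(s): ",
         paste(g$name[bad], collapse = ", "))
  for (sp in list(c("cdr1_start", "cdr1_end"), c("cdr2_start", "cdr2_end"))) {
    s <- g[[sp[1]]]; e <- g[[sp[2]]]
    has <- !is.na(s) & !is.na(e)
    bad <- which(has & (s < 1L | e > g$length | e < s |
                          (s - 1L) %% 3L != 0L | (e - s + 1L) %% 3L != 0L))
    if (length(bad))
      stop("CDR interval invalid (bounds or codon alignment) for gene(s): ",
           paste(g$name[bad], collapse = ", "))
  }
  class(g) <- c("germline_set", "data.frame")
  g
}

#' Bundled synthetic human-TRB-like germline reference
#'
#' Loads the packaged germline fixture: a synthetic reconstruction of a
#' human TRB locus subset (41 V genes, 13 J genes, IMGT-style names).
#' The sequences are not the IMGT reference sequences; they are generated
#' sequences whose ambiguity structure mirrors the human locus, in which
#' some V subfamily members (TRBV6-2/TRBV6-3, TRBV12-3/TRBV12-4,
#' TRBV6-5/TRBV6-6) are identical or near-identical and cannot be
#' distinguished by short tags.
#'
#' @return A `germline_set` (see [load_germline()]).
#' @export
trb_germline <- function() {
  load_germline(
    system.file("extdata", "synthetic_trb_germline.fasta",
                package = "tcrtag", mustWork = TRUE),
    system.file("extdata", "synthetic_trb_annotation.tsv",
                package = "tcrtag", mustWork = TRUE))
}

# Candidate tag start positions for one gene, in preference order:
# V tags as 3' as placement allows, J tags as 5' as placement allows, so
# that the inter-tag window brackets the junction.
.tag_candidates <- function(gene, tag_length, v_window, v_margin,
                            respect_conserved) {
  L <- gene$length
  if (gene$segment == "V") {
    hi <- if (respect_conserved) gene$conserved_pos - 1L - v_margin else L
    lo <- if (respect_conserved) max(1L, hi - tag_length + 1L - v_window) else 1L
    from <- hi - tag_length + 1L
    if (from < lo) starts <- integer(0)
    else starts <- seq.int(from = from, to = lo, by = -1L)
    starts <- starts[starts >= 1L]
  } else {
    lo <- if (respect_conserved) gene$conserved_pos + 3L else 1L
    hi <- L - tag_length + 1L
    if (hi < lo) starts <- integer(0)
    else starts <- seq.int(from = lo, to = hi, by = 1L)
  }
  starts
}

#' Derive identifying tags for a germline gene set
#'
#' For each gene, selects one substring of length `tag_length` that occurs
#' in no other gene of the set. V tags are placed as close to the 3' end
#' of the gene as the placement window allows; J tags as close to the 5'
#' end as possible, so the region between a read's V tag and J tag
#' brackets the recombination junction. When `respect_conserved = TRUE`
#' (the default), V tags are confined to a window of `v_window` nt ending
#' `v_margin` nt upstream of the conserved cysteine codon and J tags start
#' downstream of the conserved phenylalanine codon, keeping tags clear of
#' junctional trimming; with `respect_conserved = FALSE` the whole gene is
#' searchable.
#'
#' Genes for which no distinguishing substring exists (identical or
#' near-identical subfamily members) are handled according to
#' `on_ambiguous`:
#' \describe{
#'   \item{`"error"`}{fail, listing the indistinguishable genes;}
#'   \item{`"group"`}{assign one shared tag to the first member (in file
#'     order) of each indistinguishable group; the remaining members
#'     carry no tag of their own and reads from them are annotated with
#'     the group representative.}
#' }
#'
#' @param genes A `germline_set`.
#' @param tag_length Tag length in nt (default 20).
#' @param on_ambiguous `"error"` or `"group"` (see above).
#' @param v_window,v_margin V-tag placement window and upstream margin, nt.
#' @param respect_conserved Restrict placement relative to the conserved
#'   codons (see above).
#' @return A data.frame of tags: `keyword`, `gene` (row index into
#'   `genes`), `gene_name`, `segment`, `offset` (1-based start of the
#'   keyword in its gene), plus attribute `ambiguous`: a data.frame
#'   mapping untagged gene indices to their representative.
#' @export
build_tags <- function(genes, tag_length = 20L, on_ambiguous = "error",
                       v_window = 40L, v_margin = 6L,
                       respect_conserved = TRUE) {
  stopifnot(nrow(genes) > 0L, tag_length >= 1L)
  on_ambiguous <- match.arg(on_ambiguous, c("error", "group"))
  n <- nrow(genes)
  kw <- character(n); off <- integer(n)
  shared_with <- vector("list", n) # indices of other genes carrying the kmer

  for (i in seq_len(n)) {
    starts <- .tag_candidates(genes[i, ], tag_length, v_window, v_margin,
                              respect_conserved)
    if (!length(starts))
      stop("gene ", genes$name[i], " too short for tag_length ", tag_length)
    others <- genes$sequence[-i]
    best_s <- NA_integer_; best_hits <- NULL
    for (s in starts) {
      cand <- substr(genes$sequence[i], s, s + tag_length - 1L)
      hits <- which(vapply(others, function(x)
        grepl(cand, x, fixed = TRUE), logical(1)))
      if (!length(hits)) { best_s <- s; best_hits <- integer(0); break }
      if (is.null(best_hits) || length(hits) < length(best_hits)) {
        best_s <- s; best_hits <- hits
      }
    }
    kw[i] <- substr(genes$sequence[i], best_s, best_s + tag_length - 1L)
    off[i] <- best_s
    shared_with[[i]] <- seq_len(n)[-i][best_hits]
  }

  ambiguous_idx <- which(lengths(shared_with) > 0L)
  if (length(ambiguous_idx) && on_ambiguous == "error") {
    grp <- sort(unique(c(ambiguous_idx,
                         unlist(shared_with[ambiguous_idx]))))
    stop("no unique tag of length ", tag_length,
         " exists for indistinguishable gene(s): ",
         paste(genes$name[grp], collapse = ", "))
  }

  # group mode: representative = first member (file order) of each class
  rep_of <- seq_len(n)
  for (i in ambiguous_idx) rep_of[i] <- min(c(i, shared_with[[i]]))
  keep <- which(rep_of == seq_len(n))
  tags <- data.frame(
    keyword = kw[keep],
    gene = keep,
    gene_name = genes$name[keep],
    segment = genes$segment[keep],
    offset = off[keep],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(tags$keyword))
    stop("internal error: duplicate keywords across representatives")
  amb <- data.frame(gene = which(rep_of != seq_len(n)),
                    representative = rep_of[rep_of != seq_len(n)])
  attr(tags, "ambiguous") <- amb
  tags
}

#' Build a tag set: genes, tags and the compiled keyword trie
#'
#' Bundles a germline set with its derived (or externally supplied) tags
#' and the Aho-Corasick automaton compiled from the tag keywords.
#'
#' @param genes A `germline_set`.
#' @param tags Tag table from [build_tags()] (built with defaults when
#'   omitted).
#' @param ... Passed to [build_tags()] when `tags` is missing.
#' @return An object of class `tcr_tagset` with elements `genes`, `tags`,
#'   `trie`.
#' @export
tag_set <- function(genes, tags = NULL, ...) {
  if (is.null(tags)) tags <- build_tags(genes, ...)
  ts <- list(genes = genes, tags = tags, trie = build_trie(tags$keyword))
  class(ts) <- "tcr_tagset"
  ts
}

#' @export
print.tcr_tagset <- function(x, ...) {
  cat("<tcr_tagset> ", sum(x$genes$segment == "V"), " V / ",
      sum(x$genes$segment == "J"), " J genes, ",
      nrow(x$tags), " tags (length ",
      nchar(x$tags$keyword[1]), " nt)\n", sep = "")
  invisible(x)
}

#' Write / read a tag table
#'
#' Tags are serialized as a two-column tab-separated text file
#' (`keyword`, `gene_name`) with `offset` and `segment` as additional
#' columns, so externally curated tag files can be dropped in.
#'
#' @param tags Tag table from [build_tags()].
#' @param path Output / input file path.
#' @export
write_tags <- function(tags, path) {
  utils::write.table(tags[, c("keyword", "gene_name", "segment", "offset")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param genes The `germline_set` the tags refer to (gene names must
#'   resolve).
#' @rdname write_tags
#' @export
read_tags <- function(path, genes) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("keyword", "gene_name") %in% names(t)))
    stop("tag file must have columns 'keyword' and 'gene_name'")
  gi <- match(t$gene_name, genes$name)
  if (anyNA(gi))
    stop("tag file names unknown gene(s): ",
         paste(t$gene_name[is.na(gi)], collapse = ", "))
  if (is.null(t$offset)) {
    t$offset <- mapply(function(k, g) as.integer(regexpr(k, g, fixed = TRUE)),
                       t$keyword, genes$sequence[gi])
  }
  bad <- which(substr(genes$sequence[gi], t$offset,
                      t$offset + nchar(t$keyword) - 1L) != t$keyword)
  if (length(bad))
    stop("keyword does not occur at stated offset for gene(s): ",
         paste(t$gene_name[bad], collapse = ", "))
  out <- data.frame(keyword = t$keyword, gene = gi,
                    gene_name = t$gene_name,
                    segment = genes$segment[gi],
                    offset = as.integer(t$offset),
                    stringsAsFactors = FALSE)
  attr(out, "ambiguous") <- data.frame(gene = integer(0),
                                       representative = integer(0))
  out
}
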