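#' Simulation configuration
#'
#' Parameters of the synthetic repertoire / PCR / sequencing benchmark.
#' The defaults are the package's evaluation conditions: 10,000 distinct
#' rearrangements, per-sequence pre-PCR abundance `1 + Poisson(3)`
#' molecules, geometric junctional deletions (mean 4 nt, truncated so the
#' conserved codons survive), Poisson non-templated inserts (mean 6 nt,
#' uniform composition), 4 PCR doubling rounds (16 reads per UMI family),
#' PCR substitution rate 1e-4 per base per duplication, sequencing
#' substitution rate 1e-3 per base, 12 random UMI nucleotides.
#'
#' @param n_tcrs Number of distinct ground-truth rearrangements.
#' @param abundance_lambda Pre-PCR abundance is `1 + Poisson(lambda)`.
#' @param v_del_mean,j_del_mean Mean geometric deletion counts.
#' @param insert_len_mean Mean Poisson insert length.
#' @param pcr_rounds PCR doubling rounds.
#' @param pcr_error_rate Substitution probability per base per
#'   duplication.
#' @param seq_error_rate Sequencing substitution probability per base.
#' @param umi_length Random UMI nucleotides per molecule.
#' @param seed RNG seed; every simulation stage derives its stream from
#'   it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tcrs = 10000L, abundance_lambda = 3,
                       v_del_mean = 4, j_del_mean = 4,
                       insert_len_mean = 6,
                       pcr_rounds = 4L, pcr_error_rate = 1e-4,
                       seq_error_rate = 1e-3, umi_length = 12L,
                       seed = 1L) {
  stopifnot(n_tcrs >= 1L, pcr_rounds >= 0L,
            pcr_error_rate >= 0, pcr_error_rate <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1,
            umi_length >= 1L, abundance_lambda >= 0)
  structure(list(n_tcrs = as.integer(n_tcrs),
                 abundance_lambda = abundance_lambda,
                 v_del_mean = v_del_mean, j_del_mean = j_del_mean,
                 insert_len_mean = insert_len_mean,
                 pcr_rounds = as.integer(pcr_rounds),
                 pcr_error_rate = pcr_error_rate,
                 seq_error_rate = seq_error_rate,
                 umi_length = as.integer(umi_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.bases <- c("A", "C", "G", "T")

.random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  if (length(len) == 1L) len <- rep(len, n)
  total <- sum(len)
  chars <- sample(.bases, total, replace = TRUE)
  out <- character(n)
  idx <- rep.int(seq_len(n), len)
  nz <- len > 0L
  if (any(nz))
    out[nz] <- vapply(split(chars, factor(idx, levels = seq_len(n)[nz])),
                      paste, collapse = "", FUN.VALUE = "")
  out
}

# Per-base substitutions at the given rate; substituted bases always
# change (drawn from the three alternatives).
.mutate_seqs <- function(x, rate) {
  if (rate <= 0 || !length(x)) return(x)
  len <- nchar(x)
  k <- stats::rbinom(length(x), len, rate)
  hit <- which(k > 0L)
  for (i in hit) {
    pos <- sample.int(len[i], k[i])
    for (p in pos) {
      old <- substr(x[i], p, p)
      substr(x[i], p, p) <- sample(setdiff(.bases, old), 1L)
    }
  }
  x
}

# Tag keyword position of each gene (ambiguous genes carry their
# representative's keyword at its occurrence in their own sequence).
.gene_tag_map <- function(tagset) {
  genes <- tagset$genes
  tags <- tagset$tags
  n <- nrow(genes)
  rep_of <- seq_len(n)
  amb <- attr(tags, "ambiguous")
  if (!is.null(amb) && nrow(amb)) rep_of[amb$gene] <- amb$representative
  tag_row <- match(rep_of, tags$gene)
  if (anyNA(tag_row))
    stop("no tag resolves gene(s): ",
         paste(genes$name[is.na(tag_row)], collapse = ", "))
  kw <- tags$keyword[tag_row]
  off <- integer(n)
  for (i in seq_len(n)) {
    o <- regexpr(kw[i], genes$sequence[i], fixed = TRUE)
    if (o < 0L) stop("tag keyword absent from gene ", genes$name[i])
    off[i] <- o
  }
  data.frame(keyword = kw, offset = off, kw_len = nchar(kw),
             tag_row = tag_row)
}

#' Generate a ground-truth repertoire
#'
#' Surrogate for a generative V(D)J recombination model: V and J drawn
#' uniformly, geometric deletion counts (truncated so the conserved C/F
#' codons survive), Poisson insert lengths with uniform nucleotide
#' composition. Each drawn rearrangement is reduced to its canonical
#' classifier (the maximal-germline-extension form the annotator reports,
#' computed against the true genes), deduplicated on it, and stored with
#' its reconstructed sequence, junction truth and pre-PCR abundance.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param tagset A [tag_set()] (provides the germline genes and the tag
#'   geometry used for canonicalisation).
#' @return A data.table with one row per distinct rearrangement: `id`,
#'   `v`, `j`, `v_deletions`, `j_deletions`, `insert`, `sequence`,
#'   `junction`, `junction_aa`, `abundance`.
#' @export
simulate_repertoire <- function(cfg, tagset) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tagset, "tcr_tagset"))
  genes <- tagset$genes
  tm <- .gene_tag_map(tagset)
  v_idx_all <- which(genes$segment == "V")
  j_idx_all <- which(genes$segment == "J")
  cap_v <- pmax(0L, genes$length - genes$conserved_pos - 2L)
  cap_j <- pmax(0L, genes$conserved_pos - 1L)

  set.seed(cfg$seed)
  acc <- NULL
  seen <- character(0)
  p_v <- 1 / (1 + cfg$v_del_mean)
  p_j <- 1 / (1 + cfg$j_del_mean)
  while (is.null(acc) || nrow(acc) < cfg$n_tcrs) {
    m <- max(1000L, ceiling(cfg$n_tcrs * 1.2))
    v <- sample(v_idx_all, m, replace = TRUE)
    j <- sample(j_idx_all, m, replace = TRUE)
    vd <- pmin(stats::rgeom(m, p_v), cap_v[v])
    jd <- pmin(stats::rgeom(m, p_j), cap_j[j])
    ins <- .random_dna(m, stats::rpois(m, cfg$insert_len_mean))
    seqs <- reconstruct_sequence(v, j, vd, jd, ins, genes)
    # canonicalise against the true genes
    v_kept <- genes$length[v] - vd
    w <- .walk(seqs, v, j,
               v_start_read = tm$offset[v],
               j_start_read = v_kept + nchar(ins) + (tm$offset[j] - jd),
               v_off_gene = tm$offset[v], j_off_gene = tm$offset[j],
               v_kw_len = tm$kw_len[v], j_kw_len = tm$kw_len[j],
               genes = genes)
    key <- paste(w$v, w$j, w$v_deletions, w$j_deletions, w$insert)
    keep <- !duplicated(key) & !(key %in% seen)
    if (!any(keep))
      stop("cannot reach ", cfg$n_tcrs, " distinct rearrangements under ",
           "this configuration (classifier space too small)")
    seen <- c(seen, key[keep])
    batch <- data.table::data.table(
      v = w$v[keep], j = w$j[keep],
      v_deletions = w$v_deletions[keep], j_deletions = w$j_deletions[keep],
      insert = w$insert[keep])
    acc <- if (is.null(acc)) batch else rbind(acc, batch)
  }
  acc <- acc[seq_len(cfg$n_tcrs), ]
  acc$id <- seq_len(nrow(acc))
  acc$sequence <- reconstruct_sequence(acc$v, acc$j, acc$v_deletions,
                                       acc$j_deletions, acc$insert, genes)
  jun <- extract_junction(acc$v, acc$j, acc$v_deletions, acc$j_deletions,
                          acc$insert, genes)
  acc$junction <- jun$junction
  acc$junction_aa <- jun$junction_aa
  acc$abundance <- 1L + stats::rpois(nrow(acc), cfg$abundance_lambda)
  data.table::setcolorder(acc, c("id", "v", "j", "v_deletions",
                                 "j_deletions", "insert", "sequence",
                                 "junction", "junction_aa", "abundance"))
  acc[]
}

#' Simulate PCR amplification with UMI attachment
#'
#' Every pre-PCR molecule receives a unique-by-chance random UMI
#' (collisions are allowed — they are realistic and stress the
#' clustering). Each doubling round copies every molecule once; copies
#' acquire independent per-base substitutions at `pcr_error_rate` (on
#' both the TCR sequence and the UMI) and errors propagate to
#' descendants. Deterministic given `cfg$seed`.
#'
#' @param truth Output of [simulate_repertoire()].
#' @param cfg A [sim_config()].
#' @return A data.table of amplified molecules: `origin` (truth `id`),
#'   `molecule` (pre-PCR molecule index), `seq`, `umi`.
#' @export
simulate_pcr <- function(truth, cfg) {
  stopifnot(nrow(truth) >= 1L)
  set.seed(cfg$seed + 1L)
  origin <- rep.int(truth$id, truth$abundance)
  n0 <- length(origin)
  molecule <- seq_len(n0)
  seqs <- rep.int(truth$sequence, truth$abundance)
  umis <- .random_dna(n0, cfg$umi_length)
  for (r in seq_len(cfg$pcr_rounds)) {
    new_seq <- .mutate_seqs(seqs, cfg$pcr_error_rate)
    new_umi <- .mutate_seqs(umis, cfg$pcr_error_rate)
    seqs <- c(seqs, new_seq)
    umis <- c(umis, new_umi)
    origin <- c(origin, origin[seq_along(new_seq)])
    molecule <- c(molecule, molecule[seq_along(new_seq)])
  }
  data.table::data.table(origin = origin, molecule = molecule,
                         seq = seqs, umi = umis)
}

.umi_spacer <- "GTCA"

#' Simulate Illumina-style sequencing of amplified molecules
#'
#' Every molecule yields one read pair: the TCR read (the full molecule
#' sequence) and the UMI read (UMI first half, fixed 4-nt spacer, UMI
#' second half — the default [umi_spec()] layout). Both reads acquire
#' independent per-base substitutions at `seq_error_rate`; quality
#' strings are flat at the Phred score implied by that rate.
#' Deterministic given `cfg$seed`.
#'
#' @param molecules Output of [simulate_pcr()].
#' @param cfg A [sim_config()].
#' @return A data.table: `read_id`, `tcr_seq`, `tcr_qual`, `umi_seq`,
#'   `umi_qual`, `origin`, `molecule`.
#' @export
simulate_sequencing <- function(molecules, cfg) {
  stopifnot(nrow(molecules) >= 1L)
  set.seed(cfg$seed + 2L)
  n <- nrow(molecules)
  half <- cfg$umi_length %/% 2L
  umi_read <- paste0(substr(molecules$umi, 1L, half), .umi_spacer,
                     substr(molecules$umi, half + 1L, cfg$umi_length))
  tcr_read <- .mutate_seqs(molecules$seq, cfg$seq_error_rate)
  umi_read <- .mutate_seqs(umi_read, cfg$seq_error_rate)
  q <- if (cfg$seq_error_rate > 0)
    min(40L, max(2L, round(-10 * log10(cfg$seq_error_rate)))) else 40L
  qc <- intToUtf8(q + 33L)
  data.table::data.table(
    read_id = sprintf("r%08d", seq_len(n)),
    tcr_seq = tcr_read,
    tcr_qual = strrep(qc, nchar(tcr_read)),
    umi_seq = umi_read,
    umi_qual = strrep(qc, nchar(umi_read)),
    origin = molecules$origin,
    molecule = molecules$molecule)
}

#' Write simulated reads as a paired FASTQ
#'
#' The truth origin id is carried in the read description
#' (`origin=<id>`) for downstream scoring.
#'
#' @param reads Output of [simulate_sequencing()].
#' @param path_tcr,path_umi Output FASTQ paths (TCR read / UMI read).
#' @export
write_fastq_pair <- function(reads, path_tcr, path_umi) {
  ids <- paste0(reads$read_id, " origin=", reads$origin)
  x1 <- Biostrings::DNAStringSet(reads$tcr_seq)
  names(x1) <- ids
  x2 <- Biostrings::DNAStringSet(reads$umi_seq)
  names(x2) <- ids
  Biostrings::writeXStringSet(x1, path_tcr, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$tcr_qual))
  Biostrings::writeXStringSet(x2, path_umi, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$umi_qual))
  invisible(c(path_tcr, path_umi))
}

#' Score annotation accuracy against the ground truth
#'
#' `classifier_accuracy` is the fraction of reads whose five-part
#' classifier equals the truth record it was simulated from;
#' `junction_accuracy` the fraction whose junction amino-acid sequence
#' equals the truth junction. No-calls count as incorrect for both.
#' Results are on the 0-1 scale.
#'
#' @param annotated [annotate_reads()] output.
#' @param truth [simulate_repertoire()] output.
#' @param origin Truth `id` per annotated read.
#' @param genes `germline_set` used to reconstruct called junctions.
#' @return List with `classifier_accuracy`, `junction_accuracy`, `n`.
#' @export
score_annotation <- function(annotated, truth, origin, genes) {
  stopifnot(nrow(annotated) == length(origin))
  ti <- match(origin, truth$id)
  ok <- annotated$status == "ok"
  cls_ok <- ok &
    annotated$v == truth$v[ti] & annotated$j == truth$j[ti] &
    annotated$v_deletions == truth$v_deletions[ti] &
    annotated$j_deletions == truth$j_deletions[ti] &
    annotated$insert == truth$insert[ti]
  cls_ok[is.na(cls_ok)] <- FALSE

  jun_ok <- rep(FALSE, nrow(annotated))
  if (any(ok)) {
    # junction per distinct called classifier, then spread to reads
    key <- paste(annotated$v, annotated$j, annotated$v_deletions,
                 annotated$j_deletions, annotated$insert)[ok]
    uk <- !duplicated(key)
    jun <- extract_junction(annotated$v[ok][uk], annotated$j[ok][uk],
                            annotated$v_deletions[ok][uk],
                            annotated$j_deletions[ok][uk],
                            annotated$insert[ok][uk], genes)
    called_aa <- jun$junction_aa[match(key, key[uk])]
    jun_ok[ok] <- !is.na(called_aa) &
      called_aa == truth$junction_aa[ti][ok]
  }
  list(classifier_accuracy = mean(cls_ok),
       junction_accuracy = mean(jun_ok),
       n = nrow(annotated))
}

#' Score collapse output against the ground truth
#'
#' Recovery is measured against the canonical truth classifiers: the
#' classifiers obtained by annotating the error-free truth sequences
#' with the same tag set, so that the score isolates sequences lost or
#' introduced by PCR/sequencing error from the separate (and separately
#' scored) tag-ambiguity annotation error. `n_recovered` counts canonical
#' truth classifiers present in the collapsed output, `n_spurious`
#' collapsed classifiers absent from the canonical truth, and
#' `abundance_r` the Pearson correlation between pre-PCR molecule counts
#' and `tcr_count` over recovered classifiers.
#'
#' @param collapsed [collapse_clusters()] output.
#' @param truth [simulate_repertoire()] output.
#' @param tagset The [tag_set()] used for annotation.
#' @return List with `n_truth`, `n_recovered`, `n_lost`, `n_spurious`,
#'   `abundance_r`.
#' @export
score_collapse <- function(collapsed, truth, tagset) {
  canon <- annotate_reads(truth$sequence, tagset)
  if (any(canon$status != "ok"))
    warning(sum(canon$status != "ok"),
            " truth sequences failed error-free annotation")
  ck <- paste(canon$v, canon$j, canon$v_deletions, canon$j_deletions,
              canon$insert)[canon$status == "ok"]
  ab <- tapply(truth$abundance[canon$status == "ok"], ck, sum)
  canon_keys <- names(ab)
  out_keys <- paste(collapsed$v, collapsed$j, collapsed$v_deletions,
                    collapsed$j_deletions, collapsed$insert)
  recovered <- canon_keys %in% out_keys
  r <- NA_real_
  if (sum(recovered) >= 3L) {
    oc <- collapsed$tcr_count[match(canon_keys[recovered], out_keys)]
    r <- stats::cor(as.numeric(ab[recovered]), as.numeric(oc))
  }
  list(n_truth = length(canon_keys),
       n_recovered = sum(recovered),
       n_lost = sum(!recovered),
       n_spurious = sum(!(out_keys %in% canon_keys)),
       abundance_r = r)
}
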