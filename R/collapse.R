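#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion),
#' vectorised over pairs.
#'
#' @param a,b Character vectors (recycled when one has length 1).
#' @return Integer vector of distances.
#' @export
levenshtein <- function(a, b) {
  .lev_dist(as.character(a), as.character(b))
}

#' Percentage Levenshtein distance
#'
#' Edit distance weighted by sequence length:
#' `100 * levenshtein(a, b) / max(nchar(a), nchar(b))`. The longer length
#' is used as the denominator (the conservative reading of
#' length-weighted distance).
#'
#' @inheritParams levenshtein
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
percent_levenshtein <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("percent_levenshtein is undefined for empty strings")
  100 * levenshtein(a, b) / pmax(nchar(a), nchar(b))
}

#' Collapse configuration
#'
#' @param th_bc Maximum barcode Levenshtein distance for merging two
#'   barcode groups (non-negative integer; default 2).
#' @param th_tcr Maximum percentage Levenshtein distance between the
#'   groups' dominant TCR sequences (0-100; default 10).
#' @param max_sweeps Sweep cap for the iterative merge (default 10); a
#'   warning is issued if the cap is reached before the fixed point.
#' @return A `collapse_config` list.
#' @export
collapse_config <- function(th_bc = 2L, th_tcr = 10, max_sweeps = 10L) {
  stopifnot(th_bc >= 0L, th_tcr >= 0, th_tcr <= 100, max_sweeps >= 1L)
  structure(list(th_bc = as.integer(th_bc), th_tcr = as.numeric(th_tcr),
                 max_sweeps = as.integer(max_sweeps)),
            class = "collapse_config")
}

#' Group annotated reads by exact barcode
#'
#' One group per exact barcode string. Each group records its most
#' frequent inter-tag TCR sequence (`top_tcr`); frequency ties are broken
#' towards the lexicographically smallest sequence.
#'
#' @param reads Annotation table ([annotate_reads()] output); only
#'   status-`ok` rows with a barcode are used.
#' @return A list with `groups` (data.table: `barcode`, `size`,
#'   `top_tcr`), `tab` (per-group TCR frequency table: `grp`, `tcr`,
#'   `count`), and `tcr_levels` (the distinct inter-tag sequences
#'   referenced by integer id).
#' @export
group_by_barcode <- function(reads) {
  dt <- data.table::as.data.table(reads)
  if (!is.null(dt$status)) dt <- dt[dt$status == "ok", ]
  dt <- dt[!is.na(dt$barcode) & !is.na(dt$inter_tag_seq), ]
  if (nrow(dt) == 0L) {
    return(list(groups = data.table::data.table(barcode = character(0),
                                                size = integer(0),
                                                top_tcr = integer(0)),
                tab = data.table::data.table(grp = integer(0),
                                             tcr = integer(0),
                                             count = integer(0)),
                tcr_levels = character(0)))
  }
  tcr_levels <- sort(unique(dt$inter_tag_seq))
  dt$tcr <- match(dt$inter_tag_seq, tcr_levels)
  barcode <- NULL; tcr <- NULL; count <- NULL # NSE notes
  tab <- dt[, list(count = .N), by = list(barcode, tcr)]
  data.table::setorder(tab, barcode, -count, tcr)
  groups <- tab[, list(size = sum(count), top_tcr = tcr[1L]),
                by = barcode]
  grp_tab <- data.table::data.table(grp = match(tab$barcode, groups$barcode),
                                    tcr = tab$tcr, count = tab$count)
  list(groups = groups, tab = grp_tab, tcr_levels = tcr_levels)
}

#' Merge similar barcode groups into clusters
#'
#' Implements the pairwise UMI-cluster merge: groups are processed in a
#' deterministic order (descending read count, then barcode); a pair is
#' merged when their barcodes are within `th_bc` Levenshtein edits AND
#' their dominant TCR sequences are within `th_tcr` percent Levenshtein
#' distance. The merged group keeps the larger group's barcode and its
#' dominant TCR is recomputed over all member reads after every merge.
#' Sweeps repeat until no merge occurs (fixed point) or the sweep cap is
#' hit (then with a warning).
#'
#' @param grouping Output of [group_by_barcode()].
#' @param cfg A [collapse_config()].
#' @return A data.table of clusters: `cluster` (id), `barcode`
#'   (representative), `size` (total member reads), `top_tcr` (dominant
#'   inter-tag sequence), `n_groups` (merged barcode groups).
#' @export
merge_groups <- function(grouping, cfg = collapse_config()) {
  g <- grouping$groups
  if (nrow(g) == 0L)
    return(data.table::data.table(cluster = integer(0), barcode = character(0),
                                  size = integer(0), top_tcr = character(0),
                                  n_groups = integer(0)))
  ord <- order(-g$size, g$barcode)
  g2 <- g[ord, ]
  old2new <- match(seq_len(nrow(g)), ord)
  tab <- grouping$tab
  lv <- grouping$tcr_levels
  res <- .merge_groups_cpp(g2$barcode,
                           old2new[tab$grp], tab$tcr, tab$count,
                           lv, seq_along(lv),
                           cfg$th_bc, cfg$th_tcr, cfg$max_sweeps)
  if (!res$converged)
    warning("group merging stopped at the sweep cap (", cfg$max_sweeps,
            ") before reaching a fixed point")
  parent <- res$parent
  reps <- which(parent == seq_along(parent))
  cl_id <- match(parent, reps)
  size <- NULL; cl <- NULL
  sizes <- data.table::data.table(cl = cl_id, size = g2$size)[
    , list(size = sum(size), n_groups = .N), by = cl]
  data.table::setorder(sizes, cl)
  data.table::data.table(
    cluster = seq_along(reps),
    barcode = g2$barcode[reps],
    size = sizes$size,
    top_tcr = lv[res$top[reps]],
    n_groups = sizes$n_groups)
}

#' Collapse clusters into error-corrected TCRs
#'
#' Each cluster (estimated pre-PCR molecule) contributes one vote for the
#' classifier of its dominant inter-tag sequence. Per distinct
#' classifier, `tcr_count` is the number of supporting clusters and
#' `bc_count` the mean cluster size (reads per molecule). Output is
#' sorted by descending `tcr_count`, then classifier.
#'
#' @param clusters Output of [merge_groups()].
#' @param reads The annotation table the clusters were built from (used
#'   to map each dominant inter-tag sequence back to its classifier).
#' @return A data.table: `v`, `j`, `v_deletions`, `j_deletions`,
#'   `insert`, `tcr_count`, `bc_count`.
#' @export
collapse_clusters <- function(clusters, reads) {
  dt <- data.table::as.data.table(reads)
  if (!is.null(dt$status)) dt <- dt[dt$status == "ok", ]
  cols <- c("v", "j", "v_deletions", "j_deletions", "insert")
  if (nrow(clusters) == 0L) {
    out <- data.table::data.table(v = integer(0), j = integer(0),
                                  v_deletions = integer(0),
                                  j_deletions = integer(0),
                                  insert = character(0),
                                  tcr_count = integer(0),
                                  bc_count = numeric(0))
    return(out)
  }
  # inter-tag sequence determines the classifier (tags fix V/J; the
  # extension walk is a function of the sequence), so take the first
  # occurrence
  map <- dt[match(clusters$top_tcr, dt$inter_tag_seq), cols, with = FALSE]
  stopifnot(!anyNA(map$v))
  cc <- cbind(map, size = clusters$size)
  v <- NULL; j <- NULL; v_deletions <- NULL; j_deletions <- NULL
  insert <- NULL; size <- NULL
  out <- cc[, list(tcr_count = .N, bc_count = mean(size)),
            by = list(v, j, v_deletions, j_deletions, insert)]
  data.table::setorder(out, -tcr_count, v, j, v_deletions, j_deletions,
                       insert)
  out
}

#' Full UMI collapse of an annotation table
#'
#' Convenience chain: [group_by_barcode()] then [merge_groups()] then
#' [collapse_clusters()].
#'
#' @inheritParams group_by_barcode
#' @inheritParams merge_groups
#' @return List with `collapsed` (see [collapse_clusters()]) and
#'   `clusters` (see [merge_groups()]).
#' @export
collapse_reads <- function(reads, cfg = collapse_config()) {
  grouping <- group_by_barcode(reads)
  clusters <- merge_groups(grouping, cfg)
  list(collapsed = collapse_clusters(clusters, reads), clusters = clusters)
}

#' Write / read the collapsed TCR format
#'
#' One error-corrected TCR per line, comma-separated: the five classifier
#' fields, `tcr_count`, `bc_count`.
#'
#' @param collapsed Output of [collapse_clusters()].
#' @param path File path.
#' @export
write_collapsed <- function(collapsed, path) {
  utils::write.table(collapsed, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_collapsed
#' @export
read_collapsed <- function(path) {
  df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                        colClasses = c("integer", "integer", "integer",
                                       "integer", "character", "integer",
                                       "numeric"))
  names(df) <- c("v", "j", "v_deletions", "j_deletions", "insert",
                 "tcr_count", "bc_count")
  df$insert[is.na(df$insert)] <- ""
  data.table::as.data.table(df)
}
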