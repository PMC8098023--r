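# Small in-code germline fixtures and independent oracles shared by the
# tests. The toy set is unambiguous (every gene carries a unique tag);
# the bundled synthetic human-TRB-like set (trb_germline()) is used where
# subfamily ambiguity matters.

.toy_bases <- c("A", "C", "G", "T")

# deterministic toy germline: 6 V (150 nt, Cys codon at 136) and
# 4 J (60 nt, Phe codon at 31)
make_toy_germline <- function(seed = 101L) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(.toy_bases, .toy_bases, .toy_bases), 1,
                  paste, collapse = "")
  codons <- setdiff(codons, stops)
  rand <- function(n) paste(sample(codons, n / 3, replace = TRUE),
                            collapse = "")
  v <- vapply(1:6, function(i) {
    s <- rand(150)
    substr(s, 136, 138) <- "TGT"
    s
  }, "")
  j <- vapply(1:4, function(i) {
    s <- rand(60)
    substr(s, 31, 33) <- "TTT"
    s
  }, "")
  g <- data.frame(
    name = c(paste0("TOYV", 1:6), paste0("TOYJ", 1:4)),
    segment = rep(c("V", "J"), c(6, 4)),
    sequence = c(v, j),
    length = c(rep(150L, 6), rep(60L, 4)),
    conserved_pos = c(rep(136L, 6), rep(31L, 4)),
    cdr1_start = c(rep(40L, 6), rep(NA, 4)),
    cdr1_end = c(rep(57L, 6), rep(NA, 4)),
    cdr2_start = c(rep(76L, 6), rep(NA, 4)),
    cdr2_end = c(rep(90L, 6), rep(NA, 4)),
    stringsAsFactors = FALSE)
  class(g) <- c("germline_set", "data.frame")
  g
}

make_toy_tagset <- function(seed = 101L) {
  tag_set(make_toy_germline(seed))
}

# cache: the bundled tag set is used by several files
trb_tagset <- local({
  ts <- NULL
  function() {
    if (is.null(ts)) ts <<- tag_set(trb_germline(), on_ambiguous = "group")
    ts
  }
})

random_dna <- function(n, len) {
  len <- rep(len, length.out = n)
  vapply(seq_len(n), function(i)
    paste(sample(.toy_bases, len[i], replace = TRUE), collapse = ""), "")
}

# naive multi-keyword scan: position-by-position substring equality
naive_scan <- function(keywords, target) {
  out <- list()
  for (k in seq_along(keywords)) {
    kw <- keywords[k]
    w <- nchar(kw)
    n <- nchar(target)
    if (n < w) next
    starts <- which(substring(target, 1:(n - w + 1), w:n) == kw)
    if (length(starts))
      out[[length(out) + 1]] <- data.frame(keyword = k, start = starts)
  }
  if (!length(out))
    return(data.frame(keyword = integer(0), start = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$keyword), , drop = FALSE]
}

# classifier key used to compare annotation tables
cls_key <- function(d) {
  paste(d$v, d$j, d$v_deletions, d$j_deletions, d$insert)
}

# write a FASTQ pair for simulated reads quickly in tests
write_test_fastq <- function(reads, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f1 <- file.path(dir, "tcr.fastq")
  f2 <- file.path(dir, "umi.fastq")
  write_fastq_pair(reads, f1, f2)
  c(tcr = f1, umi = f2)
}
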