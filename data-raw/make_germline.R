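# Generates the packaged synthetic human-TRB-like germline fixture.
#
# The sequences are synthetic stand-ins (not IMGT reference sequences)
# whose ambiguity structure mirrors the human TRB locus:
#   - TRBV6-2 / TRBV6-3: identical coding sequences
#   - TRBV12-3 / TRBV12-4: differ only upstream of the tag window
#   - TRBV6-5 / TRBV6-6: differ by one codon inserted between the tag
#     region and the conserved cysteine (so the confused call shifts the
#     junction frame-preservingly by one codon)
# V genes: 300 nt (TRBV6-6: 303), conserved Cys codon at 286 (289),
# CDR1 at 79..114, CDR2 at 166..195, no stop codons in frame 0.
# J genes: 60 nt, conserved Phe codon at 31 followed by an FG-X-G-like
# motif, no stop codons in frame 0.
#
# Run from the package root: Rscript data-raw/make_germline.R

set.seed(20260901)

bases <- c("A", "C", "G", "T")
stops <- c("TAA", "TAG", "TGA")
codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
codons <- setdiff(codons, stops)

rand_codons <- function(n) paste(sample(codons, n, replace = TRUE),
                                 collapse = "")

v_names <- c("TRBV2", "TRBV3-1", "TRBV4-1", "TRBV4-2", "TRBV4-3",
             "TRBV5-1", "TRBV5-4", "TRBV5-5", "TRBV5-6", "TRBV5-8",
             "TRBV6-1", "TRBV6-2", "TRBV6-3", "TRBV6-4", "TRBV6-5",
             "TRBV6-6", "TRBV6-8", "TRBV6-9", "TRBV7-2", "TRBV7-3",
             "TRBV7-4", "TRBV7-6", "TRBV7-7", "TRBV7-8", "TRBV7-9",
             "TRBV9", "TRBV10-1", "TRBV10-2", "TRBV10-3", "TRBV11-1",
             "TRBV11-2", "TRBV11-3", "TRBV12-3", "TRBV12-4", "TRBV12-5",
             "TRBV13", "TRBV14", "TRBV15", "TRBV16", "TRBV18", "TRBV19")
j_names <- c(paste0("TRBJ1-", 1:6), paste0("TRBJ2-", 1:7))

v_len <- 300L; v_cp <- 286L       # conserved Cys codon start (1-based)
j_len <- 60L;  j_fp <- 31L        # conserved Phe codon start

make_v <- function() {
  body <- rand_codons((v_cp - 1L) / 3L)            # codons before Cys
  cys <- sample(c("TGT", "TGC"), 1L)
  tail <- rand_codons((v_len - v_cp - 2L) / 3L)
  paste0(body, cys, tail)
}

make_j <- function() {
  head <- rand_codons((j_fp - 1L) / 3L)
  phe <- sample(c("TTT", "TTC"), 1L)
  g1 <- paste0("GG", sample(bases, 1L))
  x <- sample(codons, 1L)
  g2 <- paste0("GG", sample(bases, 1L))
  tail <- rand_codons((j_len - j_fp - 2L - 9L) / 3L)
  paste0(head, phe, g1, x, g2, tail)
}

v_seq <- setNames(vapply(v_names, function(n) make_v(), ""), v_names)
j_seq <- setNames(vapply(j_names, function(n) make_j(), ""), j_names)

# --- designed subfamily ambiguity ---
# identical pair
v_seq["TRBV6-3"] <- v_seq["TRBV6-2"]

# pair differing only upstream of the tag window (codons 20,30,40,50,60)
s <- v_seq["TRBV12-3"]
for (k in c(20L, 30L, 40L, 50L, 60L)) {
  old <- substr(s, 3L * k - 2L, 3L * k)
  substr(s, 3L * k - 2L, 3L * k) <- sample(setdiff(codons, old), 1L)
}
v_seq["TRBV12-4"] <- s

# pair differing by one codon inserted between tag region and Cys:
# TRBV6-6 = TRBV6-5[1..282] + XYZ + TRBV6-5[283..300]; X != TRBV6-5[283]
s <- v_seq["TRBV6-5"]
first_after <- substr(s, 283L, 283L)
repeat {
  ins <- sample(codons, 1L)
  if (substr(ins, 1L, 1L) != first_after) break
}
v_seq["TRBV6-6"] <- paste0(substr(s, 1L, 282L), ins, substr(s, 283L, 300L))

# --- sanity checks on the designed ambiguity structure ---
all_seq <- c(v_seq, j_seq)
win <- function(x, cp) substr(x, cp - 1L - 6L - 59L, cp - 1L - 6L)  # tag window
occurs_elsewhere <- function(kmer, self) {
  any(vapply(setdiff(names(all_seq), self),
             function(n) grepl(kmer, all_seq[[n]], fixed = TRUE), TRUE))
}
cp_of <- function(n) if (n == "TRBV6-6") 289L else v_cp
amb_expected <- c("TRBV6-3", "TRBV12-4", "TRBV6-6")
for (n in v_names) {
  cp <- cp_of(n)
  sq <- v_seq[[n]]
  hi <- cp - 1L - 6L
  shared <- vapply(seq.int(hi - 19L, hi - 19L - 40L), function(st)
    occurs_elsewhere(substr(sq, st, st + 19L), n), TRUE)
  pairmate <- c("TRBV6-2" = "TRBV6-3", "TRBV6-3" = "TRBV6-2",
                "TRBV12-3" = "TRBV12-4", "TRBV12-4" = "TRBV12-3",
                "TRBV6-5" = "TRBV6-6", "TRBV6-6" = "TRBV6-5")
  if (n %in% names(pairmate)) {
    stopifnot(all(shared))  # no distinguishing tag may exist
  } else {
    stopifnot(!all(shared)) # a unique tag must exist
  }
}
for (n in j_names) {
  sq <- j_seq[[n]]
  shared <- vapply(seq.int(j_fp + 3L, j_len - 19L), function(st)
    occurs_elsewhere(substr(sq, st, st + 19L), n), TRUE)
  stopifnot(!all(shared))
}

# --- write fixture files ---
wrap <- function(x, width = 60L) {
  starts <- seq.int(1L, nchar(x), by = width)
  substring(x, starts, pmin(starts + width - 1L, nchar(x)))
}
fa <- unlist(lapply(names(all_seq), function(n)
  c(paste0(">", n), wrap(all_seq[[n]]))))
writeLines(fa, "inst/extdata/synthetic_trb_germline.fasta")

ann <- data.frame(
  gene = c(v_names, j_names),
  segment = c(rep("V", length(v_names)), rep("J", length(j_names))),
  conserved_pos = c(vapply(v_names, cp_of, 0L), rep(j_fp, length(j_names))),
  cdr1_start = c(rep(79L, length(v_names)), rep(NA, length(j_names))),
  cdr1_end = c(rep(114L, length(v_names)), rep(NA, length(j_names))),
  cdr2_start = c(rep(166L, length(v_names)), rep(NA, length(j_names))),
  cdr2_end = c(rep(195L, length(v_names)), rep(NA, length(j_names))))
con <- file("inst/extdata/synthetic_trb_annotation.tsv", "w")
writeLines(c("# synthetic human-TRB-like germline annotation (1-based, inclusive)",
             "# conserved_pos: start of the conserved Cys (V) / Phe (J) codon"),
           con)
write.table(ann, con, sep = "\t", quote = FALSE, row.names = FALSE)
close(con)
cat("wrote", length(v_names), "V and", length(j_names), "J genes\n")
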