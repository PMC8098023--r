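# tcrtag

Tag-based annotation of T-cell receptor (TCR) repertoire sequencing
data, with UMI-based PCR/sequencing error correction and AIRR-compliant
output — plus a repertoire/PCR/sequencing simulator for benchmarking the
whole chain.

## Who this is for

Researchers processing bulk TCR-beta amplicon libraries who need, per
read, the recombination event that produced it; per molecule, an
error-corrected abundance; and, per repertoire, a standards-compliant
rearrangement table that downstream AIRR tooling can consume.

## The method

A rearranged TCR read is not germline — V(D)J recombination trims the V
3' end and the J 5' end and inserts non-templated nucleotides between
them. `tcrtag` classifies reads with exact multi-keyword matching: each
germline V and J gene gets a short identifying *tag* (default 20 nt),
all tags are compiled into an Aho-Corasick keyword trie, and one linear
scan per read finds the V and J. Walking from the tag ends along read
and germline counts the deletions and delimits the insert, reducing the
read to the lossless five-part classifier

```
(V, J, nV deletions, nJ deletions, insert)
```

UMI error correction follows a group-then-merge scheme: reads are
grouped by exact barcode; groups whose barcodes are within a Levenshtein
threshold `th_bc` (default 2) *and* whose dominant receptor sequences
are within a percentage Levenshtein threshold `th_tcr` (default 10) are
merged iteratively to a fixed point. Each resulting cluster estimates
one pre-PCR molecule; per classifier the output reports `tcr_count`
(supporting clusters = molecule count) and `bc_count` (mean reads per
molecule). The translator reconstructs each sequence, extracts the
junction between the conserved Cys and Phe codons, flags productivity
(in-frame, C...F, stop-free) and writes an AIRR Rearrangement TSV.

The bundled germline reference is a *synthetic* human-TRB-like set
(41 V / 13 J; see the methods vignette) whose subfamily ambiguity
mirrors the human locus — near-identical TRBV6/TRBV12 members share
tags, which is what bounds classifier accuracy below 100%.

## Worked example

Simulate a 1,000-sequence repertoire through PCR (4 doubling rounds,
UMI-tagged) and sequencing, annotate, collapse, score:

```r
library(tcrtag)

ts <- tag_set(trb_germline(), on_ambiguous = "group")
#> <tcr_tagset> 41 V / 13 J genes, 51 tags (length 20 nt)

cfg <- sim_config(n_tcrs = 1000, seed = 7)
truth <- simulate_repertoire(cfg, ts)
reads <- simulate_sequencing(simulate_pcr(truth, cfg), cfg)  # 62,080 pairs

ann <- annotate_reads(reads$tcr_seq, ts, barcodes = extract_umi(reads$umi_seq))
table(ann$status)
#>  no_j  no_v    ok
#>  1446  1496 59138

res <- collapse_reads(ann)
res$collapsed[1:3]
#>        v     j v_deletions j_deletions      insert tcr_count bc_count
#> 1:     1    47           9           2 ATTGCAATTCA         9 15.33333
#> 2:     8    48           5          12      GGAACC         9 15.44444
#> 3:    10    52           0          14     TTCGAGA         9 15.66667

unlist(score_collapse(res$collapsed, truth, ts))
#>     n_truth n_recovered      n_lost  n_spurious abundance_r
#>   1000.0000   1000.0000      0.0000     11.0000      0.9978
```

The no-calls are reads with a sequencing error inside a 20-nt tag
(exact matching, ~5% at error rate 1e-3). After collapse, all 1,000
pre-PCR sequences are recovered, 11 error-derived sequences survive
correction, and corrected abundances track the true molecule counts at
r = 0.998. Translating to AIRR:

```r
rec <- make_airr(res$collapsed, ts$genes)
rec[1, c("v_call", "j_call", "junction_aa", "productive", "duplicate_count")]
#>   v_call  j_call      junction_aa productive duplicate_count
#> 1  TRBV2 TRBJ1-6 CRIAIQPDRNDRTIGF          T               9
```

A thin CLI wraps the same functions
(`system.file("exec", "tcrtag", package = "tcrtag")`): subcommands
`demultiplex`, `annotate`, `collapse`, `translate`, `simulate`, `run`.

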