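---
title: "Tag-based TCR annotation and UMI error correction: methods"
author: "tcrtag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based TCR annotation and UMI error correction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrtag)
```

## The problem

T-cell receptor (TCR) beta chains are produced by somatic V(D)J
recombination: a germline V and J segment are joined after exonucleolytic
trimming of the V 3' end and the J 5' end, with non-templated nucleotides
inserted at the junction. A sequencing read of a rearranged transcript
therefore cannot be annotated by simple germline lookup; the recombination
event has to be inferred. `tcrtag` infers it with exact short-tag matching:
every V and J gene is assigned a short identifying substring (a *tag*),
all tags are compiled into one Aho-Corasick keyword trie, and each read is
classified in a single linear scan. A read containing exactly one V tag
followed by one J tag is reduced, losslessly, to the five-part classifier

> (V gene, J gene, number of V 3' deletions, number of J 5' deletions,
> insert sequence),

from which the full nucleotide sequence can be reconstructed given the
germline references. Amplified libraries carry unique molecular
identifiers (UMIs); a clustering step collapses PCR duplicates and
sequencing errors to recover the pre-amplification molecules and their
abundances. Final output is an AIRR Community rearrangement TSV.

## Tag construction

`build_tags()` selects, per gene, one substring of length `tag_length`
(default 20 nt — long enough that random collisions between ~300 nt genes
are vanishingly rare) that occurs in no other gene of the reference.

Placement matters more than length:

* **V tags** are placed as 3' as possible — the inter-tag window must
  bracket the junction — but confined to a window (default 40 nt) ending a
  margin (default 6 nt) upstream of the conserved cysteine codon. A tag
  overlapping the CDR3-proximal nucleotides would be destroyed by normal
  junctional trimming, turning ordinary rearrangements into no-calls; the
  window also mirrors the fact that tags must sit inside amplicon read
  coverage near the junction.
* **J tags** are placed as 5' as possible, starting just downstream of the
  conserved phenylalanine codon, for the symmetric reason.

Setting `respect_conserved = FALSE` frees placement to the whole gene
(useful for toy references without conserved-residue annotations).

Some V subfamily members are identical, or identical throughout the
placement window; no distinguishing tag exists for them. By default this
is an error naming the indistinguishable genes. With
`on_ambiguous = "group"` each indistinguishable class receives a single
shared tag assigned to its first member in file order; reads from any
class member are annotated with that representative. This is the
documented mechanism by which short-tag annotation cannot separate
near-identical V subfamilies, and it is what bounds the classifier
accuracy below 100% on realistic references (see *Evaluation design*).

## Read classification

The trie reports every tag occurrence in one pass. A read is called when
it contains exactly one V-tag hit and exactly one J-tag hit, with the V
tag ending before the J tag starts; otherwise it is a no-call with a
reason code (`no_v`, `no_j`, `multiple_v`, `multiple_j`,
`order_violation`). The reverse complement is tried when the forward
orientation fails. Multiple hits of even the same tag are treated
conservatively as no-calls rather than picking one occurrence. Tags are
matched exactly; there is no single-mismatch rescue, so sequencing errors
inside a tag cost the read (counted in the run statistics).

Deletions are counted by walking from the V-tag end along read and
germline in parallel towards the gene 3' end; the V deletion count is the
number of germline nucleotides beyond the longest contiguous match. The J
side is symmetric, walking leftward. The insert is the read substring
strictly between the two matched germline segments. When read nucleotides
match germline on both sides ambiguously (overlapping extensions), the
V-side match is maximised first, then the J side — a deterministic
tie-break; the reconstructed nucleotide sequence is identical under any
tie-break, only the classifier's representation changes, so the package
consistently reports this *canonical* form. Internal coordinates are
1-based inclusive throughout (the natural R convention); file formats
document their own conventions.

## UMI collapse

Annotated reads are first grouped by exact barcode. Each group records
its dominant (most frequent) inter-tag sequence, ties broken towards the
lexicographically smallest. Groups are then merged pairwise: processing
order is deterministic (descending read count, then barcode), and a pair
merges when

* the barcode Levenshtein distance is at most `th_bc` (default 2), and
* the percentage Levenshtein distance between the dominant sequences —
  `100 * d / max(len)`, the conservative reading of length-weighted edit
  distance — is at most `th_tcr` (default 10).

The merged group keeps the larger group's barcode, and its dominant
sequence is recomputed over all member reads after every merge. Sweeps
repeat to a fixed point, with a cap (default 10 sweeps, warning if hit);
in practice two sweeps suffice. Largest-first processing makes abundant
true molecules absorb their error satellites, which is the purpose of the
step. The defaults merge one-to-two UMI errors and up to ~10% receptor
sequence divergence; both thresholds are exposed everywhere
(`collapse_config()`, CLI flags).

Each final cluster approximates one pre-PCR molecule and casts one vote
for the classifier of its dominant sequence. Per distinct classifier the
output records `tcr_count` (number of supporting clusters, i.e. estimated
molecule count) and `bc_count` (mean cluster size, i.e. reads per
molecule — a robustness indicator). Pair enumeration inside the merge
uses a pigeonhole pre-filter on barcode pieces; it is a filter only, every
candidate is verified by exact banded edit distance, so results equal the
all-pairs scan.

An optional input filter discards reads whose UMI-window mean quality is
below a threshold (off by default).

## Junction extraction, productivity, AIRR output

The reconstructed sequence (germline V minus its deletions, insert,
germline J minus its deletions; leaderless by construction of the
references) is translated in the V frame. The junction runs from the
annotated conserved cysteine codon of the called V gene through the
annotated conserved phenylalanine codon of the called J gene, inclusive.
Conserved positions come from the per-gene annotation table, not from
motif search — deterministic, and robust to motif degeneracy. A record is
productive when the junction exists, its length is divisible by three,
its translation starts with C and ends with F, and no stop codon occurs
through the junction in the V frame.

Output follows the AIRR Rearrangement TSV: all required columns are
present, with alignment/cigar columns empty (no alignment is computed)
and `d_call` empty (no D-segment tags). Custom columns carry the
five-part classifier, CDR1/CDR2 amino-acid sequences of the called V
gene, the full protein, and `bc_count`. One row per unique DNA
rearrangement; synonymous rearrangements keep separate rows.
Non-productive records are included by default.

## The simulator and the evaluation design

The simulator is a deliberately simple surrogate for a learned generative
recombination model: uniform V/J usage, geometric deletion counts (mean
4 nt per side), Poisson insert lengths (mean 6 nt) with uniform
composition. Deletions are truncated so the conserved C and F codons
survive — the generated repertoires are junction-preserving, which real
repertoires predominantly are, and which gives every truth record a
defined junction. Drawn classifiers are canonicalised (same maximal-
extension convention as the annotator, computed against the *true* genes)
and deduplicated, so the round-trip identity — error-free reads recover
the generator's classifier exactly on unambiguous references — is
well-defined.

Amplification attaches one random 12-nt UMI per pre-PCR molecule
(collisions allowed; they stress the clustering realistically), then
performs doubling rounds in which every copy acquires independent
per-base substitutions that propagate to descendants. Sequencing adds
independent per-base substitutions to both the receptor read and the UMI
read, with flat quality strings consistent with the configured rate.
Per-sequence pre-PCR abundance is `1 + Poisson(3)` molecules.

Default rates are `pcr_error_rate = 1e-4` per base per duplication over
4 rounds (16-read UMI families) and `seq_error_rate = 1e-3`. Under these
conditions the dominant mechanism creating surviving error sequences is
the first-round PCR jackpot: an error in the first duplication is carried
by half the family and wins the within-group majority vote roughly half
the time. The expected count is analytic —
`molecules x visible_length x pcr_error_rate x 1/2`, about 100 spurious
sequences per 10,000-sequence repertoire — and the benchmark measures it
empirically rather than assuming it.

The simulator does **not** emulate: non-uniform gene usage, indel
sequencing errors, quality-score-dependent error profiles, PCR
efficiency below 1, chimeras, or multi-locus libraries. Passing
benchmarks therefore demonstrate correctness of the algorithms under a
clean substitution-error model, not performance on any particular real
library.

### The bundled synthetic reference

Real germline references cannot be redistributed here byte-for-byte, so
the package ships a *synthetic* human-TRB-like reference (41 V, 13 J,
IMGT-style names; `synthetic_trb_*` files) generated by
`data-raw/make_germline.R`. Its crucial property is its ambiguity
structure, designed to mirror the human locus where short tags cannot
separate some V subfamily members:

* `TRBV6-2`/`TRBV6-3` — identical sequences (as in the human locus);
* `TRBV12-3`/`TRBV12-4` — differ only upstream of the tag window, so the
  confused call still reconstructs the correct junction;
* `TRBV6-5`/`TRBV6-6` — differ by one codon inserted between the tag
  region and the conserved cysteine, so the confused call shifts the
  junction by one codon (frame-preservingly) and corrupts it.

Under uniform V usage the expected classifier accuracy is therefore
`1 - 3/41 = 92.7%` and the expected junction accuracy `1 - 1/41 = 97.6%`:
junction accuracy strictly exceeds classifier accuracy because two of the
three confusion channels leave the junction intact. These are properties
of the reference design, verified — not assumed — by the benchmark.

### Scoring definitions

Annotation accuracy is read-level: the fraction of (error-free) reads
whose full five-part classifier, respectively junction amino-acid
sequence, equals the ground truth; no-calls count as wrong.

Collapse recovery is scored against the *canonical truth*: the
classifiers obtained by annotating the error-free truth sequences with
the same tag set. On an ambiguous reference a truth sequence from a
non-representative subfamily member can never be output under its own
gene label — that is annotation ambiguity, measured by the annotation
score — so scoring collapse against raw labels would conflate the two
error sources. Against canonical truth, `sequences lost` and `spurious
sequences retained` isolate exactly what PCR/sequencing error and the
collapse step add or lose. `abundance_r` is the Pearson correlation
between pre-PCR molecule counts and `tcr_count` over recovered
classifiers.

### Problem sizes

The packaged benchmark (`scripts/acceptance.R`, mirrored by the
acceptance test file) simulates 10,000 distinct rearrangements — about
40,000 pre-PCR molecules and 640,000 read pairs through the collapse
chain — and completes in a few minutes on one CPU. Unit and property
tests run on a 6 V / 4 J toy reference with hundreds of reads.

## Known limitations

* Exact tag matching: no mismatch rescue inside tags; a 20-nt tag at
  sequencing error rate 1e-3 loses ~2% of reads per tag as no-calls.
* Allele-level calling is out of scope (one sequence per gene), as is
  D-segment assignment.
* Order-invariance of the collapse output under read reshuffling is
  asserted on the test fixtures; the pairwise-merge fixed point is not
  guaranteed to be order-invariant for adversarial inputs.
* The abundance model and error rates are study conditions, not fits to
  any particular protocol; all are exposed in `sim_config()`.
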