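---
title: "spliceflow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spliceflow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: what each
stage computes, the assumptions behind it, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
design choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## 1. The two processing modes

**Alignment-only mode.** Each sample's paired FASTQ files are split
into interleaved chunks of `chunk_size` read pairs (default 65,536;
only the last chunk may be smaller), each chunk is aligned
independently, the per-chunk alignment files are written to a temporary
location, and a concatenation stage appends them in chunk order into
one file per sample, deleting each chunk file as it is consumed so peak
temporary disk is one chunk plus the accumulated output. The contract
is *sequential equivalence*: because chunking never splits a pair, the
aligner is deterministic, and concatenation preserves chunk order, the
per-sample record multiset is identical to an unchunked run.
`verify_equivalence()` checks this the way one would by hand: name-sort
both files with a total secondary order (flags, chromosome, position,
CIGAR) and diff the records; headers are compared only after dropping
`@PG`/`@CO` lines, which legitimately record different command lines.

**Transcript assembly mode.** Stages, in order: chunk → align → bin →
per-bin assembly → collect → redundancy removal → merge with reference
→ optional comparison. Parallelism is a pool of independent tasks over
chunks and bins whose results are merged in key order, so the final
GTF is a pure function of inputs and configuration — invariant under
worker count and completion order. The pipeline itself uses no
randomness; only the simulator is seeded.

## 2. The built-in aligner

The built-in aligner exists so the determinism and equivalence
contracts can be tested without external binaries. It is deliberately
minimal and *exactly* specified:

* Seeds are the first and last `k` bases of the mate (default `k = 25`),
  looked up in a hash of every forward-strand genomic k-mer; the
  reverse strand is searched by reverse-complementing the query.
* A candidate placement is a same-chromosome seed pair with
  non-negative inner gap. Gap zero must verify as a contiguous exact
  match (`<len>M`); a positive gap must verify as a single-intron
  alignment `aM <gap>N (len-a)M` at some split point `a`.
* Among valid split points, splits whose implied intron carries a
  canonical motif (genomic `GT..AG` forward, `CT..AC` reverse-gene) are
  preferred; ties break leftmost. Among placements, ties break by
  (chromosome, coordinate, `+` before `-`). This makes the aligner a
  deterministic function of (read bytes, index), which the
  sequential-equivalence guarantee requires.
* Anything that does not fit — mismatches, two introns in one mate, a
  junction overhang shorter than `k` (the seed itself would straddle
  the junction) — is emitted as an unmapped record, not an error, so
  record conservation (2 records per pair) remains checkable.

Two consequences are worth knowing. First, junction-spanning mates with
an overhang < `k` cannot be placed; with 100-bp reads and `k = 25` this
is a predictable fraction of junction reads, and coverage from the
remaining reads keeps assembly exact (the tests assert exact
position/CIGAR truth recovery for mates whose aligned segments are all
≥ `k`). Second, a mate whose few overhang bases happen to coincide with
the intron's first bases may verify as a contiguous match and be placed
without the splice; this mirrors real aligners' preference for ungapped
placements, introduces no spurious junction, and at worst leaks a few
bases of coverage into an intron end, which can surface as an isolated
single-exon fragment. Raising `min_junction_support`/`min_cov` or
simply ignoring single-exon calls removes this noise; intron-chain
metrics are unaffected.

## 3. Binning geometry

Bin `i` on a chromosome spans `[iS, (i+1)S + V)` (0-based half-open),
truncated at the chromosome end; defaults are `S` = 1 Mb, `V` = 100 kb.
Consecutive bins share exactly `V` bases, giving the containment
guarantee: *any interval of length ≤ V + 1 lies wholly inside at least
one bin* (checked exhaustively for all `S` in 10..50, all `V < S`).
Bins extend only rightward — a symmetric extension would double the
duplication without improving containment. Records are routed by their
full reference span (introns included), so junction evidence reaches
every bin an isoform could be assembled in; unmapped records are
dropped; mates are binned independently; sequence and quality strings
are stripped first, as assembly never reads them. The defaults were
chosen so that typical mammalian transcripts fit inside one bin; the
published runs' actual geometry is not recoverable from the main text,
so these are declared defaults, not reproductions.

## 4. The splice-graph assembler

Per bin, over coordinate-sorted records on one chromosome:

1. **Evidence.** Coverage counts `M` segments only; every `N` operation
   is one junction occurrence; junction strand comes from the genomic
   dinucleotides (`GT..AG` → `+`, `CT..AC` → `-`, else unknown).
2. **Fragments.** Maximal intervals of non-zero coverage, split at the
   boundaries of junctions meeting `min_junction_support`, kept if mean
   coverage ≥ `min_cov` (default 1.0 — for integer coverage the
   per-base and mean thresholds then coincide).
3. **Graph.** A junction with support ≥ `min_junction_support` draws an
   edge from the fragment ending at its donor to the fragment starting
   at its acceptor.
4. **Transcripts.** All maximal paths per connected component,
   enumerated leftmost-first with neighbors in genomic order, capped at
   `max_paths_per_component` (default 64; exceeding the cap truncates
   the component with a warning — never a silent reordering). Exons are
   the path's fragments (adjacent fragments without an intervening
   junction boundary are fused); transcript strand is the strand of its
   junction motifs (unspliced → `.`). Single-exon transcripts are
   emitted only for isolated fragments with no incident junctions,
   which avoids fragmenting multi-exon genes into spurious singletons.
   One gene per connected component, named by bin and ordinal.

Maximal-path enumeration was chosen over coverage decomposition because
it is exactly specifiable and deterministic; no fidelity to StringTie
or Scallop internals is claimed (they remain available as untested
adapter hooks). Transcript termini are evidence-bounded (first/last
covered base): two bins seeing the same full read set therefore produce
coordinate-identical transcripts, which downstream deduplication
requires.

**Bin containment filter.** A transcript that straddles a bin's *core
boundary* is fully contained in one bin, but the next bin still
receives the subset of its records that overlap that bin and would
assemble a left-truncated partial — possibly missing the first intron
entirely — which identity-based deduplication cannot collapse. A bin
therefore suppresses de novo transcripts not fully contained in its own
interval (`bin_span`): the containment guarantee ensures the bin that
fully contains the transcript emits the complete version, while
overlap-region transcripts contained in *both* adjacent bins are still
emitted twice and collapsed by deduplication. Verbatim guided-mode
reference emissions are exempt (identical across bins by construction).
The price is that a de novo transcript longer than `S + V` is emitted
by no bin; with the defaults that requires a >1.1-Mb transcript.

**Guided mode.** The reference annotation, filtered to the bin's
chromosome, contributes each transcript whose introns are all present
in the bin's junction set (at the support threshold); these are emitted
verbatim ahead of de novo paths, and de novo paths duplicating an
emitted reference intron chain are suppressed.

## 5. Redundancy removal and merging

`remove_bin_redundancy()` keeps exactly one copy per identical
(chromosome, strand, intron chain, exon coordinates) structure — the
copy from the lowest-ordered origin bin. It is idempotent and never
removes the last copy. Deduplication happens *before* merging, by
design: merge tools that treat overlap-region duplicates as novel
isoforms artificially depress precision, and an explicit structural
dedup is the clean fix.

`merge_with_reference()` keeps every reference transcript unchanged;
absorbs an assembled multi-exon transcript when a reference transcript
matches its (chromosome, strand-compatible, intron chain); absorbs an
assembled single-exon transcript on ≥ 80% reciprocal overlap of the
longer with a strand-compatible single-exon reference transcript (the
threshold deliberately reuses the evaluator's single-exon rule — the
merge tool's own threshold is not public); everything else is added
with a fresh `NOVEL.*` id, attached to an overlapping strand-compatible
reference gene when one exists. Strand-unknown assembled transcripts
may match either strand: unspliced evidence carries no strand. The
output is order-normalized, so merging is invariant to the assembled
list's input order. Consequence (tested as a property): the reference
is always a subset of the merged annotation, so transcript-level
sensitivity of the merged annotation against that same reference is
100% — which is also why only precision is informative post-merge.

## 6. The evaluator

Six levels, each `sensitivity = 100·matched_ref/ref_total`,
`precision = 100·correct_query/query_total`, with empty denominators
reported `NA` (never 0 or 100):

| level | counted objects | match rule |
|---|---|---|
| base | exonic base positions (union, strand-agnostic) | shared position |
| exon | distinct exact exon intervals | identity |
| intron | distinct exact intron intervals | identity |
| intron chain | distinct full ordered chains (multi-exon) | exact chain |
| transcript | transcript records | chain match, or ≥ 80% single-exon reciprocal overlap of the longer |
| locus | single-linkage clusters by exonic overlap | contains a matched transcript |

Decisions taken where the rules were ambiguous: the 80% ratio is over
the *longer* transcript (the stricter reading); exon matching is exact
including terminal exons (terminal-exon fuzziness is not specified
anywhere testable); base counting is strand-agnostic; at transcript
level the query total counts *records* while only one record per
distinct matched structure counts as correct — so bin-overlap
duplicates genuinely lower transcript precision (and only there; chain
level counts distinct chains). Strand `.` is compatible with either
strand. Every level is validated against an independent naive O(n²)
comparator on 1,000 random annotation pairs.

## 7. The simulator: what it emulates, what it does not

`sim_config()` defaults state the package's reference world: 2
chromosomes × 1 Mb of uniform random A/C/G/T, 20 genes placed
non-overlapping with ≥ 1 kb gaps, 2 isoforms per gene, 2–6 exons of
150–400 bp (minimum ≥ read length, so a read touches at most one
junction), introns 100–1000 bp, and zero-error 100-bp paired-end reads
at 1000 pairs per transcript with fragment length ~ N(250, 25²)
(typical short-insert libraries), uniform fragment starts. Intron
boundary dinucleotides are overwritten to `GT..AG` on the gene's strand
so motif-based strand inference works. In disjoint-isoform mode (the
default, and the assembler's exact-recovery regime) isoforms of a gene
occupy disjoint genomic sub-intervals, sharing no exons or junctions.
Multi-sample mode partitions transcripts round-robin across samples to
emulate single-cell expression heterogeneity.

Not emulated, deliberately: sequencing error profiles beyond uniform
substitutions, PCR duplicates, expression-level distributions, GC and
length bias, overlapping genes, shared-exon isoforms. A green test on
this world therefore establishes the *pipeline contracts* (determinism,
equivalence, geometry, exact recovery under clean evidence) — not
performance on real tissue data, where assembly accuracy is dominated
by factors this generator excludes. Uniform fragment starts (rather
than a length-biased model) are the simplest model satisfying the
coverage assumptions of the exact-recovery property.

## 8. Numerical and degenerate-input choices

* All text ordering uses C-locale radix sorting, so outputs are
  locale-independent.
* Empty FASTQ input yields zero chunks (not one empty chunk); empty
  annotations round-trip through comment-only GTF files.
* Coordinates are 1-based inclusive in GTF/SAM space and 0-based
  half-open in bin space; `reference_span()` is the single conversion
  point for records.
* `chunk_size` larger than the sample collapses to one chunk;
  oversized bins (over `max_bin_records`) fail with the three
  documented remediations (batching samples, more memory per worker,
  align-then-assemble) rather than exhausting worker memory.
* Ambiguity tie-breaks (seed placements, split points, duplicate
  structures) are all total orders, stated in the function docs —
  determinism is treated as part of correctness, not a nice-to-have.

## 9. Known limitations

The built-in aligner is exact-match, single-intron, and unsuitable for
real reads; it exists to make the framework's guarantees testable. The
assembler does not estimate expression and will enumerate at most
`max_paths_per_component` isoforms per component. De novo transcripts
longer than `bin_size + bin_overlap` are not assembled. GffCompare-style
class codes and per-transcript tmap outputs are out of scope, as are
cloud/cluster execution, autoscaling and the comparison of wall-clock
performance that motivated the original distributed design.
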