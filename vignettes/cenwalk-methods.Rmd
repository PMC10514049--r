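---
title: "Methods: walking assembly and CENP-A domain mapping with cenwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: walking assembly and CENP-A domain mapping with cenwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`cenwalk` is a desk-scale pipeline for a specific epigenomics problem:
a satellite-free centromere whose underlying reference sequence is
misassembled — a false tandem duplication, N-gaps, and a redundant unplaced
contig — so that the CENP-A ChIP-seq enrichment peak over the locus is
irregular and riddled with coverage dips. The package (i) rebuilds the locus
from raw reads by iterative chromosome walking, (ii) patches the reference
and emits a coordinate liftover, (iii) profiles CENP-A enrichment as an
RPKM-normalized ChIP-minus-input track, (iv) calls broad enrichment islands
with a window/gap scan and FDR filtering, and (v) classifies whether the
CENP-A domain position is conserved across tissues of one individual or has
slid. A seeded synthetic-data generator reproduces the whole study design in
miniature and provides ground truth for every stage.

## The synthetic study system

`make_true_locus()` draws an i.i.d. base sequence at a chosen GC content
(default 0.42, a typical mammalian value). An i.i.d. sequence is effectively
repeat-free at the k-mer sizes used by the walker (40–95 nt) and the aligner
(30 nt), which is precisely the property that makes a satellite-free
centromere mappable with short reads; this is the one feature of the real
locus the generator must reproduce faithfully.

`corrupt_reference()` inverts the curation the pipeline is meant to perform:
it duplicates a chosen block in tandem, separates the two copies with an
N-run, inserts further N-gaps, and optionally emits an unplaced contig equal
to the duplicated block — the anatomy of the misassembly the true data
presented.

Read simulation (`simulate_wgs_pairs()`, `simulate_chip_pairs()`) draws
fragments of 200–800 bp (the sonication range of the emulated libraries) and
sequences 75-nt mates from the two fragment ends. ChIP enrichment uses a
plateau model: a fragment whose midpoint falls inside the CENP-A domain of
the homolog chosen for it (probability `mixture`, default 0.5) is sampled
with weight `fold`, all other positions with weight 1. A plateau is the
simplest model consistent with the broad, roughly rectangular domains the
method targets; Gaussian tapering is deliberately not modelled. Two homologs
with different domain intervals produce positional epialleles; the default
panels use coincident homologs. Errors are substitutions only — indels would
break exact-match walking and are out of scope by design; this is a
documented limitation, not an accident. Defaults that the study design does
not pin down were fixed once as field-realistic values: ChIP enrichment fold
8, sequencing depth 30x per library, substitution rate 0.001; WGS depth 50x
error-free for assembly fixtures; long reads exponential around 5 kb at
20x. The simulated panels therefore do *not* emulate GC bias, fragment-size
bias, PCR duplicates, mappability structure, satellite arrays, or diploid
SNPs — passing tests demonstrate the algorithms recover what they were given
under clean, known conditions; they do not certify performance on real
libraries.

Coordinates are 1-based inclusive everywhere inside the package; conversion
to 0-based half-open happens only at BED/bedGraph boundaries.

## The walking assembler

The walker reimplements, as code, a procedure that was originally
semi-manual: design a query of 60–95 bp from the end of trusted sequence,
retrieve every joined read pair containing it verbatim (either mate, either
orientation), align the retrieved reads, extend the consensus, design a new
query on the new end, repeat.

Choices that needed fixing where the original procedure relied on judgement:

* **Exact query matching.** Queries are matched as verbatim substrings (the
  original used `grep`); error tolerance is delegated entirely to consensus
  voting across reads.
* **Consensus thresholds.** A column is emitted while coverage is at least
  `min_support` (default 5 reads) and the majority base reaches
  `min_agreement` (default 0.8). Any column failing agreement stops the walk
  rather than emitting an ambiguity code — the automated stand-in for
  correcting non-ACGTN consensus bases by visual inspection.
* **Branches.** If two bases each reach `branch_fraction` (default 0.3) of a
  well-covered column, the walk stops and reports the base counts. The
  walker never chooses a branch silently; heterozygosity and repeat
  decisions are surfaced to the caller.
* **Query length.** The default query is 60 nt, the short end of the
  60–95 nt range: with 75-nt mates a read can only extend the consensus when
  it contains the query with bases to spare, so longer queries leave
  nothing to extend with. When a step yields no extension, it is retried
  with successively shorter queries down to `min_query_len` (default 40 nt)
  — the in-silico analogue of varying the query length when a walk stalls.
  On an i.i.d. locus a 40-mer is still unique with overwhelming margin.
* **Mate independence.** Mates are searched independently; mate-pair
  distance is never used for ordering or scaffolding.

`close_gap()` walks inward from both flanks and merges as soon as a suffix
of the left consensus equals a prefix of the right consensus over at least
`min_merge_overlap` (default 100) exactly matching bases, checking after
every extension so walks never overshoot. `resolve_region()` splices the
merged sequence back into the draft between `query_len`-wide trusted flanks.

**Known limitation (by construction).** Overlap merging cannot distinguish
one copy of a repeat from two when the repeat is longer than
`min_merge_overlap`: walking into a genuine 2 kb tandem duplication from
both sides, the walks meet *inside* the repeat and collapse it — every
window of the collapsed sequence is individually read-supported, so no
short-read evidence contradicts it. Copy-number adjudication is therefore
delegated to `validate_structure()`, which counts long reads containing the
diagnostic junction string of each candidate structure (anchors of 500 bp
around the divergent region; for the collapsed candidate the diagnostic
spans the entire repeated block, since its short junction also occurs at the
second copy's exit). A read supports at most one structure. This mirrors the
role long reads played in the original analysis.

## Reference patching and QC

`replace_interval()` performs a single-interval splice (prefix + new
sequence + suffix), drops listed redundant contigs, and emits a liftover map
as a three-column block table: positions before the interval map
identically, positions after shift by the length difference, positions
inside (and dropped contigs) map to deleted. A simple block table was chosen
over a chain dialect because it is bit-exact, trivially parseable and
sufficient for single-interval edits; multi-interval patching and
inversions are out of scope. `assembly_stats()` reports N-content as
`n_count * 100000 / length`, rounded to two decimals (the conventional
QUAST-style precision).

## Enrichment profile

`align_reads_minimal()` is deliberately minimal and fully specified: exact
30-nt seed (first bases of the read, both orientations), full-length
verification allowing at most 3 substitutions, and a *unique best*
placement; ties — exactly what a false tandem duplication produces — leave
the mate unmapped, keeping all downstream counts deterministic. This is a
contract stand-in for a production aligner, not a competitor to one.

Tracks are binned at 50 bp by default (small enough to preserve kb-scale
peak shape; the normalization granularity is not dictated by the study
design, so it is exposed as a parameter), each mapped mate counting once at
its leftmost coordinate. RPKM normalization is
`count / ((bin/1000) * (library/1e6))`; the ChIP-minus-input difference
keeps negative values. Note one consequence of RPKM-subtractive
normalization worth knowing when reading the tracks: because ChIP reads
redistribute into the domain, the background outside a strong domain sits
slightly *below* zero rather than at it.

## Island calling

The window/gap island framework is used with its two published parameters —
200 bp windows, 1000 bp gaps — and FDR filtering at 0.01. The framework's
internal thresholds are not published alongside those parameters, so this
module fixes a self-contained, deterministic variant, documented here and
not claimed byte-identical to any external tool:

* window eligibility against a genome-wide Poisson background
  `lambda_w = total_reads * window_bp / effective_len` at upper-tail
  probability < 0.20 (`effective_len` = non-N reference length);
* candidate islands by merging eligible windows whose start-to-start
  separation is at most `gap_bp + window_bp` (bridging up to `gap_bp` of
  ineligible sequence);
* island significance against the input-scaled expectation
  `expected = max(input reads in island, 1, island_len * genome-wide input
  rate) * chip_total / input_total`, scored with the exact Poisson upper
  tail;
* Benjamini–Hochberg q-values, islands kept at q <= 0.01.

Two refinements proved necessary for the q-values to mean what they claim
— without them, fold-1 null libraries produced "significant" islands in
most runs:

* **Selection-aware expectation.** Islands are assembled from windows
  selected for high counts, so under the null an island's summed ChIP count
  systematically exceeds `lambda_w` per window. The expectation is floored
  at the eligibility-conditioned value
  `n_eligible * E[X | X >= c] + n_bridged * E[X | X < c]` (with `c` the
  eligibility count threshold), and at the genome-wide input rate over the
  island — a locally under-sampled input is a noisy Poisson draw, not a
  known mean, and taking a low draw at face value manufactures
  significance (the same reasoning behind max-lambda backgrounds in
  established peak callers).
* **Scan-level multiplicity.** BH corrects over the number of windows
  scanned, not merely the islands that survived eligibility: the scan is
  the experiment, the islands are its selected outcomes.

With these, a fold-1 panel yields FDR-significant islands in well under 5%
of seeded runs while an 8-fold domain is recovered with p-values
indistinguishable from zero. With no input library (ChIP-only mode) islands
are scored against the genome-wide background over their own length, with
the same selection floor. Read-redundancy filtering is off by default
because simulated reads are unique.

## Domain comparison

Islands within 10 kb merge into domains; each domain carries its area (sum
of positive difference signal), apex (maximum bin midpoint), an apex
asymmetry statistic (signed difference of positive signal mass right minus
left of the apex, as a fraction of area — it annotates tail-shaped domains
but never changes any label), and optional sub-peaks. `split_subdomains()`
cuts at maximal runs of at least 2 kb where the signal drops below 0.25
times the smaller flanking sub-peak maximum (running maxima on either side,
so edge valleys never split); two well-separated epiallele peaks yield two
subdomains, coincident homologs one.

Conservation had no published numeric criterion — the original call was
made visually and by island concordance — so the package operationalizes it
explicitly and reports the thresholds in every output: a tissue's
best-matching domain (maximal overlap coefficient
`|a intersect b| / min(|a|,|b|)`, ties by smaller center shift) is
*conserved* when the overlap is at least 0.5 and the midpoint shift at most
half the reference span; *slid* otherwise; *absent* with no domains at all.
The panel summary is conserved only if every tissue is. Half-span is a
deliberately coarse bound: one-generation sliding events of 50–80 kb on
~100–200 kb domains move the midpoint by roughly half a span or more, while
resampling noise on a recovered domain boundary is a few windows.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full design in
miniature, chosen so every stage's contract is exercised at meaningful
coverage: 30 kb loci with a 2 kb false duplication and 1 kb gap for
assembly recovery (error-free 50x WGS pairs, 20 seeds); a 40 kb locus with
an 8 kb fold-8 domain at 30x ChIP + input for domain recovery; 200 fold-1
runs for the FDR null; five-tissue panels over 50 seeds for conservation
and sliding (a 12 kb slide, 1.5x the domain span). Poisson tails use the
exact upper-tail sum (stable far beyond the lambda ~ 1e4 regime these
window counts reach); ties in consensus voting resolve alphabetically via
the stable sort of base counts, making every walk deterministic; all
randomness flows from explicit seeds, with per-stage seeds derived by a
fixed integer hash so that stages are independently reproducible.
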