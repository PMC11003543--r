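---
title: "Curating and annotating transposable elements with tecurator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and annotating transposable elements with tecurator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecurator)
```

## The problem

Transposable elements (TEs) make up large fractions of eukaryotic genomes.
Annotating them requires two linked artifacts: a *library* of family
consensus sequences, and per-genome *annotations* locating every
recognisable copy. De novo family discovery tools tend to emit consensus
models that are truncated relative to the real element, and library-based
annotators emit fragmented, overlapping intervals. `tecurator` implements
the computational core of a curation-and-annotation workflow that addresses
both: an iterative consensus-extension procedure that grows truncated
consensus models out to true element boundaries, and a post-annotation
refinement pass that defragments, de-overlaps and summarises the
annotations. A paired genome simulator and a nucleotide-level benchmark
close the loop, so every stage can be tested against ground truth.

De novo family discovery itself is out of scope: every workflow here starts
from a user-supplied library (`run_pipeline(..., library = )`).

## Iterative consensus extension

Each `RAW` consensus is curated by `beat_curate()`:

1. **Tandem triage** (`triage_consensus`). A consensus that is more than 90%
   tandem repeat is classified `TANDEM` and never curated. Between 50% and
   90%, the longest non-tandem section becomes the final consensus. At or
   below 50%, curation proceeds. Thresholds are strict: exactly 0.90 is not
   "more than 90%", and exactly 0.50 proceeds.
2. **Copy search** (`find_hits` + `select_candidates`). Genomic copies with
   identity > 0.70 and query coverage > 0.50 are candidates; the top 20 by
   score are used. Fewer than 3 ends curation (on the first iteration the
   record is `LOW_COPY`).
3. **Flank extension** (`extend_flanks`): each copy is extracted with
   1,000 bp of flank on each side (clamped at contig ends; minus-strand
   copies reverse-complemented into query orientation).
4. **Validation** (`validate_extended`): every extract must still align to
   the *round-0* consensus at the same thresholds. This prevents the
   iteration from locking onto a more abundant repeat that happens to
   neighbour a genuine copy.
5. **Mutual-support trimming** (`trim_to_mutual_support`): flank sequence is
   kept only where at least one other extract aligns to it; unsupported
   tails are removed, and the pre-extension core is never trimmed.
6. **Consensus rebuild** (`build_consensus`): a centre-star multiple
   alignment of the trimmed extracts plus the starting consensus is built;
   columns holding exactly one non-gap symbol are removed; the starting
   consensus row is removed; the remaining rows are realigned and a
   majority-rule consensus emitted (columns with fewer than two non-gap
   symbols emit nothing).
7. **Assessment** (`assess_iteration`): a new consensus that is shorter than
   the previous one, or covers less than 80% of it, is a quality reduction
   and the previous consensus is final (`REVERT`). Growth below half the
   flank size means the element is complete (`DONE`); growth of at least
   half the flank size triggers another round, up to 10 iterations.

After the loop, `classify_satellites()` flags consensuses that are more than
50% tandem; among those, a single contiguous region covering more than 90%
of the sequence with period of at least 200 bp makes the record a
`MACROSATELLITE`, trimmed to exactly one period.

### Numerical choices

* The internal aligner is a k-mer-seeded (k = 11, both strands), diagonally
  clustered, banded affine-gap local aligner scoring match +2, mismatch -3,
  gap open -5, gap extend -2 (a gap of length L costs 5 + 2L). A full
  Smith-Waterman under the same scoring backs `pairwise_align()`. The test
  suite checks the seeded engine against an independent Smith-Waterman
  implementation (Biostrings) on planted copies: top-hit identity agrees
  within 0.02 and coordinates within 5 bp.
* Seed clusters need at least 2 k-mer seeds (`engine_params(min_seeds=)`)
  before a banded extension is attempted. A single shared 11-mer between
  unrelated kilobase-scale sequences is expected by chance; requiring two on
  one diagonal suppresses that noise at negligible sensitivity cost for
  copies of annotatable length.
* Mutual-support trimming requires support alignments to score at least 45
  and to be contiguous with the core (support intervals merged across gaps
  of at most 100 bp; the crop is the merged block containing the core).
  Without these guards, chance micro-alignments between unrelated host
  flanks retain whole flanks and the consensus over-extends well past the
  true element boundary.
* Majority rule breaks ties in fixed base order A < C < G < T; `N` is
  non-gap but never beats a concrete base. The centre-star MSA uses
  free-end-gap banded alignment against the longest sequence, with the band
  centred on the seeded-alignment diagonals.
* The growth comparison is made against the *previous iteration's*
  consensus, consistent with the revert and continue rules that surround it.
* Validation is always against the round-0 consensus, not the current one.

## Tandem detection

`detect_tandem()` scans every candidate period from 1 to 2,000 bp and
extracts maximal segments in which the sequence matches itself shifted by
the period at 75% or more of positions (scored +1/-3 so non-negative
segments satisfy the bound, with an X-drop cutoff and a minimum net score of
10 to exclude chance self-similarity in random sequence). Regions detected
at a harmonic of an already-covered region are suppressed, so each region
carries its fundamental period — this matters for the macrosatellite rule,
where a 150 bp unit must not be reported at period 300. The detector is
deterministic, and every reported region is re-verifiable by direct
counting.

## Annotation and refinement

`annotate_genome()` searches every library consensus against every contig on
both strands and resolves competing hits greedily by descending score: a
locus keeps its best-scoring family, and lower-scoring hits are truncated to
whatever remains free (fragments under 10 bp are dropped). Ties break by
longer alignment, then family id, making the output deterministic. Each
annotation carries a raw p-distance and a Kimura 2-parameter distance
computed from the transition/transversion counts of its alignment.

`defragment()` merges same-family, same-strand annotations separated by at
most 150 bp (inclusive) into one locus; the merged divergence is the
length-weighted mean, which keeps remnants of one degraded insertion from
counting as several young fragments. Supplied full-length-LTR intervals
additionally merge LTR-classified annotations that fall inside them.
`resolve_overlaps()` drops annotations contained in another and splits
partial overlaps at the midpoint (odd overlap: extra base to the leftmost
annotation), conserving exactly the union of annotated bases.
`length_filter()` optionally removes annotations under 100 bp and is off by
default.

`summarize_annotations()` produces the classification pie (summing to 100%
of the genome), the family table (sorted by bp), and a repeat landscape of
genome percent per 1% Kimura-divergence bin from 0 to 50. Kimura distances
use the plain two-parameter form `K = -ln((1-2p-q) sqrt(1-2q))/2` without
CpG adjustment; outside the valid domain the distance is saturated and the
annotation is excluded from the landscape (values above 0.50 clamp into the
last bin with a warning).

## The simulator: what it emulates, and what it does not

`simulate_genome()` builds an i.i.d. base sequence at a configured GC
content, inserts every family's copies at uniform-random distinct positions
(strand uniform; per-copy divergence uniform on `[0, divergence_max]` with
transitions twice as likely as transversions; a configured fraction of
copies truncated), then inserts nested copies inside first-pass insertions.
Insertions *expand* the genome rather than overwrite it, so non-TE bases
stay uncontaminated and the confusion matrix is well defined. Host
insertions keep one record spanning their full extent; nested children
carry `parent_id`.

Values the underlying design leaves open were fixed once and are exposed in
`sim_config()` / `random_sim_config()`:

* copy numbers: rounded normal draws, mean 150, sd 120, clamped to
  [5, 732] — few families at low copy number, most intermediate, few very
  high;
* fragmentation removes a uniform(10%, 90%) prefix or suffix (coin flip);
* nested copies number `round(nested_fraction * copy_number)` per family and
  are mutated but not fragmented;
* default divergence ceiling 0.30, matching heavily decayed real content.

The simulator does **not** emulate target-site duplications, insertion-site
preference, segmental duplication, GC heterogeneity along the genome, or
indel-dominated decay (indels are off by default; with the default
substitution-only mode the genome length is exactly base + inserted bp). A
green benchmark therefore establishes that the pipeline recovers what it
was pointed at under idealised copy structure — not that it handles
structural complexity beyond what is modelled.

## Benchmarking

`confusion()` labels every base TP/FP/FN/TN by presence in the test and
reference interval unions (element identity is ignored at this stage) and
`mcc()` computes the Matthews correlation coefficient with the usual
zero-denominator-means-zero convention. `classification_agreement()` works
per reference copy at a 50% coverage threshold, comparing top-level classes
(the part before `/`). `fragmentation_ratio()` reports the mean number of
overlapping test annotations per shared reference annotation.
`consensus_length_band()` pairs each test consensus to its best-scoring real
sequence and reports lengths as percent of real, summarised by the 95–105%
band.

The acceptance suite ties these together: identical annotations score MCC
+1, the exact complement scores -1, coverage-matched random annotations
average 0 within ±0.05; curating truncated seeds across 20 simulated
families recovers at least 80% of consensuses to within 95–105% of true
length; and simulate → annotate (true library) → refine scores MCC ≥ 0.95
with zero overlapping bases. Those runs use 2–3 Mb genomes — deliberately
below the multi-hundred-Mb scale of real assemblies — so a green suite
demonstrates correctness of the machinery at desk scale, not performance
parity with production annotators.

## Known limitations

* The annotator has no small-RNA-gene exclusion and no equivalent of
  RepeatMasker's sensitive-mode engines.
* 5'-truncation-aware asymmetric extension (relevant to LINEs) is not
  implemented; extension is symmetric.
* Full-length LTR intervals are consumed from a file, never computed.
* The centre-star MSA is a heuristic; for highly diverged families a true
  progressive aligner would produce cleaner columns. The external-aligner
  adapter seam exists (`build_consensus` is a pure function of its inputs)
  but only the internal aligner is tested.
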