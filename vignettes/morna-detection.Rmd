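---
title: "Detecting miRNAs, moRNAs and their isoforms with moRquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNAs, moRNAs and their isoforms with moRquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moRquant)
```

## The biological problem

MicroRNA precursors (pre-miRNAs) are ~60-110 nt hairpin transcripts. Drosha
and Dicer excise the mature miRNA from one arm of the stem, but small RNA
sequencing shows that the same hairpin locus produces a richer set of
products: the complementary (star) miRNA from the opposite arm,
miRNA-offset RNAs (moRNAs) from the regions immediately adjacent to the
hairpin on either side, reads from the terminal loop, and sequence isoforms
of all of these (isomiRs/isomoRs) that differ in end positions or carry
non-templated 3' additions. Generic miRNA quantifiers ignore moRNAs and
loop reads; moRquant characterizes all of them with homogeneous criteria.

## The pipeline

Per sample the stages are:

1. **Preprocessing.** 3' adapters are trimmed (partial adapter at the read
   end allowed, error rate <= 0.1); reads with no adapter are discarded as
   non-read-through inserts. Trimmed reads are filtered by length
   (`MIN_LEN`/`MAX_LEN_FILTER`, default 18/30 nt), mean Phred quality
   (`MEAN_QUAL_FILTER`, default 30) and at most 2 bases below Phred 20.
   Survivors are collapsed into unique counted sequence tags; tags with
   fewer than `MIN_COUNT` reads (default 10) are removed as background.
2. **Genome filter.** Tags are matched exactly against the genome on both
   strands. A tag with more than `MAX_OUTSIDE_LOCI` (default 5) hits
   *outside* precursor loci is discarded as an unresolvable multi-mapper;
   hits inside precursors do not count against it, so multi-locus miRNA
   families survive. Tags with zero genome hits are retained: a read with
   non-templated 3' additions matches no genomic window exactly but still
   aligns to its precursor with mismatches.
3. **Hairpin geometry.** Each precursor is extended by 30 genomic
   nucleotides per side (moRNAs live in these flanks) and folded. The star
   interval of every annotated mature is projected through the base-pair
   table with the canonical 2-nt 3' overhang of the Drosha/Dicer duplex.
4. **Assignment.** Tags are aligned to the extended precursors allowing up
   to 2 mismatches; 2-mismatch alignments are kept only when both
   mismatches sit on the two 3'-terminal read positions (non-templated
   addition). Perfect alignments are clustered into blocks seeded by the
   most abundant tag; blocks define which annotated miRs are expressed,
   which star projections become new miRNAs, and the data-driven
   coordinates of moRNAs (blocks inside the flank windows, length >=
   `MIN_MORNA_LEN`) and of the loop sRNA. A conservative filter
   (`MORFILTER`) removes moRNAs whose sequence is shared with any miR in
   the catalog. Every surviving alignment is then assigned to the sRNA
   whose ends it matches within `ALLOWED_OVERHANG` (default 3 nt), with
   maximal reciprocal overlap and the precedence miR > new miR > moR >
   loop; everything else is reported as unassigned rather than silently
   dropped.
5. **Isoform quantification.** Each assigned read gets exactly one of 8
   labels: `canonical`, `mm1`, `mm2_3p`, `short5p`, `short3p`, `long5p`,
   `long3p`, `len_both`. Mismatch labels take precedence over length labels
   when both apply, but the full end offsets and mismatch positions are
   emitted in the isoform table, so the single label loses no information.
   Counts are summed per isoform and per sRNA; CPM normalization can drop
   loop rows first (they are flagged), renormalizing the remainder.

## Design choices where the design was open

* **Base-pair maximization instead of thermodynamic folding.** Only the
  pairing topology is consumed (star projection), so the built-in folder is
  a Nussinov-style maximum base-pair DP (Watson-Crick + G:U, minimum loop
  3) with a deterministic traceback (unpaired preferred on ties, otherwise
  the outermost partner). An external MFE dot-bracket can be supplied per
  precursor (`fold_tsv`) and is validated against the same invariants; the
  suite checks that feeding the generator's true structures reproduces the
  built-in calls on the simulated fixture.
* **Star acceptance.** A star is projected only when >= 60% of the mature's
  positions are paired, and is vetoed when it would overlap an annotated
  mature by more than 3 nt. Both thresholds are configurable arguments of
  `project_star()`; they are this package's choices, not values taken from
  any reference implementation.
* **Star overhang direction.** The star interval is the pairing-partner
  span shifted by +2 in transcript coordinates. This is the standard 2-nt
  3'-overhang duplex geometry; on a perfect stem it holds for matures on
  either arm.
* **Block boundaries.** Alignment blocks are seeded by the most abundant
  tag (ties: longer, leftmost, lexicographic) and alignments join a block
  when they overlap its seed by more than half their own length. Seeds are
  allowed to overlap by a few terminal bases: a moR block adjacent to a
  highly expressed miR overlaps it by design (real moRs overlap their miR
  in a few terminal bases), so blocks are only merged when a later seed
  overlaps an earlier one by more than half of its own length. The
  package asserts the correspondingly relaxed non-overlap invariant.
* **moR windows without expressed miRs.** A moR window exists whenever its
  arm is *defined* (by annotation or star projection), whether or not that
  arm product is itself expressed. Requiring expression would make moR
  detection depend on the adjacent miR's abundance, which contradicts the
  observation that some moRs outnumber their miR.
* **Cross-mapping.** A tag assignable on several precursors contributes its
  full count to each, with a `cross_map` flag, supporting multi-locus
  miRNAs; the duplication is visible in the isoform table.
* **Adapter-less reads are discarded** (counted in the run log): with
  read-through small RNA protocols, a missing adapter means the insert was
  longer than the read.
* **N-containing reads are dropped at collapsing**: exact tag matching is
  meaningless with ambiguous bases. The count is logged and enters the
  conservation identity.

## What the simulator emulates

`simulate_dataset()` builds a fully stated world: perfect-stem hairpins
(stem 30 bp, loop 14 nt, 22-nt matures inset 4 nt from the stem ends,
30-nt random flanks), embedded on alternating strands in random background
separated by 200-600 nt gaps, with annotated matures cycling through the
3p arm, the 5p arm and both arms. Planted per precursor: the annotated
miR(s), the star product, a 20-nt moR on each side overlapping the arm
product by 2 nt (the few-terminal-bases overlap seen in real data), and
the ~20-nt loop sRNA. Default planted counts are 500 (miR), 120 (star),
50 (moR) and 25 (loop) reads - a realistic abundance ordering in which
moRs and loops are minor products but all exceed the default `MIN_COUNT`.
Reads carry the 3' adapter and flat Phred-40 qualities; isoform variants
and low-quality bases are planted deterministically, never sampled as
instrument noise.

Because the planted star/moR/loop truth is computed analytically from the
duplex geometry, the generator rejection-samples each hairpin
(deterministically from the seeded RNG) until the built-in folder's star
projection reproduces the analytic star exactly. This makes end-to-end
recovery a property of the stated world rather than of a lucky seed - any
seed yields a consistent fixture.

What the simulator does **not** emulate: realistic expression
distributions, ligation bias, sequencing error beyond planted positions,
imperfect hairpins (unless `bulges > 0`), overlapping precursor loci, and
annotation errors. A green end-to-end test therefore establishes that the
machinery is lossless and exact on ideal data; it does not establish
sensitivity or specificity on real libraries.

## Numerical choices and degenerate inputs

* Intervals are 0-based half-open on the transcribed strand everywhere
  inside the package; GFF3 I/O converts once at the boundary, and the
  conversion round-trips exactly on both strands.
* Mean read quality is the arithmetic mean of Phred values, not of error
  probabilities - simpler, monotone, and testable.
* The aligner reports only the best mismatch stratum (all 0-mm placements
  if any, else 1-mm, else 2-mm), mirroring stratified short-read alignment.
* Ties are broken deterministically at every stage (block seeding order,
  assignment precedence, traceback), so identical inputs give
  byte-identical outputs.
* Degenerate cases: empty FASTQ yields an empty (headers-only) output set;
  a sample whose total count is zero makes CPM normalization fail loudly;
  a precursor on a missing chromosome is an error; flanks are truncated at
  contig edges and the obtained lengths recorded.

## Known limitations

* No novel-precursor prediction: unannotated precursors enter only through
  the extra-precursor GFF3 input.
* No probabilistic multi-mapper rescue; cross-mapped counts are duplicated
  and flagged rather than apportioned.
* The built-in folder ignores thermodynamics; a bulged or G:U-rich stem
  may fold differently than an MFE folder would, shifting star projections
  by a few nucleotides (use external-fold mode when exact parity with an
  MFE folder matters).
* Differential expression and TMM normalization are downstream of this
  package; only raw counts and CPM are produced.
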