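---
title: "Classifying knock-in insertion patterns from nanopore amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying knock-in insertion patterns from nanopore amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knockinr)
library(dplyr)
```

## The problem

A double-cut donor plasmid delivered alongside CRISPR-Cas9 is linearized in
the cell into two pieces: the expression cassette (here called `F`) and the
plasmid backbone (`B`). At the genomic double-strand break, zero, one or
several of these pieces — in either orientation, sometimes degraded,
sometimes accompanied by unrelated DNA — are captured. Long-read amplicon
sequencing across the edited locus reveals this whole spectrum at once, but
at a ~5% per-base, indel-dominated error rate that defeats naive exact
matching and alignment-first genotyping of low-frequency species.

knockinr classifies each read of a pooled, barcoded nanopore amplicon run
into this outcome space. It is organised around a simple and robust idea:
**short exact k-mer probes + expected-length arithmetic**. An individual
17-mer survives 5% noise with probability $0.95^{17} \approx 0.42$, so a
modest panel of probes per target detects the target in essentially every
read, while a chance exact 17-mer match has probability $4^{-17}$ per
position and effectively never happens. Read length, which nanopore
preserves well apart from a small indel random walk, does the rest of the
work of distinguishing compositions.

## The amplicon model

The background (unedited) amplicon is `left flank + right flank` around the
cut (146 bp + 186 bp = 332 bp in the locus design used throughout the
package's defaults). An insertion product for a multiset of fragments has
expected length

$$L(\text{composition}) = L_{\text{background}} + \sum_i L_i .$$

With two fragment types and up to three captured pieces there are
$\sum_{k=1}^{3}\binom{2+k-1}{k} = 9$ compositions (B, F, BF, BB, FF, BBF,
BFF, BBB, FFF) and $4 + 16 + 64$ orientation-resolved chains. Reads are
binned by a window of ±20% of the expected product length, with the
half-width rounded to the nearest 100 bp; the single-backbone product of
2506 bp thus collects reads of 2006–3006 bp.

```{r categories}
set.seed(20260922)
refs <- sim_references()
cats <- enumerate_categories(refs$library, refs$locus)
cats |> select(category, n_pieces, expected_length, lo, hi)
```

Windows of different categories may overlap (BB against F, BF against BBB).
A read in several windows is tested against each candidate and resolved by
probe content; a read whose probe content matches more than one candidate
is reported `ambiguous` rather than double-counted.

## Probe design

* **Flank probes** (k = 17, step 20 along each retained flank, plus one
  probe anchored at the flank's inner end) verify that the read is an
  amplicon of the target site and anchor the insert's inner edges, Alb-L-r
  and Alb-R-l in the locus nomenclature.
* **Component probes** (20 evenly spaced 17-mers per fragment and
  orientation; reverse probes are reverse complements) are screened at
  panel build time against the flanks, the other components and any
  editing-plasmid references, so a hit is unambiguous evidence for one
  component in one orientation.
* **Barcode probes (BCseqs)**: the 11-mers at step 1 from the 11-nt barcode
  plus the first 6 nt of the shared primer. Any single edit in the outer
  parts of this 17-nt region leaves an intact 11-mer; edits in the central
  overlap of all seven windows (positions 7–11) cannot be rescued by exact
  matching, which is why a few percent of heavily noise-hit reads end up
  `unassigned` rather than misassigned. `barcode_spec(prefix_len = 11)`
  shrinks the blind spot to the last two barcode bases at the cost of a
  longer probe region.

A fragment's homology arm is, by construction, also genomic flank sequence.
Flank probes falling inside the arm therefore also hit the donor copy of
the arm inside the insert. The caller projects every flank hit back to the
flank start it implies and takes the **leftmost** projection cluster for
the left flank (the genuine flank is always the leftmost occurrence) and
the rightmost for the right flank; anchors that still imply an absurd
pre-flank prefix are re-derived from the opposite anchor and the read
length. This matters for patterns where the cassette sits away from the
left junction.

## Pattern calling

For each read with both flank anchors, each length-window candidate
category is scored inside a restricted probe range: the perfect insert span
(`147..2320` for single-B) shrunk inward by a 300 bp margin per side
(`447..2020`), which keeps junction-spanning noise out of the evidence. A
component orientation is *present* with at least `min_hits = 2` exact probe
hits. The default margin reproduces the published single-backbone example;
`min_hits = 2` is calibrated so that a full-length fragment is missed with
probability well under 1% at 5% error (a binomial tail with ~14–18 in-range
probes at 0.42 survival), while two chance exact 17-mers in one read are
essentially impossible — raising it to 3 costs ~3% of single-backbone calls
for no practical specificity gain.

Chains are reconstructed from hit positions: per present
component-orientation, hits are clustered into the number of copies the
candidate composition requires (cutting at the largest positional gaps;
per-probe occurrence counts apportion copies between orientations), and the
chain is ordered by cluster medians. The called chain's multiset must equal
exactly one candidate composition.

Proportions divide pattern counts by the number of reads carrying both
flank anchors, and are aggregated into the field's four report groups:
single-F, single-B, complete donor (exactly one F and one B) and compound.

## NHEJ versus HDR

End-joining capture of the intact donor leaves the homology arm twice in
tandem (the genomic copy, then the donor's copy); homology-directed repair
collapses them into one. The classifier aligns each arm locally
(identity ≥ 80, matches over alignment columns) inside a junction window of
arm length + 200 bp per side, merges alignments overlapping by more than
10 bp, and counts copies: two on any evaluable arm ⇒ NHEJ, exactly one on
every evaluable arm ⇒ HDR, otherwise Other. Directly adjacent (tandem)
matches are deliberately *not* merged — tandem arm duplication is precisely
the NHEJ signature. Alignments shorter than half the arm are ignored so
that micro-homologies do not masquerade as copies. An armless side (as in
an HA85-0 donor's right side) is simply not evaluable.

## Foreign and degraded inserts

Reads with both flanks but no matching category are routed to the foreign
scan. The insert is extracted strictly between the refined Alb-L-r and
Alb-R-l anchors and cascaded through:

1. **Degraded donor**: read < 2 kb with backbone probes and insert
   < 1700 bp ⇒ short-B; read < 5 kb with cassette probes and insert
   < 4400 bp ⇒ short-F. Both gates sit below 80% of the respective full
   lengths, the definition of a degraded insert.
2. **Editing-plasmid remnants**: exact 17-mers from the unique regions of
   the Cas9 plasmid (step 100) and of the sgRNA/U6 plasmid (step 40), both
   strands; one screened-unique hit is already decisive evidence.
3. **Genomic fragments**: local alignment of the insert against every
   genome contig sharing an exact 13-mer seed with it, identity ≥ 80,
   retained segments ≥ 50 bp, matches inside the user-supplied exclusion
   regions (the locus itself and cassette-homologous loci) discarded, the
   highest-identity contig winning where several explain the same stretch.
4. **LINE-1**: the same contract against a single retrotransposon consensus.

A read may carry several classes; segments are reported in insert order
with a compound flag when two or more distinct classes co-occur.

## Deletion metrics

Background-length reads are aligned glocally to the wild-type amplicon —
the reference end to end, the read ends free, so an internal deletion must
open a gap and cannot be silently clipped. From per-position depth the
**deletion index** is $(R - \overline{\text{depth}})/R$ with $R$ the number
of anchored reads: zero for gap-free coverage, and exactly $f$ when every
read deletes the same fraction $f$ (this closed form is why $R$ is the read
count, not the maximum depth, which the formula's wording would also
admit). **D100** is the fraction of reads whose largest deletion gap
overlapping the cut site (±50 bp window) exceeds 100 bp. Gap structure can
equally be ingested from SAM records; both paths agree exactly on
noise-free input.

## The simulator

`simulate_reads()` generates the full outcome spectrum with per-read
ground truth: `barcode + primer + left flank + insert + right flank`,
random strand, then an error model with independent per-base errors, 75%
of them indels (split evenly between 1-bp insertions and deletions), 5%
total by default. Its defaults are the conditions of the HA85-0 donor
study the package's tests reproduce:

* mixture weights: single-F 40.24% (38% of cassette insertions forward),
  single-B 44.47% (orientation split evenly — backbone orientation is not
  reported separately), complete donor 14.16% spread evenly over the eight
  two-piece chains, and the residual 1.13% spread over six representative
  compound patterns;
* HDR in 55% of forward single-cassette insertions (reported range
  54–65%); HDR removes the donor's left-arm copy, NHEJ retains it;
* foreign capture rates per read: genomic 1%, LINE-1 0.05%, each editing
  plasmid 0.1%, degraded backbone and cassette 1% each — matching the
  reported relative frequencies;
* large (>100 bp) deletions through the cut in 1.5% of background reads,
  110–250 bp (sizes are a design choice; the source data reports only the
  >100 bp rate);
* fragment length choices where no number is printed: degraded backbone
  350–1600 bp and cassette 600–4200 bp (mostly under half the full
  length, as observed, and always under the detection gates with a margin
  that keeps them out of the full-length windows), genomic inserts
  50–400 bp (98% of observed inserts are < 400 bp), LINE-1 fragments
  100–1505 bp and 3'-anchored (all observed inserts were truncated, the
  longest 1505 bp), U6-plasmid remnants 100–500 bp and Cas9-plasmid
  remnants 150–3000 bp (the observed modes are ~300 bp and < 500 bp /
  ~3 kb).

All reference sequences are random DNA with the real lengths (flanks
146/186, backbone 2174, cassette 5526, left arm 85 shared between the left
flank and the cassette head). Only lengths and sequence-sharing structure
matter to every algorithm in the package, so nothing is lost by not using
the real locus. What the simulator does *not* emulate: homopolymer-biased
nanopore errors, chimeric reads, quality-score structure (qualities are a
constant placeholder), PCR length bias between categories, and real
genomic repeat structure. Passing tests therefore demonstrate algorithmic
correctness and statistical calibration under the stated error model, not
robustness to every artefact of a real flow cell.

## A worked run

```{r run, eval = FALSE}
set.seed(1)
refs <- sim_references()
cfg <- simulation_config(refs, n_reads = 2000)
sim <- simulate_reads(cfg)
report <- run_pipeline(
  sim$reads, cfg$specs, refs$locus, refs$library,
  genome = refs$genome, line1 = refs$line1
)
glance(report)
autoplot(report$samples[[1]]$proportions)
```

## Numerical choices and edge cases

* Coordinates are 1-based inclusive throughout; exclusion regions use BED
  (0-based half-open) convention at the file boundary.
* Window padding is anchored on the *total product* length: the text that
  motivated the rule says "insertion size", but the only printed example
  (2506 ± 500) matches 20% of the product rounded to the nearest 100 bp,
  so that is the default and an exact (unrounded) mode is available.
* The probe-range margin is an absolute 300 bp per side (reproducing
  447–2020 from 147–2320); a fractional margin is available. A margin that
  empties the range falls back to the full insert span with a warning.
* A read in the background window is only called background if its
  projected insert is ≤ 30 bp; anything longer is routed to the foreign
  scan, so a 60-bp genomic capture is not swallowed by the background bin.
* Local alignment uses match 2, mismatch −3, gap open 5, gap extend 2;
  identity is matches over alignment columns, gaps included. Amplicon
  alignment for deletion metrics is global (so deleted reference bases
  must open a gap instead of being clipped) with gap open 24, extend 0.5:
  scattered 1-bp sequencing indels do not chain into large gaps, and a
  long deletion is not split by coincidental short matches inside it
  (a split must gain ≥12 matched bases). The barcode+primer prefix is
  trimmed before this alignment — left attached, it gets woven into the
  gap of a read whose left flank is heavily deleted. A deletion flanked
  by micro-homology has several placements yielding the identical read;
  the aligner's choice can shift the reported interval by a few bases,
  which the ±50 bp cut-site window makes immaterial.
* Zero-denominator proportion tables and zero-read coverage profiles are
  flagged undefined rather than silently returning numbers.
* Simulation problem sizes in the test suite (10,000 reads for mixture and
  deletion recovery, 2,000 for the noise-free oracle equivalence, hundreds
  for per-module checks) are chosen so every stochastic check has the
  statistical power its tolerance needs.

## Known limitations

* Chain order within repeated same-orientation copies (e.g. FfFf) is
  resolved by hit clustering, which is exact on clean reads but has probe-
  spacing resolution (~300 bp) on noisy ones; base-level junction
  refinement is out of scope and best done by aligning the emitted
  per-pattern references with a long-read aligner.
* HDR calling is restricted to forward single-donor insertions, as in the
  source method; compound insertions are never HDR-classified.
* Demultiplexing by exact 11-mers cannot rescue edits in the centre of the
  barcode region (see above); with 4 barcodes at 5% error about a fifth of
  reads are unassigned, while cross-assignment stays below 1%.
* The genomic scan is desk-scale by design (mini-genome, seed-and-extend
  local alignment). A full mammalian genome should be scanned with an
  external aligner and the hits fed back in as exclusion-filtered
  segments.
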