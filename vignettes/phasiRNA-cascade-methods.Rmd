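---
title: "Methods: small RNA target scoring, degradome validation and phasiRNA cascade inference"
author: "phasiCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA target scoring, degradome validation and phasiRNA cascade inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasiCascade)
```

# The biological problem

In plants, a ~21–22-nt miRNA guides Argonaute-mediated cleavage of its
target transcript between the bases paired to miRNA nucleotides 10 and 11.
When the trigger is 22 nt, the 3' cleavage fragment can be converted to
double-stranded RNA and diced processively into *phased* secondary siRNAs
(phasiRNAs): 21-nt duplexes laid head-to-tail from the cleavage site, each
duplex carrying the 2-nt 3' overhangs left by Dicer. PhasiRNAs in turn can
cleave transcripts in *trans* or in *cis*, seeding further phasiRNA
production and building a small regulatory cascade.

phasiCascade implements the full inference chain for discovering such
cascades on individual transcripts: expectation-scored target prediction,
precursor (hairpin) validation, degradome-based cleavage validation,
phasing-locus detection with register enumeration, secondary-trigger
inference, and network assembly — plus a seeded generator that produces all
of these data types with recorded ground truth.

# Target scoring

`scoreDuplex()` computes the optimal antiparallel alignment of an sRNA
against a transcript window under a penalty ("expectation") scheme standard
for plant miRNA target prediction: Watson–Crick pair 0, G:U wobble 0.5,
mismatch 1, affine gap penalties (open 2, extend 0.5), with every penalty
multiplied by 2 at sRNA positions 2–13 (the functionally critical pairing
region). Lower is better; `predictTargets()` reports sites with expectation
≤ 3.5 by default. All constants live in `scoringScheme()`.

Two numerical choices matter:

* **Bounded bulges.** At most `maxBulges = 2` gap events are allowed per
  duplex. Plant miRNA duplexes are near-ungapped; the bound also keeps the
  exhaustive test oracle (a memoised recursion over alignment states)
  tractable, so the dynamic programme in C++ can be verified column by
  column against an independent implementation.
* **Tie-breaks.** Overlapping candidate windows are collapsed to the local
  best; equal-expectation ties go to the smallest start coordinate, and for
  a fixed start to the shortest window. This makes site lists reproducible
  bit for bit.

The predicted cleavage position is the transcript base paired with sRNA
position 10 (`siteEnd − 9` for a gap-free duplex) — the expected 5' end of
the 3' fragment seen in degradome data. If position 10 falls in a bulge the
nearest paired base is returned and flagged.

# Precursor validation

`validatePrecursor()` applies five annotation criteria to a
`HairpinCandidate` (sequence + dot-bracket + MFE + annotated mature/star
arms): (1) read support strictly greater than two summed across libraries;
(2) folding free energy strictly below −30 kcal/mol; (3) 2-nt 3' overhangs
on both strands of the miRNA/miRNA* duplex; (4) at most one asymmetric
bulge and at most four mismatched mature bases within the duplex; (5) MFEI
≥ 0.85, where MFEI = (|MFE|/length × 100) / GC%. Read support is pooled
across libraries because the emulated study pools six tissue libraries; a
per-library rule is a threshold away. All comparisons are strict on the
boundary (a count of exactly 2, an MFE of −29.9, an MFEI of 0.625 all
fail), matching the usual reading of "more than", "less than", "at least".

Duplex geometry is derived solely from the dot-bracket pairing of the
annotated arms: a 3' overhang is the run of terminal 3' bases whose
partners lie outside the opposite arm (or are unpaired); an asymmetric
bulge is an unpaired run on one strand with no opposing unpaired run; a
symmetric internal loop counts its mature-side bases as mismatches.

`foldFallback()` exists so structure-dependent code paths can run with no
external folding step: it is a maximum base-pairing (Nussinov-style)
dynamic programme over AU/GC/GU pairs with a minimum loop of 3, returning a
pseudo-energy of −2 kcal/mol per pair that is always flagged
`approximate`. It is a deliberate approximation for fixtures, not a
thermodynamic model, and is never substituted silently where a measured MFE
is required.

# Degradome validation

`buildTplot()` accumulates degradome 5'-end counts per transcript position.
`categorizePosition()` assigns the standard five-level PARE category:
0 unique maximum, 1 shared maximum, 2 above the median of nonzero
positions, 3 at or below it, 4 singleton — with the median taken over
nonzero positions so that sparse backgrounds do not deflate it.
`validateCleavage()` inspects positions within ±1 nt of the predicted
cleavage site (tolerance configurable; ±1 absorbs the register wobble seen
in degradome practice), picks the highest count (ties toward the predicted
position), and accepts categories ≤ 2 by default. 5'-RACE evidence is
represented as degradome signals with a `race` library label and flows
through the same path, so cloned-fragment frequencies act as counts.

# Phasing-locus detection

A read is *in phase* with register r (a residue class modulo the period p,
default 21 nt) iff its length is exactly p and its leftmost transcript
coordinate is congruent to r on the plus strand, or to r minus the
2-nt Dicer offset on the minus strand. The offset follows duplex geometry:
if a sense phasiRNA occupies positions a..a+20, its duplex partner occupies
a−2..a+18, so folding minus reads back by 2 nt puts both strands of one
duplex into the same cycle. With that convention the occupied-cycle count k
is bounded by the number of cycles in the window, and antisense register k
starts at `origin + (k−1)·p − 2`.

`detectPhasingLoci()` slides a window of 9 cycles in steps of one period,
for every candidate period 18–25 and every register, computing k, the
in-phase mass P and the out-of-phase mass U (off-length reads always count
toward U). The window score is the PhaseTank-lineage statistic

$$S = \ln\left[\left(1 + 10\,\frac{P}{1+U}\right)^{k-2}\right], \qquad k \ge 3.$$

Score alone does not control false calls on unstructured libraries: each
window effectively tests p registers, and at the default threshold (S ≥ 3)
about 7% of windows of 30 uniformly placed 21-nt reads pass by chance.
Window acceptance therefore also requires the hypergeometric register
p-value — the probability that at least k of the n occupied positions fall
on the q = 9 in-phase positions of the m = 9p window positions under
uniform placement — to clear a Bonferroni bound over the p registers
tested: `p · pvalue ≤ maxPvalue` (default 0.05). Genuine loci have
p-values around 1e−10 or smaller and are unaffected; measured type-I on
random reads drops below 5% and period recovery at occupancy 0.6 with 8
registers stays above 95%.

Accepted windows overlapping by at least one period merge into a locus; the
locus takes the period and register of its best window, and its register
origin (start of sense register D1) is the smallest in-phase effective
start. `enumerateRegisters()` then names every register D1..Dmax on both
strands — `gene-siRD{k}(+)` and `gene-siRD{k}(-)` — whether or not a read
was sequenced: species absent from the library are reported with abundance
0, because enumeration counts registers, not detections.

# Cascade inference

`inferTriggers()` scores every pool sRNA (miRNAs and enumerated phasiRNAs)
against the locus transcript and asks whether its predicted cleavage sits
one base upstream of register D1: `register_match` holds iff
`(cleavage + 1 − origin) mod p` is within ±1 nt of zero. The cleavage/origin
convention — D1 starts at `cleavage + 1`, the peak position being the last
base of the 5' fragment's complement on the 3' fragment — is fixed and the
±1 tolerance absorbs the residual ambiguity of whether phasing initiates at
or after the peak position. Secondary triggers are *not* required to be 22
nt (observed secondary triggers are 21-nt phasiRNAs); trigger length is
recorded but unconstrained. `buildCascadeNetwork()` assembles `cleaves`
edges (evidence: `predicted`, `degradome` or `race`) and `produces` edges
(transcript → phasiRNA within a detected locus), permits self-cleavage
(cis-acting species), and orders rows deterministically.

# The synthetic-data generator

`simulatePhasiRNALocus()` emulates: a random transcript carrying a perfect
site for a random 22-nt trigger whose position-10 pairing defines the
cleavage site; 21-nt registers downstream occupied per strand with
probability `occupancy`; log-normal integer abundances (floor, minimum 1),
reflecting the strongly heterogeneous register abundances seen in real
loci; and a configured fraction of off-phase read mass at uniform positions
and lengths 20–22. The defaults — 2000-nt transcript, cleavage at 600, 12
registers, occupancy 0.8, noise fraction 0.05, log-normal σ 0.8 — are the
study conditions used throughout the tests. `simulateDegradome()` draws a
Poisson(0.2) background per position and gives each peak an equal share of
`peakFraction` (default 0.9) of the total tag mass.
`simulateTissueProfiles()` orders the miRNA root > stem > flower > leaf and
makes target means inversely proportional with multiplicative log-normal
noise. All generators are pure functions of their seed.

Two bundled presets (`smmterf33_preset_synthetic`,
`smmterf45_preset_synthetic`) encode locus geometries with 27 and 28
registers per strand — the per-gene totals reported for the emulated
transcripts (54 and 56 species) — with occupancy 0.76 for the first,
reflecting that roughly a quarter of enumerated species go undetected in
sequencing. Their sequences are synthetic; only the geometry mirrors the
reported loci.

What the generator does **not** emulate: sequencing errors, multi-locus
transcriptome backgrounds, ligation biases in degradome libraries, or
abundance-dependent mapping artefacts. Passing tests therefore demonstrate
correctness of the inference chain under its stated model, not performance
on raw sequencing data.

# Problem sizes and budgets

The test suite runs desk-scale problems chosen to keep the full suite
around a few minutes: 110-nt transcripts for the exhaustive scan oracle
(the memoised R oracle is ~1000× slower than the C++ kernel), 500-nt
transcripts for the 200-replicate recovery and 100-replicate cascade
properties, 1000-nt transcripts for the 200-replicate degradome register
recovery, and the 2000-nt default geometry for the end-to-end runs.

# Known limitations

* The expectation scheme is an operational definition of the published
  scoring family; absolute scores from other implementations may differ in
  gap handling, though the perfect-complement, single-defect and threshold
  semantics coincide.
* Phasing detection is transcript-level; no genome-scale PHAS discovery,
  and no 24-nt reproductive phasiRNA class support.
* `foldFallback()` maximises pairing, not free energy; MFE-dependent
  criteria should use structures from a thermodynamic folder whenever one
  is available.
* Expression anticorrelation uses Spearman rank correlation because the
  claims being checked are orderings across a handful of tissues; with four
  tissues the correlation is coarse (ties matter) and is meant as
  supporting, not primary, evidence.
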