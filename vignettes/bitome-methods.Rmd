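---
title: "Methods: building and analysing binary genome feature matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and analysing binary genome feature matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind the package, the choices that
were genuinely open when it was designed, and what its synthetic-data
tests do and do not demonstrate about real genomes.

## The representation

A bitome is a sparse binary matrix with one column per genomic position
and one row per *feature row key*. An element is 1 exactly when the
feature is present at the position; absence is 0, and re-adding an
overlapping feature is an OR, never a count. Keeping the matrix binary
forces a row-splitting discipline:

* **Six-row categories** (genes, pseudogenes, RNA genes, codons, amino
  acids, proteins, COG categories, structural tracks): split by strand
  and by reading frame, the frame being the mod-3 class of the anchoring
  coordinate. Without the frame split, overlapping genes in different
  frames would collide in one row and information would be lost.
* **Two-row categories** (operons, transcription units, promoters and
  their −10/−35/TSS elements, terminators, attenuators, Shine–Dalgarno
  sites, riboswitches, nucleobases, repeats): one row set per strand.
* **Single-row categories** (regulons, sigmulons, i-modulons, TF binding
  sites): no strand information exists for these, so one row each. They
  also carry no coordinates of their own and are painted over the
  intervals of their linked genes.

Eight nucleobase rows (4 bases × 2 strands, the reverse strand holding
the complement) are always present, which is why every column carries at
least two bits: the column-count floor is a structural property of the
sequence tracks, not of the annotation.

**Frame anchor.** "Mod-3 of the start" is ambiguous for reverse-strand
features: the *leftmost* coordinate and the *first transcribed* base
differ. The package anchors on the leftmost genomic coordinate for both
strands by default — the simplest reproducible reading — and offers
`frame_anchor = "coding_start"` to anchor reverse-strand features on
their rightmost base instead. Note that within one CDS both conventions
put every codon in the same row as its parent gene, because codon
leftmost coordinates step by 3.

**Coordinates.** Everything internal is 0-based half-open; GenBank and
the TSV dialect are 1-based inclusive and converted exactly once at the
I/O boundary. This makes frame arithmetic (`start %% 3`) and window
arithmetic exact, with no ±1 bookkeeping inside the package.

**Stop codons and selenocysteine.** The codon track covers the full CDS
including the stop codon, so codon coverage equals CDS coverage; the
amino-acid track excludes stop positions, so amino-acid coverage matches
protein length. An annotated `U` in a translation (a recoded internal
TGA) is honoured, giving a 21st amino-acid subtype; the annotation's
translation always wins over the standard code, with a warning when they
disagree anywhere else.

**Proteins.** Protein rows are implemented as per-gene presence tracks
over the whole coding span, in the same six strand × frame variants as
genes. This is an interpretation — a per-protein row block is the other
reading — and is flagged as such.

## Derived statistics

All metrics are matrix arithmetic and satisfy exact identities that the
test suite asserts: total bits = Σ row sums = Σ column sums; genome-wide
density × genome length = total bits; the length-weighted mean of
densities over any partition equals the genome-wide density; inter-TU
regions and TU coverage tile the genome with no overlap and no gap.

Tunable parameters, with defaults and units:

| parameter | default | meaning |
|---|---|---|
| `moving_density(window)` | 100 000 bp | density window |
| `moving_density(step)` | 1 000 bp | window stride (the window size is conventional; the stride is not, so it is explicit) |
| `window_fold_energies(window)` | 100 bp | folding window |
| `tight_structure_regions(fraction)` | 0.10 | lower quantile defining "tight" structure |
| `lockbox_split(fraction)` | 0.20 | held-out class-stratified fraction |
| `cv_evaluate(k, n_downsamples)` | 5, 5 | folds × downsampled resamples |
| `model_spec_svm_l1(C)` | 0.1 | loss weight of the L1 linear SVM |

Promoter geometry uses the floor of the interval midpoint as a box
"center" (even-length boxes have no integer midpoint; flooring is the
deterministic choice) and measures the spacer between the facing ends of
the −35 and −10 boxes. Distances are reported unsigned with an
`upstream` flag, since a signed convention is not universal.

Quantile ties in the tight-structure threshold are *included* (energy ≤
threshold), which is deterministic and errs toward reporting more
structure; the selection is still minimal in the sense that excluding
the threshold value would select fewer than the requested fraction.

Zero-length UTRs (a gene abutting its TU boundary) are recorded but
excluded from summary views by default, since length distributions
conventionally describe existing UTRs; `drop_zero = FALSE` restores
them.

## The folding engine

The mRNA-structure windows need only a *relative* structure propensity,
so the built-in engine is a base-pair-maximization dynamic program
(Watson–Crick plus G·U wobble, minimum hairpin loop of 3 nt) returning
the negated maximal pair count, implemented in C++ for speed. It is not
a thermodynamic model: no stacking energies, no pseudoknots, no
temperature. Any `function(subsequence) -> scalar` — e.g. a wrapper
around an external MFE tool — can be plugged in; the windowing and the
lowest-decile thresholding are independent of the engine.

## The rank test

The Mann–Whitney *U* comparison of bit counts at SNP positions versus
all coding positions faces massive ties (bit counts are small integers),
so the large-sample path uses the tie-corrected normal approximation
with continuity correction. Small instances are handled by exact
enumeration of all group assignments of the pooled values, which remains
valid under ties; the exact path engages when the number of assignments
is at most 5 × 10⁵. SNP records are deduplicated to unique positions by
default — recurrence across experiments is a property of the experiment
set, not the genome — with `dedup = FALSE` to preserve multiplicity.

## The classification harness

Gene feature vectors are bitome sub-matrices collapsed column-wise (sum
for bit totals, mean for per-bp rates; the two differ exactly by gene
length, asserted element-wise in tests), min/max normalized per feature
with constant features mapped to 0. The workflow enforces the lockbox
contract: a class-stratified 20% holdout is split off first and touched
only by the final evaluation; the identity of lockbox genes never enters
any fold, which the tests assert on gene ids rather than indices.

Class imbalance is handled by downsampling the majority class (the
default, mirrored by repeated resampling inside cross-validation) or by
class-frequency-weighted losses (`class_weight = "balanced"`), the
choice belonging to the model spec. A shuffled-label control runs the
identical pipeline on permuted labels; on balanced data its expected
accuracy is 0.5, and any gap between the control and the real labels is
the signal estimate.

No installed R package provides an L1-penalized *linear SVM*, so the
package authors its own solver: FISTA proximal gradient with
backtracking on the objective `||w||₁ + C Σᵢ sᵢ max(0, 1 − yᵢ(xᵢw + b))²`
(squared hinge, primal, unpenalized intercept). The L1 prox is
soft-thresholding; convergence is declared at a relative objective
change of 10⁻⁷ with a 2 000-iteration budget, and non-convergence is
surfaced as a warning plus a `converged` flag rather than silently
accepted. L1 logistic regression (glmnet) ships as the second mandatory
spec and doubles as an independent cross-check of support recovery in
the tests. Other learners plug in through the same
`fit`/`decision` spec interface rather than being reimplemented.

One design fork deserves a note: descriptions of lockbox evaluation that
involve "re-training on downsampled versions of the lockbox" are
internally ambiguous. The package trains on the training set only and
evaluates on the untouched lockbox, because training on any part of the
lockbox would void the holdout contract; evaluating against several
downsampled lockbox views is possible by subsetting, but the default
reports the full lockbox with a per-true-class normalized confusion
matrix and a rank-based AUC.

## The synthetic generator

`generate_annotation()` lays out non-overlapping operons, each with one
transcription unit, 1–3 genes with valid ORFs (ATG start, in-frame
internal stops only at a planted selenocysteine, terminal stop), 5′/3′
UTRs drawn from geometric distributions with median ≈ 50 bp, promoters
with −10 boxes at −12..−7 and −35 boxes at −35..−30 relative to the TSS
(±1 bp jitter, canonical 17 bp spacer), terminators, Shine–Dalgarno
sites, TFBS in inter-TU gaps, and regulons/sigmulons/i-modulons as
random gene subsets. Defaults are desk-scale: 80 kb genomes, 40 operons,
300–900 bp genes (real enterobacterial genes average nearer 950 bp; the
shorter range keeps fixture genomes small without changing any geometry
the analyses consume). Every planted quantity is returned in a truth
record, and tests compare analysis output to that truth, never to
hard-coded constants.

What the generator deliberately does **not** emulate: codon usage bias,
GC skew, macrodomain structure, overlapping genes, operons with internal
promoters, and any correlation between regulatory sites and sequence
motifs. Passing tests therefore demonstrate the *mechanics* of the
representation and the statistics — coordinate handling, conservation,
calibration, power against planted effects — not biological conclusions
about real genomes, which additionally depend on annotation quality and
the real feature correlations absent here.

SNP generation places unique positions with odds multiplied by a
configured factor on below-median bit-count positions (and optionally on
positions of chosen amino acids), which is exactly the alternative the
rank test is designed to detect; odds ratio 1 recovers the uniform null
used for calibration. Label generation draws Bernoulli labels through a
logistic model on chosen (min/max normalized) features with optional
label noise.

## Problem sizes and determinism

The shipped tests and the acceptance script use a 30 kb / 12-operon
genome for construction, conservation, census and rank-test checks, a
420 kb / 500-gene genome for the classification harness, 500 replicates
for null calibration, 200 for power, and 50 refit seeds for importance
recovery — sizes chosen so the whole suite completes in a few minutes on
one core while keeping Monte-Carlo error well inside the asserted
margins. All randomness flows from explicit integer seeds; generation,
matrix assembly and model fitting are deterministic given the seed, and
byte-identical outputs under seed reuse are part of the test contract.

## Known limitations

* Single replicon per bitome; multi-chromosome genomes need one bitome
  per replicon.
* Origin-wrapping features are supported, but the GenBank writer emits
  only non-wrapping locations, so wrap-around fixtures are constructed
  in code.
* The folding stand-in is a pairing count, not an energy model.
* Structural tracks (secondary structure, residue exposure) are consumed
  from per-residue annotations, never computed.
* The hand-written GenBank reader targets well-formed single-record
  flat files of the kind reference genomes and the package's own writer
  produce; exotic location operators beyond
  `complement`/`join`/`order` are rejected rather than guessed.
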