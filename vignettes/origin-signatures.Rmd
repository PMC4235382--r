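---
title: "Sequence signatures of replication origins: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence signatures of replication origins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oriseq)
```

## The problem

Budding-yeast replication origins (ORIs) are short, AT-rich loci carrying
the ACS consensus (T/A)TTTAT(A/G)TTT(T/A), preferentially located in
nucleosome-depleted regions and distributed non-randomly with respect to
transcription units. None of these signals is individually strong enough to
identify origins, which is what makes a quantitative treatment worthwhile:
`oriseq` computes the compositional, informational and positional statistics
of origin neighbourhoods and evaluates how far each feature family
discriminates origin windows from their immediate upstream flanks.

## Signal definitions and numerical conventions

**GC profile and GC skew.** Both are ratios of window base counts:
GC profile = (G+C)/(A+C+G+T) and GC skew = (G−C)/(G+C). Bases other than
A/C/G/T (N after input normalisation) are excluded from numerator and
denominator alike. A window with a zero denominator (all-N, or no G/C for
the skew) propagates as a missing value, never an exception, and missing
windows are excluded from profile means. Trailing partial windows of a
sliding scan are discarded rather than padded, so every window shares one
denominator width.

**Entropy and information redundancy.** H = −Σ p_a log₂ p_a is the Shannon
entropy of window base composition (log base 2 throughout; units are bits).
The k-order redundancy D_{k+2} = 2H + Σ p_{ij} log₂ p_{ij} measures the
dependence between bases separated by k intervening positions; k = 0 is the
adjacent correlation, and the subscript convention labels it D₂. Two
readings of H are possible:

* `marginals = "pair"` (default): H is the entropy of the *mixture marginal*
  of the lag-k pair ensemble (the mean of the first- and second-position
  marginals). Then D = 2·H_mix − H_joint, which is non-negative (by
  concavity, H_joint ≤ H(X) + H(Y) ≤ 2·H_mix) and bounded by 2 bits — a
  mutual-information-style divergence from independence. This is the
  testable convention: the hand-derivable example D("ATAT", k=0) =
  2·1 − (log₂3 − 2/3) = 1.08170 bits comes from it.
* `marginals = "sequence"`: H from whole-sequence base frequencies — the
  literal composition-entropy reading, retained for comparison; it can go
  slightly negative on finite sequences.

**Estimating an averaged spectrum.** The plug-in estimator of D carries an
upward finite-sample bias of roughly 6/(N ln 2) bits for N observed pairs
(≈0.03 bits for a single 300-bp sequence). Averaging per-sequence spectra
averages the bias, not away. `redundancy_spectrum_set(..., method =
"pooled")` therefore pools the lag-k pair counts across all sequences before
forming probabilities, making the bias shrink with the pooled count
(≈0.0003 bits for 100 × 300 bp); this is the default and what the spectrum
analyses report. `method = "mean"` provides the naive average for
comparison.

**Coordinates and anchoring.** All internal coordinates are 0-based
half-open (the BED convention); GFF3 input is converted once at the parsing
boundary. An origin's anchor is its midpoint, floor((start+end)/2) — a
symmetric, length-independent choice, since annotated origin intervals vary
in width. In anchored profiles each sliding window's value is assigned to
the offset of the window centre, so a symmetric signal produces a dip or
peak centred at offset 0. GC skew profiles are computed on the plus strand
for all anchors because origins carry no annotated orientation; any
sign-change interpretation at the anchor is subject to that caveat.

**Rank-sum comparisons.** Region-set contrasts use the two-sided
Mann–Whitney test: exact when the smaller group has ≤ 8 untied values,
tie-corrected normal approximation otherwise. The nucleosome contrast
(`ndr_contrast`) compares the 151-bp core window around each origin with
flank windows of the *same width* centred beyond ±500 bp (two per origin).
Equal widths matter: under a stationary track, core and flank means are
then exchangeable and the null p-value is calibrated, whereas comparing a
short core against long flank averages mixes distributions of different
variance and skew and produces spurious significance on null data.

## Positional annotation

Intergenic regions form between consecutive non-overlapping genes:
(−,+) flanks are divergent (both promoters face the gap), (+,−) convergent
(both terminators), equal strands tandem. Clusters of overlapping genes are
merged out of consideration and the gaps adjacent to them excluded, as are
chromosome-terminal gaps (one flanking gene only, orientation undefined).
Each origin receives exactly one category via the midpoint rule — a
partition, so category fractions sum to 1. Inside a gene body, the 5′-most
25% of the gene is "head" and the 3′-most 25% "tail" (strand-aware); the
fraction is configurable since no standard definition exists. ORI–TSS
distance is midpoint-to-TSS, and the proximity summary counts strictly
less-than-threshold distances (a distance of exactly 500 bp is out).

## Discrimination experiment

Positives are the 300 bp centred on each origin midpoint; negatives the
300 bp immediately upstream (lower coordinates, abutting; origins are
unstranded). Feature vectors are the per-window signal profiles across the
instance — 251 values for GC profile/skew (50-bp windows, 1-bp step), 151
for D₂ (150-bp windows), 300 per-base values for nucleosome occupancy —
rather than scalar summaries, which would collapse GC families to one
dimension. Negative windows overlapping another origin's positive window
are dropped as label noise. The classifier is an RBF SVM (cost 1, kernel
width 1/(dims × mean feature variance)) under stratified 10-fold
cross-validation: features standardised per fold on training instances
only, missing values imputed with the training-fold mean, zero-variance
training features dropped per fold. Confusion totals accumulate over
held-out folds; Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc from totals. With a
fixed seed the whole procedure is bit-reproducible.

## What the generator emulates — and what it does not

`generator_spec()` defaults define the study conditions used in the
analyses and tests: one 1-Mb chromosome of iid background at GC 0.38;
100 non-overlapping 300-bp origins resampled at GC 0.317 (non-motif base
frequencies compensated so the whole window hits the target in expectation
despite the AT-rich motif); one ACS instance planted at each origin centre
on a uniformly random strand; a first-order adjacent-copy process
(probability 0.2) inside origins creating the D₂ elevation; a gene model of
~1.4-kb genes with random strands yielding all three intergenic classes;
TSSs at gene 5′ ends with 30-bp jitter; 31% of origins placed within
500 bp of a TSS and the remainder kept clear, so the realised proximity
rate equals the planted one; and a nucleosome track built as a positive
165-bp-period sinusoid times Gaussian depletion envelopes (depth 0.7 at
origins, 0.5 at promoters) plus noise. The null generator keeps the genome,
genes, promoter depletion and uniformly-placed origin intervals but
disables every origin-specific signal.

These choices make each signal axis independently tunable and recoverable,
which is what validation needs. They do not make the genome realistic:
there is no chromatin-state structure, no replication timing, no
genome-wide ACS background occurrences, no correlated base composition
outside origins, and the nucleosome track is phenomenological rather than a
positioning model. Passing tests therefore demonstrate that the statistics
recover planted signals of the stated magnitudes under iid noise — not that
they would reach any particular accuracy on a real genome, where the
contrasts are weaker and confounded.

## Problem sizes and degenerate inputs

The analyses and acceptance checks run on the 1-Mb / 100-origin conditions
(seconds per stage); determinism of the full pipeline is exercised on a
200-kb / 40-origin bundle, and file round-trips on a 60-kb one — sizes
chosen so the whole validation suite completes in a couple of minutes while
leaving every contrast orders of magnitude clearer than its threshold.
Degenerate inputs follow one rule: impossible requests error early and
loudly (empty anchor sets, genes without strand, intervals with start ≥
end, fewer than 20 usable origins for cross-validation), while undefined
*values* propagate as missing and are excluded from denominators (all-N
windows, skew without G+C, origins on chromosomes without TSSs — the last
with a warning).

## Known limitations

* GC-skew orientation: without per-origin strand assignments the skew
  profile averages plus-strand values; a genuine replichore-style sign
  change would partially cancel across oppositely-oriented origins.
* The redundancy spectrum is reported for origin-centred fixed-width
  (300-bp) sequences; annotated origins of very different widths would mix
  origin and flank sequence at the edges.
* The SVM experiment evaluates discrimination of given windows only; it is
  not a genome-wide origin scanner, and no feature fusion across families
  is attempted.
* Category fractions depend on the declared head/tail fraction (25%) and
  the midpoint rule; other conventions shift fractions between adjacent
  categories.
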