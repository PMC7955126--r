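---
title: "apatail: model, features and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{apatail: model, features and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The task

Given a genome, per-base RNA-Seq coverage and a transcriptome GTF, decide
for every 100-base bin of every (modified) 3' terminal exon whether an
expressed polyadenylation site falls in it, then rewrite transcript 3'
ends accordingly. The task is supervised: labels come from 3'-end
sequencing (PolyA-Seq-style) site sets, and a model trained on one
labelled sample is applied to unlabelled samples.

## Coordinate conventions

Internally everything is 1-based inclusive, the GTF convention. BED and
bedGraph are 0-based half-open and are converted in the readers/writers
only: a single-base BED record `(start, end) = (99, 100)` is internal
position 100. Unstranded GTF records are dropped rather than guessed,
because every downstream step (extension, refinement, labelling,
placement) is strand-specific.

## Transcript processing

* **Extension.** Each terminal exon is extended `10000 + 2 * bin_size`
  bases downstream (10,200 at the default 100). The two extra bins give
  the flanking context of the last informative bin room to exist.
  Extensions are trimmed so they do not overlap the exon span (first exon
  start to last exon end) of any *same-strand* neighbour, and are never
  trimmed past the original stop.
* **Refinement.** Walking 5'→3' from the original stop in `bin_size`
  windows, the extension is truncated at the first window whose mean
  depth falls below `max(min_abs_cov, frac * D0)`, with `D0` the mean
  depth over the window ending at the original stop. The published
  description defers the exact criteria to supplementary material; this
  window-mean rule is our declared concrete instantiation of the
  coverage-continuity idea used by APA-from-coverage tools, and both
  parameters (`min_abs_cov = 5`, `frac = 0.05`) are exposed. The rule
  only ever shortens or keeps the extension, is idempotent, and never
  cuts into the original terminal exon.
* **Merging and binning.** Overlapping refined regions are merged (union;
  sources and stops concatenated) before training so no genomic bin is
  duplicated across training rows; prediction keeps per-transcript
  regions so each placement maps to a source transcript. Regions are
  tiled from their 5' boundary; a trailing sub-bin remnant is dropped so
  every real bin has identical width (the feature definitions assume it).
  Regions longer than 300 bins are *chunked*, not truncated, so no span
  is silently unexaminable; the final chunk is padded at its 3' tail with
  masked bins. Padding at the 3' tail (rather than 5') keeps bin `i` of a
  chunk at a fixed genomic phase, and the mask excludes padded bins from
  the loss, the standardization statistics and all metrics.

## The 27 features

Each real bin sees a window of itself plus 100 bases of flank on each
side, oriented 5'→3' along the transcript strand (sequence
reverse-complemented, coverage reversed on `-`), with `N`/0 fill beyond
chromosome ends.

* **PAS (4).** A 6-base sliding window scans from 35 bases upstream of
  the bin's 5' edge through the bin's 3' edge — exactly the placement
  window implied by a signal 10–35 nt upstream of a cleavage site
  anywhere in the bin. Four ±1 features: AATAAA; ATTAAA; AGTAAA; any
  minor variant. The minor-variant class implemented is the eight
  hexamers AAGAAA, AAAAAG, AATACA, TATAAA, GATAAA, AATATA, CATAAA,
  AATAGA (commonly cited lists are ambiguous about a ninth; the set is
  frozen and hashed into the model bundle). The anchor `pas_pos` is the
  highest-priority class's 3'-most occurrence.
* **Elements (8).** Scored in regions placed relative to `pas_pos` (or a
  neutral anchor 15 bases into the bin when no PAS is found): downstream
  `[P+6, P+106)`, upstream `[P−100, P)`, near-downstream `[P+6, P+40)`.
  The eight detectors and thresholds (≥3 non-overlapping GGG; ≥2 TTT
  near-downstream; ≥6 overlapping GT/TG; ≥2 GTGT/TGTG; T fraction ≥ 0.4
  immediately downstream and upstream; ≥2 TGTA/TATA upstream; A+T
  fraction ≥ 0.65 over both flanks) encode the canonical positional
  grammar of cleavage sites (GU/U-rich downstream elements, U-rich and
  UGUA upstream elements). Every threshold is a `feature_config()`
  argument; the published description likewise defers exact definitions
  to supplementary material, so these are declared defaults, not claimed
  reproductions.
* **RNA (14).** Median depth (robust to single-base spikes) over three
  regions in two scenarios: intra-bin (the window's three 100-base
  thirds) and inter-bin (previous real bin, current bin, next real bin
  along the region; a missing neighbour is a region of zeros). Each
  scenario contributes seven contrasts: `s(mU,mM)`, `s(mM,mD)`,
  `s(mU,mD)` with `s(a,b) = (a−b)/(a+b+1)`; `log1p(mM)`; two `log1p`
  differences; and the drop fraction `mD/(mU+1)`. The `+1` terms keep
  every feature finite and bounded at zero coverage; `|s| < 1` always.
* **Annotation (1).** ±1 for "an original transcript's 3' stop is in this
  bin".

The feature order is frozen; models store a hash of the full feature
configuration and refuse inputs featurized under a different one.

## The classifier

A bidirectional LSTM with 20 units per direction over the 300 × 27 masked
sequence, followed by a per-bin dense sigmoid. It is implemented directly
in base-R matrix code (forward pass, full backpropagation through time,
Adam); the gradients are validated against finite differences in the test
suite to ~1e-6 relative error. Details that the published description
leaves open, decided here:

* **Class weights** `w_c = N / (2 N_c)` over real training bins (the
  standard inverse-frequency scheme; "class weights were used" is all
  that is stated).
* **"Minimum loss"** is read as minimum *validation* loss — training and
  validation are monitored to prevent overfitting, and the checkpointed
  weights are those of the best validation epoch among the 25.
* **Masking** carries hidden/cell state through padded timesteps
  unchanged in both directions, so padded tails cannot influence real
  bins (asserted by an exact-equality training test).
* **Optimizer scale.** Adam with learning rate 0.02 and minibatch 32.
  The published pipeline trains on tens of thousands of sequences, where
  a 1e-3 learning rate sees hundreds of thousands of updates over 25
  epochs; at the desk scale this package targets (a few hundred
  sequences, a few hundred updates) the same schedule would barely leave
  initialisation, so the default step size is larger. Both are
  `apa_model_config()` arguments.
* **Validation loss is unweighted** (class weights shape the training
  objective only), the usual convention.

Standardization (z-scoring) applies to the 14 quantitative features only,
uses training-split statistics over real bins only, and leaves a zero-sd
feature centered at zero. Splits are at the region level — all chunks of
a merged region travel together — so no genomic locus leaks across
train/validation/test.

Two flat comparator engines (random forest, logistic regression on
per-bin rows with the sequence context dropped) share the prediction
interface; they exist as fast baselines for tests and sanity checks, not
as recommended models.

## Integration

A positive bin proposes the bin's 3'-most base as a new stop, unless
(1) the transcript's original stop lies in that bin, or (2) the proposal
is within 100 bases of the original stop (both inclusive). Rule (1)'s
"region" is read as the *bin* — reading it as the whole terminal region
would suppress every placement. Each accepted proposal adds a new isoform
(`<id>.apa<k>`, numbered by genomic position) that shares the source's
intron chain; originals are never modified, so the output is a strict
superset of the input. A proposal 5' of the terminal exon's own start is
rejected (an added isoform must not cut into the intron). By default a
site is added per transcript even if another isoform already stops there,
mirroring the published behaviour; `dedup_across_isoforms = TRUE` is the
opt-in alternative and also makes re-integration idempotent.

## The synthetic data generator

`sim_apa_data()` emulates exactly the structure the method exploits, at
desk scale: 200 two-exon transcripts on both strands of two 1.5-Mb
uniform-random chromosomes; 1–3 polyA sites per transcript, 400–2,500
bases apart, the first site being the annotated stop; a PAS hexamer
planted with its 3' end 10–35 nt upstream of each site
(canonical/ATTAAA/AGTAAA/minor at 0.70/0.15/0.05/0.10, roughly the
relative frequencies reported for mammalian sites); downstream GT-rich
and T-rich elements each planted with probability 0.6; and coverage that
is a staircase — expected depth 100 at the terminal exon's 5' end,
stepping down past each site in proportion to site usage (uniform 0.5–1.5
shares, normalized) — with per-base Poisson noise and a 5% read-through
tail of 500 bases modelling precursor-mRNA reads. Gene loci are spaced so
same-strand neighbours do not clip the 10,200-base extensions.

What it deliberately does **not** model: non-uniform background
composition (isochores, repeats), fragment-level coverage
autocorrelation, spliced 3' UTR introns, overlapping genes, library
biases, or mis-mapped reads. Passing tests on this generator therefore
demonstrate that the pipeline recovers the signal it is designed around —
not that real-data performance matches the published figures, which
require the original alignments and PolyA-Seq labels. `degrade_fixture()`
corrupts one channel at a time (shuffled labels, zeroed coverage,
stripped PAS grammar) to support the single-omics and null comparisons.

## Numerical choices and degenerate inputs

* Metric conventions: any `0/0` among P, R, F is 0; average precision
  follows the plain step sum over descending distinct thresholds, with no
  interpolation, and refuses inputs with no positive labels.
* The ±100-base terminus match is inclusive at the boundary.
* Probability threshold edge cases: `threshold = 0` calls everything,
  `threshold = 1` calls nothing.
* Regions shorter than one bin are skipped with a warning; all-one-class
  training labels are an error; sub-3-region data sets cannot be split.
* BAM coverage uses split-aware counting (N-gap segments contribute
  nothing), excludes secondary and supplementary alignments, and keeps
  duplicates by default — whether duplicates were removed upstream is not
  stated in the published pipeline, so the choice is exposed as
  `keep_duplicates`.

## Problem sizes used by tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline on the
200-transcript generator default (≈5,000 real bins, ≈370 sites) and the
unit tests on a 6-transcript miniature. These sizes were chosen as the
smallest at which the class imbalance, multi-site transcripts and both
strands are all represented well enough for stable metrics.

## Known limitations

* The recurrent engine is CPU-bound base R: fine for the intended
  refine-an-annotation use (hundreds to tens of thousands of sequences),
  not for hyperparameter sweeps.
* Only the biLSTM engine serializes to the JSON model bundle.
* No pre-trained weights ship with the package; users train on their own
  labelled sample (or the synthetic fixture, for demonstration).
* The intron chain is taken as given: the method evaluates and rewrites
  3' ends only.
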