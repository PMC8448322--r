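---
title: "Genome-wide regulatory element prediction with dynamic hard-negative mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide regulatory element prediction with dynamic hard-negative mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(regscan)
```

## The problem

Promoters initiate transcription at a transcription start site (TSS);
enhancers amplify transcription from a distance and are themselves
bidirectionally transcribed, so both element classes share a common
sequence architecture and can be modeled together as
"transcription-initiation regulatory elements". Classifiers trained to
separate a fixed set of such elements from an equal number of random
genomic sequences routinely report excellent accuracy and then fail at
genome scale, because a genome scan evaluates millions of candidate
windows: even a 1% false-positive rate yields thousands of spurious
calls per megabase, swamping the true elements. Worse, many
non-regulatory regions genuinely resemble regulatory ones (elevated GC,
isolated core-promoter motifs), and a random negative set almost never
contains them, so the classifier never learns to reject them and falls
back on crude features such as GC content.

`regscan` addresses this with two coupled ideas:

1. **A two-model scan/refine scanner.** A *scan model* slides across the
   genome at a 50 bp stride and flags candidate regions; wherever it
   fires, a position-specific *prediction model* re-scores every
   single-base center in a 100 bp window to pinpoint the TSS. Survivors
   above the 0.5 decision threshold are distance-filtered (greedy
   non-maximum suppression, 500 bp minimum separation) and a third
   *strand model* assigns the direction of transcription: `+` or `-`
   for promoters, `.` for bidirectional enhancers.

2. **Dynamic hard-negative mining.** Training alternates with scanning:
   every confident prediction further than 500 bp from any annotated
   element is a hard false positive and is added to the negative
   training set for the next round. Iterating this forces the models to
   learn the features that separate true elements from their most
   confusable genomic look-alikes. To prevent the network from simply
   memorizing the (finite) negative set, every negative is re-centered
   each epoch by a fresh uniform random shift — the negative set becomes
   effectively infinite and only generalizable patterns survive.

## The scorer

All three models share one architecture: a 1-D residual convolutional
network over one-hot encoded DNA windows of 1001 bp centered on the
candidate position (`A`,`C`,`G`,`T` map to unit columns; `N` and
off-chromosome padding map to zero columns, so padding cannot imitate
signal). Each residual block is conv → batch norm → leaky ReLU → conv →
batch norm, added to an identity (or 1×1-projected) skip path, passed
through a leaky ReLU and average-pooled. The final feature map is
*flattened* into the feature vector — position-preserving, which is what
lets the prediction model tell a centered TSS from an off-center one (a
globally pooled head is nearly translation-invariant and cannot be
position-specific) — then dropout with keep probability 0.5, one dense
layer and a softmax produce class probabilities. Training is Adam on
softmax cross-entropy with L2 weight decay and early stopping on a
class-balanced validation loss.

The default configuration is deliberately desk-scale: 3 residual blocks
with a channel ramp 8→16→32, kernel width 9 bp, and pooling strides
(8, 4, 2). Pooling hardest at the full-resolution first block is what
makes CPU-only genome scans practical; the channel ramp follows the
classic ResNet pattern of widening as resolution drops. Deeper and wider
variants (e.g. five blocks of 32 channels) are one `model_config()` call
away and use the identical code path. The engine itself is written
against BLAS: convolutions are im2col gathers followed by dense matrix
products, the backward pass scatter-adds with `rowsum()`, and for
inference the batch-norm affine transforms are folded into the
convolution weights.

Two numerical properties are worth knowing. First, inference is
deterministic and batch-size invariant (dropout off, batch norm on its
running statistics). Second, the genome scanner exploits the fact that
the first residual block is position-local in inference mode: its
pre-pooling activation is computed once per chromosome and per-window
activations are slices of that map, with the outermost 8 window columns
recomputed exactly where per-window zero padding differs from
chromosome context. The fast path is bit-identical to scoring each
window separately (this is asserted by a test).

## Training and mining parameters

| parameter | default | meaning |
|---|---|---|
| `window_len` | 1001 bp | input window centered on the TSS/midpoint |
| `stride` | 50 bp | coarse scan step |
| `refine_span` / `refine_step` | 100 bp / 1 bp | refinement region and step |
| `scan_threshold`, `pred_threshold` | 0.5 | decision thresholds (inclusive) |
| `min_separation` | 500 bp | distance-filter radius; matches the evaluation margin so one element yields one call |
| `margin` | 500 bp | matching margin for TP/FP and negative exclusion |
| `pos_shift_scan` | 25 bp | positive-window jitter for the scan model — half the stride, so a stride-aligned window always sees the TSS within its trained tolerance |
| `pos_shift_pred` | 5 bp | small jitter for the prediction model: keeps augmentation diversity, calls stay within a few bp of the TSS |
| `neg_shift` | 250 bp | per-epoch random re-centering of random-pool negatives |
| `hard_neg_shift` | 50 bp | per-epoch jitter for mined hard negatives — enough to defeat memorization, small enough to keep the confusable locus in view |
| `neg_ratio` | 2 | negatives sampled per positive each epoch |
| `pos_repeats` | 3 | times each positive appears per epoch (fresh shifts) |
| `neg_cap_ratio` | 2 | cap on newly mined negatives per iteration, × positive count |
| `n_iterations` | 3 | train/mine rounds |

Choices that were genuinely open, and how they were settled:

* **Negative retention and emphasis.** Mined negatives accumulate across
  iterations; discarding old ones would re-open previously fixed errors.
  Duplicate mining hits within 25 bp of an existing entry collapse onto
  it, since refinement emits clusters of adjacent false positives. Every
  epoch includes all mined hard negatives (capped at 2/3 of the epoch's
  negatives) with random-pool draws filling the rest: subsampling them
  uniformly from the accumulated pool dilutes the very examples the
  method exists to exploit, while letting them crowd out random
  negatives entirely degrades background calibration.
* **Warm starting.** Scan and prediction models are retrained every
  iteration against the updated negative set, continuing from the
  previous iteration's parameters; the strand model is trained once
  because its training data (the positives) never changes.
* **Strand-model geometry.** The orientation signal (which side the TATA
  box sits on, the direction of the Initiator) is local and
  fine-grained, so the strand model defaults to its own configuration —
  a 201 bp window with gentle pooling (4, 2, 2) and a higher learning
  rate — rather than the wide, heavily pooled detection geometry, and
  trains with the same jitter augmentation as the other models.
* **Small-data oversampling.** Desk-scale runs have tens of positives
  where a real truth set has hundreds of thousands; `pos_repeats`
  restores a sensible number of gradient steps per epoch without
  changing the data distribution (each appearance draws a fresh shift).
* **Class-balanced validation.** The validation split at desk scale can
  contain only a handful of positives. An unweighted validation loss is
  then either too noisy (few negatives) or rewards majority-class
  collapse (many negatives); weighting both classes equally makes early
  stopping select calibrated checkpoints.
* **Inclusive thresholds.** Both scan stages accept `score >=
  threshold`; with continuous scores the boundary case is immaterial,
  and one consistent rule keeps the prediction invariant
  (`score >= pred_threshold`) exact.
* **NMS tie-breaks.** Candidates are ranked by score descending, ties by
  smaller coordinate — determinism over any claim of optimality.

## Evaluation

A prediction matches a truth element iff it lies within 500 bp of the
element's anchor (TSS for promoters, interval midpoint for enhancers —
enhancers are bidirectional, so the midpoint is the natural anchor).
True positives are counted at the region level (an element with one or
more matching predictions counts once); false positives at the
prediction level. The report carries recall, precision, F1,
FP-per-correct (= FP/TP, meaningful exactly because of the mixed
counting units) and FP per megabase, which is the genome-scale error
rate independent of the truth-set size. Degenerate denominators yield 0
for the rates and an `Inf` sentinel for FP-per-correct when TP = 0 with
FP > 0.

`recall_at_threshold_curve()` re-thresholds retained candidates without
rescanning; distance filtering is applied once at threshold 0 so that
recall is non-increasing in the threshold by construction (re-running
NMS per threshold can violate monotonicity in edge cases).

## The synthetic genome

`generate_genome()` plants a minimal but honest regulatory grammar in
i.i.d. background sequence of 41% GC:

* **Promoters**: an Initiator consensus (`BBCABW`, its `A` on the TSS),
  a TATA box (`TATAWAWR`) 30 ± 2 bp upstream in half of the promoters,
  and a +0.12 GC boost over ±100 bp. Half are planted on the minus
  strand as the reverse complement of the cassette.
* **Enhancers**: a central `CCGACC` motif (80% of enhancers), a milder
  +0.08 GC boost, no strand.
* **Decoys**, the substrate for hard-negative mining, at realistic
  per-megabase rates (20/20/10): TATA-only loci (motif without
  Initiator or GC core), GC islands (promoter-level GC, no motifs), and
  base-shuffled promoter cassettes (exact promoter composition, motifs
  destroyed). A GC-threshold classifier tuned on the positives flags
  most GC-island decoys — which is precisely why a model trained on
  random negatives produces false positives for mining to harvest.

All elements (truth and decoys) are ≥ 2000 bp apart and ≥ 1000 bp from
chromosome edges, so the 500 bp evaluation margin is unambiguous.
`plant_pair_dependency()` additionally ties two TSS-relative offsets to
a correlated base pair (e.g. equal bases) while keeping each position's
marginal uniform — an epistatic signal invisible to any single-position
statistic, used to validate the pair-dependency analysis.

What the generator does **not** emulate: repeats and repeat families,
isochore structure, CpG-island dinucleotide statistics, tissue-specific
activity, or the long-tailed spacing of real TSS clusters. Passing
tests on this grammar demonstrates that the algorithms are implemented
correctly and that mining measurably helps on confusable negatives; it
does not certify performance on a real genome.

## Interpretation suite

All analyses accept either a trained scorer or any scoring function, so
each is validated against closed forms with stub models:

* `mutation_map()` — score change for every single-base substitution
  (4×L, reference entries zero; exactly 3L evaluations).
* `window_substitution_profile()` — mean relative score change when a
  sliding 7 bp window is replaced by random bases.
* `motif_effect()` — PWM occurrences (internal log-odds scanner, both
  strands, match = 80% of the maximum achievable score) replaced by
  random bases; effects reported as `(orig - new) / orig`.
* `pair_dependency_map()` — `V(i,j) = delta(i,j) - delta(i) - delta(j)`
  where "removing" a position is the mean over its three alternative
  bases. The deterministic averaging makes the additive-model null
  exact (`V` vanishes analytically for any model linear in the one-hot
  input); random replacement is retained for multi-base spans
  (`region_dependency()`), where enumeration would be exponential.
* `independence_test()` — Welch t-test comparing the dependency of two
  matched motifs against the dependency of the first motif with random
  same-width spans.
* `cluster_maps()` — k-means (k = 10, Frobenius distance on flattened
  matrices) with seeded k-means++ initialization; clusters are reported
  largest-first.

The score-adjustment transform `log(1 + s/(1-s)) = -log(1-s)` undoes
softmax saturation and is intended for correlating scores with
quantitative expression; all interpretation routines operate on the raw
softmax score.

## Problem sizes and reproducibility

The package's end-to-end checks run on one CPU at these sizes, chosen so
a full run of the test suite and the acceptance script completes in tens
of minutes: mining efficacy on a 2 Mb genome (4 × 500 kb, one
chromosome held out) with 60 promoters, 20 enhancers and ~100 decoys,
3 iterations, 3 seeds; capacity checks on 500 + 500 windows; the
matcher fuzzed on 1000 random instances. Every stochastic step draws
its seed from a single run-level seed by fixed offsets, so a run is
reproducible from `(config, seed)` alone.

## Known limitations

* The desk-scale model is orders of magnitude smaller than a
  GPU-trained production model; absolute recall/precision on the
  synthetic genome are not comparable to published genome-wide figures,
  only the *relative* improvement from mining is meaningful here.
* Scores are softmax probabilities from a small network and are not
  calibrated; the fixed 0.5 threshold is a convention, and
  `recall_at_threshold_curve()` exists precisely to examine the
  trade-off.
* Fine-grained features learn slowly in a small CNN: a signal carried by
  one or two bases (the Initiator's orientation, a planted correlated
  base pair) needs either many training elements or many epochs to
  emerge, while extended signals (GC cores, full motif cassettes) are
  learned in a handful of epochs. In practice this caps held-out strand
  accuracy at desk scale (~0.6 with tens of training promoters, ~0.73
  with a couple of hundred) even though the planted grammar makes
  orientation fully decodable in principle.
* The PWM scanner thresholds on fraction-of-maximum log-odds, not on a
  p-value; ranks match a p-value scanner but absolute match counts may
  differ.
* Chromosomes shorter than the model window are skipped (with a
  warning), not padded-and-scanned.
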