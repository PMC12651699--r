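---
title: "Spatial soft labels and template-based tooth-numbering correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial soft labels and template-based tooth-numbering correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentalign)
```

## The problem

FDI tooth numbering assigns each of the 32 permanent teeth a two-digit code:
quadrant (1 upper right, 2 upper left, 3 lower left, 4 lower right, facing
the patient) times within-quadrant position (1 central incisor … 8 third
molar). An object detector trained to emit these codes on periapical
radiographs faces two structural difficulties. First, the 32 classes are not
exchangeable: adjacent teeth look alike, so most classification errors land
on a neighbour, and a one-hot ("hard") training target treats a
neighbour confusion and a cross-mouth confusion as equally wrong. Second, a
periapical film shows only a 2–8 tooth window of one arch; when a tooth has
been extracted or replaced, the detector sees an unremarkable gap and the
remaining teeth are easily numbered as if the arch were contiguous, shifting
every label past the gap.

`dentalign` addresses both ends: a spatial soft-label loss component for
training, and a template-based sequence-correction pipeline plus a full
evaluation suite for inference-time post-processing. The detector itself is
out of scope — the package consumes its outputs (boxes, labels, scores,
optionally 32-class probability vectors) and its base loss as an opaque
scalar.

## The linear arch index

All spatial reasoning runs over a linear index 1..32 rather than the raw
codes: upper arch 18…11, 21…28 ↦ 1..16 and lower arch 48…41, 31…38 ↦ 17..32,
ascending viewer-left to viewer-right on a standard dental chart. This makes
physically adjacent teeth numerically adjacent *including across the
midline* (11/21 are indices 8/9), which is exactly what a one-hot code space
lacks: |15 − 21| in code space says nothing about anatomy. Index 0 is
reserved for the missing-tooth placeholder; it participates in sequences but
never in distances or code conversion. The published description never
prints its own code↔index table; if a downstream consumer uses the mirrored
(film-side) orientation, the `try_reversed` option of `correct_sequence()`
scores the reversed template as well and keeps the better match.

Distances across arches are a sentinel (`Inf`), not a large finite number:
the soft label must give the opposing arch exactly zero mass by default, and
no finite cap does that.

## The spatial soft label and its loss

For a ground-truth tooth $t$ the soft label is

$$P_\text{soft}(i) \propto \exp\!\big(-d(i, t)/\tau\big)$$

over same-arch classes, where $d$ is the arch distance in tooth steps and
$\tau$ (the `temperature`, default 1, in tooth steps) sets the decay scale;
cross-arch classes receive a configurable `floor` (default 0) shared
uniformly. The requirements on the kernel are only that it peaks at the
truth, decays strictly with distance, and treats equidistant neighbours
equally; exponential decay is the simplest such choice, and at the default
temperature the weight at distance 5 is already below 1% of the peak —
"close to zero" in practice. As $\tau \to 0$ the hard label is recovered.

The divergence from a predicted distribution $P_\text{pred}$ to the soft
label is the Kullback–Leibler divergence in natural-log units,

$$\mathrm{DivLoss} = \sum_i P_\text{soft}(i)\,
  \log\frac{P_\text{soft}(i)}{P_\text{pred}(i)},$$

entering training as $\text{total} = \text{base} + \alpha\cdot
\mathrm{DivLoss}$. The default $\alpha = 0.7$ is the weight at which
training converges fastest without costing accuracy. Numerical choices:
$0\log 0 = 0$; $P_\text{pred}$ is clamped at $\varepsilon = 10^{-12}$ before
the log so that a prediction assigning zero mass where the soft label does
not stays finite; the log base is natural, the standard for loss functions.
Whether the divergence is averaged per detection, per image, or per batch
before weighting is a property of the training loop, not of the loss;
`batch_mean_kl()` provides the per-batch arithmetic mean as one reduction,
documented as such.

## Sequence correction

The pipeline for one image is:

1. **Sort** detections by `x_min` ascending (ties by `y_min`, then input
   order).
2. **Insert placeholders.** For each adjacent pair, the empty horizontal gap
   is `x_min(next) − x_max(prev)`. A gap above the threshold is read as
   missing teeth and filled with `k = min(max(1, round(gap/pitch)),`
   `max_insertions)` placeholder records (label 0, score 0, synthesized
   boxes evenly spaced in the gap).
3. **Choose the arch**: `U` counts labels in 1..16, `L` in 17..32;
   the upper template is used iff `U > L` (ties go lower, the literal
   "otherwise" branch). Placeholders count in neither — a placeholder
   carries no arch evidence, and counting 0 as "≤ 16" would bias arch
   choice toward upper.
4. **Slide the template**: over offsets $0..16-n$, count label agreements;
   the best offset is the argmax, with ties resolved to the smallest offset
   (the argmax is otherwise ill-defined; smallest is deterministic).
5. **Correct** when the match count `M > 1`: two agreeing anchor teeth are
   the minimum evidence that the alignment is real. Each slot whose label is
   positive and disagrees with the template value is rewritten; slots with
   label 0 keep 0 — the formula's `p > 0` guard — while the template value
   they would take is reported separately as the inferred number of the
   missing tooth. Keeping 0 internally and reporting the inference
   separately honours the guard while still delivering the filled-in
   numbering for display. With `M ≤ 1` labels pass through unchanged.

A sequence longer than 16 slots cannot belong to one arch and raises a
domain error rather than a silent truncation; sequences spanning both arches
in one image are out of scope.

### The gap rule

The threshold is deliberately scale-free: `0.5 ×` median box width of the
sequence by default, configurable as absolute pixels. Crowns in a periapical
view nearly abut — intact neighbours are separated by far less than half a
crown — while a single missing tooth opens a gap wider than a full crown, so
half a width separates the two regimes with margin on both sides across
radiograph resolutions.

The per-gap insertion count needs a pitch (centre-to-centre spacing)
estimate. It is the median spacing over the *intact* adjacent pairs (gap
below threshold): spacings measured across a missing-tooth gap are inflated
by the gap itself, and in a 5-tooth window with two adjacent teeth missing
the raw median would be dominated by it, inserting one placeholder where two
teeth are absent. When no intact pair remains (two surviving boxes flanking
one gap), pitch falls back to `1.2 ×` the median crown width — the centre
spacing of abutting teeth exceeds the crown width only by the interproximal
contact margin. Insertions are capped at 2 per gap (`max_insertions`):
beyond two consecutive missing teeth the remaining evidence in a periapical
window is too thin for the inferred count to be trustworthy, and the
correction degrades gracefully to "a gap is here".

## Evaluation metrics

Matching is greedy one-to-one in descending confidence, each prediction
claiming the unmatched ground truth with the highest IoU ≥ 0.5 (the standard
detection-evaluation convention; class agreement additionally required in
class-aware mode). On top of the matches:

- precision, sensitivity and F1 are the literal count ratios (micro over
  classes, class-aware); a `0/0` ratio is flagged `NA`, never silently 0 —
  small scenes hit these constantly and a fake 0 would poison aggregation;
- specificity has no natural "true negative box", so it is macro-averaged
  one-vs-rest over the classes present: for class $c$, TNs are matched
  pairs involving $c$ neither as truth nor prediction, FPs the unmatched
  predictions of $c$. This is the only construction that yields the
  near-unity values a 32-class problem produces;
- average precision per class is the area under the precision envelope of
  the score-ranked PR curve (all-point interpolation, the modern
  convention), and mAP50 averages over classes present in the ground truth
  — absent classes are skipped, not counted as 0;
- the FDI position error is the mean absolute *linear-index* difference
  over class-blind matched pairs, so a mislabel one tooth over costs 1
  regardless of quadrant boundaries; cross-arch mismatches are capped at 16
  (the arch length), as no meaningful spatial distance spans the occlusion;
- top-1 confidence is the mean score over class-aware true positives;
- the 32×32 confusion matrix counts class-blind matched pairs by
  (true, predicted).

Pooling over images translates each image onto a disjoint band of a virtual
canvas (cross-image IoU exactly 0) and evaluates once, which keeps per-image
matching and global score ranking simultaneously correct.

## The synthetic scenario generator

The generator emulates what a detector emits for one periapical field of
view, with defaults chosen as a realistic operating point and then left
alone: one arch, 5 consecutive teeth (range 2–8), pitch 60 px, crowns
50 × 80 px, 5% uniform geometric jitter; a surviving tooth's label is
replaced by a same-arch neighbour at distance 1 with probability 0.2
(adjacent confusion is the dominant observed error mode); a tooth is dropped
with probability 0.1, leaving its gap; each interior gap gains a spurious
random-label box with probability 0.05. Confidence scores are Beta
distributed — mean 0.9 for clean detections, 0.6 for corrupted ones — so
that correct predictions inhabit the high-confidence regime a converged
detector shows without claiming to match any particular detector. Batches
derive one seed per case from the batch seed, recorded in the case, so any
case regenerates independently and batches are byte-reproducible.

`evaluate_correction_gain()` scores each case before and after correction
(label accuracy and FDI error over class-blind IoU ≥ 0.5 matches) and
reports missing-tooth recall over *interior* drops — a dropped tooth whose
flanking neighbours both survive leaves a measurable gap; an edge drop
leaves none and is invisible to any gap-based mechanism by construction.
The `eligible` variant restricts further to gaps above threshold holding at
most `max_insertions` drops, the regime the mechanism is designed for.

What the generator does **not** model: pixel appearance (so nothing here
validates the detector's visual errors being neighbour-biased — that is
assumed, not derived), rotated or overlapping boxes beyond mild jitter,
bitewing or panoramic two-arch geometry, deciduous teeth, and correlated
failure modes (e.g. a dark film degrading every score at once). Passing
tests on these scenarios therefore establishes the post-processing
machinery's correctness and its behaviour under the stated noise model, not
clinical performance.

## Problem sizes and verification

The test suite checks the alignment against a deliberately naive
enumeration oracle on every label sequence of length ≤ 3 over {0..32} (both
templates) plus 10⁴ seeded random sequences up to length 16; repairs every
single-error corruption of every consecutive run of length 3–8 on both
arches exhaustively; verifies KL non-negativity on 10⁵ random distribution
pairs and against closed forms; cross-checks average precision on 100
seeded random scenes against both an in-suite brute-force PR-area oracle
and an independent numpy implementation; and measures the correction gain
on 500 seeded scenarios at the default configuration, where post-correction
label accuracy exceeds pre-correction accuracy, FDI error falls, and
eligible-gap missing-tooth recall is 1. `scripts/acceptance.R` recomputes
the batch-level quantities from scratch for any seed.

## Known limitations

- One arch per image; a sequence mixing arches is corrected against the
  majority arch, and an over-long sequence errors out.
- The correction trusts horizontal order: a detector output with grossly
  wrong box geometry (swapped neighbours) is corrected *into* the template
  order, which may not match reality.
- With `M ≤ 1` nothing is corrected even when the single match is right;
  with exactly two anchors a consistent double-error can fool the argmax.
- More than two consecutive missing teeth exceed the placeholder cap by
  design, and an edge drop cannot be detected from geometry at all.
- The soft-label kernel shape (exponential) and its default temperature are
  modelling choices; only the qualitative constraints (peak, monotone
  decay, near-zero at distance ≥ 5, zero cross-arch mass) are fixed by the
  problem.
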