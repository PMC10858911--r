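---
title: "Methods: flash-pattern trajectorization, classification and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flash-pattern trajectorization, classification and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own methods: the models and
procedures, the parameters that matter, what the synthetic generator does
and does not emulate, the numerical choices, and the known limitations. It
states no empirical number that the test suite or `scripts/acceptance.R`
does not itself compute.

## From detections to sequences

The input is a table of 3D flash localizations `(recording_id, frame, x, y,
z)` at 30 frames per second. Two linkage stages turn detections into
individuals:

* **Streaks** (`link_streaks()`): detections at strictly consecutive frames
  within `radius_m` of each other are one continuous flash as the insect
  moves. The radius is not pinned down by field practice, so the default is
  0.2 m per frame step — generous for realistic flight speeds (well under
  1 m/s) yet far below typical inter-individual spacing — and it is
  exposed as an argument. When several detections share a frame, active
  streaks are extended greedily by ascending distance, which is
  deterministic and adequate at realistic swarm densities.
* **Trajectories** (`link_trajectories()`): streaks whose endpoints occur
  within both `max_gap_s = 1` s and `max_dist_m = 1` m are assumed to come
  from the same individual, and trajectories are the transitive closure
  (connected components) of that relation. The rule compares the *end* of
  the earlier-starting streak to the *start* of the later one — the
  simplest reading of endpoint proximity; minimum pairwise distance over
  all detection pairs would be a stricter alternative but changes nothing
  when streaks are short relative to the thresholds.

Binarization (`trajectories_to_sequences()`) marks a 1 for every frame
containing a flash of the trajectory, spanning its first to last flash, so
every sequence starts and ends with 1. Frames are 0-based; a sequence's
time axis starts at its first flash.

Cleaning fills interflash gaps of 1–2 bits (< 0.07 s at 30 fps), which are
tracking dropouts or brief occlusions rather than behavior; the rule is
idempotent and never removes light. Cleaning runs *before* the single-flash
threshold so that flashes reconnected by filling count as one: a trajectory
whose only structure was a spurious 1-bit gap is then correctly discarded
as a single flash. Species with fewer than 100 trajectories are dropped —
below that the classifiers cannot robustly learn a pattern.

`fps` is fixed at 30 by default (the recording standard); other rates are
accepted, but the gap-filling rule is defined in *bits*, and the 0.07 s
equivalence holds only at 30 fps.

## The GRU classifier

The classifier is a 2-layer gated recurrent network with 128-dimensional
hidden states, reading the raw bit at each timestep — no handcrafted
features, so classification rests on temporal structure alone. Gates follow
the standard formulation (reset and update gates, tanh candidate state).
Training uses Adam on the cross-entropy loss, batch size 8, learning rate
1e-5, global gradient-norm clipping at 0.1, and early stopping on the
validation loss with a patience of 50 epochs, returning the
best-validation-loss parameters. An epoch cap (`max_epochs = 1000`) bounds
runtime; it is a safety net, not part of the protocol. A sweep grid of
batch size {8, 16, 32} × learning rate {1e-3, 1e-4, 1e-5} is expressible
through `gru_config()` but not automated.

Design choices the protocol leaves open:

* **Readout head.** A single affine map from the final hidden state of the
  last layer to the species logits. The stated LeakyReLU (negative slope
  0.1) placement is ambiguous ("activation layers"); it is applied between
  the recurrent stack and the readout. Both the placement and slope are
  configuration fields.
* **Input encoding.** One bit per timestep as a 1-dimensional input;
  chunked encodings were considered and rejected as they would smuggle in a
  handcrafted timescale.
* **Batching.** Variable-length sequences are right-padded with a
  per-timestep mask that freezes the hidden state of finished sequences, so
  the state at the last padded step equals the state at the sequence's own
  last frame. The test suite asserts batched and unbatched forward passes
  agree, and verifies the full backpropagation-through-time gradient
  against numerical differentiation — the strongest available oracle for a
  from-scratch implementation.
* **Seeding.** One master seed in the config governs initialization and
  shuffling; identical data and config reproduce the model exactly.

Everything (forward pass, BPTT, Adam, clipping) is plain R matrix code: no
R deep-learning runtime is part of the package's dependency set, and the
network is small enough that BLAS-backed matrix products on CPU are
adequate at the problem sizes used here.

## Reference-based baselines

Literature references encode each species' published pattern — entered as
alternating on/off durations in seconds (`literature_patterns()`, also
shipped as a CSV fixture) — into binary series at 30 fps, each segment
contributing `round(duration × fps)` bits with a 1-bit floor.
*B. wickershamorum* has no published pattern; its absence is represented
explicitly (six literature references, never a zero template). Population
references average a species' training sequences: sequences all start with
a flash, so they are left-aligned at onset, zero-padded right to the
longest length, and averaged elementwise, giving a real-valued template in
[0, 1]. Alignment before averaging is an open choice; onset alignment is
the canonical one given the sequence invariant.

Scores against references:

* **Jaccard**: intersection `Σ a_i b_i` over the overlapping prefix,
  divided by the *summed mass* `Σa + Σb`. Note this "union" makes 0.5, not
  1, the maximum for identical binary sequences; the definitions are used
  literally. Real-valued (population) references reuse the same sums.
* **Dot product**: `Σ a_i b_i` over the overlapping prefix.
* **DTW**: classic full-path dynamic programming with local cost
  `|a_i − b_j|`, steps (1,0), (0,1), (1,1), no window. Distances are
  *negated* before the softmax so that smaller distance means higher
  probability; the alternative (softmax of raw distances) would select the
  most distant species, which cannot be the intent given DTW's reported
  competitiveness.
* **SVM**: RBF kernel on the standardized 3-vector (flash count, mean
  flash duration, mean gap) with `cost = 1` and `gamma = 1/3` defaults
  (no protocol values exist; both exposed).

Probabilities are softmax at temperature 1; ties everywhere break toward
the lowest label-encoded species, deterministically. Single-flash
sequences have no defined gap, so `svm_features()` refuses them — the
pipeline thresholds them out beforehand anyway.

## Evaluation protocol

`stratified_folds()` implements 60-fold stratified cross-validation: each
fold is a 90/10 split preserving class ratios, with test membership cycling
through ten disjoint stratified bins so every sequence is tested at least
once across folds and never used for training and testing simultaneously
within a fold. The training portion is randomly undersampled without
replacement to the minority-class count ("secondary sampling until classes
are equalized" admits several readings; plain seeded undersampling is the
simplest and the sampler is exposed). A validation set is carved from the
equalized pool (10 % of it) because the training protocol monitors a
validation loss but the split specification only defines train/test
fractions. All leftover data join the test pool.

Metrics: weighted precision/recall (class-support weights; an unpredicted
class contributes precision 0), accuracy, row-normalized confusion matrices
(diagonal = per-class recall), and one-vs-rest ROC/AUC per species (via
pROC). Ensemble results across folds are means with standard errors.

`sympatry_experiment()` mixes two held-out species at minority proportions
from 0.5 % (2 of 400) to 50 % (200/200), classifies the mixture, and
records each species' true-positive rate over 500 iterations for all
ordered pairs (20 for the five holdout species of `holdout_table()`).
Sampling is with replacement when a held-out day is smaller than requested.
Since inference is deterministic, each held-out sequence is classified once
and iterations resample indices — exactly equivalent and far cheaper.

## Confidence filtering and characterization

`top_confident_subset()` is the filtration algorithm verbatim: keep
(probability, index) pairs where the arg max matches the true label, sort
by probability descending (ties by ascending index), take the top 100 (all,
if fewer qualify). `characterize_population()` pools statistics at the
*event* level — each flash duration and each gap contributes once, one
count per sequence — because the target distributions are event-level;
per-sequence means would converge to the same expectations for independent
draws but weight sequences differently. Histograms are normalized to sum
to 1 with bin widths of 1 flash and 1 frame (1/30 s), both configurable.
Raw and filtered variants are both obtainable (characterize the full table
or the filtered subset). Significance testing between data and literature
distributions is out of scope; `compare_to_literature()` reports plain
deltas, with `NA` where no published value exists.

## The synthetic generator

`generate_population()` draws pulse trains per population: flash count =
rounded normal draw floored at 2 (mirroring the single-flash threshold so
nothing generated is discarded); each flash duration and each gap an
independent normal draw in seconds, quantized to the frame grid with floors
of 1 frame and 3 frames respectively (3 so that gap cleaning is a no-op on
generated data — both floors are arguments for tests that exercise the
cleaning rule). Quantization rounds half away from zero for cross-platform
determinism. The twelve presets of `preset_table2()` carry the
field-characterized means and standard deviations verbatim. Normality is an
emulation choice: the field distributions are characterized only by mean ±
sd, and independent normal timing is the minimal model consistent with
them. The generator therefore emulates first- and second-moment structure
and the alternating on/off grammar of real flash patterns, but *not*
within-sequence correlations (e.g. drifting gap lengths), temperature
dependence, truncated patterns from occlusion, or synchronization between
individuals — so passing tests demonstrate pipeline correctness under the
stated statistical conditions, not field performance.

`generate_swarm_events()` embeds fireflies as Gaussian random walks in an
arena, emitting each on-frame as a detection with optional positional noise
and frame drops, and returns the planted firefly identity per event. It
deliberately omits flight kinematics and interaction; its purpose is to
exercise the linkage rules against a known partition.

## Problem sizes and numerical choices

The test suite runs the classification experiment at 200/50/50
train/validation/test sequences per species for two synthetic populations
with disjoint parameters (3 × 0.10 s flashes at 0.30 s gaps vs 4 × 0.20 s
flashes at 0.80 s gaps), a GRU of 2 layers × 32 hidden units at learning
rate 0.01 with clipping at 1.0 — a CPU-scale instance of the architecture;
the full-scale defaults remain in `gru_config()`. Parameter-recovery checks
use 10,000 sequences per preset. DTW is verified against exhaustive
warping-path enumeration on all binary pairs of length ≤ 6; weighted
metrics against a per-class tally oracle. Softmax uses max-subtraction; an
all-zero Jaccard union returns 0; `tsne_embed()` (in-package t-SNE, used to
visualize the hidden-state embedding) is deterministic under its seed and
refuses degenerate all-identical input.

## Known limitations

* **Single-flash species.** Species flashing once with > 1 s dark periods
  cannot be trajectorized under the 1 s rule and are out of scope.
* **Duration quantization.** At 30 fps, flash durations near or below one
  frame (e.g. 0.04 s) are floored at 1 frame ≈ 0.033 s, biasing recovered
  duration means for the fastest-flashing populations; gap and count
  statistics are unaffected at realistic scales. The recovery guarantees
  in the tests therefore target gaps ≥ 0.3 s and durations ≥ 0.15 s.
* **DTW against averaged references.** Unnormalized full-path DTW must
  traverse the entire reference, and averaging imperfectly aligned training
  sequences smears the longer reference into intermediate values that cost
  ≈ 0.5 per frame against any binary sequence. When candidate species
  differ in typical sequence length, this systematically favors the
  *shorter* reference, and DTW collapses toward predicting the
  short-pattern species regardless of input. Path-length-normalized DTW
  variants would remove the bias but are deliberately out of scope (the
  distance here is the classic unnormalized one). The same mechanism is
  consistent with DTW's weak recall against single literature references
  on real data.
* **Greedy streak matching** resolves simultaneous detections locally; a
  globally optimal assignment (Hungarian matching) could differ in very
  dense swarms.
* **Field generalization.** All quantitative guarantees in the test suite
  are under the synthetic generator's assumptions; applying the pipeline to
  new recordings still requires labeled, single-species footage per class,
  and about one hundred trajectories per species before patterns are
  robustly distinguishable.
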