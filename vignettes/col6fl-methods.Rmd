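---
title: "Methods: a synthetic two-site benchmark for federated collagen VI phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a synthetic two-site benchmark for federated collagen VI phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(col6fl)
```

## The problem this package models

Collagen VI-related dystrophies (COL6-RD) span Bethlem myopathy to Ullrich
congenital muscular dystrophy. The dominant-negative variants behind most
cases fall into three mechanism groups — glycine substitutions disrupting
the Gly-X-Y triple-helix motif, the recurrent COL6A1 intron-11 pseudoexon
insertion, and in-frame exon skipping — and each leaves a subtly different
signature in immunofluorescence images of the collagen VI matrix deposited
by cultured dermal fibroblasts. A classifier that reads those signatures
can triage variants of uncertain significance; but patient images are rare,
privacy-restricted, and scattered across institutions with very different
microscopes. That is the natural setting for horizontal federated learning
(FL): institutions share a feature space but not patients, each trains
locally, and only model parameters reach an aggregator (FedAvg).

The images behind the original two-site evaluation are private and cannot
be redistributed, so the single-node-versus-federated experiment is not
directly rerunnable. This package replaces the two institutional datasets
with a procedural generator that emulates what matters for the federated
comparison — four-class structure, two-site size asymmetry (300 vs 31
images from 90 patients), multi-image patients, and site-dependent
acquisition physics — so the full experimental design runs on a desk in
minutes, deterministically, from a single seed.

## The synthetic imaging model

Each image is a field of beaded microfibrils over a dim background,
rendered in the green channel of an RGB image (with fixed bleed-through
into red and blue so that hue is defined and HSV-based augmentation is
meaningful). Six texture parameters drive the renderer; each class draws
them uniformly from class-specific bounds (`texture_bounds()`):

* `filament_density` (filaments per 1e4 px²) — controls high, exon
  skipping low;
* `orientation_coherence` (0–1) — mapped to the concentration of a von
  Mises distribution over filament orientations; controls aligned, glycine
  substitution disordered;
* `bead_spacing` / `bead_contrast` — period and depth of the sinusoidal
  intensity modulation along each filament; the pseudoexon class has
  attenuated beading;
* `fragmentation` — probability a filament is broken into segments; high
  for exon skipping;
* `puncta_rate` — isolated bright puncta per 1e4 px²; high for the
  speckled glycine-substitution phenotype.

The bounds deliberately overlap between neighbouring classes so the task is
learnable but not saturated; they are calibrated so that a pooled linear
model on the frozen texture features clears macro-F1 0.9 on a patient-level
hold-out (the test-suite checks this on a 68-image hold-out, large enough
that the estimate is not quantized by single images, and without
augmentation, whose variants would shift the training distribution away
from the clean evaluation images) while single-site models remain clearly
worse — the regime the benchmark is meant to probe. Site physics then apply in a fixed order:
background addition, Gaussian blur, brightness gain, additive Gaussian
noise, clipping to [0, 1]. The defaults
(`default_site_profiles()`) make the large site (NIH, 320×320 px native)
clean and the small site (UCL, 272×272 px) brighter, blurrier and noisier,
so the federation is non-IID in both covariates and label proportions
(the per-class counts follow the published distribution exactly). The
native sizes differ between sites to exercise the resize stage; both are
desk-scale choices — what matters is heterogeneity, not absolute pixel
count.

Patients: the published total is 90 patients for 331 images, with no
per-site breakdown available. We allocate 81 patients to the large site
and 9 to the small one (2–3 per class), keeping the overall ~3.7 images
per patient at both sites. Per-patient image counts are drawn uniformly
from 2–6 and the last patient of each class absorbs the remainder, so
per-class totals match exactly. One root seed determines everything; each
image derives its own stream from a documented counter, so any image can be
re-rendered independently and generation order is immaterial.

What the generator does *not* model: physically accurate optics, z-stacks,
real fibroblast morphology, or the actual visual appearance of clinical
images. A benchmark pass here shows the pipeline's statistical machinery
works under realistic class overlap and site shift; it says nothing about
accuracy on real microscopy.

## Preprocessing and augmentation

All partitions are bilinearly resized to 256×256 and normalized to [0, 1]
(8-bit inputs divided by 255). The training partition is additionally
expanded 5× per image: one 45° rotation, one horizontal flip, and HSV
value-channel scalings by 1.25 and 1.5 (the published augmentation recipe;
all multiples of 45° are available via `augmentation_config()`). The
augmentation refuses to touch rows tagged `partition == "test"` —
validation/test images are only resized and normalized. Design choices
worth noting:

* "45-degree rotations" is read conservatively as the single angle 45°,
  configurable to all multiples.
* Odd multiples of 45° would push image corners out of frame; we
  reflect-pad before rotating and center-crop after, because black corners
  would trivially mark an image as augmented to the classifier. Right-angle
  multiples are exact index permutations.
* The HSV value scaling is implemented as its algebraic equivalent (a
  per-pixel rescale of all channels by `min(f·V, 1)/V`, V = max(R,G,B)),
  which preserves hue and saturation exactly; the test-suite pins it
  against an explicit colorspace-conversion oracle.

## Features and the trainable head

The default backend is a deterministic hand-crafted texture descriptor
(d = 82): per-channel 16-bin intensity histograms and moments, multiscale
gradient-magnitude statistics (256/128/64 px scales), an
orientation histogram with circular coherence and entropy, band-pass
(unsharp) statistics that respond to beads and puncta, a high-frequency
energy ratio, and connected-component statistics of the thresholded signal
that track network fragmentation. Orientation, band-pass and fragmentation
statistics are computed at half resolution — they are coarse-scale
properties, and this halves the descriptor cost. The descriptor needs no
downloaded weights, which keeps the repository self-contained; a
`pretrained_cnn` backend id is reserved for a frozen ImageNet-pretrained
convolutional backbone with global average pooling, and errors with
instructions when its weights are absent.

On top of the raw descriptor sits a frozen per-feature affine scaling
(`feature_scaling()`). The raw feature groups span three orders of
magnitude, which leaves full-batch gradient descent on the softmax head so
ill-conditioned that its convex optimum is unreachable in any reasonable
epoch budget. The constants were computed once over a
reference pool of 480 synthetic images spanning both sites, all classes and
all augmentation variants, rounded, and frozen into the package — exactly
like the fixed normalization statistics inside any frozen pretrained
backbone. Every node and every arm uses the same constants, so federated
and centralized training see identically scaled inputs and no per-node
statistics are ever shared.

The trainable model is a single dense softmax layer (d×K weights + K
biases), minimizing mean cross-entropy plus `lambda * ||W||²` (bias
unpenalized) by full-batch gradient descent with a fixed learning rate.
With frozen features this objective is convex; the loss is non-increasing
for small enough rates, and the whole optimization is deterministic given a
seed (mini-batch mode exists and seeds its shuffling). Only these head
parameters are ever federated.

## Federated training and baselines

`run_federated()` implements FedAvg with full participation: broadcast,
`local_update()` on each node (initializing from the global parameters,
`E` local epochs), then an element-wise weighted average with weights
`n_k / Σn` (or `1/M` uniform). The privacy boundary is structural: nothing
in the federation module accepts raw data from more than one node — nodes
emit only `(params, n)`. Secure aggregation, encryption and differential
privacy are out of scope; the boundary here is an API contract, not a
cryptographic one. The pooled-centralized baseline, which deliberately
pools all features as an upper reference, lives in the orchestration layer
instead.

Two schedules matter:

* `fedavg_config()` defaults — 20 rounds, one full-batch local epoch,
  learning rate 0.1, lambda 1e-3, sample-count weighting. In this regime
  each federated round is *mathematically identical* to one full-batch
  gradient step on the pooled data, which gives an exact oracle: the
  test-suite checks 20 rounds against pooled descent to < 1e-6.
* `experiment_config()` defaults — 300 rounds, otherwise the same regime,
  learning rate 0.5, lambda 1e-4 on scaled features. Twenty steps cannot
  fit a four-class head; three hundred reach the neighbourhood of the
  convex optimum in ~1 s per arm. Keeping E = 1 and full batch means the
  exact FedAvg/centralized identity still holds round for round, so the
  federated arm is transparently interpretable as pooled descent.

Single-node baselines receive the same total epoch budget (`rounds ×
local_epochs`) and seed discipline, so comparisons are not confounded by
training length.

## Evaluation

Per-class precision and recall come from the confusion matrix (true classes
in rows); F1 is their harmonic mean; macro-F1 is the unweighted arithmetic
mean over classes; accuracy is the fraction correct. Conventions: any
zero-denominator metric is 0 (a class never present and never predicted
scores 0, a conservative choice); multi-trial spreads use the sample (n−1)
SD; the four-to-two collapse maps control to negative and pools the three
pathogenic mechanisms as positive. All of this is pinned against
independent brute-force tallies in the tests.

## The benchmark experiment

`run_comparison()` reproduces the published design in silico: per trial,
generate the 331-image scenario, split at the patient level to a 24-image
hold-out (20 large-site, 4 small-site; whole patients only, stratified over
classes as evenly as the 2–6-image patient granularity allows, randomized
with restarts until the count is met exactly), augment the training
partitions only, extract features, train the two single-node arms, the
federated arm and the pooled reference under the matched epoch budget, and
evaluate everything — four-class and binarized — on the trial's shared
hold-out. Ten trials with per-trial derived seeds (rendering, split,
augmentation and training all re-randomized) yield mean ± SD summaries.
The published protocol selected ten hold-out images by expert criteria;
that is not emulable and is replaced by stratified random patient
selection.

Runtime is dominated by rendering and feature extraction, roughly 90 s
per trial on one core (~15 min for the 10-trial default). Determinism is
end-to-end: identical config and seed give bit-identical reports.

## Numerical and degenerate-input choices

* Gaussian blur is a separable banded-matrix product with mirrored
  boundary (rows sum to 1, so flat images stay flat); radius 3σ.
* Bilinear resize is EBImage's; a target-sized [0, 1] input is returned
  untouched.
* The von Mises sampler is the Best–Fisher rejection scheme; at
  coherence → 0 it degrades gracefully to the uniform circle.
* `filament_density = 0` with `puncta_rate = 0` renders the exact constant
  `background × gain`; doubling the gain doubles every pixel while nothing
  clips.
* Rendering below 32×32 px errors: the texture model is undefined there.
* Patient-level splits error when a site's request exceeds its images;
  requests that no whole-patient combination can hit exactly are met with
  minimal excess by the last selected patient.
* Softmax probabilities are computed with the max-subtraction trick;
  log-loss clamps probabilities at 1e-300.

## Known limitations

The descriptor is not a learned representation; its 82 statistics were
chosen for the synthetic phenotype axes and will not transfer to real
immunofluorescence images. The generator's class differences are
parametric conveniences, not biology. The federated simulation runs
in-process — no networking, stragglers, or secure aggregation — and with
two always-available nodes, client sampling is out of scope. Results on
this benchmark demonstrate correctness of the pipeline (splitting,
augmentation hygiene, FedAvg arithmetic, metric definitions) rather than
clinical performance.
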