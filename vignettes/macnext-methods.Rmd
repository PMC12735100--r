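---
title: "MACNeXt: model, training protocol and synthetic benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MACNeXt: model, training protocol and synthetic benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macnext)
```

## The model

MACNeXt is a compact, fully convolutional classifier for colony
photographs. Its residual main block runs two parallel feature extractors
(a grouped 3×3 convolution for spatial texture and a grouped 1×1 for
channel mixing), concatenates them into an inverted bottleneck at twice
the stage width, squeezes back, and then passes the first residual sum
through *two* parallel activation branches — one GELU, one ReLU — whose
sum feeds a second residual. The working assumption is that the two
nonlinearities are complementary: GELU preserves small smooth responses
(faint colony texture, gradual hemolysis edges), ReLU produces sparse
high-contrast responses (colony borders), and adding both before the final
batch normalization lets either pathway dominate per channel. Batch
normalization appears after every convolution; biases would be absorbed by
its shift, so no convolution carries one. Only the fully connected output
layer has a bias.

All shape arithmetic uses the "same"/ceiling convention: a stride-1 3×3
convolution preserves its input, and a stride-2 convolution maps a side of
`n` to `ceiling(n / 2)` (with asymmetric zero padding when `n` is odd).
This is what makes the reference geometry exact: 224 → 56 (stem) → 28 →
14 → 7. Configurations whose sides would collapse to 1 before the final
stage are rejected at validation rather than silently padded.

## Fixing the group convention

The architecture is specified up to one genuine unknown: every grouped
convolution's group count. We resolve it with the one hard constraint
available — the network's total budget of 4.4 million learnable
parameters — by evaluating the closed-form per-layer counts
(`countParameters(cfg, "closed_form")`) over a uniform channels-per-group
constant `c` and the two structurally ambiguous 1×1 layers of the block
(the 2F→2F expansion and the 2F→F squeeze, each of which can be read as
grouped or plain):

* expansion grouped, squeeze plain: total `2,196,936 + 43,872 c`; the
  largest admissible `c` (48, one single group per layer... i.e. the
  least-grouped reading) reaches only 4.30M;
* both grouped: `40,392 + 46,080 c`; no admissible `c` lands on 4.4M;
* both plain: over 6.5M regardless of `c`;
* **expansion plain, squeeze grouped**: total `4,353,480 + 41,664 c`,
  which hits the printed budget at `c = 2` (4,436,808 → 4.4M). `c = 1`
  is structurally impossible here (a 2F→F squeeze cannot have 2F groups),
  and `c = 3` overshoots to 4.5M.

The reference convention is therefore frozen at **two channels per group,
plain expansion, grouped squeeze**, and both grouping flags
(`expansionGrouped`, `squeezeGrouped`) remain exposed in
`macnextConfig()` so the alternative reading is one argument away. The
`built` and `closed_form` counting modes are independent computations
(enumeration of allocated arrays versus layer algebra) and must agree
exactly; the test suite enforces this over random configurations.

```{r params}
cfg <- macnextConfig()
countParameters(cfg, "closed_form")$total
traceShapes(cfg)
```

## Numerical choices

* **GELU** uses the exact error-function form `x * pnorm(x)`, not the tanh
  approximation, so oracle comparisons are deterministic to machine
  precision.
* **Batch normalization**: epsilon `1e-5`, running-statistics momentum
  0.1, biased batch variance inside the normalization and the unbiased
  correction in the running estimate. Inference mode uses running
  statistics only, which is why per-sample outputs are identical whether
  a batch is scored jointly or one sample at a time.
* **Initialization**: fan-in-scaled normal weights for convolutions,
  fan-based uniform for the FC layer, all drawn from a single seeded
  stream in a fixed layer order — two builds from one `initSeed` are
  bit-identical.
* **Softmax** subtracts the per-sample maximum logit before
  exponentiation.
* **Metrics**: one-vs-rest TP/FP/TN/FN per class; zero-denominator
  precision/recall/F1 are reported as 0 with a `degenerate` flag instead
  of NaN. Aggregate precision/recall/F1 are macro (unweighted class
  means) by default — the per-class analyses this model family is judged
  by treat classes symmetrically regardless of their sample counts — with
  a weighted option. ROC AUC is one-vs-rest with trapezoidal integration
  over the unique-score thresholds, which equals the Mann–Whitney
  statistic with ties counted one half; classes absent from the truth are
  excluded from the macro mean with a warning.

## Training protocol

Defaults mirror the study protocol: a two-stage split (20% test held out
first, then 20% of the remainder to validation, yielding 64/16/20, both
stages by `floor` with the remainder going to training), momentum SGD
(momentum 0.9) at a constant learning rate of 0.01, mini-batches of 128,
30 epochs, cross-entropy loss. Where the protocol is silent the package
makes these choices: weight decay `1e-4` on convolution and FC weights
only; stratified splitting by default (it protects the 177-sample tail
classes; an unstratified flag exists); no learning-rate schedule; no data
augmentation; both the final and the best-validation checkpoints are
saved, since which of the two produced any given headline number is
generally unknowable. Class-aware mini-batches — each batch holding a
near-uniform class mix by cycling per-class pools — are implemented as the
optional `balancedBatches` sampler and are off by default, matching the
default-settings description of the protocol.

Training is deterministic given the two seeds (`initSeed` for weights,
`TrainConfig@seed` for splitting/shuffling): identical seeds reproduce
identical per-epoch logs bit for bit.

## The synthetic generator

The clinical image collection this architecture targets is not publicly
distributable, so the package ships a generator that reproduces its
*structure*: 24 species classes with the exact per-class counts (2562 at
the head, 177 at the tail, 18,221 in total — `table1Manifest()`,
scalable with round-half-even and a per-class floor so rare classes never
vanish), and plate-like scenes: a blood-agar disc on a dark bench, mild
illumination gradient, colonies with jittered radius, radially perturbed
borders, dome shading, optional hemolysis rings (amber clearing for beta,
green shift for alpha) and texture grain, plus additive sensor noise.
Pixels are quantized to the 8-bit grid before writing so PNG round trips
are byte-exact, and each image's seed derives from
`(dataset seed, class id, index)`, so adding classes never perturbs
existing images.

All morphology parameters are invented. They were chosen once to make the
24 classes pairwise distinct in at least two parameters and visually
plate-like, and are **not** calibrated to any real species' appearance.
Consequently the synthetic benchmarks demonstrate that the pipeline
learns genuinely class-correlated signal end to end — they say nothing
about accuracy on real colony photographs, where intra-class variance,
focus, and inter-species similarity (the *Staphylococcus*/*Streptococcus*
problem) are the actual difficulty.

## Benchmark problem sizes

The learnability benchmark uses four morphologically distant classes
(rows 2, 5, 10 and 20 of `defaultClassSpecs()`: yellow-cream, tan-brown,
bright-white and green-gray colonies), 200 images per class at 64×64, a
reduced network (`F = [16, 32]`, `R = [1, 1]`, 4 classes — about 21k
parameters), and the standard protocol (SGDM, lr 0.01, batch 128) for 50
epochs; this was fixed after the first implementation run, reaches 100%
test accuracy, and completes in a few minutes on one CPU core. A
capacity check trains on a single 32-sample batch for 200 steps and
requires 100% accuracy on that batch. Unit tests use still smaller scenes
(32×32, `F = [8, 16]`) so the full suite stays fast.

## Known limitations

* CPU-only: the hand-written kernels are im2col/GEMM based and fine for
  desk-scale experiments, but training the full 4.4M-parameter network on
  a 224×224, 18k-image dataset is out of their intended scope.
* No claim of biological fidelity in the generator, and no pretrained
  weights: the package reproduces the architecture and protocol, not any
  trained model.
* The group convention is inferred from the parameter budget, not stated
  by the architecture's authors; if per-stage group counts were ever
  published, `channelsPerGroup` would need to become a vector.
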