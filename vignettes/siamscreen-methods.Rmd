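---
title: "Siamese MLP similarity searching: model, pruning and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Siamese MLP similarity searching: model, pruning and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siamscreen)
```

## The problem

Ligand-based virtual screening (LBVS) ranks a compound library by
similarity to known active reference structures, without using the
protein target. The standard instrument is the continuous Tanimoto
coefficient between count fingerprints,

$$T(a, b) = \frac{\sum_i a_i b_i}{\sum_i a_i^2 + \sum_i b_i^2 - \sum_i a_i b_i},$$

which works well when an activity class is structurally homogeneous
(mean pairwise similarity of its actives around 0.3–0.4) and degrades
badly on heterogeneous classes (around 0.1). `siamscreen` implements a
learned alternative: a Siamese multi-layer perceptron that is trained on
labelled molecule pairs to output a similarity score in (0, 1), together
with the full evaluation protocol used to compare similarity methods in
this literature — top-percent recall tables, node pruning sweeps, and
Kendall-W concordance ranking.

## The model

Both fingerprints pass through the *same* feed-forward rectifier encoder
(weight sharing is structural: there is one set of encoder parameters,
used by both branches, so the score is exactly symmetric in its
arguments). The two embeddings $e_A, e_B$ are compared element-wise by
two fixed distance layers:

* Manhattan distance $d_{AB} = |e_A - e_B|$,
* exponential Manhattan distance $E_{AB} = \exp(-|e_A - e_B|)$,

a fusion layer joins them, and a trainable rectifier head ends in a
single logistic-sigmoid unit. Training minimises binary cross-entropy on
pair labels (1 = same activity class, 0 = different) with the RMSprop
optimizer at batch size 256.

Three points in this architecture are genuinely open design choices, and
we document the readings adopted:

* **Where the distance layers attach.** Descriptions of this
  architecture are ambiguous between distances on the raw input cells
  and distances on encoder outputs. We attach them to the encoder
  outputs; `encoder_sizes = integer(0)` makes the encoder the identity
  and recovers the raw-input reading, so both are available under one
  configuration knob.
* **The fusion operator.** We concatenate the two distance vectors and
  let the post-fusion stack learn the combination; concatenation loses
  no information and matches the presence of "multiple layers after the
  fusion".
* **Layer widths and epochs.** The published account states the
  hyperparameters were tuned but does not print them. Widths are
  configuration with defaults encoder (512, 256) and head (256, 128, 64)
  at input width 1024; the learning rate defaults to the conventional
  RMSprop 1e-3.

Every source of randomness (initialisation, epoch shuffling, pair
sampling, query selection) is governed by explicit integer seeds, and
the implementation is single-threaded base-R matrix code, so any run
replays exactly. Parameters use fan-in-scaled (He) normal
initialisation with zero biases. The backward pass is hand-written and
verified against central finite differences to better than 1e-4
relative error. One numerical subtlety: with zero initial biases a
sample whose previous layer is entirely inactive sits exactly on the
ReLU kink, where the loss is not differentiable and the implementation
takes the conventional subgradient 0 — the gradient check is therefore
performed at a generic parameter point (all parameters perturbed by
continuous noise), where kinks have probability zero.

## Node pruning by signal-to-noise ratio

Each hidden node is one column of its layer's incoming weight matrix;
its signal-to-noise ratio is $|\mu_i| / \sigma_i$, the column's absolute
mean over its spread. Pruning a fraction $r$ masks the
$\lfloor r \cdot n_\text{prunable} \rfloor$ nodes with the smallest SNR:
the incoming column is zeroed and the node's output is suppressed, so a
masked node contributes exactly zero to every forward pass. There is no
retraining after pruning.

Choices and conventions:

* $\sigma$ is the **population standard deviation**, not the variance,
  although some presentations label it "variance": signal-to-noise is
  conventionally $|\mu|/\sigma$, and the Bayesian pruning literature this
  criterion descends from uses $\mu/\sigma$. `sigma = "var"` switches to
  the variance reading.
* SNRs are pooled **globally** across all prunable layers (the hidden
  encoder and post-fusion nodes; input cells, the weightless
  distance/fusion layers and the output unit are never prunable),
  because a single dataset-wide ratio is applied; `scope = "per_layer"`
  prunes each layer proportionally instead.
* A constant nonzero column has $\sigma = 0$ and receives an $\infty$
  sentinel (never pruned); an all-zero column scores 0, which makes
  pruning idempotent at a fixed ratio.
* SNR ties break by (layer, column) ascending so pruning replays
  deterministically.

## Screening protocol

Ten reference structures per activity class are drawn at random as
queries. Every `TEST` molecule is scored against each query and the
per-query scores are fused with the **MAX** group-fusion rule (the
similarity-searching convention for multiple references; `mean` is
available — the published protocol does not state its rule, so this is a
documented gap). Queries are excluded both from the ranking and from the
recall denominator, preventing self-retrieval inflation. Top-$p$%
recall takes $\lfloor p/100 \cdot n \rfloor$ molecules from the head of
the ranking — the slice is never expanded at score ties; ties break by
molecule id ascending — and reports the percentage of the class's test
actives retrieved, at full float precision (only printing rounds).

Recall tables (classes × methods) carry a mean row and "shaded cell"
marks: within each class row every method attaining the row maximum is
marked, and a method's shaded count is the number of rows it wins.
Externally published per-class recall columns can be merged for
side-by-side comparison; transcriptions of the published MDDR/MUV/DUD
benchmark tables ship with the package
(`benchmark_recall_table()`).

## Concordance analysis

Activity classes act as raters ranking the methods: within each class
row the worst method gets rank 1 and the best rank $n$, with tied
recalls receiving average ranks. From the rank totals $R_i$, their
grand mean $\bar{R} = m(n+1)/2$ and $\delta = \sum_i (R_i - \bar{R})^2$,

$$W = \frac{12\,\delta}{m^2(n^3 - n) - m \sum_j T_j}, \qquad
T_j = \sum_{\text{tie groups}} (t^3 - t).$$

The tie-corrected denominator is the default: the classical formula has
no tie term, but the published DUD concordance value is only reproduced
with average ranks plus the standard correction (the original analysis
used a statistics suite that applies it); `tie_correction = FALSE`
gives the raw form, which coincides with the corrected one whenever no
ties occur. Significance uses the large-$m$ chi-square approximation
$\chi^2 = m(n-1)W$ with $n-1$ degrees of freedom and the conventional
0.05 threshold; whether the published p-values used this approximation
or an exact distribution is not stated — the approximation reproduces
their magnitudes. If every rater ties every object, $W$ is 0/0 and
`NaN` is returned.

## The synthetic library generator

Licensed benchmark data (MDDR) cannot ship, so the generator emulates
the *statistics the model consumes*: per-class active counts (tens to
thousands), a large decoy background, and a calibrated intra-class mean
pairwise Tanimoto ("diversity") spanning the published range — roughly
0.10 (heterogeneous, MUV-like) to 0.39 (homogeneous). The published
class structures are available as presets via
`benchmark_class_structure()`.

* **Background.** Fingerprint positions are occupied independently with
  probability 0.12, occupied counts are 1 + Poisson(0.3). Two
  independent draws then share a mean pairwise Tanimoto of about 0.05,
  emulating unbiased (MUV-style) decoys. Decoys are independent
  background draws, not perturbed prototypes.
* **Actives.** Each class is a background prototype plus count-mass
  perturbations: each prototype count is moved with probability
  `noise` (removed from its position, re-added uniformly at random).
  Noise 0 gives identical copies (diversity 1); noise 1 fully
  randomises the support (diversity at background level). Total count
  and non-negativity are preserved.
* **Calibration.** The per-class noise is found by bisection against the
  class's own realised diversity until it lands within ±0.02 of the
  target. The class's randomness (prototype, removal orders, add
  positions, one uniform per molecule) is drawn once per seed and a
  noise level is realised as an edit-count prefix
  $d_i = F^{-1}_{\mathrm{Binom}(N,\ \text{noise})}(u_i)$, so the
  measured diversity is a fine-grained, near-monotone deterministic
  function of noise and the bisection is well-posed even for short
  fingerprints. Calibration failure (a target outside the achievable
  bracket) is reported with the best achieved diversity.
* **Training pairs.** Balanced 1:1 positive/negative sampling (same
  class vs different label; decoy–decoy pairs never occur). How
  training pairs were drawn in the original benchmark studies is not
  published; the balanced scheme is a declared stand-in, chosen because
  binary cross-entropy training is best behaved balanced.

What the generator deliberately does **not** emulate: real chemistry —
scaffolds, physicochemical properties, the correlation structure of
actual ECFC hashing. Passing tests on synthetic libraries therefore
demonstrate that the implementation is correct and that the method
separates count-vector class structure of the published shape; they do
not certify recall levels on MDDR/MUV/DUD themselves.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen once as realistic
miniatures: the learning and pruning benchmarks use 3 classes × 60
actives at diversity 0.35 over 3000 decoys at fingerprint width 256,
with 2000 training pairs, encoder (128, 64) and head (64, 32) — the
same configuration as `default_pipeline_config()` (which additionally
spans diversities 0.35/0.20/0.12 to exercise the heterogeneous case).
Generator calibration is exercised across 20 random specifications at
width 512. The published-table arithmetic (means, shaded counts,
Kendall W blocks) is recomputed exactly from the shipped
transcriptions.

## Known limitations

* Absolute recall values on the licensed benchmarks are out of reach by
  construction; comparisons against the published BIN/SQB/SDBN methods
  consume their printed recall columns as data.
* One trained model per library, one-shot pruning of that model; whether
  the original study retrained per pruning ratio is unstated.
* The optional SMILES adapter (`smiles_fingerprints()`) uses this
  package's own neighborhood-hashing fold and does not claim
  bit-for-bit fidelity to any commercial ECFC implementation, whose
  folding parameters are unpublished.
* Training is plain single-threaded RMSprop; no GPU, no early
  architecture search. At the published input width (1024) and default
  widths, models train in minutes on one CPU at the desk scales above.
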