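---
title: "methydeep: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methydeep: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bisulfite sequencing reports, for every cytosine, how many aligned reads
support a methylated versus an unmethylated call. Coverage is uneven: many
sites fall below a usable read depth and their methylation state is unknown.
In plants this matters in all three sequence contexts — CpG, CHG and CHH
(H = A, C or T) — and genome annotation is usually too sparse to drive
feature-based imputation. `methydeep` predicts the binary methylation state
of a cytosine from two complementary signals that are always available:

* the **DNA sequence** around the site, and
* the **observed methylation states of nearby cytosines**, which are highly
  autocorrelated along the chromosome.

## Preprocessing rules

A site's label comes from its read counts: with depth `n_meth + n_unmeth`
below `min_depth` (default **4** reads) the label is NA; otherwise the
methylation rate `n_meth / depth` is rounded to a state. Two rounding rules
coexist deliberately:

* **input labels** round half up: a rate of exactly 0.5 becomes 1;
* **predictions** binarize strictly: probability > 0.5 becomes 1, ≤ 0.5
  becomes 0.

The input-side tie rule is a package decision (observed rates of exactly 0.5
are rare and depth-limited); the prediction-side rule is part of the model
contract and is used everywhere a probability is thresholded, including
`confusion()` and `impute_genome()`.

Context is always recomputed from the reference genome, even when the report
supplies a context column; a mismatch warning counts disagreements. This
guards against genome-version drift between aligner and analysis. Sites
whose context triplet contains N or runs off a chromosome end are
*indeterminate*: they are carried through imputation with an NA state and a
flag rather than being silently predicted.

Train/validation/test splits are whole chromosomes (`split_spec()`), so
evaluation is always on chromosomes the model has never seen.

## Encodings

The sequence input is a one-hot matrix over a window of ±500 bp
(length 1001) centered on the target cytosine, with column order A, T, G, C.
Minus-strand sites are reverse-complemented so the model always sees a
centered C in a consistent orientation; the reference is silent on strand
handling and this is the symmetric choice. N bases and positions beyond
chromosome ends are all-zero rows.

The neighbor input encodes the **25 nearest labeled cytosines on each side**
as a 100-long vector: 50 state slots followed by 50 distance slots, both in
genomic order (upstream farthest→nearest, then downstream nearest→farthest).
Distances are divided by `d_max` — the largest gap between consecutive
cytosines anywhere in the genome, computed over all cytosines regardless of
context or label availability — and clipped to 1. Missing neighbors (edges,
sparse chromosomes) pad with state 0.5 and distance 1.0, the maximally
uninformative values. Whether the original layout interleaved state/distance
per neighbor or blocked them is not documented anywhere we could find; the
blocked layout is this package's fixed, tested convention.

Neighbor eligibility pools all three contexts by default. Per-context
modeling is available simply by filtering the site table before
`build_dataset()`.

## The three models

All networks are trained with binary cross-entropy; every probability comes
out of a sigmoid head.

**DNA model** (`build_dna_model()`): conv(128 filters, kernel 11, stride 1)
→ max-pool 4 → conv(256, kernel 3) → max-pool 2 → flatten → dense → dropout
→ sigmoid. ReLU follows each convolution. The post-dropout dense output is
the model's embedding. The published description is internally inconsistent
about this width (a 128-unit dense layer versus a 256-dimensional output
consumed by the joint model); we default to **256** so that the joint
model's documented 768-long input (256 + 512) holds, and expose `fc_units`
for either choice.

**Methylation model** (`build_meth_model()`): the 100-vector reshaped to
50 timesteps × 2 features → time-distributed dense (width 32, a package
choice; the layer is documented but not its size) → BiGRU(128) with L1 and
L2 penalties of 1e-4 on that layer's weights → BiGRU(256, last state) →
dropout → sigmoid. The embedding is the 512-long concatenated final hidden
state.

**Joint model** (`build_joint_model()`): concat(256, 512) → dense(512) →
dense(512) → sigmoid, trained **end-to-end from scratch** by default. Which
of end-to-end versus warm-start the original used is unstated; warm-starting
from trained single models is available via `init_from`.

The engine behind these (`conv1d` as im2col + BLAS, pooling with stored
argmax, batched GRU with backpropagation through time, Adam, inverted
dropout) is implemented in the package itself and validated against
finite-difference gradients in the test suite. One numerical note: ReLU is
applied after pooling rather than before, which is mathematically identical
(max commutes with any nondecreasing function) and halves the number of
full-resolution temporaries.

## Training

Optimizer settings are package choices (none are documented upstream):
Adam at learning rate 1e-3, batch size 128, early stopping on validation
loss with patience 5 (3 in the benchmark), the learning rate halved after
any non-improving epoch, weights restored from the best epoch. The
output bias is initialized at the base-rate logit so early epochs refine
ranking rather than learn the ~1:9 class prior. Class weighting is off by
default, mirroring the evaluation's reliance on ranking metrics; an
inverse-frequency option exists. All training randomness (shuffling,
dropout) is driven by `train_config(seed=)`, and a fixed seed reproduces a
run bit-for-bit.

## Evaluation

`metrics()` reports ACC, ROC AUC, area under the precision–recall curve,
F1, MCC, TNR and TPR at the strict 0.5 rule. AUC is the Mann–Whitney
statistic with ties counted one half; the precision–recall area is average
precision (step-wise), chosen over trapezoidal interpolation because it is
standard and does not over-credit interpolated precision. Degenerate-case
conventions: single-class labels give NA for AUC/PRC with a warning; F1 is
0 when precision + recall is 0; MCC is 0 when any margin is 0.

## Imputation

`impute_genome()` fills every NA site in one pass. Neighbor features for NA
targets are built **from observed-labeled sites only** — never from
previously imputed states — because iterating predictions back into the
neighborhood would compound errors. Observed labels are never changed by
default; `overwrite = TRUE` exists for the "correct a suspect observed
state" use-case but comes with the explicit caveat that no principled
criterion for "suspect" is defined. Processing streams one chromosome at a
time so memory stays bounded.

## Motif extraction

First-layer kernels (width 11) act as position weight detectors. For a set
of windows we compute post-ReLU, pre-pooling activations at every valid
position; for each filter, the selection threshold is 50% of that filter's
**global** maximum over all windows and positions (a per-window maximum
would trivially select every window), and each window contributes at most
its single best 11-mer. Selected k-mers are position-aligned by construction
(each is centered on its activation maximum), so PWMs are built by direct
position-wise counting with a 0.5 pseudocount — no multiple alignment.
Information content is `sum(2 - entropy_bits)` per position. K-mers clipped
by window edges are discarded rather than padded.

Motif *activity* is the mean activation per (filter, window); the signed
*effect* of a motif on methylation is defined in this package as the Pearson
correlation between activity and window labels (the upstream figure colors
an "estimated effect" but never defines it; correlation is the simplest
auditable choice). The activity table (filters as points, windows as
features) is centered and projected on its top two principal axes via
`prcomp`, with each axis oriented so its largest-magnitude loading is
positive; an independent eigendecomposition oracle cross-checks this in the
tests.

## The synthetic generator

`simulate_genome()` / `simulate_methylome()` generate ground truth with the
statistical structure the models exploit:

* i.i.d. background bases at GC fraction 0.4 (typical plant euchromatin),
  with motif consensus strings stamped at Poisson positions and logged;
* a latent logit per cytosine: `beta0 + sum(beta_m * [motif m within the
  effect radius]) + u`, with `u` an AR(1) field over consecutive cytosines
  (rho 0.95, stationary sd 3 — strong local autocorrelation, the signal the
  GRU model consumes);
* `beta0` calibrated deterministically (`calibrate_beta0()`) so the marginal
  methylated fraction is 0.1, the canonical 1:9 imbalance;
* planted effects +4 (AT-rich consensus `TATTTAAATAT`, hyper-methylating)
  and −4 (CG-rich `GCGGCGCCGCG`, hypo-methylating), echoing the reported
  association of AT-rich motifs with hyper- and CG-rich motifs with
  hypo-methylation;
* Poisson(15) read depth with 20% of sites forced below 4 reads (the NA
  universe), and a 10% per-read call error so observed labels are noisy and
  perfect AUC is impossible.

What the generator does **not** emulate: transposon/gene-body methylation
landscapes, context-specific pathways (e.g. RdDM), strand-symmetric CpG
maintenance (available behind a flag conceptually but not a default), or
real read alignment artifacts. Passing the benchmark therefore demonstrates
that the architecture learns sequence- and neighborhood-driven signal under
realistic imbalance and noise — not that it reproduces any particular
organism's methylome.

## Benchmark scale

The package's standard benchmark (`run_benchmark()`) is sized for a single
CPU: a 2 Mb genome (5 × 400 kb), 14k training / 3k validation / 4k test
sites sampled from whole-chromosome splits, a 201 bp window, 10 neighbors
per side, 48+32 convolutional filters, GRU widths 16/32, dropout 0.25, and
Adam at 1e-3 with batch 128 and plateau decay. Epoch budgets go where there
is signal to learn: the convolutional branch gets its full budget (20
epochs, patience 4) only in the regimes that plant sequence signal and a
short budget where none exists; the recurrent branch converges within a few
epochs under any regime and runs on larger batches. The gentle learning
rate is a robustness choice: the convolutional branch's optimization is
sensitive to aggressive rates (it can collapse to the base-rate solution),
while the recurrent branch trains reliably under almost any setting. The full-size defaults
(1001 bp, 128+256 filters, GRU 128/256) are unchanged and are what
`encoding_spec()` and the model-spec constructors produce; the benchmark
narrows widths only, so every structural property (two conv blocks, two
BiGRU layers, joint concatenation) is exercised at the reduced scale. The
simulator's motif effect radius equals the benchmark window half-width
(100 bp) so the sequence branch can, in principle, see every causal motif.

## Known limitations

* The engine is CPU-bound R; genome-scale training at the full 1001 bp /
  128-filter configuration is possible but slow. The architecture code is
  deliberately framework-free, so porting the weights elsewhere is
  straightforward.
* The "both signals" regime gives the sequence branch a much lower
  information ceiling than the neighbor branch (the AR(1) field dominates),
  so joint-model gains over the methylation branch are modest at benchmark
  scale — consistent with the reported real-data pattern where the joint
  model's advantage is largest when neighborhoods are unreliable.
* Because plant cytosines sit only a few bases apart while motif effects
  act at window scale, the observed states of the ~20 nearest neighbors are
  a near-sufficient statistic for the local motif field even when *only*
  motif signal is planted: the neighbor model then matches or exceeds the
  sequence model despite having no direct access to sequence. In this
  generator the two branches' information ceilings coincide in the
  motif-only regime (a pairwise-AUC oracle on the true motif field tops out
  near 0.82), so which branch wins there is decided by optimization noise,
  not information. Degrading neighborhood quality (sparse or low-depth
  neighborhoods) is what genuinely separates them — which is exactly the
  situation imputation targets.
* Effect sizes, window probabilities and the noise model are simple by
  design; parameter recovery on the generator itself is part of the test
  suite, which is what makes the benchmark claims auditable.
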