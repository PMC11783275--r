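---
title: "Predicting stability change from embedding differences: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting stability change from embedding differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabemb)
```

## The problem

A single amino-acid substitution can stabilise or destabilise a folded
protein; the thermodynamic quantity of interest is the change in folding
free energy, ddG (kcal/mol). Throughout this package the sign convention
is that **negative ddG means destabilizing**. ddG obeys thermodynamic
reversibility: if mutating residue A at position *i* to B changes the
free energy by ddG, then mutating B back to A in the mutant background
changes it by exactly -ddG. A good predictor should respect this
antisymmetry, and the evaluation suite below measures how well it does.

`stabemb` implements a sequence-only regression approach: no structure
is required. A variation (one or several simultaneous substitutions) is
encoded as the element-wise difference of two per-residue embedding
matrices,

$$D = E_{wt} - E_{vt},$$

where $E_{wt}, E_{vt} \in \mathbb{R}^{L\times d}$ are the embeddings of
the wild-type and variant sequences (equal length $L$; indels are out of
scope). Because the encoding is a difference, swapping wild type and
variant flips the sign of every entry of $D$ — the input representation
is *exactly* antisymmetric, which is the structural prior that makes the
model's near-antisymmetric behaviour achievable.

In production use $E$ comes from a pretrained protein language model
(a 33-layer, 650M-parameter transformer with $d = 1280$ is the intended
default). The package deliberately does not bundle such a model: the
`embedder_custom()` adapter accepts any function returning an
$L \times d$ matrix with one row per residue (special begin/end tokens
stripped, so row $j$ aligns with residue $j$). Which internal layer of a
language model to extract, and how to handle sequences longer than its
context window, are choices the adapter owner makes; final-layer
representations are the conventional default.

## The regression head

The prediction network maps $D$ to a scalar:

1. **1D convolution** — $m$ filters of width $w = 15$ slide along the
   residue axis with zero same-padding and ReLU activation, projecting
   the $d$ input channels to an $L \times m$ matrix $C$. Same-padding is
   forced by the downstream residual connection and pooling, which need
   all $L$ rows.
2. **One transformer encoder layer** — per head $i$ of $h$ heads,
   $Q_i = C A^Q_i$, $K_i = C A^K_i$, $V_i = C A^V_i$ with
   $A^{Q,K,V}_i \in \mathbb{R}^{m \times r}$, $r = m/h$, then
   $Z_i = \mathrm{softmax}(Q_i K_i^\top / \sqrt{r})\, V_i$; the heads
   are concatenated, projected by $A^O \in \mathbb{R}^{m\times m}$ and
   added to $C$ (residual). A position-wise feed-forward network with
   $s$ hidden units and a second residual follows:
   $f_j = \mathrm{ReLU}(z_j W_1 + b_1) W_2 + b_2 + z_j$.
   There is **no positional encoding, no layer normalisation and no
   dropout**: the architecture is implemented exactly as the equations
   above state. A consequence worth knowing (and tested): the post-conv
   pipeline is permutation-invariant in the rows of $C$ — order
   information enters only through the convolution window.
3. **Dual global pooling** — column means and column maxima of $F$ over
   the residue axis, concatenated into $P \in \mathbb{R}^{2m}$.
4. **Linear output** — $\hat y = P \cdot w_O + b_O$, the predicted ddG.

The hyperparameter grid is exposed as presets `model0` … `model5`
(`ddg_config()`), from `model0` ($m=32, h=2, s=128$) to `model5`
($m=256, h=8, s=1024$); `model4` ($m=128, h=8, s=512$, hence $r = 16$)
is the selected full-scale configuration.

Two numerical points. The attention-weight softmax is computed with
per-row max subtraction, so arbitrarily large finite logits cannot
overflow. And the attention scaling is $1/\sqrt{r}$, the original
transformer convention; a plain $1/r$ scaling is available behind
`attn_scale = "r"` for sensitivity checks, because renderings of the
attention formula sometimes leave the exponent ambiguous.

Batched inference pads variable-length inputs with zero rows and masks
padding out of both the attention softmax (additive $-\infty$ before
normalisation) and the pooling (excluded from mean and max). Padding
therefore cannot change any single-sequence result; the test suite
asserts batched equals unbatched.

## Training protocol

Training minimises the mean squared error with Adam on minibatches of
128, for up to 500 epochs. Forward and backward passes are written in
plain R matrix algebra; the analytic gradients of every stage are
verified against central finite differences in the test suite. Three
protocol elements deserve comment:

* **Reversibility augmentation** (`augment_reverse()`): every direct
  record spawns its reverse — the mutated sequence as wild type, the
  inverted substitutions, the negated target. This exactly doubles the
  data and is the main mechanism pushing the model toward antisymmetric
  behaviour. Reverse records inherit their protein id, so grouped splits
  can never separate a variation from its reverse.
* **Early stopping**: a protein-grouped subset of the training proteins
  (default 10%, seeded) is held out as validation; training stops after
  `patience` epochs without a new validation-MSE minimum and the
  parameters of the best epoch are returned. We read the stopping rule
  as the standard minimum-validation-error checkpointing; the patience
  default (20) and the validation construction are this package's
  choices, exposed in `stabemb_control()`.
* **Learning rate**: no canonical value exists for this architecture;
  the default is 1e-4, deliberately conservative. The worked analyses in
  this package use 1e-3, which on the synthetic tasks below converges in
  a few dozen epochs without divergence.

## Homology-aware cross-validation

Randomly splitting variants would leak information: two variants of the
same protein — or of two homologous proteins — are not independent.
`homology_folds()` therefore (i) keeps all variations of a protein in
one fold and (ii) forbids any cross-fold protein pair with more than 25%
sequence identity. Identity is computed from a global Needleman-Wunsch
alignment (match +2, mismatch -1, gap opening 10, gap extension 0.5) as
identical pairs / alignment length, gap columns included; these scoring
constants are documented package choices. Proteins are grouped into
single-linkage clusters at the threshold — the transitive closure, so a
chain A~B, B~C confines A, B and C together even when A and C are
dissimilar — and clusters are assigned greedily, heaviest variation load
first, to the lightest fold. The balancing objective (variation counts)
is a package choice; the grouping constraints are the method's. A
post-hoc exhaustive check re-verifies the no-leak constraint and fails
loudly rather than returning a leaky split. Ties between equally loaded
clusters are broken by a seeded shuffle, making assignments
reproducible.

## Evaluation suite

`evaluate_predictions()` reports PCC, RMSE and MAE over Total / Direct /
Reverse partitions, plus two antisymmetry statistics over direct/reverse
pairs aligned by variation:

* $r_{d\text{-}r}$ — the Pearson correlation between direct and reverse
  predictions; $-1$ for a perfectly antisymmetric predictor.
* the antisymmetry bias $\delta = \sum_i (p^{dir}_i + p^{inv}_i) / 2N$ —
  zero iff the predictor is antisymmetric on the evaluated pairs. The
  normalisation ($2N$, i.e. half the mean pairwise sum) follows the
  established antisymmetry-bias convention; it is stated here because
  typography for this statistic varies across the literature.

Experimental reverse targets, when absent, are defined as the negated
direct targets — the same reversibility assumption the augmentation
uses. Undefined correlations (zero variance, or a partition with no
records) are reported as `NA`, never silently as zero, because a coerced
zero corrupts cross-tool comparisons.

## The synthetic task generator

Benchmark-grade datasets for this problem require curated thermodynamic
databases and a large pretrained embedder; neither belongs in a test
suite. `make_task()` instead generates a fully synthetic task with the
statistical structure the pipeline needs:

* random sequences (default 20 proteins of 50–80 residues — short
  enough for fast iteration, long enough that conv windows and pooling
  behave as on real proteins; 500 variants, 10% of them carrying 2–5
  simultaneous substitutions);
* a deterministic **mock embedder** (`embedder_mock()`, default
  $d = 16$, window $k = 5$) whose row $j$ is a seeded hash of the k-mer
  centred at $j$ — contextual like a real language model, so one
  substitution perturbs a window of rows, not just one. The default
  dimension and window are calibrated to the generator's stated
  learnability property: the task must be solvable to high held-out
  correlation by the smallest model preset within a desk-scale compute
  budget, so that the recovery test measures pipeline correctness
  rather than sample-starved estimation of an overly wide functional;
* ground truth $y = u \cdot \mathrm{colMeans}(D)$ for a fixed random
  functional $u$, rescaled so the noiseless targets have SD 1.5
  kcal/mol (a typical experimental ddG spread), plus Gaussian noise of
  SD 10% of the target SD by default. Linearity in $D$ makes the truth
  *exactly* antisymmetric, so antisymmetry checks are sharp; it also
  guarantees the target is representable by the network, turning the
  held-out-recovery test into a genuine optimisation/generalisation
  check rather than an aspiration.

What the mock does **not** emulate: real embedding geometry (residue
similarity structure, long-range context, anisotropy), realistic
thermodynamics (epistasis between sites, destabilising-biased ddG
distributions), or alignment-detectable homology between related
proteins. Passing the synthetic recovery test therefore demonstrates
that the architecture, gradients, augmentation and splitting machinery
work — it says nothing about accuracy on experimental data, which
depends on the real embedder and training set.

`make_dissimilar_families()` complements this with sequence families of
controlled identity (members are point-mutated copies of a family
ancestor) for exercising the homology split: within-family identity is
high (~70%), between-family identity sits at the random background,
safely below the 25% threshold.

## Worked example

A small end-to-end run (scaled down from the package's default analysis
sizes so the vignette builds quickly):

```{r example, eval = FALSE}
task <- make_task(n_proteins = 8, n_variants = 80,
                  length_range = c(40L, 60L),
                  embedder = embedder_mock(d = 16, k = 5), seed = 7)
test_prots <- names(task$sequences)[7:8]
train <- task$variants[!task$variants$protein_id %in% test_prots, ]
test  <- task$variants[task$variants$protein_id %in% test_prots, ]

fit <- stabemb(train, task$sequences, embedder = task$embedder,
               config = ddg_config("model0"),
               control = stabemb_control(epochs = 100, lr = 1e-3,
                                         patience = 20, seed = 1))
summary(fit)
plot(fit)

preds <- predict(fit, test, task$sequences, reverse = TRUE)
preds$ddg_exp <- c(test$ddg, -test$ddg)
evaluate_predictions(preds)
```

## Problem sizes used in the shipped analyses

The package's own acceptance analysis (`scripts/acceptance.R`) trains
`model0` on the default synthetic task (20 proteins, 500 variants,
reversibility-doubled) with a protein-grouped 80/20 train/test split,
learning rate 1e-3, at most 300 epochs and patience 40. These sizes
were chosen as the smallest task on which held-out generalisation
across proteins — as opposed to memorisation — is clearly measurable;
the recovery test repeats the run over three training seeds and judges
their mean, since individual runs of a stochastically trained network
fluctuate by a few hundredths of a correlation point. The unit-test
suite uses smaller instances (6–8 proteins, d = 8) where only
mechanics, not learning quality, are under test.

## Known limitations

* Substitutions only: indels change $L$ and break the difference
  encoding by construction; they are rejected early.
* Training is CPU-bound plain R; it is comfortable at the package's
  analysis sizes (seconds per epoch) but not intended for
  training-set sizes in the tens of thousands with $d = 1280$.
* The identity computation aligns full-length sequences; fragment-vs-
  full-length pairs can score lower identity than a domain-level
  comparison would.
* `X` (unknown residue) is accepted in sequences but rejected as a
  substitution endpoint: an embedding row for `X` exists, but a
  thermodynamic target for mutating to/from an unknown residue does
  not.
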