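---
title: "Multi-omics drug-response prediction with latent alignment and co-attention: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics drug-response prediction with latent alignment and co-attention: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modra)
```

## The problem

Cancer cell lines respond very differently to the same compound, and part of
that variability is written in their molecular state. Given four omics views
of each cell line — somatic mutation status (binary), copy-number variation
(integer), CpG methylation (fractions in [0, 1]) and gene expression
(nonnegative) — the task is to predict the response to a panel of D drugs,
measured as log(IC50): the log concentration needed to inhibit half the
cells. Lower values mean a more sensitive line.

Two obstacles motivate the architecture. First, when each view is embedded
by its own feature extractor the four latent spaces need not agree about
which samples resemble one another ("feature misalignment"). Second, the
views are not independent — mutation, copy number, methylation and
expression constrain each other — and a fusion step should let each view
borrow information from the others.

## The model

Each view $i$ with $g^{(i)}$ genes is embedded by a two-layer ReLU
extractor,
$$z^{(i)} = \mathrm{ReLU}\!\big(W_2^{(i)}\,\mathrm{ReLU}(W_1^{(i)} x^{(i)} + b_1^{(i)}) + b_2^{(i)}\big),$$
with dropout (rate 0.2 by default) after each ReLU during training only.

**Latent alignment.** For a batch of $bs$ samples the cross-view sample
similarity is the inner-product matrix $S_{i,j} = z^{(i)\top} z^{(j)}$.
A soft target is built from the four intra-view similarities,
$$T = \mathrm{softmax}\Big(\tfrac{1}{4\tau}\big(S_{1,1}+S_{2,2}+S_{3,3}+S_{4,4}\big)\Big)$$
(row-wise, temperature $\tau$), and the alignment loss sums the symmetrised
soft-label cross-entropies over the six unordered view pairs:
$$L_{la} = \sum_{i<j} \tfrac12\big(\mathrm{CE}(S_{i,j},T) + \mathrm{CE}(S_{j,i},T)\big),
\qquad \mathrm{CE}(S,T) = -\tfrac1{bs}\sum_a \sum_b T_{ab}\,\log \mathrm{softmax}(S_{a\cdot}/\tau)_b.$$
By Gibbs' inequality $L_{la} \ge 6\,\bar H(T)$, with equality exactly when
all four embeddings coincide; the test suite asserts this bound.

**Co-attention fusion.** Bilinear affinities
$F_{i,j} = \tanh(z^{(j)\top} M_{i,j}\, z^{(i)})$ let view $i$ aggregate the
other views, $H^{(i)} = \tanh(W_z^{(i)} z^{(i)} + \sum_{j\ne i} W_z^{(j)} z^{(j)} F_{i,j})$,
which is scored to a scalar per sample, $a^{(i)} = \mathrm{softmax}(W_H^{(i)} H^{(i)})$,
and the reweighted embeddings $z'^{(i)} = a^{(i)} \odot z^{(i)}$ are
concatenated into $Z'$. A two-hidden-layer ReLU head maps $Z'$ to the D
drug responses with a linear output (log IC50 can be negative).

**Loss.** Masked mean squared error over observed responses plus the
alignment loss, weighted $\gamma_r : \gamma_l = 1:1$ by default. The
regression objective is MSE; mean absolute error is available behind
`model_config(loss = "mae")`.

## Design choices the equations leave open

These were genuinely open points; the package resolves each one explicitly
and records the choice in the fitted object.

**Softmax axis of the attention weights.** Taken literally, the score
$W_H^{(i)} H^{(i)}$ is a $1 \times bs$ row and its softmax runs over the
*batch*, which makes inference depend on batch composition (with a batch of
600, each weight is forced near 1/600). `model_config(literal_batch_softmax
= TRUE)` (the default) implements the literal reading and is pinned by
oracle tests; the per-sample mode (`FALSE`) — softmax across the four views
for each sample, so the four weights of a sample sum to one — is what every
training experiment in this package uses, and is recommended for any real
use. Both modes are tested for permutation equivariance.

**Stop-gradient on the alignment target.** Whether gradients should flow
through $T$ is unstated. Letting them flow makes the composite objective
collapsible: the optimiser discovers that all rows of $T$ can be driven
toward a single large-norm "attractor" column, after which every cross-view
softmax can match $T$ without any per-sample correspondence — the loss
approaches its lower bound while cross-view retrieval stays at chance. We
observed exactly this on synthetic data. The package therefore treats $T$
as a constant per batch (`detach_target = TRUE`), the standard treatment
for soft-target contrastive losses; `detach_target = FALSE` computes the
exact composite gradient and is used by the finite-difference gradient
checks.

**Input normalisation.** The soft target peaks at the column with the
largest embedding norm, so heterogeneous per-sample input norms cap how
diagonal (and hence how informative) $T$ can be. Training therefore
standardises every gene (training-fold mean/sd) and scales each sample's
view vector to unit L2 norm (`train_config(normalize_inputs = TRUE)`).
Statistics come from the training fold only and are stored in the fit, so
held-out predictions never leak. Masking a view (for the importance
analysis) zeroes the *raw* inputs before this normalisation, which keeps
`predict(fit, data, masked_view = v)` identical to physically zeroing the
view's input file.

**Temperature.** $\tau = 1$ by default; it is a free, configurable
hyperparameter of both softmaxes.

**Unstated dimensions.** The published architecture fixes $d_1 = 1024$,
$k = 40$, $D = 31$; the extractor output $d_2$ and predictor hiddens
$d_3, d_4$ are unstated and default to 256/512/128. Desk-scale experiments
in the tests and acceptance script use a proportionally smaller model
($d_1 = 64$, $d_2 = 32$, $k = 16$, $d_3 = 64$, $d_4 = 32$).

**Optimisation.** The optimiser family, batch size and initialisation are
unstated upstream; the package defaults to Adam (SGD available), batch size
32, He/Xavier initialisation, and records every choice in the run manifest.
The configured default learning rates (1e-5 extractor / 1e-6 predictor)
follow the published protocol; the synthetic-data experiments below use
1e-3, the standard Adam rate, because at a few thousand update steps the
published rates barely move the parameters. Dropout 0.2 is applied to the
extractors only.

**Eq-10 exponent.** The printed regression objective lacks the square; the
package implements MSE, consistent with the evaluation protocol that is
explicitly MSE-based.

**Tie handling in binarization.** A response is labelled "sensitive" (1)
iff strictly below the per-drug training median; ties go to "resistant".
Aggregate F1/AUROC are unweighted macro-averages over drugs (`pooled =
TRUE` pools all drug–sample pairs instead). AUROC uses midranks; drugs with
single-class held-out truth report `NA` and are excluded from the
aggregate.

**Gene attribution.** How per-gene "contribution" was computed in the
original analysis is not documented; the package offers saliency-times-input
(`grad_x_input`, default) and single-gene occlusion, records the method in
the output, and demonstrates on an effectively linear model that the two
agree (Spearman rho > 0.95) and match the closed-form chain rule. Top-gene
selection takes the top `ceiling(q N)` of all genes across views
(`q = 0.03` by default).

## The synthetic-data generator

`generate_dataset()` draws latent factors $U \in \mathbb{R}^{n\times r}$
(standard normal) shared by all informative views; view $i$ observes
$U B_i + E_i$ (loadings $B_i$ standard normal, noise sd 0.5) mapped into the
view's range: indicator(> 0) for mutation, `round()` for CNV, logistic for
methylation, softplus for expression. Responses are $Y = U W_y +
\varepsilon$ with noise sd 0.5 by default, so each drug has a closed-form
best attainable $R^2 = \lVert w_d\rVert^2 / (\lVert w_d\rVert^2 +
\sigma^2)$. Defaults: 600 samples, 200 genes per view, rank 5, 31 drugs, no
missingness (missing entries can be planted at a configurable rate to
exercise the preprocessing pipeline). The latent factors and loadings are
attached to the returned dataset for oracle checks.

What the generator deliberately does **not** emulate: real marginal
distributions of DepMap views, linkage/chromosomal structure, drug–drug
correlation beyond the shared latent space, and batch effects. Passing
tests on this generator demonstrates that the machinery (alignment, fusion,
optimisation, attribution) works when a shared low-rank structure exists;
it says nothing about predictive performance on real cell-line panels.

## Problem sizes used by the tests and acceptance script

The package's own experiments are sized for a single CPU: retrieval
(n = 300, rank 5, 100 epochs, batch 8 — chance level 1/8), predictive
recovery (n = 600, rank 5, 200 epochs, batch 32, threefold split), and
masking importance (n = 300, only view 1 informative, 80 epochs, three
generator seeds). With the small model above, each run takes well under a
minute. Batch size matters scientifically here: both the alignment loss and
literal batch-softmax attention depend on batch composition, so it is
recorded in every run manifest.

## Numerical details

* Softmaxes and log-softmaxes subtract the row maximum; similarity values
  are not clipped.
* The backward pass is hand-derived reverse-mode differentiation, verified
  against central finite differences (tolerance 1e-4 relative) in all four
  configurations (both softmax axes, alignment on/off, attention on/off,
  MSE and MAE).
* Mean imputation errors on any feature with zero observed values; the
  all-zero gene filter treats fully-missing features as all-zero and drops
  them.
* The missingness filter keeps samples at exactly the threshold (strictly
  greater drops); it is idempotent.
* After mean imputation a mutation view may contain fractional values;
  these are deliberately not re-binarized.
* Sample alignment orders the shared samples lexicographically.
* Checkpoints store every tensor with 17 significant digits, which
  round-trips IEEE doubles bit-exactly.
* Hypergeometric enrichment uses the exact upper tail
  (`phyper(k - 1, ..., lower.tail = FALSE)`), reports $-\log_{10} p$ to
  match the conventional enrichment axis, and adds Benjamini–Hochberg FDR
  across the tested sets as standard practice.

## Known limitations

* The literal batch-softmax attention mode is faithful but unsuitable for
  inference on batches that differ from training composition; use the
  per-view mode.
* With the exact composite gradient (`detach_target = FALSE`) the alignment
  objective can and does collapse; the flag exists for gradient
  verification, not training.
* The model is drug-blind beyond its D output heads: it cannot generalise
  to unseen drugs, only to unseen samples.
* Gene attribution explains the network's input representation; when
  inputs are normalised the scores are on standardised scales, which is
  the comparable-across-views scale but not raw concentration units.
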