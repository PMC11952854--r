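---
title: "Predicting drug response from clinical gene-panel mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug response from clinical gene-panel mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelDRP)
```

## The problem

Clinical-grade NGS (cNGS) panels sequence a few hundred recurrently
altered cancer genes — FoundationOne CDx covers 324 — and report somatic
mutations together with variant-level annotations. Predicting a patient's
response to chemotherapy from such a report faces two obstacles: the
mutation profile is extremely sparse (most patients carry a handful of
mutations across the panel), and labeled patient response data are scarce,
while cell lines contribute abundant dose-response labels but differ from
patients both in mutation distribution and in how response is measured
(real-valued area under the dose-response curve, AUDRC, versus categorical
RECIST). panelDRP addresses both with a three-stage pipeline: annotation-
based feature engineering, unsupervised domain-invariant representation
learning, and supervised multi-task response prediction.

## Stage I: variant-annotation features

Mutation calls are first filtered to nine coding / function-altering MAF
classifications (missense, in-frame and frameshift indels, splice site,
nonsense, nonstop, translation start site). Each retained mutation carries
three annotations:

* a ClinVar clinical significance collapsed to PATHOGENIC / BENIGN / VUS
  (the raw-string grouping is configurable via `default_clinvar_mapping()`;
  anything unrecognized is conservatively a VUS, making the map total);
* a protein-location category — protein information unit (PIU), linker
  unit (LU) or non-coding unit (NCU);
* 17 binary deleteriousness predictions whose mean is the d-score
  (`x / 17` for `x` algorithms flagging the mutation; missing flags count
  as not-deleterious with the denominator held at 17).

Per gene, the d-scores of member mutations are summarized within each of
the six categories by mean, max, sum and count, giving 24 features per
gene; a 324-gene panel yields a 7,776-column profile. A mutation
contributes to exactly one location category and one significance
category, so both taxonomies partition the gene's mutations. Empty
categories — including mutation-free genes — contribute zeros, which makes
the zero pattern of the matrix meaningful and motivates the zero-inflated
likelihoods of Stage II. The column order (gene-major; PIU, LU, NCU,
PATHOGENIC, BENIGN, VUS; mean, max, sum, count) is fixed by this package
so files and models interoperate.

```{r stage1}
calls <- data.frame(sample_id = "P1", gene_symbol = "TP53",
                    variant_classification = "Missense_Mutation",
                    mutation_key = "m1")
ann <- data.frame(mutation_key = "m1", sample_id = "P1", gene = "TP53",
                  clinvar_raw = "Pathogenic", gpd_category = "PIU")
ann[paste0("alg_", 1:17)] <- as.list(as.integer(seq_len(17) <= 12))
mat <- build_profile_matrix(calls, ann, c("TP53", "KRAS"))
mat[, mat[1, ] != 0, drop = FALSE]
```

## Stage II: zero-inflated VAEs with CORAL alignment

Cell lines and patients are modeled by two separate variational
autoencoders over the same feature space. The encoder infers the mean and
standard deviation of a latent normal posterior; the decoder produces an
intermediate reconstruction from which three linear heads emit the
parameters of a zero-inflated likelihood:

* `Pi = sigmoid(Xbar W_Pi)` — per-entry probability of an excess zero,
* `Omega = exp(Xbar W_Omega)` — negative-binomial mean (count data) or
  normal mean (real data),
* `Theta = exp(Xbar W_Theta)` — NB inverse dispersion, or normal variance.

The negative binomial is parameterized by mean and inverse dispersion,
`NB(x; mu, theta) = G(x+theta)/(G(theta) x!) (theta/(theta+mu))^theta
(mu/(theta+mu))^x`. For real-valued data the exact-zero mass is mixed with
the normal density piecewise at `x == 0`; exact comparison is safe because
the feature builder emits exact zeros. The printed exponential activation
is kept for the normal mean (our features are nonnegative); an
unconstrained mean is available via `mean_activation = "identity"`.

The training objective per domain is the reconstruction NLL plus
`lambda ||Pi||_F^2` (discouraging the degenerate everything-is-a-zero
solution) plus the KL divergence to the standard-normal prior; a CORAL
term — the squared Frobenius distance between the two domains' batch
covariance matrices of the posterior means — aligns the latent spaces.
Representations for all downstream use are the posterior means, so
encoding is deterministic.

Numerical choices: mixture logs go through log-sum-exp; `Pi` is clamped to
`[1e-6, 1 - 1e-6]` during training (the NLL functions clamp only from
above so `Pi = 0` degenerates exactly to the plain likelihood); the
log-variance is the direct parameterization, clamped to `|log s^2| <= 15`;
head exponents are clamped at 30. Gradients are hand-derived and verified
against finite differences in the test suite. CORAL is computed on the
posterior means (not sampled latents), and the `Pi` penalty uses the same
`lambda` in both domains.

Three training-scale choices matter in practice and are worth stating:

* **Loss scaling.** The loss terms are entry sums; the trainer divides
  each batch total by the batch size — a uniform rescaling with the same
  minimizer that keeps sensible Adam step sizes across feature counts.
  The exported loss functions keep the sum convention.
* **KLD weight.** `kld_weight` scales the KL term (beta-VAE style). With
  thousands of output dimensions per sample the reconstruction term can
  otherwise be minimized while the posterior collapses to the prior,
  leaving uninformative latents.
* **Column subsampling.** With `k` features the three `k x k` heads
  dominate the cost (`O(k^2)` per sample). `feature_subsample = m` draws
  `m` columns per step, evaluates the likelihood on them and rescales by
  `k/m`, giving an unbiased gradient at a fraction of the cost; only the
  sampled head columns receive updates that step. Full evaluation remains
  the default and is used by all exactness tests.

## Stage III: multi-task response prediction

A feedforward embedder maps the drug's binary circular fingerprint
(Morgan/ECFP; radius 2, 1,024 bits by default, via the Open Babel backend
for SMILES input) to a dense vector. The AUDRC regressor consumes the
cell-line latent concatenated with the drug embedding; the RECIST
classifier consumes the patient latent concatenated with the same drug
embedding. RECIST categories are binarized upstream: CR/PR are
responders, SD/PD non-responders.

Training minimizes the Chebyshev scalarization
`max(lambda_P * L_BCE, lambda_C * L_MSE)`: each step draws one batch per
domain, evaluates both task losses, and steps along the exact subgradient
of the larger weighted term (ties resolve to the classification term).
Unlike a weighted sum, the maximum can reach non-convex parts of the
Pareto front. Defaults `lambda_P = lambda_C = 1`.

The Stage II encoders are attached to the model. Whether to fine-tune
them is the one place where we deviate from the attach-and-fine-tune
default one might expect: with a few hundred labeled patient pairs and
thousands of input features, fine-tuning drives training AUROC to 1.0
while held-out AUROC drops — classic small-sample overfitting — so the
pipeline driver freezes the encoders by default
(`fine_tune_encoders = FALSE`) and trains only the compact heads, with
decoupled weight decay (`weight_decay = 1`) as additional shrinkage.
`train_mtl()` itself defaults to fine-tuning (with a separate
`encoder_learning_rate` knob) for the data-rich regime. With frozen
encoders the latent representations are precomputed once, which makes
Stage III training essentially free.

Inference for a (patient, drug) pair touches only the patient encoder,
the drug embedder and the RECIST head, and returns
`sigmoid(f_P([z_P, z_D]))`, a response probability in (0, 1). The test
suite asserts this by poisoning the cell-line branch with NaN and checking
patient predictions are unchanged.

Per-drug specialization follows a pretrain-then-fine-tune recipe:
`pretrain_then_finetune()` clones a trained model and continues training
on the pairs of a single drug.

## The synthetic cohort and what it shows

`generate_cohort()` emulates the pipeline's inputs at desk scale. Defaults
describe the package's reference setting: 600 cell lines, 200 patients, a
100-gene panel, 4 drugs. Per sample, the number of mutated genes is
truncated Poisson (mean 6 for cell lines, 4 for patients — sparse profiles
in line with a few-mutations-per-panel clinical report); mutated genes
receive `1 + Poisson(0.3)` mutations each so multi-mutation aggregation is
exercised. Domain shift enters through the annotation category
probabilities (patients skew toward NCU and VUS calls) and a lower
per-algorithm deleteriousness rate; a chi-squared two-sample test
separates the domains at n = 500 in the test suite.

`plant_response_signal()` defines a sample score `s = phi(x) . w` with `w`
sparse over the annotation-bearing columns (pathogenic/protein-unit means
and sums, VUS counts) of 15 signal genes — deliberately linear in the
Stage I feature map, so that recovery is a fair test of the model class,
and deliberately annotation-dependent, so that binary presence/absence
retains only part of it. Per (sample, drug) the latent response adds a
per-drug fingerprint effect; cell lines get standardized scores plus
Gaussian noise (sd 0.1) as AUDRC, patients are thresholded at the median
and flipped with probability 0.1 before mapping to CR/PR vs SD/PD
(responders split uniformly CR/PR; only the binarized label matters
downstream).

What passing on this simulator does and does not show: it demonstrates
end-to-end signal recovery under sparsity, domain shift and label noise
inside the model class; it does not demonstrate performance on real
cohorts, where the mutation-response relation is not linear in the
features, mutational signatures and gene-gene co-occurrence structure
exist, and panels, drugs and response assessments carry their own biases.

## Evaluation protocol

Labeled (patient, drug) pairs are split 80-20 by simple random sampling
with three seeds; cell-line pairs always train. Because Stage II is
unsupervised — it never sees a response label — one representation fit
serves all three splits; Stage III is retrained per split as a
three-model seed-ensemble whose predicted probabilities are averaged.
Pairs appearing in several test splits get their predictions averaged
before overall metrics are computed. AUROC uses midranks for ties; AUPRC
uses step-wise summation without interpolation; the AUPRC baseline is the
positive fraction. `alteration_frequency_table()` contrasts per-gene
mutation frequencies between the top and bottom 20th percentile of
predicted response (boundary patients inclusive), mirroring the oncoplot
reading of which alterations mark predicted non-responders.

## Problem sizes and defaults used by the shipped checks

The acceptance computations use the reference cohort above with: Stage II
`d_z = 128`, hidden 128/128, 16 epochs, batch 256, learning rate 2e-3,
`coral_weight = 10`, `feature_subsample = 400` on the 2,400-column
annotated features; Stage III 150 epochs, batch 256, weight decay 1,
frozen encoders, ensemble of 3 per split. The binary-feature ablations
(`no_va`: mutation presence instead of annotations; `no_va_no_zi`:
additionally `zero_inflated = FALSE`, a configuration change, not a code
fork) use `d_z = 32` — roughly a third of their 100 input columns — so
that their representation step is genuinely compressive, and model their
0/1 inputs with the ZINB likelihood, the same convention used for one-hot
copy-number input in the multimodal extension. The domain-invariance
check uses dedicated 4-epoch Stage II runs across three seeds and
compares the full-cohort covariance gap of the representations after
training against the same model at initialization.

Known limitations: drugs are treated independently (no regimens), there
is no survival head, the encoders' architecture is a repository default
rather than a tuned quantity, and Chebyshev training updates only the
active task per step, so with very unbalanced losses one head can train
slowly.
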