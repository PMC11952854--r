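# panelDRP

Drug response prediction from the restricted gene panels used in clinical
sequencing reports.

## The problem

Clinical-grade NGS (cNGS) panels such as FoundationOne CDx sequence only a
few hundred recurrently altered cancer genes, and most patients treated
with chemotherapy have no matched response label. Predicting RECIST
response from such a report therefore has to work with (1) extremely
sparse mutation profiles, (2) abundant but biologically different
cell-line dose-response data, and (3) variant-level annotation detail that
presence/absence encodings throw away. panelDRP is aimed at method
developers and computational oncologists who want a complete, testable
implementation of a transfer-learning drug-response model for panel data,
together with a synthetic cohort generator that makes every stage
verifiable without access to clinical datasets.

## The model

Three stages, each exposed as ordinary R functions:

1. **Variant-annotation features.** Coding mutations (9 MAF
   classifications) are annotated with a ClinVar significance category
   (PATHOGENIC / BENIGN / VUS), a protein-location category (PIU / LU /
   NCU) and a d-score — the fraction `x/17` of 17 deleteriousness
   algorithms flagging the mutation. Per gene, member d-scores are
   aggregated by mean, max, sum and count within each of the 6 categories:
   24 features per gene, `G x 24` columns per sample (7,776 for a 324-gene
   panel). `build_profile_matrix()`.

2. **Domain-invariant representations.** One zero-inflated variational
   autoencoder per domain (cell lines, patients), with likelihood
   parameters `Pi = sigmoid(Xbar W_Pi)`, `Omega = exp(Xbar W_Omega)`,
   `Theta = exp(Xbar W_Theta)` (zero-inflated negative binomial for
   counts, zero-inflated normal for real values), trained jointly with
   the CORAL loss `|| C(z_C) - C(z_P) ||_F^2` between the batch
   covariances of the latent means. `train_domain_vaes()`,
   `vae_encode()`.

3. **Multi-task response prediction.** A drug embedder over binary
   circular (Morgan) fingerprints feeds an AUDRC regressor on
   `[z_C, z_D]` and a RECIST responder classifier on `[z_P, z_D]`,
   trained by Chebyshev scalarization
   `L = max(lambda_P L_BCE, lambda_C L_MSE)`. Inference returns
   `sigmoid(f_P([z_P, z_D]))`, a probability of response (CR/PR).
   `train_mtl()`, `predict_response_prob()`.

A two-domain simulator (`generate_cohort()`, `plant_response_signal()`)
emits every input format the pipeline reads — MAF-style calls, annotation
tables, CNV categories, fingerprints, response tables — with configurable
sparsity, domain shift and a planted, annotation-dependent
mutation-to-response signal. `run_drp_pipeline()` drives the 80-20
three-split evaluation protocol with cross-split prediction averaging.

## Worked example

A mid-size synthetic cohort: 300 cell lines, 120 patients, a 50-gene
panel, 3 drugs, 10% RECIST label noise.

```r
library(panelDRP)

cfg <- simulation_config(n_cell = 300, n_patient = 120, G = 50,
                         n_drugs = 3, seed = 7)
cohort <- plant_response_signal(generate_cohort(cfg))

dim(cohort$profiles$PATIENT)
#> [1]  120 1200

res <- run_drp_pipeline(
  cohort,
  variant = "full",
  split_seeds = c(1, 2, 3),
  stage2_config = stage_two_config(d_z = 64, hidden = c(128, 128),
                                   epochs = 16, batch_size = 128,
                                   learning_rate = 2e-3, coral_weight = 10),
  base_seed = 7)

res$per_split
#>   seed     auroc     auprc baseline_auprc
#> 1    1 0.8560189 0.8888948      0.5694444
#> 2    2 0.8126935 0.8286811      0.4722222
#> 3    3 0.7922780 0.8060204      0.5138889

round(c(auroc = res$metrics$auroc, auprc = res$metrics$auprc,
        baseline_auprc = res$metrics$baseline_auprc), 3)
#>          auroc          auprc baseline_auprc
#>          0.816          0.824          0.489

round(c(responders = res$prob_responders,
        non_responders = res$prob_nonresponders), 3)
#>     responders non_responders
#>          0.643          0.299
```

`per_split` holds the held-out patient AUROC/AUPRC of each 80-20 split;
the second block is the overall metrics after averaging the predictions
of pairs seen in several test splits (baseline AUPRC is the positive
fraction — anything above it beats a no-information classifier); the last
line shows that predicted response probabilities are substantially higher
for true responders than for non-responders, i.e. the planted
mutation-to-response signal is recovered from held-out patients.

The same steps are available from a shell via the bundled CLI
(`inst/cli/paneldrp`): `simulate`, `featurize`, `pretrain`, `train`,
`finetune`, `predict`, `evaluate`, each writing a JSON manifest with the
seed, config echo and input checksums.

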