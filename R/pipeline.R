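# End-to-end driver: features -> domain-invariant representations ->
# multi-task response model -> held-out patient evaluation, following the
# 80-20 x 3-split protocol with cross-split prediction averaging. The
# `variant` argument selects the full model or one of its ablations:
#   "full"        annotated 24-per-gene features, zero-inflated likelihood
#   "no_va"       binary mutation-presence features, zero-inflated
#   "no_va_no_zi" binary features, plain (non-inflated) likelihood
#
# The representation stage is unsupervised (it never sees response labels),
# so one Stage II fit per run serves every labeled-pair split; Stage III is
# retrained per split as a small seed-ensemble whose predicted
# probabilities are averaged.

#' Default training configurations of the pipeline driver
#'
#' Compact problem sizes chosen so a full two-domain run (hundreds of
#' samples, a 100-gene panel) trains in minutes on one CPU; all overridable
#' per call. Stage II uses a wide latent (d_z = 128) with column-subsampled
#' likelihood updates; Stage III trains compact heads on frozen encoders
#' with decoupled weight decay.
#'
#' @name pipeline-defaults
#' @return A config object.
NULL

#' @rdname pipeline-defaults
#' @export
default_pipeline_stage2 <- function() {
  stage_two_config(d_z = 128L, hidden = c(128L, 128L), epochs = 16L,
                   batch_size = 256L, learning_rate = 2e-3,
                   coral_weight = 10, feature_subsample = 400L)
}

#' @rdname pipeline-defaults
#' @export
default_pipeline_stage3 <- function() {
  stage_three_config(epochs = 150L, batch_size = 256L, learning_rate = 1e-3,
                     weight_decay = 1, fine_tune_encoders = FALSE)
}

# Zero-preserving column standardization: divide each column by its pooled
# standard deviation so the zero-inflated likelihood still sees exact zeros.
scale_profiles <- function(XC, XP) {
  sds <- apply(rbind(XC, XP), 2, stats::sd)
  sds[sds < 1e-8] <- 1
  list(CELL_LINE = sweep(XC, 2, sds, "/"), PATIENT = sweep(XP, 2, sds, "/"),
       sds = sds)
}

#' Run the full drug-response pipeline on a labeled cohort
#'
#' Trains the Stage II VAE pair once on all samples of both domains
#' (unsupervised, zero-preserving column scaling applied first), then for
#' each split seed: split the labeled (patient, drug) pairs 80-20, train a
#' small ensemble of Stage III multi-task models on all cell-line pairs
#' plus the patient training pairs, and average their predicted response
#' probabilities on the held-out patient pairs. Predictions of pairs
#' appearing in several test splits are averaged; overall and per-split
#' AUROC/AUPRC are reported.
#'
#' @param cohort a labeled `synthetic_cohort` (see
#'   [plant_response_signal()]), or any list with the same fields.
#' @param variant model variant (see above).
#' @param split_seeds integer vector; one train/test split (and Stage III
#'   training) per seed.
#' @param stage2_config,stage3_config training configurations.
#' @param base_seed seed of the Stage II run (and root of the Stage III
#'   ensemble substreams).
#' @param n_ensemble Stage III models per split.
#' @param test_fraction held-out fraction of patient pairs.
#' @return List: `variant`, `per_split` (data.frame seed, auroc, auprc,
#'   baseline_auprc), `predictions` (cross-split averaged with labels),
#'   `metrics` ([metric_report()] of the averaged predictions),
#'   `prob_responders` / `prob_nonresponders` (mean predicted probability
#'   over true responders / non-responders), `init_coral_gap`,
#'   `final_coral_gap` (full-cohort representation covariance gap of the
#'   Stage II fit).
#' @export
run_drp_pipeline <- function(cohort,
                             variant = c("full", "no_va", "no_va_no_zi"),
                             split_seeds = c(1L, 2L, 3L),
                             stage2_config = default_pipeline_stage2(),
                             stage3_config = default_pipeline_stage3(),
                             base_seed = 1L, n_ensemble = 3L,
                             test_fraction = 0.2) {
  variant <- match.arg(variant)
  profiles <- if (variant == "full") {
    cohort$profiles %||% cohort_profiles(cohort)
  } else {
    cohort_binary_profiles(cohort)
  }
  if (variant == "no_va_no_zi") stage2_config$zero_inflated <- FALSE
  if (!is.null(stage2_config$feature_subsample) &&
      stage2_config$feature_subsample >= ncol(profiles$CELL_LINE)) {
    stage2_config$feature_subsample <- NULL
  }

  resp <- cohort$responses
  cell_pairs <- resp[resp$domain == "CELL_LINE", , drop = FALSE]
  cell_pairs$label <- as.numeric(cell_pairs$label)
  patient_pairs <- resp[resp$domain == "PATIENT", , drop = FALSE]
  patient_pairs$label <- binarize_recist(patient_pairs$label)

  if (variant == "full") {
    # zero-preserving standardization of the real-valued annotation features
    sc <- scale_profiles(profiles$CELL_LINE, profiles$PATIENT)
    XC <- sc$CELL_LINE
    XP <- sc$PATIENT
  } else {
    # binary presence profiles are 0/1 counts: ZINB likelihood, no scaling
    XC <- domain_matrix(profiles$CELL_LINE, "CELL_LINE", "count")
    XP <- domain_matrix(profiles$PATIENT, "PATIENT", "count")
  }

  stage2_config$seed <- substream_seed(base_seed, paste0("s2_", variant))
  fit2 <- train_domain_vaes(XC, XP, stage2_config)

  splits <- make_splits(patient_pairs, test_fraction, split_seeds)
  per_split <- list(); preds <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    train_pp <- patient_pairs[sp$train, , drop = FALSE]
    test_pp <- patient_pairs[sp$test, , drop = FALSE]
    smat <- matrix(0, nrow(test_pp), n_ensemble)
    for (e in seq_len(n_ensemble)) {
      s3 <- stage3_config
      s3$seed <- substream_seed(base_seed,
                                sprintf("s3_%s_%d_%d", variant,
                                        split_seeds[i], e))
      fit3 <- train_mtl(cell_pairs, train_pp, fit2$vae_C, fit2$vae_P,
                        XC, XP, cohort$drugs, s3)
      for (d in unique(test_pp$drug_id)) {
        rows <- test_pp$drug_id == d
        smat[rows, e] <- predict_response_prob(
          fit3$model, XP[test_pp$sample_id[rows], , drop = FALSE],
          cohort$drugs[d, ])
      }
    }
    score <- rowMeans(smat)
    preds[[i]] <- data.frame(sample_id = test_pp$sample_id,
                             drug_id = test_pp$drug_id,
                             score = score, label = test_pp$label,
                             stringsAsFactors = FALSE)
    per_split[[i]] <- data.frame(
      seed = split_seeds[i],
      auroc = auroc(test_pp$label, score),
      auprc = auprc(test_pp$label, score),
      baseline_auprc = baseline_auprc(test_pp$label))
  }
  per_split <- do.call(rbind, per_split)

  agg <- aggregate_cross_split(preds)
  metrics <- metric_report(agg)
  list(variant = variant, per_split = per_split, predictions = agg,
       metrics = metrics,
       prob_responders = mean(agg$score[agg$label == 1]),
       prob_nonresponders = mean(agg$score[agg$label == 0]),
       init_coral_gap = fit2$init_coral_gap,
       final_coral_gap = fit2$final_coral_gap)
}
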