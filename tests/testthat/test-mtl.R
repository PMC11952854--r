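# Stage III: drug embedding, multi-task training, fine-tuning, the
# inference path and SMILES fingerprints.

test_that("drug embedding is deterministic with the configured width", {
  fit <- tiny_fitted()
  model <- fit$fit3$model
  fp <- fit$cohort$drugs[1, ]
  e1 <- embed_drug(model, fp)
  expect_equal(ncol(e1), 8L)
  expect_identical(e1, embed_drug(model, fp))
  expect_error(embed_drug(model, c(fp, 0L)), "length")

  # zero fingerprint through a bias-free embedder maps to zero
  m0 <- model
  m0$params$ed_b1 <- m0$params$ed_b1 * 0
  m0$params$ed_b2 <- m0$params$ed_b2 * 0
  expect_true(all(embed_drug(m0, fp * 0L) == 0))
})

test_that("multi-task training is seeded, reducing and gradient-isolated", {
  fit <- tiny_fitted()
  coh <- fit$cohort
  prof <- coh$profiles

  # planted signal: final training loss below the initial one
  log <- fit$fit3$log
  expect_lt(log$l_mtl[nrow(log)], log$l_mtl[1])

  # determinism: re-train with the same seed
  fit3b <- train_mtl(fit$cell, fit$pat, fit$fit2$vae_C, fit$fit2$vae_P,
                     prof$CELL_LINE, prof$PATIENT, coh$drugs,
                     tiny_stage3(seed = 3L, epochs = 40L,
                                 fine_tune_encoders = TRUE))
  expect_identical(fit3b$log, fit$fit3$log)

  # frozen encoders stay bit-identical through training
  frozen <- train_mtl(fit$cell, fit$pat, fit$fit2$vae_C, fit$fit2$vae_P,
                      prof$CELL_LINE, prof$PATIENT, coh$drugs,
                      tiny_stage3(seed = 4L, fine_tune_encoders = FALSE))
  expect_identical(frozen$model$enc_P$params, fit$fit2$vae_P$params[
    names(frozen$model$enc_P$params)])

  # fine-tuned encoders move
  expect_false(identical(fit$fit3$model$enc_P$params$enc_W1,
                         fit$fit2$vae_P$params$enc_W1))
})

test_that("a vanishing regression weight silences the cell-line branch", {
  fit <- tiny_fitted()
  coh <- fit$cohort; prof <- coh$profiles
  # weight decay off: it would shrink even gradient-free parameters
  cfg <- tiny_stage3(seed = 9L, epochs = 5L, lambda_C = 1e-12,
                     fine_tune_encoders = TRUE, weight_decay = 0)
  trained <- train_mtl(fit$cell, fit$pat, fit$fit2$vae_C, fit$fit2$vae_P,
                       prof$CELL_LINE, prof$PATIENT, coh$drugs, cfg)
  set.seed(substream_seed(cfg$seed, "stage3"))
  init <- new_mtl_model(fit$fit2$vae_C, fit$fit2$vae_P, ncol(coh$drugs), cfg)
  # the AUDRC head and the cell-line encoder receive no gradient
  expect_identical(trained$model$params$fc_W1, init$params$fc_W1)
  expect_identical(trained$model$enc_C$params$enc_W1,
                   fit$fit2$vae_C$params$enc_W1)
  # while the RECIST head trains
  expect_false(identical(trained$model$params$fp_W1, init$params$fp_W1))
})

test_that("inference touches only the patient branch", {
  fit <- tiny_fitted()
  coh <- fit$cohort; prof <- coh$profiles
  model <- fit$fit3$model
  x <- prof$PATIENT[1:3, ]
  fp <- coh$drugs[1, ]
  p1 <- predict_response_prob(model, x, fp)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, predict_response_prob(model, x, fp))

  poisoned <- model
  poisoned$params$fc_W1[] <- NaN
  poisoned$params$fc_W2[] <- NaN
  poisoned$enc_C$params$enc_W1[] <- NaN
  expect_identical(predict_response_prob(poisoned, x, fp), p1)

  expect_error(predict_response_prob(model, x[, 1:5], fp), "patient encoder")
})

test_that("trained predictions recover the planted signal direction", {
  fit <- tiny_fitted()
  coh <- fit$cohort; prof <- coh$profiles
  model <- fit$fit3$model

  # cell-line branch: predictions rank-correlate with true AUDRC
  preds <- numeric(nrow(fit$cell))
  for (d in rownames(coh$drugs)) {
    rows <- fit$cell$drug_id == d
    preds[rows] <- predict_audrc(
      model, prof$CELL_LINE[fit$cell$sample_id[rows], , drop = FALSE],
      coh$drugs[d, ])
  }
  expect_gt(cor(preds, fit$cell$label, method = "spearman"), 0)
  expect_true(all(is.finite(preds)))
  expect_equal(preds[1], predict_audrc(
    model, prof$CELL_LINE[fit$cell$sample_id[1], , drop = FALSE],
    coh$drugs[fit$cell$drug_id[1], ])[1], tolerance = 1e-10)

  # patient branch: responders score above non-responders on average
  prob <- numeric(nrow(fit$pat))
  for (d in rownames(coh$drugs)) {
    rows <- fit$pat$drug_id == d
    prob[rows] <- predict_response_prob(
      model, prof$PATIENT[fit$pat$sample_id[rows], , drop = FALSE],
      coh$drugs[d, ])
  }
  expect_gt(mean(prob[fit$pat$label == 1]), mean(prob[fit$pat$label == 0]))
})

test_that("per-drug fine-tuning clones then specializes the base model", {
  fit <- tiny_fitted()
  coh <- fit$cohort; prof <- coh$profiles
  drugs <- rownames(coh$drugs)

  zero <- pretrain_then_finetune(fit$fit3, drugs[1], fit$cell, fit$pat,
                                 prof$CELL_LINE, prof$PATIENT, coh$drugs,
                                 tiny_stage3(seed = 8L, epochs = 0L))
  expect_identical(zero$model$params, fit$fit3$model$params)

  tuned1 <- pretrain_then_finetune(fit$fit3, drugs[1], fit$cell, fit$pat,
                                   prof$CELL_LINE, prof$PATIENT, coh$drugs,
                                   tiny_stage3(seed = 8L, epochs = 3L))
  expect_false(identical(tuned1$model$params$fp_W1,
                         fit$fit3$model$params$fp_W1))

  tuned2 <- pretrain_then_finetune(fit$fit3, drugs[2], fit$cell, fit$pat,
                                   prof$CELL_LINE, prof$PATIENT, coh$drugs,
                                   tiny_stage3(seed = 8L, epochs = 3L))
  expect_false(identical(tuned1$model$params$fp_W1,
                         tuned2$model$params$fp_W1))

  expect_error(
    pretrain_then_finetune(fit$fit3, "no_such_drug", fit$cell, fit$pat,
                           prof$CELL_LINE, prof$PATIENT, coh$drugs,
                           tiny_stage3(epochs = 1L)),
    "no_such_drug")
})

test_that("pair validation names the offending drug", {
  fit <- tiny_fitted()
  coh <- fit$cohort; prof <- coh$profiles
  bad <- fit$cell
  bad$drug_id[1] <- "mystery_compound"
  expect_error(
    train_mtl(bad, fit$pat, fit$fit2$vae_C, fit$fit2$vae_P,
              prof$CELL_LINE, prof$PATIENT, coh$drugs, tiny_stage3()),
    "mystery_compound")
  expect_error(
    train_mtl(fit$cell, fit$pat[0, ], fit$fit2$vae_C, fit$fit2$vae_P,
              prof$CELL_LINE, prof$PATIENT, coh$drugs, tiny_stage3()),
    "empty")
})

test_that("SMILES fingerprints are deterministic and canonical", {
  fp1 <- fingerprint_from_smiles("CCO", n_bits = 256)
  expect_length(fp1, 256L)
  expect_true(all(fp1 %in% c(0L, 1L)))
  expect_gt(sum(fp1), 0)
  expect_identical(fp1, fingerprint_from_smiles("CCO", n_bits = 256))
  # a different spelling of ethanol folds to the same bits
  expect_identical(fp1, fingerprint_from_smiles("OCC", n_bits = 256))
  # different molecule, different bits
  expect_false(identical(fp1,
                         fingerprint_from_smiles("c1ccccc1O", n_bits = 256)))
  expect_error(fingerprint_from_smiles("not_a_smiles(((", n_bits = 256),
               "SMILES")
})
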