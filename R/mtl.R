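# Stage III: multi-task drug response prediction.
#
# A drug embedder maps the binary circular fingerprint to a dense vector
# z_D; the AUDRC regressor f_C consumes [z_C, z_D] (cell-line latent +
# drug) and the RECIST classifier f_P consumes [z_P, z_D] (patient latent +
# drug). Training minimizes max(lambda_P * L_BCE, lambda_C * L_MSE)
# (Chebyshev scalarization); the subgradient flows through the active term
# only (ties resolve to the classification term). The Stage II encoders are
# attached and, by default, fine-tuned with the rest of the network.

#' Stage III configuration
#'
#' @param lambda_P,lambda_C positive Chebyshev weights for the RECIST (BCE)
#'   and AUDRC (MSE) terms.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size per-domain minibatch size.
#' @param seed integer seed.
#' @param embed_dim drug embedding width.
#' @param hidden hidden width of the embedder and both task heads.
#' @param fingerprint_radius,fingerprint_bits circular fingerprint
#'   parameters used when drugs arrive as SMILES.
#' @param fine_tune_encoders propagate gradients into the attached Stage II
#'   encoders.
#' @param weight_decay decoupled L2 decay applied to weight matrices (not
#'   biases) after each Adam step; the labeled patient set is usually tiny
#'   relative to the panel feature count, so some shrinkage is essential.
#' @param encoder_learning_rate Adam step size for the attached encoders
#'   when fine-tuning (defaults to `learning_rate`); a smaller value lets
#'   the encoders adapt without discarding the unsupervised solution.
#' @return A `stage_three_config` list.
#' @export
stage_three_config <- function(lambda_P = 1, lambda_C = 1,
                               learning_rate = 1e-3, epochs = 100L,
                               batch_size = 64L, seed = 1L,
                               embed_dim = 32L, hidden = 64L,
                               fingerprint_radius = 2L,
                               fingerprint_bits = 1024L,
                               fine_tune_encoders = TRUE,
                               weight_decay = 1e-3,
                               encoder_learning_rate = NULL) {
  if (lambda_P <= 0 || lambda_C <= 0) stop_panel("lambda_P, lambda_C must be > 0")
  stopifnot(weight_decay >= 0)
  structure(list(lambda_P = lambda_P, lambda_C = lambda_C,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 embed_dim = as.integer(embed_dim), hidden = as.integer(hidden),
                 fingerprint_radius = as.integer(fingerprint_radius),
                 fingerprint_bits = as.integer(fingerprint_bits),
                 fine_tune_encoders = isTRUE(fine_tune_encoders),
                 weight_decay = weight_decay,
                 encoder_learning_rate = encoder_learning_rate %||%
                   learning_rate),
            class = "stage_three_config")
}

#' Initialize a multi-task response model
#'
#' @param vae_C,vae_P trained Stage II domain VAEs (their encoders are
#'   copied into the model).
#' @param fp_length fingerprint bit length accepted by the drug embedder.
#' @param config a [stage_three_config()].
#' @return An `mtl_model` object.
#' @export
new_mtl_model <- function(vae_C, vae_P, fp_length,
                          config = stage_three_config()) {
  h <- config$hidden; de <- config$embed_dim
  params <- list(
    ed_W1 = init_weight(fp_length, h), ed_b1 = init_bias(h),
    ed_W2 = init_weight(h, de), ed_b2 = init_bias(de),
    fc_W1 = init_weight(vae_C$d_z + de, h), fc_b1 = init_bias(h),
    fc_W2 = init_weight(h, 1L), fc_b2 = init_bias(1L),
    fp_W1 = init_weight(vae_P$d_z + de, h), fp_b1 = init_bias(h),
    fp_W2 = init_weight(h, 1L), fp_b2 = init_bias(1L))
  encoder_of <- function(vae) {
    list(params = vae$params[c("enc_W1", "enc_b1", "enc_W2", "enc_b2",
                               "W_mu", "b_mu")],
         d_in = vae$d_in, d_z = vae$d_z, hidden = vae$hidden)
  }
  structure(list(params = params,
                 enc_C = encoder_of(vae_C),
                 enc_P = encoder_of(vae_P),
                 fp_length = as.integer(fp_length),
                 fine_tune_encoders = config$fine_tune_encoders),
            class = "mtl_model")
}

encoder_mu <- function(enc, X) {
  p <- enc$params
  h2 <- dense_relu(dense_relu(X, p$enc_W1, p$enc_b1), p$enc_W2, p$enc_b2)
  dense_linear(h2, p$W_mu, p$b_mu)
}

#' Embed drug fingerprints
#'
#' Deterministic feedforward map from the binary fingerprint to the drug
#' representation z_D.
#'
#' @param model an `mtl_model`.
#' @param fp binary vector of length `model$fp_length`, or a matrix of such
#'   rows.
#' @return Embedding matrix (one row per fingerprint).
#' @export
embed_drug <- function(model, fp) {
  fp <- if (is.null(dim(fp))) matrix(fp, nrow = 1L) else as.matrix(fp)
  if (ncol(fp) != model$fp_length) {
    stop_panel("fingerprint length %d does not match embedder input %d",
               ncol(fp), model$fp_length)
  }
  p <- model$params
  dense_linear(dense_relu(fp, p$ed_W1, p$ed_b1), p$ed_W2, p$ed_b2)
}

# Forward through one task branch; branch in {"C","P"}. With `z_cached`
# (frozen encoders) the encoder forward is skipped entirely.
mtl_forward <- function(model, X, fp, branch, z_cached = NULL) {
  p <- model$params
  enc <- if (branch == "C") model$enc_C else model$enc_P
  ep <- enc$params
  if (is.null(z_cached)) {
    h1 <- dense_relu(X, ep$enc_W1, ep$enc_b1)
    h2 <- dense_relu(h1, ep$enc_W2, ep$enc_b2)
    z <- dense_linear(h2, ep$W_mu, ep$b_mu)
  } else {
    h1 <- h2 <- NULL
    z <- z_cached
  }
  e1 <- dense_relu(fp, p$ed_W1, p$ed_b1)
  zd <- dense_linear(e1, p$ed_W2, p$ed_b2)
  u <- cbind(z, zd)
  if (branch == "C") {
    t1 <- dense_relu(u, p$fc_W1, p$fc_b1)
    out <- dense_linear(t1, p$fc_W2, p$fc_b2)
  } else {
    t1 <- dense_relu(u, p$fp_W1, p$fp_b1)
    out <- dense_linear(t1, p$fp_W2, p$fp_b2)
  }
  list(h1 = h1, h2 = h2, z = z, e1 = e1, zd = zd, u = u, t1 = t1,
       out = as.vector(out))
}

# Backward for one branch given dout (vector). Returns grads for the shared
# params (+ encoder grads under enc_prefix when fine-tuning).
mtl_backward <- function(model, X, fp, fw, dout, branch, fine_tune) {
  p <- model$params
  enc <- if (branch == "C") model$enc_C else model$enc_P
  W1 <- if (branch == "C") p$fc_W1 else p$fp_W1
  W2 <- if (branch == "C") p$fc_W2 else p$fp_W2
  dout <- matrix(dout, ncol = 1L)
  grads <- list()
  bk2 <- dense_linear_backward(fw$t1, W2, dout)
  bk1 <- dense_relu_backward(fw$u, W1, fw$t1, bk2$dx)
  if (branch == "C") {
    grads$fc_W2 <- bk2$dW; grads$fc_b2 <- bk2$db
    grads$fc_W1 <- bk1$dW; grads$fc_b1 <- bk1$db
  } else {
    grads$fp_W2 <- bk2$dW; grads$fp_b2 <- bk2$db
    grads$fp_W1 <- bk1$dW; grads$fp_b1 <- bk1$db
  }
  dz <- bk1$dx[, seq_len(enc$d_z), drop = FALSE]
  dzd <- bk1$dx[, enc$d_z + seq_len(ncol(fw$zd)), drop = FALSE]
  bke2 <- dense_linear_backward(fw$e1, p$ed_W2, dzd)
  bke1 <- dense_relu_backward(fp, p$ed_W1, fw$e1, bke2$dx)
  grads$ed_W2 <- bke2$dW; grads$ed_b2 <- bke2$db
  grads$ed_W1 <- bke1$dW; grads$ed_b1 <- bke1$db
  enc_grads <- NULL
  if (fine_tune) {
    ep <- enc$params
    bkm <- dense_linear_backward(fw$h2, ep$W_mu, dz)
    bk <- dense_relu_backward(fw$h1, ep$enc_W2, fw$h2, bkm$dx)
    bk0 <- dense_relu_backward(X, ep$enc_W1, fw$h1, bk$dx)
    enc_grads <- list(W_mu = bkm$dW, b_mu = bkm$db,
                      enc_W2 = bk$dW, enc_b2 = bk$db,
                      enc_W1 = bk0$dW, enc_b1 = bk0$db)
  }
  list(shared = grads, enc = enc_grads)
}

validate_pairs <- function(pairs, what, drugs) {
  assert_columns(pairs, c("sample_id", "drug_id", "label"), what)
  if (!nrow(pairs)) stop_panel("%s is empty", what)
  miss <- setdiff(unique(pairs$drug_id), rownames(drugs))
  if (length(miss)) {
    stop_panel("no fingerprint for drug(s): %s", paste(miss, collapse = ", "))
  }
  pairs
}

#' Train the multi-task drug response model
#'
#' Each optimization step draws one cell-line batch (AUDRC targets, MSE) and
#' one patient batch (binarized RECIST targets, BCE), evaluates both task
#' losses, and takes an Adam step along the subgradient of
#' `max(lambda_P * L_BCE, lambda_C * L_MSE)` — only the currently larger
#' weighted term propagates gradients (ties resolve to BCE). Gradients
#' enter the attached encoders iff `config$fine_tune_encoders`.
#'
#' @param cell_pairs data.frame `sample_id`, `drug_id`, `label` (real
#'   AUDRC).
#' @param patient_pairs data.frame `sample_id`, `drug_id`, `label` (0/1
#'   responder; use [binarize_recist()] upstream for RECIST categories).
#' @param vae_C,vae_P trained Stage II VAEs supplying the encoders.
#' @param profiles_C,profiles_P feature matrices with sample_id rownames.
#' @param drugs fingerprint matrix with drug_id rownames (0/1 entries).
#' @param config a [stage_three_config()].
#' @return List with `model` (an `mtl_model`) and `log` (epoch, l_bce,
#'   l_mse, l_mtl).
#' @export
train_mtl <- function(cell_pairs, patient_pairs, vae_C, vae_P,
                      profiles_C, profiles_P, drugs,
                      config = stage_three_config()) {
  drugs <- as.matrix(drugs)
  validate_pairs(cell_pairs, "cell-line pair table", drugs)
  validate_pairs(patient_pairs, "patient pair table", drugs)
  if (!all(patient_pairs$label %in% c(0, 1))) {
    stop_panel("patient labels must be binarized to 0/1 before training")
  }
  set.seed(substream_seed(config$seed, "stage3"))
  model <- new_mtl_model(vae_C, vae_P, ncol(drugs), config)
  model <- continue_mtl_training(model, cell_pairs, patient_pairs,
                                 profiles_C, profiles_P, drugs, config)
  model
}

# Shared training loop; used for both initial training and fine-tuning.
continue_mtl_training <- function(model, cell_pairs, patient_pairs,
                                  profiles_C, profiles_P, drugs, config) {
  rowC <- match(cell_pairs$sample_id, rownames(profiles_C))
  rowP <- match(patient_pairs$sample_id, rownames(profiles_P))
  if (anyNA(rowC) || anyNA(rowP)) {
    stop_panel("response pairs reference samples missing from the profiles")
  }
  dC <- match(cell_pairs$drug_id, rownames(drugs))
  dP <- match(patient_pairs$drug_id, rownames(drugs))
  yC <- as.numeric(cell_pairs$label)
  yP <- as.numeric(patient_pairs$label)
  nC <- nrow(cell_pairs); nP <- nrow(patient_pairs)
  b <- min(config$batch_size, nC, nP)
  steps <- max(1L, ceiling(max(nC, nP) / b))
  stt <- adam_init(model$params)
  ste_C <- adam_init(model$enc_C$params)
  ste_P <- adam_init(model$enc_P$params)
  wd <- config$weight_decay %||% 0
  enc_lr <- config$encoder_learning_rate %||% config$learning_rate
  frozen <- !model$fine_tune_encoders
  if (frozen) {
    # encoders receive no gradients: cache all latent representations once
    ZC_all <- encoder_mu(model$enc_C, profiles_C)
    ZP_all <- encoder_mu(model$enc_P, profiles_P)
  }
  decay <- function(params) {
    if (wd > 0) {
      for (nm in names(params)) {
        if (is.matrix(params[[nm]])) {
          params[[nm]] <- params[[nm]] * (1 - config$learning_rate * wd)
        }
      }
    }
    params
  }
  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    acc <- c(l_bce = 0, l_mse = 0, l_mtl = 0)
    for (s in seq_len(steps)) {
      iC <- sample.int(nC, b); iP <- sample.int(nP, b)
      XCb <- if (frozen) NULL else profiles_C[rowC[iC], , drop = FALSE]
      XPb <- if (frozen) NULL else profiles_P[rowP[iP], , drop = FALSE]
      FCb <- drugs[dC[iC], , drop = FALSE]
      FPb <- drugs[dP[iP], , drop = FALSE]
      fwC <- mtl_forward(model, XCb, FCb, "C",
                         if (frozen) ZC_all[rowC[iC], , drop = FALSE])
      fwP <- mtl_forward(model, XPb, FPb, "P",
                         if (frozen) ZP_all[rowP[iP], , drop = FALSE])
      l_mse <- mse_loss(yC[iC], fwC$out)
      l_bce <- bce_logit_loss(yP[iP], fwP$out)
      l_mtl <- chebyshev_loss(l_bce, l_mse, config$lambda_P, config$lambda_C)
      if (!is.finite(l_mtl)) {
        stop_panel("non-finite multi-task loss at epoch %d (bce=%g, mse=%g)",
                   epoch, l_bce, l_mse)
      }
      if (config$lambda_P * l_bce >= config$lambda_C * l_mse) {
        dout <- config$lambda_P * (sigmoid(fwP$out) - yP[iP]) / b
        bk <- mtl_backward(model, XPb, FPb, fwP, dout, "P",
                           model$fine_tune_encoders)
        if (!is.null(bk$enc)) {
          up <- adam_step(model$enc_P$params, bk$enc, ste_P, enc_lr)
          model$enc_P$params <- decay(up$params); ste_P <- up$state
        }
      } else {
        dout <- config$lambda_C * 2 * (fwC$out - yC[iC]) / b
        bk <- mtl_backward(model, XCb, FCb, fwC, dout, "C",
                           model$fine_tune_encoders)
        if (!is.null(bk$enc)) {
          up <- adam_step(model$enc_C$params, bk$enc, ste_C, enc_lr)
          model$enc_C$params <- decay(up$params); ste_C <- up$state
        }
      }
      up <- adam_step(model$params, bk$shared, stt, config$learning_rate)
      model$params <- decay(up$params); stt <- up$state
      acc <- acc + c(l_bce = l_bce, l_mse = l_mse, l_mtl = l_mtl)
    }
    log[[epoch]] <- data.frame(epoch = epoch, t(acc / steps))
  }
  log <- if (config$epochs) do.call(rbind, log) else
    data.frame(epoch = integer(), l_bce = numeric(), l_mse = numeric(),
               l_mtl = numeric())
  list(model = model, log = log)
}

#' Clone a trained model and fine-tune it on one drug
#'
#' Copies all weights of `base` and continues training only on the response
#' pairs whose `drug_id` matches `drug`; with zero fine-tuning epochs the
#' returned model is identical to the base model.
#'
#' @param base result of [train_mtl()] (list with `model`).
#' @param drug drug identifier to specialize for.
#' @param cell_pairs,patient_pairs,profiles_C,profiles_P,drugs as in
#'   [train_mtl()].
#' @param config a [stage_three_config()] controlling the fine-tune run.
#' @return List with `model` and `log`, as [train_mtl()].
#' @export
pretrain_then_finetune <- function(base, drug, cell_pairs, patient_pairs,
                                   profiles_C, profiles_P, drugs,
                                   config = stage_three_config()) {
  cp <- cell_pairs[cell_pairs$drug_id == drug, , drop = FALSE]
  pp <- patient_pairs[patient_pairs$drug_id == drug, , drop = FALSE]
  if (!nrow(cp) && !nrow(pp)) {
    stop_panel("no response pairs match drug '%s'", drug)
  }
  model <- base$model
  if (config$epochs == 0L) return(list(model = model, log = base$log[0, ]))
  # A drug-specific run may lose one of the two tasks; fall back to the
  # matching pairs that exist (the active Chebyshev term handles the rest).
  if (!nrow(cp)) cp <- cell_pairs
  if (!nrow(pp)) pp <- patient_pairs
  set.seed(substream_seed(config$seed, paste0("finetune_", drug)))
  continue_mtl_training(model, cp, pp, profiles_C, profiles_P,
                        as.matrix(drugs), config)
}

#' Predict the probability of RECIST response for patient profiles
#'
#' Inference path: encode the annotated mutation profile with the patient
#' encoder (posterior mean), embed the drug fingerprint, concatenate, apply
#' the RECIST head and a sigmoid. Only the patient branch is touched; the
#' cell-line branch plays no role at inference.
#'
#' @param model an `mtl_model`.
#' @param X patient profile row(s): matrix with `model$enc_P$d_in` columns.
#' @param fp drug fingerprint (vector) or matrix of one fingerprint per row
#'   of `X`; a single fingerprint is recycled across rows.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_response_prob <- function(model, X, fp) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != model$enc_P$d_in) {
    stop_panel("profile width %d does not match the patient encoder (%d)",
               ncol(X), model$enc_P$d_in)
  }
  fp <- if (is.null(dim(fp))) {
    matrix(rep(fp, nrow(X)), nrow = nrow(X), byrow = TRUE)
  } else as.matrix(fp)
  if (ncol(fp) != model$fp_length) {
    stop_panel("fingerprint length %d does not match embedder input %d",
               ncol(fp), model$fp_length)
  }
  fw <- mtl_forward(model, X, fp, "P")
  as.vector(sigmoid(fw$out))
}

#' Predict AUDRC for cell-line profiles
#'
#' @param model an `mtl_model`.
#' @param X cell-line profile row(s).
#' @param fp drug fingerprint (vector, recycled) or matrix.
#' @return Numeric vector of predicted AUDRC values.
#' @export
predict_audrc <- function(model, X, fp) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != model$enc_C$d_in) {
    stop_panel("profile width %d does not match the cell-line encoder (%d)",
               ncol(X), model$enc_C$d_in)
  }
  fp <- if (is.null(dim(fp))) {
    matrix(rep(fp, nrow(X)), nrow = nrow(X), byrow = TRUE)
  } else as.matrix(fp)
  fw <- mtl_forward(model, X, fp, "C")
  fw$out
}

#' Circular (Morgan-style) fingerprint from a SMILES string
#'
#' Computed with the Open Babel backend (`obabel`, ECFP with the requested
#' radius, folded to `n_bits`). Open Babel canonicalizes internally, so
#' different SMILES spellings of the same molecule give identical bits.
#'
#' @param smiles a single SMILES string.
#' @param radius circular neighborhood radius (ECFP diameter = 2 * radius).
#' @param n_bits folded fingerprint length.
#' @return Integer 0/1 vector of length `n_bits`.
#' @export
fingerprint_from_smiles <- function(smiles, radius = 2L, n_bits = 1024L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, n_bits >= 16)
  if (Sys.which("obabel") == "") {
    stop_panel("the 'obabel' executable is required for SMILES fingerprints")
  }
  fpname <- paste0("ECFP", 2L * as.integer(radius))
  out <- suppressWarnings(system2(
    "obabel", c(paste0("-:", shQuote(smiles)), "-ofpt",
                paste0("-xf", fpname), paste0("-xN", as.integer(n_bits))),
    stdout = TRUE, stderr = TRUE))
  hex <- out[grepl("^[0-9a-fA-F ]+$", trimws(out)) & nzchar(trimws(out))]
  if (!length(hex) || any(grepl("0 molecules converted", out))) {
    stop_panel("could not parse SMILES string: %s", smiles)
  }
  # expand the hex dump nibble-by-nibble, most-significant bit first
  nibbles <- strtoi(strsplit(gsub("\\s", "", paste(hex, collapse = "")),
                             "")[[1]], 16L)
  bits <- as.integer(vapply(nibbles,
                            function(n) as.integer(intToBits(n)[4:1]),
                            integer(4)))
  bits <- bits[seq_len(min(length(bits), n_bits))]
  if (length(bits) < n_bits) bits <- c(bits, integer(n_bits - length(bits)))
  as.integer(bits)
}
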