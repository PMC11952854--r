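# Stage II: per-domain zero-inflated variational autoencoders with CORAL
# alignment.
#
# Each domain (cell line, patient) gets its own VAE. The encoder infers the
# posterior mean mu and standard deviation sigma of a d_z-dimensional latent
# normal; the decoder reconstructs an intermediate matrix Xbar from which
# three linear heads produce the zero-inflated likelihood parameters
#   Pi    = sigmoid(Xbar W_Pi)   (zero-inflation probability)
#   Omega = exp(Xbar W_Omega)    (NB mean, or normal mean)
#   Theta = exp(Xbar W_Theta)    (NB inverse dispersion, or normal variance)
# Training minimizes reconstruction NLL + lambda ||Pi||_F^2 + KLD per domain
# plus the CORAL loss between the two domains' posterior means. Inference
# uses mu only, so encoding is deterministic.

#' Construct a domain data matrix
#'
#' Tags a numeric matrix with its domain and data kind so downstream code
#' can pick the matching likelihood (`"real"` -> zero-inflated normal,
#' `"count"` -> zero-inflated negative binomial).
#'
#' @param values numeric matrix, samples in rows; no missing entries.
#' @param domain `"CELL_LINE"` or `"PATIENT"`.
#' @param kind `"real"` or `"count"`; count matrices must be nonnegative
#'   integers.
#' @return The matrix with `domain` and `data_kind` attributes.
#' @export
domain_matrix <- function(values, domain = c("CELL_LINE", "PATIENT"),
                          kind = c("real", "count")) {
  domain <- match.arg(domain)
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop_panel("domain matrix has missing entries")
  if (kind == "count" && !is_count_vector(as.numeric(values))) {
    stop_panel("count domain matrix must contain nonnegative integers")
  }
  attr(values, "domain") <- domain
  attr(values, "data_kind") <- kind
  values
}

data_kind_of <- function(x, default = "real") {
  attr(x, "data_kind") %||% default
}

#' Stage II configuration
#'
#' Defaults are repository choices (the useful ranges are problem-dependent):
#' `d_z` latent width, `lambda_pi` weight of the `||Pi||_F^2` penalty that
#' discourages degenerate all-zero reconstructions, `coral_weight` scale of
#' the alignment term, `mean_activation` either `"exp"` (positive mean, the
#' printed head activation) or `"identity"` (unconstrained normal mean), and
#' `zero_inflated = FALSE` drops the mixture (Pi forced to 0) and the Pi
#' penalty, giving the plain-likelihood ablation as a configuration.
#'
#' @param d_z latent dimension.
#' @param lambda_pi coefficient of the Pi Frobenius penalty.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size per-domain minibatch size (equal in both domains).
#' @param seed integer seed for initialization, batching and sampling.
#' @param coral_weight weight of the CORAL term in the training objective.
#' @param kld_weight multiplier of the KL divergence term in the training
#'   objective (beta-VAE style); values below 1 trade prior regularity for
#'   more informative latents and guard against posterior collapse. The
#'   loss report always shows the unweighted KLD.
#' @param hidden integer vector of the two hidden-layer widths.
#' @param feature_subsample optional integer: per training step, evaluate
#'   the likelihood (and update the three k x k parameter heads) on this
#'   many randomly sampled feature columns instead of all k, rescaling by
#'   `k / feature_subsample` so the gradient stays unbiased. Cuts the
#'   dominant O(k^2) cost for wide panels; `NULL` disables.
#' @param zero_inflated use the zero-inflated mixture likelihood.
#' @param mean_activation activation for the mean head (real data).
#' @return A `stage_two_config` list.
#' @export
stage_two_config <- function(d_z = 64L, lambda_pi = 1e-4,
                             learning_rate = 1e-3, epochs = 200L,
                             batch_size = 64L, seed = 1L, coral_weight = 1,
                             kld_weight = 1, hidden = c(256L, 256L),
                             feature_subsample = NULL,
                             zero_inflated = TRUE,
                             mean_activation = c("exp", "identity")) {
  stopifnot(d_z > 0, lambda_pi >= 0, learning_rate > 0, epochs >= 0,
            batch_size > 0, coral_weight >= 0, kld_weight >= 0,
            length(hidden) == 2L)
  structure(list(d_z = as.integer(d_z), lambda_pi = lambda_pi,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 coral_weight = coral_weight, kld_weight = kld_weight,
                 hidden = as.integer(hidden),
                 feature_subsample = if (!is.null(feature_subsample))
                   as.integer(feature_subsample),
                 zero_inflated = isTRUE(zero_inflated),
                 mean_activation = match.arg(mean_activation)),
            class = "stage_two_config")
}

#' Initialize a domain VAE
#'
#' @param d_in input feature dimension.
#' @param config a [stage_two_config()].
#' @param data_kind `"real"` (ZI-normal) or `"count"` (ZINB).
#' @return A `domain_vae` object (list of parameter matrices plus metadata).
#' @export
new_domain_vae <- function(d_in, config = stage_two_config(),
                           data_kind = c("real", "count")) {
  data_kind <- match.arg(data_kind)
  h <- config$hidden
  params <- list(
    enc_W1 = init_weight(d_in, h[1]), enc_b1 = init_bias(h[1]),
    enc_W2 = init_weight(h[1], h[2]), enc_b2 = init_bias(h[2]),
    W_mu = init_weight(h[2], config$d_z), b_mu = init_bias(config$d_z),
    W_lv = init_weight(h[2], config$d_z) * 0.1, b_lv = init_bias(config$d_z),
    dec_W1 = init_weight(config$d_z, h[2]), dec_b1 = init_bias(h[2]),
    dec_W2 = init_weight(h[2], h[1]), dec_b2 = init_bias(h[1]),
    dec_W3 = init_weight(h[1], d_in), dec_b3 = init_bias(d_in),
    W_pi = init_weight(d_in, d_in) * 0.1,
    W_om = init_weight(d_in, d_in) * 0.1,
    W_th = init_weight(d_in, d_in) * 0.1)
  structure(list(params = params, d_in = d_in, d_z = config$d_z,
                 hidden = h, data_kind = data_kind,
                 zero_inflated = config$zero_inflated,
                 mean_activation = config$mean_activation),
            class = "domain_vae")
}

#' Evaluate the zero-inflation parameter heads
#'
#' `Pi = sigmoid(Xbar W_Pi)`, `Omega = exp(Xbar W_Omega)`,
#' `Theta = exp(Xbar W_Theta)`; `Pi` is clamped to `[1e-6, 1 - 1e-6]` and
#' the exponents are clamped at 30 in absolute value for numerical safety.
#'
#' @param x_recon decoded matrix Xbar (batch x k).
#' @param heads list with matrices `W_pi`, `W_om`, `W_th` (k x k).
#' @param mean_activation `"exp"` or `"identity"` for the Omega head.
#' @return List with entries `Pi`, `Omega`, `Theta`.
#' @export
zi_param_heads <- function(x_recon, heads, mean_activation = "exp") {
  if (any(!is.finite(x_recon))) stop_panel("non-finite reconstruction input")
  A_pi <- x_recon %*% heads$W_pi
  A_om <- clamp(x_recon %*% heads$W_om, -30, 30)
  A_th <- clamp(x_recon %*% heads$W_th, -30, 30)
  list(Pi = clamp(sigmoid(A_pi), PI_EPS, 1 - PI_EPS),
       Omega = if (mean_activation == "exp") exp(A_om) else A_om,
       Theta = exp(A_th))
}

# Full forward pass with caches for the backward pass. eps = NULL disables
# sampling (z = mu). `cols` restricts the likelihood heads to a column
# subset (stochastic feature subsampling for very wide inputs): the decoder
# still reconstructs all of Xbar, but Pi/M/V (and hence the NLL) are
# evaluated on the sampled columns only — an unbiased estimator of the full
# column sum after rescaling by k/|cols|.
vae_forward <- function(vae, X, eps = NULL, cols = NULL) {
  p <- vae$params
  h1 <- dense_relu(X, p$enc_W1, p$enc_b1)
  h2 <- dense_relu(h1, p$enc_W2, p$enc_b2)
  mu <- dense_linear(h2, p$W_mu, p$b_mu)
  lv <- clamp(dense_linear(h2, p$W_lv, p$b_lv), -15, 15)
  sig <- exp(0.5 * lv)
  z <- if (is.null(eps)) mu else mu + sig * eps
  g1 <- dense_relu(z, p$dec_W1, p$dec_b1)
  g2 <- dense_relu(g1, p$dec_W2, p$dec_b2)
  xbar <- dense_linear(g2, p$dec_W3, p$dec_b3)
  W_om <- if (is.null(cols)) p$W_om else p$W_om[, cols, drop = FALSE]
  W_th <- if (is.null(cols)) p$W_th else p$W_th[, cols, drop = FALSE]
  A_om <- clamp(xbar %*% W_om, -30, 30)
  A_th <- clamp(xbar %*% W_th, -30, 30)
  M <- if (vae$data_kind == "real" && vae$mean_activation == "identity")
    A_om else exp(A_om)
  V <- exp(A_th)
  if (vae$zero_inflated) {
    W_pi <- if (is.null(cols)) p$W_pi else p$W_pi[, cols, drop = FALSE]
    Pi <- clamp(sigmoid(xbar %*% W_pi), PI_EPS, 1 - PI_EPS)
  } else {
    Pi <- array(0, dim = dim(A_om))
  }
  list(h1 = h1, h2 = h2, mu = mu, lv = lv, sig = sig, eps = eps, z = z,
       g1 = g1, g2 = g2, xbar = xbar, Pi = Pi, M = M, V = V, cols = cols)
}

# Reconstruction NLL terms for a forward cache (rescaled to the full column
# count when the forward pass was column-subsampled).
vae_recon_terms <- function(vae, X, fw, lambda_pi) {
  Xs <- if (is.null(fw$cols)) X else X[, fw$cols, drop = FALSE]
  if (vae$data_kind == "count") {
    nll <- sum(nll_zinb_entries(Xs, fw$Pi, fw$M, fw$V))
  } else {
    nll <- sum(nll_zinormal_entries(Xs, fw$Pi, fw$M, fw$V))
  }
  pi_pen <- if (vae$zero_inflated) lambda_pi * sum(fw$Pi^2) else 0
  upscale <- if (is.null(fw$cols)) 1 else ncol(X) / length(fw$cols)
  list(nll = nll * upscale, pi_pen = pi_pen * upscale)
}

# Backward pass. d_mu_extra: extra gradient on mu (e.g. from CORAL),
# already scaled. scale multiplies the recon+kld entry sums (1/batch).
# Returns list(grads, recon, kld).
vae_backward <- function(vae, X, fw, lambda_pi, scale = 1,
                         d_mu_extra = NULL, sample = TRUE, kld_weight = 1) {
  p <- vae$params
  b <- nrow(X)
  cols <- fw$cols
  Xs <- if (is.null(cols)) X else X[, cols, drop = FALSE]
  upscale <- if (is.null(cols)) 1 else ncol(X) / length(cols)
  W_om <- if (is.null(cols)) p$W_om else p$W_om[, cols, drop = FALSE]
  W_th <- if (is.null(cols)) p$W_th else p$W_th[, cols, drop = FALSE]
  if (vae$data_kind == "count") {
    g <- grad_zinb(Xs, fw$Pi, fw$M, fw$V)
    dM <- g$dmu; dV <- g$dtheta
  } else {
    g <- grad_zinormal(Xs, fw$Pi, fw$M, fw$V)
    dM <- g$dmean; dV <- g$dvar
  }
  dPi <- g$dpi
  grads <- list()
  # heads (rescaled so the subsampled gradient is unbiased for the full sum)
  dA_om <- if (vae$data_kind == "real" && vae$mean_activation == "identity")
    dM else dM * fw$M
  dA_th <- dV * fw$V
  if (upscale != 1) { dA_om <- dA_om * upscale; dA_th <- dA_th * upscale }
  dxbar <- dA_om %*% t(W_om) + dA_th %*% t(W_th)
  grads$W_om <- head_grad(crossprod(fw$xbar, dA_om), cols)
  grads$W_th <- head_grad(crossprod(fw$xbar, dA_th), cols)
  if (vae$zero_inflated) {
    W_pi <- if (is.null(cols)) p$W_pi else p$W_pi[, cols, drop = FALSE]
    dPi_total <- dPi + 2 * lambda_pi * fw$Pi
    dA_pi <- dPi_total * fw$Pi * (1 - fw$Pi)
    if (upscale != 1) dA_pi <- dA_pi * upscale
    dxbar <- dxbar + dA_pi %*% t(W_pi)
    grads$W_pi <- head_grad(crossprod(fw$xbar, dA_pi), cols)
  }
  # decoder
  bk <- dense_linear_backward(fw$g2, p$dec_W3, dxbar)
  grads$dec_W3 <- bk$dW; grads$dec_b3 <- bk$db
  bk <- dense_relu_backward(fw$g1, p$dec_W2, fw$g2, bk$dx)
  grads$dec_W2 <- bk$dW; grads$dec_b2 <- bk$db
  bk <- dense_relu_backward(fw$z, p$dec_W1, fw$g1, bk$dx)
  grads$dec_W1 <- bk$dW; grads$dec_b1 <- bk$db
  dz <- bk$dx
  # KLD + reparameterization
  dmu <- dz + kld_weight * fw$mu                      # dKLD/dmu = mu
  dlv <- kld_weight * 0.5 * (exp(fw$lv) - 1)          # dKLD/dlogvar
  if (sample && !is.null(fw$eps)) dlv <- dlv + dz * 0.5 * fw$sig * fw$eps
  # scale the per-entry-sum objective, then add external mu gradient
  grads <- lapply(grads, scale_grad, scale = scale)
  dmu <- dmu * scale
  dlv <- dlv * scale
  if (!is.null(d_mu_extra)) dmu <- dmu + d_mu_extra
  # encoder
  bk_mu <- dense_linear_backward(fw$h2, p$W_mu, dmu)
  bk_lv <- dense_linear_backward(fw$h2, p$W_lv, dlv)
  grads$W_mu <- bk_mu$dW; grads$b_mu <- bk_mu$db
  grads$W_lv <- bk_lv$dW; grads$b_lv <- bk_lv$db
  bk <- dense_relu_backward(fw$h1, p$enc_W2, fw$h2, bk_mu$dx + bk_lv$dx)
  grads$enc_W2 <- bk$dW; grads$enc_b2 <- bk$db
  bk <- dense_relu_backward(X, p$enc_W1, fw$h1, bk$dx)
  grads$enc_W1 <- bk$dW; grads$enc_b1 <- bk$db
  grads
}

#' Stage II loss breakdown at the current weights
#'
#' Deterministic (no latent sampling: z = mu) evaluation of the five loss
#' terms: per-domain reconstruction NLL (plus the `lambda ||Pi||_F^2`
#' penalty) and KL divergence, and the CORAL loss between the posterior
#' means, together with their total
#' `recon_C + kld_C + recon_P + kld_P + coral`. All terms use the plain
#' entry-sum convention.
#'
#' @param XC,XP cell-line / patient data matrices (same feature count).
#' @param vaeC,vaeP the two domain VAEs.
#' @param config a [stage_two_config()].
#' @return List with `total`, `recon_C`, `kld_C`, `recon_P`, `kld_P`,
#'   `coral`.
#' @export
stage_two_loss <- function(XC, XP, vaeC, vaeP, config = stage_two_config()) {
  if (ncol(XC) != ncol(XP)) stop_panel("domain feature dimensions differ")
  fwC <- vae_forward(vaeC, XC)
  fwP <- vae_forward(vaeP, XP)
  rc <- vae_recon_terms(vaeC, XC, fwC, config$lambda_pi)
  rp <- vae_recon_terms(vaeP, XP, fwP, config$lambda_pi)
  kc <- kld_loss(fwC$mu, exp(0.5 * fwC$lv))
  kp <- kld_loss(fwP$mu, exp(0.5 * fwP$lv))
  cl <- config$coral_weight * coral_loss(fwC$mu, fwP$mu)
  recon_C <- rc$nll + rc$pi_pen
  recon_P <- rp$nll + rp$pi_pen
  list(total = recon_C + kc + recon_P + kp + cl,
       recon_C = recon_C, kld_C = kc, recon_P = recon_P, kld_P = kp,
       coral = cl)
}

check_finite_terms <- function(terms, epoch) {
  bad <- names(terms)[!vapply(terms, is.finite, logical(1))]
  if (length(bad)) {
    stop_panel("non-finite loss term(s) at epoch %d: %s", epoch,
               paste(bad, collapse = ", "))
  }
}

#' Train the two domain VAEs jointly
#'
#' Minimizes per-domain reconstruction + KLD plus the CORAL alignment loss
#' by Adam with reparameterized latent sampling (one Monte Carlo draw per
#' step). Every step draws equal-size minibatches independently from each
#' domain (the smaller domain is resampled with replacement), computes the
#' CORAL term on the batch posterior means, and updates both VAEs. The
#' per-batch entry sums are divided by the batch size before stepping; the
#' training log records these batch-scaled terms per epoch.
#'
#' @param XC,XP training matrices; `data_kind` attributes (see
#'   [domain_matrix()]) pick the likelihood, defaulting to `"real"`.
#' @param config a [stage_two_config()].
#' @return List with `vae_C`, `vae_P`, and `log` (data.frame: epoch,
#'   recon_C, kld_C, recon_P, kld_P, coral, total).
#' @export
train_domain_vaes <- function(XC, XP, config = stage_two_config()) {
  XC <- as.matrix(XC); XP <- as.matrix(XP)
  if (ncol(XC) != ncol(XP)) {
    stop_panel("domain feature dimensions differ (%d vs %d)",
               ncol(XC), ncol(XP))
  }
  set.seed(substream_seed(config$seed, "stage2"))
  vaeC <- new_domain_vae(ncol(XC), config, data_kind_of(XC))
  vaeP <- new_domain_vae(ncol(XP), config, data_kind_of(XP))
  stC <- adam_init(vaeC$params)
  stP <- adam_init(vaeP$params)
  # covariance gap between the full-cohort representations before training
  init_gap <- coral_loss(vae_encode(vaeC, XC), vae_encode(vaeP, XP))
  b <- min(config$batch_size, nrow(XC), nrow(XP))
  steps <- max(1L, ceiling(max(nrow(XC), nrow(XP)) / b))
  log <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    acc <- c(recon_C = 0, kld_C = 0, recon_P = 0, kld_P = 0, coral = 0)
    for (s in seq_len(steps)) {
      iC <- sample.int(nrow(XC), b, replace = nrow(XC) < b * steps)
      iP <- sample.int(nrow(XP), b, replace = nrow(XP) < b * steps)
      XCb <- XC[iC, , drop = FALSE]
      XPb <- XP[iP, , drop = FALSE]
      epsC <- matrix(stats::rnorm(b * config$d_z), b)
      epsP <- matrix(stats::rnorm(b * config$d_z), b)
      fs <- config$feature_subsample
      cols <- if (!is.null(fs) && fs < ncol(XC)) sort(sample.int(ncol(XC), fs))
      fwC <- vae_forward(vaeC, XCb, epsC, cols = cols)
      fwP <- vae_forward(vaeP, XPb, epsP, cols = cols)
      gcor <- grad_coral(fwC$mu, fwP$mu)
      gC <- vae_backward(vaeC, XCb, fwC, config$lambda_pi, scale = 1 / b,
                         d_mu_extra = config$coral_weight * gcor$dzC,
                         kld_weight = config$kld_weight)
      gP <- vae_backward(vaeP, XPb, fwP, config$lambda_pi, scale = 1 / b,
                         d_mu_extra = config$coral_weight * gcor$dzP,
                         kld_weight = config$kld_weight)
      rc <- vae_recon_terms(vaeC, XCb, fwC, config$lambda_pi)
      rp <- vae_recon_terms(vaeP, XPb, fwP, config$lambda_pi)
      terms <- list(recon_C = (rc$nll + rc$pi_pen) / b,
                    kld_C = kld_loss(fwC$mu, fwC$sig) / b,
                    recon_P = (rp$nll + rp$pi_pen) / b,
                    kld_P = kld_loss(fwP$mu, fwP$sig) / b,
                    coral = config$coral_weight * coral_loss(fwC$mu, fwP$mu))
      check_finite_terms(terms, epoch)
      acc <- acc + unlist(terms)
      up <- adam_step(vaeC$params, gC, stC, config$learning_rate)
      vaeC$params <- up$params; stC <- up$state
      up <- adam_step(vaeP$params, gP, stP, config$learning_rate)
      vaeP$params <- up$params; stP <- up$state
    }
    avg <- acc / steps
    log[[epoch]] <- data.frame(epoch = epoch, t(avg),
                               total = sum(avg))
  }
  log <- if (config$epochs) do.call(rbind, log) else
    data.frame(epoch = integer(), recon_C = numeric(), kld_C = numeric(),
               recon_P = numeric(), kld_P = numeric(), coral = numeric(),
               total = numeric())
  final_gap <- coral_loss(vae_encode(vaeC, XC), vae_encode(vaeP, XP))
  list(vae_C = vaeC, vae_P = vaeP, log = log,
       init_coral_gap = init_gap, final_coral_gap = final_gap)
}

#' Encode samples to their latent representations
#'
#' Returns the inferred posterior means (no sampling), the representation
#' used for all downstream tasks. Deterministic: encoding twice gives
#' bit-identical output.
#'
#' @param vae a `domain_vae`.
#' @param X matrix with `vae$d_in` columns.
#' @return `nrow(X) x d_z` matrix of latent means.
#' @export
vae_encode <- function(vae, X) {
  X <- as.matrix(X)
  if (ncol(X) != vae$d_in) {
    stop_panel("input has %d features but the VAE expects %d",
               ncol(X), vae$d_in)
  }
  p <- vae$params
  h2 <- dense_relu(dense_relu(X, p$enc_W1, p$enc_b1), p$enc_W2, p$enc_b2)
  dense_linear(h2, p$W_mu, p$b_mu)
}

#' Train one VAE pair per data modality and concatenate representations
#'
#' For multimodal inputs (e.g. real-valued annotated mutations plus count
#' CNV one-hots), a separate VAE pair is trained per block with the
#' likelihood chosen by the block's `data_kind`; downstream representations
#' are the column-concatenation of the per-block latent means in block
#' order. All blocks within a domain must share sample order (rownames).
#'
#' @param blocks_C,blocks_P named lists of matrices (same names/order).
#' @param config a [stage_two_config()]; each block trains with
#'   `seed = substream_seed(config$seed, block_name)`.
#' @return List with `fits` (per-block [train_domain_vaes()] results) and
#'   `encode(XC_blocks)`-style helper [encode_multimodal()] works on it.
#' @export
train_multimodal <- function(blocks_C, blocks_P, config = stage_two_config()) {
  stopifnot(length(blocks_C) == length(blocks_P), length(blocks_C) >= 1L)
  if (is.null(names(blocks_C))) names(blocks_C) <- paste0("block", seq_along(blocks_C))
  if (is.null(names(blocks_P))) names(blocks_P) <- names(blocks_C)
  check_block_order <- function(blocks, domain) {
    ref <- rownames(blocks[[1]])
    for (bl in blocks) {
      if (!identical(rownames(bl), ref)) {
        stop_panel("%s blocks disagree on sample order", domain)
      }
    }
  }
  check_block_order(blocks_C, "cell-line")
  check_block_order(blocks_P, "patient")
  fits <- lapply(seq_along(blocks_C), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L   # block 1 matches train_domain_vaes
    train_domain_vaes(blocks_C[[i]], blocks_P[[i]], cfg)
  })
  names(fits) <- names(blocks_C)
  structure(list(fits = fits, block_names = names(blocks_C)),
            class = "multimodal_vaes")
}

#' Concatenated multimodal representation
#'
#' @param mm a `multimodal_vaes` fit from [train_multimodal()].
#' @param blocks named list of matrices matching the training blocks.
#' @param domain `"CELL_LINE"` or `"PATIENT"`: which domain's encoders.
#' @return Matrix `n x (n_blocks * d_z)`.
#' @export
encode_multimodal <- function(mm, blocks, domain = c("CELL_LINE", "PATIENT")) {
  domain <- match.arg(domain)
  stopifnot(identical(names(blocks), mm$block_names))
  reps <- lapply(mm$block_names, function(nm) {
    vae <- if (domain == "CELL_LINE") mm$fits[[nm]]$vae_C else mm$fits[[nm]]$vae_P
    vae_encode(vae, blocks[[nm]])
  })
  do.call(cbind, reps)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are versioned containers holding the weights, a config echo,
#' the seed and the loss history; they round-trip exactly.
#'
#' @param object any model object (VAE pair, MTL model, ...).
#' @param config the configuration used to train it.
#' @param path file path.
#' @name checkpoints
#' @return `load_checkpoint` returns the saved list.
NULL

#' @rdname checkpoints
#' @export
save_checkpoint <- function(object, config, path) {
  saveRDS(list(format_version = 1L,
               package_version = as.character(utils::packageVersion("panelDRP")),
               config = config, seed = config$seed, object = object),
          path)
  invisible(path)
}

#' @rdname checkpoints
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version)) stop_panel("not a panelDRP checkpoint: %s", path)
  ck
}
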