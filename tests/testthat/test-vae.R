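# Stage II: zero-inflation heads, analytic gradients, joint training,
# encoding and the multimodal extension.

test_that("parameter heads follow the sigmoid/exp closed forms", {
  set.seed(1)
  k <- 6; b <- 4
  heads <- list(W_pi = matrix(rnorm(k * k, sd = 0.3), k),
                W_om = matrix(rnorm(k * k, sd = 0.3), k),
                W_th = matrix(rnorm(k * k, sd = 0.3), k))
  zero <- matrix(0, b, k)
  out <- zi_param_heads(zero, heads)
  expect_true(all(out$Pi == 0.5))
  expect_true(all(out$Omega == 1))
  expect_true(all(out$Theta == 1))

  xbar <- matrix(rnorm(b * k), b)
  out <- zi_param_heads(xbar, heads)
  expect_equal(out$Pi, 1 / (1 + exp(-xbar %*% heads$W_pi)), tolerance = 1e-9)
  expect_equal(out$Omega, exp(xbar %*% heads$W_om), tolerance = 1e-9)
  expect_equal(out$Theta, exp(xbar %*% heads$W_th), tolerance = 1e-9)

  # Pi is monotone in the pre-activation
  bumped <- xbar; bumped[2, ] <- bumped[2, ] + solve(t(heads$W_pi), rep(1, k))
  expect_true(all(zi_param_heads(bumped, heads)$Pi[2, ] > out$Pi[2, ]))

  expect_error(zi_param_heads(matrix(NaN, 2, k), heads), "non-finite")
})

test_that("analytic VAE gradients agree with finite differences", {
  cfg <- stage_two_config(d_z = 2L, hidden = c(4L, 4L), lambda_pi = 0.01)
  k <- 5; b <- 4
  for (kind in c("real", "count")) {
    # seed chosen away from ReLU kinks (finite differences cross them)
    set.seed(13)
    vae <- new_domain_vae(k, cfg, kind)
    vae$params <- lapply(vae$params, function(p) p * 0.3)
    X <- if (kind == "count") matrix(rpois(b * k, 0.8), b) else
      matrix(rpois(b * k, 1) * abs(rnorm(b * k)), b)
    eps <- matrix(rnorm(b * cfg$d_z), b)
    objective <- function(params) {
      v <- vae; v$params <- params
      fw <- panelDRP:::vae_forward(v, X, eps)
      rt <- panelDRP:::vae_recon_terms(v, X, fw, cfg$lambda_pi)
      rt$nll + rt$pi_pen + kld_loss(fw$mu, exp(0.5 * fw$lv))
    }
    fw <- panelDRP:::vae_forward(vae, X, eps)
    analytic <- panelDRP:::vae_backward(vae, X, fw, cfg$lambda_pi)
    numeric <- numerical_gradient(objective, vae$params)
    for (nm in names(numeric)) {
      denom <- max(1, max(abs(numeric[[nm]])))
      expect_lt(max(abs(analytic[[nm]] - numeric[[nm]])) / denom, 1e-4)
    }
  }
})

test_that("CORAL gradient agrees with finite differences", {
  set.seed(12)
  zC <- matrix(rnorm(15), 5, 3)
  zP <- matrix(rnorm(12), 4, 3)
  g <- panelDRP:::grad_coral(zC, zP)
  for (mat in c("C", "P")) {
    z <- if (mat == "C") zC else zP
    num <- z * 0
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- zp[i] + 1e-6
      zm <- z; zm[i] <- zm[i] - 1e-6
      num[i] <- if (mat == "C") {
        (coral_loss(zp, zP) - coral_loss(zm, zP)) / 2e-6
      } else {
        (coral_loss(zC, zp) - coral_loss(zC, zm)) / 2e-6
      }
    }
    expect_lt(max(abs((if (mat == "C") g$dzC else g$dzP) - num)), 1e-6)
  }
})

test_that("stage-two loss is the sum of its five reported terms", {
  dm <- shifted_domain_matrices(20, 15, 8, seed = 21)
  cfg <- tiny_stage2(seed = 7L)
  set.seed(7)
  vaeC <- new_domain_vae(8, cfg, "real")
  vaeP <- new_domain_vae(8, cfg, "real")
  terms <- stage_two_loss(dm$XC, dm$XP, vaeC, vaeP, cfg)
  expect_equal(terms$total,
               terms$recon_C + terms$kld_C + terms$recon_P + terms$kld_P +
                 terms$coral, tolerance = 1e-9)
  # components match their independent oracles (deterministic z = mu)
  fwC <- panelDRP:::vae_forward(vaeC, dm$XC)
  expect_equal(terms$kld_C, kld_loss(fwC$mu, exp(0.5 * fwC$lv)))
  expect_equal(terms$recon_C,
               nll_zinormal(dm$XC, fwC$Pi, fwC$M, fwC$V) +
                 cfg$lambda_pi * sum(fwC$Pi^2), tolerance = 1e-8)
  fwP <- panelDRP:::vae_forward(vaeP, dm$XP)
  expect_equal(terms$coral,
               cfg$coral_weight * coral_loss(fwC$mu, fwP$mu))

  # identical batches with coral only: alignment term vanishes
  same <- stage_two_loss(dm$XC, dm$XC, vaeC, vaeC, cfg)
  expect_equal(same$coral, 0)
})

test_that("disabling zero inflation reproduces the plain likelihood", {
  dm <- shifted_domain_matrices(12, 12, 6, seed = 31)
  cfg <- tiny_stage2(zero_inflated = FALSE, lambda_pi = 0, seed = 3L)
  set.seed(3)
  vae <- new_domain_vae(6, cfg, "real")
  fw <- panelDRP:::vae_forward(vae, dm$XC)
  plain <- -sum(dnorm(dm$XC, fw$M, sqrt(fw$V), log = TRUE))
  rt <- panelDRP:::vae_recon_terms(vae, dm$XC, fw, 0)
  expect_equal(rt$nll, plain, tolerance = 1e-8)
  expect_equal(rt$pi_pen, 0)
})

test_that("joint training reduces the loss deterministically", {
  set.seed(41)
  XC <- matrix(rpois(100 * 50, 0.5) * abs(rnorm(100 * 50)), 100)
  XP <- matrix(rpois(100 * 50, 0.8) * abs(rnorm(100 * 50, 1.2)), 100)
  cfg <- stage_two_config(d_z = 8L, hidden = c(24L, 24L), epochs = 8L,
                          batch_size = 50L, seed = 13L)
  fit <- train_domain_vaes(XC, XP, cfg)
  expect_true(all(is.finite(as.matrix(fit$log[-1]))))
  expect_lte(fit$log$total[nrow(fit$log)], fit$log$total[1])
  expect_named(fit$log, c("epoch", "recon_C", "kld_C", "recon_P", "kld_P",
                          "coral", "total"))

  fit2 <- train_domain_vaes(XC, XP, cfg)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$vae_C$params$enc_W1, fit2$vae_C$params$enc_W1)
})

test_that("column-subsampled training gives finite decreasing loss", {
  dm <- shifted_domain_matrices(60, 40, 30, seed = 51)
  cfg <- stage_two_config(d_z = 8L, hidden = c(16L, 16L), epochs = 6L,
                          batch_size = 30L, feature_subsample = 10L,
                          seed = 5L)
  fit <- train_domain_vaes(dm$XC, dm$XP, cfg)
  expect_true(all(is.finite(as.matrix(fit$log[-1]))))
  expect_lte(fit$log$total[nrow(fit$log)], fit$log$total[1])
  # same seed reproduces despite the extra column randomness
  fit2 <- train_domain_vaes(dm$XC, dm$XP, cfg)
  expect_identical(fit$log, fit2$log)
})

test_that("training shrinks the representation covariance gap", {
  dm <- shifted_domain_matrices(80, 60, 25, seed = 61)
  cfg <- stage_two_config(d_z = 16L, hidden = c(32L, 32L), epochs = 15L,
                          batch_size = 40L, coral_weight = 10, seed = 9L)
  fit <- train_domain_vaes(dm$XC, dm$XP, cfg)
  expect_lt(fit$final_coral_gap, fit$init_coral_gap)
})

test_that("encoding is deterministic with the contracted shape", {
  dm <- shifted_domain_matrices(10, 10, 6, seed = 71)
  fit <- train_domain_vaes(dm$XC, dm$XP, tiny_stage2(epochs = 2L, seed = 1L))
  Z <- vae_encode(fit$vae_C, dm$XC)
  expect_equal(dim(Z), c(10L, 8L))
  expect_identical(Z, vae_encode(fit$vae_C, dm$XC))
  X2 <- dm$XC[c(1, 1, 3), ]
  Z2 <- vae_encode(fit$vae_C, X2)
  expect_identical(Z2[1, ], Z2[2, ])
  expect_error(vae_encode(fit$vae_C, dm$XC[, 1:3]), "expects")
})

test_that("multimodal training concatenates per-block representations", {
  dm1 <- shifted_domain_matrices(20, 15, 6, seed = 81)
  set.seed(82)
  cnvC <- matrix(rbinom(20 * 9, 1L, 0.3), 20)
  cnvP <- matrix(rbinom(15 * 9, 1L, 0.4), 15)
  rownames(dm1$XC) <- rownames(cnvC) <- paste0("C", 1:20)
  rownames(dm1$XP) <- rownames(cnvP) <- paste0("P", 1:15)
  blocksC <- list(mut = dm1$XC, cnv = domain_matrix(cnvC, "CELL_LINE", "count"))
  blocksP <- list(mut = dm1$XP, cnv = domain_matrix(cnvP, "PATIENT", "count"))
  cfg <- tiny_stage2(epochs = 2L, seed = 6L)
  mm <- train_multimodal(blocksC, blocksP, cfg)
  expect_equal(mm$fits$cnv$vae_C$data_kind, "count")
  Z <- encode_multimodal(mm, blocksC, "CELL_LINE")
  expect_equal(dim(Z), c(20L, 16L))   # two blocks x d_z = 8

  # single block degenerates to train_domain_vaes with the same substream
  single <- train_multimodal(blocksC["mut"], blocksP["mut"], cfg)
  cfg1 <- cfg; cfg1$seed <- cfg$seed
  ref <- train_domain_vaes(dm1$XC, dm1$XP, cfg1)
  expect_equal(single$fits$mut$log, ref$log)

  bad <- blocksP
  rownames(bad$cnv) <- rev(rownames(bad$cnv))
  expect_error(train_multimodal(blocksC, bad, cfg), "sample order")
})

test_that("checkpoints round-trip exactly", {
  dm <- shifted_domain_matrices(10, 10, 5, seed = 91)
  cfg <- tiny_stage2(epochs = 1L, seed = 4L)
  fit <- train_domain_vaes(dm$XC, dm$XP, cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit, cfg, path)
  ck <- load_checkpoint(path)
  expect_identical(ck$object$vae_C$params, fit$vae_C$params)
  expect_identical(ck$seed, cfg$seed)
  expect_identical(ck$config, cfg)
  unlink(path)
})
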