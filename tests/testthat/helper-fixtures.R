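# Shared fixture builders. Everything is generated in code; nothing is read
# from disk.

# A hand-written call table with known classifications.
toy_calls <- function() {
  data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S2"),
    gene_symbol = c("TP53", "KRAS", "TP53", "KRAS", "BRCA1"),
    variant_classification = c("Missense_Mutation", "In_Frame_Del",
                               "Silent", "Splice_Site", "3'UTR"),
    mutation_key = paste0("m", 1:5),
    stringsAsFactors = FALSE)
}

# Annotation rows for the given keys with controllable categories/flags.
toy_annotations <- function(keys, sample_ids, genes,
                            clinvar = "Uncertain_significance",
                            gpd = "PIU", n_flags_true = 5L) {
  ann <- data.frame(mutation_key = keys, sample_id = sample_ids,
                    gene = genes,
                    clinvar_raw = rep_len(clinvar, length(keys)),
                    gpd_category = rep_len(gpd, length(keys)),
                    stringsAsFactors = FALSE)
  flags <- t(vapply(rep_len(n_flags_true, length(keys)),
                    function(k) as.integer(seq_len(17) <= k), integer(17)))
  ann[paste0("alg_", 1:17)] <- flags
  ann
}

# Random annotated-mutation data.frame for aggregation tests.
random_mutations <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    gpd_category = sample(gpd_categories(), n, replace = TRUE),
    clinvar_category = sample(clinvar_categories(), n, replace = TRUE),
    dscore = sample(0:17, n, replace = TRUE) / 17,
    stringsAsFactors = FALSE)
}

# Independent re-aggregation oracle: group-by loops, one statistic at a time.
aggregate_oracle <- function(mutations) {
  out <- numeric(24)
  idx <- 0
  for (cat in feature_categories()) {
    in_cat <- if (cat %in% gpd_categories()) {
      mutations$gpd_category == cat
    } else {
      mutations$clinvar_category == cat
    }
    d <- mutations$dscore[in_cat]
    vals <- if (length(d) == 0) c(0, 0, 0, 0) else
      c(mean(d), max(d), sum(d), length(d))
    out[idx + 1:4] <- vals
    idx <- idx + 4
  }
  out
}

# Small two-domain matrices with a mean/scale shift for VAE tests.
shifted_domain_matrices <- function(n_c = 60, n_p = 40, k = 20, seed = 1) {
  set.seed(seed)
  mask_c <- matrix(rbinom(n_c * k, 1, 0.4), n_c)
  mask_p <- matrix(rbinom(n_p * k, 1, 0.25), n_p)
  XC <- mask_c * abs(matrix(rnorm(n_c * k, 1.0, 0.5), n_c))
  XP <- mask_p * abs(matrix(rnorm(n_p * k, 1.6, 0.8), n_p))
  list(XC = XC, XP = XP)
}

# A tiny labeled cohort for MTL tests (fast to train).
tiny_labeled_cohort <- function(seed = 5) {
  cfg <- simulation_config(n_cell = 80L, n_patient = 50L, G = 20L,
                           n_drugs = 2L, fp_length = 32L,
                           n_signal_genes = 6L, seed = seed)
  plant_response_signal(generate_cohort(cfg))
}

# Stage II/III configs small enough for unit tests.
tiny_stage2 <- function(epochs = 4L, ...) {
  stage_two_config(d_z = 8L, hidden = c(16L, 16L), epochs = epochs,
                   batch_size = 32L, learning_rate = 1e-3, ...)
}

tiny_stage3 <- function(epochs = 10L, ...) {
  stage_three_config(epochs = epochs, batch_size = 32L, embed_dim = 8L,
                     hidden = 16L, ...)
}

# Train the tiny cohort end to end once and memoize; several MTL tests
# inspect the same fitted model.
tiny_fit_cache <- new.env(parent = emptyenv())

tiny_fitted <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    coh <- tiny_labeled_cohort()
    prof <- coh$profiles
    fit2 <- train_domain_vaes(prof$CELL_LINE, prof$PATIENT,
                              tiny_stage2(seed = 2L))
    resp <- coh$responses
    cell <- resp[resp$domain == "CELL_LINE", ]
    cell$label <- as.numeric(cell$label)
    pat <- resp[resp$domain == "PATIENT", ]
    pat$label <- binarize_recist(pat$label)
    fit3 <- train_mtl(cell, pat, fit2$vae_C, fit2$vae_P,
                      prof$CELL_LINE, prof$PATIENT, coh$drugs,
                      tiny_stage3(seed = 3L, epochs = 40L,
                                  fine_tune_encoders = TRUE))
    tiny_fit_cache$fit <- list(cohort = coh, fit2 = fit2, fit3 = fit3,
                               cell = cell, pat = pat)
  }
  tiny_fit_cache$fit
}

# Finite-difference gradient of f at params (lists of arrays).
numerical_gradient <- function(f, params, eps = 1e-5) {
  g <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    p <- params[[nm]]
    for (i in seq_along(p)) {
      up <- params; up[[nm]][i] <- p[i] + eps
      dn <- params; dn[[nm]][i] <- p[i] - eps
      g[[nm]][i] <- (f(up) - f(dn)) / (2 * eps)
    }
  }
  g
}
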