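# Two-domain synthetic cohort simulator.
#
# Emulates the inputs the pipeline consumes — MAF-style mutation calls,
# per-mutation annotation tables, per-gene CNV categories, binary drug
# fingerprints and response labels — for a cell-line domain and a patient
# domain with configurable sparsity and domain shift, plus a planted
# mutation-to-response signal that is linear in the Stage I feature map
# (deliberately inside the model class, so signal recovery is a fair test
# of the whole pipeline).

#' Simulation configuration
#'
#' Per-domain knobs are length-2 vectors / 2-row inputs named
#' `c("CELL_LINE", "PATIENT")`. Defaults describe a mid-size two-domain
#' study: 600 cell lines vs 200 patients on a 100-gene panel with 4 drugs,
#' moderately sparse mutation profiles (about 6 and 4 mutated genes per
#' sample), a mild annotation-distribution shift between domains, 10%
#' RECIST label flips and median-threshold responders.
#'
#' @param n_cell,n_patient cohort sizes.
#' @param G panel size (genes are named g001, g002, ...).
#' @param mean_mutations per-domain mean number of mutated genes per sample
#'   (truncated-Poisson, the single sparsity knob).
#' @param extra_mutation_rate Poisson rate of additional mutations within an
#'   already-mutated gene (exercises multi-mutation aggregation).
#' @param gpd_probs,clinvar_probs per-domain category probability vectors
#'   (2 x 3 matrices, rows CELL_LINE / PATIENT); rows must sum to 1. The
#'   defaults shift patients toward non-coding and VUS calls.
#' @param flag_prob per-domain per-algorithm deleteriousness probability.
#' @param cnv_probs probabilities of (loss, no_change, amplification).
#' @param n_drugs,fp_length number of drugs and fingerprint bit length.
#' @param fp_density expected fraction of set fingerprint bits.
#' @param n_signal_genes number of panel genes carrying planted weights.
#' @param signal_scale standard deviation of nonzero planted weights.
#' @param drug_effect_scale scale of the per-drug fingerprint effect.
#' @param audrc_noise_sd Gaussian noise added to standardized AUDRC labels.
#' @param recist_flip_prob probability of flipping a patient's binary
#'   response label.
#' @param responder_quantile quantile of the patient score distribution used
#'   as the responder threshold (0.5 = median split).
#' @param seed integer seed; all realizations are functions of (config, seed).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cell = 600L, n_patient = 200L, G = 100L,
                              mean_mutations = c(CELL_LINE = 6, PATIENT = 4),
                              extra_mutation_rate = 0.3,
                              gpd_probs = rbind(
                                CELL_LINE = c(PIU = 0.55, LU = 0.25, NCU = 0.20),
                                PATIENT = c(PIU = 0.40, LU = 0.25, NCU = 0.35)),
                              clinvar_probs = rbind(
                                CELL_LINE = c(PATHOGENIC = 0.35, BENIGN = 0.15, VUS = 0.50),
                                PATIENT = c(PATHOGENIC = 0.25, BENIGN = 0.10, VUS = 0.65)),
                              flag_prob = c(CELL_LINE = 0.45, PATIENT = 0.35),
                              cnv_probs = c(loss = 0.1, no_change = 0.8,
                                            amplification = 0.1),
                              n_drugs = 4L, fp_length = 128L,
                              fp_density = 0.3,
                              n_signal_genes = 15L, signal_scale = 1.0,
                              drug_effect_scale = 0.5,
                              audrc_noise_sd = 0.1,
                              recist_flip_prob = 0.1,
                              responder_quantile = 0.5,
                              seed = 1L) {
  check_probs <- function(p, what) {
    if (any(p < 0) || any(p > 1)) stop_panel("%s must be in [0, 1]", what)
  }
  check_simplex <- function(m, what) {
    check_probs(m, what)
    if (any(abs(rowSums(m) - 1) > 1e-8)) {
      stop_panel("%s rows must sum to 1", what)
    }
  }
  check_simplex(gpd_probs, "gpd_probs")
  check_simplex(clinvar_probs, "clinvar_probs")
  check_simplex(matrix(cnv_probs, 1), "cnv_probs")
  check_probs(flag_prob, "flag_prob")
  check_probs(recist_flip_prob, "recist_flip_prob")
  stopifnot(n_cell > 0, n_patient > 0, G > 0, n_drugs > 0, fp_length > 0,
            all(mean_mutations >= 0), responder_quantile > 0,
            responder_quantile < 1)
  structure(list(n_cell = as.integer(n_cell), n_patient = as.integer(n_patient),
                 G = as.integer(G), mean_mutations = mean_mutations,
                 extra_mutation_rate = extra_mutation_rate,
                 gpd_probs = gpd_probs, clinvar_probs = clinvar_probs,
                 flag_prob = flag_prob, cnv_probs = cnv_probs,
                 n_drugs = as.integer(n_drugs),
                 fp_length = as.integer(fp_length), fp_density = fp_density,
                 n_signal_genes = as.integer(n_signal_genes),
                 signal_scale = signal_scale,
                 drug_effect_scale = drug_effect_scale,
                 audrc_noise_sd = audrc_noise_sd,
                 recist_flip_prob = recist_flip_prob,
                 responder_quantile = responder_quantile,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# ClinVar raw strings the simulator emits per category (exercises the
# mapping, including multi-word raw values).
clinvar_raw_pool <- function() {
  list(PATHOGENIC = c("Pathogenic", "Likely_pathogenic"),
       BENIGN = c("Benign", "Likely_benign"),
       VUS = c("Uncertain_significance", "not_provided"))
}

#' Generate a two-domain synthetic cohort
#'
#' Per sample the number of mutated genes is truncated-Poisson; mutated
#' genes are drawn uniformly without replacement and each carries
#' `1 + Poisson(extra_mutation_rate)` mutations whose GPD and ClinVar
#' categories follow the domain's probability vectors and whose 17
#' deleteriousness flags are iid Bernoulli. CNV categories are iid per
#' (sample, gene). Drug fingerprints are iid Bernoulli bits. Deterministic
#' given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A `synthetic_cohort` list: `panel`, `calls`, `annotations`,
#'   `cnv`, `drugs` (fingerprint matrix, drug ids in rownames), `samples`
#'   (data.frame sample_id, domain), `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  set.seed(substream_seed(config$seed, "simulate"))
  panel <- sprintf("g%03d", seq_len(config$G))
  samples <- data.frame(
    sample_id = c(sprintf("CL%04d", seq_len(config$n_cell)),
                  sprintf("PT%04d", seq_len(config$n_patient))),
    domain = rep(c("CELL_LINE", "PATIENT"),
                 c(config$n_cell, config$n_patient)),
    stringsAsFactors = FALSE)

  calls <- list(); annos <- list()
  pool <- clinvar_raw_pool()
  vclasses <- retained_variant_classes()
  key_counter <- 0L
  for (i in seq_len(nrow(samples))) {
    dom <- samples$domain[i]
    n_genes <- min(stats::rpois(1L, config$mean_mutations[[dom]]), config$G)
    if (n_genes == 0L) next
    genes <- sample(panel, n_genes)
    n_per_gene <- 1L + stats::rpois(n_genes, config$extra_mutation_rate)
    gene_of <- rep(genes, n_per_gene)
    m <- length(gene_of)
    keys <- sprintf("m%07d", key_counter + seq_len(m))
    key_counter <- key_counter + m
    cat_gpd <- sample(gpd_categories(), m, replace = TRUE,
                      prob = config$gpd_probs[dom, ])
    cat_clin <- sample(clinvar_categories(), m, replace = TRUE,
                       prob = config$clinvar_probs[dom, ])
    raw_clin <- vapply(cat_clin, function(cc) sample(pool[[cc]], 1L), "")
    flags <- matrix(stats::rbinom(m * 17L, 1L, config$flag_prob[[dom]]),
                    nrow = m)
    calls[[i]] <- data.frame(
      sample_id = samples$sample_id[i], gene_symbol = gene_of,
      variant_classification = sample(vclasses, m, replace = TRUE),
      mutation_key = keys, stringsAsFactors = FALSE)
    ann <- data.frame(mutation_key = keys, sample_id = samples$sample_id[i],
                      gene = gene_of, clinvar_raw = unname(raw_clin),
                      gpd_category = cat_gpd, stringsAsFactors = FALSE)
    ann[annotation_flag_columns()] <- flags
    annos[[i]] <- ann
  }
  calls <- do.call(rbind, calls)
  annotations <- do.call(rbind, annos)
  rownames(calls) <- rownames(annotations) <- NULL

  cnv_cat <- sample(cnv_categories(), nrow(samples) * config$G,
                    replace = TRUE, prob = config$cnv_probs)
  cnv <- data.frame(sample_id = rep(samples$sample_id, each = config$G),
                    gene = rep(panel, nrow(samples)),
                    category = cnv_cat, stringsAsFactors = FALSE)

  drugs <- matrix(stats::rbinom(config$n_drugs * config$fp_length, 1L,
                                config$fp_density),
                  nrow = config$n_drugs,
                  dimnames = list(sprintf("drug%02d", seq_len(config$n_drugs)),
                                  NULL))

  structure(list(panel = panel, calls = calls, annotations = annotations,
                 cnv = cnv, drugs = drugs, samples = samples,
                 config = config),
            class = "synthetic_cohort")
}

#' Plant a mutation-to-response signal and emit labels
#'
#' A sparse ground-truth weight vector `w` over the canonical Stage I
#' feature columns defines a sample score `s = phi(x) . w`; weights sit on
#' annotation-bearing columns (pathogenic/protein-unit means and sums and
#' the VUS count) of the signal genes, so the signal is recoverable from
#' annotated features but only partially from mutation presence alone.
#' Per (sample, drug) the latent response is `r = s + u_drug . fp`; cell
#' lines receive `AUDRC = standardize(r) + N(0, sd)`, patients receive a
#' binary responder label `r > threshold` flipped with the configured
#' probability, then mapped to RECIST categories (responders uniformly
#' CR/PR, non-responders uniformly SD/PD).
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @return The cohort with added `responses` (data.frame `sample_id`,
#'   `drug_id`, `domain`, `label`), `profiles` (per-domain matrices), and
#'   `truth` (list: `w`, `drug_effects`, `scores`, `threshold`,
#'   `true_binary`).
#' @export
plant_response_signal <- function(cohort) {
  config <- cohort$config
  set.seed(substream_seed(config$seed, "plant"))
  profiles <- cohort_profiles(cohort)

  cols <- profile_column_names(cohort$panel)
  w <- numeric(length(cols)); names(w) <- cols
  signal_genes <- sample(cohort$panel, min(config$n_signal_genes, config$G))
  target_feats <- c("PATHOGENIC__mean", "PATHOGENIC__sum", "PIU__mean",
                    "PIU__sum", "VUS__count")
  for (g in signal_genes) {
    feats <- paste(g, target_feats, sep = "__")
    w[feats] <- stats::rnorm(length(feats), sd = config$signal_scale)
  }
  drug_effects <- matrix(stats::rnorm(nrow(cohort$drugs) * ncol(cohort$drugs),
                                      sd = config$drug_effect_scale /
                                        sqrt(ncol(cohort$drugs))),
                         nrow = nrow(cohort$drugs),
                         dimnames = dimnames(cohort$drugs))
  u <- rowSums(cohort$drugs * drug_effects)      # per-drug scalar effect

  score_C <- as.vector(profiles$CELL_LINE %*% w)
  score_P <- as.vector(profiles$PATIENT %*% w)
  names(score_C) <- rownames(profiles$CELL_LINE)
  names(score_P) <- rownames(profiles$PATIENT)

  drug_ids <- rownames(cohort$drugs)
  grid_C <- expand.grid(sample_id = names(score_C), drug_id = drug_ids,
                        stringsAsFactors = FALSE)
  grid_P <- expand.grid(sample_id = names(score_P), drug_id = drug_ids,
                        stringsAsFactors = FALSE)
  r_C <- score_C[grid_C$sample_id] + u[grid_C$drug_id]
  r_P <- score_P[grid_P$sample_id] + u[grid_P$drug_id]

  audrc <- as.vector(scale(r_C)) +
    stats::rnorm(length(r_C), sd = config$audrc_noise_sd)

  threshold <- stats::quantile(r_P, config$responder_quantile, names = FALSE)
  if (threshold <= min(r_P) || threshold >= max(r_P)) {
    warning("responder threshold outside the observed score range; labels degenerate",
            call. = FALSE)
  }
  true_binary <- as.integer(r_P > threshold)
  flip <- stats::rbinom(length(true_binary), 1L, config$recist_flip_prob)
  observed <- ifelse(flip == 1L, 1L - true_binary, true_binary)
  recist <- ifelse(observed == 1L,
                   sample(c("CR", "PR"), length(observed), replace = TRUE),
                   sample(c("SD", "PD"), length(observed), replace = TRUE))

  responses <- rbind(
    data.frame(sample_id = grid_C$sample_id, drug_id = grid_C$drug_id,
               domain = "CELL_LINE", label = as.character(round(audrc, 6)),
               stringsAsFactors = FALSE),
    data.frame(sample_id = grid_P$sample_id, drug_id = grid_P$drug_id,
               domain = "PATIENT", label = recist, stringsAsFactors = FALSE))

  cohort$profiles <- profiles
  cohort$responses <- responses
  cohort$truth <- list(w = w, drug_effects = u, signal_genes = signal_genes,
                       scores = list(CELL_LINE = score_C, PATIENT = score_P),
                       latent = list(CELL_LINE = r_C, PATIENT = r_P),
                       threshold = threshold, true_binary = true_binary,
                       observed_binary = observed)
  cohort
}

#' Stage I profile matrices of a synthetic cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return List of matrices `CELL_LINE` and `PATIENT` (all samples of the
#'   domain, including mutation-free ones).
#' @export
cohort_profiles <- function(cohort) {
  out <- lapply(c(CELL_LINE = "CELL_LINE", PATIENT = "PATIENT"), function(dom) {
    ids <- cohort$samples$sample_id[cohort$samples$domain == dom]
    build_profile_matrix(cohort$calls[cohort$calls$sample_id %in% ids, ,
                                      drop = FALSE],
                         cohort$annotations, cohort$panel, sample_ids = ids)
  })
  out
}

#' Binary mutation-presence matrices of a synthetic cohort
#'
#' One column per panel gene; 1 iff the sample has at least one retained
#' coding mutation in the gene. This is the input of the
#' annotation-ablated model variant.
#'
#' @param cohort a `synthetic_cohort`.
#' @return List of 0/1 matrices `CELL_LINE` and `PATIENT`.
#' @export
cohort_binary_profiles <- function(cohort) {
  calls <- filter_coding_mutations(cohort$calls)
  lapply(c(CELL_LINE = "CELL_LINE", PATIENT = "PATIENT"), function(dom) {
    ids <- cohort$samples$sample_id[cohort$samples$domain == dom]
    mat <- matrix(0, length(ids), length(cohort$panel),
                  dimnames = list(ids, cohort$panel))
    sub <- calls[calls$sample_id %in% ids &
                   calls$gene_symbol %in% cohort$panel, , drop = FALSE]
    if (nrow(sub)) {
      mat[cbind(match(sub$sample_id, ids),
                match(sub$gene_symbol, cohort$panel))] <- 1
    }
    mat
  })
}
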