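# Stage I: coding filter, d-score, category mapping, gene-level
# aggregation and the profile matrix layout.

test_that("coding filter keeps the nine retained classes and drops the rest", {
  keep <- data.frame(sample_id = "S", gene_symbol = "G",
                     variant_classification = retained_variant_classes(),
                     mutation_key = paste0("k", 1:9))
  expect_equal(nrow(filter_coding_mutations(keep)), 9L)

  expect_equal(nrow(filter_coding_mutations(toy_calls())), 3L)
  expect_equal(filter_coding_mutations(toy_calls())$mutation_key,
               c("m1", "m2", "m4"))

  empty <- toy_calls()[0, ]
  expect_equal(nrow(filter_coding_mutations(empty)), 0L)

  bad <- toy_calls()
  bad$variant_classification[2] <- ""
  expect_error(filter_coding_mutations(bad), "empty variant_classification")
})

test_that("d-score is the fraction of 17 deleteriousness flags", {
  expect_equal(compute_dscore(rep(TRUE, 17)), 1.0)
  expect_equal(compute_dscore(rep(FALSE, 17)), 0.0)
  expect_equal(compute_dscore(c(rep(1, 5), rep(0, 12))), 0.29412,
               tolerance = 1e-4)
  expect_error(compute_dscore(rep(TRUE, 16)), "exactly 17")
  expect_error(compute_dscore(rep(2, 17)), "0/1")
})

test_that("ClinVar mapping covers the vocabulary and falls back to VUS", {
  expect_equal(map_clinvar_category("Pathogenic"), "PATHOGENIC")
  expect_equal(map_clinvar_category("Likely_pathogenic"), "PATHOGENIC")
  expect_equal(map_clinvar_category("Benign"), "BENIGN")
  expect_equal(map_clinvar_category("Uncertain_significance"), "VUS")
  expect_equal(map_clinvar_category("foo"), "VUS")
  expect_equal(map_clinvar_category("Benign/Likely_benign"), "BENIGN")
  expect_equal(map_clinvar_category(c("pathogenic", "BENIGN", "x")),
               c("PATHOGENIC", "BENIGN", "VUS"))
})

test_that("gene aggregation produces the 24 canonical statistics", {
  empty <- aggregate_gene_features(random_mutations(0))
  expect_length(empty, 24L)
  expect_true(all(empty == 0))

  two <- data.frame(gpd_category = c("PIU", "PIU"),
                    clinvar_category = c("VUS", "VUS"),
                    dscore = c(0.2, 0.4))
  block <- aggregate_gene_features(two)
  expect_equal(unname(block[1:4]), c(0.3, 0.4, 0.6, 2))     # PIU
  expect_equal(unname(block[21:24]), c(0.3, 0.4, 0.6, 2))   # VUS
  expect_true(all(block[5:20] == 0))                        # LU..BENIGN

  for (seed in 1:5) {
    m <- random_mutations(50, seed)
    expect_equal(unname(aggregate_gene_features(m)), aggregate_oracle(m))
  }
})

test_that("profile matrix has the canonical gene-major layout", {
  panel324 <- sprintf("G%03d", 1:324)
  calls <- data.frame(sample_id = "S1", gene_symbol = "G001",
                      variant_classification = "Missense_Mutation",
                      mutation_key = "m1")
  ann <- toy_annotations("m1", "S1", "G001")
  mat <- build_profile_matrix(calls, ann, panel324)
  expect_equal(ncol(mat), 7776L)
  expect_equal(ncol(mat) / length(panel324), 24)

  # mutation-free sample on a 2-gene panel: all-zero row of width 48
  mat2 <- build_profile_matrix(calls, ann, c("G001", "G002"),
                               sample_ids = c("S1", "S0"))
  expect_equal(ncol(mat2), 48L)
  expect_true(all(mat2["S0", ] == 0))
  expect_true(all(mat2["S1", 25:48] == 0))    # G002 block empty

  # d-score 5/17 lands in PIU and VUS blocks of G001
  expect_equal(unname(mat2["S1", "G001__PIU__mean"]), 5 / 17)
  expect_equal(unname(mat2["S1", "G001__VUS__count"]), 1)
})

test_that("profile matrix equals the per-gene aggregation oracle", {
  cfg <- simulation_config(n_cell = 3L, n_patient = 3L, G = 10L,
                           mean_mutations = c(CELL_LINE = 5, PATIENT = 5),
                           seed = 42L)
  coh <- generate_cohort(cfg)
  ids <- coh$samples$sample_id
  mat <- build_profile_matrix(coh$calls, coh$annotations, coh$panel,
                              sample_ids = ids)
  ann <- annotate_mutations(filter_coding_mutations(coh$calls),
                            coh$annotations)
  for (s in ids) {
    for (gi in seq_along(coh$panel)) {
      g <- coh$panel[gi]
      sub <- ann[ann$sample_id == s & ann$gene_symbol == g, ]
      expect_equal(unname(mat[s, (gi - 1) * 24 + 1:24]),
                   aggregate_oracle(sub))
    }
  }
})

test_that("profile matrix is permutation-equivariant and respects counts", {
  cfg <- simulation_config(n_cell = 6L, n_patient = 4L, G = 12L, seed = 9L)
  coh <- generate_cohort(cfg)
  ids <- coh$samples$sample_id
  mat <- build_profile_matrix(coh$calls, coh$annotations, coh$panel,
                              sample_ids = ids)
  # shuffled input rows give bit-identical output
  shuffled <- coh$calls[sample(nrow(coh$calls)), ]
  mat_sh <- build_profile_matrix(shuffled, coh$annotations, coh$panel,
                                 sample_ids = ids)
  expect_identical(mat, mat_sh)

  # taxonomy counts both sum to the per-(sample, gene) mutation count
  ann <- annotate_mutations(filter_coding_mutations(coh$calls),
                            coh$annotations)
  counts <- table(ann$sample_id, ann$gene_symbol)
  cidx <- function(stat, cats) {
    as.vector(outer(match(cats, feature_categories()) * 4 - 4 + stat,
                    (seq_along(coh$panel) - 1) * 24, "+"))
  }
  for (s in ids) {
    per_gene_gpd <- rowSums(matrix(mat[s, sort(cidx(4, gpd_categories()))],
                                   nrow = length(coh$panel), byrow = TRUE))
    per_gene_clin <- rowSums(matrix(mat[s, sort(cidx(4, clinvar_categories()))],
                                    nrow = length(coh$panel), byrow = TRUE))
    expect_equal(per_gene_gpd, per_gene_clin)
    for (g in colnames(counts)) {
      expect_equal(per_gene_gpd[match(g, coh$panel)],
                   unname(counts[s, g]))
    }
  }

  # mean * count == sum within every block
  means <- mat[, seq(1, ncol(mat), 4)]
  sums <- mat[, seq(3, ncol(mat), 4)]
  cnts <- mat[, seq(4, ncol(mat), 4)]
  expect_lt(max(abs(means * cnts - sums)), 1e-9)

  # zero fraction at least the mutation-free (sample, gene) fraction
  mutated <- length(unique(paste(ann$sample_id, ann$gene_symbol)))
  free_frac <- 1 - mutated / (length(ids) * length(coh$panel))
  expect_gte(mean(mat == 0), free_frac)
})

test_that("off-panel and duplicate-key handling follow the contract", {
  calls <- data.frame(sample_id = "S1", gene_symbol = c("A", "ZZZ"),
                      variant_classification = "Missense_Mutation",
                      mutation_key = c("m1", "m2"))
  ann <- toy_annotations(c("m1", "m2"), "S1", c("A", "ZZZ"))
  expect_warning(mat <- build_profile_matrix(calls, ann, c("A", "B")),
                 "off-panel")
  expect_equal(ncol(mat), 48L)
  expect_error(
    suppressWarnings(build_profile_matrix(calls, ann, c("A", "B"),
                                          strict = TRUE)),
    "ZZZ")

  dup <- calls; dup$mutation_key <- c("m1", "m1")
  expect_error(filter_coding_mutations(dup), "duplicate mutation_key")
})

test_that("CNV one-hot encoding places exactly one 1 per gene triple", {
  v <- encode_cnv_onehot(c(), sprintf("g%d", 1:4))
  expect_equal(unname(which(v == 1)), c(2L, 5L, 8L, 11L))   # all no_change

  v2 <- encode_cnv_onehot(c(g1 = "amplification"), c("g1", "g2"))
  expect_equal(unname(v2), c(0L, 0L, 1L, 0L, 1L, 0L))

  set.seed(1)
  panel <- sprintf("g%d", 1:10)
  cats <- sample(c("loss", "no_change", "amplification"), 10, replace = TRUE)
  names(cats) <- panel
  v3 <- encode_cnv_onehot(cats, panel)
  expect_true(all(colSums(matrix(v3, nrow = 3)) == 1))

  expect_error(encode_cnv_onehot(c(g1 = "gain"), panel), "unknown CNV")
})
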