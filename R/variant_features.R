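# Stage I: variant-annotation feature engineering.
#
# Each retained coding mutation carries three annotations: a ClinVar clinical
# significance collapsed to {PATHOGENIC, BENIGN, VUS}, a protein-location
# category from {PIU, LU, NCU} (protein information / linker / non-coding
# unit), and 17 binary deleteriousness calls whose mean is the d-score.
# Per gene, the d-scores of member mutations are summarized within each of
# the 6 categories by (mean, max, sum, count), giving 24 features per gene
# and G*24 columns for a G-gene panel (7,776 for a 324-gene panel).

#' Variant classifications retained as coding/function-altering
#'
#' The nine MAF `Variant_Classification` values kept by the coding filter:
#' missense, in-frame indels, splice site, nonsense, frameshift indels,
#' nonstop and translation start site mutations.
#'
#' @return Character vector of the nine retained classification strings.
#' @export
retained_variant_classes <- function() {
  c("Missense_Mutation", "In_Frame_Del", "Splice_Site", "Nonsense_Mutation",
    "Frame_Shift_Ins", "Frame_Shift_Del", "Nonstop_Mutation",
    "Translation_Start_Site", "In_Frame_Ins")
}

#' Canonical annotation category and statistic orders
#'
#' Feature columns are laid out gene-major; within a gene the category order
#' is PIU, LU, NCU, PATHOGENIC, BENIGN, VUS and within a category the
#' statistic order is mean, max, sum, count.
#'
#' @name feature-layout
#' @return Character vectors of level names.
NULL

#' @rdname feature-layout
#' @export
gpd_categories <- function() c("PIU", "LU", "NCU")

#' @rdname feature-layout
#' @export
clinvar_categories <- function() c("PATHOGENIC", "BENIGN", "VUS")

#' @rdname feature-layout
#' @export
feature_categories <- function() c(gpd_categories(), clinvar_categories())

#' @rdname feature-layout
#' @export
feature_statistics <- function() c("mean", "max", "sum", "count")

#' Column names of the annotated profile matrix for a panel
#'
#' @param panel character vector of panel gene symbols (no duplicates).
#' @return Character vector of length `24 * length(panel)`, gene-major.
#' @export
profile_column_names <- function(panel) {
  panel <- validate_panel(panel)
  as.vector(t(outer(panel, as.vector(t(outer(feature_categories(),
                                             feature_statistics(),
                                             paste, sep = "__"))),
                    paste, sep = "__")))
}

validate_panel <- function(panel) {
  panel <- trimws(as.character(panel))
  if (!length(panel) || any(!nzchar(panel))) {
    stop_panel("gene panel must be a non-empty vector of non-empty symbols")
  }
  if (anyDuplicated(panel)) {
    stop_panel("gene panel contains duplicated symbols: %s",
               paste(unique(panel[duplicated(panel)]), collapse = ", "))
  }
  panel
}

validate_calls <- function(calls) {
  assert_columns(calls, c("sample_id", "gene_symbol", "variant_classification",
                          "mutation_key"), "mutation call table")
  dup <- duplicated(calls[, c("sample_id", "mutation_key")])
  if (any(dup)) {
    stop_panel("duplicate mutation_key within a sample: %s",
               paste(unique(calls$mutation_key[dup]), collapse = ", "))
  }
  if (any(is.na(calls$gene_symbol) | !nzchar(trimws(calls$gene_symbol)))) {
    stop_panel("mutation call table has empty gene_symbol entries")
  }
  calls
}

#' Keep only coding / function-altering mutation calls
#'
#' Filters a call table down to the nine retained variant classifications
#' (see [retained_variant_classes()]). Unknown but non-empty classifications
#' (e.g. `"Silent"`, `"3'UTR"`) are dropped silently; an empty or missing
#' classification is a validation error because it usually indicates a
#' malformed input file.
#'
#' @param calls data.frame with columns `sample_id`, `gene_symbol`,
#'   `variant_classification`, `mutation_key`.
#' @return The input rows whose classification is retained, original order.
#' @export
filter_coding_mutations <- function(calls) {
  validate_calls(calls)
  vc <- calls$variant_classification
  if (length(vc) && any(is.na(vc) | !nzchar(trimws(vc)))) {
    bad <- which(is.na(vc) | !nzchar(trimws(vc)))
    stop_panel("empty variant_classification at row(s): %s",
               paste(utils::head(bad, 10L), collapse = ", "))
  }
  calls[vc %in% retained_variant_classes(), , drop = FALSE]
}

#' Deleteriousness score of a mutation
#'
#' The d-score is the fraction of the 17 deleteriousness prediction
#' algorithms that flag the mutation, i.e. `x / 17` for `x` flags set.
#'
#' @param flags logical (or 0/1) vector of exactly 17 algorithm calls.
#' @return A real number in `[0, 1]`.
#' @export
compute_dscore <- function(flags) {
  if (length(flags) != 17L) {
    stop_panel("d-score requires exactly 17 flags, got %d", length(flags))
  }
  if (is.logical(flags)) flags <- as.numeric(flags)
  if (!all(flags %in% c(0, 1))) {
    stop_panel("deleteriousness flags must be logical or 0/1")
  }
  sum(flags) / 17
}

#' Default ClinVar significance to 3-category mapping
#'
#' Collapses raw ClinVar clinical-significance strings to PATHOGENIC, BENIGN
#' or VUS. Matching is case-insensitive after replacing spaces, slashes and
#' commas with underscores. The mapping is configurable because the exact
#' grouping used upstream of cNGS reports varies; anything unmapped falls
#' back to VUS, making categorization total.
#'
#' @return Named character vector: normalized raw string -> category.
#' @export
default_clinvar_mapping <- function() {
  c(pathogenic = "PATHOGENIC",
    likely_pathogenic = "PATHOGENIC",
    pathogenic_likely_pathogenic = "PATHOGENIC",
    benign = "BENIGN",
    likely_benign = "BENIGN",
    benign_likely_benign = "BENIGN",
    uncertain_significance = "VUS",
    conflicting_interpretations_of_pathogenicity = "VUS",
    not_provided = "VUS",
    other = "VUS")
}

normalize_clinvar_raw <- function(raw) {
  tolower(gsub("_+", "_", gsub("[ /,]", "_", trimws(raw))))
}

#' Map raw ClinVar significance strings to the 3 analysis categories
#'
#' @param raw_significance character vector of raw ClinVar strings.
#' @param mapping named character vector as in [default_clinvar_mapping()].
#' @return Character vector over \{PATHOGENIC, BENIGN, VUS\}; unmapped
#'   strings default to VUS.
#' @export
map_clinvar_category <- function(raw_significance,
                                 mapping = default_clinvar_mapping()) {
  if (!all(mapping %in% clinvar_categories())) {
    stop_panel("clinvar mapping values must be in {%s}",
               paste(clinvar_categories(), collapse = ", "))
  }
  out <- unname(mapping[normalize_clinvar_raw(raw_significance)])
  out[is.na(out)] <- "VUS"
  out
}

annotation_flag_columns <- function() paste0("alg_", 1:17)

validate_annotations <- function(annotations) {
  assert_columns(annotations,
                 c("mutation_key", "sample_id", "gene", "clinvar_raw",
                   "gpd_category", annotation_flag_columns()),
                 "annotation table")
  bad_gpd <- !annotations$gpd_category %in% gpd_categories()
  if (any(bad_gpd)) {
    stop_panel("unknown gpd_category at row(s) %s: %s",
               paste(utils::head(which(bad_gpd), 5L), collapse = ", "),
               paste(utils::head(unique(annotations$gpd_category[bad_gpd]), 5L),
                     collapse = ", "))
  }
  flags <- as.matrix(annotations[, annotation_flag_columns()])
  if (!all(flags %in% c(0, 1))) {
    stop_panel("annotation alg_1..alg_17 columns must be 0/1")
  }
  annotations
}

#' Join mutation calls with their annotations
#'
#' Attaches the ClinVar category, protein-location (GPD) category and
#' d-score to each retained call via `mutation_key`. Missing deleteriousness
#' flags are treated as not-deleterious; the d-score denominator stays 17.
#'
#' @param calls filtered mutation call table (see
#'   [filter_coding_mutations()]).
#' @param annotations annotation table with columns `mutation_key`,
#'   `sample_id`, `gene`, `clinvar_raw`, `gpd_category`, `alg_1` .. `alg_17`.
#' @param clinvar_mapping mapping passed to [map_clinvar_category()].
#' @return data.frame with one row per call: `sample_id`, `gene_symbol`,
#'   `mutation_key`, `gpd_category`, `clinvar_category`, `dscore`.
#' @export
annotate_mutations <- function(calls, annotations,
                               clinvar_mapping = default_clinvar_mapping()) {
  validate_calls(calls)
  validate_annotations(annotations)
  idx <- match(calls$mutation_key, annotations$mutation_key)
  if (anyNA(idx)) {
    miss <- calls$mutation_key[is.na(idx)]
    stop_panel("no annotation found for mutation_key(s): %s",
               paste(utils::head(miss, 10L), collapse = ", "))
  }
  ann <- annotations[idx, , drop = FALSE]
  flags <- as.matrix(ann[, annotation_flag_columns()])
  flags[is.na(flags)] <- 0
  data.frame(sample_id = calls$sample_id,
             gene_symbol = trimws(calls$gene_symbol),
             mutation_key = calls$mutation_key,
             gpd_category = ann$gpd_category,
             clinvar_category = map_clinvar_category(ann$clinvar_raw,
                                                     clinvar_mapping),
             dscore = rowSums(flags) / 17,
             stringsAsFactors = FALSE)
}

#' Aggregate the annotated mutations of one gene into its 24-feature block
#'
#' For each of the 6 categories (PIU, LU, NCU, PATHOGENIC, BENIGN, VUS) the
#' member mutations' d-scores are summarized by mean, max and sum, and count
#' is the number of member mutations. A mutation contributes to exactly one
#' GPD and exactly one ClinVar category. Empty categories (including a
#' mutation-free gene) contribute zeros.
#'
#' @param mutations data.frame with columns `gpd_category`,
#'   `clinvar_category`, `dscore` for one (sample, gene); may have 0 rows.
#' @return Named numeric vector of length 24 in canonical order.
#' @export
aggregate_gene_features <- function(mutations) {
  out <- numeric(24L)
  names(out) <- as.vector(t(outer(feature_categories(), feature_statistics(),
                                  paste, sep = "__")))
  if (!is.null(mutations) && nrow(mutations)) {
    for (ci in seq_along(feature_categories())) {
      cat <- feature_categories()[ci]
      member <- if (ci <= 3L) mutations$gpd_category == cat
                else mutations$clinvar_category == cat
      d <- mutations$dscore[member]
      if (length(d)) {
        out[(ci - 1L) * 4L + 1:4] <- c(mean(d), max(d), sum(d), length(d))
      }
    }
  }
  out
}

#' Build the annotated profile matrix for a cohort
#'
#' One row per sample, `24 * G` columns in the canonical gene-major layout.
#' Genes without mutations in a sample yield 24-dimensional zero blocks, so
#' mutation-free samples are all-zero rows. Calls on genes outside the panel
#' are dropped with a warning, or rejected when `strict = TRUE`.
#'
#' @param calls mutation call table (coding filter is applied internally).
#' @param annotations annotation table (see [annotate_mutations()]).
#' @param panel character vector of panel gene symbols.
#' @param sample_ids optional character vector fixing the row set and order;
#'   defaults to the unique sample ids present in `calls`.
#' @param strict error (instead of warn+drop) on off-panel genes.
#' @param clinvar_mapping mapping passed to [map_clinvar_category()].
#' @return Numeric matrix with `rownames = sample_ids` and canonical column
#'   names (class `c("annotated_profile_matrix", "matrix", "array")`).
#' @export
build_profile_matrix <- function(calls, annotations, panel,
                                 sample_ids = NULL, strict = FALSE,
                                 clinvar_mapping = default_clinvar_mapping()) {
  panel <- validate_panel(panel)
  calls <- filter_coding_mutations(calls)
  if (is.null(sample_ids)) sample_ids <- unique(calls$sample_id)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop_panel("sample_ids must be unique")

  ann <- annotate_mutations(calls, annotations, clinvar_mapping)
  off <- setdiff(unique(ann$gene_symbol), panel)
  if (length(off)) {
    if (strict) {
      stop_panel("calls reference gene(s) outside the panel: %s",
                 paste(off, collapse = ", "))
    }
    warning(sprintf("dropping calls in %d off-panel gene(s): %s",
                    length(off), paste(utils::head(off, 10L), collapse = ", ")),
            call. = FALSE)
    ann <- ann[ann$gene_symbol %in% panel, , drop = FALSE]
  }
  unknown_samples <- setdiff(unique(ann$sample_id), sample_ids)
  if (length(unknown_samples)) {
    stop_panel("calls reference sample(s) not in sample_ids: %s",
               paste(utils::head(unknown_samples, 10L), collapse = ", "))
  }

  mat <- matrix(0, nrow = length(sample_ids), ncol = 24L * length(panel),
                dimnames = list(sample_ids, profile_column_names(panel)))
  if (nrow(ann)) {
    # Long form: one row per (mutation, taxonomy); cat index 1..6 follows the
    # canonical category order.
    long <- rbind(
      data.frame(sample = ann$sample_id, gene = ann$gene_symbol,
                 cat = match(ann$gpd_category, feature_categories()),
                 dscore = ann$dscore),
      data.frame(sample = ann$sample_id, gene = ann$gene_symbol,
                 cat = match(ann$clinvar_category, feature_categories()),
                 dscore = ann$dscore))
    key <- paste(long$sample, long$gene, long$cat, sep = "\r")
    grp <- split(long$dscore, key)
    first <- long[!duplicated(key), , drop = FALSE]
    ord <- match(names(grp), key[!duplicated(key)])
    first <- first[ord, , drop = FALSE]
    row <- match(first$sample, sample_ids)
    colbase <- (match(first$gene, panel) - 1L) * 24L + (first$cat - 1L) * 4L
    mat[cbind(row, colbase + 1L)] <- vapply(grp, mean, numeric(1))
    mat[cbind(row, colbase + 2L)] <- vapply(grp, max, numeric(1))
    mat[cbind(row, colbase + 3L)] <- vapply(grp, sum, numeric(1))
    mat[cbind(row, colbase + 4L)] <- lengths(grp)
  }
  class(mat) <- c("annotated_profile_matrix", class(mat))
  attr(mat, "panel") <- panel
  mat
}

cnv_categories <- function() c("loss", "no_change", "amplification")

#' One-hot encode per-gene copy-number categories
#'
#' Each panel gene contributes a (loss, no_change, amplification) triple with
#' exactly one 1, gene-major. Genes absent from `categories` default to
#' `no_change`.
#'
#' @param categories named character vector (names = gene symbols) over
#'   \{loss, no_change, amplification\}.
#' @param panel character vector of panel gene symbols.
#' @return Integer 0/1 vector of length `3 * length(panel)` with names
#'   `gene__category`.
#' @export
encode_cnv_onehot <- function(categories, panel) {
  panel <- validate_panel(panel)
  if (length(categories)) {
    bad <- !categories %in% cnv_categories()
    if (any(bad)) {
      stop_panel("unknown CNV category value(s): %s",
                 paste(unique(categories[bad]), collapse = ", "))
    }
  }
  per_gene <- rep("no_change", length(panel))
  names(per_gene) <- panel
  hit <- intersect(names(categories), panel)
  per_gene[hit] <- categories[hit]
  out <- integer(3L * length(panel))
  names(out) <- as.vector(t(outer(panel, cnv_categories(), paste, sep = "__")))
  out[(seq_along(panel) - 1L) * 3L + match(per_gene, cnv_categories())] <- 1L
  out
}

#' Build the one-hot CNV matrix for a cohort
#'
#' @param cnv data.frame with columns `sample_id`, `gene`, `category`.
#' @param panel character vector of panel gene symbols.
#' @param sample_ids character vector fixing row set/order.
#' @return Integer matrix `length(sample_ids) x (3 * length(panel))`.
#' @export
build_cnv_matrix <- function(cnv, panel, sample_ids) {
  assert_columns(cnv, c("sample_id", "gene", "category"), "CNV table")
  panel <- validate_panel(panel)
  mat <- matrix(0L, length(sample_ids), 3L * length(panel),
                dimnames = list(sample_ids, NULL))
  for (s in seq_along(sample_ids)) {
    rows <- cnv$sample_id == sample_ids[s]
    cats <- cnv$category[rows]
    names(cats) <- cnv$gene[rows]
    mat[s, ] <- encode_cnv_onehot(cats, panel)
  }
  colnames(mat) <- as.vector(t(outer(panel, cnv_categories(), paste,
                                     sep = "__")))
  mat
}
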