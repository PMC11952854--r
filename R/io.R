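# Readers and writers for the tab-delimited interchange formats.
#
# All tabular files are UTF-8, tab-delimited with a header row; lines
# starting with '#' are comments (MAF convention). Gene symbols are matched
# case-sensitively after whitespace stripping.

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop_panel("%s file not found: %s", what, path)
  utils::read.delim(path, sep = "\t", comment.char = "#", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a MAF-style mutation call table
#'
#' Requires columns `Hugo_Symbol`, `Variant_Classification`,
#' `Tumor_Sample_Barcode`; extra columns are ignored. An optional
#' `Mutation_Key` column links calls to the annotation table; if absent, a
#' synthetic key `sample:row` is generated.
#'
#' @param path tab-delimited file ('#' comment lines are skipped).
#' @return data.frame `sample_id`, `gene_symbol`, `variant_classification`,
#'   `mutation_key`.
#' @export
read_maf <- function(path) {
  df <- read_tsv_checked(path, "MAF")
  assert_columns(df, c("Hugo_Symbol", "Variant_Classification",
                       "Tumor_Sample_Barcode"), sprintf("MAF file %s", path))
  key <- if ("Mutation_Key" %in% names(df)) df$Mutation_Key
         else if (nrow(df) == 0L) character(0)
         else paste0(df$Tumor_Sample_Barcode, ":", seq_len(nrow(df)))
  if (nrow(df) == 0L) {
    df$Hugo_Symbol <- df$Variant_Classification <-
      df$Tumor_Sample_Barcode <- character(0)
  }
  data.frame(sample_id = df$Tumor_Sample_Barcode,
             gene_symbol = trimws(df$Hugo_Symbol),
             variant_classification = df$Variant_Classification,
             mutation_key = key, stringsAsFactors = FALSE)
}

#' @rdname read_maf
#' @param calls standardized call table (as returned by [read_maf()]).
#' @export
write_maf <- function(calls, path) {
  write_tsv(data.frame(Hugo_Symbol = calls$gene_symbol,
                       Variant_Classification = calls$variant_classification,
                       Tumor_Sample_Barcode = calls$sample_id,
                       Mutation_Key = calls$mutation_key), path)
}

#' Read / write a per-mutation annotation table
#'
#' Columns: `mutation_key`, `sample_id`, `gene`, `clinvar_raw`,
#' `gpd_category`, `alg_1` .. `alg_17` (0/1 deleteriousness flags).
#'
#' @param path tab-delimited file.
#' @return Validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  validate_annotations(read_tsv_checked(path, "annotation"))
}

#' @rdname read_annotations
#' @param annotations annotation table.
#' @export
write_annotations <- function(annotations, path) write_tsv(annotations, path)

#' Read / write a gene panel (one symbol per line)
#'
#' @param path text file; blank lines and '#' comments are skipped.
#' @return Character vector of gene symbols.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop_panel("panel file not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE, encoding = "UTF-8"))
  validate_panel(x[nzchar(x) & !startsWith(x, "#")])
}

#' @rdname read_panel
#' @param panel character vector of gene symbols.
#' @export
write_panel <- function(panel, path) {
  writeLines(validate_panel(panel), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write drug fingerprints
#'
#' Tab-delimited with columns `drug_id` and either `bits` (a 0/1 string) or
#' `smiles` (converted through [fingerprint_from_smiles()]).
#'
#' @param path tab-delimited file.
#' @param radius,n_bits fingerprint parameters used for the SMILES route.
#' @return 0/1 matrix, one row per drug, drug ids as rownames.
#' @export
read_drugs <- function(path, radius = 2L, n_bits = 1024L) {
  if (!file.exists(path)) stop_panel("drug file not found: %s", path)
  # bit strings must stay character: leading zeros are significant
  df <- utils::read.delim(path, sep = "\t", comment.char = "#", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  assert_columns(df, "drug_id", sprintf("drug file %s", path))
  if (anyDuplicated(df$drug_id)) stop_panel("duplicate drug_id in %s", path)
  if ("bits" %in% names(df)) {
    rows <- lapply(seq_len(nrow(df)), function(i) {
      b <- strsplit(as.character(df$bits[i]), "")[[1]]
      if (!all(b %in% c("0", "1"))) {
        stop_panel("drug file %s row %d: bits must be a 0/1 string", path, i)
      }
      as.integer(b)
    })
    len <- unique(lengths(rows))
    if (length(len) != 1L) {
      stop_panel("drug file %s: fingerprints have unequal lengths", path)
    }
    mat <- do.call(rbind, rows)
  } else if ("smiles" %in% names(df)) {
    mat <- do.call(rbind, lapply(df$smiles, fingerprint_from_smiles,
                                 radius = radius, n_bits = n_bits))
  } else {
    stop_panel("drug file %s needs a 'bits' or 'smiles' column", path)
  }
  rownames(mat) <- df$drug_id
  mat
}

#' @rdname read_drugs
#' @param drugs 0/1 fingerprint matrix with drug-id rownames.
#' @export
write_drugs <- function(drugs, path) {
  write_tsv(data.frame(drug_id = rownames(drugs),
                       bits = apply(drugs, 1L, paste, collapse = "")), path)
}

#' Read / write a response table
#'
#' Columns `sample_id`, `drug_id`, `domain`, `label`; `domain` is
#' `CELL_LINE` (real-valued AUDRC label) or `PATIENT` (RECIST category in
#' CR/PR/SD/PD). Violations are reported with their row number.
#'
#' @param path tab-delimited file.
#' @return data.frame with a character `label` column.
#' @export
read_responses <- function(path) {
  df <- read_tsv_checked(path, "response")
  assert_columns(df, c("sample_id", "drug_id", "domain", "label"),
                 sprintf("response file %s", path))
  bad_dom <- !df$domain %in% c("CELL_LINE", "PATIENT")
  if (any(bad_dom)) {
    stop_panel("response file %s row %d: unknown domain '%s'",
               path, which(bad_dom)[1], df$domain[which(bad_dom)[1]])
  }
  pat <- df$domain == "PATIENT"
  bad_lab <- pat & !df$label %in% c("CR", "PR", "SD", "PD")
  if (any(bad_lab)) {
    stop_panel("response file %s row %d: invalid RECIST label '%s'",
               path, which(bad_lab)[1], df$label[which(bad_lab)[1]])
  }
  cl_num <- suppressWarnings(as.numeric(df$label[!pat]))
  if (anyNA(cl_num)) {
    stop_panel("response file %s row %d: cell-line label is not numeric",
               path, which(!pat)[which(is.na(cl_num))[1]])
  }
  df$label <- as.character(df$label)
  df
}

#' @rdname read_responses
#' @param responses response table.
#' @export
write_responses <- function(responses, path) write_tsv(responses, path)

#' Read / write a per-gene CNV category table
#'
#' Columns `sample_id`, `gene`, `category` over \{loss, no_change,
#' amplification\}.
#'
#' @param path tab-delimited file.
#' @return Validated data.frame.
#' @export
read_cnv <- function(path) {
  df <- read_tsv_checked(path, "CNV")
  assert_columns(df, c("sample_id", "gene", "category"),
                 sprintf("CNV file %s", path))
  bad <- !df$category %in% cnv_categories()
  if (any(bad)) {
    stop_panel("CNV file %s row %d: unknown category '%s'",
               path, which(bad)[1], df$category[which(bad)[1]])
  }
  df
}

#' @rdname read_cnv
#' @param cnv CNV table.
#' @export
write_cnv <- function(cnv, path) write_tsv(cnv, path)

#' Write / read an annotated profile matrix
#'
#' Tab-delimited with the canonical column names and a leading `sample_id`
#' column.
#'
#' @param mat profile matrix with sample-id rownames.
#' @param path tab-delimited file.
#' @return `read_profile_matrix` returns the numeric matrix.
#' @export
write_profile_matrix <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path) {
  df <- read_tsv_checked(path, "profile matrix")
  assert_columns(df, "sample_id", sprintf("profile matrix %s", path))
  mat <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(mat) <- df$sample_id
  storage.mode(mat) <- "double"
  mat
}

#' Write the files of a synthetic cohort to a directory
#'
#' Emits exactly the formats the pipeline consumes: `calls.maf`,
#' `annotations.tsv`, `panel.txt`, `drugs.tsv`, `cnv.tsv` and (when labels
#' have been planted) `responses.tsv`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(calls = file.path(dir, "calls.maf"),
             annotations = file.path(dir, "annotations.tsv"),
             panel = file.path(dir, "panel.txt"),
             drugs = file.path(dir, "drugs.tsv"),
             cnv = file.path(dir, "cnv.tsv"),
             samples = file.path(dir, "samples.tsv"))
  write_maf(cohort$calls, paths["calls"])
  write_annotations(cohort$annotations, paths["annotations"])
  write_panel(cohort$panel, paths["panel"])
  write_drugs(cohort$drugs, paths["drugs"])
  write_cnv(cohort$cnv, paths["cnv"])
  write_tsv(cohort$samples, paths["samples"])
  if (!is.null(cohort$responses)) {
    paths["responses"] <- file.path(dir, "responses.tsv")
    write_responses(cohort$responses, paths["responses"])
  }
  invisible(paths)
}

#' Write a run manifest
#'
#' Records the configuration echo, global seed, package version and input
#' file checksums so any output is reproducible from its inputs.
#'
#' @param path output JSON path.
#' @param seed global seed of the run.
#' @param config configuration list (echoed verbatim).
#' @param inputs character vector of input file paths to checksum.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(path, seed, config = list(), inputs = character()) {
  manifest <- list(
    package = "panelDRP",
    version = as.character(utils::packageVersion("panelDRP")),
    seed = seed,
    config = config,
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
    } else NULL)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
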