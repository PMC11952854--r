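# Evaluation protocol: RECIST binarization, 80-20 random splits, AUROC /
# AUPRC with the positive-fraction AUPRC baseline, cross-split prediction
# averaging and percentile-based alteration-frequency tables.

#' Binarize RECIST categories
#'
#' Complete response (CR) and partial response (PR) are responders (1);
#' stable disease (SD) and progressive disease (PD) are non-responders (0).
#'
#' @param category character vector over \{CR, PR, SD, PD\}.
#' @return Integer 0/1 vector.
#' @export
binarize_recist <- function(category) {
  bad <- !category %in% c("CR", "PR", "SD", "PD")
  if (any(bad)) {
    stop_panel("unknown RECIST category at position(s) %s: %s",
               paste(utils::head(which(bad), 5L), collapse = ", "),
               paste(utils::head(unique(category[bad]), 5L), collapse = ", "))
  }
  as.integer(category %in% c("CR", "PR"))
}

#' Random train/test splits of response pairs
#'
#' Simple (unstratified) random sampling of the configured test fraction,
#' one split per seed; reproducible per seed, and train/test always
#' partition the pairs.
#'
#' @param pairs data.frame of (sample, drug) response pairs (>= 5 rows).
#' @param fraction test fraction in (0, 1).
#' @param seeds integer vector, one split per seed.
#' @return List of `split_plan` lists: `train`, `test` (integer row
#'   indices), `fraction`, `seed`, `index`.
#' @export
make_splits <- function(pairs, fraction = 0.2, seeds = c(1L, 2L, 3L)) {
  if (fraction <= 0 || fraction >= 1) stop_panel("fraction must be in (0, 1)")
  n <- nrow(pairs)
  if (is.null(n) || n < 5L) stop_panel("need at least 5 pairs to split")
  lapply(seq_along(seeds), function(i) {
    set.seed(substream_seed(seeds[i], "split"))
    test <- sort(sample.int(n, round(n * fraction)))
    structure(list(train = setdiff(seq_len(n), test), test = test,
                   fraction = fraction, seed = seeds[i], index = i),
              class = "split_plan")
  })
}

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop_panel("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    stop_panel("both classes must be present to compute ranking metrics")
  }
}

#' Area under the ROC curve
#'
#' Computed from the Wilcoxon rank statistic with midranks for ties, i.e.
#' the probability that a random positive outscores a random negative
#' (ties counted half).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  check_two_classes(labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation (no interpolation): scores are sorted decreasingly
#' and each positive contributes precision-at-its-rank times its recall
#' increment; ties are processed in score groups.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(labels, scores) {
  check_two_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  n_pos <- sum(y)
  # group ties so identical scores share one operating point
  grp <- factor(cumsum(!duplicated(s)))   # levels already in rank order
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  tp <- cumsum(tp_g); n_cum <- cumsum(n_g)
  prec <- tp / n_cum
  rec <- tp / n_pos
  sum(prec * diff(c(0, rec)))
}

#' Baseline AUPRC of a label set
#'
#' The fraction of positive pairs among all pairs — the AUPRC of a
#' no-information classifier.
#'
#' @param labels 0/1 vector.
#' @return Positive fraction.
#' @export
baseline_auprc <- function(labels) mean(labels == 1)

#' Average predictions of pairs seen in several test splits
#'
#' @param predictions list of data.frames with columns `sample_id`,
#'   `drug_id`, `score` (and optionally `label`), one per split.
#' @return One row per distinct (sample, drug) pair with the mean score
#'   across the splits in which it appears.
#' @export
aggregate_cross_split <- function(predictions) {
  all <- do.call(rbind, predictions)
  key <- paste(all$sample_id, all$drug_id, sep = "\r")
  agg <- tapply(all$score, key, mean)
  first <- all[!duplicated(key), , drop = FALSE]
  first <- first[match(names(agg), key[!duplicated(key)]), , drop = FALSE]
  first$score <- as.vector(agg)
  rownames(first) <- NULL
  first
}

#' Metric report for a prediction table
#'
#' @param preds data.frame with `sample_id`, `drug_id`, `score`, `label`
#'   (0/1).
#' @return List with `auroc`, `auprc`, `baseline_auprc`, `n_pairs` and a
#'   `per_drug` data.frame (metrics are NA for single-class drugs).
#' @export
metric_report <- function(preds) {
  per_drug <- do.call(rbind, lapply(split(preds, preds$drug_id), function(d) {
    one_class <- length(unique(d$label)) < 2L
    data.frame(drug_id = d$drug_id[1], n_pairs = nrow(d),
               auroc = if (one_class) NA_real_ else auroc(d$label, d$score),
               auprc = if (one_class) NA_real_ else auprc(d$label, d$score),
               baseline_auprc = baseline_auprc(d$label))
  }))
  rownames(per_drug) <- NULL
  list(auroc = auroc(preds$label, preds$score),
       auprc = auprc(preds$label, preds$score),
       baseline_auprc = baseline_auprc(preds$label),
       n_pairs = nrow(preds), per_drug = per_drug)
}

#' Per-gene alteration frequencies in prediction percentile extremes
#'
#' Partitions the patients predicted for one drug into the bottom and top
#' `percentile` groups of predicted response (patients exactly at the
#' cutoff are included in the extreme group) and reports, for the 15 most
#' frequently altered genes of the anchor group, the fraction of patients
#' in each group with at least one retained coding mutation in the gene.
#'
#' @param predictions data.frame `sample_id`, `score` for one drug
#'   (>= 5 patients).
#' @param calls mutation call table covering those patients.
#' @param percentile group size in percent, in (0, 50].
#' @param anchor `"bottom"` or `"top"`: which group ranks the genes.
#' @param n_genes number of anchor-group genes reported.
#' @return data.frame `gene`, `freq_top`, `freq_bottom`, `n_top`,
#'   `n_bottom`.
#' @export
alteration_frequency_table <- function(predictions, calls, percentile = 20,
                                       anchor = c("bottom", "top"),
                                       n_genes = 15L) {
  anchor <- match.arg(anchor)
  if (percentile <= 0 || percentile > 50) {
    stop_panel("percentile must be in (0, 50]")
  }
  if (nrow(predictions) < 5L) stop_panel("need >= 5 patients for the drug")
  calls <- filter_coding_mutations(calls)
  s <- predictions$score
  lo_cut <- stats::quantile(s, percentile / 100, names = FALSE)
  hi_cut <- stats::quantile(s, 1 - percentile / 100, names = FALSE)
  bottom <- predictions$sample_id[s <= lo_cut]
  top <- predictions$sample_id[s >= hi_cut]
  freq_in <- function(group) {
    sub <- calls[calls$sample_id %in% group, , drop = FALSE]
    vapply(split(sub$sample_id, sub$gene_symbol),
           function(ss) length(unique(ss)) / length(group), numeric(1))
  }
  f_bottom <- freq_in(bottom)
  f_top <- freq_in(top)
  anchor_freq <- if (anchor == "bottom") f_bottom else f_top
  genes <- names(sort(anchor_freq, decreasing = TRUE))
  genes <- utils::head(genes, n_genes)
  data.frame(gene = genes,
             freq_top = unname(ifelse(genes %in% names(f_top),
                                      f_top[genes], 0)),
             freq_bottom = unname(ifelse(genes %in% names(f_bottom),
                                         f_bottom[genes], 0)),
             n_top = length(top), n_bottom = length(bottom),
             stringsAsFactors = FALSE)
}
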