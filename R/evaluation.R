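# Per-sample evaluation of predicted somatic calls against truth, count
# correlation, and the single-feature separability screen.

variant_site_key <- function(variants) {
  paste(normalize_chrom(variants$chrom), variants$pos,
        variants$ref_allele, variants$alt_allele, sep = ":")
}

#' Per-sample precision / recall / F1
#'
#' Counts TP/FP/FN per sample by exact (chrom, pos, ref, alt) set
#' intersection of predicted and true somatic calls.  A sample with no
#' predictions has precision 0 (and recall 0) when truth is nonempty; a
#' sample where both sets are empty scores 1/1.
#'
#' @param predicted data.frame of predicted somatic variants (sample_id,
#'   chrom, pos, ref_allele, alt_allele).
#' @param truth data.frame of true somatic variants, same columns.
#' @return data.frame (sample_id, TP, FP, FN, precision, recall, f1) with a
#'   \code{summary} attribute holding cohort medians and means.
#' @export
per_sample_metrics <- function(predicted, truth) {
  samples <- sort(unique(c(predicted$sample_id, truth$sample_id)))
  pred_keys <- split(variant_site_key(predicted), predicted$sample_id)
  true_keys <- split(variant_site_key(truth), truth$sample_id)
  rows <- lapply(samples, function(sid) {
    p <- unique(pred_keys[[sid]])
    t <- unique(true_keys[[sid]])
    tp <- length(intersect(p, t))
    fp <- length(setdiff(p, t))
    fn <- length(setdiff(t, p))
    if (length(p) == 0 && length(t) == 0) {
      prec <- rec <- 1
    } else {
      prec <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(sample_id = sid, TP = tp, FP = fp, FN = fn,
               precision = prec, recall = rec, f1 = f1)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(
    median_precision = median(out$precision), median_recall = median(out$recall),
    median_f1 = median(out$f1),
    mean_precision = mean(out$precision), mean_recall = mean(out$recall),
    mean_f1 = mean(out$f1))
  out
}

#' Spearman correlation between predicted and true mutation counts
#'
#' @param pred_counts,true_counts numeric vectors of per-sample counts,
#'   aligned by position or by shared names.
#' @return list with \code{rho} and \code{p} (ties mid-ranked).
#' @export
count_correlation <- function(pred_counts, true_counts) {
  if (!is.null(names(pred_counts)) && !is.null(names(true_counts))) {
    common <- intersect(names(pred_counts), names(true_counts))
    pred_counts <- pred_counts[common]
    true_counts <- true_counts[common]
  }
  if (length(pred_counts) < 3) {
    stop("count_correlation: need at least 3 samples", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(pred_counts, true_counts,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

# Best F1 and PR area of a single numeric feature as a threshold classifier,
# for one orientation (higher values called somatic).  Thresholds sweep all
# observed values plus the predict-nothing extreme; computed by cumulative
# sums over the value-sorted labels.
threshold_scan <- function(values, is_somatic) {
  ord <- order(values, decreasing = TRUE)
  y <- as.integer(is_somatic[ord])
  v <- values[ord]
  n_som <- sum(y)
  tp <- cumsum(y)
  npred <- seq_along(y)
  # merge ties: only positions where the next value differs are valid cuts
  valid <- c(v[-1] != v[-length(v)], TRUE)
  tp <- tp[valid]; npred <- npred[valid]
  precision <- tp / npred
  recall <- tp / n_som
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  # PR curve: prepend the zero-recall end at the first cut's precision
  r_pts <- c(0, recall)
  p_pts <- c(precision[1], precision)
  auc <- sum(diff(r_pts) * (head(p_pts, -1) + p_pts[-1]) / 2)
  list(best_f1 = max(f1, 0), pr_auc = auc)
}

#' Single-feature separability screen
#'
#' For each feature column: a two-sided Wilcoxon rank-sum test between the
#' somatic and germline values, the best F1 achievable by thresholding the
#' feature alone (both orientations, thresholds at all observed values), and
#' the trapezoidal area under the precision-recall curve of the better
#' orientation.  Quantifies how far any single feature gets, and hence how
#' much the ensemble adds.
#'
#' @param features data.frame of numeric feature columns.
#' @param labels \code{somatic}/\code{germline} per row; both classes must
#'   be present.
#' @return data.frame (feature, p_value, best_f1, pr_auc).
#' @export
single_feature_screen <- function(features, labels) {
  is_somatic <- as.character(labels) == "somatic"
  if (all(is_somatic) || !any(is_somatic)) {
    stop("single_feature_screen: both classes must be present", call. = FALSE)
  }
  rows <- lapply(names(features), function(fn) {
    v <- as.numeric(features[[fn]])
    p <- if (length(unique(v)) == 1) {
      1
    } else {
      suppressWarnings(
        wilcox.test(v[is_somatic], v[!is_somatic],
                    alternative = "two.sided")$p.value)
    }
    hi <- threshold_scan(v, is_somatic)
    lo <- threshold_scan(-v, is_somatic)
    data.frame(feature = fn, p_value = p,
               best_f1 = max(hi$best_f1, lo$best_f1),
               pr_auc = max(hi$pr_auc, lo$pr_auc))
  })
  do.call(rbind, rows)
}
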