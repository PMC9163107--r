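# Fold-wise random-forest ensemble with majority vote.
#
# Training protocol: the cohort is split sample-wise into a training set of
# 100 samples and a held-out test set; the 100 training samples are divided
# into 5 folds (80 train / 20 validation each); one 50-tree forest is fitted
# per fold on the fold's training samples' variants; unseen variants are
# labeled by the majority vote of the five forests.  Folds are sample-wise,
# never variant-wise, so no sample's variants leak across a fold boundary.

#' Split a cohort into training and test samples
#'
#' @param sample_ids character vector of cohort sample identifiers.
#' @param n_train number of training samples drawn uniformly without
#'   replacement (default 100).
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return list with \code{train_ids} and \code{test_ids} (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(sample_ids, n_train = 100, seed = 1) {
  sample_ids <- unique(as.character(sample_ids))
  if (length(sample_ids) < n_train) {
    stop("split_cohort: cohort has ", length(sample_ids),
         " samples, fewer than n_train = ", n_train, call. = FALSE)
  }
  set.seed(seed)
  train_ids <- if (n_train > 0) sample(sample_ids, n_train) else character(0)
  list(train_ids = train_ids, test_ids = setdiff(sample_ids, train_ids))
}

#' Divide training samples into cross-validation folds
#'
#' @param train_ids training-sample identifiers; must divide evenly into k
#'   validation blocks.
#' @param k number of folds (default 5, giving 80/20 splits of 100 samples).
#' @param seed RNG seed for the shuffle.
#' @return list of k fold assignments, each with \code{fold_index},
#'   \code{train_sample_ids}, \code{validation_sample_ids}; the validation
#'   blocks partition \code{train_ids}.
#' @export
make_folds <- function(train_ids, k = 5, seed = 1) {
  train_ids <- as.character(train_ids)
  n <- length(train_ids)
  if (n %% k != 0) {
    stop("make_folds: ", n, " training samples do not divide into ", k,
         " equal validation blocks", call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(train_ids)
  block <- n / k
  lapply(seq_len(k), function(i) {
    val <- shuffled[((i - 1) * block + 1):(i * block)]
    list(fold_index = i,
         train_sample_ids = setdiff(train_ids, val),
         validation_sample_ids = val)
  })
}

#' Train the fold-wise forest ensemble
#'
#' Fits one random forest per fold (50 trees, floor(sqrt(p)) candidate
#' features per split by default) on the labeled variants of the fold's
#' training samples, and records per-sample validation precision/recall on
#' the fold's validation samples.  Class imbalance is left as-is by default
#' (germline heavily outnumbers somatic); \code{downsample_germline}
#' optionally subsamples the germline class to match the somatic count
#' within each fold.
#'
#' @param features data.frame of 31 feature columns (frozen order), one row
#'   per labeled variant.
#' @param labels factor/character of \code{somatic}/\code{germline} labels.
#' @param sample_ids sample identifier per variant row (fold membership is
#'   by sample).
#' @param folds fold assignments from [make_folds()].
#' @param n_trees trees per forest (default 50).
#' @param mtry candidate features per split (default floor(sqrt(ncol))).
#' @param seed base RNG seed; fold i trains with seed + i.
#' @param downsample_germline logical, default FALSE.
#' @return object of class \code{somatic_ensemble}.
#' @export
train_ensemble <- function(features, labels, sample_ids, folds,
                           n_trees = 50, mtry = floor(sqrt(ncol(features))),
                           seed = 1, downsample_germline = FALSE) {
  stopifnot(identical(names(features), feature_names()))
  labels <- factor(as.character(labels), levels = c("germline", "somatic"))
  if (any(is.na(labels))) {
    stop("train_ensemble: labels must be 'somatic' or 'germline'",
         call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  forests <- vector("list", length(folds))
  fold_metrics <- vector("list", length(folds))
  for (fold in folds) {
    i <- fold$fold_index
    overlap <- intersect(fold$train_sample_ids, fold$validation_sample_ids)
    if (length(overlap) > 0) {
      stop("train_ensemble: fold ", i, " has samples on both sides",
           call. = FALSE)
    }
    in_train <- sample_ids %in% fold$train_sample_ids
    y <- labels[in_train]
    if (length(unique(y)) < 2) {
      stop("train_ensemble: fold ", i, " has only one class", call. = FALSE)
    }
    x <- features[in_train, , drop = FALSE]
    if (downsample_germline) {
      set.seed(seed + 1000 + i)
      som <- which(y == "somatic")
      germ <- which(y == "germline")
      keep <- sort(c(som, sample(germ, min(length(germ), length(som)))))
      x <- x[keep, , drop = FALSE]
      y <- y[keep]
    }
    forests[[i]] <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                                   mtry = mtry, importance = "impurity",
                                   num.threads = 1, seed = seed + i,
                                   verbose = FALSE)
    in_val <- sample_ids %in% fold$validation_sample_ids
    if (any(in_val)) {
      pred <- stats::predict(forests[[i]],
                             data = features[in_val, , drop = FALSE],
                             num.threads = 1)$predictions
      fold_metrics[[i]] <- validation_sample_metrics(
        pred, labels[in_val], sample_ids[in_val], fold_index = i)
    }
  }
  structure(list(forests = forests,
                 feature_names = feature_names(),
                 feature_hash = feature_hash(),
                 n_trees = n_trees, mtry = mtry, seed = seed,
                 downsample_germline = downsample_germline,
                 fold_metrics = do.call(rbind, fold_metrics)),
            class = "somatic_ensemble")
}

# Per-sample precision/recall of predicted vs. true labels within one fold's
# validation block.
validation_sample_metrics <- function(pred, truth, sample_ids, fold_index) {
  res <- lapply(unique(sample_ids), function(sid) {
    sel <- sample_ids == sid
    tp <- sum(pred[sel] == "somatic" & truth[sel] == "somatic")
    fp <- sum(pred[sel] == "somatic" & truth[sel] == "germline")
    fn <- sum(pred[sel] == "germline" & truth[sel] == "somatic")
    data.frame(fold_index = fold_index, sample_id = sid,
               TP = tp, FP = fp, FN = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               recall = if (tp + fn > 0) tp / (tp + fn) else 0)
  })
  do.call(rbind, res)
}

#' @export
print.somatic_ensemble <- function(x, ...) {
  cat("somatic_ensemble: ", length(x$forests), " forests x ", x$n_trees,
      " trees (mtry ", x$mtry, "), feature hash ", x$feature_hash, "\n",
      sep = "")
  if (!is.null(x$fold_metrics)) {
    cat("  validation median precision ",
        signif(median(x$fold_metrics$precision), 3), ", recall ",
        signif(median(x$fold_metrics$recall), 3), "\n", sep = "")
  }
  invisible(x)
}

#' Classify variants by majority vote of the ensemble
#'
#' Each of the five forests votes somatic or germline; the label receiving
#' at least three votes wins.  With five binary voters no tie is possible.
#'
#' @param model a \code{somatic_ensemble}.
#' @param features data.frame of 31 feature columns in the frozen order.
#' @return factor of \code{somatic}/\code{germline} labels with an
#'   attribute \code{somatic_votes} (integer votes per variant).
#' @export
predict_majority <- function(model, features) {
  if (!identical(names(features), model$feature_names) ||
      feature_hash(names(features)) != model$feature_hash) {
    stop("predict_majority: feature ordering does not match the trained model",
         call. = FALSE)
  }
  votes <- vapply(model$forests, function(f) {
    as.integer(stats::predict(f, data = features,
                              num.threads = 1)$predictions == "somatic")
  }, integer(nrow(features)))
  if (nrow(features) == 1) votes <- matrix(votes, nrow = 1)
  somatic_votes <- rowSums(votes)
  out <- factor(ifelse(somatic_votes >= ceiling((length(model$forests) + 1) / 2),
                       "somatic", "germline"),
                levels = c("germline", "somatic"))
  attr(out, "somatic_votes") <- as.integer(somatic_votes)
  out
}

#' Resolve a vote pattern to a label
#'
#' @param votes logical/0-1 vector of per-forest somatic votes (odd length).
#' @return "somatic" when a strict majority votes somatic, else "germline".
#' @export
majority_label <- function(votes) {
  votes <- as.integer(votes)
  stopifnot(length(votes) %% 2 == 1, all(votes %in% c(0L, 1L)))
  if (sum(votes) > length(votes) / 2) "somatic" else "germline"
}

#' Save / load a trained ensemble
#'
#' The archive is a directory holding one serialized forest per fold
#' (forest_1.rds .. forest_5.rds) plus a JSON metadata file recording the
#' feature ordering and hash, seeds and hyperparameters, so that a loaded
#' model refuses mismatched features.
#'
#' @param model a \code{somatic_ensemble}.
#' @param dir archive directory (created if needed).
#' @return the directory (save) or the restored \code{somatic_ensemble}
#'   (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(model$forests)) {
    saveRDS(model$forests[[i]], file.path(dir, sprintf("forest_%d.rds", i)))
  }
  meta <- model[setdiff(names(model), "forests")]
  meta$n_forests <- length(model$forests)
  meta$package_version <- as.character(utils::packageVersion("rnasomatic"))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, dataframe = "columns", digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  forests <- lapply(seq_len(meta$n_forests), function(i) {
    readRDS(file.path(dir, sprintf("forest_%d.rds", i)))
  })
  structure(list(forests = forests,
                 feature_names = meta$feature_names,
                 feature_hash = meta$feature_hash,
                 n_trees = meta$n_trees, mtry = meta$mtry, seed = meta$seed,
                 downsample_germline = isTRUE(meta$downsample_germline),
                 fold_metrics = as.data.frame(meta$fold_metrics)),
            class = "somatic_ensemble")
}

#' Averaged impurity-based feature importance
#'
#' Each forest's Gini (mean-decrease-impurity) importances are normalized to
#' sum to 1, then averaged across the five forests.
#'
#' @param model a \code{somatic_ensemble}.
#' @return data.frame (feature, importance), sorted descending; importances
#'   sum to 1.
#' @export
feature_importance <- function(model) {
  imps <- vapply(model$forests, function(f) {
    imp <- f$variable.importance
    imp / sum(imp)
  }, numeric(length(model$feature_names)))
  avg <- rowMeans(imps)
  out <- data.frame(feature = names(avg), importance = unname(avg))
  out[order(-out$importance), , drop = FALSE]
}
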