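# Test-time pipeline: feature extraction + majority-vote classification
# (step 2) followed by the RNA filter chain (step 3); step 1 — the upstream
# tumor-only caller — is external, its tabular output is this pipeline's
# input.  Also the end-to-end cohort study used for benchmarking on
# simulated bundles.

config_hash <- function(x) {
  feature_hash(paste(deparse(x), collapse = ""))
}

#' Run the tumor-only classification pipeline on a variant table
#'
#' @param variants data.frame of candidate variants from the tumor-only
#'   caller (see [read_variant_table()]).
#' @param model trained \code{somatic_ensemble}.
#' @param resources named list of the four germline resources
#'   (dbsnp/gnomad/g1000/esp).
#' @param exac population-exome resource for the frequency filter.
#' @param dna_pon,rna_pon \code{pon_histogram} panels.
#' @param editing_sites,artifact_genes filter resources.
#' @param config [filter_config()] thresholds.
#' @param out_dir optional directory; when given, writes
#'   \code{predicted_somatic.tsv} (pre-filter), \code{final_somatic.tsv},
#'   \code{filter_report.tsv} and \code{provenance.json}.
#' @param realign_hook optional realignment pass, see
#'   [apply_filter_chain()].
#' @return list with \code{final} (surviving somatic variant table),
#'   \code{predicted} (majority-vote labels for all input variants), and
#'   \code{report} (the \code{filter_report}).
#' @export
run_pipeline <- function(variants, model, resources, exac, dna_pon, rna_pon,
                         editing_sites = character(0),
                         artifact_genes = character(0),
                         config = filter_config(), out_dir = NULL,
                         realign_hook = NULL) {
  features <- extract_features(variants, resources, dna_pon, rna_pon)
  predicted <- predict_majority(model, features)
  somatic <- variants[predicted == "somatic", , drop = FALSE]
  filtered <- apply_filter_chain(somatic, config, exac, dna_pon, rna_pon,
                                 editing_sites, artifact_genes, realign_hook)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_variant_table(somatic, file.path(out_dir, "predicted_somatic.tsv"))
    write_variant_table(filtered$survivors,
                        file.path(out_dir, "final_somatic.tsv"))
    data.table::fwrite(
      data.frame(filter = names(filtered$report$filter_counts),
                 removed = unname(filtered$report$filter_counts)),
      file.path(out_dir, "filter_report.tsv"), sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("rnasomatic")),
           feature_hash = model$feature_hash,
           model_seed = model$seed,
           config_hash = config_hash(config),
           n_input = nrow(variants),
           n_predicted_somatic = nrow(somatic),
           n_final = nrow(filtered$survivors)),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  }
  list(final = filtered$survivors, predicted = predicted,
       report = filtered$report)
}

#' End-to-end cohort study on a simulated bundle
#'
#' Splits the bundle's samples into a training and a test cohort, trains the
#' fold-wise ensemble on matched-normal-derived labels, runs the test-time
#' pipeline on the held-out samples, and evaluates per-sample precision /
#' recall and count correlation against the simulated truth.
#'
#' @param bundle a \code{sim_bundle} from [simulate_cohort()].
#' @param n_train training-cohort size (default 100).
#' @param seed RNG seed driving the split, the folds, and the forests.
#' @param downsample_germline passed to [train_ensemble()].
#' @return list with the trained \code{model}, \code{metrics} (per-sample
#'   test metrics from [per_sample_metrics()]), \code{count_cor},
#'   \code{final} (final somatic table for the test cohort),
#'   \code{report}, and the \code{split}.
#' @export
run_cohort_study <- function(bundle, n_train = 100, seed = 1,
                             downsample_germline = FALSE) {
  variants <- bundle$variants
  split <- split_cohort(unique(variants$sample_id), n_train = n_train,
                        seed = seed)
  folds <- make_folds(split$train_ids, k = 5, seed = seed + 1)

  train_rows <- variants$sample_id %in% split$train_ids
  train_variants <- variants[train_rows, , drop = FALSE]
  labels <- label_from_matched_normal(train_variants$failure_reasons,
                                      train_variants$passed_full_pipeline)
  labeled <- labels != "unlabeled"
  train_features <- extract_features(train_variants[labeled, , drop = FALSE],
                                     bundle$resources, bundle$dna_pon,
                                     bundle$rna_pon)
  model <- train_ensemble(train_features, droplevels(labels[labeled]),
                          train_variants$sample_id[labeled], folds,
                          seed = seed + 2,
                          downsample_germline = downsample_germline)

  test_variants <- variants[!train_rows, , drop = FALSE]
  run <- run_pipeline(test_variants, model, bundle$resources, bundle$exac,
                      bundle$dna_pon, bundle$rna_pon, bundle$editing_sites,
                      bundle$artifact_genes)
  truth <- test_variants[test_variants$truth == "somatic", , drop = FALSE]
  metrics <- per_sample_metrics(run$final, truth)
  pred_counts <- compute_tmb(run$final, sample_ids = split$test_ids)
  true_counts <- compute_tmb(truth, sample_ids = split$test_ids)
  # count correlation over all somatic calls (not only non-silent)
  pred_all <- table(factor(run$final$sample_id, levels = split$test_ids))
  true_all <- table(factor(truth$sample_id, levels = split$test_ids))
  list(model = model, metrics = metrics,
       count_cor = count_correlation(as.integer(pred_all),
                                     as.integer(true_all)),
       tmb_pred = pred_counts, tmb_true = true_counts,
       final = run$final, report = run$report, split = split)
}
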