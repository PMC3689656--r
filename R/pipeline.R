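#' Run the full site-prediction pipeline on one balanced dataset
#'
#' End-to-end driver used by the worked examples and the evaluation scripts:
#' extract windows, build the balanced datasets, split one of them into
#' train/test, fit the position-frequency table on positive training windows,
#' encode all six feature families, rank features by mRMR on the training
#' split, run incremental feature selection under cross-validation, pick the
#' optimal prefix, train the final forest and evaluate it on the held-out
#' test split.
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param sites Site tibble (`protein_id`, `position`, `label`).
#' @param annotations Per-residue annotation tibble from
#'   [collect_annotations()].
#' @param config A [window_config()] or bare odd window length.
#' @param dataset Which balanced dataset (1..`parts`) to run.
#' @param parts Number of negative parts.
#' @param folds,trees Cross-validation folds and trees per forest.
#' @param seed Integer seed driving every random step.
#' @param k_max Largest IFS prefix evaluated (defaults to all ranked
#'   features).
#' @param mrmr_n Number of mRMR rounds (defaults to all features; a prefix
#'   at least `k_max` long is required).
#' @param freq_on Fit the frequency table on `"positive"` (default) or
#'   `"all"` training windows.
#' @return A list of class `pyr_pipeline_result`: `windows`, `split`,
#'   `catalog`, `freq_table`, `ranking`, `curve`, `optimal_k`,
#'   `selected_features`, `model`, `test_predictions`, `test_counts`,
#'   `test_metrics`, `roc`, `seed`.
#' @export
run_site_pipeline <- function(proteins, sites, annotations,
                              config = window_config(17),
                              dataset = 1L, parts = 4L,
                              folds = 10L, trees = 10L, seed = 1L,
                              k_max = NULL, mrmr_n = NULL,
                              freq_on = "positive") {
  config <- as_window_config(config)
  windows <- build_sample_set(proteins, sites, config)
  bundled <- build_datasets(windows, parts = parts, seed = seed)
  ds <- dplyr::filter(bundled, .data$dataset == !!as.integer(dataset))
  ds <- dplyr::select(ds, -"dataset")
  split_ds <- split_train_test(ds, fraction = 0.8, seed = seed + dataset)

  train_windows <- dplyr::filter(split_ds, .data$split == "train")
  freq <- fit_frequency_table(train_windows, config, on = freq_on)
  catalog <- build_catalog(config)
  features <- encode_windows(dplyr::select(split_ds, -"split"),
                             annotations, freq, catalog)
  features$split <- split_ds$split
  train_feat <- dplyr::select(
    dplyr::filter(features, .data$split == "train"), -"split")
  test_feat <- dplyr::select(
    dplyr::filter(features, .data$split == "test"), -"split")

  if (!is.null(k_max) && is.null(mrmr_n)) mrmr_n <- k_max
  disc <- discretize_features(train_feat)
  ranking <- mrmr_rank(disc, train_feat$label, n_select = mrmr_n)
  curve <- run_ifs(train_feat, ranking, folds = folds, trees = trees,
                   seed = seed, k_max = k_max)
  k_opt <- select_optimal(curve)
  selected <- ranking$feature[seq_len(k_opt)]
  model <- train_final(train_feat, selected, trees = trees, seed = seed)
  pred <- stats::predict(model, test_feat)
  counts <- confusion_counts(test_feat$label, pred$class)
  metrics <- metric_set(counts)
  roc <- roc_curve(test_feat$label, pred$score)

  structure(list(windows = windows, split = split_ds, catalog = catalog,
                 freq_table = freq, ranking = ranking, curve = curve,
                 optimal_k = k_opt, selected_features = selected,
                 model = model, test_predictions = pred,
                 test_counts = counts, test_metrics = metrics,
                 roc = roc, seed = seed, dataset = as.integer(dataset)),
            class = "pyr_pipeline_result")
}

#' @export
print.pyr_pipeline_result <- function(x, ...) {
  m <- x$test_metrics
  cat("<pipeline result> dataset", x$dataset,
      "| optimal k =", x$optimal_k, "\n",
      sprintf("test: Sn %.2f%%  Sp %.2f%%  Ac %.2f%%  MCC %.4f  AUC %.4f\n",
              100 * m$sn, 100 * m$sp, 100 * m$ac, m$mcc, roc_auc(x$roc)))
  invisible(x)
}

#' Jaccard overlap between two feature sets
#'
#' Used to quantify how well incremental feature selection recovers a known
#' planted feature set.
#'
#' @param a,b Character vectors of feature names.
#' @return `|a intersect b| / |a union b|` (0 when both are empty).
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
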