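#' Build balanced datasets from an unbalanced sample set
#'
#' The extracted sample set is heavily unbalanced (many more negative than
#' positive serines). The negatives are shuffled under `seed` and partitioned
#' into `parts` disjoint, near-equal parts (sizes differ by at most one);
#' each dataset then pairs all positives with one negative part. With 407
#' negatives and 4 parts the part sizes are three of 102 and one of 101, so
#' the datasets have 148, 148, 148 and 147 samples.
#'
#' @param windows Window tibble ([build_sample_set()]) or feature tibble —
#'   anything with a `label` column.
#' @param parts Number of negative parts (datasets); must be `>= 2`.
#' @param seed Integer seed for the negative shuffle.
#' @return The input rows with a prepended `dataset` column (integer in
#'   `1:parts`); positive rows are repeated once per dataset.
#' @export
build_datasets <- function(windows, parts = 4L, seed = 1L) {
  parts <- as.integer(parts)
  if (is.na(parts) || parts < 2L) stop("parts must be >= 2", call. = FALSE)
  stopifnot("label" %in% names(windows))
  pos <- dplyr::filter(windows, .data$label == "positive")
  neg <- dplyr::filter(windows, .data$label == "negative")
  if (nrow(neg) < parts) {
    stop("Fewer negatives (", nrow(neg), ") than parts (", parts, ")",
         call. = FALSE)
  }
  set.seed(seed)
  neg <- neg[sample.int(nrow(neg)), , drop = FALSE]
  sizes <- rep(nrow(neg) %/% parts, parts)
  extra <- nrow(neg) %% parts
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  part_id <- rep(seq_len(parts), times = sizes)
  out <- purrr::map_dfr(seq_len(parts), function(k) {
    dplyr::bind_rows(
      dplyr::mutate(pos, dataset = k, .before = 1),
      dplyr::mutate(neg[part_id == k, , drop = FALSE], dataset = k,
                    .before = 1)
    )
  })
  out
}

#' Stratified train/test split
#'
#' Splits a dataset into training and testing parts, sampling within each
#' class so the class proportions are preserved; the training part receives
#' `ceiling(fraction * n)` samples of each class. Stratification guarantees
#' positives in both parts even for small positive classes.
#'
#' @param data Tibble with a `label` column.
#' @param fraction Training fraction (default 0.8, i.e. 4/5 train, 1/5 test).
#' @param seed Integer seed.
#' @return The input with a prepended `split` column (`"train"`/`"test"`).
#' @export
split_train_test <- function(data, fraction = 0.8, seed = 1L) {
  stopifnot("label" %in% names(data), fraction > 0, fraction < 1)
  counts <- table(data$label)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("Each class needs at least 2 members to split", call. = FALSE)
  }
  set.seed(seed)
  split <- rep("test", nrow(data))
  for (cl in names(counts)) {
    idx <- which(data$label == cl)
    n_train <- ceiling(fraction * length(idx))
    split[sample(idx, n_train)] <- "train"
  }
  dplyr::mutate(data, split = split, .before = 1)
}

rf_factor <- function(labels) factor(labels, levels = c("negative", "positive"))

fit_rf <- function(x, y, trees, seed) {
  set.seed(seed)
  randomForest::randomForest(x = x, y = y, ntree = trees)
}

# vote-fraction score for "positive" plus the tie->negative class rule
rf_predict_scores <- function(forest, x) {
  votes <- stats::predict(forest, x, type = "vote")
  score <- votes[, "positive"]
  cls <- ifelse(score > 0.5, "positive", "negative")
  tibble::tibble(score = unname(score), class = unname(cls))
}

stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Incremental feature selection under cross-validation
#'
#' Walks down a ranked feature list, and for each prefix size `k` scores a
#' fresh `trees`-tree random forest on the first `k` features under
#' stratified `folds`-fold cross-validation of the training set. The fold
#' partition is drawn once from `seed` and reused for every `k`, so curves
#' across `k` are comparable. Per fold, sensitivity, specificity, accuracy
#' and MCC are computed on the held-out fold and averaged over folds
#' (per-fold averaging; pooled fold confusions are available via
#' `pool = TRUE`).
#'
#' @param train_features Feature tibble (`sample_id`, `label`, features) of
#'   the training split.
#' @param ranking Ranking tibble from [mrmr_rank()] (or [maxrel_rank()]).
#' @param folds Number of CV folds.
#' @param trees Trees per forest.
#' @param seed Integer seed (fold assignment + per-fit seeds).
#' @param k_max Largest prefix size to evaluate (defaults to the full
#'   ranking).
#' @param pool Pool fold confusion counts instead of averaging fold metrics.
#' @return A tibble of class `pyr_ifs_curve`: columns `k`, `feature_added`,
#'   `sn`, `sp`, `ac`, `mcc`.
#' @export
run_ifs <- function(train_features, ranking, folds = 10L, trees = 10L,
                    seed = 1L, k_max = NULL, pool = FALSE) {
  stopifnot(all(ranking$feature %in% names(train_features)))
  labels <- rf_factor(train_features$label)
  if (any(table(labels) < folds)) {
    stop("A class has fewer members (", min(table(labels)),
         ") than folds (", folds, "); use fewer folds", call. = FALSE)
  }
  if (is.null(k_max)) k_max <- nrow(ranking)
  k_max <- min(as.integer(k_max), nrow(ranking))
  x_all <- feature_values(train_features)[, ranking$feature, drop = FALSE]
  fold <- stratified_folds(as.character(labels), folds, seed)
  set.seed(seed)
  fit_seeds <- matrix(sample.int(2^30, k_max * folds),
                      nrow = k_max, ncol = folds)
  rows <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    xk <- x_all[, seq_len(k), drop = FALSE]
    fold_metrics <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      forest <- fit_rf(xk[tr, , drop = FALSE], labels[tr],
                       trees, fit_seeds[k, f])
      pred <- rf_predict_scores(forest, xk[!tr, , drop = FALSE])
      fold_metrics[[f]] <- confusion_counts(as.character(labels[!tr]),
                                            pred$class)
    }
    cc <- dplyr::bind_rows(fold_metrics)
    if (pool) {
      m <- metric_set(dplyr::summarise(cc, dplyr::across(
        dplyr::everything(), sum)))
    } else {
      per_fold <- dplyr::bind_rows(lapply(seq_len(folds), function(f)
        metric_set(cc[f, ])))
      m <- dplyr::summarise(per_fold, dplyr::across(dplyr::everything(),
                                                    ~ mean(.x, na.rm = TRUE)))
    }
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(k = k, feature_added = ranking$feature[k]), m)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pyr_ifs_curve", class(out))
  out
}

#' Pick the optimal prefix size from an IFS curve
#'
#' The optimal feature set is the smallest prefix achieving the maximum MCC
#' (when two prefix sizes tie at the maximum, the smaller, more parsimonious
#' one is taken).
#'
#' @param curve IFS curve from [run_ifs()].
#' @return The optimal `k` (integer).
#' @export
select_optimal <- function(curve) {
  stopifnot(nrow(curve) >= 1, "mcc" %in% names(curve))
  curve$k[which.max(curve$mcc)]
}

#' Pick the optimal window length from per-window average MCCs
#'
#' Given the average (over datasets) best MCC achieved at each candidate
#' window length, returns the window with the maximum average MCC; ties are
#' resolved toward the larger window (more sequence context at equal
#' performance).
#'
#' @param window_mcc Tibble with columns `window_length` and `mcc`.
#' @return The selected window length (integer).
#' @export
select_window <- function(window_mcc) {
  stopifnot(nrow(window_mcc) >= 1,
            all(c("window_length", "mcc") %in% names(window_mcc)))
  best <- max(window_mcc$mcc)
  cand <- window_mcc$window_length[window_mcc$mcc == best]
  as.integer(max(cand))
}

#' Train the final random-forest site predictor
#'
#' Fits one `trees`-tree random forest on the full training split restricted
#' to the selected features. Ten trees with otherwise default forest
#' hyperparameters define the reference model for this task.
#'
#' @param train_features Training feature tibble.
#' @param features Character vector of selected feature names.
#' @param trees Number of trees.
#' @param seed Integer seed.
#' @return An object of class `pyr_rf` carrying the forest, the feature
#'   names, tree count and seed.
#' @export
train_final <- function(train_features, features, trees = 10L, seed = 1L) {
  if (length(features) == 0) stop("Empty feature selection", call. = FALSE)
  missing <- setdiff(features, names(train_features))
  if (length(missing)) {
    stop("Selected feature not in the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- feature_values(train_features)[, features, drop = FALSE]
  y <- rf_factor(train_features$label)
  forest <- fit_rf(x, y, trees, seed)
  structure(list(forest = forest, features = features,
                 trees = as.integer(trees), seed = as.integer(seed),
                 n_train = nrow(x)),
            class = "pyr_rf")
}

#' @export
print.pyr_rf <- function(x, ...) {
  cat("<pyruvoyl-site random forest>", x$trees, "trees,",
      length(x$features), "features,", x$n_train, "training samples\n")
  invisible(x)
}

#' Predict pyruvoyl-serine sites with a trained model
#'
#' Runs each sample down the forest; the score is the fraction of trees
#' voting positive and the class is the majority vote, with 50/50 ties
#' resolved to negative (conservative for a rare-positive screen).
#'
#' @param object A `pyr_rf` model from [train_final()].
#' @param newdata Feature tibble containing at least the model's features.
#' @param ... Unused.
#' @return A tibble with `sample_id` (if present), `score` and `class`.
#' @export
predict.pyr_rf <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop("Missing feature column: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- feature_values(newdata)[, object$features, drop = FALSE]
  out <- rf_predict_scores(object$forest, x)
  if ("sample_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = newdata$sample_id), out)
  }
  out
}

#' Tidy and glance methods for fitted site predictors
#'
#' `tidy()` reports per-feature importance (mean decrease in Gini impurity);
#' `glance()` reports one-row model-level information.
#'
#' @param x A `pyr_rf` model.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pyr_rf <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble::tibble(feature = rownames(imp),
                 importance = as.numeric(imp[, 1])) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname tidy.pyr_rf
#' @export
glance.pyr_rf <- function(x, ...) {
  conf <- x$forest$confusion
  tibble::tibble(trees = x$trees,
                 n_features = length(x$features),
                 n_train = x$n_train,
                 oob_error = mean(x$forest$err.rate[x$trees, "OOB"]))
}
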