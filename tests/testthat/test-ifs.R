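test_that("negative partition is disjoint, covering and near-equal", {
  set.seed(1)
  ws <- tibble::tibble(
    sample_id = paste0("s", 1:453),
    label = c(rep("positive", 46), rep("negative", 407))
  )
  b <- build_datasets(ws, parts = 4, seed = 3)
  sizes <- table(b$dataset)
  expect_equal(sort(as.integer(sizes), decreasing = TRUE),
               c(148L, 148L, 148L, 147L))
  # every dataset holds every positive
  pos_per <- tapply(b$label == "positive", b$dataset, sum)
  expect_true(all(pos_per == 46))
  # negatives: disjoint parts covering all negatives
  negs <- b$sample_id[b$label == "negative"]
  expect_equal(sort(unique(negs)), sort(ws$sample_id[ws$label == "negative"]))
  expect_false(anyDuplicated(negs) > 0)

  # arbitrary n / parts stays a true partition
  ws2 <- tibble::tibble(sample_id = paste0("t", 1:25),
                        label = c(rep("positive", 4), rep("negative", 21)))
  b2 <- build_datasets(ws2, parts = 5, seed = 9)
  negs2 <- b2$sample_id[b2$label == "negative"]
  expect_equal(sort(unique(negs2)), sort(ws2$sample_id[5:25]))
  expect_equal(as.integer(table(b2$dataset)), c(9L, 8L, 8L, 8L, 8L))
  expect_error(build_datasets(ws2, parts = 1), "parts")
})

test_that("train/test split is stratified with ceiling(0.8 n) per class", {
  d <- tibble::tibble(sample_id = seq_len(148),
                      label = c(rep("positive", 46), rep("negative", 102)))
  s <- split_train_test(d, 0.8, seed = 4)
  expect_equal(sum(s$split == "train" & s$label == "positive"), 37L)
  expect_equal(sum(s$split == "test" & s$label == "positive"), 9L)
  expect_equal(sum(s$split == "train" & s$label == "negative"), 82L)

  toy <- tibble::tibble(label = rep(c("positive", "negative"), each = 10))
  st <- split_train_test(toy, 0.8, seed = 1)
  expect_equal(as.vector(table(st$split, st$label)),
               c(2L, 8L, 2L, 8L))

  expect_identical(split_train_test(d, 0.8, seed = 7),
                   split_train_test(d, 0.8, seed = 7))
  expect_error(split_train_test(tibble::tibble(label = c("positive", "negative")),
                                0.8, 1), "at least 2")
})

make_toy_features <- function(n_pos = 30, n_neg = 60, p_noise = 5, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  label <- c(rep("positive", n_pos), rep("negative", n_neg))
  truth <- as.numeric(label == "positive")
  noise <- matrix(stats::runif(n * p_noise), nrow = n,
                  dimnames = list(NULL, paste0("noise", seq_len(p_noise))))
  dplyr::bind_cols(
    tibble::tibble(sample_id = paste0("s", seq_len(n)), label = label,
                   oracle = truth),
    tibble::as_tibble(noise))
}

test_that("IFS reaches MCC 1 at k = 1 on a separable toy and has one row per k", {
  feats <- make_toy_features()
  ranking <- mrmr_rank(discretize_features(feats), feats$label)
  expect_equal(ranking$feature[1], "oracle")
  curve <- run_ifs(feats, ranking, folds = 5, trees = 10, seed = 2)
  expect_equal(nrow(curve), 6L)
  expect_equal(curve$k, 1:6)
  expect_equal(curve$mcc[1], 1.0)
  expect_equal(select_optimal(curve), 1L)
})

test_that("IFS on pure noise stays near-zero MCC", {
  feats <- make_toy_features(n_pos = 46, n_neg = 102, p_noise = 8, seed = 5)
  feats$oracle <- NULL
  ranking <- mrmr_rank(discretize_features(feats), feats$label)
  curve <- run_ifs(feats, ranking, folds = 10, trees = 10, seed = 5)
  expect_true(all(abs(curve$mcc) < 0.3))
})

test_that("select_optimal picks the smallest k at the maximum", {
  curve <- tibble::tibble(k = 1:25, mcc = c(rep(0.5, 8), 1, rep(0.7, 12),
                                            1, rep(0.6, 3)))
  expect_equal(select_optimal(curve), 9L)
  expect_equal(select_optimal(tibble::tibble(k = 1:5, mcc = 1:5 / 5)), 5L)
  expect_equal(select_optimal(tibble::tibble(k = 1:5, mcc = rep(0.4, 5))), 1L)
})

test_that("select_window takes the max average MCC with ties to the larger window", {
  tbl <- tibble::tibble(window_length = c(15L, 17L, 19L, 21L),
                        mcc = c(0.9803, 0.9803, 0.9753, 0.9655))
  expect_equal(select_window(tbl), 17L)
  expect_equal(select_window(tbl[3, ]), 19L)
  expect_equal(select_window(tibble::tibble(window_length = c(15L, 19L),
                                            mcc = c(0.9, 0.95))), 19L)
})

test_that("final model resubstitutes perfectly on a separable toy and is deterministic", {
  feats <- make_toy_features()
  model <- train_final(feats, c("oracle", "noise1"), trees = 10, seed = 3)
  pred <- predict(model, feats)
  expect_equal(metric_set(confusion_counts(feats$label, pred$class))$mcc, 1.0)
  pred2 <- predict(train_final(feats, c("oracle", "noise1"), trees = 10,
                               seed = 3), feats)
  expect_identical(pred, pred2)
  # vote-fraction scores are quantized to elevenths with 10 trees
  expect_true(all(pred$score %in% (0:10 / 10)))

  expect_error(train_final(feats, character()), "Empty")
  expect_error(train_final(feats, "nope"), "nope")
  expect_error(predict(model, feats[, 1:3]), "noise1")
})

test_that("tidy and glance summarize a fitted model", {
  feats <- make_toy_features()
  model <- train_final(feats, c("oracle", "noise1", "noise2"), seed = 1)
  td <- tidy(model)
  expect_equal(sort(td$feature), sort(c("oracle", "noise1", "noise2")))
  expect_equal(td$feature[1], "oracle")  # dominant importance
  gl <- glance(model)
  expect_equal(gl$trees, 10L)
  expect_equal(gl$n_features, 3L)
})

test_that("planted-signal recovery: selected features overlap the planted set", {
  # three seeds here to keep the unit suite fast; the acceptance suite runs ten
  pf <- planted_features(window_config(17))
  res <- vapply(1:3, function(s) {
    r <- run_synthetic_pipeline(seed = 300 + s)
    c(jaccard(r$selected_features, pf), r$test_metrics$mcc)
  }, numeric(2))
  expect_gte(mean(res[1, ]), 0.4)
  expect_gte(mean(res[2, ]), 0.7)
})
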