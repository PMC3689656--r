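#' Confusion counts for binary site prediction
#'
#' Tallies true/false positives and negatives. Labels are `"positive"` /
#' `"negative"` strings (or factors coercible to them).
#'
#' @param truth,predicted Equal-length vectors of class labels.
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("confusion_counts: length mismatch (", length(truth), " vs ",
         length(predicted), ")", call. = FALSE)
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  ok <- c("positive", "negative")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("Labels must be 'positive' or 'negative'", call. = FALSE)
  }
  tibble::tibble(
    tp = sum(truth == "positive" & predicted == "positive"),
    fp = sum(truth == "negative" & predicted == "positive"),
    tn = sum(truth == "negative" & predicted == "negative"),
    fn = sum(truth == "positive" & predicted == "negative")
  )
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' \itemize{
#'   \item `Sn = TP / (TP + FN)` — fraction of true pyruvoyl serines recovered.
#'   \item `Sp = TN / (TN + FP)` — fraction of non-pyruvoyl serines recovered.
#'   \item `Ac = (TP + TN) / (TP + FP + TN + FN)`.
#'   \item `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#'     in `[-1, 1]`; when any denominator factor is 0 the coefficient is
#'     defined as 0 (the no-relationship convention extended to degenerate
#'     counts).
#' }
#' `Sn` (`Sp`) is `NA` when no positive (negative) samples are present — the
#' rate is undefined, and the `NA` is deliberate rather than a silent 0.
#'
#' @param counts One-row tibble from [confusion_counts()], or `tp` given as a
#'   scalar together with `fp`, `tn`, `fn`.
#' @param fp,tn,fn Scalar counts when `counts` is given as `tp`.
#' @return A one-row tibble with columns `sn`, `sp`, `ac`, `mcc`.
#' @examples
#' metric_set(tibble::tibble(tp = 8, fp = 1, tn = 22, fn = 1))
#' @export
metric_set <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.data.frame(counts)) {
    counts <- tibble::tibble(tp = counts, fp = fp, tn = tn, fn = fn)
  }
  stopifnot(nrow(counts) == 1, all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (any(c(tp, fp, tn, fn) < 0) || tp + fp + tn + fn < 1) {
    stop("Confusion counts must be non-negative and total >= 1", call. = FALSE)
  }
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ac <- (tp + tn) / (tp + fp + tn + fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  tibble::tibble(sn = sn, sp = sp, ac = ac, mcc = mcc)
}

#' Round half-up and format as a percentage
#'
#' Reported rates are conventionally printed as percentages rounded half-up
#' to two decimals (so 0.988875 prints as `98.89`).
#'
#' @param x Proportion(s) in `[0, 1]`.
#' @param digits Decimal places.
#' @return Numeric percentage(s).
#' @export
as_percent <- function(x, digits = 2) {
  round_half_up(100 * x, digits)
}

#' @rdname as_percent
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Reconstruct the smallest confusion matrix consistent with printed rates
#'
#' Published tables report `Sn`, `Sp` and `Ac` as percentages rounded to two
#' decimals. This helper searches for the smallest integer counts
#' (minimal positive-class size, then minimal negative-class size) whose
#' exact rates round half-up to the printed values, so that `MCC` and `Ac`
#' can be recomputed from a table row.
#'
#' @param sn_pct,sp_pct Printed sensitivity/specificity percentages.
#' @param ac_pct Optional printed accuracy percentage (checked when given).
#' @param max_class Largest class size to search.
#' @return A one-row tibble of counts (`tp`, `fp`, `tn`, `fn`).
#' @examples
#' min_confusion_from_rates(88.89, 95.65, 93.75)
#' @export
min_confusion_from_rates <- function(sn_pct, sp_pct, ac_pct = NULL,
                                     max_class = 500L) {
  match_rate <- function(pct) {
    for (n in seq_len(max_class)) {
      k <- 0:n
      hit <- which(as_percent(k / n) == pct)
      if (length(hit)) return(c(k[hit[1]], n))
    }
    stop("No class size <= ", max_class, " reproduces ", pct, "%",
         call. = FALSE)
  }
  pos <- match_rate(sn_pct)   # (tp, npos)
  neg <- match_rate(sp_pct)   # (tn, nneg)
  # grow the classes jointly until the printed accuracy (if any) also matches
  for (mult in 1:400) {
    tp <- pos[1] * mult; npos <- pos[2] * mult
    for (mult2 in 1:400) {
      tn <- neg[1] * mult2; nneg <- neg[2] * mult2
      ac <- (tp + tn) / (npos + nneg)
      if (is.null(ac_pct) || as_percent(ac) == ac_pct) {
        return(tibble::tibble(tp = tp, fp = nneg - tn,
                              tn = tn, fn = npos - tp))
      }
    }
  }
  stop("No confusion matrix consistent with the printed rates found",
       call. = FALSE)
}

#' ROC curve and AUC from vote-fraction scores
#'
#' Sweeps a threshold over the distinct scores (equal scores are grouped),
#' accumulating the true- and false-positive rates, and computes the area
#' under the curve by the trapezoid rule. With a 10-tree forest the scores
#' are vote fractions quantized to 0, 0.1, ..., 1, giving at most 11
#' thresholds.
#'
#' @param truth Class labels (`"positive"`/`"negative"`), both present.
#' @param score Numeric scores, larger meaning more positive.
#' @return A tibble of class `pyr_roc` with columns `threshold`, `fpr`,
#'   `tpr`, and the AUC in `attr(, "auc")` (also via [roc_auc()]).
#' @export
roc_curve <- function(truth, score) {
  if (length(truth) != length(score)) {
    stop("roc_curve: length mismatch", call. = FALSE)
  }
  truth <- as.character(truth)
  npos <- sum(truth == "positive")
  nneg <- sum(truth == "negative")
  if (npos == 0 || nneg == 0) {
    stop("ROC requires both classes to be present", call. = FALSE)
  }
  ord <- order(-score)
  s <- score[ord]
  is_pos <- truth[ord] == "positive"
  # group tied scores: cumulative counts at the last index of each tie group
  last <- which(!duplicated(s, fromLast = TRUE))
  ctp <- cumsum(is_pos)[last]
  cfp <- cumsum(!is_pos)[last]
  out <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, cfp / nneg),
    tpr = c(0, ctp / npos)
  )
  auc <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) +
                              utils::tail(out$tpr, -1)) / 2)
  structure(out, auc = auc, class = c("pyr_roc", class(out)))
}

#' @rdname roc_curve
#' @param roc A `pyr_roc` object.
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "pyr_roc"))
  attr(roc, "auc")
}
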