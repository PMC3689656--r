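#' Discretize a feature matrix for mutual-information estimation
#'
#' Mutual information between a feature and the class is estimated from
#' finite samples, which requires discrete codes. Features with at most three
#' distinct values (binary one-hot bits, constants) are passed through as
#' categorical codes; continuous features are cut into three levels at
#' mean +/- one standard deviation, the convention of the original mRMR
#' program. A constant feature keeps a single code (its MI with anything
#' is 0).
#'
#' @param features Feature tibble (`sample_id`, `label`, numeric columns) or
#'   a bare numeric matrix.
#' @return An object of class `pyr_discretized`: list with `codes` (integer
#'   matrix, codes starting at 1), `n_levels` (integer per feature) and
#'   `scheme` (`"categorical"` or `"three_bin"` per feature).
#' @export
discretize_features <- function(features) {
  m <- if (is.data.frame(features)) feature_values(features) else features
  if (!is.matrix(m) || nrow(m) == 0) {
    stop("Cannot discretize an empty feature matrix", call. = FALSE)
  }
  codes <- matrix(1L, nrow = nrow(m), ncol = ncol(m),
                  dimnames = dimnames(m))
  n_levels <- integer(ncol(m))
  scheme <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ux <- sort(unique(x))
    if (length(ux) <= 3) {
      codes[, j] <- match(x, ux)
      n_levels[j] <- length(ux)
      scheme[j] <- "categorical"
    } else {
      mu <- mean(x)
      sdev <- stats::sd(x)
      codes[, j] <- 1L + (x >= mu - sdev) + (x > mu + sdev)
      n_levels[j] <- 3L
      scheme[j] <- "three_bin"
    }
  }
  structure(list(codes = codes, n_levels = n_levels, scheme = scheme,
                 feature = colnames(m)),
            class = "pyr_discretized")
}

#' @export
print.pyr_discretized <- function(x, ...) {
  cat("<discretized matrix>", nrow(x$codes), "samples x",
      ncol(x$codes), "features;",
      sum(x$scheme == "three_bin"), "three-binned\n")
  invisible(x)
}

#' Mutual information between two discrete vectors (bits)
#'
#' Plug-in (maximum-likelihood) estimate over the observed joint cells:
#' `sum p(x, y) * log2(p(x, y) / (p(x) p(y)))`, with empty cells contributing
#' 0 and no pseudo-counts. Non-negative and symmetric; base 2 so the unit is
#' bits.
#'
#' @param x,y Vectors of equal length; coerced to integer codes.
#' @return The MI estimate in bits (a non-negative scalar).
#' @examples
#' x <- rep(0:1, each = 8)
#' mutual_information(x, x)  # 1 bit
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("mutual_information: length mismatch (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) == 0) stop("mutual_information: empty vectors", call. = FALSE)
  xi <- as.integer(factor(x))
  yi <- as.integer(factor(y))
  mi_codes(xi, max(xi), yi, max(yi))
}

# fast core: xi in 1..kx, yi in 1..ky
mi_codes <- function(xi, kx, yi, ky) {
  n <- length(xi)
  joint <- tabulate((xi - 1L) * ky + yi, nbins = kx * ky) / n
  px <- tabulate(xi, nbins = kx) / n
  py <- tabulate(yi, nbins = ky) / n
  pxy <- rep(px, each = ky) * rep.int(py, kx)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / pxy[nz]))
}

check_two_classes <- function(labels) {
  u <- unique(labels)
  if (length(u) < 2) {
    stop("Feature ranking requires both classes to be present", call. = FALSE)
  }
}

label_codes <- function(labels) {
  li <- as.integer(factor(labels))
  list(codes = li, k = max(li))
}

#' Rank features by relevance to the class (MaxRel)
#'
#' Orders features by decreasing mutual information with the class label;
#' ties are broken by ascending catalog (column) index so the ranking is
#' bit-reproducible.
#'
#' @param disc A `pyr_discretized` object (or a feature tibble, which is
#'   discretized on the fly).
#' @param labels Class vector (two classes required).
#' @return A tibble with columns `rank`, `feature`, `index` (catalog column
#'   index) and `relevance` (MI with the class, bits).
#' @export
maxrel_rank <- function(disc, labels) {
  disc <- as_discretized(disc)
  check_two_classes(labels)
  lab <- label_codes(labels)
  rel <- vapply(seq_len(ncol(disc$codes)), function(j) {
    mi_codes(disc$codes[, j], disc$n_levels[j], lab$codes, lab$k)
  }, numeric(1))
  ord <- order(-rel, seq_along(rel))
  tibble::tibble(rank = seq_along(ord),
                 feature = disc$feature[ord],
                 index = ord,
                 relevance = rel[ord])
}

as_discretized <- function(x) {
  if (inherits(x, "pyr_discretized")) x else discretize_features(x)
}

#' Rank features by minimum redundancy, maximum relevance (mRMR)
#'
#' Greedy forward selection: at each round the candidate maximizing
#' `D(f) - R(f)` is added, where `D(f)` is the mutual information between the
#' feature and the class and `R(f)` is the mean mutual information between
#' the feature and the already-selected set. In round 1 the selected set is
#' empty, so `R = 0` and the first pick is the MaxRel top feature. Ties are
#' broken by ascending catalog index. The round index records when each
#' feature was selected: the earlier, the better the relevance/redundancy
#' trade-off.
#'
#' @inheritParams maxrel_rank
#' @param n_select Number of rounds to run (defaults to all features).
#' @return A tibble with columns `round`, `feature`, `index`, `relevance`
#'   (`D`), `redundancy` (`R` at selection time) and `score` (`D - R`).
#' @export
mrmr_rank <- function(disc, labels, n_select = NULL) {
  disc <- as_discretized(disc)
  check_two_classes(labels)
  lab <- label_codes(labels)
  p <- ncol(disc$codes)
  if (is.null(n_select)) n_select <- p
  n_select <- min(as.integer(n_select), p)
  rel <- vapply(seq_len(p), function(j) {
    mi_codes(disc$codes[, j], disc$n_levels[j], lab$codes, lab$k)
  }, numeric(1))

  selected <- integer(0)
  red_sum <- numeric(p)         # running sum of MI(f, each selected feature)
  remaining <- rep(TRUE, p)
  out_round <- integer(n_select)
  out_index <- integer(n_select)
  out_rel <- numeric(n_select)
  out_red <- numeric(n_select)

  for (r in seq_len(n_select)) {
    m <- length(selected)
    red <- if (m == 0) numeric(p) else red_sum / m
    score <- rel - red
    score[!remaining] <- -Inf
    pick <- which.max(score)    # which.max returns the first (lowest index) max
    out_round[r] <- r
    out_index[r] <- pick
    out_rel[r] <- rel[pick]
    out_red[r] <- if (m == 0) 0 else red[pick]
    remaining[pick] <- FALSE
    selected <- c(selected, pick)
    if (r < n_select) {
      cand <- which(remaining)
      red_sum[cand] <- red_sum[cand] + vapply(cand, function(j) {
        mi_codes(disc$codes[, j], disc$n_levels[j],
                 disc$codes[, pick], disc$n_levels[pick])
      }, numeric(1))
    }
  }
  tibble::tibble(round = out_round,
                 feature = disc$feature[out_index],
                 index = out_index,
                 relevance = out_rel,
                 redundancy = out_red,
                 score = out_rel - out_red)
}
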