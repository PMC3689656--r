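#' Build the feature catalog for a window length
#'
#' For a `(2w+1)`-residue window the encoding comprises six feature families:
#' \describe{
#'   \item{pssm}{20 conservation scores per site: `20 * (2w+1)` features,
#'     the PSSM weighted percentages in `[0, 1]`.}
#'   \item{disorder}{one disorder score per site: `2w+1` features.}
#'   \item{ss}{3-bit one-hot secondary structure per site (`helix`/`strand`/
#'     `other`): `3 * (2w+1)` features.}
#'   \item{sa}{2-bit one-hot solvent accessibility per site
#'     (`buried`/`exposed`): `2 * (2w+1)` features.}
#'   \item{aaf}{five Atchley amino-acid factors per flanking site (the center
#'     is always serine, so it carries none): `5 * 2w` features.}
#'   \item{freq}{the training-set occurrence frequency of the observed symbol
#'     at each flanking site: `2w` features.}
#' }
#' Total: `64w + 26` features. Descriptors are ordered by family (in the
#' order above), then site offset (1..`2w+1`, center at `w+1`), then detail
#' alphabetically, and this order is fixed: every feature matrix aligns to it.
#'
#' @param config A [window_config()] or a bare odd window length.
#' @return A tibble with columns `feature` (canonical name), `family`,
#'   `offset` and `detail`, with `64w + 26` rows.
#' @examples
#' nrow(build_catalog(window_config(17)))  # 538
#' @export
build_catalog <- function(config = window_config()) {
  config <- as_window_config(config)
  w <- config$w
  len <- config$window_length
  center <- w + 1L
  all_off <- seq_len(len)
  flank_off <- setdiff(all_off, center)
  rows <- list(
    tidyr::expand_grid(family = "pssm", offset = all_off,
                       detail = aa_alphabet()),
    tidyr::expand_grid(family = "disorder", offset = all_off, detail = ""),
    tidyr::expand_grid(family = "ss", offset = all_off,
                       detail = sort(ss_states())),
    tidyr::expand_grid(family = "sa", offset = all_off,
                       detail = sort(sa_states())),
    tidyr::expand_grid(family = "aaf", offset = flank_off,
                       detail = aaf_factor_names()),
    tidyr::expand_grid(family = "freq", offset = flank_off, detail = "")
  )
  cat_tbl <- dplyr::bind_rows(rows)
  cat_tbl <- dplyr::mutate(cat_tbl, feature = feature_name(
    .data$family, .data$offset, .data$detail))
  cat_tbl[, c("feature", "family", "offset", "detail")]
}

feature_name <- function(family, offset, detail) {
  n <- max(length(family), length(offset), length(detail))
  family <- rep_len(family, n)
  offset <- rep_len(offset, n)
  detail <- rep_len(detail, n)
  base <- sprintf("%s_o%02d", family, offset)
  ifelse(detail == "", base, paste0(base, "_", detail))
}

#' Fit the position-specific symbol frequency table
#'
#' Computes, for each flanking site offset (the center is always serine and
#' is excluded), the occurrence frequency of each of the 21 symbols (20 amino
#' acids plus the padding character `"X"`) over the supplied training
#' windows. By default only positive training windows are used, so the table
#' characterizes the neighborhood of true pyruvoyl serines; fitting on all
#' training windows is available as an option.
#'
#' @param windows Window tibble (see [build_sample_set()]); training rows only.
#' @param config A [window_config()] or a bare odd window length.
#' @param on `"positive"` (default) to fit on positive windows only, or
#'   `"all"`.
#' @return A tibble with columns `offset`, `symbol` and `freq`; per offset
#'   the frequencies sum to 1.
#' @export
fit_frequency_table <- function(windows, config = window_config(),
                                on = c("positive", "all")) {
  on <- match.arg(on)
  config <- as_window_config(config)
  len <- config$window_length
  center <- config$w + 1L
  if (on == "positive") {
    windows <- dplyr::filter(windows, .data$label == "positive")
  }
  if (nrow(windows) == 0) {
    stop("No ", if (on == "positive") "positive " else "",
         "training windows to fit the frequency table on", call. = FALSE)
  }
  stopifnot(all(nchar(windows$residues) == len))
  symbols <- c(aa_alphabet(), "X")
  mat <- do.call(rbind, strsplit(windows$residues, ""))
  out <- purrr::map_dfr(setdiff(seq_len(len), center), function(off) {
    counts <- table(factor(mat[, off], levels = symbols))
    tibble::tibble(offset = off, symbol = symbols,
                   freq = as.numeric(counts) / nrow(mat))
  })
  out
}

#' Assemble per-residue annotations with PSSM tracks
#'
#' Joins the tabular disorder/secondary-structure/solvent-accessibility
#' annotations with per-protein PSSM matrices into one per-residue tibble
#' used by the encoder, and checks that every track covers every residue.
#'
#' @param annotation_tbl Tibble from [read_annotation_table()].
#' @param pssms Named list of PSSM matrices (one per protein id) as returned
#'   by [read_pssm_ascii()].
#' @param proteins Optional protein tibble; when given, track lengths are
#'   checked against sequence lengths.
#' @return A tibble with columns `protein_id`, `position`, `disorder`, `ss`,
#'   `sa` and 20 `pssm_*` columns.
#' @export
collect_annotations <- function(annotation_tbl, pssms, proteins = NULL) {
  annotation_tbl <- validate_annotation_table(annotation_tbl)
  ids <- unique(annotation_tbl$protein_id)
  missing <- setdiff(ids, names(pssms))
  if (length(missing)) {
    stop("No PSSM supplied for protein: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pssm_tbl <- purrr::map_dfr(ids, function(id) {
    m <- pssms[[id]]
    colnames(m) <- paste0("pssm_", colnames(m))
    dplyr::bind_cols(tibble::tibble(protein_id = id,
                                    position = seq_len(nrow(m))),
                     tibble::as_tibble(m))
  })
  out <- dplyr::inner_join(annotation_tbl, pssm_tbl,
                           by = c("protein_id", "position"))
  if (nrow(out) != nrow(annotation_tbl)) {
    stop("PSSM rows do not cover every annotated residue", call. = FALSE)
  }
  if (!is.null(proteins)) {
    lens <- dplyr::count(out, .data$protein_id, name = "n_track")
    ref <- tibble::tibble(protein_id = proteins$id,
                          n_seq = nchar(proteins$sequence))
    chk <- dplyr::inner_join(lens, ref, by = "protein_id")
    bad <- chk$protein_id[chk$n_track != chk$n_seq]
    if (length(bad)) {
      stop("Annotation track length != sequence length for: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Encode peptide windows into the 64w+26 feature matrix
#'
#' Encodes each window against the feature catalog. Real residues contribute
#' their PSSM percentages, disorder score, one-hot secondary structure and
#' solvent accessibility bits, Atchley factors and the position-specific
#' frequency of the observed symbol; padded (`"X"`) sites contribute zeros
#' for all annotation-derived and Atchley features, while the `freq` feature
#' still reports the table frequency of `"X"` at that offset. Feature values
#' are used unscaled: the downstream random forest is insensitive to
#' monotone rescaling.
#'
#' @param windows Window tibble (see [build_sample_set()]).
#' @param annotations Per-residue annotation tibble from
#'   [collect_annotations()].
#' @param freq_table Frequency table from [fit_frequency_table()].
#' @param catalog Feature catalog from [build_catalog()]; its window length
#'   must match the windows.
#' @return A tibble with `sample_id`, `label`, then one numeric column per
#'   catalog feature, rows in input order.
#' @export
encode_windows <- function(windows, annotations, freq_table, catalog) {
  if (nrow(windows) == 0) stop("No windows to encode", call. = FALSE)
  len <- max(catalog$offset)
  w <- (len - 1L) %/% 2L
  center <- w + 1L
  stopifnot(all(nchar(windows$residues) == len))
  if (!"sample_id" %in% names(windows)) {
    windows <- dplyr::mutate(windows, sample_id = paste0(
      .data$protein_id, ":", .data$center_pos))
  }
  symbols <- c(aa_alphabet(), "X")

  # long layout: one row per (sample, offset)
  long <- tidyr::expand_grid(row = seq_len(nrow(windows)),
                             offset = seq_len(len))
  long$protein_id <- windows$protein_id[long$row]
  long$position <- windows$center_pos[long$row] - center + long$offset
  res_mat <- do.call(rbind, strsplit(windows$residues, ""))
  long$symbol <- res_mat[cbind(long$row, long$offset)]
  if (!all(long$symbol %in% symbols)) {
    stop("Window contains a symbol outside the amino-acid alphabet + 'X'",
         call. = FALSE)
  }
  in_seq <- long$symbol != "X"
  # every in-sequence site must have an annotation row
  ann <- dplyr::left_join(long, annotations,
                          by = c("protein_id", "position"))
  miss <- in_seq & is.na(ann$disorder)
  if (any(miss)) {
    i <- which(miss)[1]
    stop("Missing annotation for ", ann$protein_id[i], " position ",
         ann$position[i], " (sample ", windows$sample_id[long$row[i]], ")",
         call. = FALSE)
  }

  n <- nrow(windows)
  values <- matrix(0, nrow = n, ncol = nrow(catalog),
                   dimnames = list(NULL, catalog$feature))

  idx <- cbind(ann$row, ann$offset)  # (sample, offset) coordinates
  # pssm family
  for (aa in aa_alphabet()) {
    col <- ann[[paste0("pssm_", aa)]]
    col[!in_seq] <- 0
    tgt <- feature_name("pssm", ann$offset, aa)
    values[cbind(ann$row, match(tgt, catalog$feature))] <- col
  }
  # disorder
  dis <- ann$disorder
  dis[!in_seq] <- 0
  values[cbind(ann$row,
               match(feature_name("disorder", ann$offset, ""),
                     catalog$feature))] <- dis
  # ss one-hot
  for (st in ss_states()) {
    bit <- as.numeric(!is.na(ann$ss) & ann$ss == st & in_seq)
    values[cbind(ann$row,
                 match(feature_name("ss", ann$offset, st),
                       catalog$feature))] <- bit
  }
  # sa one-hot
  for (st in sa_states()) {
    bit <- as.numeric(!is.na(ann$sa) & ann$sa == st & in_seq)
    values[cbind(ann$row,
                 match(feature_name("sa", ann$offset, st),
                       catalog$feature))] <- bit
  }
  # aaf: Atchley factors of the window residue itself ('X' -> 0); flanks only
  af <- atchley_factors()
  flank <- ann$offset != center
  for (fct in aaf_factor_names()) {
    v <- numeric(nrow(ann))
    real <- ann$symbol != "X"
    v[real] <- af[ann$symbol[real], fct]
    coord <- cbind(ann$row,
                   match(feature_name("aaf", ann$offset, fct),
                         catalog$feature))
    values[coord[flank, , drop = FALSE]] <- v[flank]
  }
  # freq: table frequency of the observed symbol (including 'X'); flanks only
  ft <- dplyr::left_join(
    ann[flank, c("row", "offset", "symbol")], freq_table,
    by = c("offset", "symbol"))
  fv <- ifelse(is.na(ft$freq), 0, ft$freq)
  values[cbind(ft$row,
               match(feature_name("freq", ft$offset, ""),
                     catalog$feature))] <- fv

  dplyr::bind_cols(
    tibble::tibble(sample_id = windows$sample_id, label = windows$label),
    tibble::as_tibble(values)
  )
}

#' Encode a single peptide window
#'
#' Convenience wrapper around [encode_windows()] for one window row.
#'
#' @param window One-row window tibble.
#' @inheritParams encode_windows
#' @return A one-row feature tibble.
#' @export
encode_window <- function(window, annotations, freq_table, catalog) {
  stopifnot(nrow(window) == 1)
  encode_windows(window, annotations, freq_table, catalog)
}

#' Extract the numeric feature block of a feature tibble
#'
#' @param features Feature tibble (`sample_id`, `label`, feature columns).
#' @return A numeric matrix with sample ids as row names.
#' @export
feature_values <- function(features) {
  cols <- setdiff(names(features), c("sample_id", "label"))
  m <- as.matrix(features[, cols])
  rownames(m) <- features$sample_id
  m
}
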