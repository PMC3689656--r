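#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a tibble of protein records. The
#' identifier of each record is the header token before the first whitespace.
#' Sequences must use the 20 standard amino-acid letters only: ambiguous or
#' non-standard letters (B, J, O, U, X, Z) are rejected rather than silently
#' coerced, because downstream composition features would be corrupted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `sequence` (uppercase
#'   character), one row per record in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKSSA", ">P2", "GGSAG"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(nzchar(trimws(lines)))) {
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  # pre-scan sequence lines so parse errors carry a line number
  ok <- paste0(aa_alphabet(), collapse = "")
  seq_lines <- which(!startsWith(lines, ">") & nzchar(trimws(lines)))
  for (i in seq_lines) {
    bad <- stringr::str_detect(toupper(trimws(lines[i])),
                               paste0("[^", ok, "]"))
    if (bad) {
      stop("Invalid sequence character in FASTA at line ", i,
           ": only the 20 standard amino-acid letters are accepted",
           call. = FALSE)
    }
  }
  aas <- Biostrings::readAAStringSet(path)
  ids <- stringr::str_extract(names(aas), "^\\S+")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("Duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(aas))
  if (any(nchar(seqs) == 0)) {
    stop("FASTA record with empty sequence: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: writes one record per row of `proteins`.
#'
#' @param proteins Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$id[i]), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the plain-text PSSM that PSI-BLAST writes (the `-Q` output dialect:
#' two header lines, then one row per residue carrying the residue index and
#' letter, 20 integer log-odds columns and 20 integer weighted observed
#' percentage columns). By default the weighted percentage columns are
#' returned divided by 100, i.e. per-residue probabilities against mutation
#' to each of the 20 amino acids, in `[0, 1]`. The log-odds columns are
#' available as a documented alternative.
#'
#' @param path Path to the ASCII PSSM file.
#' @param expected_length Number of residues the matrix must cover (the
#'   protein's sequence length); a mismatch is an error.
#' @param values `"percentages"` (default; divided by 100) or `"log_odds"`.
#' @return A numeric matrix with `expected_length` rows and 20 columns named
#'   by amino acid in alphabetical order.
#' @export
read_pssm_ascii <- function(path, expected_length,
                            values = c("percentages", "log_odds")) {
  values <- match.arg(values)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  # data rows start with an integer residue index followed by a letter
  is_row <- grepl("^\\s*\\d+\\s+[A-Z]\\s", lines)
  rows <- lines[is_row]
  if (length(rows) != expected_length) {
    stop("PSSM at ", path, " has ", length(rows),
         " residue rows; expected ", expected_length, call. = FALSE)
  }
  out <- matrix(NA_real_, nrow = expected_length, ncol = 20,
                dimnames = list(NULL, aa_alphabet()))
  offset <- if (values == "log_odds") 2L else 22L
  for (i in seq_along(rows)) {
    tok <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    if (length(tok) < 42) {
      stop("Unparseable PSSM row ", i, " in ", path,
           ": expected 42+ fields, got ", length(tok), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(tok[(offset + 1):(offset + 20)]))
    if (anyNA(v)) {
      stop("Unparseable PSSM row ", i, " in ", path, call. = FALSE)
    }
    out[i, pssm_column_order()] <- v
  }
  if (values == "percentages") out <- out / 100
  out
}

#' Write a PSI-BLAST ASCII PSSM file
#'
#' Writes per-residue weighted observed percentages (and synthesized log-odds
#' scores) in the PSI-BLAST ASCII layout read by [read_pssm_ascii()]. Used by
#' the synthetic fixture generator so the synthetic and real-data paths share
#' one reader.
#'
#' @param percentages Integer-valued matrix, rows = residues, 20 columns named
#'   by amino acid (values 0..100, each row summing to 100).
#' @param sequence Protein sequence (one letter per matrix row).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pssm_ascii <- function(percentages, sequence, path) {
  stopifnot(nrow(percentages) == nchar(sequence))
  pct <- percentages[, pssm_column_order(), drop = FALSE]
  bg <- background_aa_freq()[pssm_column_order()]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts")
  ), con)
  hdr <- paste0("     ",
                paste(sprintf("%3s", pssm_column_order()), collapse = ""),
                "  ",
                paste(sprintf("%4s", pssm_column_order()), collapse = ""))
  writeLines(hdr, con)
  res <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(pct))) {
    p <- pct[i, ]
    lo <- round(2 * log2((p / 100 + 0.01) / bg))
    writeLines(paste0(sprintf("%4d %s ", i, res[i]),
                      paste(sprintf("%3d", lo), collapse = ""),
                      "  ",
                      paste(sprintf("%4d", as.integer(p)), collapse = ""),
                      sprintf("  %5.2f %9.2f", 0, 0)), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read a per-residue annotation table
#'
#' Reads the tab-separated sidecar carrying the disorder, secondary-structure
#' and solvent-accessibility tracks (the outputs of a disorder predictor and
#' a structure predictor, one row per residue). Columns: `protein_id`,
#' `position` (1-based), `disorder` (in `[0, 1]`), `ss` (`helix`/`strand`/
#' `other`), `sa` (`buried`/`exposed`). Per protein, positions must run
#' contiguously from 1.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the five validated columns, ordered by protein then
#'   position.
#' @export
read_annotation_table <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    disorder = readr::col_double(),
    ss = readr::col_character(),
    sa = readr::col_character()
  ))
  validate_annotation_table(tbl)
}

validate_annotation_table <- function(tbl) {
  need <- c("protein_id", "position", "disorder", "ss", "sa")
  stopifnot(all(need %in% names(tbl)))
  bad <- which(tbl$disorder < 0 | tbl$disorder > 1)
  if (length(bad)) {
    stop("Disorder score outside [0, 1] at row ", bad[1],
         " (protein ", tbl$protein_id[bad[1]], ", position ",
         tbl$position[bad[1]], ")", call. = FALSE)
  }
  if (!all(tbl$ss %in% ss_states())) {
    stop("Unknown secondary-structure label: ",
         paste(unique(setdiff(tbl$ss, ss_states())), collapse = ", "),
         call. = FALSE)
  }
  if (!all(tbl$sa %in% sa_states())) {
    stop("Unknown solvent-accessibility label: ",
         paste(unique(setdiff(tbl$sa, sa_states())), collapse = ", "),
         call. = FALSE)
  }
  tbl <- dplyr::arrange(tbl, .data$protein_id, .data$position)
  chk <- dplyr::summarise(dplyr::group_by(tbl, .data$protein_id),
                          ok = all(.data$position == seq_along(.data$position)),
                          .groups = "drop")
  if (!all(chk$ok)) {
    stop("Positions not contiguous from 1 (gap or duplicate) for protein: ",
         paste(chk$protein_id[!chk$ok], collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Write a per-residue annotation table
#'
#' @param annotations Tibble with columns `protein_id`, `position`,
#'   `disorder`, `ss`, `sa`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(annotations, path) {
  readr::write_tsv(annotations[, c("protein_id", "position",
                                   "disorder", "ss", "sa")], path)
  invisible(path)
}

#' Read and write site annotation tables
#'
#' A site table lists annotated serine positions: tab-separated with columns
#' `protein_id`, `position` (1-based) and `label` (`positive`/`negative`).
#' Positive rows mark experimentally observed pyruvoyl-forming serines; all
#' other serines are treated as negatives during window extraction.
#'
#' @param path Path to the TSV file.
#' @return `read_site_table`: a tibble with the three columns.
#' @export
read_site_table <- function(path) {
  stopifnot(file.exists(path))
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    label = readr::col_character()
  ))
  if (!all(tbl$label %in% c("positive", "negative"))) {
    stop("Site labels must be 'positive' or 'negative'", call. = FALSE)
  }
  tbl
}

#' @rdname read_site_table
#' @param sites Tibble with columns `protein_id`, `position`, `label`.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites[, c("protein_id", "position", "label")], path)
  invisible(path)
}

#' Write and read a feature matrix
#'
#' The on-disk feature matrix is a TSV with one header row of catalog feature
#' names and one row per sample: `sample_id`, `label`, then one column per
#' feature. `read_feature_matrix` reproduces the written values at full
#' printed precision, so the pair round-trips exactly.
#'
#' @param features Feature tibble as produced by [encode_windows()]:
#'   `sample_id`, `label`, then numeric feature columns.
#' @param path Output path.
#' @param catalog Optional feature catalog ([build_catalog()]); when given,
#'   the feature columns must match it exactly.
#' @return Invisibly, `path` (writer); the feature tibble (reader).
#' @export
write_feature_matrix <- function(features, path, catalog = NULL) {
  stopifnot(is.data.frame(features))
  if (nrow(features) == 0) stop("Feature matrix is empty", call. = FALSE)
  feat_cols <- setdiff(names(features), c("sample_id", "label"))
  if (length(feat_cols) == 0) stop("Feature matrix has no feature columns",
                                   call. = FALSE)
  if (!is.null(catalog) && !identical(feat_cols, catalog$feature)) {
    stop("Feature columns do not match the catalog (",
         length(feat_cols), " vs ", nrow(catalog), " features)",
         call. = FALSE)
  }
  readr::write_tsv(features, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  stopifnot(file.exists(path))
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    label = readr::col_character(),
    .default = readr::col_double()
  ))
}
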