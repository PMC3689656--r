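#' Window configuration
#'
#' A candidate site is represented by the peptide of length `2w + 1` centered
#' on a serine, with `w` residues upstream and `w` downstream. Windows that
#' would run past either end of the protein are completed with the character
#' `"X"`. Typical window lengths for this task are 15, 17, 19 and 21
#' (`w` in 7..10), but any `w >= 1` is legal.
#'
#' @param window_length Odd integer `>= 3`, the full window length `2w + 1`.
#' @return An object of class `pyr_window_config` with elements `w` and
#'   `window_length`.
#' @examples
#' window_config(17)
#' @export
window_config <- function(window_length = 17L) {
  window_length <- as.integer(window_length)
  if (is.na(window_length) || window_length < 3L || window_length %% 2L == 0L) {
    stop("window_length must be an odd integer >= 3", call. = FALSE)
  }
  structure(list(w = (window_length - 1L) %/% 2L,
                 window_length = window_length),
            class = "pyr_window_config")
}

as_window_config <- function(config) {
  if (inherits(config, "pyr_window_config")) return(config)
  window_config(config)
}

#' @export
print.pyr_window_config <- function(x, ...) {
  cat("<window config> length", x$window_length, "(w =", x$w, ")\n")
  invisible(x)
}

#' Extract serine-centered peptide windows from one protein
#'
#' Enumerates every serine in `sequence` (including positions at the very
#' ends of the chain, where the window is padded with `"X"`) and emits one
#' labeled window per serine. Serines listed in `positive_positions` are
#' labeled `positive`; every other serine is a `negative`
#' (a non-observed pyruvoyl serine).
#'
#' @param sequence Protein sequence string (20-letter alphabet, uppercase).
#' @param positive_positions Integer vector of 1-based serine positions with
#'   an observed pyruvoyl modification (may be empty).
#' @param config A [window_config()] or a bare odd window length.
#' @param protein_id Identifier recorded in the output.
#' @return A tibble with columns `protein_id`, `center_pos`, `residues`
#'   (string of length `2w + 1`), and `label`, ordered by position.
#' @examples
#' extract_windows("SAAAAAAAA", 1L, window_config(17), "P1")
#' @export
extract_windows <- function(sequence, positive_positions = integer(),
                            config = window_config(), protein_id = "protein") {
  config <- as_window_config(config)
  w <- config$w
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  positive_positions <- as.integer(positive_positions)
  if (length(positive_positions)) {
    oob <- positive_positions[positive_positions < 1L |
                              positive_positions > n]
    if (length(oob)) {
      stop("Positive position out of bounds for ", protein_id, ": ",
           paste(oob, collapse = ", "), call. = FALSE)
    }
    not_ser <- positive_positions[chars[positive_positions] != "S"]
    if (length(not_ser)) {
      stop("Positive position is not a serine in ", protein_id, ": ",
           paste(not_ser, collapse = ", "), call. = FALSE)
    }
  }
  centers <- which(chars == "S")
  if (length(centers) == 0) {
    return(tibble::tibble(protein_id = character(), center_pos = integer(),
                          residues = character(), label = character()))
  }
  padded <- c(rep("X", w), chars, rep("X", w))
  residues <- vapply(centers, function(pos) {
    paste0(padded[pos:(pos + 2L * w)], collapse = "")
  }, character(1))
  tibble::tibble(
    protein_id = protein_id,
    center_pos = centers,
    residues = residues,
    label = ifelse(centers %in% positive_positions, "positive", "negative")
  )
}

#' Build the full labeled sample set over many proteins
#'
#' Applies [extract_windows()] to every protein, in protein order then
#' ascending position, so downstream seeded sampling is reproducible. Each
#' sample gets an id of the form `"<protein_id>:<center_pos>"`.
#'
#' @param proteins Tibble with columns `id`, `sequence` (see [read_fasta()]).
#' @param sites Tibble with columns `protein_id`, `position`, `label`; rows
#'   labeled `positive` mark observed pyruvoyl serines.
#' @param config A [window_config()] or a bare odd window length.
#' @return A tibble of windows with columns `sample_id`, `protein_id`,
#'   `center_pos`, `residues`, `label`.
#' @export
build_sample_set <- function(proteins, sites, config = window_config()) {
  config <- as_window_config(config)
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  stopifnot(all(c("protein_id", "position") %in% names(sites)))
  pos_sites <- sites
  if ("label" %in% names(sites)) {
    pos_sites <- dplyr::filter(sites, .data$label == "positive")
  }
  unknown <- setdiff(pos_sites$protein_id, proteins$id)
  if (length(unknown)) {
    stop("Site annotation references unknown protein: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  out <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    id <- proteins$id[i]
    pp <- pos_sites$position[pos_sites$protein_id == id]
    extract_windows(proteins$sequence[i], pp, config, protein_id = id)
  })
  dplyr::mutate(out,
                sample_id = paste0(.data$protein_id, ":", .data$center_pos),
                .before = 1)
}
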