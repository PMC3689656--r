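#' Configuration for the synthetic fixture generator
#'
#' The generator emulates the shape of the curated pyruvoyl-serine corpus —
#' a few dozen proteins, one annotated pyruvoyl serine each, and several
#' hundred background serines — together with the input tracks the pipeline
#' consumes (PSSM profiles, disorder scores, secondary structure, solvent
#' accessibility), so the whole pipeline runs and is testable without any
#' external database or predictor.
#'
#' Planted signal mirrors what is known about true sites: the neighborhood of
#' the nucleophilic serine is evolutionarily conserved, a glycine commonly
#' precedes it, and true sites sit near buried residues and a downstream
#' beta-strand. The decisive signal is carried by six conserved alignment
#' columns: at six fixed offsets around the site, the PSSM column of a
#' positive window is peaked at a fixed target amino acid (threonine and
#' glycine upstream, the serine itself, then valine, glutamate and leucine
#' downstream), each independently with probability `conservation_bias`. No
#' single column is sufficient to classify and no column is always present,
#' so recovering the signal requires most of the six features named by
#' [planted_features()]. Sequence-level glycine enrichment before the site
#' and buried/strand enrichment around it are planted on top as weaker,
#' realistic side-signal. Setting `signal = FALSE` removes all enrichment
#' (background everywhere), which is the null condition.
#'
#' @param n_proteins Number of proteins (one positive site each).
#' @param length_range Min/max protein length (uniform).
#' @param conservation_bias Probability that each of the six planted PSSM
#'   columns is peaked in a positive window.
#' @param pre_center_g_prob Probability that a glycine immediately precedes a
#'   positive site in the sequence.
#' @param buried_prob Probability that the residues flanking a positive site
#'   (one upstream, one downstream) are buried.
#' @param strand_prob Probability of a beta-strand call two residues
#'   downstream of a positive site.
#' @param background_ss Background secondary-structure distribution.
#' @param background_buried Background probability of a buried call.
#' @param site_margin Minimum distance of a planted site from either chain
#'   end.
#' @param signal When `FALSE`, all enrichment parameters are reset to
#'   background (zero planted signal).
#' @param seed Integer seed; the generator is fully deterministic under it.
#' @return A list of class `pyr_synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 46L,
                             length_range = c(90L, 160L),
                             conservation_bias = 0.7,
                             pre_center_g_prob = 0.6,
                             buried_prob = 0.7,
                             strand_prob = 0.7,
                             background_ss = c(helix = 0.30, strand = 0.25,
                                               other = 0.45),
                             background_buried = 0.45,
                             site_margin = 12L,
                             signal = TRUE,
                             seed = 1L) {
  if (!signal) {
    conservation_bias <- 0
    pre_center_g_prob <- 0
    buried_prob <- background_buried
    strand_prob <- unname(background_ss["strand"])
  }
  probs <- c(conservation_bias, pre_center_g_prob,
             buried_prob, strand_prob, background_buried, background_ss)
  if (any(probs < 0 | probs > 1)) {
    stop("All probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length_range[1] < 2 * site_margin + 1) {
    stop("Proteins too short to place a site site_margin away from both ends",
         call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 conservation_bias = conservation_bias,
                 pre_center_g_prob = pre_center_g_prob,
                 buried_prob = buried_prob,
                 strand_prob = strand_prob,
                 background_ss = background_ss,
                 background_buried = background_buried,
                 site_margin = as.integer(site_margin),
                 seed = as.integer(seed)),
            class = "pyr_synthetic_config")
}

#' Names of the catalog features carrying planted signal
#'
#' The six conserved alignment columns the generator plants, as catalog
#' feature names: target amino acids T and G at the two sites preceding the
#' center, S at the center, and V, E, L at sites two to four residues
#' downstream (window offsets `w-1`, `w`, `w+1`, `w+3`, `w+4`, `w+5`).
#'
#' @param config A [window_config()] or bare odd window length (`w >= 4`).
#' @return Character vector of six PSSM feature names.
#' @export
planted_features <- function(config = window_config()) {
  config <- as_window_config(config)
  w <- config$w
  if (w < 4) stop("Planted signal needs w >= 4", call. = FALSE)
  spots <- planted_pssm_spots(w)
  feature_name("pssm", spots$offset, spots$target)
}

# planted conserved columns: window offset, offset relative to the site, and
# the target amino acid of the conserved column
planted_pssm_spots <- function(w) {
  tibble::tibble(
    offset = c(w - 1L, w, w + 1L, w + 3L, w + 4L, w + 5L),
    rel = c(-2L, -1L, 0L, 2L, 3L, 4L),
    target = c("T", "G", "S", "V", "E", "L")
  )
}

# one background PSSM percentage row (integers summing to 100); own residue
# moderately favored, remainder spread over the alphabet
background_pssm_row <- function(own) {
  own_pct <- round(100 * stats::rbeta(1, 2, 5) * 0.6)
  rest <- stats::rgamma(20, shape = 0.5)
  rest[match(own, aa_alphabet())] <- 0
  rest <- round((100 - own_pct) * rest / sum(rest))
  row <- rest
  row[match(own, aa_alphabet())] <- own_pct
  fix_row_sum(row)
}

peaked_pssm_row <- function(target) {
  peak <- round(100 * stats::runif(1, 0.70, 0.95))
  rest <- stats::rgamma(20, shape = 0.5)
  rest[match(target, aa_alphabet())] <- 0
  rest <- round((100 - peak) * rest / sum(rest))
  row <- rest
  row[match(target, aa_alphabet())] <- peak
  fix_row_sum(row)
}

fix_row_sum <- function(row) {
  row <- pmax(row, 0)
  diff <- 100 - sum(row)
  j <- which.max(row)
  row[j] <- row[j] + diff
  names(row) <- aa_alphabet()
  row
}

#' Generate a complete synthetic input bundle
#'
#' Draws protein sequences from background amino-acid frequencies, plants one
#' positive serine site per protein with the configured sequence/annotation
#' enrichment, and writes every input file the pipeline reads: a FASTA file,
#' a site table, a per-residue annotation table and one ASCII PSSM file per
#' protein. A ground-truth manifest (planted sites, planted feature names,
#' exact serine counts) accompanies the files so tests can compute every
#' expected count.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return A list of class `pyr_fixture_bundle`: `fasta`, `sites`,
#'   `annotations` (file paths), `pssm_dir`, `pssm_files` (named paths), and
#'   `manifest` (list with `sites` tibble, `planted_features_w` function
#'   input, `n_positive`, `n_negative`, `total_serines`, `config`).
#' @export
generate_fixtures <- function(config = synthetic_config(), dir = tempfile()) {
  stopifnot(inherits(config, "pyr_synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pssm_dir <- file.path(dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  set.seed(config$seed)
  bg <- background_aa_freq()
  ss_lab <- names(config$background_ss)

  proteins <- vector("list", config$n_proteins)
  sites <- vector("list", config$n_proteins)
  ann <- vector("list", config$n_proteins)
  pssm_int <- vector("list", config$n_proteins)

  for (i in seq_len(config$n_proteins)) {
    id <- sprintf("SYN%03d", i)
    L <- sample(seq(config$length_range[1], config$length_range[2]), 1)
    chars <- sample(aa_alphabet(), L, replace = TRUE, prob = bg)
    site <- sample(seq(config$site_margin + 1L, L - config$site_margin), 1)
    chars[site] <- "S"
    if (stats::runif(1) < config$pre_center_g_prob) chars[site - 1L] <- "G"

    # PSSM: background rows, then each planted conserved column fires
    # independently with probability conservation_bias
    pm <- t(vapply(chars, background_pssm_row, numeric(20)))
    spots <- planted_pssm_spots(1L)  # rel/target only; offsets unused here
    for (j in seq_len(nrow(spots))) {
      if (stats::runif(1) < config$conservation_bias) {
        pm[site + spots$rel[j], ] <- peaked_pssm_row(spots$target[j])
      }
    }
    rownames(pm) <- NULL
    colnames(pm) <- aa_alphabet()

    # annotation tracks
    ss <- sample(ss_lab, L, replace = TRUE, prob = config$background_ss)
    sa <- ifelse(stats::runif(L) < config$background_buried,
                 "buried", "exposed")
    disorder <- round(stats::rbeta(L, 2, 3), 4)
    # enrichment near the planted site
    sa[site - 1L] <- ifelse(stats::runif(1) < config$buried_prob,
                            "buried", "exposed")
    sa[site + 1L] <- ifelse(stats::runif(1) < config$buried_prob,
                            "buried", "exposed")
    if (stats::runif(1) < config$strand_prob) ss[site + 2L] <- "strand"

    proteins[[i]] <- tibble::tibble(id = id,
                                    sequence = paste0(chars, collapse = ""))
    sites[[i]] <- tibble::tibble(protein_id = id, position = site,
                                 label = "positive")
    ann[[i]] <- tibble::tibble(protein_id = id, position = seq_len(L),
                               disorder = disorder, ss = ss, sa = sa)
    pssm_int[[i]] <- pm
  }

  proteins <- dplyr::bind_rows(proteins)
  sites <- dplyr::bind_rows(sites)
  ann <- dplyr::bind_rows(ann)

  fasta <- file.path(dir, "proteins.fasta")
  write_fasta(proteins, fasta)
  sites_path <- file.path(dir, "sites.tsv")
  write_site_table(sites, sites_path)
  ann_path <- file.path(dir, "annotations.tsv")
  write_annotation_table(ann, ann_path)
  pssm_files <- stats::setNames(
    file.path(pssm_dir, paste0(proteins$id, ".pssm")), proteins$id)
  for (i in seq_len(nrow(proteins))) {
    write_pssm_ascii(pssm_int[[i]], proteins$sequence[i], pssm_files[i])
  }

  total_serines <- sum(stringr::str_count(proteins$sequence, "S"))
  manifest <- list(
    sites = sites,
    pssm_matrices = lapply(pssm_int, function(m) m / 100),
    n_positive = nrow(sites),
    total_serines = total_serines,
    n_negative = total_serines - nrow(sites),
    config = config
  )
  structure(list(dir = dir, fasta = fasta, sites = sites_path,
                 annotations = ann_path, pssm_dir = pssm_dir,
                 pssm_files = pssm_files, manifest = manifest),
            class = "pyr_fixture_bundle")
}

#' @export
print.pyr_fixture_bundle <- function(x, ...) {
  cat("<synthetic fixture bundle>", x$manifest$n_positive, "positive /",
      x$manifest$n_negative, "negative serines in",
      length(x$pssm_files), "proteins at", x$dir, "\n")
  invisible(x)
}

#' Expected window and dataset counts for a fixture bundle
#'
#' Computes, from the ground-truth manifest alone, the counts every
#' downstream stage must reproduce: total windows (one per serine,
#' independent of window length), class counts, and the balanced dataset
#' sizes after partitioning the negatives.
#'
#' @param bundle A `pyr_fixture_bundle`.
#' @param config A [window_config()] (window length does not change counts).
#' @param parts Number of negative parts.
#' @return A list with `n_windows`, `n_positive`, `n_negative`,
#'   `part_sizes` (sorted decreasing) and `dataset_sizes`.
#' @export
expected_counts <- function(bundle, config = window_config(), parts = 4L) {
  stopifnot(inherits(bundle, "pyr_fixture_bundle"))
  n_neg <- bundle$manifest$n_negative
  sizes <- rep(n_neg %/% parts, parts)
  extra <- n_neg %% parts
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  list(n_windows = bundle$manifest$total_serines,
       n_positive = bundle$manifest$n_positive,
       n_negative = n_neg,
       part_sizes = sizes,
       dataset_sizes = sizes + bundle$manifest$n_positive)
}

#' Load a fixture bundle back through the standard readers
#'
#' Convenience wrapper that reads every generated file with the package's
#' own IO functions and assembles the encoder-ready annotation tibble.
#'
#' @param bundle A `pyr_fixture_bundle`.
#' @return A list with `proteins`, `sites`, `annotations` (the assembled
#'   per-residue tibble including PSSM columns).
#' @export
load_fixtures <- function(bundle) {
  stopifnot(inherits(bundle, "pyr_fixture_bundle"))
  proteins <- read_fasta(bundle$fasta)
  sites <- read_site_table(bundle$sites)
  ann_tbl <- read_annotation_table(bundle$annotations)
  pssms <- lapply(stats::setNames(proteins$id, proteins$id), function(id) {
    read_pssm_ascii(bundle$pssm_files[[id]],
                    expected_length = nchar(
                      proteins$sequence[proteins$id == id]))
  })
  annotations <- collect_annotations(ann_tbl, pssms, proteins)
  list(proteins = proteins, sites = sites, annotations = annotations)
}
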