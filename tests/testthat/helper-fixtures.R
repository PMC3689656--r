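# Shared in-code fixtures for the test suite.

# two tiny proteins with hand-placed serines
tiny_proteins <- function() {
  tibble::tibble(
    id = c("P1", "P2"),
    sequence = c("MKSSAGGSAGTSLE",   # serines at 3, 4, 8, 12
                 "SAAAAAAAASAA")     # serines at 1, 10
  )
}

tiny_sites <- function() {
  tibble::tibble(protein_id = "P1", position = 4L, label = "positive")
}

# deterministic annotations for the tiny proteins: disorder = position/10
# mod 1, ss cycling helix/strand/other, sa alternating, PSSM peaked at the
# residue's own letter with weight 0.5 spread over A
tiny_annotations <- function(proteins = tiny_proteins()) {
  purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    L <- nchar(proteins$sequence[i])
    chars <- strsplit(proteins$sequence[i], "")[[1]]
    pssm <- matrix(0, nrow = L, ncol = 20,
                   dimnames = list(NULL, aa_alphabet()))
    pssm[cbind(seq_len(L), match(chars, aa_alphabet()))] <- 0.5
    pssm[, "A"] <- pssm[, "A"] + 0.5
    out <- tibble::tibble(
      protein_id = proteins$id[i],
      position = seq_len(L),
      disorder = (seq_len(L) %% 10) / 10,
      ss = rep_len(c("helix", "strand", "other"), L),
      sa = rep_len(c("buried", "exposed"), L)
    )
    colnames(pssm) <- paste0("pssm_", colnames(pssm))
    dplyr::bind_cols(out, tibble::as_tibble(pssm))
  })
}

# a small random discrete matrix for MI / mRMR oracle tests
random_discrete_matrix <- function(n, p, k = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(sample.int(k, n * p, replace = TRUE), nrow = n,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  m
}

# brute-force plug-in mutual information over the joint histogram (bits);
# independent of the package implementation
mi_brute_force <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  total <- 0
  for (a in ux) {
    for (b in uy) {
      pxy <- sum(x == a & y == b) / n
      if (pxy > 0) {
        total <- total + pxy * log2(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
      }
    }
  }
  total
}

# exhaustive per-round mRMR oracle: at each round scan every remaining
# candidate, computing D - R from scratch with mi_brute_force
mrmr_oracle <- function(codes, labels) {
  p <- ncol(codes)
  rel <- vapply(seq_len(p), function(j) mi_brute_force(codes[, j], labels),
                numeric(1))
  selected <- integer(0)
  remaining <- seq_len(p)
  for (r in seq_len(p)) {
    score <- vapply(remaining, function(j) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(sdx)
          mi_brute_force(codes[, j], codes[, sdx]), numeric(1)))
      }
      rel[j] - red
    }, numeric(1))
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

# quick pipeline wrapper on a fresh synthetic bundle
run_synthetic_pipeline <- function(seed, signal = TRUE, k_max = 30,
                                   window_length = 17) {
  b <- generate_fixtures(synthetic_config(signal = signal, seed = seed),
                         dir = file.path(tempfile()))
  fx <- load_fixtures(b)
  run_site_pipeline(fx$proteins, fx$sites, fx$annotations,
                    window_config(window_length),
                    dataset = 1, seed = seed, k_max = k_max)
}
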