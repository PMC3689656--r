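test_that("catalog totals follow 64w + 26 with the documented family counts", {
  for (len in c(15L, 17L, 19L, 21L)) {
    w <- (len - 1L) %/% 2L
    catalog <- build_catalog(window_config(len))
    expect_equal(nrow(catalog), 64L * w + 26L)
    counts <- table(catalog$family)
    expect_equal(unname(counts["pssm"]), 20L * len, ignore_attr = TRUE)
    expect_equal(unname(counts["disorder"]), len, ignore_attr = TRUE)
    expect_equal(unname(counts["ss"]), 3L * len, ignore_attr = TRUE)
    expect_equal(unname(counts["sa"]), 2L * len, ignore_attr = TRUE)
    expect_equal(unname(counts["aaf"]), 5L * 2L * w, ignore_attr = TRUE)
    expect_equal(unname(counts["freq"]), 2L * w, ignore_attr = TRUE)
    expect_false(anyDuplicated(catalog$feature) > 0)
    # aaf and freq never sit at the center (always serine there)
    center <- w + 1L
    expect_false(any(catalog$offset == center &
                       catalog$family %in% c("aaf", "freq")))
  }
})

test_that("frequency table sums to one per offset and recovers planted bias", {
  cfg <- window_config(9)
  # two positive windows, both with G just before the center
  ws <- tibble::tibble(
    protein_id = c("A", "B"), center_pos = c(10L, 10L),
    residues = c("AAAGSAAAA", "CCCGSCCCC"), label = "positive"
  )
  ft <- fit_frequency_table(ws, cfg)
  expect_equal(nrow(ft), 8L * 21L)
  sums <- tapply(ft$freq, ft$offset, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(ft$freq[ft$offset == 4 & ft$symbol == "G"], 1.0)
  expect_equal(ft$freq[ft$offset == 4 & ft$symbol == "W"], 0.0)

  expect_error(fit_frequency_table(ws[0, ], cfg), "No positive")
})

test_that("planted symbol frequency is recovered within binomial error", {
  set.seed(33)
  n <- 200
  pre <- ifelse(stats::runif(n) < 0.8, "G", "A")
  ws <- tibble::tibble(
    protein_id = paste0("P", seq_len(n)), center_pos = 10L,
    residues = paste0("AAA", pre, "SAAAA"), label = "positive"
  )
  ft <- fit_frequency_table(ws, window_config(9))
  est <- ft$freq[ft$offset == 4 & ft$symbol == "G"]
  se <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(est - 0.8), 3 * se)
})

test_that("encoding maps annotation tracks onto the right catalog columns", {
  cfg <- window_config(9)
  catalog <- build_catalog(cfg)
  proteins <- tiny_proteins()
  ann <- tiny_annotations(proteins)
  ws <- build_sample_set(proteins, tiny_sites(), cfg)
  ft <- fit_frequency_table(ws, cfg)
  fm <- encode_windows(ws, ann, ft, catalog)
  expect_equal(nrow(fm), nrow(ws))
  expect_equal(ncol(fm) - 2L, nrow(catalog))

  # sample P1:8 (serine at position 8): offset 5 is the center, position 8.
  # tiny annotations: position 8 -> ss cycles helix/strand/other so pos 8 is
  # strand; sa alternates buried/exposed so pos 8 is exposed; disorder 0.8
  row <- fm[fm$sample_id == "P1:8", ]
  expect_equal(row$ss_o05_strand, 1)
  expect_equal(row$ss_o05_helix, 0)
  expect_equal(row$ss_o05_other, 0)
  expect_equal(row$sa_o05_exposed, 1)
  expect_equal(row$sa_o05_buried, 0)
  expect_equal(row$disorder_o05, 0.8)
  # PSSM at the center: own letter S gets 0.5, A gets 0.5
  expect_equal(row$pssm_o05_S, 0.5)
  expect_equal(row$pssm_o05_A, 0.5)
  # Atchley factors of the residue at offset 4 (position 7 = G)
  expect_equal(row$aaf_o04_polarity, atchley_factors()["G", "polarity"])
})

test_that("padded flanks contribute zeros across pssm/disorder/ss/sa/aaf", {
  cfg <- window_config(9)
  catalog <- build_catalog(cfg)
  proteins <- tiny_proteins()
  ann <- tiny_annotations(proteins)
  ws <- build_sample_set(proteins, tiny_sites(), cfg)
  ft <- fit_frequency_table(ws, cfg)
  fm <- encode_windows(ws, ann, ft, catalog)
  # P2:1 -> first serine of P2 at position 1: offsets 1..4 are all padding
  row <- fm[fm$sample_id == "P2:1", ]
  padded_cols <- catalog$feature[catalog$offset <= 4 &
                                   catalog$family != "freq"]
  expect_true(all(row[, padded_cols] == 0))
  # ss bits per padded site sum to 0, per real site to 1
  for (off in c(2L, 6L)) {
    bits <- row[, catalog$feature[catalog$family == "ss" &
                                    catalog$offset == off]]
    expect_equal(sum(bits), ifelse(off <= 4, 0, 1))
  }
  # the freq feature of a padded offset reports the table frequency of 'X'
  expect_equal(row$freq_o01,
               ft$freq[ft$offset == 1 & ft$symbol == "X"])
})

test_that("encoding is deterministic and encode_window matches encode_all rows", {
  cfg <- window_config(9)
  catalog <- build_catalog(cfg)
  proteins <- tiny_proteins()
  ann <- tiny_annotations(proteins)
  ws <- build_sample_set(proteins, tiny_sites(), cfg)
  ft <- fit_frequency_table(ws, cfg)
  fm1 <- encode_windows(ws, ann, ft, catalog)
  fm2 <- encode_windows(ws, ann, ft, catalog)
  expect_identical(fm1, fm2)
  one <- encode_window(ws[3, ], ann, ft, catalog)
  expect_equal(one, fm1[3, ])
})

test_that("missing annotations and empty inputs raise errors", {
  cfg <- window_config(9)
  catalog <- build_catalog(cfg)
  proteins <- tiny_proteins()
  ann <- tiny_annotations(proteins)
  ws <- build_sample_set(proteins, tiny_sites(), cfg)
  ft <- fit_frequency_table(ws, cfg)
  expect_error(encode_windows(ws[0, ], ann, ft, catalog), "No windows")
  ann_missing <- ann[ann$protein_id != "P2", ]
  expect_error(encode_windows(ws, ann_missing, ft, catalog),
               "Missing annotation")
})

test_that("full fixture encoding yields the expected matrix shape", {
  b <- generate_fixtures(synthetic_config(n_proteins = 10, seed = 2))
  fx <- load_fixtures(b)
  cfg <- window_config(17)
  ws <- build_sample_set(fx$proteins, fx$sites, cfg)
  ft <- fit_frequency_table(ws, cfg)
  fm <- encode_windows(ws, fx$annotations, ft, build_catalog(cfg))
  expect_equal(dim(fm), c(b$manifest$total_serines, 538L + 2L))
  expect_false(anyNA(fm))
})
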