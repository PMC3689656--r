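#' Amino-acid alphabets and physicochemical constants
#'
#' `aa_alphabet()` returns the 20 standard amino-acid one-letter codes in
#' alphabetical order (the order used throughout the feature catalog);
#' `pssm_column_order()` returns the 20 letters in the column order of a
#' PSI-BLAST ASCII PSSM file; `atchley_factors()` returns the five Atchley
#' numeric summaries of amino-acid physicochemical variation as a 20 x 5
#' matrix (rows = amino acids, alphabetical; columns = factor names).
#'
#' The Atchley factors condense a large panel of physicochemical indices into
#' five orthogonal scores per residue: polarity/accessibility, secondary
#' structure propensity, molecular volume, codon diversity and electrostatic
#' charge. They are used to encode the residues flanking a candidate serine.
#'
#' @return A character vector (`aa_alphabet`, `pssm_column_order`) or a
#'   numeric matrix (`atchley_factors`).
#' @examples
#' aa_alphabet()
#' atchley_factors()["G", ]
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
pssm_column_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Symbol names for the five factors, alphabetical (catalog detail order).
aaf_factor_names <- function() {
  c("codon_diversity", "electrostatic_charge", "molecular_volume",
    "polarity", "secondary_structure")
}

ss_states <- function() c("helix", "strand", "other")
sa_states <- function() c("buried", "exposed")

#' @rdname aa_alphabet
#' @export
atchley_factors <- function() {
  # columns: factor I (polarity), II (secondary structure), III (molecular
  # volume), IV (codon diversity), V (electrostatic charge)
  vals <- c(
    # polarity, secondary_structure, molecular_volume, codon_diversity, electrostatic_charge
    A = c(-0.591, -1.302, -0.733,  1.570, -0.146),
    C = c(-1.343,  0.465, -0.862, -1.020, -0.255),
    D = c( 1.050,  0.302, -3.656, -0.259, -3.242),
    E = c( 1.357, -1.453,  1.477,  0.113, -0.837),
    F = c(-1.006, -0.590,  1.891, -0.397,  0.412),
    G = c(-0.384,  1.652,  1.330,  1.045,  2.064),
    H = c( 0.336, -0.417, -1.673, -1.474, -0.078),
    I = c(-1.239, -0.547,  2.131,  0.393,  0.816),
    K = c( 1.831, -0.561,  0.533, -0.277,  1.648),
    L = c(-1.019, -0.987, -1.505,  1.266, -0.912),
    M = c(-0.663, -1.524,  2.219, -1.005,  1.212),
    N = c( 0.945,  0.828,  1.299, -0.169,  0.933),
    P = c( 0.189,  2.081, -1.628,  0.421, -1.392),
    Q = c( 0.931, -0.179, -3.005, -0.503, -1.853),
    R = c( 1.538, -0.055,  1.502,  0.440,  2.897),
    S = c(-0.228,  1.399, -4.760,  0.670, -2.647),
    T = c(-0.032,  0.326,  2.213,  0.908,  1.313),
    V = c(-1.337, -0.279, -0.544,  1.242, -1.262),
    W = c(-0.595,  0.009,  0.672, -2.128, -0.184),
    Y = c( 0.260,  0.830,  3.097, -0.838,  1.512)
  )
  m <- matrix(vals, nrow = 20, byrow = TRUE,
              dimnames = list(aa_alphabet(),
                              c("polarity", "secondary_structure",
                                "molecular_volume", "codon_diversity",
                                "electrostatic_charge")))
  # reorder columns to the alphabetical detail order used in the catalog
  m[, aaf_factor_names()]
}

# Approximate Swiss-Prot background amino-acid frequencies (proportions).
background_aa_freq <- function() {
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.63, T = 5.34, W = 1.09,
         Y = 2.92, V = 6.87)
  f <- f[aa_alphabet()]
  f / sum(f)
}
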