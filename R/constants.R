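# Alphabets, channel layouts and vendored lookup tables used across the
# package.  The packed benchmark layout is 700 residue slots x 57 channels
# per protein: [1,22] amino-acid one-hot incl. NoSeq, [23,31] structure
# labels incl. NoSeq, [32,33] terminal flags, [34,35] solvent
# accessibility, [36,57] logistic-rescaled profile incl. NoSeq.

#' @keywords internal
AA_ORDER <- strsplit("ACDEFGHIKLMNPQRSTVWXY", "")[[1]]  # 21 symbols, X = unknown

#' @keywords internal
Q8_STATES <- c("C", "B", "E", "G", "I", "H", "S", "T")

#' @keywords internal
Q3_STATES <- c("H", "E", "C")

# channel index helpers (1-based, within a 57-channel residue slot)
CHAN <- list(
  onehot  = 1:22,    # 21 residues + NoSeq (22nd)
  labels  = 23:31,   # 8 states + NoSeq (31st)
  term    = 32:33,
  solvacc = 34:35,
  profile = 36:57    # 21 residues + NoSeq (57th)
)
SLOT_WIDTH <- 57L
MAX_LEN <- 700L
ROW_WIDTH <- SLOT_WIDTH * MAX_LEN  # 39900

#' Amino-acid background frequencies
#'
#' Robinson–Robinson amino-acid background frequencies over the 20
#' standard residues, normalised onto the simplex.  Used as the default
#' background vector `P_i` when recovering profile probabilities from
#' logistic-rescaled substitution scores.
#'
#' @return Named numeric vector of length 20 summing to 1, ordered as the
#'   20 standard residues of the packed-array alphabet (no `X`).
#' @export
#' @examples
#' sum(background_frequencies())
background_frequencies <- function() {
  f <- c(
    A = 0.07805, C = 0.01925, D = 0.05364, E = 0.06295, F = 0.03856,
    G = 0.07377, H = 0.02199, I = 0.05142, K = 0.05744, L = 0.09019,
    M = 0.02243, N = 0.04487, P = 0.05203, Q = 0.04264, R = 0.05129,
    S = 0.07120, T = 0.05841, V = 0.06441, W = 0.01330, Y = 0.03216
  )
  f / sum(f)
}

#' Physicochemical property lookup table
#'
#' Seven per-residue physicochemical parameters (steric parameter,
#' polarizability, normalised van der Waals volume, hydrophobicity,
#' isoelectric point, helix probability, sheet probability), one row per
#' symbol of the 21-letter alphabet.  The `X` (unknown) row is the mean
#' of the 20 standard residues.  Values follow the commonly used
#' 7-parameter amino-acid descriptor set; pass a modified copy to
#' [assemble_features()] to override.
#'
#' @return 21 x 7 numeric matrix with residue rownames and parameter
#'   colnames.
#' @export
physchem_table <- function() {
  vals <- rbind(
    A = c(1.28, 0.05, 1.00,  0.31, 6.11, 0.42, 0.23),
    C = c(1.77, 0.13, 2.43,  1.54, 6.35, 0.17, 0.41),
    D = c(1.60, 0.11, 2.78, -0.77, 2.95, 0.25, 0.20),
    E = c(1.56, 0.15, 3.78, -0.64, 3.09, 0.42, 0.21),
    F = c(2.94, 0.29, 5.89,  1.79, 5.67, 0.30, 0.38),
    G = c(0.00, 0.00, 0.00,  0.00, 6.07, 0.13, 0.15),
    H = c(2.99, 0.23, 4.66,  0.13, 7.69, 0.27, 0.30),
    I = c(4.19, 0.19, 4.00,  1.80, 6.04, 0.30, 0.45),
    K = c(1.89, 0.22, 4.77, -0.99, 9.99, 0.32, 0.27),
    L = c(2.59, 0.19, 4.00,  1.70, 6.04, 0.39, 0.31),
    M = c(2.35, 0.22, 4.43,  1.23, 5.71, 0.38, 0.32),
    N = c(1.60, 0.13, 2.95, -0.60, 6.52, 0.21, 0.22),
    P = c(2.67, 0.00, 2.72,  0.72, 6.80, 0.13, 0.34),
    Q = c(1.56, 0.18, 3.95, -0.22, 5.65, 0.36, 0.25),
    R = c(2.34, 0.29, 6.13, -1.01, 10.74, 0.36, 0.25),
    S = c(1.31, 0.06, 1.60, -0.04, 5.70, 0.20, 0.28),
    T = c(3.03, 0.11, 2.60,  0.26, 5.60, 0.21, 0.36),
    V = c(3.67, 0.14, 3.00,  1.22, 6.02, 0.27, 0.49),
    W = c(3.21, 0.41, 8.08,  2.25, 5.94, 0.32, 0.42),
    Y = c(2.94, 0.30, 6.47,  0.96, 5.66, 0.25, 0.41)
  )
  x_row <- colMeans(vals)
  tab <- rbind(vals, X = x_row)[AA_ORDER, , drop = FALSE]
  colnames(tab) <- c("steric", "polarizability", "volume", "hydrophobicity",
                     "isoelectric", "helix_prob", "sheet_prob")
  tab
}

#' Benchmark Q8 state frequencies
#'
#' Per-state frequencies (percent) of the eight DSSP states in the CB513
#' benchmark test labels, used as the default label distribution of the
#' synthetic generator so report layouts are exercised realistically.
#'
#' @return Named numeric vector (percent) over the Q8 states.
#' @export
cb513_q8_frequencies <- function() {
  c(C = 21.14, B = 1.39, E = 21.25, G = 3.69, I = 0.04,
    H = 30.86, S = 9.81, T = 11.81)
}
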