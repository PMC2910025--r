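# Embedded amino-acid property tables used by the sequence descriptor schemes.
# All tables index the 20 standard residues in one-letter alphabetical order.

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Sandberg et al. (1998) five z-scales: principal-property scores of the 20
# coded amino acids. z1 ~ hydrophobicity, z2 ~ steric bulk/polarisability,
# z3 ~ polarity, z4/z5 ~ electronic effects.
.ZSCALES <- matrix(
  c(
    #  z1     z2     z3     z4     z5
     0.24, -2.32,  0.60, -0.14,  1.30, # A
     0.84, -1.67,  3.71,  0.18, -2.65, # C
     3.98,  0.93,  1.93, -2.46,  0.75, # D
     3.11,  0.26, -0.11, -3.04, -0.25, # E
    -4.22,  1.94,  1.06,  0.54, -0.62, # F
     2.05, -4.06,  0.36, -0.82, -0.38, # G
     2.47,  1.95,  0.26,  3.90,  0.09, # H
    -3.89, -1.73, -1.71, -0.84,  0.26, # I
     2.29,  0.89, -2.49,  1.49,  0.31, # K
    -4.28, -1.30, -1.49, -0.72,  0.84, # L
    -2.85, -0.22,  0.47,  1.94, -0.98, # M
     3.05,  1.62,  1.04, -1.15,  1.61, # N
    -1.66,  0.27,  1.84,  0.70,  2.00, # P
     1.75,  0.50, -1.44, -1.34,  0.66, # Q
     3.52,  2.50, -3.50,  1.99, -0.17, # R
     2.39, -1.07,  1.15, -1.39,  0.67, # S
     0.75, -2.18, -1.12, -1.46, -0.40, # T
    -2.59, -2.64, -1.54, -0.85, -0.02, # V
    -4.36,  3.94,  0.59,  3.44, -1.59, # W
    -2.54,  2.44,  0.43,  0.04, -1.47  # Y
  ),
  nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET, paste0("z", 1:5))
)

#' Amino-acid z-scale table
#'
#' The five principal-property z-scales of Sandberg et al. for the 20 coded
#' amino acids, used to encode residues numerically in the aligned, ACC and
#' MACC description schemes.
#'
#' @return A tibble with columns `aa`, `z1` ... `z5`, one row per residue in
#'   alphabetical one-letter order.
#' @export
#' @examples
#' zscales()
zscales <- function() {
  tibble::as_tibble(cbind(
    tibble::tibble(aa = AA_ALPHABET),
    tibble::as_tibble(.ZSCALES)
  ))
}

# CTD attribute classes (Dubchak-style three-class partitions of the
# alphabet for seven physico-chemical attributes).
.CTD_CLASSES <- list(
  hydrophobicity = list(
    "RKEDQN",   # polar
    "GASTPHY",  # neutral
    "CLVIMFW"   # hydrophobic
  ),
  vdw_volume = list(
    "GASTPDC",  # normalised volume 0-2.78
    "NVEQIL",
    "MHKFRYW"
  ),
  polarity = list(
    "LIFWCMVY",
    "PATGS",
    "HQRKNED"
  ),
  polarizability = list(
    "GASDT",
    "CPNVEQIL",
    "KMHFRYW"
  ),
  charge = list(
    "KR",
    "ANCQGHILMFPSTWYV",
    "DE"
  ),
  secondary_structure = list(
    "EALMQKRH",
    "VIYCWFT",
    "GNPSD"
  ),
  solvent_accessibility = list(
    "ALFCGIVW",
    "RKQEND",
    "MSPTHY"
  )
)

#' CTD attribute class table
#'
#' The seven physico-chemical attributes (hydrophobicity, normalised van der
#' Waals volume, polarity, polarizability, charge, secondary structure,
#' solvent accessibility) each partitioning the 20 residues into three
#' classes, as used by the composition/transition/distribution descriptors.
#'
#' @return A tibble with columns `attribute`, `class` (1, 2, 3) and
#'   `residues` (the class members as a string).
#' @export
ctd_classes <- function() {
  purrr::imap_dfr(.CTD_CLASSES, function(cls, attr_name) {
    tibble::tibble(
      attribute = attr_name,
      class = 1:3,
      residues = vapply(cls, identity, character(1))
    )
  })
}

# class index per residue for each attribute: 7 x 20 integer matrix
.ctd_class_matrix <- function() {
  m <- matrix(NA_integer_, nrow = length(.CTD_CLASSES), ncol = 20,
              dimnames = list(names(.CTD_CLASSES), AA_ALPHABET))
  for (a in seq_along(.CTD_CLASSES)) {
    for (k in 1:3) {
      members <- strsplit(.CTD_CLASSES[[a]][[k]], "")[[1]]
      m[a, members] <- k
    }
  }
  stopifnot(!anyNA(m))
  m
}

# Grantham (1974) residue composition (c), polarity (p) and molecular
# volume (v), from which the published chemical distance matrix follows as
# D_ij = 50.723 * sqrt(1.833 (c_i-c_j)^2 + 0.1018 (p_i-p_j)^2
#                      + 0.000399 (v_i-v_j)^2), rounded to integers.
.GRANTHAM_CPV <- matrix(
  c(
    # c     p     v
    0.00,  8.1,  31,  # A
    2.75,  5.5,  55,  # C
    1.38, 13.0,  54,  # D
    0.92, 12.3,  83,  # E
    0.00,  5.2, 132,  # F
    0.74,  9.0,   3,  # G
    0.58, 10.4,  96,  # H
    0.00,  5.2, 111,  # I
    0.33, 11.3, 119,  # K
    0.00,  4.9, 111,  # L
    0.00,  5.7, 105,  # M
    1.33, 11.6,  56,  # N
    0.39,  8.0,  32.5,# P
    0.89, 10.5,  85,  # Q
    0.65, 10.5, 124,  # R
    1.42,  9.2,  32,  # S
    0.71,  8.6,  61,  # T
    0.00,  5.9,  84,  # V
    0.13,  5.4, 170,  # W
    0.20,  6.2, 136   # Y
  ),
  nrow = 20, byrow = TRUE,
  dimnames = list(AA_ALPHABET, c("c", "p", "v"))
)

.grantham_matrix <- function() {
  cpv <- .GRANTHAM_CPV
  d2 <- 1.833 * outer(cpv[, "c"], cpv[, "c"], "-")^2 +
    0.1018 * outer(cpv[, "p"], cpv[, "p"], "-")^2 +
    0.000399 * outer(cpv[, "v"], cpv[, "v"], "-")^2
  d <- round(50.723 * sqrt(d2))
  diag(d) <- 0
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d
}

# Property scales behind the physico-chemical distance matrix and the
# pseudo-amino-acid correlation factors: Eisenberg consensus hydrophobicity,
# Hopp-Woods hydrophilicity, and side-chain mass.
.AA_HYDROPHOBICITY <- c(
  A =  0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
  H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
  P =  0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
  W =  0.81, Y = 0.26
)
.AA_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
  H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
  P =  0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
  W = -3.4, Y = -2.3
)
.AA_SIDECHAIN_MASS <- c(
  A = 15, C = 47, D = 59, E = 73, F = 91, G = 1,
  H = 82, I = 57, K = 73, L = 57, M = 75, N = 58,
  P = 42, Q = 72, R = 101, S = 31, T = 45, V = 43,
  W = 130, Y = 107
)

# z-standardise a property over the 20 residues (population SD, n = 20)
.std20 <- function(x) {
  (x - mean(x)) / sqrt(mean((x - mean(x))^2))
}

.physchem_matrix <- function() {
  props <- cbind(
    .std20(.AA_HYDROPHOBICITY[AA_ALPHABET]),
    .std20(.AA_HYDROPHILICITY[AA_ALPHABET]),
    .std20(.AA_SIDECHAIN_MASS[AA_ALPHABET])
  )
  d2 <- 0
  for (j in 1:3) d2 <- d2 + outer(props[, j], props[, j], "-")^2
  d <- sqrt(d2 / 3)
  dimnames(d) <- list(AA_ALPHABET, AA_ALPHABET)
  d
}

#' Residue pairwise distance matrices
#'
#' Returns a 20 x 20 residue distance matrix for the sequence-order coupling
#' numbers. `"grantham"` is Grantham's chemical distance, reconstructed
#' exactly from his published composition/polarity/volume values and scaling
#' constants. `"physchem"` is this package's physico-chemical distance: the
#' root-mean-square difference of z-standardised hydrophobicity (Eisenberg),
#' hydrophilicity (Hopp-Woods) and side-chain mass.
#'
#' @param type `"physchem"` or `"grantham"`.
#' @return A symmetric numeric 20 x 20 matrix with zero diagonal, rows and
#'   columns in alphabetical one-letter order, with attribute `"tag"`.
#' @export
#' @examples
#' residue_distance_matrix("grantham")["A", "C"] # 195
residue_distance_matrix <- function(type = c("physchem", "grantham")) {
  type <- match.arg(type)
  m <- switch(type,
    grantham = .grantham_matrix(),
    physchem = .physchem_matrix()
  )
  attr(m, "tag") <- type
  m
}

# validate a protein sequence -> integer vector of residue indices (1..20)
.seq_to_idx <- function(seq, allow_gap = FALSE, what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (allow_gap) idx[chars == "-"] <- 0L
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unknown_residue: '%s' at position %d of %s",
                 chars[bad], bad, what), call. = FALSE)
  }
  idx
}
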