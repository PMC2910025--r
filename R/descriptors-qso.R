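# Sequence-order coupling numbers, quasi-sequence-order descriptors and
# type-1 pseudo-amino-acid descriptors (the SO-PAA block).

#' Sequence-order coupling numbers
#'
#' The coupling number of rank d is the sum of squared residue-pair distances
#' between all residues d positions apart:
#' tau_d = sum_i dist(s_i, s_(i+d))^2, for d = 1..`d_max`.
#'
#' @param seq A protein sequence (standard residues only).
#' @param matrix A 20 x 20 residue distance matrix from
#'   [residue_distance_matrix()].
#' @param d_max Maximum rank (default 30); must be < nchar(seq).
#' @return A named numeric vector `tau_1` ... `tau_<d_max>`.
#' @export
so_coupling_numbers <- function(seq, matrix = residue_distance_matrix("physchem"),
                                d_max = 30) {
  idx <- .seq_to_idx(seq)
  n <- length(idx)
  if (n <= d_max) {
    stop(sprintf("sequence_too_short: N = %d must exceed d_max = %d",
                 n, d_max), call. = FALSE)
  }
  tau <- vapply(seq_len(d_max), function(d) {
    sum(matrix[cbind(idx[1:(n - d)], idx[(1 + d):n])]^2)
  }, numeric(1))
  stats::setNames(tau, paste0("tau_", seq_len(d_max)))
}

#' Quasi-sequence-order descriptors
#'
#' The standard quasi-sequence-order construction: the first 20 values
#' reflect amino-acid composition, X_a = f_a / (sum_b f_b + w * sum_d tau_d),
#' and the next `d_max` values reflect sequence order,
#' X_(20+d) = w * tau_d / (same denominator). All 50 values (default `d_max`)
#' share one denominator, so they sum to 1.
#'
#' @inheritParams so_coupling_numbers
#' @param w Weighting factor for the sequence-order terms (default 0.1).
#' @return A named numeric vector of length `20 + d_max`.
#' @export
qso_descriptors <- function(seq, matrix = residue_distance_matrix("physchem"),
                            d_max = 30, w = 0.1) {
  idx <- .seq_to_idx(seq)
  f <- tabulate(idx, 20) / length(idx)
  tau <- so_coupling_numbers(seq, matrix, d_max)
  denom <- sum(f) + w * sum(tau)
  tag <- attr(matrix, "tag") %||% "d"
  stats::setNames(
    c(f / denom, w * tau / denom),
    c(paste0("qso_", tag, "_", AA_ALPHABET),
      paste0("qso_", tag, "_tau", seq_len(d_max)))
  )
}

# normalised correlation-factor properties for the pseudo-amino-acid terms
.paa_props <- function() {
  cbind(
    h1 = .std20(.AA_HYDROPHOBICITY[AA_ALPHABET]),
    h2 = .std20(.AA_HYDROPHILICITY[AA_ALPHABET]),
    m  = .std20(.AA_SIDECHAIN_MASS[AA_ALPHABET])
  )
}

#' Type-1 pseudo-amino-acid descriptors
#'
#' The standard type-1 pseudo-amino-acid construction: sequence-correlation
#' factors theta_d average, over all residue pairs d apart, the mean squared
#' difference of three z-standardised properties (hydrophobicity,
#' hydrophilicity, side-chain mass). The 20 composition terms and the
#' `lambda` correlation terms share one normalising denominator
#' sum_a f_a + w_paa * sum_d theta_d.
#'
#' @inheritParams so_coupling_numbers
#' @param lambda Number of correlation tiers (default 30); must be <
#'   nchar(seq).
#' @param w_paa Weight of the sequence-correlation part (default 0.05).
#' @return A named numeric vector of length `20 + lambda`.
#' @export
paa_descriptors <- function(seq, lambda = 30, w_paa = 0.05) {
  idx <- .seq_to_idx(seq)
  n <- length(idx)
  if (n <= lambda) {
    stop(sprintf("sequence_too_short: N = %d must exceed lambda = %d",
                 n, lambda), call. = FALSE)
  }
  props <- .paa_props()[idx, , drop = FALSE]
  theta <- vapply(seq_len(lambda), function(d) {
    dif <- props[1:(n - d), , drop = FALSE] - props[(1 + d):n, , drop = FALSE]
    mean(rowMeans(dif^2))
  }, numeric(1))
  f <- tabulate(idx, 20) / n
  denom <- sum(f) + w_paa * sum(theta)
  stats::setNames(
    c(f / denom, w_paa * theta / denom),
    c(paste0("paa_", AA_ALPHABET), paste0("paa_theta", seq_len(lambda)))
  )
}

#' Amino-acid and dipeptide composition (AAC-DC)
#'
#' The 20 amino-acid fractions followed by the 400 dipeptide fractions over
#' the N - 1 adjacent residue pairs, in fixed alphabetical order. Each of
#' the two parts sums to 1.
#'
#' @param seq A protein sequence (standard residues only, length >= 2).
#' @return A named numeric vector of length 420.
#' @export
#' @examples
#' aac_dc_descriptors("ARA")[c("aac_A", "dc_AR", "dc_RA")]
aac_dc_descriptors <- function(seq) {
  idx <- .seq_to_idx(seq)
  n <- length(idx)
  if (n < 2) stop("sequence must contain at least 2 residues", call. = FALSE)
  aac <- tabulate(idx, 20) / n
  # dipeptide index: (first - 1) * 20 + second, alphabetical both ways
  di <- (idx[-n] - 1L) * 20L + idx[-1]
  dc <- tabulate(di, 400) / (n - 1)
  dip_names <- paste0("dc_", rep(AA_ALPHABET, each = 20),
                      rep(AA_ALPHABET, 20))
  stats::setNames(c(aac, dc), c(paste0("aac_", AA_ALPHABET), dip_names))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
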