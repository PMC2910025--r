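# Alignment-free auto/cross-covariance transforms of z-scale encoded
# sequences, and their signed-maximum (MACC1) variant.

# z-scale value matrix for one sequence: N x 5
.zvals <- function(seq, what = "sequence") {
  idx <- .seq_to_idx(seq, allow_gap = FALSE, what = what)
  .ZSCALES[idx, , drop = FALSE]
}

#' Auto- and cross-covariance (ACC) transform of a protein sequence
#'
#' Encodes a sequence by the five z-scales and computes, for every ordered
#' z-scale pair (a, b) and every lag 1..`max_lag`, the covariance-style term
#' sum_i V\[a, i\] * V\[b, i + lag\] / (N - lag). Each z-scale is mean-centred
#' within the sequence first, so a homopolymer maps to the zero vector. The
#' result is a fixed-length, alignment-free description: `max_lag * 25`
#' values, ordered lag-major then (a, b) with a running slowest.
#'
#' @param seq A protein sequence (single string, standard residues only).
#' @param max_lag Maximum lag L (default 50); must be < nchar(seq).
#' @return A named numeric vector of length `max_lag * 25`; names are
#'   `acc_l<lag>_z<a>z<b>`.
#' @export
#' @examples
#' length(acc_transform("ACDEFGHIKLMNPQRSTVWY", max_lag = 5)) # 125
acc_transform <- function(seq, max_lag = 50) {
  v <- .zvals(seq)
  n <- nrow(v)
  if (n <= max_lag) {
    stop(sprintf("sequence_too_short: N = %d must exceed max_lag = %d",
                 n, max_lag), call. = FALSE)
  }
  v <- sweep(v, 2, colMeans(v))
  out <- numeric(max_lag * 25)
  nms <- character(max_lag * 25)
  pos <- 1L
  for (lag in seq_len(max_lag)) {
    head_v <- v[1:(n - lag), , drop = FALSE]
    tail_v <- v[(1 + lag):n, , drop = FALSE]
    cc <- crossprod(head_v, tail_v) / (n - lag)  # 5 x 5: [a, b]
    out[pos:(pos + 24)] <- as.vector(t(cc))      # a-major
    nms[pos:(pos + 24)] <- paste0(
      "acc_l", lag, "_z", rep(1:5, each = 5), "z", rep(1:5, 5)
    )
    pos <- pos + 25L
  }
  stats::setNames(out, nms)
}

#' MACC1 transform: signed maxima of auto/cross-covariance products
#'
#' For every z-scale pair (a, b) and lag, the products
#' V\[a, i\] * V\[b, i + lag\] over all positions are split by the sign
#' pattern of the two raw z-scale values — (+,+), (-,-), (+,-), (-,+) — and
#' the product of largest magnitude within each pattern is retained with its
#' natural sign ((+,-) and (-,+) terms are non-positive). A term is exactly 0
#' when no residue pair exhibits its sign pattern. Unlike [acc_transform()],
#' raw (uncentred) z-scale values are used, so the sign of a property keeps
#' its physico-chemical meaning (e.g. hydrophilic vs hydrophobic for z1).
#'
#' @inheritParams acc_transform
#' @return A named numeric vector of length `4 * max_lag * 25`; names are
#'   `macc_l<lag>_z<a>z<b>_<pp|nn|pn|np>`, lag-major.
#' @export
macc1_transform <- function(seq, max_lag = 50) {
  v <- .zvals(seq)
  n <- nrow(v)
  if (n <= max_lag) {
    stop(sprintf("sequence_too_short: N = %d must exceed max_lag = %d",
                 n, max_lag), call. = FALSE)
  }
  patterns <- c("pp", "nn", "pn", "np")
  out <- numeric(4 * max_lag * 25)
  nms <- character(length(out))
  pos <- 1L
  sgn <- sign(v)
  for (lag in seq_len(max_lag)) {
    i1 <- 1:(n - lag)
    i2 <- (1 + lag):n
    for (a in 1:5) {
      va <- v[i1, a]; sa <- sgn[i1, a]
      for (b in 1:5) {
        vb <- v[i2, b]; sb <- sgn[i2, b]
        prod_ab <- va * vb
        vals <- c(
          pp = .signed_max(prod_ab[sa > 0 & sb > 0]),
          nn = .signed_max(prod_ab[sa < 0 & sb < 0]),
          pn = .signed_min(prod_ab[sa > 0 & sb < 0]),
          np = .signed_min(prod_ab[sa < 0 & sb > 0])
        )
        out[pos:(pos + 3)] <- vals
        nms[pos:(pos + 3)] <- paste0("macc_l", lag, "_z", a, "z", b, "_",
                                     patterns)
        pos <- pos + 4L
      }
    }
  }
  stats::setNames(out, nms)
}

# largest positive product (sign pattern makes all candidates > 0); 0 if none
.signed_max <- function(x) if (length(x)) max(x) else 0
# most negative product (candidates < 0): the maximum magnitude, natural sign
.signed_min <- function(x) if (length(x)) min(x) else 0
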