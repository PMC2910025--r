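# Alignment-based z-scale description: gap-column filtering and per-position
# z-scale encoding of a multiple sequence alignment.

# accept a tibble with an `aligned` column or a (named) character vector
.get_aligned <- function(msa) {
  if (is.data.frame(msa)) {
    if (!"aligned" %in% names(msa)) {
      stop("expected a data frame with an `aligned` column", call. = FALSE)
    }
    ids <- if ("kinase" %in% names(msa)) msa$kinase else as.character(seq_len(nrow(msa)))
    stats::setNames(msa$aligned, ids)
  } else {
    x <- stats::setNames(as.character(msa), names(msa))
    if (is.null(names(x))) names(x) <- as.character(seq_along(x))
    x
  }
}

#' Remove gap-rich columns from a multiple sequence alignment
#'
#' Drops alignment columns in which the gap fraction strictly exceeds
#' `max_gap_fraction` (a column with exactly that fraction is retained).
#' The indices of the retained columns in the original alignment are kept in
#' the `"kept_columns"` attribute so descriptors remain traceable to
#' alignment positions.
#'
#' @param msa A named character vector of equal-length aligned sequences
#'   (gap character `-`), or a data frame with columns `kinase` and
#'   `aligned`.
#' @param max_gap_fraction Maximum tolerated gap fraction per column
#'   (default 0.5).
#' @return A named character vector of filtered aligned sequences with
#'   attribute `"kept_columns"` (integer original column indices).
#' @export
filter_gap_columns <- function(msa, max_gap_fraction = 0.5) {
  aln <- .get_aligned(msa)
  widths <- nchar(aln)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: sequences have unequal aligned lengths",
         call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(aln, ""))
  gap_frac <- colMeans(chars == "-")
  keep <- which(gap_frac <= max_gap_fraction)
  out <- apply(chars[, keep, drop = FALSE], 1, paste, collapse = "")
  out <- stats::setNames(out, names(aln))
  attr(out, "kept_columns") <- keep
  out
}

#' Encode an aligned sequence set with z-scales
#'
#' Each retained alignment position contributes five descriptors, the
#' z-scale values of the residue at that position; gaps encode as the zero
#' 5-tuple (the z-scales are centred over the amino acids, so zero plays the
#' role of an average residue). An alignment of P positions yields a block
#' of width 5 * P.
#'
#' @param msa A gap-filtered alignment as returned by
#'   [filter_gap_columns()], or any equal-length aligned set (tibble with
#'   `kinase`/`aligned` columns or named character vector).
#' @return A tibble with column `kinase` followed by `p<pos>_z<k>` numeric
#'   columns, where `<pos>` is the original alignment column index when
#'   known.
#' @export
encode_alignment_zscales <- function(msa) {
  aln <- .get_aligned(msa)
  kept <- attr(msa, "kept_columns") %||% attr(aln, "kept_columns")
  widths <- nchar(aln)
  if (length(unique(widths)) != 1) {
    stop("ragged alignment: sequences have unequal aligned lengths",
         call. = FALSE)
  }
  p <- widths[1]
  positions <- kept %||% seq_len(p)
  mat <- matrix(0, nrow = length(aln), ncol = p * 5)
  for (s in seq_along(aln)) {
    idx <- .seq_to_idx(aln[[s]], allow_gap = TRUE, what = names(aln)[s])
    z <- matrix(0, nrow = p, ncol = 5)
    res <- idx > 0
    z[res, ] <- .ZSCALES[idx[res], , drop = FALSE]
    mat[s, ] <- as.vector(t(z))  # position-major, z minor
  }
  colnames(mat) <- paste0("p", rep(positions, each = 5), "_z", rep(1:5, p))
  dplyr::bind_cols(tibble::tibble(kinase = names(aln)), tibble::as_tibble(mat))
}
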