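# Uniform entity-level descriptor blocks: one row per kinase, one column per
# descriptor, whichever description scheme is used.

.block_from_vectors <- function(ids, vecs, tag) {
  mat <- do.call(rbind, vecs)
  out <- dplyr::bind_cols(tibble::tibble(kinase = ids), tibble::as_tibble(mat))
  attr(out, "block_tag") <- tag
  out
}

#' Compute a kinase descriptor block
#'
#' Applies one of the six sequence description schemes to a set of kinase
#' sequences and returns a uniform entity-by-descriptor tibble. Alignment-free
#' schemes (`acc`, `macc`, `ctd`, `so_paa`, `aac_dc`) use the unaligned
#' `sequence` column; `aligned_z` uses the `aligned` column, filtering
#' gap-rich columns first (see [filter_gap_columns()]).
#'
#' The `so_paa` block concatenates the coupling numbers of both embedded
#' residue distance matrices (2 x 30), the quasi-sequence-order descriptors
#' for both matrices (2 x 50), and 50 pseudo-amino-acid descriptors: 210
#' columns in total.
#'
#' @param sequences A tibble with columns `kinase`, `sequence` and (for
#'   `aligned_z`) `aligned`, as produced by [generate_sequences()], or a
#'   named character vector of sequences.
#' @param method One of `"aligned_z"`, `"acc"`, `"macc"`, `"ctd"`,
#'   `"so_paa"`, `"aac_dc"`.
#' @param max_lag Maximum lag for `acc`/`macc` (default 50).
#' @param d_max,w,lambda,w_paa Parameters of the `so_paa` scheme.
#' @param max_gap_fraction Gap-column threshold for `aligned_z`.
#' @return A tibble with a `kinase` id column followed by numeric descriptor
#'   columns; the scheme is recorded in the `"block_tag"` attribute.
#' @export
#' @examples
#' seqs <- tibble::tibble(kinase = c("k1", "k2"),
#'                        sequence = c("ACDEFGHIKLMNPQRSTVWY",
#'                                     "YWVTSRQPNMLKIHGFEDCA"))
#' dim(describe_kinases(seqs, "aac_dc")) # 2 x 421
describe_kinases <- function(sequences,
                             method = c("aligned_z", "acc", "macc", "ctd",
                                        "so_paa", "aac_dc"),
                             max_lag = 50, d_max = 30, w = 0.1,
                             lambda = 30, w_paa = 0.05,
                             max_gap_fraction = 0.5) {
  method <- match.arg(method)
  if (!is.data.frame(sequences)) {
    sequences <- tibble::tibble(
      kinase = names(sequences) %||% as.character(seq_along(sequences)),
      sequence = as.character(sequences)
    )
  }
  ids <- sequences$kinase
  if (method == "aligned_z") {
    filtered <- filter_gap_columns(sequences, max_gap_fraction)
    block <- encode_alignment_zscales(filtered)
    attr(block, "block_tag") <- "aligned_z"
    return(block)
  }
  seqs <- sequences$sequence
  vecs <- switch(method,
    acc = lapply(seqs, acc_transform, max_lag = max_lag),
    macc = lapply(seqs, macc1_transform, max_lag = max_lag),
    ctd = lapply(seqs, ctd_descriptors),
    aac_dc = lapply(seqs, aac_dc_descriptors),
    so_paa = {
      m_pc <- residue_distance_matrix("physchem")
      m_gr <- residue_distance_matrix("grantham")
      lapply(seqs, function(s) {
        c(
          so_coupling_numbers(s, m_pc, d_max),
          stats::setNames(so_coupling_numbers(s, m_gr, d_max),
                          paste0("tau_gr_", seq_len(d_max))),
          qso_descriptors(s, m_pc, d_max, w),
          qso_descriptors(s, m_gr, d_max, w),
          paa_descriptors(s, lambda, w_paa)
        )
      })
    }
  )
  .block_from_vectors(ids, vecs, method)
}

#' Descriptor block tag
#'
#' @param block A descriptor tibble produced by [describe_kinases()] or the
#'   synthetic generator.
#' @return The block's scheme tag (character) or `NULL`.
#' @export
block_tag <- function(block) attr(block, "block_tag")

# split a descriptor tibble into id columns and a numeric matrix
.block_matrix <- function(block, id_cols = NULL) {
  is_num <- vapply(block, is.numeric, logical(1))
  if (is.null(id_cols)) id_cols <- names(block)[!is_num]
  mat <- as.matrix(block[, setdiff(names(block), id_cols), drop = FALSE])
  rownames(mat) <- if (length(id_cols)) as.character(block[[id_cols[1]]]) else NULL
  mat
}
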