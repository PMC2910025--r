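# Composition / transition / distribution (CTD) descriptors over seven
# three-class physico-chemical attributes.

#' CTD descriptors of a protein sequence
#'
#' Computes, for each of seven physico-chemical attributes partitioning the
#' alphabet into three classes (see [ctd_classes()]):
#' * 21 *composition* values — the fraction of residues in each class;
#' * 21 *transition* values — the count of adjacent residue pairs crossing
#'   each unordered class pair \{1,2\}, \{1,3\}, \{2,3\}, divided by N - 1;
#' * 105 *distribution* values — for each class, the 1-based positions of the
#'   first, ceil(25%)-th, ceil(50%)-th, ceil(75%)-th and last residue of that
#'   class, each divided by N (all five 0 when the class is absent).
#'
#' @param seq A protein sequence (standard residues only, length >= 2).
#' @return A named numeric vector of length 147.
#' @export
#' @examples
#' d <- ctd_descriptors("RRRR")
#' d["ctd_c_hydrophobicity_1"] # 1: all arginines are polar (class 1)
ctd_descriptors <- function(seq) {
  idx <- .seq_to_idx(seq)
  n <- length(idx)
  if (n < 2) stop("sequence must contain at least 2 residues", call. = FALSE)
  cls_mat <- .ctd_class_matrix()
  attrs <- rownames(cls_mat)
  comp <- trans <- numeric(0)
  distr <- numeric(0)
  pair_names <- c("12", "13", "23")
  for (a in attrs) {
    cl <- cls_mat[a, idx]
    # composition
    cvals <- tabulate(cl, 3) / n
    comp <- c(comp, stats::setNames(cvals, paste0("ctd_c_", a, "_", 1:3)))
    # transitions over adjacent pairs, unordered class pairs
    lo <- pmin(cl[-n], cl[-1]); hi <- pmax(cl[-n], cl[-1])
    tvals <- c(
      sum(lo == 1 & hi == 2),
      sum(lo == 1 & hi == 3),
      sum(lo == 2 & hi == 3)
    ) / (n - 1)
    trans <- c(trans, stats::setNames(tvals, paste0("ctd_t_", a, "_", pair_names)))
    # distribution quintuples
    for (k in 1:3) {
      where <- which(cl == k)
      if (length(where) == 0) {
        q <- rep(0, 5)
      } else {
        nk <- length(where)
        picks <- c(1, ceiling(0.25 * nk), ceiling(0.5 * nk),
                   ceiling(0.75 * nk), nk)
        picks <- pmax(picks, 1)
        q <- where[picks] / n
      }
      distr <- c(distr, stats::setNames(
        q, paste0("ctd_d_", a, "_", k, "_", c("first", "q25", "q50", "q75", "q100"))
      ))
    }
  }
  c(comp, trans, distr)
}
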