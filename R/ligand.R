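# Ligand descriptor ingestion and redundancy pruning.

#' Load a ligand descriptor table
#'
#' Reads a TSV/CSV file whose first column holds compound ids and whose
#' remaining columns are numeric molecular descriptors (computed upstream by
#' external descriptor software). Constant (zero-variance) columns carry no
#' information for modelling and are dropped with a warning.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` comma, otherwise tab).
#' @return A tibble with column `compound` followed by numeric descriptor
#'   columns.
#' @export
load_ligand_table <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(raw)[1] <- "compound"
  raw$compound <- as.character(raw$compound)
  if (anyDuplicated(raw$compound)) {
    stop("duplicate compound ids: ",
         paste(unique(raw$compound[duplicated(raw$compound)]), collapse = ", "),
         call. = FALSE)
  }
  desc <- raw[-1]
  for (j in seq_along(desc)) {
    if (!is.numeric(desc[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(desc[[j]]))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d",
                   names(desc)[j], bad %||% 1L), call. = FALSE)
    }
  }
  if (anyNA(desc)) {
    na_cols <- names(desc)[vapply(desc, anyNA, logical(1))]
    stop("missing values in column(s): ", paste(na_cols, collapse = ", "),
         call. = FALSE)
  }
  sds <- vapply(desc, stats::sd, numeric(1))
  const <- sds == 0
  if (any(const)) {
    warning("dropping ", sum(const), " constant descriptor column(s): ",
            paste(names(desc)[const], collapse = ", "), call. = FALSE)
    desc <- desc[!const]
  }
  out <- dplyr::bind_cols(raw["compound"], desc)
  attr(out, "block_tag") <- "ligand"
  out
}

#' Prune highly correlated ligand descriptors
#'
#' Iteratively removes redundant descriptors: while any descriptor pair has
#' pairwise r^2 above `r2_threshold`, the member of the worst-offending pair
#' whose *maximum* r^2 against all other remaining descriptors is larger is
#' dropped. Ties break lexicographically by descriptor name, so the result
#' is deterministic and order-independent. Correlations are computed on the
#' raw columns (later scaling leaves r^2 unchanged).
#'
#' @param table A ligand descriptor tibble (id column `compound` plus
#'   numeric columns), e.g. from [load_ligand_table()].
#' @param r2_threshold Squared-correlation threshold (default 0.9).
#' @return The pruned tibble; removed descriptors are recorded in the
#'   `"removed"` attribute as a tibble with columns `descriptor`, `max_r2`
#'   and `partner` (accessor: [pruning_log()]).
#' @export
prune_correlated <- function(table, r2_threshold = 0.9) {
  mat <- .block_matrix(table, id_cols = "compound")
  if (nrow(mat) < 2) stop("need >= 2 compounds to estimate correlations",
                          call. = FALSE)
  removed <- list()
  keep <- colnames(mat)
  if (length(keep) >= 2) {
    r2 <- suppressWarnings(stats::cor(mat))^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 0
    repeat {
      sub <- r2[keep, keep, drop = FALSE]
      worst <- max(sub)
      if (worst <= r2_threshold || length(keep) < 2) break
      hits <- which(sub == worst, arr.ind = TRUE)
      cand <- unique(t(apply(hits, 1, function(h) sort(keep[h]))))
      pair <- cand[order(cand[, 1], cand[, 2])[1], ]
      max_r2 <- vapply(pair, function(d) {
        others <- setdiff(keep, d)
        max(r2[d, others])
      }, numeric(1))
      # drop the member most correlated with the rest; ties -> later name
      drop <- if (max_r2[1] > max_r2[2]) pair[1]
              else if (max_r2[2] > max_r2[1]) pair[2]
              else pair[2]
      removed[[length(removed) + 1]] <- tibble::tibble(
        descriptor = drop, max_r2 = max(max_r2[drop == pair]),
        partner = setdiff(pair, drop)
      )
      keep <- setdiff(keep, drop)
    }
  }
  out <- dplyr::bind_cols(table["compound"], table[keep])
  attr(out, "removed") <- if (length(removed)) dplyr::bind_rows(removed)
    else tibble::tibble(descriptor = character(), max_r2 = numeric(),
                        partner = character())
  attr(out, "block_tag") <- "ligand"
  out
}

#' Removal log of a pruned ligand table
#'
#' @param table A tibble returned by [prune_correlated()].
#' @return A tibble listing removed descriptors with their maximum r^2 and
#'   the partner that triggered removal.
#' @export
pruning_log <- function(table) attr(table, "removed")
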