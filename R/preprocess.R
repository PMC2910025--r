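# Scaling, block weighting, NIPALS PCA and ligand x kinase cross-terms:
# the steps that turn descriptor blocks into a model-ready design matrix.

#' Mean-centre and unit-variance scale a descriptor block
#'
#' In training mode (no `state`), each numeric column is centred to mean 0
#' and scaled to standard deviation 1; zero-variance columns are dropped
#' with a warning and the fitted means/sds are stored. In apply mode the
#' stored state is applied unchanged — held-out rows are transformed with
#' the training parameters, never their own.
#'
#' @param block A descriptor tibble (id columns plus numeric columns).
#' @param state A scaling state from a previous `autoscale()` call, or
#'   `NULL` to fit one.
#' @return The scaled tibble; the state is stored in the `"scaling"`
#'   attribute (accessor: [scaling_state()]).
#' @export
autoscale <- function(block, state = NULL) {
  is_num <- vapply(block, is.numeric, logical(1))
  ids <- block[!is_num]
  mat <- as.matrix(block[is_num])
  if (is.null(state)) {
    mu <- colMeans(mat)
    sd_ <- apply(mat, 2, stats::sd)
    drop <- sd_ == 0 | is.na(sd_)
    if (any(drop)) {
      warning("dropping ", sum(drop), " zero-variance column(s)",
              call. = FALSE)
      mat <- mat[, !drop, drop = FALSE]
      mu <- mu[!drop]; sd_ <- sd_[!drop]
    }
    state <- list(mean = mu, sd = sd_, columns = colnames(mat))
  } else {
    if (!identical(state$columns, intersect(colnames(mat), state$columns)) &&
        !all(state$columns %in% colnames(mat))) {
      stop("descriptor names do not match the stored scaling state",
           call. = FALSE)
    }
    mat <- mat[, state$columns, drop = FALSE]
  }
  mat <- sweep(sweep(mat, 2, state$mean), 2, state$sd, "/")
  out <- dplyr::bind_cols(ids, tibble::as_tibble(mat))
  attr(out, "scaling") <- state
  attr(out, "block_tag") <- attr(block, "block_tag")
  out
}

#' Scaling state of an autoscaled block
#' @param block A tibble returned by [autoscale()].
#' @return A list with elements `mean`, `sd` and `columns`.
#' @export
scaling_state <- function(block) attr(block, "scaling")

#' Block-scale a set of autoscaled descriptor blocks
#'
#' Multiplies every column of block *b* by 1/sqrt(N_b), where N_b is the
#' number of descriptors in the block, so that the total sum of column
#' variances in each block equals 1 and blocks of very different widths
#' contribute equally to the model.
#'
#' @param blocks A named list of autoscaled tibbles (see [autoscale()]).
#' @return The list with each block weighted; weights are stored per block
#'   in the `"block_weight"` attribute.
#' @export
block_scale <- function(blocks) {
  if (is.data.frame(blocks)) blocks <- list(blocks)
  lapply(blocks, function(b) {
    if (is.null(attr(b, "scaling"))) {
      stop("blocks must be autoscaled before block scaling", call. = FALSE)
    }
    is_num <- vapply(b, is.numeric, logical(1))
    w <- 1 / sqrt(sum(is_num))
    b[is_num] <- lapply(b[is_num], function(col) col * w)
    attr(b, "block_weight") <- w
    b
  })
}

#' Principal component analysis by NIPALS
#'
#' Extracts principal components one at a time with the NIPALS algorithm:
#' iterate p = X't/t't, normalise p, t = Xp until the score vector changes
#' by less than `tol`, then deflate X by t p'. Extraction stops at
#' `n_components` or when the cumulative explained variance reaches
#' `variance_target`. The sign of each component is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param x A numeric matrix or descriptor tibble (id columns ignored).
#' @param n_components Number of components, at most `min(n - 1, p)`.
#' @param variance_target Alternative stopping rule: smallest number of
#'   components whose cumulative explained-variance fraction reaches this
#'   value in (0, 1].
#' @param center Centre columns first (default TRUE; scaling is the caller's
#'   business).
#' @param tol,max_iter NIPALS convergence controls.
#' @return An object of class `pcm_pca` with elements `loadings` (p x A),
#'   `scores` (n x A), `explained_variance` (fractions), `center`,
#'   `total_variance`. Supports [predict()], [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @export
pca_nipals <- function(x, n_components = NULL, variance_target = NULL,
                       center = TRUE, tol = 1e-9, max_iter = 500) {
  if (is.data.frame(x)) x <- .block_matrix(x)
  n <- nrow(x); p <- ncol(x)
  a_max <- min(n - 1, p)
  if (is.null(n_components) && is.null(variance_target)) n_components <- a_max
  if (!is.null(variance_target) &&
      (variance_target <= 0 || variance_target > 1)) {
    stop("variance_target must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(n_components) && n_components > a_max) {
    stop(sprintf("n_components = %d exceeds min(n - 1, p) = %d",
                 n_components, a_max), call. = FALSE)
  }
  mu <- if (center) colMeans(x) else rep(0, p)
  xd <- sweep(x, 2, mu)
  total_ss <- sum(xd^2)
  a_cap <- n_components %||% a_max
  loadings <- matrix(0, p, 0)
  scores <- matrix(0, n, 0)
  ev <- numeric(0)
  for (a in seq_len(a_cap)) {
    css <- colSums(xd^2)
    if (max(css) < .Machine$double.eps * total_ss) break
    t_vec <- xd[, which.max(css)]
    for (it in seq_len(max_iter)) {
      p_vec <- crossprod(xd, t_vec) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- xd %*% p_vec
      if (sqrt(sum((t_new - t_vec)^2)) < tol * sqrt(sum(t_new^2))) {
        t_vec <- t_new
        break
      }
      t_vec <- t_new
    }
    s <- sign(p_vec[which.max(abs(p_vec))])
    p_vec <- p_vec * s; t_vec <- t_vec * s
    xd <- xd - t_vec %*% t(p_vec)
    loadings <- cbind(loadings, p_vec)
    scores <- cbind(scores, t_vec)
    ev <- c(ev, sum(t_vec^2) / total_ss)
    if (!is.null(variance_target) && sum(ev) >= variance_target) break
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_along(ev))
  rownames(loadings) <- colnames(x)
  structure(
    list(loadings = loadings, scores = scores, explained_variance = ev,
         center = mu, total_variance = total_ss / max(n - 1, 1)),
    class = "pcm_pca"
  )
}

#' @export
predict.pcm_pca <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- .block_matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(names(object$center))) {
    newdata <- newdata[, names(object$center), drop = FALSE]
  }
  sweep(newdata, 2, object$center) %*% object$loadings
}

#' @export
print.pcm_pca <- function(x, ...) {
  cat(sprintf("NIPALS PCA: %d component(s), %.1f%% variance explained\n",
              ncol(x$loadings), 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Build ligand x kinase principal-component cross-terms
#'
#' Forms, for every kinase-inhibitor pair, the element-wise products of each
#' ligand PC score with each retained kinase PC score. The products encode
#' the non-linear part of the interaction — which kinase features a ligand
#' feature is selective for — while keeping the model linear in its columns.
#' Each product column is Pareto-scaled (divided by the square root of its
#' standard deviation) and multiplied by `block_weight`.
#'
#' @param ligand_scores Numeric matrix of ligand PC scores with compound ids
#'   as row names.
#' @param kinase_scores Numeric matrix of kinase PC scores with kinase ids
#'   as row names.
#' @param pairs A tibble with columns `kinase` and `compound`, one row per
#'   modelled pair.
#' @param block_weight Weight applied to the whole cross block (the sweep
#'   over this weight is part of model selection; 0 removes the block's
#'   influence).
#' @param pareto_sd Stored Pareto scale factors from a training call, or
#'   `NULL` to fit them from these rows.
#' @return A numeric matrix with `nrow(pairs)` rows and
#'   `ncol(ligand_scores) * ncol(kinase_scores)` columns, with the fitted
#'   `"pareto_sd"` attribute.
#' @export
make_cross_terms <- function(ligand_scores, kinase_scores, pairs,
                             block_weight = 1, pareto_sd = NULL) {
  al <- ncol(ligand_scores); ak <- ncol(kinase_scores)
  ls <- ligand_scores[pairs$compound, , drop = FALSE]
  ks <- kinase_scores[pairs$kinase, , drop = FALSE]
  cross <- ls[, rep(seq_len(al), each = ak), drop = FALSE] *
    ks[, rep(seq_len(ak), al), drop = FALSE]
  colnames(cross) <- paste0(
    "x_", rep(colnames(ligand_scores), each = ak), "_",
    rep(colnames(kinase_scores), al)
  )
  rownames(cross) <- NULL
  if (is.null(pareto_sd)) {
    pareto_sd <- apply(cross, 2, stats::sd)
    pareto_sd[pareto_sd == 0] <- 1
  }
  cross <- sweep(cross, 2, sqrt(pareto_sd), "/") * block_weight
  attr(cross, "pareto_sd") <- pareto_sd
  cross
}

#' Assemble a model-ready design matrix for kinase-inhibitor pairs
#'
#' Concatenates the ligand, kinase and (optionally) cross-term blocks into
#' one row per pair, centres the response with a stored mean, and carries
#' the inactive mask through.
#'
#' @param pairs A tibble with columns `kinase`, `compound`, `pkd` and
#'   optionally `inactive`.
#' @param ligand_block A (scaled) ligand descriptor tibble with `compound`
#'   ids, or matrix with compound row names.
#' @param kinase_block A (scaled) kinase descriptor tibble with `kinase`
#'   ids, or matrix with kinase row names.
#' @param cross_block Optional numeric matrix of cross-terms, row-aligned to
#'   `pairs`.
#' @param y_mean Stored response mean from a training design, or `NULL` to
#'   fit.
#' @return An object of class `pcm_design`: list with the design matrix
#'   `x`, centred response `y`, `y_mean`, `pairs`, `blocks` (column index
#'   ranges) and `inactive` mask.
#' @export
assemble_design <- function(pairs, ligand_block, kinase_block,
                            cross_block = NULL, y_mean = NULL) {
  lmat <- if (is.data.frame(ligand_block)) {
    .block_matrix(ligand_block, "compound")
  } else ligand_block
  kmat <- if (is.data.frame(kinase_block)) {
    .block_matrix(kinase_block, "kinase")
  } else kinase_block
  missing_l <- setdiff(unique(pairs$compound), rownames(lmat))
  if (length(missing_l)) {
    stop("no ligand descriptors for compound(s): ",
         paste(missing_l, collapse = ", "), call. = FALSE)
  }
  missing_k <- setdiff(unique(pairs$kinase), rownames(kmat))
  if (length(missing_k)) {
    stop("no kinase descriptors for kinase(s): ",
         paste(missing_k, collapse = ", "), call. = FALSE)
  }
  x <- cbind(lmat[pairs$compound, , drop = FALSE],
             kmat[pairs$kinase, , drop = FALSE])
  blocks <- list(ligand = seq_len(ncol(lmat)),
                 kinase = ncol(lmat) + seq_len(ncol(kmat)))
  if (!is.null(cross_block)) {
    blocks$cross <- ncol(x) + seq_len(ncol(cross_block))
    x <- cbind(x, cross_block)
  }
  rownames(x) <- NULL
  if (is.null(y_mean)) y_mean <- mean(pairs$pkd)
  structure(
    list(x = x, y = pairs$pkd - y_mean, y_mean = y_mean,
         pairs = pairs[c("kinase", "compound")],
         inactive = pairs$inactive %||% rep(FALSE, nrow(pairs)),
         blocks = blocks),
    class = "pcm_design"
  )
}

#' @export
print.pcm_design <- function(x, ...) {
  cat(sprintf("pcm_design: %d pairs x %d columns (%s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(x$blocks),
                            lengths(x$blocks)), collapse = ", ")))
  invisible(x)
}
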