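# M5-style model tree: standard-deviation-reduction splitting, linear
# models at the nodes, error-based pruning and leaf-to-root smoothing.

.m5_linmod <- function(x, y, features) {
  n <- length(y)
  if (length(features) == 0 || n < 3) {
    return(list(coef = c(`(Intercept)` = mean(y)), features = character(0),
                resid = y - mean(y), v = 1))
  }
  xm <- cbind(`(Intercept)` = 1, x[, features, drop = FALSE])
  fit <- stats::lm.fit(xm, y)
  cf <- fit$coefficients
  v <- max(1, sum(!is.na(cf)))  # parameters actually estimated
  cf[is.na(cf)] <- 0
  list(coef = cf, features = features, resid = fit$residuals, v = v)
}

.m5_model_error <- function(mod, n) {
  mae <- mean(abs(mod$resid))
  v <- mod$v
  if (n <= v) return(Inf)
  mae * (n + v) / (n - v)
}

.m5_best_split <- function(x, y, min_leaf) {
  n <- length(y)
  best <- NULL
  sd_all <- stats::sd(y)
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    ord <- order(xj)
    ys <- y[ord]; xs <- xj[ord]
    cs <- cumsum(ys); cs2 <- cumsum(ys^2)
    nl <- seq_len(n - 1)
    # candidate split after position i (left = 1..i)
    valid <- nl >= min_leaf & (n - nl) >= min_leaf & xs[nl] < xs[nl + 1]
    if (!any(valid)) next
    sl <- cs[nl]; sl2 <- cs2[nl]
    varl <- pmax(0, sl2 / nl - (sl / nl)^2)
    sr <- cs[n] - sl; sr2 <- cs2[n] - sl2
    nr <- n - nl
    varr <- pmax(0, sr2 / nr - (sr / nr)^2)
    sdr <- sd_all - (nl / n) * sqrt(varl) - (nr / n) * sqrt(varr)
    sdr[!valid] <- -Inf
    i <- which.max(sdr)
    if (is.finite(sdr[i]) && (is.null(best) || sdr[i] > best$sdr)) {
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1]) / 2,
                   sdr = sdr[i])
    }
  }
  best
}

.m5_grow <- function(x, y, rows, min_leaf, sd_root) {
  n <- length(rows)
  yv <- y[rows]
  node <- list(n = n)
  if (n < 2 * min_leaf || stats::sd(yv) < 0.05 * sd_root) {
    node$leaf <- TRUE
    node$split_features <- character(0)
    return(node)
  }
  split <- .m5_best_split(x[rows, , drop = FALSE], yv, min_leaf)
  if (is.null(split) || split$sdr <= 0) {
    node$leaf <- TRUE
    node$split_features <- character(0)
    return(node)
  }
  node$leaf <- FALSE
  node$feature <- colnames(x)[split$feature]
  node$threshold <- split$threshold
  go_left <- x[rows, split$feature] <= split$threshold
  node$left <- .m5_grow(x, y, rows[go_left], min_leaf, sd_root)
  node$right <- .m5_grow(x, y, rows[!go_left], min_leaf, sd_root)
  node$split_features <- unique(c(node$feature,
                                  node$left$split_features,
                                  node$right$split_features))
  node
}

# fit node models (on the subtree's split features) and prune bottom-up
.m5_prune <- function(node, x, y, rows, all_features) {
  yv <- y[rows]
  feats <- if (length(node$split_features)) node$split_features else all_features
  node$model <- .m5_linmod(x[rows, , drop = FALSE], yv, feats)
  node$model_error <- .m5_model_error(node$model, length(rows))
  if (node$leaf) {
    node$subtree_error <- node$model_error
    return(node)
  }
  go_left <- x[rows, node$feature] <= node$threshold
  node$left <- .m5_prune(node$left, x, y, rows[go_left], all_features)
  node$right <- .m5_prune(node$right, x, y, rows[!go_left], all_features)
  nl <- length(rows[go_left]); nr <- length(rows) - nl
  sub_err <- (nl * node$left$subtree_error + nr * node$right$subtree_error) /
    length(rows)
  # slight slack so numerically tied errors favour the simpler model
  if (node$model_error <= sub_err * (1 + 1e-7) + 1e-12) {
    node$leaf <- TRUE
    node$left <- node$right <- NULL
    node$subtree_error <- node$model_error
  } else {
    node$subtree_error <- sub_err
  }
  node
}

.m5_node_value <- function(mod, xrow) {
  val <- mod$coef[["(Intercept)"]]
  if (length(mod$features)) {
    val <- val + sum(mod$coef[mod$features] * xrow[mod$features])
  }
  unname(val)
}

.m5_predict_row <- function(node, xrow, k) {
  if (node$leaf) {
    return(list(value = .m5_node_value(node$model, xrow), n = node$n))
  }
  child <- if (xrow[[node$feature]] <= node$threshold) node$left else node$right
  below <- .m5_predict_row(child, xrow, k)
  own <- .m5_node_value(node$model, xrow)
  # smoothing: blend the child's prediction with this node's model
  list(value = (below$n * below$value + k * own) / (below$n + k),
       n = node$n)
}

#' Fit an M5-style model tree
#'
#' Grows a regression tree by standard-deviation reduction, fits a linear
#' model at every node (on the attributes tested in the node's subtree; the
#' root falls back to all attributes), prunes bottom-up by comparing each
#' node model's complexity-adjusted error with its subtree's, and smooths
#' predictions from leaf to root with the usual (n p_child + k p_node) /
#' (n + k) blend.
#'
#' When `min_leaf_grid` has several values, the minimum leaf size is chosen
#' by inner cross-validation.
#'
#' @param x A `pcm_design` or numeric design matrix.
#' @param y Response (taken from the design when `x` is a `pcm_design`).
#' @param min_leaf_grid Candidate minimum numbers of training cases per
#'   leaf (each >= 2).
#' @param smoothing_k Smoothing constant (default 15).
#' @param inner_folds,seed Inner-CV controls for the grid choice.
#' @return An object of class `pcm_m5` with the pruned tree, the selected
#'   `min_leaf`, the grid search table, and `y_mean`.
#' @export
model_tree_fit <- function(x, y = NULL, min_leaf_grid = c(4, 8, 16, 32),
                           smoothing_k = 15, inner_folds = 5, seed = 1) {
  y_mean <- 0
  if (inherits(x, "pcm_design")) {
    y <- x$y; y_mean <- x$y_mean; x <- x$x
  }
  if (any(min_leaf_grid < 2)) stop("min_leaf must be >= 2", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  min_leaf_grid <- sort(unique(pmin(min_leaf_grid, max(2, nrow(x)))))
  search <- NULL
  min_leaf <- min_leaf_grid[1]
  if (length(min_leaf_grid) > 1) {
    folds <- withr::with_seed(seed,
                              sample(rep_len(seq_len(inner_folds), nrow(x))))
    q2 <- vapply(min_leaf_grid, function(ml) {
      pred <- rep(NA_real_, nrow(x))
      for (f in seq_len(inner_folds)) {
        tr <- folds != f
        fit <- .m5_train(x[tr, , drop = FALSE], y[tr], ml, smoothing_k)
        pred[!tr] <- .m5_apply(fit, x[!tr, , drop = FALSE], smoothing_k)
      }
      q_squared(y, pred)
    }, numeric(1))
    # ties resolve to the larger (simpler) leaf size
    min_leaf <- min_leaf_grid[rev(which(q2 == max(q2)))[1]]
    search <- tibble::tibble(min_leaf = min_leaf_grid, inner_q2 = q2)
  }
  tree <- .m5_train(x, y, min_leaf, smoothing_k)
  structure(
    list(tree = tree, min_leaf = min_leaf, smoothing_k = smoothing_k,
         y_mean = y_mean, search = search, x_names = colnames(x)),
    class = "pcm_m5"
  )
}

.m5_train <- function(x, y, min_leaf, smoothing_k) {
  sd_root <- stats::sd(y)
  if (is.na(sd_root) || sd_root == 0) {
    return(list(leaf = TRUE, n = length(y), split_features = character(0),
                model = list(coef = c(`(Intercept)` = mean(y)),
                             features = character(0), resid = y - mean(y),
                             v = 1)))
  }
  grown <- .m5_grow(x, y, seq_along(y), min_leaf, sd_root)
  .m5_prune(grown, x, y, seq_along(y), colnames(x))
}

.m5_apply <- function(tree, x, k) {
  vapply(seq_len(nrow(x)), function(i) {
    .m5_predict_row(tree, x[i, ], k)$value
  }, numeric(1))
}

#' @export
predict.pcm_m5 <- function(object, newdata, ...) {
  if (inherits(newdata, "pcm_design")) newdata <- newdata$x
  newdata <- newdata[, object$x_names, drop = FALSE]
  .m5_apply(object$tree, newdata, object$smoothing_k) + object$y_mean
}

#' Number of leaves of a fitted model tree
#' @param object A `pcm_m5` model.
#' @return Integer leaf count.
#' @export
m5_n_leaves <- function(object) {
  count <- function(node) {
    if (node$leaf) 1L else count(node$left) + count(node$right)
  }
  count(object$tree)
}

#' @export
print.pcm_m5 <- function(x, ...) {
  cat(sprintf("M5-style model tree: %d leaves, min_leaf = %d\n",
              m5_n_leaves(x), x$min_leaf))
  invisible(x)
}
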