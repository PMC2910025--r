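# Non-linear correlation methods on the shared design-matrix contract:
# epsilon-SVR (RBF kernel) and distance-weighted k-nearest neighbours.

#' Default modelling control parameters
#'
#' Collects the hyperparameter grids and protocol constants used by the
#' model-fitting and cross-validation functions.
#'
#' @param ncomp_max Maximum PLS components evaluated by inner CV.
#' @param cross_weight_grid Block-weight sweep for the cross-term block,
#'   starting at 0 (no cross-terms) and increasing in regular steps.
#' @param gamma_grid,c_grid RBF-SVR kernel width and error penalty grids
#'   (log2-spaced).
#' @param epsilon_frac SVR epsilon-tube width as a fraction of the training
#'   response standard deviation.
#' @param k_grid Neighbour counts for k-NN.
#' @param kinase_weight_grid Multipliers for the kinase block weight in the
#'   k-NN distance.
#' @param min_leaf_grid Minimum-leaf-size grid for the model tree.
#' @param variance_target Fraction of kinase-block variance the retained
#'   kinase PCs must explain when building cross-terms.
#' @param inner_folds Number of inner cross-validation folds.
#' @return A named list of class `pcm_control`.
#' @export
cv_control <- function(ncomp_max = 15,
                       cross_weight_grid = seq(0, 2, by = 0.1),
                       gamma_grid = 2^seq(-7, 1, by = 2),
                       c_grid = 2^seq(-2, 6, by = 2),
                       epsilon_frac = 0.1,
                       k_grid = c(1, 3, 5, 7, 9),
                       kinase_weight_grid = c(0.25, 0.5, 1, 2, 4),
                       min_leaf_grid = c(4, 8, 16, 32),
                       variance_target = 0.95,
                       inner_folds = 5) {
  structure(
    list(ncomp_max = ncomp_max, cross_weight_grid = cross_weight_grid,
         gamma_grid = gamma_grid, c_grid = c_grid,
         epsilon_frac = epsilon_frac, k_grid = k_grid,
         kinase_weight_grid = kinase_weight_grid,
         min_leaf_grid = min_leaf_grid, variance_target = variance_target,
         inner_folds = inner_folds),
    class = "pcm_control"
  )
}

#' Fit an epsilon-SVR model with RBF kernel
#'
#' Tunes the kernel width gamma and error penalty C on a log2-spaced grid by
#' inner cross-validation (selection by pooled inner Q2; ties go to the
#' smallest C then smallest gamma), then refits on all rows. The
#' quadratic-programming core is delegated to [e1071::svm()]; the grid
#' search, the CV protocol and all scaling live here.
#'
#' @param x A `pcm_design` or numeric design matrix (already scaled).
#' @param y Response (taken from the design when `x` is a `pcm_design`).
#' @param gamma_grid,c_grid Hyperparameter grids (must be finite).
#' @param epsilon Epsilon-tube width; defaults to `epsilon_frac` of sd(y).
#' @param epsilon_frac Used when `epsilon` is `NULL`.
#' @param inner_folds,seed Inner-CV controls.
#' @return An object of class `pcm_svr` wrapping the refit
#'   [e1071::svm()] model, the selected hyperparameters and the search
#'   table.
#' @export
svr_fit <- function(x, y = NULL, gamma_grid = 2^seq(-15, 3, by = 3),
                    c_grid = 2^seq(-5, 15, by = 4), epsilon = NULL,
                    epsilon_frac = 0.1, inner_folds = 5, seed = 1) {
  y_mean <- 0
  if (inherits(x, "pcm_design")) {
    y <- x$y; y_mean <- x$y_mean; x <- x$x
  }
  if (!all(is.finite(gamma_grid)) || !all(is.finite(c_grid)) ||
      !length(gamma_grid) || !length(c_grid)) {
    stop("gamma and C grids must be non-empty and finite", call. = FALSE)
  }
  if (is.null(epsilon)) epsilon <- epsilon_frac * stats::sd(y)
  grid <- expand.grid(C = sort(c_grid), gamma = sort(gamma_grid),
                      KEEP.OUT.ATTRS = FALSE)
  search <- NULL
  best <- grid[1, ]
  if (nrow(grid) > 1) {
    folds <- withr::with_seed(seed,
                              sample(rep_len(seq_len(inner_folds), nrow(x))))
    q2 <- vapply(seq_len(nrow(grid)), function(g) {
      pred <- rep(NA_real_, nrow(x))
      for (f in seq_len(inner_folds)) {
        tr <- folds != f
        fit <- e1071::svm(x[tr, , drop = FALSE], y[tr],
                          type = "eps-regression", kernel = "radial",
                          gamma = grid$gamma[g], cost = grid$C[g],
                          epsilon = epsilon, scale = FALSE)
        pred[!tr] <- stats::predict(fit, x[!tr, , drop = FALSE])
      }
      q_squared(y, pred)
    }, numeric(1))
    best <- grid[which.max(q2), ]  # grid ordered simple -> complex
    search <- tibble::as_tibble(cbind(grid, inner_q2 = q2))
  }
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                    gamma = best$gamma, cost = best$C, epsilon = epsilon,
                    scale = FALSE)
  structure(
    list(fit = fit, gamma = best$gamma, C = best$C, epsilon = epsilon,
         y_mean = y_mean, search = search),
    class = "pcm_svr"
  )
}

#' @export
predict.pcm_svr <- function(object, newdata, ...) {
  if (inherits(newdata, "pcm_design")) newdata <- newdata$x
  as.numeric(stats::predict(object$fit, newdata)) + object$y_mean
}

#' @export
print.pcm_svr <- function(x, ...) {
  cat(sprintf("epsilon-SVR (RBF): gamma = %g, C = %g, epsilon = %.3g\n",
              x$gamma, x$C, x$epsilon))
  invisible(x)
}

# inverse-distance weighted k-NN prediction from a squared-distance matrix
# (rows = test, cols = train); exact matches (d = 0) return the mean y of
# all zero-distance neighbours.
.knn_from_dist2 <- function(d2, y_train, k) {
  k <- min(k, ncol(d2))
  apply_row <- function(i) {
    d2i <- d2[i, ]
    zero <- d2i <= .Machine$double.eps * 100
    if (any(zero)) return(mean(y_train[zero]))
    nn <- order(d2i)[seq_len(k)]
    w <- 1 / sqrt(d2i[nn])
    sum(w * y_train[nn]) / sum(w)
  }
  vapply(seq_len(nrow(d2)), apply_row, numeric(1))
}

#' Distance-weighted k-nearest-neighbour prediction
#'
#' Predicts each test pair's activity as the 1/distance-weighted mean of
#' the activities of its k nearest training pairs in the block-scaled
#' descriptor space. The relative importance of kinase vs ligand similarity
#' is governed by a multiplier on the kinase block weight; k and the
#' multiplier are chosen by inner cross-validation (pooled inner Q2; ties
#' prefer larger k, then the grid order of the weight).
#'
#' @param train A `pcm_design` for the training pairs (must contain `ligand`
#'   and `kinase` blocks).
#' @param test A `pcm_design` (or matrix with matching columns) for the
#'   pairs to predict.
#' @param k_grid Candidate neighbour counts.
#' @param kinase_weight_grid Candidate kinase-block weight multipliers.
#' @param inner_folds,seed Inner-CV controls.
#' @return A list with `predictions` (numeric, response scale), the chosen
#'   `k` and `kinase_weight`, and the `search` table.
#' @export
knn_predict <- function(train, test, k_grid = c(1, 3, 5, 7, 9),
                        kinase_weight_grid = c(0.25, 0.5, 1, 2, 4),
                        inner_folds = 5, seed = 1) {
  stopifnot(inherits(train, "pcm_design"))
  if (any(k_grid > nrow(train$x))) {
    stop("k exceeds the number of training pairs", call. = FALSE)
  }
  xte <- if (inherits(test, "pcm_design")) test$x else test
  li <- train$blocks$ligand; ki <- train$blocks$kinase
  xtr_l <- train$x[, li, drop = FALSE]; xtr_k <- train$x[, ki, drop = FALSE]
  xte_l <- xte[, li, drop = FALSE]; xte_k <- xte[, ki, drop = FALSE]
  d2 <- function(a, b) {
    # squared Euclidean distances, rows of a vs rows of b
    an <- rowSums(a^2); bn <- rowSums(b^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(a, b), 0)
  }
  grid <- expand.grid(k = sort(k_grid, decreasing = TRUE),
                      kinase_weight = kinase_weight_grid,
                      KEEP.OUT.ATTRS = FALSE)
  best <- grid[1, ]
  search <- NULL
  if (nrow(grid) > 1) {
    folds <- withr::with_seed(
      seed, sample(rep_len(seq_len(inner_folds), nrow(train$x))))
    d2_ll <- d2(xtr_l, xtr_l); d2_kk <- d2(xtr_k, xtr_k)
    q2 <- vapply(seq_len(nrow(grid)), function(g) {
      wk2 <- grid$kinase_weight[g]^2
      pred <- rep(NA_real_, nrow(train$x))
      for (f in seq_len(inner_folds)) {
        tr <- folds != f
        dd <- d2_ll[!tr, tr, drop = FALSE] + wk2 * d2_kk[!tr, tr, drop = FALSE]
        pred[!tr] <- .knn_from_dist2(dd, train$y[tr],
                                     min(grid$k[g], sum(tr)))
      }
      q_squared(train$y, pred)
    }, numeric(1))
    best <- grid[which.max(q2), ]
    search <- tibble::as_tibble(cbind(grid, inner_q2 = q2))
  }
  wk2 <- best$kinase_weight^2
  dd <- d2(xte_l, xtr_l) + wk2 * d2(xte_k, xtr_k)
  pred <- .knn_from_dist2(dd, train$y, best$k) + train$y_mean
  list(predictions = pred, k = best$k, kinase_weight = best$kinase_weight,
       search = search)
}
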