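# NIPALS partial least-squares regression (PLS1/PLS2) and PLS discriminant
# analysis.

#' Fit a PLS regression model (NIPALS)
#'
#' Projects X and Y simultaneously to latent variables that maximise their
#' covariance. Single-response fits use the direct PLS1 recursion; matrix
#' responses (e.g. class indicators for PLS-DA) use the iterative PLS2 inner
#' loop. X is deflated per component. The model exposes a single regression
#' coefficient matrix, so predictions can be read as one interpretable
#' linear equation per response.
#'
#' @param x Design: a `pcm_design` from [assemble_design()], or a numeric
#'   matrix (already scaled and centred as desired).
#' @param y Response vector/matrix, centred; ignored (taken from the design)
#'   when `x` is a `pcm_design`.
#' @param n_components Number of PLS components A (>= 1).
#' @param tol,max_iter PLS2 inner-loop convergence controls.
#' @return An object of class `pcm_pls`: weights `W`, loadings `P`,
#'   response loadings `Q`, scores `T`, coefficients for every component
#'   count 1..A, `y_mean` (0 for plain matrices). Supports [predict()],
#'   [tidy()][generics::tidy] and [glance()][generics::glance].
#' @export
pls_fit <- function(x, y = NULL, n_components = 2, tol = 1e-12,
                    max_iter = 500) {
  y_mean <- 0
  if (inherits(x, "pcm_design")) {
    y <- x$y
    y_mean <- x$y_mean
    x <- x$x
  }
  y <- as.matrix(y)
  if (nrow(y) != nrow(x)) stop("x and y sizes differ", call. = FALSE)
  if (all(apply(y, 2, stats::sd) == 0)) {
    stop("degenerate response: zero variance", call. = FALSE)
  }
  n_components <- max(1L, as.integer(n_components))
  n <- nrow(x); p <- ncol(x); m <- ncol(y)
  if (m == 1) return(.pls1_fit(x, y, n_components, y_mean))
  xd <- x; yd <- y
  W <- P <- matrix(0, p, 0)
  Q <- matrix(0, m, 0)
  Tm <- matrix(0, n, 0)
  for (a in seq_len(n_components)) {
    if (sum(xd^2) < 1e-12 || sum(yd^2) < 1e-12) break
    u <- yd[, which.max(colSums(yd^2))]
    degenerate <- FALSE
    if (m == 1) {
      w <- crossprod(xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_vec <- xd %*% w
    } else {
      for (it in seq_len(max_iter)) {
        w <- crossprod(xd, u)[, 1]
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) { degenerate <- TRUE; break }
        w <- w / nw
        t_vec <- xd %*% w
        q <- crossprod(yd, t_vec)[, 1] / sum(t_vec^2)
        if (sum(q^2) < 1e-24) { degenerate <- TRUE; break }
        u_new <- yd %*% q / sum(q^2)
        if (sqrt(sum((u_new - u)^2)) < tol * sqrt(sum(u_new^2))) {
          u <- u_new
          break
        }
        u <- u_new
      }
    }
    if (degenerate) break
    tt <- sum(t_vec^2)
    if (tt < 1e-12) break
    p_vec <- crossprod(xd, t_vec)[, 1] / tt
    q_vec <- crossprod(yd, t_vec)[, 1] / tt
    xd <- xd - t_vec %*% t(p_vec)
    yd <- yd - t_vec %*% t(q_vec)
    W <- cbind(W, w); P <- cbind(P, p_vec)
    Q <- cbind(Q, q_vec); Tm <- cbind(Tm, t_vec)
  }
  a_used <- ncol(W)
  # R = W (P'W)^-1 maps original X to scores; B_a = R[,1:a] Q[,1:a]'
  R <- if (a_used > 0) W %*% solve(crossprod(P, W)) else W
  structure(
    list(W = W, P = P, Q = Q, T = Tm, R = R,
         n_components = a_used, y_mean = y_mean,
         x_names = colnames(x), y_names = colnames(y)),
    class = "pcm_pls"
  )
}

# Single-response PLS with covariance-vector deflation (Dayal-MacGregor):
# only X'y is deflated, never X, which gives the same weights, loadings and
# coefficients as the classical deflating recursion at a fraction of the
# memory traffic.
.pls1_fit <- function(x, y, n_components, y_mean) {
  n <- nrow(x); p <- ncol(x)
  xty <- crossprod(x, y)[, 1]
  W <- P <- R <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  for (a in seq_len(n_components)) {
    nrm <- sqrt(sum(xty^2))
    if (nrm < 1e-12) break
    w <- xty / nrm
    r <- w
    if (a > 1) {
      for (j in seq_len(a - 1)) r <- r - sum(P[, j] * r) * R[, j]
    }
    t_vec <- x %*% r
    tt <- sum(t_vec^2)
    if (tt < 1e-12) break
    p_vec <- crossprod(x, t_vec)[, 1] / tt
    q_a <- sum(r * xty) / tt
    xty <- xty - p_vec * (q_a * tt)
    W <- cbind(W, w); P <- cbind(P, p_vec); R <- cbind(R, r)
    Tm <- cbind(Tm, t_vec)
    q <- c(q, q_a)
  }
  structure(
    list(W = W, P = P, Q = matrix(q, nrow = 1), T = Tm, R = R,
         n_components = ncol(W), y_mean = y_mean,
         x_names = colnames(x), y_names = colnames(y) %||% "y"),
    class = "pcm_pls"
  )
}

#' Predict from a PLS model
#'
#' @param object A `pcm_pls` model.
#' @param newdata Numeric matrix (same columns/scaling as the training
#'   design) or a `pcm_design`.
#' @param n_components Component count to predict with (default: all
#'   fitted).
#' @param path `"coefficients"` computes X B; `"scores"` walks the
#'   score/deflation path. The two agree to numerical precision.
#' @param ... Unused.
#' @return Predicted response (vector for single-response models), on the
#'   training-response scale (the stored `y_mean` is added back).
#' @export
predict.pcm_pls <- function(object, newdata, n_components = NULL,
                            path = c("coefficients", "scores"), ...) {
  path <- match.arg(path)
  if (inherits(newdata, "pcm_design")) newdata <- newdata$x
  a <- min(n_components %||% object$n_components, object$n_components)
  if (path == "coefficients") {
    B <- object$R[, seq_len(a), drop = FALSE] %*%
      t(object$Q[, seq_len(a), drop = FALSE])
    pred <- newdata %*% B
  } else {
    xd <- newdata
    pred <- matrix(0, nrow(newdata), nrow(object$Q))
    for (k in seq_len(a)) {
      t_vec <- xd %*% object$W[, k]
      pred <- pred + t_vec %*% t(object$Q[, k, drop = FALSE])
      xd <- xd - t_vec %*% t(object$P[, k])
    }
  }
  pred <- pred + object$y_mean
  if (ncol(pred) == 1) pred[, 1] else pred
}

#' PLS regression coefficients
#' @param object A `pcm_pls` model.
#' @param n_components Component count (default: all fitted).
#' @return Coefficient matrix (p x responses) on the scaled-X scale.
#' @export
pls_coefficients <- function(object, n_components = NULL) {
  a <- min(n_components %||% object$n_components, object$n_components)
  B <- object$R[, seq_len(a), drop = FALSE] %*%
    t(object$Q[, seq_len(a), drop = FALSE])
  rownames(B) <- object$x_names
  colnames(B) <- object$y_names
  B
}

#' @export
print.pcm_pls <- function(x, ...) {
  cat(sprintf("NIPALS PLS model: %d component(s), %d predictors, %d response(s)\n",
              x$n_components, nrow(x$W), nrow(x$Q)))
  invisible(x)
}

#' PLS discriminant analysis of kinase groups
#'
#' Regresses a 0/1 class-indicator matrix (one column per group) on a
#' descriptor block with PLS2, and reports per-class and overall
#' cross-validated Q2. Scaling is refit inside every cross-validation
#' training fold; the component count maximising overall CV Q2 (up to
#' `n_components`) is retained.
#'
#' @param block A descriptor tibble (id column + numeric descriptors), e.g.
#'   from [describe_kinases()].
#' @param groups A factor/character vector of class labels, one per row of
#'   `block`; every class needs >= 2 members.
#' @param n_components Maximum number of PLS components evaluated.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return An object of class `pcm_plsda`: the final full-data `pcm_pls`
#'   fit plus `q2_overall`, `q2_per_class` (tibble), `n_components` and the
#'   pooled CV predictions.
#' @export
plsda_fit <- function(block, groups, n_components = 10, cv_folds = 5,
                      seed = 1) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 classes", call. = FALSE)
  if (any(table(groups) < 2)) {
    stop("singleton class: every class needs >= 2 members", call. = FALSE)
  }
  mat <- .block_matrix(block)
  y_ind <- stats::model.matrix(~ groups - 1)
  colnames(y_ind) <- levels(groups)
  n <- nrow(mat)
  a_max <- min(n_components, n - ceiling(n / cv_folds) - 1, ncol(mat))
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv_pred <- array(0, c(n, ncol(y_ind), a_max))
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    sc <- .scale_fit(mat[tr, , drop = FALSE])
    xtr <- .scale_apply(mat[tr, , drop = FALSE], sc)
    xte <- .scale_apply(mat[!tr, , drop = FALSE], sc)
    ym <- colMeans(y_ind[tr, , drop = FALSE])
    fit <- pls_fit(xtr, sweep(y_ind[tr, , drop = FALSE], 2, ym),
                   n_components = a_max)
    for (a in seq_len(a_max)) {
      if (fit$n_components == 0) {
        # inseparable fold: fall back to the class means
        cv_pred[!tr, , a] <- matrix(ym, sum(!tr), length(ym), byrow = TRUE)
      } else {
        pr <- predict(fit, xte,
                      n_components = min(a, fit$n_components))
        cv_pred[!tr, , a] <- sweep(as.matrix(pr), 2, ym, "+")
      }
    }
  }
  press <- apply(cv_pred, 3, function(pr) sum((y_ind - pr)^2))
  ss <- sum(sweep(y_ind, 2, colMeans(y_ind))^2)
  q2_by_a <- 1 - press / ss
  a_best <- which.max(q2_by_a)
  best_pred <- cv_pred[, , a_best, drop = TRUE]
  per_class <- vapply(seq_len(ncol(y_ind)), function(j) {
    1 - sum((y_ind[, j] - best_pred[, j])^2) /
      sum((y_ind[, j] - mean(y_ind[, j]))^2)
  }, numeric(1))
  sc <- .scale_fit(mat)
  fit <- pls_fit(.scale_apply(mat, sc),
                 sweep(y_ind, 2, colMeans(y_ind)), n_components = a_best)
  structure(
    list(fit = fit, scaling = sc, classes = levels(groups),
         n_components = a_best,
         q2_overall = q2_by_a[a_best],
         q2_per_class = tibble::tibble(class = colnames(y_ind),
                                       q2 = per_class),
         cv_predictions = best_pred),
    class = "pcm_plsda"
  )
}

#' @export
print.pcm_plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d classes, %d component(s), overall CV Q2 = %.3f\n",
              length(x$classes), x$n_components, x$q2_overall))
  invisible(x)
}

# minimal internal column scaler (matrix in/out)
.scale_fit <- function(x) {
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  list(mean = mu, sd = sd_)
}
.scale_apply <- function(x, sc) sweep(sweep(x, 2, sc$mean), 2, sc$sd, "/")
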