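# Double (nested) cross-validation, predictive metrics (Q2 / P2 / P2_kin),
# ROC analysis, prediction-error histograms and the dataset-size sweep.

#' Cross-validated squared correlation coefficient Q2
#'
#' Q2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2), with ybar the mean of the
#' observed values of the evaluated set. A perfect model gives 1, a
#' mean-only (random) model gives 0, and worse-than-mean predictions give
#' negative values.
#'
#' @param y_obs,y_pred Observed and predicted values (equal length >= 2).
#' @return A single numeric value.
#' @export
#' @examples
#' q_squared(c(0, 1, 2), c(0, 1, 4)) # 1 - 4/2 = -1
q_squared <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) < 2) {
    stop("y_obs and y_pred must have equal length >= 2", call. = FALSE)
  }
  ss <- sum((y_obs - mean(y_obs))^2)
  if (ss == 0) stop("undefined_q2: y_obs is constant", call. = FALSE)
  1 - sum((y_obs - y_pred)^2) / ss
}

#' Bundle activity data with descriptor blocks for modelling
#'
#' @param activity A long tibble with columns `kinase`, `compound`, `pkd`
#'   and optionally `inactive` (the censoring mask).
#' @param kinase_block A kinase descriptor tibble (raw, unscaled), e.g.
#'   from [describe_kinases()].
#' @param ligand_block A ligand descriptor tibble (raw, unscaled) with a
#'   `compound` id column.
#' @return An object of class `pcm_data`.
#' @export
prepare_pcm_data <- function(activity, kinase_block, ligand_block) {
  stopifnot(all(c("kinase", "compound", "pkd") %in% names(activity)))
  if (!"inactive" %in% names(activity)) activity$inactive <- FALSE
  missing_k <- setdiff(unique(activity$kinase), kinase_block$kinase)
  if (length(missing_k)) {
    stop("kinase(s) without descriptors: ",
         paste(utils::head(missing_k, 3), collapse = ", "), call. = FALSE)
  }
  missing_c <- setdiff(unique(activity$compound), ligand_block$compound)
  if (length(missing_c)) {
    stop("compound(s) without descriptors: ",
         paste(utils::head(missing_c, 3), collapse = ", "), call. = FALSE)
  }
  structure(
    list(pairs = tibble::as_tibble(activity),
         kinase_matrix = .block_matrix(kinase_block, "kinase"),
         ligand_matrix = .block_matrix(ligand_block, "compound")),
    class = "pcm_data"
  )
}

#' @export
print.pcm_data <- function(x, ...) {
  cat(sprintf(
    "pcm_data: %d pairs (%d kinases x %d compounds), %d kinase + %d ligand descriptors\n",
    nrow(x$pairs), nrow(x$kinase_matrix), nrow(x$ligand_matrix),
    ncol(x$kinase_matrix), ncol(x$ligand_matrix)))
  invisible(x)
}

#' Assign rows or kinases to cross-validation parts
#'
#' Uniform random assignment (balanced to within one element) of
#' kinase-inhibitor pairs (`pairwise`) or whole kinases (`kinasewise`) to
#' `n_parts` parts. In kinase-wise mode every pair of the same kinase lands
#' in the same part, so held-out kinases are entirely unseen.
#'
#' @param pairs A tibble with columns `kinase` and `compound`.
#' @param mode `"pairwise"` or `"kinasewise"`.
#' @param n_parts Number of parts (default 25).
#' @param seed RNG seed for the assignment.
#' @return An integer vector of part ids, one per row of `pairs`.
#' @export
split_plan <- function(pairs, mode = c("pairwise", "kinasewise"),
                       n_parts = 25, seed = 1) {
  mode <- match.arg(mode)
  if (mode == "pairwise") {
    withr::with_seed(seed, sample(rep_len(seq_len(n_parts), nrow(pairs))))
  } else {
    kin <- unique(pairs$kinase)
    if (length(kin) < n_parts) {
      stop(sprintf("kinasewise mode needs >= %d kinases (have %d)",
                   n_parts, length(kin)), call. = FALSE)
    }
    kp <- withr::with_seed(seed,
                           sample(rep_len(seq_len(n_parts), length(kin))))
    names(kp) <- kin
    unname(kp[pairs$kinase])
  }
}

# ---- internal: per-training-set preprocessing ------------------------------

# Build scaled train/test design matrices for one training set, refitting
# every state (scaling, block weights, PCA, Pareto factors, response mean)
# on the training rows only.
.build_prep <- function(data, train_idx, test_idx, method, control,
                        cache = NULL) {
  tr <- data$pairs[train_idx, ]
  te <- data$pairs[test_idx, ]
  kb <- data$kinase_matrix
  lb <- data$ligand_matrix
  tr_k <- unique(tr$kinase); tr_c <- unique(tr$compound)
  # preprocessing states depend only on the training entity sets, so they
  # are memoised across inner folds that share those sets
  key_k <- paste(sort(tr_k), collapse = ",")
  key_l <- paste(sort(tr_c), collapse = ",")
  kb_s <- .cached(cache, paste0("kscale:", key_k), function() {
    .scale_apply(kb, .scale_fit(kb[tr_k, , drop = FALSE])) / sqrt(ncol(kb))
  })
  lb_s <- .cached(cache, paste0("lscale:", key_l), function() {
    .scale_apply(lb, .scale_fit(lb[tr_c, , drop = FALSE])) / sqrt(ncol(lb))
  })
  prep <- list(
    ytr = tr$pkd, yte = te$pkd, y_mean = mean(tr$pkd),
    train_pairs = tr, test_pairs = te
  )
  if (method %in% c("pls_x", "tree")) {
    lig_pca <- .cached(cache, paste0("lpca:", key_l), function() {
      pca_nipals(lb_s[tr_c, , drop = FALSE],
                 n_components = min(length(tr_c) - 1, ncol(lb_s)),
                 tol = 1e-7, max_iter = 150)
    })
    kin_pca <- .cached(cache, paste0("kpca:", key_k), function() {
      pca_nipals(kb_s[tr_k, , drop = FALSE],
                 variance_target = control$variance_target,
                 tol = 1e-7, max_iter = 150)
    })
    ls_all <- predict(lig_pca, lb_s)
    ks_all <- predict(kin_pca, kb_s)
    if (method == "tree") {
      prep$xtr <- cbind(ls_all[tr$compound, , drop = FALSE],
                        ks_all[tr$kinase, , drop = FALSE])
      prep$xte <- cbind(ls_all[te$compound, , drop = FALSE],
                        ks_all[te$kinase, , drop = FALSE])
      colnames(prep$xtr) <- colnames(prep$xte) <-
        c(paste0("L", seq_len(ncol(ls_all))), paste0("K", seq_len(ncol(ks_all))))
      rownames(prep$xtr) <- rownames(prep$xte) <- NULL
      return(prep)
    }
    cross_tr <- make_cross_terms(ls_all, ks_all, tr, block_weight = 1)
    cross_te <- make_cross_terms(ls_all, ks_all, te, block_weight = 1,
                                 pareto_sd = attr(cross_tr, "pareto_sd"))
    prep$cross_tr <- cross_tr
    prep$cross_te <- cross_te
    prep$n_kin_pcs <- ncol(ks_all)
  }
  prep$xtr <- cbind(lb_s[tr$compound, , drop = FALSE],
                    kb_s[tr$kinase, , drop = FALSE])
  prep$xte <- cbind(lb_s[te$compound, , drop = FALSE],
                    kb_s[te$kinase, , drop = FALSE])
  rownames(prep$xtr) <- rownames(prep$xte) <- NULL
  prep$blocks <- list(ligand = seq_len(ncol(lb_s)),
                      kinase = ncol(lb_s) + seq_len(ncol(kb_s)))
  prep
}

# ---- internal: grid evaluation and final fits ------------------------------

# hyperparameter grid for a method, ordered simple -> complex so that
# which.max breaks ties toward the simpler model
.hyper_grid <- function(method, control, n_train) {
  switch(method,
    pls = tibble::tibble(ncomp = seq_len(control$ncomp_max)),
    pls_x = tidyr::crossing(
      cross_weight = control$cross_weight_grid,
      ncomp = seq_len(control$ncomp_max)
    ),
    svm = tidyr::expand_grid(C = sort(control$c_grid),
                             gamma = sort(control$gamma_grid)),
    knn = tidyr::expand_grid(kinase_weight = control$kinase_weight_grid,
                             k = sort(control$k_grid[control$k_grid <= n_train],
                                      decreasing = TRUE)),
    tree = tibble::tibble(min_leaf = sort(control$min_leaf_grid,
                                          decreasing = TRUE))
  )
}

# predictions (centred scale) for every grid row; returns n_test x n_grid
.eval_grid <- function(prep, method, control, grid) {
  ytr_c <- prep$ytr - prep$y_mean
  n_te <- length(prep$yte)
  out <- matrix(NA_real_, n_te, nrow(grid))
  if (method %in% c("pls", "pls_x")) {
    a_cap <- min(control$ncomp_max, nrow(prep$xtr) - 1)
    weights <- if (method == "pls") 0 else unique(grid$cross_weight)
    for (w in weights) {
      xtr <- prep$xtr; xte <- prep$xte
      if (method == "pls_x") {
        xtr <- cbind(xtr, w * prep$cross_tr)
        xte <- cbind(xte, w * prep$cross_te)
      }
      fit <- pls_fit(xtr, ytr_c, n_components = a_cap)
      rows <- if (method == "pls") seq_len(nrow(grid))
              else which(grid$cross_weight == w)
      for (r in rows) {
        a <- min(grid$ncomp[r], fit$n_components)
        out[, r] <- predict(fit, xte, n_components = a)
      }
    }
  } else if (method == "svm") {
    eps <- control$epsilon_frac * stats::sd(prep$ytr)
    # the RBF kernel depends on gamma only through exp(-gamma * D2), so the
    # squared-distance matrices are computed once and reused across the grid
    d2 <- function(a, b) {
      pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0)
    }
    d2_tr <- d2(prep$xtr, prep$xtr)
    d2_te <- d2(prep$xte, prep$xtr)
    for (g in unique(grid$gamma)) {
      ktr <- kernlab::as.kernelMatrix(exp(-g * d2_tr))
      kte <- exp(-g * d2_te)
      for (r in which(grid$gamma == g)) {
        fit <- kernlab::ksvm(ktr, ytr_c, type = "eps-svr",
                             C = grid$C[r], epsilon = eps)
        sv <- kernlab::SVindex(fit)
        out[, r] <- kernlab::predict(
          fit, kernlab::as.kernelMatrix(kte[, sv, drop = FALSE]))
      }
    }
  } else if (method == "knn") {
    li <- prep$blocks$ligand; ki <- prep$blocks$kinase
    d2 <- function(a, b) {
      pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0)
    }
    d2l <- d2(prep$xte[, li, drop = FALSE], prep$xtr[, li, drop = FALSE])
    d2k <- d2(prep$xte[, ki, drop = FALSE], prep$xtr[, ki, drop = FALSE])
    for (wk in unique(grid$kinase_weight)) {
      dd <- d2l + wk^2 * d2k
      for (r in which(grid$kinase_weight == wk)) {
        out[, r] <- .knn_from_dist2(dd, ytr_c, grid$k[r])
      }
    }
  } else if (method == "tree") {
    for (r in seq_len(nrow(grid))) {
      fit <- .m5_train(prep$xtr, ytr_c, grid$min_leaf[r], smoothing_k = 15)
      out[, r] <- .m5_apply(fit, prep$xte, 15)
    }
  }
  out
}

# Evaluate one train/test split: inner-CV hyperparameter selection on the
# training rows (folds given by inner_fold id per training row), refit on
# all training rows, predict the test rows.
.evaluate_split <- function(data, train_idx, test_idx, inner_fold,
                            method, control) {
  grid <- .hyper_grid(method, control, length(train_idx))
  n_folds <- max(inner_fold)
  cache <- new.env(parent = emptyenv())
  inner_pred <- matrix(NA_real_, length(train_idx), nrow(grid))
  for (f in seq_len(n_folds)) {
    val <- inner_fold == f
    prep <- .build_prep(data, train_idx[!val], train_idx[val],
                        method, control, cache)
    inner_pred[val, ] <- .eval_grid(prep, method, control, grid) +
      prep$y_mean
  }
  y_inner <- data$pairs$pkd[train_idx]
  inner_q2 <- apply(inner_pred, 2, function(p) q_squared(y_inner, p))
  best <- which.max(inner_q2)
  search <- dplyr::mutate(grid, inner_q2 = inner_q2)
  prep <- .build_prep(data, train_idx, test_idx, method, control, cache)
  pred <- .eval_grid(prep, method, control, grid[best, , drop = FALSE])[, 1] +
    prep$y_mean
  list(predictions = pred, selected = grid[best, ], search = search)
}

#' Double (nested) cross-validation of a proteochemometric model
#'
#' Splits the dataset into `n_parts` parts (by pair or by kinase), then runs
#' five outer rounds: each round puts 5/25 of the parts aside, selects
#' hyperparameters by 5-fold inner cross-validation on the remaining 20/25
#' (training on 16/25, validating on 4/25 per inner fold), refits on the
#' full 20/25 with the selected hyperparameters, and scores the untouched
#' 5/25. All preprocessing — scaling, block weights, PCA, Pareto factors,
#' response centring — is refit inside every training set. The pooled
#' outer-loop predictions give P2 (`pairwise` mode) or P2_kin
#' (`kinasewise` mode), unbiased estimates for new kinase-inhibitor pairs
#' and for entirely unseen kinases respectively.
#'
#' @param data A `pcm_data` object from [prepare_pcm_data()].
#' @param method `"pls"` (no cross-terms), `"pls_x"` (PLS with
#'   PC cross-terms and block-weight sweep), `"svm"`, `"knn"` or `"tree"`.
#' @param mode `"pairwise"` or `"kinasewise"` outer splitting.
#' @param n_parts Total number of parts (default 25; must be a multiple of
#'   5).
#' @param seed Seed governing all random assignments.
#' @param control A [cv_control()] list of grids and protocol constants.
#' @return An object of class `pcm_cv`: pooled `predictions` tibble, `p2`,
#'   `metric` name, per-round `hyperparameters` and search tables, `roc`
#'   (a `pcm_roc`), `auc`, and the part/round bookkeeping. Supports
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot].
#' @export
double_cv <- function(data, method = c("pls_x", "pls", "svm", "knn", "tree"),
                      mode = c("pairwise", "kinasewise"), n_parts = 25,
                      seed = 1, control = cv_control()) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(inherits(data, "pcm_data"))
  if (n_parts %% 5 != 0) stop("n_parts must be a multiple of 5", call. = FALSE)
  part <- split_plan(data$pairs, mode, n_parts, seed)
  if (any(tabulate(part, n_parts) == 0)) {
    stop("dataset too small: empty cross-validation part", call. = FALSE)
  }
  per_round <- n_parts / 5
  rounds <- split(seq_len(n_parts),
                  rep(seq_len(5), each = per_round))
  n <- nrow(data$pairs)
  pred <- rep(NA_real_, n)
  round_of <- integer(n)
  hyper <- list()
  for (r in seq_len(5)) {
    test_parts <- rounds[[r]]
    test_idx <- which(part %in% test_parts)
    train_idx <- which(!part %in% test_parts)
    # outer-loop purity audit
    if (length(intersect(train_idx, test_idx)) > 0) {
      stop("internal audit failure: outer train/test rows overlap")
    }
    if (mode == "kinasewise") {
      overlap <- intersect(data$pairs$kinase[train_idx],
                           data$pairs$kinase[test_idx])
      if (length(overlap) > 0) {
        stop("internal audit failure: kinase in both outer sets")
      }
    }
    train_parts <- setdiff(seq_len(n_parts), test_parts)
    fold_of_part <- stats::setNames(rep_len(seq_len(control$inner_folds),
                                            length(train_parts)),
                                    train_parts)
    inner_fold <- fold_of_part[as.character(part[train_idx])]
    res <- .evaluate_split(data, train_idx, test_idx, inner_fold,
                           method, control)
    pred[test_idx] <- res$predictions
    round_of[test_idx] <- r
    hyper[[r]] <- list(selected = res$selected, search = res$search)
  }
  predictions <- dplyr::bind_cols(
    data$pairs[c("kinase", "compound", "pkd", "inactive")],
    tibble::tibble(predicted = pred, part = part, outer_round = round_of)
  )
  p2 <- q_squared(predictions$pkd, predictions$predicted)
  roc <- roc_analysis(predictions$pkd, predictions$predicted)
  structure(
    list(predictions = predictions, p2 = p2,
         metric = if (mode == "pairwise") "P2" else "P2_kin",
         method = method, mode = mode, n_parts = n_parts, seed = seed,
         hyperparameters = hyper, roc = roc, auc = roc$auc),
    class = "pcm_cv"
  )
}

#' @export
print.pcm_cv <- function(x, ...) {
  cat(sprintf("double CV (%s, %s): %s = %.3f, AUC = %.3f over %d pairs\n",
              x$method, x$mode, x$metric, x$p2, x$auc,
              nrow(x$predictions)))
  invisible(x)
}

#' Modelling performance as a function of dataset size
#'
#' For each training fraction, repeatedly draws a random training subset
#' (of pairs, or of whole kinases in `kinasewise` mode), selects
#' hyperparameters by inner cross-validation within that subset, refits and
#' evaluates on all remaining data, and averages the resulting P2 (or
#' P2_kin) over repeats. A fraction of 1 degenerates to [double_cv()].
#'
#' @inheritParams double_cv
#' @param fractions Training fractions to evaluate.
#' @param n_repeats Number of random splits per fraction (default 10).
#' @return A list with `results` (per-repeat tibble) and `summary` (mean
#'   and sd of P2 per fraction), of class `pcm_size_sweep`.
#' @export
dataset_size_sweep <- function(data, method = "pls_x",
                               mode = c("pairwise", "kinasewise"),
                               fractions = c(0.8, 0.6, 0.4, 0.2, 0.1),
                               n_repeats = 10, seed = 1,
                               control = cv_control()) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "pcm_data"))
  rows <- list()
  for (f_i in seq_along(fractions)) {
    f <- fractions[f_i]
    if (f >= 1) {
      cv <- double_cv(data, method, mode, seed = seed, control = control)
      rows[[length(rows) + 1]] <- tibble::tibble(
        fraction = 1, repeat_id = 1L, p2 = cv$p2)
      next
    }
    for (rep_i in seq_len(n_repeats)) {
      split_seed <- seed + 1000 * f_i + rep_i
      if (mode == "pairwise") {
        n <- nrow(data$pairs)
        train_idx <- withr::with_seed(split_seed,
                                      sample(n, max(2, round(f * n))))
      } else {
        kin <- unique(data$pairs$kinase)
        kin_tr <- withr::with_seed(
          split_seed, sample(kin, max(2, round(f * length(kin)))))
        train_idx <- which(data$pairs$kinase %in% kin_tr)
      }
      test_idx <- setdiff(seq_len(nrow(data$pairs)), train_idx)
      inner_fold <- .inner_folds_for(data$pairs[train_idx, ], mode,
                                     control$inner_folds, split_seed + 1)
      res <- .evaluate_split(data, train_idx, test_idx, inner_fold,
                             method, control)
      rows[[length(rows) + 1]] <- tibble::tibble(
        fraction = f, repeat_id = rep_i,
        p2 = q_squared(data$pairs$pkd[test_idx], res$predictions))
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$fraction),
    mean_p2 = mean(.data$p2), sd_p2 = stats::sd(.data$p2),
    n_repeats = dplyr::n(), .groups = "drop"
  )
  summary <- dplyr::arrange(summary, dplyr::desc(.data$fraction))
  structure(list(results = results, summary = summary, method = method,
                 mode = mode,
                 metric = if (mode == "pairwise") "P2" else "P2_kin"),
            class = "pcm_size_sweep")
}

# memoise helper: evaluate fn() once per key within a cache environment
.cached <- function(cache, key, fn) {
  if (is.null(cache)) return(fn())
  if (!exists(key, envir = cache, inherits = FALSE)) {
    assign(key, fn(), envir = cache)
  }
  get(key, envir = cache, inherits = FALSE)
}

# inner fold ids for a training subset (respecting kinase grouping)
.inner_folds_for <- function(train_pairs, mode, n_folds, seed) {
  if (mode == "pairwise") {
    withr::with_seed(seed, sample(rep_len(seq_len(n_folds),
                                          nrow(train_pairs))))
  } else {
    kin <- unique(train_pairs$kinase)
    kf <- withr::with_seed(seed,
                           sample(rep_len(seq_len(n_folds), length(kin))))
    names(kf) <- kin
    unname(kf[train_pairs$kinase])
  }
}

#' @export
print.pcm_size_sweep <- function(x, ...) {
  cat(sprintf("dataset-size sweep (%s, %s):\n", x$method, x$mode))
  print(x$summary)
  invisible(x)
}

#' ROC analysis of interacting vs non-interacting classification
#'
#' Treats pairs with observed pK_d at or above `active_threshold` as truly
#' interacting and uses the predicted pK_d as the classification score.
#' Sensitivity (TP / (TP + FN)) and specificity (TN / (TN + FP)) are traced
#' over all distinct score thresholds; the area under the curve is computed
#' by the trapezoidal rule and, equivalently, as the Mann-Whitney rank
#' statistic.
#'
#' @param y_obs Observed pK_d values.
#' @param y_pred Predicted pK_d values (the scores).
#' @param active_threshold Detection threshold for a true interaction
#'   (default 5.0).
#' @param at_sensitivity Sensitivities at which to report the achievable
#'   specificity.
#' @return An object of class `pcm_roc`: `points` tibble (threshold,
#'   sensitivity, specificity), `auc` (trapezoid), `auc_rank`
#'   (Mann-Whitney), class counts and an `operating` tibble of
#'   specificities at the requested sensitivities.
#' @export
roc_analysis <- function(y_obs, y_pred, active_threshold = 5.0,
                         at_sensitivity = c(0.80, 0.90)) {
  truth <- y_obs >= active_threshold
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present for ROC analysis", call. = FALSE)
  }
  thr <- sort(unique(y_pred), decreasing = TRUE)
  ord <- order(y_pred, decreasing = TRUE)
  truth_ord <- truth[ord]
  score_ord <- y_pred[ord]
  cum_tp <- cumsum(truth_ord)
  cum_fp <- cumsum(!truth_ord)
  last_of_thr <- cumsum(rle(score_ord)$lengths)
  tp <- cum_tp[last_of_thr]; fp <- cum_fp[last_of_thr]
  sens <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  # Mann-Whitney formulation with tie correction
  rk <- rank(y_pred)
  auc_rank <- (sum(rk[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  points <- tibble::tibble(
    threshold = c(Inf, thr),
    sensitivity = sens,
    specificity = 1 - fpr
  )
  operating <- purrr::map_dfr(at_sensitivity, function(s) {
    ok <- points$sensitivity >= s
    tibble::tibble(sensitivity = s,
                   specificity = if (any(ok)) max(points$specificity[ok])
                                 else 0)
  })
  structure(
    list(points = points, auc = auc, auc_rank = auc_rank,
         n_active = n_pos, n_inactive = n_neg,
         active_threshold = active_threshold, operating = operating),
    class = "pcm_roc"
  )
}

#' @export
print.pcm_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d active vs %d inactive)\n",
              x$auc, x$n_active, x$n_inactive))
  invisible(x)
}

#' Cumulative distribution of absolute prediction errors
#'
#' Reports the fraction of pairs whose absolute prediction error falls at
#' or below each edge (cumulative), plus plot-ready histogram bins.
#'
#' @param y_obs,y_pred Observed and predicted values.
#' @param bin_edges Cumulative error edges in pK_d units.
#' @return A list of class `pcm_error_hist` with `cumulative` (edge,
#'   fraction, count) and `bins` tibbles.
#' @export
error_histogram <- function(y_obs, y_pred,
                            bin_edges = c(0.25, 0.5, 1.0, 2.0)) {
  stopifnot(length(y_obs) == length(y_pred))
  err <- abs(y_obs - y_pred)
  edges <- sort(bin_edges)
  cumulative <- tibble::tibble(
    edge = edges,
    count = vapply(edges, function(e) sum(err <= e), numeric(1)),
    fraction = vapply(edges, function(e) mean(err <= e), numeric(1))
  )
  breaks <- c(0, edges, max(edges, max(err)) + 1e-9)
  bins <- tibble::tibble(
    lower = utils::head(breaks, -1),
    upper = utils::tail(breaks, -1),
    count = as.integer(table(cut(err, breaks, include.lowest = TRUE)))
  )
  structure(list(cumulative = cumulative, bins = bins, n = length(err)),
            class = "pcm_error_hist")
}

#' @export
print.pcm_error_hist <- function(x, ...) {
  cat("cumulative |error| fractions:\n")
  print(x$cumulative)
  invisible(x)
}
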