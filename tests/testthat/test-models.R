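test_that("PLS fits noiseless linear systems exactly at full rank", {
  set.seed(50)
  x <- matrix(rnorm(40 * 6), 40, 6)
  xc <- sweep(x, 2, colMeans(x))
  beta <- rnorm(6)
  y <- as.vector(xc %*% beta)
  fit <- pls_fit(xc, y - mean(y), n_components = 6)
  expect_lt(max(abs(predict(fit, xc) + mean(y) - y)), 1e-8)
})

test_that("one-component weights align with the informative column", {
  set.seed(51)
  x <- cbind(strong = rnorm(60), matrix(rnorm(60 * 4, sd = 1), 60, 4))
  y <- 3 * x[, 1] + rnorm(60, sd = 0.01)
  fit <- pls_fit(x, y - mean(y), n_components = 1)
  expect_equal(unname(which.max(abs(fit$W[, 1]))), 1L)
})

test_that("NIPALS PLS matches an independent SIMPLS oracle", {
  set.seed(52)
  for (rep in 1:3) {
    x <- matrix(rnorm(50 * 20), 50, 20)
    y <- as.vector(x %*% rnorm(20) * 0.3 + rnorm(50))
    xc <- sweep(x, 2, colMeans(x)); yc <- y - mean(y)
    for (a in c(2, 5, 10)) {
      fit <- pls_fit(xc, yc, n_components = a)
      b_oracle <- simpls_oracle(xc, yc, a)
      expect_lt(max(abs(xc %*% b_oracle - predict(fit, xc))), 1e-6)
    }
  }
})

test_that("coefficient-path and score-path predictions coincide", {
  set.seed(53)
  x <- matrix(rnorm(30 * 15), 30, 15)
  y <- rnorm(30)
  fit <- pls_fit(x, y - mean(y), n_components = 6)
  xnew <- matrix(rnorm(10 * 15), 10, 15)
  expect_equal(predict(fit, xnew, path = "coefficients"),
               predict(fit, xnew, path = "scores"), tolerance = 1e-8)
})

test_that("degenerate responses are rejected", {
  expect_error(pls_fit(matrix(rnorm(20), 10, 2), rep(2, 10)), "degenerate")
})

test_that("PLS-DA separates the planted kinase groups but not shuffled labels", {
  panel <- tiny_panel()
  block <- describe_kinases(panel$sequences, "aligned_z")
  fit <- plsda_fit(block, panel$sequences$group, n_components = 8, seed = 2)
  expect_gte(fit$q2_overall, 0.6)
  expect_equal(nrow(fit$q2_per_class), 7)
  shuffled <- withr::with_seed(9, sample(panel$sequences$group))
  fit0 <- plsda_fit(block, shuffled, n_components = 8, seed = 2)
  expect_lt(fit0$q2_overall, 0.15)
  expect_error(plsda_fit(block, c("a", rep("b", 27))), "singleton")
})

test_that("duplicated sequences across two classes are inseparable", {
  seqs <- vapply(60:69, function(s) random_seq(50, s), character(1))
  block <- describe_kinases(
    tibble::tibble(kinase = sprintf("k%02d", 1:20),
                   sequence = rep(seqs, 2)), "ctd")
  labels <- rep(c("one", "two"), each = 10)  # classes share identical rows
  fit <- plsda_fit(block, labels, n_components = 4, seed = 3)
  expect_lt(fit$q2_overall, 0.1)
})

test_that("epsilon-SVR beats linear PLS on a smooth non-linear surface", {
  set.seed(54)
  n <- 150
  x <- matrix(runif(n * 2, -2, 2), n, 2)
  y <- sin(2 * x[, 1]) * cos(x[, 2]) + rnorm(n, sd = 0.05)
  svr <- svr_fit(x, y, gamma_grid = 2^(-3:1), c_grid = 2^(0:4), seed = 4)
  best_svr <- max(svr$search$inner_q2)
  folds <- withr::with_seed(4, sample(rep_len(1:5, n)))
  pred_pls <- rep(NA_real_, n)
  for (f in 1:5) {
    tr <- folds != f
    fit <- pls_fit(x[tr, ], y[tr] - mean(y[tr]), n_components = 2)
    pred_pls[!tr] <- predict(fit, x[!tr, ]) + mean(y[tr])
  }
  expect_gt(best_svr, q_squared(y, pred_pls))
})

test_that("vanishing C collapses SVR towards constant predictions", {
  set.seed(55)
  x <- matrix(rnorm(80 * 3), 80, 3)
  y <- x[, 1] + rnorm(80, sd = 0.1)
  fit <- svr_fit(x, y, gamma_grid = 0.1, c_grid = 1e-6)
  pred <- predict(fit, x)
  expect_lt(sd(pred), 0.05 * sd(y))
  expect_error(svr_fit(x, y, gamma_grid = numeric(0), c_grid = 1),
               "non-empty")
})

test_that("duplicated training rows are predicted within the epsilon tube", {
  # five well-separated sites, 16 copies each: RBF kernels barely overlap,
  # so a large C must fit every site inside the tube
  sites <- matrix(c(0, 0, 6, 0, 0, 6, 6, 6, 12, 12), 5, 2, byrow = TRUE)
  x <- sites[rep(1:5, each = 16), ]
  y <- rep(c(1, 3, 5, 7, 9), each = 16)
  eps <- 0.1 * sd(y)
  fit <- svr_fit(x, y, gamma_grid = 1, c_grid = 100, epsilon = eps)
  expect_true(all(abs(predict(fit, x) - y) <= eps + 1e-6))
})

# hand-built two-block design for k-NN geometry tests
knn_design <- function(lig_vals, kin_vals, y) {
  n <- length(y)
  x <- cbind(L = lig_vals, K = kin_vals)
  structure(list(
    x = x, y = y - mean(y), y_mean = mean(y),
    pairs = tibble::tibble(kinase = paste0("k", seq_len(n)),
                           compound = paste0("c", seq_len(n))),
    inactive = rep(FALSE, n),
    blocks = list(ligand = 1L, kinase = 2L)
  ), class = "pcm_design")
}

test_that("k-NN returns exact matches and inverse-distance weighted means", {
  train <- knn_design(c(0, 1, 3), c(0, 0, 0), y = c(10, 4, 8))
  test1 <- knn_design(0, 0, y = 0)
  out <- knn_predict(train, test1, k_grid = 1, kinase_weight_grid = 1)
  expect_equal(out$predictions, 10)  # identical training point wins
  # distances 1 and 3 from x = 0 after dropping the exact match:
  train2 <- knn_design(c(1, 3), c(0, 0), y = c(4, 8))
  out2 <- knn_predict(train2, test1, k_grid = 2, kinase_weight_grid = 1)
  expect_equal(out2$predictions, (4 / 1 + 8 / 3) / (1 + 1 / 3))  # 5.0
})

test_that("an all-inactive neighbourhood predicts the floor exactly", {
  train <- knn_design(c(1, 1.5, 2, 9), c(0, 0, 0, 0), y = c(4, 4, 4, 9))
  test <- knn_design(1.4, 0, y = 0)
  out <- knn_predict(train, test, k_grid = 3, kinase_weight_grid = 1)
  expect_equal(out$predictions, 4)
})

test_that("the kinase block weight steers neighbour ranking monotonically", {
  # neighbour A is close in ligand space, B is close in kinase space
  train <- knn_design(c(0.1, 5), c(5, 0.1), y = c(1, 9))
  test <- knn_design(0, 0, y = 0)
  lig_led <- knn_predict(train, test, k_grid = 1, kinase_weight_grid = 0.01)
  kin_led <- knn_predict(train, test, k_grid = 1, kinase_weight_grid = 100)
  expect_equal(lig_led$predictions, 1)
  expect_equal(kin_led$predictions, 9)
  expect_error(knn_predict(train, test, k_grid = 10,
                           kinase_weight_grid = 1), "exceeds")
})

test_that("model trees recover a planted split and prune pure linear fits", {
  set.seed(57)
  x <- matrix(runif(200, -1, 1), 100, 2,
              dimnames = list(NULL, c("a", "b")))
  y_step <- ifelse(x[, 1] <= 0.2, 1, 5) + rnorm(100, sd = 0.05)
  tree <- model_tree_fit(x, y_step, min_leaf_grid = 8)
  expect_gte(m5_n_leaves(tree), 2)
  expect_equal(tree$tree$feature, "a")
  expect_equal(tree$tree$threshold, 0.2, tolerance = 0.1)
  # pure linear response collapses to few leaves with near-OLS coefficients
  y_lin <- as.vector(x %*% c(2, -1))
  tree_lin <- model_tree_fit(x, y_lin, min_leaf_grid = 8)
  expect_lte(m5_n_leaves(tree_lin), 2)
  expect_equal(unname(predict(tree_lin, x)), unname(y_lin), tolerance = 0.05)
})

test_that("min_leaf = n yields the global linear model in a single leaf", {
  set.seed(58)
  x <- matrix(rnorm(30 * 2), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.vector(x %*% c(1, 2)) + rnorm(30, sd = 0.01)
  tree <- model_tree_fit(x, y, min_leaf_grid = 30)
  expect_equal(m5_n_leaves(tree), 1)
  ols <- coef(lm(y ~ x))
  expect_equal(unname(tree$tree$model$coef[c("(Intercept)", "a", "b")]),
               unname(ols), tolerance = 0.01)
  # constant response: single leaf, no error
  flat <- model_tree_fit(x, rep(3, 30), min_leaf_grid = 4)
  expect_equal(m5_n_leaves(flat), 1)
  expect_equal(unname(predict(flat, x)), rep(3, 30))
  expect_error(model_tree_fit(x, y, min_leaf_grid = 1), "min_leaf")
})
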