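make_block <- function(n = 12, p = 6, seed = 40, id = "kinase") {
  set.seed(seed)
  dplyr::bind_cols(
    tibble::tibble(!!id := sprintf("e%02d", seq_len(n))),
    tibble::as_tibble(matrix(rnorm(n * p, mean = 3, sd = 2), n,
                             dimnames = list(NULL, paste0("d", seq_len(p)))))
  )
}

test_that("autoscale centres and scales, and apply mode reuses the state", {
  b <- make_block()
  scaled <- autoscale(b)
  mat <- as.matrix(scaled[-1])
  expect_equal(unname(colMeans(mat)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(mat, 2, sd)), rep(1, 6), tolerance = 1e-10)
  # idempotence: applying the stored state to the training block itself
  reapplied <- autoscale(b, scaling_state(scaled))
  expect_equal(as.matrix(reapplied[-1]), mat, tolerance = 1e-12)
  # held-out rows generally do not come out centred
  held <- make_block(seed = 41)
  applied <- autoscale(held, scaling_state(scaled))
  expect_gt(max(abs(colMeans(as.matrix(applied[-1])))), 0.01)
  bad <- make_block(p = 3, seed = 42)
  names(bad)[2:4] <- c("x1", "x2", "x3")
  expect_error(autoscale(bad, scaling_state(scaled)), "names")
})

test_that("zero-variance columns are dropped with a warning", {
  b <- make_block()
  b$d3 <- 7
  expect_warning(scaled <- autoscale(b), "zero-variance")
  expect_false("d3" %in% names(scaled))
})

test_that("block scaling equalises total block variances at 1/sqrt(N)", {
  wide <- autoscale(make_block(n = 20, p = 50, seed = 43))
  narrow <- autoscale(make_block(n = 20, p = 1, seed = 44, id = "compound"))
  scaled <- block_scale(list(kin = wide, lig = narrow))
  v_wide <- sum(apply(as.matrix(scaled$kin[-1]), 2, var))
  expect_equal(v_wide, 1, tolerance = 1e-10)
  expect_equal(unname(apply(as.matrix(scaled$kin[-1]), 2, var)[1]), 1 / 50,
               tolerance = 1e-10)
  # single-column block is unchanged (weight 1) and already unit variance
  expect_equal(sum(apply(as.matrix(scaled$lig[-1]), 2, var)), 1,
               tolerance = 1e-10)
  expect_equal(as.matrix(scaled$lig[-1]), as.matrix(narrow[-1]))
  expect_error(block_scale(list(raw = make_block())), "autoscaled")
})

test_that("NIPALS PCA reconstructs the data losslessly at full rank", {
  set.seed(45)
  x <- matrix(rnorm(38 * 50), 38, 50)
  pca <- pca_nipals(x, n_components = 37)
  recon <- pca$scores %*% t(pca$loadings)
  centred <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(recon - centred)), 1e-8)
})

test_that("explained variance vanishes past the true rank", {
  set.seed(46)
  x <- matrix(rnorm(30 * 2), 30, 2) %*% matrix(rnorm(2 * 8), 2, 8)
  pca <- pca_nipals(x, n_components = 3)
  third <- if (length(pca$explained_variance) >= 3) {
    pca$explained_variance[3]
  } else 0  # extraction may stop at the numerical rank
  expect_lt(third, 1e-10)
})

test_that("NIPALS agrees with a direct eigendecomposition", {
  set.seed(47)
  x <- matrix(rnorm(25 * 10), 25, 10)
  pca <- pca_nipals(x, n_components = 5)
  xc <- sweep(x, 2, colMeans(x))
  eig <- eigen(crossprod(xc), symmetric = TRUE)
  evf <- eig$values / sum(diag(crossprod(xc)))
  expect_equal(pca$explained_variance, evf[1:5], tolerance = 1e-7)
  for (k in 1:5) {
    expect_equal(abs(sum(pca$loadings[, k] * eig$vectors[, k])), 1,
                 tolerance = 1e-6)
  }
  expect_error(pca_nipals(x, n_components = 30), "exceeds")
  expect_error(pca_nipals(x, variance_target = 1.2), "variance_target")
})

test_that("scores are reproducible as data times loadings", {
  set.seed(48)
  x <- matrix(rnorm(20 * 12), 20, 12)
  pca <- pca_nipals(x, n_components = 4)
  expect_equal(unname(predict(pca, x)), unname(pca$scores), tolerance = 1e-6)
})

test_that("cross-terms multiply every ligand PC with every kinase PC", {
  set.seed(49)
  ls <- matrix(rnorm(6 * 3), 6, dimnames = list(paste0("c", 1:6),
                                                paste0("PC", 1:3)))
  ks <- matrix(rnorm(9 * 4), 9, dimnames = list(paste0("k", 1:9),
                                                paste0("PC", 1:4)))
  pairs <- tidyr::expand_grid(kinase = rownames(ks), compound = rownames(ls))
  cross <- make_cross_terms(ls, ks, pairs, block_weight = 1)
  expect_equal(ncol(cross), 12)
  expect_equal(nrow(cross), 54)
  # weight 0 removes the block's contribution entirely
  zero <- make_cross_terms(ls, ks, pairs, block_weight = 0)
  expect_true(all(zero == 0))
  # Pareto scaling: post-scaling sd is the square root of the raw sd
  raw <- make_cross_terms(ls, ks, pairs, block_weight = 1,
                          pareto_sd = rep(1, 12))
  sds_raw <- apply(raw, 2, sd)
  expect_equal(apply(cross, 2, sd), sqrt(sds_raw), tolerance = 1e-10)
})

test_that("design assembly produces one centred row per pair", {
  panel <- tiny_panel()
  pairs <- panel$activity
  lig <- autoscale(panel$ligand_table)
  kin <- autoscale(describe_kinases(panel$sequences, "ctd"))
  design <- assemble_design(pairs, lig, kin)
  expect_equal(nrow(design$x), 350)  # 35 kinases x 10 inhibitors
  expect_equal(mean(design$y), 0, tolerance = 1e-12)
  expect_equal(design$y + design$y_mean, pairs$pkd)
  expect_equal(length(design$blocks$ligand) + length(design$blocks$kinase),
               ncol(design$x))
  missing <- pairs
  missing$kinase[1] <- "nope"
  expect_error(assemble_design(missing, lig, kin), "nope")
})

test_that("the full default panel shape matches the modelled kinome screen", {
  cfg <- synth_config()
  expect_equal(cfg$n_kinases * cfg$n_inhibitors, 12046)
})
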