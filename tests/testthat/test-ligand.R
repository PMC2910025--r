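write_ligand_file <- function(df, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  readr::write_delim(df, path, delim = if (ext == "csv") "," else "\t")
  path
}

test_that("ligand tables load with ids and numeric descriptors", {
  set.seed(30)
  df <- data.frame(id = sprintf("c%02d", 1:38),
                   matrix(rnorm(38 * 150), 38,
                          dimnames = list(NULL, sprintf("D%03d", 1:150))))
  tbl <- load_ligand_table(write_ligand_file(df))
  expect_equal(dim(tbl), c(38, 151))
  expect_equal(names(tbl)[1], "compound")
})

test_that("constant columns are dropped with a warning", {
  df <- data.frame(id = c("a", "b", "c"), d1 = c(1, 2, 3), d2 = c(5, 5, 5))
  expect_warning(tbl <- load_ligand_table(write_ligand_file(df)), "constant")
  expect_equal(names(tbl), c("compound", "d1"))
})

test_that("duplicate ids and non-numeric cells are rejected", {
  dup <- data.frame(id = c("a", "a"), d1 = c(1, 2))
  expect_error(load_ligand_table(write_ligand_file(dup)), "duplicate")
  bad <- data.frame(id = c("a", "b"), d1 = c("1.5", "oops"))
  expect_error(load_ligand_table(write_ligand_file(bad)), "non-numeric")
})

test_that("identical columns are pruned down to one survivor", {
  set.seed(31)
  x <- rnorm(10)
  tbl <- tibble::tibble(compound = letters[1:10],
                        d1 = x, d2 = x, d3 = rnorm(10))
  pruned <- prune_correlated(tbl, 0.9)
  expect_equal(ncol(pruned), 3)  # compound + 2 descriptors
  expect_true("d3" %in% names(pruned))
  expect_equal(nrow(pruning_log(pruned)), 1)
})

test_that("uncorrelated tables pass through unchanged", {
  set.seed(32)
  tbl <- tibble::tibble(compound = letters[1:20],
                        a = rnorm(20), b = rnorm(20), c = rnorm(20))
  pruned <- prune_correlated(tbl, 0.9)
  expect_equal(names(pruned), names(tbl))
  expect_equal(nrow(pruning_log(pruned)), 0)
})

# independent naive implementation of the pruning rule
prune_oracle <- function(mat, thr) {
  keep <- colnames(mat)
  repeat {
    r2 <- suppressWarnings(cor(mat[, keep, drop = FALSE]))^2
    diag(r2) <- 0
    if (max(r2) <= thr) break
    hits <- which(r2 == max(r2), arr.ind = TRUE)
    pairs <- unique(t(apply(hits, 1, function(h) sort(keep[h]))))
    pair <- pairs[order(pairs[, 1], pairs[, 2])[1], ]
    worst <- sapply(pair, function(d) max(r2[d, setdiff(keep, d)]))
    drop <- if (worst[1] > worst[2]) pair[1] else pair[2]
    keep <- setdiff(keep, drop)
  }
  sort(keep)
}

test_that("pruning matches the exhaustive oracle on planted structures", {
  set.seed(33)
  for (rep in 1:5) {
    base <- matrix(rnorm(40), 20, 2)
    mat <- cbind(
      v1 = base[, 1],
      v2 = base[, 1] + rnorm(20, sd = 0.05),
      v3 = base[, 2],
      v4 = base[, 2] * 0.9 + rnorm(20, sd = 0.1),
      v5 = rnorm(20)
    )
    tbl <- dplyr::bind_cols(tibble::tibble(compound = letters[1:20]),
                            tibble::as_tibble(mat))
    pruned <- prune_correlated(tbl, 0.9)
    expect_equal(sort(setdiff(names(pruned), "compound")),
                 prune_oracle(mat, 0.9))
  }
})

test_that("no surviving pair is correlated and order does not matter", {
  set.seed(34)
  base <- matrix(rnorm(60), 20, 3)
  mat <- base[, c(1, 1, 2, 2, 3, 3)] + matrix(rnorm(120, sd = 0.1), 20, 6)
  colnames(mat) <- paste0("d", 1:6)
  tbl <- dplyr::bind_cols(tibble::tibble(compound = letters[1:20]),
                          tibble::as_tibble(mat))
  pruned <- prune_correlated(tbl, 0.8)
  surv <- as.matrix(pruned[-1])
  r2 <- cor(surv)^2; diag(r2) <- 0
  expect_true(max(r2) <= 0.8)
  shuffled <- tbl[, c("compound", sample(paste0("d", 1:6)))]
  pruned2 <- prune_correlated(shuffled, 0.8)
  expect_setequal(names(pruned2), names(pruned))
})
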