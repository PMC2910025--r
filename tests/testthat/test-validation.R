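test_that("Q2 matches hand-computed values and its boundary cases", {
  y <- c(0, 1, 2)
  expect_equal(q_squared(y, y), 1)
  expect_equal(q_squared(y, rep(mean(y), 3)), 0)
  expect_equal(q_squared(y, c(0, 1, 4)), -1)  # 1 - 4/2
  expect_error(q_squared(c(2, 2, 2), c(1, 2, 3)), "undefined_q2")
  expect_error(q_squared(1:3, 1:4), "equal length")
})

test_that("split plans are balanced and kinase-wise splits keep kinases whole", {
  pairs <- tidyr::expand_grid(kinase = sprintf("k%03d", 1:60),
                              compound = sprintf("c%02d", 1:10))
  pw <- split_plan(pairs, "pairwise", n_parts = 25, seed = 3)
  expect_equal(length(pw), 600)
  expect_true(all(abs(tabulate(pw, 25) - 24) <= 1))
  kw <- split_plan(pairs, "kinasewise", n_parts = 25, seed = 3)
  per_kinase <- tapply(kw, pairs$kinase, function(p) length(unique(p)))
  expect_true(all(per_kinase == 1))
  counts <- table(tapply(kw, pairs$kinase, unique))
  expect_true(max(counts) - min(counts) <= 1)
  few <- pairs[pairs$kinase %in% sprintf("k%03d", 1:10), ]
  expect_error(split_plan(few, "kinasewise", n_parts = 25), "25 kinases")
})

test_that("ROC analysis matches hand computations and the rank formulation", {
  # 4 points, classes (1,1,0,0) with scores (0.9, 0.4, 0.6, 0.2)
  roc <- roc_analysis(c(6, 6, 4, 4), c(0.9, 0.4, 0.6, 0.2),
                      active_threshold = 5)
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$auc_rank, 0.75)
  perfect <- roc_analysis(c(6, 7, 4, 3), c(8, 9, 1, 2))
  expect_equal(perfect$auc, 1)
  set.seed(60)
  y <- sample(c(4, 6), 4000, replace = TRUE)
  roc_rand <- roc_analysis(y, rnorm(4000))
  expect_equal(roc_rand$auc, 0.5, tolerance = 0.05)
  expect_error(roc_analysis(c(6, 7), c(1, 2)), "both classes")
})

test_that("trapezoid AUC equals the Mann-Whitney statistic under ties", {
  set.seed(61)
  for (rep in 1:5) {
    y <- sample(c(4, 4, 4, 6), 60, replace = TRUE)
    scores <- round(rnorm(60), 1)  # heavy ties
    roc <- roc_analysis(y, scores)
    expect_equal(roc$auc, roc$auc_rank, tolerance = 1e-10)
  }
})

test_that("operating points report achievable specificity at set sensitivity", {
  roc <- roc_analysis(c(6, 6, 6, 6, 4, 4, 4, 4),
                      c(9, 8, 7, 3, 6, 2, 1, 0.5),
                      at_sensitivity = c(0.75, 1))
  # sens 0.75 reached at threshold 7 with no false positives; sens 1 needs
  # threshold 3, which picks up the score-6 inactive (specificity 3/4)
  expect_equal(roc$operating$specificity[roc$operating$sensitivity == 0.75],
               1)
  expect_equal(roc$operating$specificity[roc$operating$sensitivity == 1],
               0.75)
})

test_that("error histograms report cumulative fractions at the edges", {
  eh <- error_histogram(c(1, 2, 3), c(1.1, 2.6, 4.5))
  expect_equal(eh$cumulative$fraction, c(1 / 3, 1 / 3, 2 / 3, 1))
  expect_true(all(diff(eh$cumulative$fraction) >= 0))
  perfect <- error_histogram(1:5, 1:5)
  expect_equal(perfect$cumulative$fraction, rep(1, 4))
  expect_equal(sum(eh$bins$count), 3)
})

test_that("double CV predicts every pair exactly once with pure outer folds", {
  panel <- tiny_panel()
  kb <- describe_kinases(panel$sequences, "ctd")
  pd <- prepare_pcm_data(panel$activity, kb, panel$ligand_table)
  ctrl <- cv_control(ncomp_max = 5)
  for (mode in c("pairwise", "kinasewise")) {
    cv <- double_cv(pd, "pls", mode, n_parts = 25, seed = 9, control = ctrl)
    expect_equal(nrow(cv$predictions), nrow(panel$activity))
    expect_false(any(is.na(cv$predictions$predicted)))
    expect_true(all(tabulate(cv$predictions$part, 25) > 0))
    expect_equal(sort(unique(cv$predictions$outer_round)), 1:5)
    # outer purity audit from the emitted bookkeeping
    for (r in 1:5) {
      te <- cv$predictions[cv$predictions$outer_round == r, ]
      tr <- cv$predictions[cv$predictions$outer_round != r, ]
      if (mode == "kinasewise") {
        expect_length(intersect(te$kinase, tr$kinase), 0)
      }
      expect_equal(nrow(te) + nrow(tr), nrow(cv$predictions))
    }
    # the reported metric is reproducible from the emitted predictions
    expect_equal(cv$p2, q_squared(cv$predictions$pkd,
                                  cv$predictions$predicted))
    expect_equal(cv$auc, cv$roc$auc)
  }
})

test_that("hyperparameter search tables accompany every outer round", {
  panel <- tiny_panel()
  kb <- describe_kinases(panel$sequences, "aac_dc")
  pd <- prepare_pcm_data(panel$activity, kb, panel$ligand_table)
  cv <- double_cv(pd, "knn", "pairwise", seed = 10,
                  control = cv_control(k_grid = c(1, 3, 5),
                                       kinase_weight_grid = c(0.5, 1, 2)))
  expect_length(cv$hyperparameters, 5)
  for (h in cv$hyperparameters) {
    expect_equal(nrow(h$search), 9)
    expect_equal(max(h$search$inner_q2),
                 h$search$inner_q2[h$search$k == h$selected$k &
                                   h$search$kinase_weight ==
                                     h$selected$kinase_weight])
  }
})

test_that("the dataset-size sweep is deterministic and degenerates at 1", {
  panel <- tiny_panel()
  kb <- describe_kinases(panel$sequences, "ctd")
  pd <- prepare_pcm_data(panel$activity, kb, panel$ligand_table)
  ctrl <- cv_control(ncomp_max = 4)
  sw1 <- dataset_size_sweep(pd, "pls", "pairwise", fractions = c(0.6, 0.3),
                            n_repeats = 2, seed = 20, control = ctrl)
  sw2 <- dataset_size_sweep(pd, "pls", "pairwise", fractions = c(0.6, 0.3),
                            n_repeats = 2, seed = 20, control = ctrl)
  expect_equal(sw1$results, sw2$results)
  expect_equal(nrow(sw1$results), 4)
  expect_equal(nrow(sw1$summary), 2)
  full <- dataset_size_sweep(pd, "pls", "pairwise", fractions = 1,
                             n_repeats = 3, seed = 20, control = ctrl)
  ref <- double_cv(pd, "pls", "pairwise", seed = 20, control = ctrl)
  expect_equal(full$results$p2, ref$p2)
})

test_that("tidiers expose predictions and summary statistics", {
  panel <- tiny_panel()
  kb <- describe_kinases(panel$sequences, "ctd")
  pd <- prepare_pcm_data(panel$activity, kb, panel$ligand_table)
  cv <- double_cv(pd, "pls", "pairwise", seed = 2,
                  control = cv_control(ncomp_max = 4))
  expect_s3_class(tidy(cv), "tbl_df")
  g <- glance(cv)
  expect_equal(g$p2, cv$p2)
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(cv$roc), "ggplot")
  eh <- error_histogram(cv$predictions$pkd, cv$predictions$predicted)
  expect_s3_class(autoplot(eh), "ggplot")
})
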