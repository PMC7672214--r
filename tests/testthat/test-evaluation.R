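test_that("indicator matrices one-hot encode in sorted label order", {
  pair <- confusion_to_indicators(c("a", "b"), c("a", "b"))
  expect_equal(unname(pair$X), rbind(c(1, 0), c(0, 1)))
  expect_equal(pair$X, pair$Y)
  expect_error(confusion_to_indicators("a", "z", labels = c("a", "b")),
               "outside the declared label set")
  # random vectors: rows sum to 1, column sums tally class counts
  withr::with_seed(31, {
    truth <- sample(letters[1:4], 50, replace = TRUE)
    pred <- sample(letters[1:4], 50, replace = TRUE)
  })
  pr <- confusion_to_indicators(truth, pred)
  expect_true(all(rowSums(pr$X) == 1) && all(rowSums(pr$Y) == 1))
  expect_equal(colSums(pr$Y), table(factor(truth, levels = letters[1:4]))[pr$labels],
               ignore_attr = TRUE)
})

test_that("multiclass MCC hits its exact landmark values", {
  withr::with_seed(7, truth <- sample(letters[1:3], 30, replace = TRUE))
  expect_equal(multiclass_mcc(truth, truth), 1)
  flip <- c(a = "b", b = "a")
  t2 <- rep(c("a", "b"), c(12, 8))
  expect_equal(multiclass_mcc(t2, unname(flip[t2])), -1)
  # constant prediction: degenerate denominator -> 0 by convention
  expect_equal(multiclass_mcc(t2, rep("a", 20)), 0)
})

test_that("for two classes the covariance form equals the classical binary MCC", {
  withr::with_seed(11, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      truth <- sample(c("neg", "pos"), n, replace = TRUE)
      pred <- sample(c("neg", "pos"), n, replace = TRUE)
      expect_equal(multiclass_mcc(truth, pred, labels = c("neg", "pos")),
                   oracle_binary_mcc(truth, pred, "pos"),
                   tolerance = 1e-10)
    }
  })
})

test_that("MCC stays within [-1, 1] on random prediction pairs", {
  withr::with_seed(13, {
    for (i in 1:200) {
      K <- sample(2:6, 1)
      n <- sample(5:40, 1)
      truth <- sample(letters[1:K], n, replace = TRUE)
      pred <- sample(letters[1:K], n, replace = TRUE)
      v <- multiclass_mcc(truth, pred, labels = letters[1:K])
      expect_gte(v, -1)
      expect_lte(v, 1)
    }
  })
})

test_that("accuracy metrics follow the hand tally and the weighted-recall identity", {
  am <- accuracy_metrics(c("a", "a", "b", "b"), c("a", "b", "b", "b"))
  expect_equal(am$acc, 0.75)
  expect_equal(am$per_class$accuracy, c(0.5, 1.0))
  # permutation invariance
  am2 <- accuracy_metrics(c("b", "a", "b", "a"), c("b", "a", "b", "b"))
  expect_equal(am2$acc, am$acc)
  expect_equal(am2$per_class, am$per_class)
  # acc == class-size-weighted mean of recalls, exactly
  withr::with_seed(3, {
    truth <- sample(letters[1:5], 80, replace = TRUE)
    pred <- sample(letters[1:5], 80, replace = TRUE)
  })
  am3 <- accuracy_metrics(truth, pred)
  expect_identical(am3$acc,
                   sum(am3$per_class$n * am3$per_class$accuracy) / sum(am3$per_class$n))
})

test_that("evaluate_subset is deterministic and leak-free, and aces separable data", {
  out <- generate_table(synthetic_spec(n_classes = 3, class_sizes = c(10, 14, 20),
                                       n_informative = 5, n_redundant = 0,
                                       n_noise = 5, effect_size = 5,
                                       within_class_sd = 0.2, zero_inflation = 0,
                                       seed = 21))
  inf <- out$truth$taxon_id[out$truth$role == "informative"]
  rec <- evaluate_subset(out$table, inf, learner("knn"), seed = 2)
  expect_equal(rec$mcc, 1)
  expect_equal(rec$acc, 1)
  # identical call -> identical record and predictions
  rec2 <- evaluate_subset(out$table, inf, learner("knn"), seed = 2)
  expect_identical(rec2, rec)
  # default scope: pooled test predictions come from original samples only
  preds <- attr(rec, "predictions")
  expect_equal(nrow(preds), nrow(out$table))
  expect_false(any(grepl("^smote_", preds$sample_id)))
  expect_error(evaluate_subset(out$table, "nope", learner("knn")), "unknown taxa")
})

test_that("label-permuted data scores at chance level", {
  out <- generate_table(synthetic_spec(n_classes = 3, class_sizes = rep(20, 3),
                                       n_informative = 5, n_redundant = 0,
                                       n_noise = 5, seed = 33))
  mccs <- vapply(1:20, function(s) {
    tbl <- out$table
    tbl$label <- withr::with_seed(s, sample(tbl$label))
    evaluate_subset(tbl, taxon_ids(tbl)[1:5], learner("knn"), n_folds = 5,
                    seed = s)$mcc
  }, 0)
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("IFS records nested prefixes and picks the smallest max-MCC subset", {
  tbl <- random_table(41, n = 50, m = 8, K = 3)
  rk <- mrmr_rank(tbl)
  res <- run_ifs(tbl, rk, learner("knn"), step = 2, max_size = 8, n_folds = 5,
                 seed = 5)
  expect_equal(res$records$subset_size, c(2, 4, 6, 8))
  best <- max(res$records$mcc)
  expect_equal(res$optimum_size,
               min(res$records$subset_size[res$records$mcc == best]))
  expect_equal(res$optimum_features, rk$taxon_id[seq_len(res$optimum_size)])
  # ranking of length 1 -> exactly one record
  one <- run_ifs(tbl, rk$taxon_id[1], learner("knn"), n_folds = 5, seed = 5)
  expect_equal(nrow(one$records), 1)
  # determinism of the full sweep
  expect_identical(run_ifs(tbl, rk, learner("knn"), step = 2, max_size = 8,
                           n_folds = 5, seed = 5)$records, res$records)
})

test_that("the global optimum is the exhaustive maximum over learners", {
  tbl <- random_table(51, n = 60, m = 6, K = 3)
  rk <- mrmr_rank(tbl)
  res <- list(
    knn = run_ifs(tbl, rk, learner("knn"), step = 3, max_size = 6, n_folds = 5, seed = 2),
    dt = run_ifs(tbl, rk, learner("dt"), step = 3, max_size = 6, n_folds = 5, seed = 2)
  )
  glob <- select_global_optimum(res)
  all_mccs <- unlist(lapply(res, function(r) r$records$mcc))
  expect_equal(max(glob$result$records$mcc), max(all_mccs))
  # single learner returns itself
  expect_equal(select_global_optimum(res["knn"])$learner, "knn")
  expect_error(select_global_optimum(list()), "no IFS results")
})
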