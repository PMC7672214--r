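test_that("kNN honours its exact-match and majority limits", {
  tbl <- random_table(5, n = 15, m = 3, K = 3)
  # k = 1 on a training point returns that point's label
  expect_equal(knn_fit_predict(tbl, tbl[4, ], k = 1), tbl$label[4])
  # k = n returns the global majority whatever the test point
  maj <- names(which.max(table(factor(tbl$label, levels = label_set(tbl)))))
  far <- abundance_table(matrix(999, 1, 3), labels = "a",
                         taxon_ids = taxon_ids(tbl))
  expect_equal(knn_fit_predict(tbl, far, k = nrow(tbl)), maj)
})

test_that("kNN agrees with the brute-force distance oracle", {
  for (s in 1:5) {
    train <- random_table(s, n = 40, m = 4, K = 3)
    test <- random_table(100 + s, n = 15, m = 4, K = 3)
    got <- knn_fit_predict(train, test, k = 5)
    want <- oracle_knn(abundance_matrix(train), train$label,
                       abundance_matrix(test), k = 5)
    expect_equal(got, unname(want))
  }
})

test_that("CART handles pure input, the 1-D textbook split, and full growth", {
  # pure single-class input -> a single leaf of that class
  pure <- abundance_table(matrix(rexp(8), 4, 2), labels = rep("only", 4))
  tp <- cart_fit(pure)
  expect_equal(nrow(tp$nodes), 1)
  expect_equal(tp$nodes$class, "only")
  # values (1,2,8,9), labels (A,A,B,B): of the midpoints 1.5, 5, 8.5 only 5
  # splits both classes cleanly -> depth-1 tree with threshold 5
  tbl <- abundance_table(matrix(c(1, 2, 8, 9), 4, 1),
                         labels = c("A", "A", "B", "B"), taxon_ids = "x")
  tr <- cart_fit(tbl)
  expect_equal(nrow(tr$nodes), 3)
  expect_equal(tr$nodes$threshold[1], 5)
  expect_equal(predict(tr, tbl), c("A", "A", "B", "B"))
  # fully-grown tree memorizes distinct training data
  big <- random_table(7, n = 60, m = 5, K = 4)
  expect_equal(predict(cart_fit(big), big), big$label)
})

test_that("CART matches the exhaustive split-search oracle on small instances", {
  for (s in 1:8) {
    tbl <- random_table(s, n = 30, m = 5, K = 3)
    tree <- cart_fit(tbl)
    probe <- random_table(200 + s, n = 20, m = 5, K = 3)
    want <- oracle_cart_predict(abundance_matrix(tbl), tbl$label,
                                abundance_matrix(probe))
    expect_equal(predict(tree, probe), unname(want), info = paste("seed", s))
  }
})

test_that("CART thresholds sit strictly inside the split feature's range", {
  tbl <- random_table(12, n = 50, m = 4, K = 3)
  tree <- cart_fit(tbl)
  m <- abundance_matrix(tbl)
  internal <- tree$nodes[!tree$nodes$is_leaf, ]
  for (i in seq_len(nrow(internal))) {
    v <- m[, internal$taxon_id[i]]
    expect_gt(internal$threshold[i], min(v))
    expect_lt(internal$threshold[i], max(v))
  }
})

test_that("the forest reduces to a single CART and is seed-deterministic", {
  tbl <- random_table(3, n = 40, m = 4, K = 3)
  test <- random_table(303, n = 15, m = 4, K = 3)
  # one tree, no bootstrap, full feature pool == plain CART
  expect_equal(
    rf_fit_predict(tbl, test, n_trees = 1, bootstrap = FALSE, mtry = 4, seed = 1),
    predict(cart_fit(tbl), test)
  )
  p1 <- rf_fit_predict(tbl, test, n_trees = 20, seed = 42)
  p2 <- rf_fit_predict(tbl, test, n_trees = 20, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1 %in% label_set(tbl)))
})

test_that("bagging does not fall behind a single tree on separable data", {
  # linearly separable 2-class problem, 20 seeds
  worse <- 0
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- 60
      lab <- rep(c("a", "b"), each = n / 2)
      shift <- ifelse(lab == "a", 0, 4)
      X <- matrix(runif(n * 3), n, 3) + shift
      tr_idx <- sample(n, 40)
    })
    train <- abundance_table(X[tr_idx, ], labels = lab[tr_idx])
    test <- abundance_table(X[-tr_idx, ], labels = lab[-tr_idx])
    acc_rf <- mean(rf_fit_predict(train, test, n_trees = 25, seed = s) == test$label)
    acc_dt <- mean(predict(cart_fit(train), test) == test$label)
    if (acc_rf < acc_dt - 0.05) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("learners only ever predict labels seen in training", {
  tbl <- random_table(21, n = 30, m = 4, K = 3)
  test <- random_table(22, n = 10, m = 4, K = 3)
  for (nm in c("knn", "dt", "rf")) {
    lrn <- learner(nm)
    expect_true(all(lrn$fit_predict(tbl, test, seed = 1) %in% label_set(tbl)))
  }
})
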