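test_that("identical spec and seed reproduce the table bit-for-bit", {
  spec <- synthetic_spec(n_classes = 3, class_sizes = c(5, 8, 12),
                         n_informative = 4, n_redundant = 2, n_noise = 10,
                         seed = 7)
  a <- generate_table(spec)
  b <- generate_table(spec)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  # a different seed changes the draw
  spec2 <- synthetic_spec(n_classes = 3, class_sizes = c(5, 8, 12),
                          n_informative = 4, n_redundant = 2, n_noise = 10,
                          seed = 8)
  expect_false(identical(generate_table(spec2)$table, a$table))
})

test_that("spec invariant violations name the offending field", {
  expect_error(synthetic_spec(n_classes = 1), "n_classes")
  expect_error(synthetic_spec(class_sizes = c(1, 5, 5, 5, 5, 5, 5, 5)), "class_sizes")
  expect_error(synthetic_spec(zero_inflation = 1), "zero_inflation")
  expect_error(synthetic_spec(redundancy_corr = 1.2), "redundancy_corr")
  expect_error(synthetic_spec(n_informative = -1), "n_informative")
  expect_error(synthetic_spec(n_informative = 0, n_redundant = 3), "n_redundant")
})

test_that("taxon roles are disjoint and cover all taxa", {
  out <- generate_table(synthetic_spec(n_classes = 3, class_sizes = c(4, 6, 8),
                                       n_informative = 3, n_redundant = 5,
                                       n_noise = 7, seed = 2))
  expect_setequal(out$truth$taxon_id, taxon_ids(out$table))
  expect_identical(anyDuplicated(out$truth$taxon_id), 0L)
  expect_equal(unname(table(out$truth$role)[c("informative", "redundant", "noise")]),
               c(3L, 5L, 7L), ignore_attr = TRUE)
  # every redundant taxon points to an informative parent
  red <- out$truth[out$truth$role == "redundant", ]
  inf <- out$truth$taxon_id[out$truth$role == "informative"]
  expect_true(all(red$parent_id %in% inf))
  # every class appears in at least one signature
  sigs <- unlist(strsplit(out$truth$signature_classes[out$truth$role == "informative"], ","))
  expect_setequal(unique(sigs), sprintf("class%02d", 1:3))
})

test_that("geometric class-size interpolation hits the named imbalance profiles", {
  sp <- synthetic_spec(n_classes = 4, n_min = 5, imbalance_ratio = 33,
                       n_informative = 1, n_redundant = 0, n_noise = 0)
  expect_equal(max(sp$class_sizes) / min(sp$class_sizes), 33)
  expect_equal(sp$class_sizes, c(5, 16, 51, 165))
  sp_k <- synthetic_spec(imbalance_ratio = "kraken")
  expect_equal(max(sp_k$class_sizes) / min(sp_k$class_sizes), 33)
  sp_s <- synthetic_spec(imbalance_ratio = "shogun")
  expect_equal(max(sp_s$class_sizes) / min(sp_s$class_sizes), 64.5, tolerance = 0.01)
})

test_that("null-signal tables carry no class information", {
  # delta = 0, no redundancy, no zeros: every taxon's relevance is ~ the
  # plug-in MI estimation bias, far below any real signal
  spec <- synthetic_spec(n_classes = 4, class_sizes = rep(100, 4),
                         n_informative = 20, n_redundant = 0, n_noise = 0,
                         effect_size = 0, zero_inflation = 0, seed = 11)
  out <- generate_table(spec)
  rk <- mrmr_rank(out$table)
  expect_lt(max(rk$relevance), 0.06)
  expect_lt(mean(rk$relevance), 0.03)
})

test_that("abundances are non-negative and the zero fraction matches zero_inflation", {
  zi <- 0.25
  spec <- synthetic_spec(n_classes = 3, class_sizes = rep(60, 3),
                         n_informative = 5, n_redundant = 0, n_noise = 25,
                         effect_size = 0, zero_inflation = zi, seed = 5)
  m <- abundance_matrix(generate_table(spec)$table)
  expect_true(all(m >= 0))
  n_cells <- length(m)
  sd3 <- 3 * sqrt(zi * (1 - zi) / n_cells)
  expect_lt(abs(mean(m == 0) - zi), sd3)
})

test_that("redundant taxa track their parents at the target log-scale correlation", {
  spec <- synthetic_spec(n_classes = 2, class_sizes = c(300, 300),
                         n_informative = 2, n_redundant = 4, n_noise = 0,
                         effect_size = 0, zero_inflation = 0,
                         redundancy_corr = 0.9, seed = 3)
  out <- generate_table(spec)
  m <- log(abundance_matrix(out$table))
  red <- out$truth[out$truth$role == "redundant", ]
  cors <- mapply(function(r, p) cor(m[, r], m[, p]), red$taxon_id, red$parent_id)
  expect_true(all(abs(cors - 0.9) < 0.05))
})

test_that("planted informative taxa have detectably higher MI than noise taxa", {
  # strong-signal case: in every seed, each informative taxon's MI with the
  # label exceeds the 95th percentile of the noise-taxon MIs
  for (s in 1:20) {
    spec <- synthetic_spec(n_classes = 8, class_sizes = rep(50, 8),
                           n_informative = 10, n_redundant = 0, n_noise = 90,
                           effect_size = 3, seed = s)
    out <- generate_table(spec)
    disc <- discretize(out$table)
    mi <- vapply(seq_len(ncol(disc$states)),
                 function(j) mutual_information(disc$states[, j], disc$labels), 0)
    role <- out$truth$role[match(colnames(disc$states), out$truth$taxon_id)]
    expect_gt(min(mi[role == "informative"]),
              quantile(mi[role == "noise"], 0.95))
  }
})

test_that("at study-condition effect sizes informative taxa beat noise taxa on average", {
  for (s in 1:10) {
    spec <- synthetic_spec(n_classes = 4, class_sizes = rep(30, 4),
                           n_informative = 8, n_redundant = 0, n_noise = 60,
                           effect_size = 1.5, seed = 100 + s)
    out <- generate_table(spec)
    disc <- discretize(out$table)
    mi <- vapply(seq_len(ncol(disc$states)),
                 function(j) mutual_information(disc$states[, j], disc$labels), 0)
    role <- out$truth$role[match(colnames(disc$states), out$truth$taxon_id)]
    expect_gt(mean(mi[role == "informative"]), mean(mi[role == "noise"]))
  }
})
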