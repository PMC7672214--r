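#' Fit a CART decision tree
#'
#' Grows a binary classification tree by exhaustive Gini split search:
#' at each node every (feature, midpoint-threshold) candidate is scored by
#' the weighted Gini impurity of the two children, and the best strictly
#' impurity-reducing split is taken. Growing stops at pure nodes, nodes
#' smaller than `min_samples_split`, depth `max_depth`, or when no split
#' reduces impurity. No pruning is applied; interpretability is controlled
#' through the two stopping parameters instead. Ties between equally good
#' splits go to the lower feature index, then the lower threshold, so the
#' fit is fully deterministic.
#'
#' @param table an abundance table tibble (labels in the `label` column).
#' @param taxa optional subset of taxon columns to train on.
#' @param min_samples_split smallest node size still considered for
#'   splitting; default 2 (fully grown).
#' @param max_depth maximum tree depth (`Inf` for unlimited).
#' @return A `cart_tree`: a list with a `nodes` tibble (`node_id`, `depth`,
#'   `is_leaf`, `taxon_id`, `threshold`, `left`, `right`, `class`, `n`), the
#'   per-node class-count matrix `counts`, the sorted class levels and the
#'   taxon columns used.
#' @export
cart_fit <- function(table, taxa = NULL, min_samples_split = 2, max_depth = Inf) {
  validate_abundance_table(table)
  taxa <- taxa %||% taxon_ids(table)
  X <- abundance_matrix(table, taxa)
  lev <- label_set(table)
  y <- match(table$label, lev) - 1L
  md <- if (is.infinite(max_depth)) -1L else as.integer(max_depth)
  raw <- cart_grow_cpp(X, y, length(lev), as.integer(min_samples_split), md, 0L)
  new_cart_tree(raw, lev, taxa)
}

new_cart_tree <- function(raw, classes, taxa) {
  is_leaf <- raw$feature < 0
  feat_idx <- raw$feature + 1L
  feat_idx[is_leaf] <- NA_integer_
  nodes <- tibble::tibble(
    node_id = seq_along(raw$feature),
    depth = raw$depth,
    is_leaf = is_leaf,
    taxon_id = taxa[feat_idx],
    threshold = ifelse(is_leaf, NA_real_, raw$threshold),
    left = ifelse(is_leaf, NA_integer_, raw$left + 1L),
    right = ifelse(is_leaf, NA_integer_, raw$right + 1L),
    class = classes[raw$pred + 1L],
    n = raw$n
  )
  counts <- raw$counts
  colnames(counts) <- classes
  structure(list(nodes = nodes, counts = counts, classes = classes, taxa = taxa),
            class = "cart_tree")
}

#' @export
print.cart_tree <- function(x, ...) {
  cat("CART tree:", nrow(x$nodes), "nodes,", sum(x$nodes$is_leaf), "leaves,",
      length(x$classes), "classes\n")
  invisible(x)
}

#' Predict class labels from a fitted CART tree
#'
#' @param object a `cart_tree` from [cart_fit()].
#' @param newdata an abundance table tibble (or numeric matrix) containing
#'   every taxon the tree splits on.
#' @param ... unused.
#' @return Character vector of predicted labels, one per row of `newdata`.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) {
    newdata[, object$taxa, drop = FALSE]
  } else {
    abundance_matrix(newdata, object$taxa)
  }
  nd <- object$nodes
  feat0 <- ifelse(nd$is_leaf, -1L, match(nd$taxon_id, object$taxa) - 1L)
  thr <- ifelse(nd$is_leaf, 0, nd$threshold)
  idx <- cart_predict_cpp(as.integer(feat0), as.numeric(thr),
                          as.integer(ifelse(nd$is_leaf, 0L, nd$left - 1L)),
                          as.integer(ifelse(nd$is_leaf, 0L, nd$right - 1L)),
                          as.integer(match(nd$class, object$classes) - 1L),
                          X)
  object$classes[idx]
}

#' k-nearest-neighbor classification
#'
#' Predicts each test sample as the majority label among its `k` nearest
#' training samples by Euclidean distance. All tie-breaks are pinned:
#' equal distances are resolved by the lower training-row index, vote ties
#' by the smaller mean distance of the tied label's neighbors, remaining
#' ties by the lower (sorted) label index.
#'
#' @param train an abundance table tibble with labels.
#' @param test an abundance table tibble (label column not required)
#'   containing the training taxa.
#' @param k neighborhood size, `1 <= k <= nrow(train)`; default 1.
#' @return Character vector of predicted labels for the rows of `test`.
#' @export
knn_fit_predict <- function(train, test, k = 1) {
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  stopifnot(k >= 1, k <= nrow(train))
  taxa <- taxon_ids(train)
  Xtr <- abundance_matrix(train, taxa)
  Xte <- if (is.matrix(test)) test[, taxa, drop = FALSE] else abundance_matrix(test, taxa)
  lev <- label_set(train)
  ytr <- match(train$label, lev)

  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * tcrossprod(Xte, Xtr)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)

  out <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    ord <- order(d[i, ], seq_len(ncol(d)))  # distance ties -> lower train index
    top <- ord[seq_len(k)]
    votes <- tabulate(ytr[top], nbins = length(lev))
    cand <- which(votes == max(votes))
    if (length(cand) > 1) {
      mean_d <- vapply(cand, function(cl) mean(d[i, top[ytr[top] == cl]]), 0)
      cand <- cand[order(mean_d, cand)]  # then lower label index
    }
    out[i] <- lev[cand[1]]
  }
  out
}

#' Bagged random-forest classification
#'
#' Grows `n_trees` CART trees, each on a bootstrap resample of the training
#' rows with the candidate-feature pool at every split restricted to `mtry`
#' features (default `floor(sqrt(m))`), and predicts by majority vote across
#' trees (vote ties go to the lowest sorted label index). Given a seed the
#' whole ensemble is reproducible.
#'
#' @inheritParams knn_fit_predict
#' @param n_trees number of trees; default 100.
#' @param mtry per-split candidate-feature count; default `floor(sqrt(m))`.
#' @param bootstrap draw bootstrap resamples (default `TRUE`); with
#'   `bootstrap = FALSE` every tree sees the full training set.
#' @param min_samples_split,max_depth passed to each tree (see [cart_fit()]).
#' @param seed RNG seed for resampling and feature subsampling.
#' @return Character vector of predicted labels for the rows of `test`.
#' @export
rf_fit_predict <- function(train, test, n_trees = 100, mtry = NULL,
                           bootstrap = TRUE, min_samples_split = 2,
                           max_depth = Inf, seed = 1L) {
  if (nrow(train) == 0) stop("empty training set", call. = FALSE)
  stopifnot(n_trees >= 1)
  withr::local_seed(seed)
  taxa <- taxon_ids(train)
  Xtr <- abundance_matrix(train, taxa)
  Xte <- if (is.matrix(test)) test[, taxa, drop = FALSE] else abundance_matrix(test, taxa)
  lev <- label_set(train)
  y <- match(train$label, lev) - 1L
  m <- ncol(Xtr)
  mtry <- as.integer(mtry %||% max(1, floor(sqrt(m))))
  md <- if (is.infinite(max_depth)) -1L else as.integer(max_depth)

  votes <- matrix(0L, nrow(Xte), length(lev))
  for (b in seq_len(n_trees)) {
    idx <- if (bootstrap) sample.int(nrow(Xtr), replace = TRUE) else seq_len(nrow(Xtr))
    raw <- cart_grow_cpp(Xtr[idx, , drop = FALSE], y[idx], length(lev),
                         as.integer(min_samples_split), md, mtry)
    tree <- new_cart_tree(raw, lev, taxa)
    p <- predict(tree, Xte)
    votes[cbind(seq_len(nrow(Xte)), match(p, lev))] <-
      votes[cbind(seq_len(nrow(Xte)), match(p, lev))] + 1L
  }
  lev[apply(votes, 1, which.max)]  # first max -> lowest label index
}

#' Construct a classifier for the IFS workflow
#'
#' Wraps the built-in classifiers (and an optional support-vector-machine
#' adapter over the \pkg{e1071} package, if installed) behind one contract:
#' a named object whose `fit_predict(train, test, seed)` trains on `train`
#' and returns predicted labels for `test`. All built-ins are pure functions
#' of (data, hyperparameters, seed).
#'
#' @param name one of `"knn"`, `"dt"`, `"rf"`, `"svm"`.
#' @param ... hyperparameter overrides: `k` (knn, default 1);
#'   `min_samples_split`, `max_depth` (dt); `n_trees`, `mtry` (rf);
#'   any [e1071::svm()] argument (svm).
#' @return A `taxa_learner` object.
#' @examples
#' learner("knn", k = 3)
#' @export
learner <- function(name = c("knn", "dt", "rf", "svm"), ...) {
  name <- match.arg(name)
  params <- list(...)
  fp <- switch(
    name,
    knn = function(train, test, seed = 1L) {
      knn_fit_predict(train, test, k = params$k %||% 1)
    },
    dt = function(train, test, seed = 1L) {
      tree <- cart_fit(train,
                       min_samples_split = params$min_samples_split %||% 2,
                       max_depth = params$max_depth %||% Inf)
      predict(tree, test)
    },
    rf = function(train, test, seed = 1L) {
      rf_fit_predict(train, test,
                     n_trees = params$n_trees %||% 100,
                     mtry = params$mtry,
                     seed = seed)
    },
    svm = function(train, test, seed = 1L) {
      if (!requireNamespace("e1071", quietly = TRUE)) {
        stop("the 'svm' learner needs the e1071 package", call. = FALSE)
      }
      taxa <- taxon_ids(train)
      fit <- do.call(e1071::svm, c(
        list(x = abundance_matrix(train, taxa),
             y = factor(train$label, levels = label_set(train))),
        params
      ))
      as.character(predict(fit, abundance_matrix(test, taxa)))
    }
  )
  structure(list(name = name, params = params, fit_predict = fp),
            class = "taxa_learner")
}

as_learner <- function(x) {
  if (inherits(x, "taxa_learner")) x else learner(x)
}

#' @export
print.taxa_learner <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste0(" (", paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "), ")")
  } else ""
  cat("<taxa_learner: ", x$name, ps, ">\n", sep = "")
  invisible(x)
}
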