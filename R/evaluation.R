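#' One-hot indicator matrices for truth and prediction
#'
#' Builds the pair of n x K binary matrices underlying the multiclass
#' Matthews correlation coefficient: `Y` one-hot encodes the true classes and
#' `X` the predicted classes, with columns in sorted label-set order.
#'
#' @param truth,prediction label vectors of equal length.
#' @param labels the label set; defaults to the sorted union of the observed
#'   labels. A label outside this set is an error.
#' @return A list with matrices `X` (predicted) and `Y` (true) and the
#'   `labels` used for the columns. Every row of each matrix sums to 1.
#' @export
confusion_to_indicators <- function(truth, prediction, labels = NULL) {
  truth <- as.character(truth)
  prediction <- as.character(prediction)
  if (length(truth) != length(prediction)) {
    stop("truth and prediction must have equal length", call. = FALSE)
  }
  labels <- labels %||% sort(unique(c(truth, prediction)))
  bad <- setdiff(unique(c(truth, prediction)), labels)
  if (length(bad) > 0) {
    stop("label outside the declared label set: ", bad[1], call. = FALSE)
  }
  n <- length(truth)
  K <- length(labels)
  one_hot <- function(v) {
    m <- matrix(0, n, K, dimnames = list(NULL, labels))
    m[cbind(seq_len(n), match(v, labels))] <- 1
    m
  }
  list(X = one_hot(prediction), Y = one_hot(truth), labels = labels)
}

#' Multiclass Matthews correlation coefficient
#'
#' The correlation between the one-hot predicted and true class-indicator
#' matrices, `cov(X, Y) / sqrt(cov(X, X) * cov(Y, Y))` with
#' `cov(A, B) = sum_k sum_i (A_ik - mean_k A)(B_ik - mean_k B)`. It is +1 for
#' perfect prediction, near 0 for chance-level prediction, and -1 for total
#' disagreement in the binary case; for K = 2 it reduces exactly to the
#' classical binary MCC. When either self-covariance is zero (constant
#' predictions or constant truth) the value is 0 by convention.
#'
#' @inheritParams confusion_to_indicators
#' @return A number in `[-1, 1]`.
#' @examples
#' multiclass_mcc(c("a", "b", "c"), c("a", "b", "c"))   # +1
#' multiclass_mcc(c("a", "a", "b", "b"), c("b", "b", "a", "a"))  # -1
#' @export
multiclass_mcc <- function(truth, prediction, labels = NULL) {
  pair <- confusion_to_indicators(truth, prediction, labels)
  mcc_from_indicators(pair$X, pair$Y)
}

mcc_from_indicators <- function(X, Y) {
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  cxy <- sum(Xc * Yc)
  cxx <- sum(Xc * Xc)
  cyy <- sum(Yc * Yc)
  if (cxx == 0 || cyy == 0) {
    return(0)
  }
  cxy / sqrt(cxx * cyy)
}

#' Overall and per-class accuracy
#'
#' @inheritParams confusion_to_indicators
#' @return A list with `acc` (fraction of correct predictions) and
#'   `per_class`, a tibble (`label`, `n`, `accuracy`) where accuracy is the
#'   class's recall: correct within class / class size. `acc` always equals
#'   the class-size-weighted mean of the per-class accuracies.
#' @export
accuracy_metrics <- function(truth, prediction) {
  truth <- as.character(truth)
  prediction <- as.character(prediction)
  if (length(truth) != length(prediction)) {
    stop("truth and prediction must have equal length", call. = FALSE)
  }
  per_class <- tibble::tibble(label = truth, hit = truth == prediction) |>
    dplyr::summarise(n = dplyr::n(), accuracy = mean(.data$hit), .by = "label") |>
    dplyr::arrange(.data$label)
  list(acc = mean(truth == prediction), per_class = per_class)
}

derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 131 + salt) %% 2147483647)
}

#' Cross-validated evaluation of one feature subset
#'
#' Scores a feature subset by stratified k-fold cross-validation: for every
#' fold the taxon columns are restricted to the subset, the training
#' partition is SMOTE-balanced (default scope `"fold"` — test folds are
#' never touched by oversampling, so no synthetic information leaks into the
#' score), the learner is fitted and the held-out fold predicted. The
#' out-of-fold predictions are pooled over all folds before computing the
#' metric triple, which keeps the estimate stable for very small classes.
#'
#' @param table an abundance table tibble.
#' @param features non-empty character vector of taxon columns to use.
#' @param learner a [learner()] object or its name.
#' @param n_folds number of folds; default 10.
#' @param folds optional precomputed fold vector (see [assign_folds()]);
#'   supplying it keeps fold assignment identical across subset sizes.
#' @param smote_scope `"fold"` (balance each training partition, default),
#'   `"global"` (balance the whole table once, before fold assignment —
#'   provided to emulate balancing outside cross-validation, at the price of
#'   synthetic-sample leakage into test folds), or `"none"`.
#' @param smote_k SMOTE neighborhood size.
#' @param seed master seed; all fold, SMOTE and learner seeds derive from it.
#' @return A one-row tibble: `subset_size`, `learner`, `seed`, `acc`, `mcc`,
#'   then one `acc_<label>` recall column per class. The pooled per-sample
#'   predictions are attached as attribute `"predictions"`.
#' @export
evaluate_subset <- function(table, features, learner, n_folds = 10,
                            folds = NULL,
                            smote_scope = c("fold", "global", "none"),
                            smote_k = 5, seed = 1L) {
  smote_scope <- match.arg(smote_scope)
  learner <- as_learner(learner)
  if (length(features) == 0) stop("empty feature subset", call. = FALSE)
  missing <- setdiff(features, taxon_ids(table))
  if (length(missing) > 0) {
    stop("subset references unknown taxa: ", missing[1], call. = FALSE)
  }
  sub <- table[, c("sample_id", "label", features)]
  if (smote_scope == "global") {
    sub <- smote_balance(sub, k_neighbors = smote_k, seed = derive_seed(seed, 1))
    folds <- NULL
  }
  folds <- folds %||% assign_folds(sub$label, n_folds = n_folds,
                                   seed = derive_seed(seed, 2))
  stopifnot(length(folds) == nrow(sub))

  prediction <- character(nrow(sub))
  for (f in sort(unique(folds))) {
    train <- sub[folds != f, , drop = FALSE]
    test <- sub[folds == f, , drop = FALSE]
    if (smote_scope == "fold") {
      train <- smote_balance(train, k_neighbors = smote_k,
                             seed = derive_seed(seed, 100 + f))
    }
    prediction[folds == f] <- learner$fit_predict(train, test,
                                                  seed = derive_seed(seed, 200 + f))
  }

  am <- accuracy_metrics(sub$label, prediction)
  mcc <- multiclass_mcc(sub$label, prediction, labels = label_set(sub))
  wide <- stats::setNames(as.list(am$per_class$accuracy),
                          paste0("acc_", am$per_class$label))
  rec <- dplyr::bind_cols(
    tibble::tibble(subset_size = length(features), learner = learner$name,
                   seed = as.integer(seed), acc = am$acc, mcc = mcc),
    tibble::as_tibble(wide)
  )
  attr(rec, "predictions") <- tibble::tibble(sample_id = sub$sample_id,
                                             truth = sub$label,
                                             prediction = prediction,
                                             fold = folds)
  rec
}

#' Incremental feature selection over a ranked feature list
#'
#' Evaluates nested prefixes of the ranking — the top `step` features, the
#' top `2 * step`, and so on up to `max_size` — with [evaluate_subset()],
#' records the metric triple for every prefix, and selects the optimum
#' subset: the prefix with the highest multiclass MCC, smallest size on
#' ties. With `step = 1` the prefix sequence grows one feature at a time;
#' larger steps are a scaled-down sweep, flagged in the result.
#'
#' @inheritParams evaluate_subset
#' @param ranking an `mrmr_ranking` tibble (see [mrmr_rank()]) or a
#'   character vector of taxon ids in rank order.
#' @param step prefix-size increment (>= 1).
#' @param max_size largest prefix size; default the full ranking.
#' @return An `ifs_result`: list with `records` (one row per prefix, the IFS
#'   curve data), `optimum_size`, `optimum_features`, `learner`, `step`,
#'   `smote_scope`, `n_folds`, `seed`. [generics::tidy()] returns the
#'   records; [generics::glance()] the one-row optimum summary;
#'   [ggplot2::autoplot()] draws the IFS curve.
#' @export
run_ifs <- function(table, ranking, learner, step = 1, max_size = NULL,
                    n_folds = 10, smote_scope = c("fold", "global", "none"),
                    smote_k = 5, seed = 1L) {
  smote_scope <- match.arg(smote_scope)
  learner <- as_learner(learner)
  ordered_ids <- if (is.data.frame(ranking)) ranking$taxon_id else as.character(ranking)
  max_size <- max_size %||% length(ordered_ids)
  if (step < 1 || max_size < 1 || max_size > length(ordered_ids)) {
    stop("invalid step/max_size", call. = FALSE)
  }
  sizes <- seq(step, max_size, by = step)

  work <- table
  if (smote_scope == "global") {
    work <- smote_balance(work, k_neighbors = smote_k, seed = derive_seed(seed, 1))
  }
  folds <- assign_folds(work$label, n_folds = n_folds, seed = derive_seed(seed, 2))
  inner_scope <- if (smote_scope == "fold") "fold" else "none"

  records <- purrr::map_dfr(sizes, function(sz) {
    evaluate_subset(work, ordered_ids[seq_len(sz)], learner,
                    n_folds = n_folds, folds = folds,
                    smote_scope = inner_scope, smote_k = smote_k, seed = seed)
  })

  best_mcc <- max(records$mcc)
  optimum_size <- min(records$subset_size[records$mcc == best_mcc])
  structure(
    list(
      records = records,
      optimum_size = optimum_size,
      optimum_features = ordered_ids[seq_len(optimum_size)],
      learner = learner$name,
      step = step,
      smote_scope = smote_scope,
      n_folds = n_folds,
      seed = as.integer(seed)
    ),
    class = "ifs_result"
  )
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("IFS result (", x$learner, "): ", nrow(x$records), " subset sizes",
      if (x$step > 1) paste0(" [scaled-down sweep, step ", x$step, "]"),
      "\n  optimum: ", x$optimum_size, " features, MCC ",
      signif(max(x$records$mcc), 4), "\n", sep = "")
  invisible(x)
}

#' Pick the best learner across IFS results
#'
#' Mirrors the workflow's final model choice: among the per-learner IFS
#' results, returns the one with the highest optimum MCC; ties go to the
#' result with fewer optimum features, then to learner name order. The
#' winner's optimum subset is the run's global optimum feature set.
#'
#' @param results a list of `ifs_result` objects (one per learner).
#' @return A list with `learner` (name) and `result` (the winning
#'   `ifs_result`).
#' @export
select_global_optimum <- function(results) {
  if (length(results) == 0) stop("no IFS results supplied", call. = FALSE)
  stats <- purrr::map_dfr(results, function(r) {
    tibble::tibble(learner = r$learner, mcc = max(r$records$mcc),
                   size = r$optimum_size)
  })
  ord <- order(-stats$mcc, stats$size, stats$learner)
  best <- ord[1]
  list(learner = stats$learner[best], result = results[[best]])
}
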