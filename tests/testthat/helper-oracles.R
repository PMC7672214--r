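# Independent oracles used to check the package implementations. These are
# deliberately written with different primitives (table(), explicit loops)
# than the code under test.

# plug-in MI via table(), natural log
oracle_mi <- function(x, y) {
  jt <- table(x, y)
  p <- jt / sum(jt)
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  unname(s)
}

# exhaustive step-by-step greedy mRMR on a states matrix: at every step
# re-evaluate every unchosen candidate from scratch
oracle_mrmr <- function(states, labels, criterion = "difference") {
  m <- ncol(states)
  rel <- vapply(seq_len(m), function(j) oracle_mi(states[, j], labels), 0)
  chosen <- integer(0)
  for (step in seq_len(m)) {
    cand <- setdiff(seq_len(m), chosen)
    crit <- vapply(cand, function(j) {
      if (length(chosen) == 0) {
        rel[j]
      } else {
        red <- mean(vapply(chosen, function(s) oracle_mi(states[, j], states[, s]), 0))
        if (criterion == "difference") rel[j] - red
        else rel[j] / max(red, .Machine$double.eps)
      }
    }, 0)
    chosen <- c(chosen, cand[which.max(crit)])
  }
  chosen
}

# brute-force kNN with the pinned tie-breaks, via explicit loops
oracle_knn <- function(Xtr, ytr, Xte, k) {
  lev <- sort(unique(ytr))
  out <- character(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    d <- apply(Xtr, 1, function(r) sqrt(sum((r - Xte[i, ])^2)))
    ord <- order(d, seq_along(d))
    top <- ord[1:k]
    tab <- table(factor(ytr[top], levels = lev))
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1) {
      md <- sapply(cand, function(cl) mean(d[top[ytr[top] == cl]]))
      cand <- cand[order(md, match(cand, lev))]
    }
    out[i] <- cand[1]
  }
  out
}

# exhaustive CART split search + recursive growth in plain R
oracle_cart_predict <- function(Xtr, ytr, Xte, min_split = 2) {
  gini <- function(y) {
    p <- table(y) / length(y)
    1 - sum(p^2)
  }
  best_split <- function(X, y) {
    parent <- gini(y)
    best <- NULL
    for (f in seq_len(ncol(X))) {
      v <- sort(unique(X[, f]))
      if (length(v) < 2) next
      for (thr in (head(v, -1) + tail(v, -1)) / 2) {
        l <- X[, f] <= thr
        imp <- (sum(l) * gini(y[l]) + sum(!l) * gini(y[!l])) / length(y)
        if (is.null(best) || imp < best$imp - 1e-12) {
          best <- list(f = f, thr = thr, imp = imp)
        }
      }
    }
    if (!is.null(best) && best$imp < parent - 1e-12) best else NULL
  }
  grow <- function(X, y) {
    lev <- sort(unique(y))
    maj <- names(which.max(table(factor(y, levels = lev))))
    if (length(unique(y)) == 1 || length(y) < min_split) {
      return(list(leaf = TRUE, class = maj))
    }
    sp <- best_split(X, y)
    if (is.null(sp)) return(list(leaf = TRUE, class = maj))
    l <- X[, sp$f] <= sp$thr
    list(leaf = FALSE, f = sp$f, thr = sp$thr,
         left = grow(X[l, , drop = FALSE], y[l]),
         right = grow(X[!l, , drop = FALSE], y[!l]))
  }
  tree <- grow(Xtr, ytr)
  pred1 <- function(node, x) {
    while (!node$leaf) node <- if (x[node$f] <= node$thr) node$left else node$right
    node$class
  }
  apply(Xte, 1, function(x) pred1(tree, x))
}

# classical binary MCC from a 2x2 confusion table
oracle_binary_mcc <- function(truth, prediction, positive) {
  tp <- sum(truth == positive & prediction == positive)
  tn <- sum(truth != positive & prediction != positive)
  fp <- sum(truth != positive & prediction == positive)
  fn <- sum(truth == positive & prediction != positive)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# small random abundance table fixture
random_table <- function(seed, n = 24, m = 6, K = 3) {
  withr::with_seed(seed, {
    vals <- matrix(rexp(n * m), n, m)
    abundance_table(vals, labels = sample(letters[1:K], n, replace = TRUE))
  })
}
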