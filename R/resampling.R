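#' SMOTE oversampling to equal class sizes
#'
#' Augments every minority class with synthetic samples until all class
#' counts equal the majority count, so that severely imbalanced cohorts do
#' not dominate model training. A synthetic sample is `x + u * (y - x)` with
#' `u ~ Uniform(0, 1)`, where `x` is a uniformly drawn member of the class
#' and `y` a uniformly drawn member of `x`'s `k_neighbors` nearest same-class
#' neighbors (Euclidean distance on the table's current taxon columns).
#' Original samples are preserved unchanged and synthetic samples get fresh
#' `smote_*` sample identifiers, so provenance is checkable afterwards.
#'
#' Neighbors are computed among the original class members only; a class
#' with fewer than `k_neighbors + 1` members uses all other members as the
#' neighbor pool, and a singleton class duplicates its lone member.
#'
#' @param table an abundance table tibble.
#' @param k_neighbors neighborhood size (>= 1); default 5.
#' @param seed RNG seed; the result is fully seed-deterministic.
#' @return The balanced abundance table: all original rows first (unchanged),
#'   then the synthetic rows.
#' @export
smote_balance <- function(table, k_neighbors = 5, seed = 1L) {
  validate_abundance_table(table)
  stopifnot(k_neighbors >= 1)
  withr::local_seed(seed)

  taxa <- taxon_ids(table)
  m <- abundance_matrix(table)
  counts <- table(table$label)
  if (any(counts < 1)) stop("empty class", call. = FALSE)
  n_max <- max(counts)

  synth <- list()
  for (cls in sort(names(counts))) {
    need <- n_max - counts[[cls]]
    if (need == 0) next
    members <- which(table$label == cls)
    n_c <- length(members)
    if (n_c == 1) {
      new_rows <- m[rep(members, need), , drop = FALSE]
    } else {
      d <- as.matrix(stats::dist(m[members, , drop = FALSE]))
      k_eff <- min(k_neighbors, n_c - 1)
      # neighbor index table: for member i, its k_eff nearest other members
      nbr <- t(apply(d, 1, function(row) {
        order(row, seq_along(row))[2:(k_eff + 1)]
      }))
      nbr <- matrix(nbr, nrow = n_c)  # guard k_eff == 1 dropping dims
      xi <- sample.int(n_c, need, replace = TRUE)
      yj <- nbr[cbind(xi, sample.int(k_eff, need, replace = TRUE))]
      u <- stats::runif(need)
      x <- m[members[xi], , drop = FALSE]
      y <- m[members[yj], , drop = FALSE]
      new_rows <- x + u * (y - x)
    }
    synth[[cls]] <- abundance_table(
      new_rows,
      labels = rep(cls, need),
      sample_ids = sprintf("smote_%s_%04d", cls, seq_len(need)),
      taxon_ids = taxa
    )
  }
  if (length(synth) == 0) {
    return(table)
  }
  dplyr::bind_rows(table, dplyr::bind_rows(synth))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `n_folds` cross-validation folds by
#' shuffling within each class (seeded) and dealing fold ids round-robin
#' from a random per-class starting fold. Within every class the fold sizes
#' differ by at most one, so per-fold class proportions track the global
#' proportions as closely as integer counts allow.
#'
#' @param labels per-sample class labels.
#' @param n_folds number of folds (>= 2); default 10.
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..n_folds`, aligned with `labels`.
#' @export
assign_folds <- function(labels, n_folds = 10, seed = 1L) {
  stopifnot(n_folds >= 2)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("class '", names(counts)[counts < 2][1], "' has fewer than 2 samples",
         call. = FALSE)
  }
  withr::local_seed(seed)
  fold <- integer(length(labels))
  for (cls in sort(names(counts))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    offset <- sample.int(n_folds, 1) - 1L
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% n_folds) + 1L
  }
  fold
}
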