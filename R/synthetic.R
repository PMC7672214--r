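#' Specify a synthetic labeled abundance table
#'
#' Builds the generative specification for [generate_table()]. The generator
#' emulates the statistical structure of real multi-class microbiome matrices:
#' many imbalanced classes, a minority of class-informative taxa whose
#' log-scale means are shifted in class-specific subsets, groups of mutually
#' redundant taxa that are noisy copies of informative ones, class-independent
#' noise taxa, and hard zeros (sparsity).
#'
#' Class sizes are either given explicitly or interpolated geometrically
#' between `n_min` and `n_min * imbalance_ratio`, mirroring the severe
#' imbalance of real cancer-type cohorts. `imbalance_ratio` accepts the named
#' profiles `"kraken"` (ratio 33) and `"shogun"` (ratio 64.5).
#'
#' @param n_classes number of class labels (>= 2).
#' @param class_sizes optional integer vector of per-class sample counts
#'   (length `n_classes`, each >= 2); overrides `n_min`/`imbalance_ratio`.
#' @param n_min smallest class size used for geometric interpolation.
#' @param imbalance_ratio largest/smallest class-size ratio, or `"kraken"` /
#'   `"shogun"`.
#' @param n_informative,n_redundant,n_noise taxon counts by role.
#' @param effect_size log-scale mean shift delta of an informative taxon in
#'   the classes of its signature (dimensionless).
#' @param within_class_sd log-scale standard deviation sigma of abundances.
#'   The default (0.4, i.e. delta/sigma = 3.75 with the default effect size)
#'   is calibrated so that the planted signal is recoverable by the built-in
#'   learners and the best cross-validated MCC on default tables is
#'   comparable to what the published TCGA microbiome models attained on
#'   real cohorts; see the methods vignette.
#' @param redundancy_corr target log-scale correlation rho between a redundant
#'   taxon and its parent, in `[0, 1]`.
#' @param zero_inflation probability in `[0, 1)` that a measured abundance is
#'   set to exactly 0.
#' @param seed RNG seed; identical spec + seed reproduces tables bit-for-bit.
#'
#' @return An object of class `synthetic_spec` (a named list).
#' @examples
#' spec <- synthetic_spec(n_classes = 4, n_min = 5, imbalance_ratio = 33)
#' spec$class_sizes
#' @export
synthetic_spec <- function(n_classes = 8,
                           class_sizes = NULL,
                           n_min = 6,
                           imbalance_ratio = "kraken",
                           n_informative = 10,
                           n_redundant = 20,
                           n_noise = 170,
                           effect_size = 1.5,
                           within_class_sd = 0.4,
                           redundancy_corr = 0.9,
                           zero_inflation = 0.1,
                           seed = 1L) {
  if (is.character(imbalance_ratio)) {
    imbalance_ratio <- switch(match.arg(imbalance_ratio, c("kraken", "shogun")),
                              kraken = 33, shogun = 64.5)
  }
  if (!is.numeric(n_classes) || n_classes < 2) {
    stop("invalid 'n_classes': must be >= 2", call. = FALSE)
  }
  n_classes <- as.integer(n_classes)
  if (is.null(class_sizes)) {
    if (n_min < 2) stop("invalid 'n_min': must be >= 2", call. = FALSE)
    if (imbalance_ratio < 1) stop("invalid 'imbalance_ratio': must be >= 1", call. = FALSE)
    class_sizes <- round(n_min * imbalance_ratio^((seq_len(n_classes) - 1) / (n_classes - 1)))
  }
  class_sizes <- as.integer(class_sizes)
  if (length(class_sizes) != n_classes) {
    stop("invalid 'class_sizes': length must equal n_classes", call. = FALSE)
  }
  if (any(class_sizes < 2)) {
    stop("invalid 'class_sizes': every class needs >= 2 samples", call. = FALSE)
  }
  for (fld in c("n_informative", "n_redundant", "n_noise")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      stop("invalid '", fld, "': must be a non-negative count", call. = FALSE)
    }
  }
  if (n_redundant > 0 && n_informative == 0) {
    stop("invalid 'n_redundant': redundant taxa need informative parents", call. = FALSE)
  }
  if (zero_inflation < 0 || zero_inflation >= 1) {
    stop("invalid 'zero_inflation': must be in [0, 1)", call. = FALSE)
  }
  if (redundancy_corr < 0 || redundancy_corr > 1) {
    stop("invalid 'redundancy_corr': must be in [0, 1]", call. = FALSE)
  }
  if (within_class_sd <= 0) {
    stop("invalid 'within_class_sd': must be > 0", call. = FALSE)
  }
  structure(
    list(
      n_classes = n_classes,
      class_sizes = class_sizes,
      n_informative = as.integer(n_informative),
      n_redundant = as.integer(n_redundant),
      n_noise = as.integer(n_noise),
      effect_size = effect_size,
      within_class_sd = within_class_sd,
      redundancy_corr = redundancy_corr,
      zero_inflation = zero_inflation,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

# Draw class signatures: a logical n_classes x n_informative matrix saying in
# which classes a taxon's log-mean is shifted by delta. Rejection-sample so
# that every class carries >= 1 signature taxon (all classes learnable) and
# every informative taxon is shifted in >= 1 but not all classes (so it
# actually separates something).
draw_signatures <- function(n_classes, n_informative) {
  if (n_informative == 0) {
    return(matrix(FALSE, n_classes, 0))
  }
  repeat {
    sig <- matrix(stats::runif(n_classes * n_informative) < 0.5,
                  n_classes, n_informative)
    taxon_ok <- colSums(sig) >= 1 & colSums(sig) < n_classes
    class_ok <- rowSums(sig) >= 1
    if (all(taxon_ok) && all(class_ok)) {
      return(sig)
    }
  }
}

#' Generate a labeled abundance table with planted structure
#'
#' Draws a samples x taxa table under the model of [synthetic_spec()]:
#' log-normal abundances `exp(Normal(mu_jk, sigma^2))` where the log-mean
#' `mu_jk` is `delta` when taxon `j` is in class `k`'s signature and 0
#' otherwise; redundant taxa are their parent's value times a log-normal
#' jitter whose variance is calibrated so the log-scale correlation with the
#' parent is approximately `redundancy_corr`; every measured cell is then set
#' to 0 independently with probability `zero_inflation`.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with components:
#' \describe{
#'   \item{table}{the abundance table tibble (see [abundance_table()]); taxon
#'     columns are named `inf*`, `red*`, `noise*` by role.}
#'   \item{truth}{a ground-truth tibble with one row per taxon: `taxon_id`,
#'     `role` (informative / redundant / noise), `parent_id` (the informative
#'     parent of a redundant taxon, `NA` otherwise) and `signature_classes`
#'     (comma-separated labels of the classes in which the taxon is shifted).}
#' }
#' @examples
#' out <- generate_table(synthetic_spec(n_classes = 3, class_sizes = c(5, 8, 12),
#'                                      n_informative = 4, n_redundant = 2,
#'                                      n_noise = 10, seed = 42))
#' dim(out$table)
#' dplyr::count(out$truth, role)
#' @export
generate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::local_seed(spec$seed)

  K <- spec$n_classes
  sizes <- spec$class_sizes
  n <- sum(sizes)
  labels <- rep(sprintf("class%02d", seq_len(K)), times = sizes)
  cls_idx <- rep(seq_len(K), times = sizes)

  inf_ids <- if (spec$n_informative > 0) sprintf("inf%02d", seq_len(spec$n_informative)) else character()
  red_ids <- if (spec$n_redundant > 0) sprintf("red%02d", seq_len(spec$n_redundant)) else character()
  noise_ids <- if (spec$n_noise > 0) sprintf("noise%03d", seq_len(spec$n_noise)) else character()

  sig <- draw_signatures(K, spec$n_informative)

  # log-scale draws for informative + noise taxa
  p_base <- spec$n_informative + spec$n_noise
  mu <- matrix(0, n, p_base)
  if (spec$n_informative > 0) {
    mu[, seq_len(spec$n_informative)] <- spec$effect_size * sig[cls_idx, , drop = FALSE]
  }
  L_base <- mu + spec$within_class_sd * matrix(stats::rnorm(n * p_base), n, p_base)

  # redundant taxa: parent log value + calibrated jitter
  parents <- integer(0)
  L_red <- matrix(0, n, spec$n_redundant)
  if (spec$n_redundant > 0) {
    parents <- ((seq_len(spec$n_redundant) - 1L) %% spec$n_informative) + 1L
    rho <- spec$redundancy_corr
    if (rho == 0) {
      L_red <- spec$within_class_sd * matrix(stats::rnorm(n * spec$n_redundant), n, spec$n_redundant)
    } else {
      jitter_sd <- spec$within_class_sd * sqrt(1 / rho^2 - 1)
      L_red <- L_base[, parents, drop = FALSE] +
        jitter_sd * matrix(stats::rnorm(n * spec$n_redundant), n, spec$n_redundant)
    }
  }

  L <- cbind(L_base[, seq_len(spec$n_informative), drop = FALSE],
             L_red,
             L_base[, spec$n_informative + seq_len(spec$n_noise), drop = FALSE])
  values <- exp(L)
  if (spec$zero_inflation > 0) {
    mask <- matrix(stats::runif(length(values)) < spec$zero_inflation,
                   nrow(values), ncol(values))
    values[mask] <- 0
  }

  taxa <- c(inf_ids, red_ids, noise_ids)
  colnames(values) <- taxa
  tbl <- abundance_table(values,
                         labels = labels,
                         sample_ids = sprintf("s%04d", seq_len(n)),
                         taxon_ids = taxa)

  class_names <- sprintf("class%02d", seq_len(K))
  sig_string <- function(j) paste(class_names[sig[, j]], collapse = ",")
  truth <- tibble::tibble(
    taxon_id = taxa,
    role = rep(c("informative", "redundant", "noise"),
               c(spec$n_informative, spec$n_redundant, spec$n_noise)),
    parent_id = c(rep(NA_character_, spec$n_informative),
                  inf_ids[parents],
                  rep(NA_character_, spec$n_noise)),
    signature_classes = c(vapply(seq_len(spec$n_informative), sig_string, ""),
                          vapply(parents, sig_string, ""),
                          rep("", spec$n_noise))
  )

  list(table = tbl, truth = truth)
}
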