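#' Three-state discretization of an abundance table
#'
#' Each taxon is discretized against its own mean and population standard
#' deviation: state `+1` if the value exceeds `mu + t*sigma`, `-1` if it is
#' below `mu - t*sigma`, and `0` otherwise. A constant taxon (sigma = 0) maps
#' to all-zero states. This realizes the probability masses used by the
#' mutual-information estimates that drive the mRMR ranking.
#'
#' @param table an abundance table tibble.
#' @param t threshold multiplier (> 0); default 1.
#' @return A `discretized_table`: a list with `states` (samples x taxa integer
#'   matrix over \{-1, 0, +1\}), `labels`, `sample_ids` and a `thresholds`
#'   tibble (`taxon_id`, `mu`, `sigma`, `t`).
#' @export
discretize <- function(table, t = 1) {
  stopifnot(t > 0)
  validate_abundance_table(table)
  m <- abundance_matrix(table)
  n <- nrow(m)
  mu <- colMeans(m)
  sigma <- sqrt(colMeans(m^2) - mu^2)  # population SD
  sigma[sigma < 0] <- 0                # guard tiny negative rounding
  hi <- sweep(m, 2, mu + t * sigma, ">")
  lo <- sweep(m, 2, mu - t * sigma, "<")
  states <- matrix(0L, n, ncol(m), dimnames = dimnames(m))
  states[hi] <- 1L
  states[lo] <- -1L
  states[, sigma == 0] <- 0L
  structure(
    list(
      states = states,
      labels = as.character(table$label),
      sample_ids = table$sample_id,
      thresholds = tibble::tibble(taxon_id = colnames(m), mu = unname(mu),
                                  sigma = unname(sigma), t = t)
    ),
    class = "discretized_table"
  )
}

# MI in nats between two integer-coded vectors (codes in 1..nx / 1..ny),
# plug-in estimate over observed cells with 0 * log(0) == 0.
mi_codes <- function(ix, iy, nx, ny) {
  n <- length(ix)
  joint <- tabulate(ix + nx * (iy - 1L), nx * ny) / n
  px <- tabulate(ix, nx) / n
  py <- tabulate(iy, ny) / n
  outer_p <- as.vector(outer(px, py))
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer_p[nz]))
}

#' Mutual information between two discrete vectors
#'
#' Plug-in estimate `sum p(x, y) * ln( p(x, y) / (p(x) p(y)) )` over the
#' observed joint cells, in nats. Symmetric in its arguments and always
#' non-negative; zero exactly when the empirical joint factorizes.
#'
#' @param x,y discrete vectors (any atomic type) of equal length.
#' @return MI in nats (>= 0).
#' @examples
#' mutual_information(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # ln 2
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  fx <- factor(x)
  fy <- factor(y)
  mi_codes(as.integer(fx), as.integer(fy), nlevels(fx), nlevels(fy))
}

#' mRMR feature ranking
#'
#' Orders all taxa by greedy minimum-redundancy / maximum-relevance
#' selection on the discretized table. Relevance of a taxon is its mutual
#' information with the class label; redundancy is its mean MI with the taxa
#' already selected. The first pick maximizes relevance alone; every later
#' pick maximizes `relevance - redundancy` (`"difference"`, the default, also
#' known as MID) or `relevance / redundancy` (`"quotient"`, MIQ). Ties are
#' broken by the lower original column index, so the ranking is fully
#' deterministic and independent of sample order.
#'
#' @param table an abundance table tibble, or a `discretized_table` from
#'   [discretize()].
#' @param t discretization threshold multiplier (ignored when `table` is
#'   already discretized).
#' @param criterion `"difference"` or `"quotient"`.
#' @return An `mrmr_ranking` tibble with columns `rank`, `taxon_id`, `score`
#'   (the selection score at the step the taxon was picked, nats) and
#'   `relevance` (MI with the class label, nats).
#' @export
mrmr_rank <- function(table, t = 1, criterion = c("difference", "quotient")) {
  criterion <- match.arg(criterion)
  disc <- if (inherits(table, "discretized_table")) table else discretize(table, t = t)
  states <- disc$states
  m <- ncol(states)
  if (m == 0) stop("no features to rank", call. = FALSE)
  n <- nrow(states)

  codes <- states + 2L  # {-1,0,1} -> {1,2,3}
  lab <- factor(disc$labels)
  ilab <- as.integer(lab)
  K <- nlevels(lab)

  relevance <- vapply(seq_len(m), function(j) mi_codes(codes[, j], ilab, 3L, K), 0)

  selected <- integer(m)
  scores <- numeric(m)
  red_sum <- numeric(m)      # sum of MI with already-selected features
  remaining <- rep(TRUE, m)

  for (step in seq_len(m)) {
    if (step == 1) {
      crit <- relevance
    } else {
      mean_red <- red_sum / (step - 1)
      crit <- if (criterion == "difference") {
        relevance - mean_red
      } else {
        relevance / pmax(mean_red, .Machine$double.eps)
      }
    }
    crit[!remaining] <- -Inf
    pick <- which.max(crit)  # which.max returns the first (lowest index) tie
    selected[step] <- pick
    scores[step] <- crit[pick]
    remaining[pick] <- FALSE
    if (any(remaining)) {
      for (j in which(remaining)) {
        red_sum[j] <- red_sum[j] + mi_codes(codes[, j], codes[, pick], 3L, 3L)
      }
    }
  }

  structure(
    tibble::tibble(
      rank = seq_len(m),
      taxon_id = colnames(states)[selected],
      score = scores,
      relevance = relevance[selected]
    ),
    class = c("mrmr_ranking", class(tibble::tibble()))
  )
}
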