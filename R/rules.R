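#' Extract IF-THEN classification rules from a CART tree
#'
#' Turns every root-to-leaf path of a fitted tree into one rule: the path's
#' split conditions in order, simplified so that each taxon keeps at most one
#' upper (`<=`) and one lower (`>`) bound (the tightest ones; condition order
#' across taxa is preserved for readability), predicting the leaf's majority
#' class. Because the tree's leaves partition the feature space, the rules
#' are mutually exclusive and jointly exhaustive: every possible sample
#' satisfies exactly one rule.
#'
#' @param tree a `cart_tree` from [cart_fit()].
#' @return A `rule_set`: list with `rules` (each rule a list with `rule_id`,
#'   `class`, a `conditions` tibble of (`taxon_id`, `comparator`,
#'   `threshold`), `support` = training samples at the leaf, `purity` = leaf
#'   majority fraction), the source classes, and a `fingerprint` digest tying
#'   the rules to the tree they came from.
#' @export
extract_rules <- function(tree) {
  stopifnot(inherits(tree, "cart_tree"))
  nd <- tree$nodes
  if (nrow(nd) == 0) stop("empty tree", call. = FALSE)

  rules <- list()
  walk <- function(node_id, conds) {
    if (nd$is_leaf[node_id]) {
      cnt <- tree$counts[node_id, ]
      rules[[length(rules) + 1]] <<- list(
        rule_id = length(rules) + 1L,
        class = nd$class[node_id],
        conditions = simplify_conditions(conds),
        support = nd$n[node_id],
        purity = max(cnt) / sum(cnt)
      )
      return(invisible())
    }
    tx <- nd$taxon_id[node_id]
    thr <- nd$threshold[node_id]
    walk(nd$left[node_id],
         append(conds, list(list(taxon_id = tx, comparator = "<=", threshold = thr))))
    walk(nd$right[node_id],
         append(conds, list(list(taxon_id = tx, comparator = ">", threshold = thr))))
  }
  walk(1L, list())

  new_rule_set(rules, fingerprint = rlang::hash(nd), classes = tree$classes)
}

# Keep the tightest bound per (taxon, comparator): min threshold for <=,
# max for >. First occurrence keeps its position in the condition order.
simplify_conditions <- function(conds) {
  if (length(conds) == 0) {
    return(tibble::tibble(taxon_id = character(), comparator = character(),
                          threshold = double()))
  }
  df <- purrr::map_dfr(conds, tibble::as_tibble)
  df$ord <- seq_len(nrow(df))
  df |>
    dplyr::summarise(
      threshold = if (.data$comparator[1] == "<=") min(.data$threshold) else max(.data$threshold),
      ord = min(.data$ord),
      .by = c("taxon_id", "comparator")
    ) |>
    dplyr::arrange(.data$ord) |>
    dplyr::select("taxon_id", "comparator", "threshold")
}

new_rule_set <- function(rules, fingerprint, classes = NULL) {
  classes <- classes %||% sort(unique(vapply(rules, function(r) r$class, "")))
  structure(list(rules = rules, classes = classes, fingerprint = fingerprint),
            class = "rule_set")
}

#' @export
print.rule_set <- function(x, ...) {
  cat("Rule set:", length(x$rules), "rules over", length(x$classes), "classes\n")
  invisible(x)
}

#' @export
length.rule_set <- function(x) length(x$rules)

tidy_rules <- function(rule_set) {
  if (length(rule_set$rules) == 0) {
    return(tibble::tibble(rule_id = integer(), class = character(),
                          n_conditions = integer(), conditions = character(),
                          support = integer(), purity = double()))
  }
  purrr::map_dfr(rule_set$rules, function(r) {
    tibble::tibble(
      rule_id = r$rule_id,
      class = r$class,
      n_conditions = nrow(r$conditions),
      conditions = paste(sprintf("%s%s%.17g", r$conditions$taxon_id,
                                 r$conditions$comparator, r$conditions$threshold),
                         collapse = " & "),
      support = as.integer(r$support),
      purity = r$purity
    )
  })
}

#' @export
tidy.rule_set <- function(x, ...) tidy_rules(x)

#' @export
glance.rule_set <- function(x, ...) {
  counts <- rule_counts(x)
  tibble::tibble(n_rules = length(x$rules), n_classes = length(x$classes),
                 max_rules_per_class = max(counts$n_rules),
                 min_rules_per_class = min(counts$n_rules))
}

rule_counts <- function(rule_set) {
  got <- table(factor(vapply(rule_set$rules, function(r) r$class, ""),
                      levels = rule_set$classes))
  tibble::tibble(class = rule_set$classes, n_rules = as.integer(got))
}

#' Apply a rule set as a classifier
#'
#' Matches every sample against every rule's conditions and returns the
#' predicted class of the single rule that fires. On any input this
#' reproduces the source tree's predictions exactly (100% fidelity); a
#' sample matching zero or several rules signals a corrupted rule set and is
#' an error.
#'
#' @param rule_set a `rule_set` from [extract_rules()].
#' @param table an abundance table tibble containing every taxon the rules
#'   reference.
#' @return Character vector of predicted labels, one per sample.
#' @export
apply_rules <- function(rule_set, table) {
  stopifnot(inherits(rule_set, "rule_set"))
  used <- unique(unlist(lapply(rule_set$rules, function(r) r$conditions$taxon_id)))
  missing <- setdiff(used, names(table))
  if (length(missing) > 0) {
    stop("table is missing taxon referenced by rules: ", missing[1], call. = FALSE)
  }
  n <- nrow(table)
  fired <- matrix(FALSE, n, length(rule_set$rules))
  for (j in seq_along(rule_set$rules)) {
    r <- rule_set$rules[[j]]
    ok <- rep(TRUE, n)
    cd <- r$conditions
    for (i in seq_len(nrow(cd))) {
      v <- table[[cd$taxon_id[i]]]
      ok <- ok & if (cd$comparator[i] == "<=") v <= cd$threshold[i] else v > cd$threshold[i]
    }
    fired[, j] <- ok
  }
  hits <- rowSums(fired)
  if (any(hits != 1)) {
    bad <- which(hits != 1)[1]
    stop("sample ", bad, " matched ", hits[bad],
         " rules; rule set is corrupted", call. = FALSE)
  }
  classes <- vapply(rule_set$rules, function(r) r$class, "")
  classes[apply(fired, 1, which.max)]
}

#' Render rules as text
#'
#' @param rule_set a `rule_set`.
#' @param digits significant digits for displayed thresholds (display only;
#'   stored thresholds keep full precision).
#' @return Character vector, one `IF ... THEN ...` line per rule.
#' @export
format_rules <- function(rule_set, digits = 4) {
  vapply(rule_set$rules, function(r) {
    lhs <- if (nrow(r$conditions) == 0) {
      "TRUE"
    } else {
      paste(sprintf("%s %s %s", r$conditions$taxon_id, r$conditions$comparator,
                    signif(r$conditions$threshold, digits)),
            collapse = " AND ")
    }
    sprintf("IF %s THEN %s  [support=%d, purity=%.3f]",
            lhs, r$class, as.integer(r$support), r$purity)
  }, "")
}

#' Per-class rule counts and readable rule listing
#'
#' Summarizes a rule set the way a classification-rules table reports it:
#' the number of rules predicting each class (classes with no rules are
#' reported as 0, not omitted) plus the human-readable rendering, ordered by
#' class label and, within a class, by rule support descending.
#'
#' @param rule_set a `rule_set`.
#' @return A list with `counts` (tibble `class`, `n_rules`, whose `n_rules`
#'   sum to the total rule count) and `text` (character lines).
#' @export
rule_report <- function(rule_set) {
  ord <- order(vapply(rule_set$rules, function(r) r$class, ""),
               -vapply(rule_set$rules, function(r) as.double(r$support), 0))
  sorted <- new_rule_set(rule_set$rules[ord], rule_set$fingerprint,
                         rule_set$classes)
  list(counts = rule_counts(rule_set), text = format_rules(sorted))
}
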