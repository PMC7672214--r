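# Tabular serialization. Doubles are written as %.17g so that every
# write/read pair is an exact inverse (IEEE doubles round-trip at 17
# significant digits); readers parse them back with readr.

fmt_dbl <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

write_tsv_exact <- function(df, path) {
  out <- dplyr::mutate(df, dplyr::across(dplyr::where(is.double), fmt_dbl))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE, ...)
}

#' Read an abundance table from TSV/CSV
#'
#' The canonical on-disk layout is a TSV with taxa as rows (the common
#' microbiome-matrix convention): first column taxon identifiers, remaining
#' columns one per sample. A samples-as-rows layout is accepted via
#' `orientation`. Labels come either from a two-column `sample_id` / `label`
#' TSV (`labels` = path or data frame) or, for samples-as-rows input, from a
#' label column named by `label_column`.
#'
#' @param path matrix file; `.csv` is parsed comma-separated, anything else
#'   tab-separated.
#' @param labels path to a two-column sample-to-label TSV, or a data frame
#'   with columns `sample_id` and `label`.
#' @param orientation `"taxa_as_rows"` (default) or `"samples_as_rows"`.
#' @param label_column for samples-as-rows input only: name of the label
#'   column inside the matrix file.
#' @return A validated abundance table tibble.
#' @export
read_abundance_table <- function(path,
                                 labels = NULL,
                                 orientation = c("taxa_as_rows", "samples_as_rows"),
                                 label_column = NULL) {
  orientation <- match.arg(orientation)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    function(p) readr::read_csv(p, progress = FALSE, show_col_types = FALSE)
  } else {
    read_tsv_quiet
  }
  raw <- reader(path)
  if (ncol(raw) < 2) stop("matrix file needs an id column plus data columns", call. = FALSE)

  if (orientation == "taxa_as_rows") {
    taxa <- as.character(raw[[1]])
    m <- t(as.matrix(raw[, -1, drop = FALSE]))
    colnames(m) <- taxa
    sample_ids <- names(raw)[-1]
  } else {
    sample_ids <- as.character(raw[[1]])
    body <- raw[, -1, drop = FALSE]
    lab_from_col <- NULL
    if (!is.null(label_column)) {
      if (!label_column %in% names(body)) {
        stop("label column '", label_column, "' not found", call. = FALSE)
      }
      lab_from_col <- as.character(body[[label_column]])
      body <- body[, setdiff(names(body), label_column), drop = FALSE]
    }
    m <- as.matrix(body)
    rownames(m) <- sample_ids
    if (!is.null(lab_from_col)) {
      labels <- tibble::tibble(sample_id = sample_ids, label = lab_from_col)
    }
  }
  if (!is.numeric(m)) stop("non-numeric abundance values in ", path, call. = FALSE)

  if (is.null(labels)) stop("no label source given", call. = FALSE)
  if (is.character(labels) && length(labels) == 1) {
    labels <- read_tsv_quiet(labels)
  }
  if (!all(c("sample_id", "label") %in% names(labels))) {
    stop("label table needs 'sample_id' and 'label' columns", call. = FALSE)
  }
  idx <- match(sample_ids, labels$sample_id)
  if (anyNA(idx)) {
    stop("unlabeled sample: ", sample_ids[which(is.na(idx))[1]], call. = FALSE)
  }
  abundance_table(m, labels = as.character(labels$label)[idx],
                  sample_ids = sample_ids)
}

#' Write an abundance table to TSV
#'
#' Writes the canonical taxa-as-rows matrix TSV plus a two-column label TSV.
#' Values are serialized losslessly; [read_abundance_table()] is an exact
#' inverse.
#'
#' @param table an abundance table tibble.
#' @param path matrix output path.
#' @param labels_path label output path; default `<path>` with a `.labels.tsv`
#'   suffix.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path,
                                  labels_path = paste0(path, ".labels.tsv")) {
  validate_abundance_table(table)
  m <- abundance_matrix(table)
  df <- tibble::as_tibble(t(m), .name_repair = "minimal")
  names(df) <- table$sample_id
  df <- dplyr::bind_cols(tibble::tibble(taxon_id = taxon_ids(table)), df)
  write_tsv_exact(df, path)
  readr::write_tsv(table[, c("sample_id", "label")], labels_path, progress = FALSE)
  invisible(path)
}

#' Write the ground-truth sidecar of a synthetic table
#'
#' @param truth the `truth` tibble from [generate_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(truth, path, na = "", progress = FALSE)
  invisible(path)
}

#' Summarize the class distribution of a labeled table
#'
#' Tallies samples per class and derives the imbalance summary used
#' throughout the package: total sample count, largest and smallest class,
#' and their ratio.
#'
#' @param x an abundance table tibble (any data frame with a `label` column),
#'   or a pre-tallied data frame with columns `label` and `n`.
#' @return A `class_distribution` tibble with columns `label` and `n`, one
#'   row per class sorted by label; [generics::glance()] on it returns the
#'   one-row summary (`total`, `n_classes`, `max_count`, `min_count`,
#'   `imbalance_ratio`).
#' @examples
#' d <- summarize_class_distribution(
#'   data.frame(label = c("a", "a", "a", "b"))
#' )
#' glance(d)
#' @export
summarize_class_distribution <- function(x) {
  stopifnot(is.data.frame(x), "label" %in% names(x))
  if ("n" %in% names(x) && !"sample_id" %in% names(x)) {
    counts <- dplyr::arrange(dplyr::select(x, "label", "n"), .data$label)
  } else {
    counts <- dplyr::count(dplyr::as_tibble(x), .data$label)
  }
  counts$n <- as.integer(counts$n)
  structure(counts, class = c("class_distribution", class(tibble::tibble())))
}

#' @export
glance.class_distribution <- function(x, ...) {
  tibble::tibble(
    total = sum(x$n),
    n_classes = nrow(x),
    max_count = max(x$n),
    min_count = min(x$n),
    imbalance_ratio = max(x$n) / min(x$n)
  )
}

#' Per-cancer sample sizes of the TCGA microbiome cohorts
#'
#' The published per-cancer-type sample counts of the two alternative TCGA
#' microbiome matrices (the Kraken- and SHOGUN-profiled variants), shipped as
#' a plain-text table. These counts are the reference imbalance profiles the
#' synthetic generator mirrors: the Kraken cohort's largest/smallest ratio
#' rounds to 33 and the SHOGUN cohort's to 64.5.
#'
#' @return A tibble with columns `cancer_type`, `kraken`, `shogun`.
#' @examples
#' cohorts <- tcga_cohorts()
#' sum(cohorts$kraken)
#' @export
tcga_cohorts <- function() {
  path <- system.file("extdata", "tcga_cohorts.tsv", package = "taxarules",
                      mustWork = TRUE)
  read_tsv_quiet(path, col_types = "cii")
}

#' Write / read a ranked feature list
#'
#' Serializes a feature ranking (see [mrmr_rank()]) in the layout
#' rank / taxon_id / score / relevance; reading preserves order exactly.
#'
#' @param ranking a ranking tibble with columns `rank`, `taxon_id`, `score`,
#'   `relevance`.
#' @param path output TSV path.
#' @return `path` invisibly (writer); the ranking tibble (reader).
#' @export
write_feature_list <- function(ranking, path) {
  write_tsv_exact(ranking[, c("rank", "taxon_id", "score", "relevance")], path)
}

#' @rdname write_feature_list
#' @export
read_feature_list <- function(path) {
  out <- read_tsv_quiet(path, col_types = "icdd")
  structure(out, class = c("mrmr_ranking", class(tibble::tibble())))
}

#' Write / read an IFS metric table
#'
#' One row per evaluated subset size with overall accuracy, multiclass MCC
#' and the per-class accuracies (wide columns `acc_<label>`).
#'
#' @param ifs an `ifs_result` (see [run_ifs()]) or its records tibble.
#' @param path output TSV path.
#' @return `path` invisibly (writer); the records tibble (reader).
#' @export
write_ifs_table <- function(ifs, path) {
  records <- if (inherits(ifs, "ifs_result")) ifs$records else ifs
  write_tsv_exact(records, path)
}

#' @rdname write_ifs_table
#' @export
read_ifs_table <- function(path) {
  read_tsv_quiet(path)
}

#' Write / read an extracted rule set
#'
#' The tabular form has one row per rule: `rule_id`, `class`, `n_conditions`,
#' the serialized conditions (`taxon<=thr` / `taxon>thr`, joined by ` & `,
#' thresholds at full precision), `support` and `purity`. An optional
#' human-readable rendering ("IF ... THEN ...") is written alongside.
#'
#' @param rule_set a `rule_set` (see [extract_rules()]).
#' @param path output TSV path.
#' @param text_path optional path for the plain-text rendering.
#' @return `path` invisibly (writer); a `rule_set` (reader).
#' @export
write_rules <- function(rule_set, path, text_path = NULL) {
  df <- tidy_rules(rule_set)
  write_tsv_exact(df, path)
  if (!is.null(text_path)) {
    writeLines(format_rules(rule_set), text_path)
  }
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  df <- read_tsv_quiet(path, col_types = "icicid")
  rules <- purrr::pmap(df, function(rule_id, class, n_conditions, conditions,
                                    support, purity) {
    conds <- if (is.na(conditions) || conditions == "") {
      tibble::tibble(taxon_id = character(), comparator = character(),
                     threshold = double())
    } else {
      parts <- strsplit(conditions, " & ", fixed = TRUE)[[1]]
      purrr::map_dfr(parts, function(p) {
        cmp <- if (grepl("<=", p, fixed = TRUE)) "<=" else ">"
        bits <- strsplit(p, cmp, fixed = TRUE)[[1]]
        tibble::tibble(taxon_id = bits[1], comparator = cmp,
                       threshold = as.numeric(bits[2]))
      })
    }
    list(rule_id = rule_id, class = class, conditions = conds,
         support = support, purity = purity)
  })
  new_rule_set(rules, fingerprint = NA_character_)
}
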