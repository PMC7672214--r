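#' Construct an abundance table
#'
#' The canonical in-memory representation of a labeled taxon abundance table
#' is an ordinary tibble with one row per sample: a `sample_id` character
#' column, a `label` character column (the sample's class), and one numeric
#' column per taxon holding non-negative abundances. Every user-facing
#' function in the package takes and returns this shape, so pipelines chain
#' naturally with the pipe.
#'
#' @param values numeric matrix, samples x taxa, all values >= 0.
#' @param labels character vector of per-sample class labels (length `nrow(values)`).
#' @param sample_ids,taxon_ids optional identifier vectors; defaults are taken
#'   from `dimnames(values)` or generated as `s1, s2, ...` / `t1, t2, ...`.
#'
#' @return A tibble with columns `sample_id`, `label`, then one column per taxon.
#' @examples
#' m <- matrix(c(0, 2, 1, 0, 5, 3), nrow = 2)
#' abundance_table(m, labels = c("a", "b"))
#' @export
abundance_table <- function(values, labels, sample_ids = NULL, taxon_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(values) %||% paste0("t", seq_len(ncol(values)))
  }
  tbl <- tibble::as_tibble(values, .name_repair = "minimal")
  names(tbl) <- taxon_ids
  tbl <- dplyr::bind_cols(
    tibble::tibble(sample_id = as.character(sample_ids), label = as.character(labels)),
    tbl
  )
  validate_abundance_table(tbl)
}

#' Taxon identifiers of an abundance table
#'
#' @param table an abundance table tibble (see [abundance_table()]).
#' @return Character vector of taxon column names, in column order.
#' @export
taxon_ids <- function(table) {
  setdiff(names(table), c("sample_id", "label"))
}

#' Extract the samples x taxa numeric matrix
#'
#' @inheritParams taxon_ids
#' @param taxa optional subset of taxon identifiers (kept in the given order).
#' @return Numeric matrix with `sample_id` rownames and taxon colnames.
#' @export
abundance_matrix <- function(table, taxa = NULL) {
  taxa <- taxa %||% taxon_ids(table)
  missing <- setdiff(taxa, names(table))
  if (length(missing) > 0) {
    stop("unknown taxa requested: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(table[, taxa, drop = FALSE])
  rownames(m) <- table$sample_id
  storage.mode(m) <- "double"
  m
}

#' Sorted label set of an abundance table
#'
#' Class labels are indexed everywhere downstream in the sorted order of the
#' unique labels, so that tie-breaking is stable across the whole pipeline.
#'
#' @inheritParams taxon_ids
#' @return Character vector of unique labels, sorted.
#' @export
label_set <- function(table) {
  sort(unique(as.character(table$label)))
}

#' Validate an abundance table
#'
#' Checks the structural invariants every downstream stage relies on: the
#' `sample_id`/`label` columns exist, sample and taxon identifiers are unique,
#' all abundance columns are numeric with no missing values, and all
#' abundances are non-negative. The first offending record is named in the
#' error message.
#'
#' @inheritParams taxon_ids
#' @return The table, invisibly unchanged, for use in pipes.
#' @export
validate_abundance_table <- function(table) {
  if (!is.data.frame(table)) stop("abundance table must be a data frame", call. = FALSE)
  if (!all(c("sample_id", "label") %in% names(table))) {
    stop("abundance table needs 'sample_id' and 'label' columns", call. = FALSE)
  }
  if (anyDuplicated(table$sample_id)) {
    stop("duplicate sample_id: ", table$sample_id[duplicated(table$sample_id)][1],
         call. = FALSE)
  }
  taxa <- taxon_ids(table)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon_id: ", taxa[duplicated(taxa)][1], call. = FALSE)
  }
  if (anyNA(table$label)) {
    stop("unlabeled sample: ", table$sample_id[which(is.na(table$label))[1]],
         call. = FALSE)
  }
  for (tx in taxa) {
    v <- table[[tx]]
    if (!is.numeric(v)) stop("taxon column '", tx, "' is not numeric", call. = FALSE)
    if (anyNA(v)) {
      stop("missing abundance at sample '", table$sample_id[which(is.na(v))[1]],
           "', taxon '", tx, "'", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative abundance at sample '", table$sample_id[which(v < 0)[1]],
           "', taxon '", tx, "'", call. = FALSE)
    }
  }
  invisible(table)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
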