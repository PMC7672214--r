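#' Run the full classification workflow
#'
#' Orchestrates the end-to-end analysis on one labeled abundance table:
#' mRMR feature ranking, incremental feature selection under stratified
#' cross-validation for every requested learner, selection of the global
#' optimum learner/subset, and extraction of IF-THEN classification rules
#' from a CART tree trained on the decision-tree optimum subset. Every
#' artifact is written to `out_dir` as plain TSV/JSON, together with a
#' machine-readable manifest of the full configuration and all derived
#' seeds; an identical configuration always reproduces byte-identical
#' outputs, and [replay_run()] re-executes a run from its manifest alone.
#'
#' Files written: `input_table.tsv` (+ `.labels.tsv`, and
#' `ground_truth.tsv` for synthetic input), `ranking.tsv`,
#' `ifs_<learner>.tsv` and `optimum_features_<learner>.tsv` per learner,
#' `global_optimum.tsv`, `optimum_features_global.tsv`, `rules.tsv`,
#' `rules.txt`, `rule_counts.tsv`, `manifest.json`.
#'
#' @param table an abundance table tibble, or `NULL` to generate one.
#' @param spec a [synthetic_spec()] used when `table` is `NULL`.
#' @param out_dir output directory (created if needed).
#' @param learners character vector of learner names (see [learner()]).
#' @param learner_params named list of per-learner hyperparameter lists,
#'   e.g. `list(knn = list(k = 3))`.
#' @param t discretization threshold multiplier for [discretize()].
#' @param criterion mRMR criterion, `"difference"` or `"quotient"`.
#' @param step,max_size IFS sweep controls (see [run_ifs()]).
#' @param n_folds cross-validation folds.
#' @param smote_k,smote_scope SMOTE controls (see [evaluate_subset()]).
#' @param rules_balance train the rule tree on the SMOTE-balanced table
#'   (default `TRUE`); `FALSE` uses the raw table.
#' @param seed master seed; every module seed derives from it.
#' @param table_path internal (used by [replay_run()]): read the input table
#'   from this matrix file instead of `table`/`spec`.
#' @return Invisibly, a list with the run directory and all in-memory
#'   results (`table`, `ranking`, `ifs` per learner, `global`, `tree`,
#'   `rules`, `manifest`).
#' @export
run_pipeline <- function(table = NULL, spec = NULL, out_dir,
                         learners = c("knn", "dt"),
                         learner_params = list(),
                         t = 1, criterion = "difference",
                         step = 1, max_size = NULL, n_folds = 10,
                         smote_k = 5, smote_scope = "fold",
                         rules_balance = TRUE, seed = 1L,
                         table_path = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input <- NULL
  truth <- NULL
  if (!is.null(table_path)) {
    table <- read_abundance_table(table_path,
                                  labels = paste0(table_path, ".labels.tsv"))
    input <- list(type = "file", path = table_path)
  } else if (is.null(table)) {
    if (is.null(spec)) stop("supply a table, a spec, or a table_path", call. = FALSE)
    gen <- generate_table(spec)
    table <- gen$table
    truth <- gen$truth
    write_ground_truth(truth, file.path(out_dir, "ground_truth.tsv"))
    input <- list(type = "synthetic", spec = unclass(spec))
  } else {
    input <- list(type = "file",
                  path = normalizePath(file.path(out_dir, "input_table.tsv"),
                                       mustWork = FALSE))
  }
  validate_abundance_table(table)
  write_abundance_table(table, file.path(out_dir, "input_table.tsv"))

  ranking <- mrmr_rank(table, t = t, criterion = criterion)
  write_feature_list(ranking, file.path(out_dir, "ranking.tsv"))

  results <- list()
  for (nm in learners) {
    lrn <- do.call(learner, c(list(name = nm), learner_params[[nm]] %||% list()))
    res <- run_ifs(table, ranking, lrn, step = step, max_size = max_size,
                   n_folds = n_folds, smote_scope = smote_scope,
                   smote_k = smote_k, seed = seed)
    results[[nm]] <- res
    write_ifs_table(res, file.path(out_dir, paste0("ifs_", nm, ".tsv")))
    write_feature_list(ranking[seq_len(res$optimum_size), ],
                       file.path(out_dir, paste0("optimum_features_", nm, ".tsv")))
  }

  global <- select_global_optimum(results)
  write_tsv_exact(
    purrr::map_dfr(results, glance) |>
      dplyr::mutate(global_optimum = .data$learner == global$learner),
    file.path(out_dir, "global_optimum.tsv")
  )
  write_feature_list(ranking[seq_len(global$result$optimum_size), ],
                     file.path(out_dir, "optimum_features_global.tsv"))

  # Rules come from a CART on the decision-tree optimum subset (the tree is
  # the interpretable model); fall back to the global optimum subset when no
  # "dt" learner was run.
  rule_basis <- if ("dt" %in% names(results)) results[["dt"]] else global$result
  rule_features <- rule_basis$optimum_features
  rules_table <- table[, c("sample_id", "label", rule_features)]
  if (rules_balance) {
    rules_table <- smote_balance(rules_table, k_neighbors = smote_k,
                                 seed = derive_seed(seed, 3))
  }
  dt_params <- learner_params[["dt"]] %||% list()
  tree <- cart_fit(rules_table, taxa = rule_features,
                   min_samples_split = dt_params$min_samples_split %||% 2,
                   max_depth = dt_params$max_depth %||% Inf)
  rules <- extract_rules(tree)
  write_rules(rules, file.path(out_dir, "rules.tsv"),
              text_path = file.path(out_dir, "rules.txt"))
  readr::write_tsv(rule_counts(rules), file.path(out_dir, "rule_counts.tsv"),
                   progress = FALSE)

  manifest <- list(
    package = "taxarules",
    version = as.character(utils::packageVersion("taxarules")),
    input = input,
    config = list(
      learners = learners,
      learner_params = learner_params,
      t = t, criterion = criterion, step = step, max_size = max_size,
      n_folds = n_folds, smote_k = smote_k, smote_scope = smote_scope,
      rules_balance = rules_balance, seed = as.integer(seed)
    ),
    defaults_in_effect = list(
      knn_k = (learner_params$knn$k %||% 1),
      rf_n_trees = (learner_params$rf$n_trees %||% 100),
      discretization_t = t,
      smote_k = smote_k,
      smote_scope = smote_scope
    ),
    files = sort(setdiff(list.files(out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(dir = out_dir, table = table, truth = truth,
                 ranking = ranking, ifs = results, global = global,
                 tree = tree, rules = rules, manifest = manifest))
}

#' Replay a pipeline run from its manifest
#'
#' Re-executes [run_pipeline()] with exactly the configuration recorded in a
#' run's `manifest.json`. Because every source of randomness derives from
#' the recorded master seed, the replay writes byte-identical artifacts.
#'
#' @param manifest_path path to a run's `manifest.json`.
#' @param out_dir directory for the replayed run.
#' @return Invisibly, the [run_pipeline()] result of the replay.
#' @export
replay_run <- function(manifest_path, out_dir) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  args <- list(
    out_dir = out_dir,
    learners = cfg$learners,
    learner_params = cfg$learner_params %||% list(),
    t = cfg$t, criterion = cfg$criterion, step = cfg$step,
    max_size = cfg$max_size, n_folds = cfg$n_folds,
    smote_k = cfg$smote_k, smote_scope = cfg$smote_scope,
    rules_balance = cfg$rules_balance, seed = cfg$seed
  )
  if (identical(man$input$type, "synthetic")) {
    sp <- man$input$spec
    args$spec <- synthetic_spec(
      n_classes = sp$n_classes, class_sizes = sp$class_sizes,
      n_informative = sp$n_informative, n_redundant = sp$n_redundant,
      n_noise = sp$n_noise, effect_size = sp$effect_size,
      within_class_sd = sp$within_class_sd,
      redundancy_corr = sp$redundancy_corr,
      zero_inflation = sp$zero_inflation, seed = sp$seed
    )
  } else {
    args$table_path <- man$input$path
  }
  do.call(run_pipeline, args)
}

#' Compare the optimum feature sets of two runs
#'
#' Set arithmetic over two feature sets — the analogue of comparing the key
#' taxa selected on two alternative profiling variants of the same cohort.
#'
#' @param a,b run directories (their `optimum_features_global.tsv` is read),
#'   `ifs_result` objects, or character vectors of taxon ids.
#' @return A list with `common`, `only_a`, `only_b` (character vectors) and
#'   `summary`, a one-row tibble (`n_a`, `n_b`, `n_common`, `jaccard`).
#' @export
compare_runs <- function(a, b) {
  as_features <- function(x) {
    if (is.character(x) && length(x) == 1 && dir.exists(x)) {
      read_feature_list(file.path(x, "optimum_features_global.tsv"))$taxon_id
    } else if (inherits(x, "ifs_result")) {
      x$optimum_features
    } else {
      as.character(x)
    }
  }
  fa <- as_features(a)
  fb <- as_features(b)
  common <- intersect(fa, fb)
  list(
    common = common,
    only_a = setdiff(fa, fb),
    only_b = setdiff(fb, fa),
    summary = tibble::tibble(
      n_a = length(fa), n_b = length(fb), n_common = length(common),
      jaccard = length(common) / length(union(fa, fb))
    )
  )
}
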