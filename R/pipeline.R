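#' End-to-end prioritization pipeline
#'
#' `run_pipeline()` orchestrates the full study workflow — simulate (or
#' load) descriptor tables, curate, build category schemas, train the two
#' competing predictors, predict on the application set, assess
#' applicability domains, and evaluate — from a single configuration list,
#' writing versioned outputs and a reproducibility manifest (input/output
#' checksums, config hash, seeds). Rerunning with an identical config
#' reproduces every output bitwise.
#'
#' @name pipeline
NULL

.PIPELINE_STAGES <- c("simulate", "curate", "categorize", "train",
                      "predict", "ad", "evaluate")

default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "toxprio-run",
    simulate = list(),          # generator_config() arguments, or NULL
    paths = NULL,               # list(replicates = c(3 paths), application =,
                                #      metadata =) when loading real tables
    curation = list(),          # curate() arguments
    schemas = c("ghs", "kmeans"),
    kmeans = list(k = 4L, n_boot = 500L, train_frac = 0.9),
    split = list(frac = 0.9),
    grids = list(regression = NULL, classification = NULL),
    folds = 3L,
    importance = "permutation",
    importance_threshold = 0.01,
    ad_subsets = c("full", "regression", "classification")
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults and returns an itemized error list (as an error) when the
#' config cannot support the requested stages.
#'
#' @param config configuration list (see [default_run_config()] internals;
#'   any subset of its fields).
#' @param stages stages to be run.
#' @return the completed config, invisibly errors otherwise.
#' @export
validate_run_config <- function(config, stages = .PIPELINE_STAGES) {
  full <- default_run_config()
  full[names(config)] <- config
  problems <- character(0)
  bad_stage <- setdiff(stages, .PIPELINE_STAGES)
  if (length(bad_stage))
    problems <- c(problems, paste("unknown stage(s):",
                                  paste(bad_stage, collapse = ", ")))
  has_sim <- "simulate" %in% stages && !is.null(full$simulate)
  if (!has_sim && any(c("curate") %in% stages)) {
    p <- full$paths
    if (is.null(p))
      problems <- c(problems,
                    "no simulate stage and no input paths configured")
    else {
      if (length(p$replicates) != 3L)
        problems <- c(problems, "paths$replicates must list three files")
      missing <- c(p$replicates, p$application)[!file.exists(
        c(p$replicates, p$application))]
      if (length(missing))
        problems <- c(problems, paste("missing input file(s):",
                                      paste(missing, collapse = ", ")))
    }
  }
  if ("ad" %in% stages &&
      !any(c("simulate", "curate") %in% stages) && is.null(full$paths))
    problems <- c(problems, "stage 'ad' needs an application table")
  if (!all(full$schemas %in% c("ghs", "kmeans")))
    problems <- c(problems, "schemas must be among 'ghs', 'kmeans'")
  if (length(problems))
    stop("invalid pipeline config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  full
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the prioritization pipeline
#'
#' @param config configuration list; missing fields take defaults.
#' @param stages subset of
#'   `c("simulate", "curate", "categorize", "train", "predict", "ad",
#'   "evaluate")`, run in canonical order.
#' @return the run manifest (also written to `manifest.json` in the output
#'   directory), listing per-stage outputs with md5 checksums, the config
#'   hash and all seeds. The full in-memory state (tables, schemas, models,
#'   reports) is attached as attribute `"state"`.
#' @export
run_pipeline <- function(config = list(), stages = .PIPELINE_STAGES) {
  config <- validate_run_config(config, stages)
  stages <- intersect(.PIPELINE_STAGES, stages)  # canonical order
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  state <- list()
  outputs <- character(0)

  need <- function(what, from) {
    if (is.null(state[[what]]))
      stop("stage '", from, "' needs '", what,
           "' from an earlier stage (or configured paths)", call. = FALSE)
  }
  emit <- function(path) outputs <<- c(outputs, path)

  if ("simulate" %in% stages && !is.null(config$simulate)) {
    gc <- do.call(generator_config, c(config$simulate, list(seed = seed)))
    tr <- generate_training(gc)
    app <- generate_application(gc)
    state$replicates <- tr$replicates
    state$chemicals <- tr$chemicals
    state$application <- app$table
    for (r in 1:3) {
      f <- file.path(outdir, sprintf("training_replicate%d.csv", r))
      write_descriptor_table(tr$replicates[[r]], f); emit(f)
    }
    f <- file.path(outdir, "application.csv")
    write_descriptor_table(app$table, f); emit(f)
    f <- file.path(outdir, "metadata.csv")
    utils::write.csv(tr$chemicals, f, row.names = FALSE); emit(f)
  } else if (!is.null(config$paths)) {
    meta <- NULL
    if (!is.null(config$paths$metadata))
      meta <- utils::read.csv(config$paths$metadata,
                              stringsAsFactors = FALSE)
    state$replicates <- lapply(seq_along(config$paths$replicates),
                               function(i) load_descriptor_table(
                                 config$paths$replicates[i],
                                 metadata = meta, replicate_id = i))
    state$chemicals <- state$replicates[[1L]]$chemicals
    state$application <- load_descriptor_table(config$paths$application)
  }

  if ("curate" %in% stages) {
    need("replicates", "curate"); need("application", "curate")
    cur <- do.call(curate, c(list(state$replicates, state$application),
                             config$curation))
    state$training <- cur$training
    state$application_curated <- cur$application
    state$curation_report <- cur$report
    f <- file.path(outdir, "curated_training.csv")
    write_descriptor_table(cur$training, f); emit(f)
    f <- file.path(outdir, "curated_application.csv")
    write_descriptor_table(cur$application, f); emit(f)
    f <- file.path(outdir, "curation_report.json")
    write_curation_report(cur$report, f); emit(f)
    pca <- pca_scores(cur$training$values)
    f <- file.path(outdir, "pca_scores.csv")
    utils::write.csv(data.frame(id = chemical_ids(cur$training),
                                pca$scores), f, row.names = FALSE)
    emit(f)
  }

  if ("categorize" %in% stages) {
    need("chemicals", "categorize")
    chem <- state$chemicals
    state$schemas <- list()
    if ("ghs" %in% config$schemas) {
      state$schemas$ghs <- ghs_schema()
      f <- file.path(outdir, "schema_ghs.json")
      write_schema(state$schemas$ghs, f); emit(f)
    }
    if ("kmeans" %in% config$schemas) {
      km <- config$kmeans
      state$schemas$kmeans <- fit_kmeans_categorizer(
        cbind(log10(chem$lc50), chem$monoisotopic_mass),
        k = km$k %||% 4L, n_boot = km$n_boot %||% 500L,
        train_frac = km$train_frac %||% 0.9, seed = seed)
      f <- file.path(outdir, "schema_kmeans.json")
      write_schema(state$schemas$kmeans, f); emit(f)
    }
    lab <- data.frame(id = chem$id, stringsAsFactors = FALSE)
    for (nm in names(state$schemas))
      lab[[nm]] <- assign_category(state$schemas[[nm]], chem$lc50,
                                   chem$monoisotopic_mass)
    state$training_categories <- lab
    f <- file.path(outdir, "training_categories.csv")
    utils::write.csv(lab, f, row.names = FALSE); emit(f)
  }

  if ("train" %in% stages) {
    need("training", "train"); need("schemas", "train")
    X <- state$training$values
    chem <- state$chemicals
    y <- log10(chem$lc50)
    state$split <- split_train_test(nrow(X), config$split$frac %||% 0.9,
                                    seed = seed)
    tr_i <- state$split$train
    state$regressor <- train_model(
      X[tr_i, , drop = FALSE], y[tr_i], "regression",
      grid = config$grids$regression, folds = config$folds, seed = seed,
      importance = config$importance,
      importance_threshold = config$importance_threshold)
    f <- file.path(outdir, "model_regression.rds")
    write_model(state$regressor, f); emit(f); emit(paste0(f, ".json"))
    state$classifiers <- list()
    for (nm in names(state$schemas)) {
      labels <- state$training_categories[[nm]]
      state$classifiers[[nm]] <- train_model(
        X[tr_i, , drop = FALSE], labels[tr_i], "classification",
        grid = config$grids$classification, folds = config$folds,
        seed = seed, importance = config$importance,
        importance_threshold = config$importance_threshold,
        schema = state$schemas[[nm]])
      f <- file.path(outdir, sprintf("model_classifier_%s.rds", nm))
      write_model(state$classifiers[[nm]], f); emit(f)
      emit(paste0(f, ".json"))
    }
  }

  if ("predict" %in% stages) {
    need("regressor", "predict"); need("application_curated", "predict")
    app <- state$application_curated
    pred <- data.frame(id = chemical_ids(app), stringsAsFactors = FALSE)
    pred$log_lc50_pred <- predict_lc50(state$regressor, app$values)
    masses <- app$chemicals$monoisotopic_mass
    for (nm in names(state$schemas)) {
      pred[[paste0("two_step_", nm)]] <- two_step_categorize(
        state$regressor, state$schemas[[nm]], app$values, masses)
      pred[[paste0("direct_", nm)]] <- predict_category_direct(
        state$classifiers[[nm]], app$values)
    }
    state$application_predictions <- pred
    f <- file.path(outdir, "application_predictions.csv")
    utils::write.csv(pred, f, row.names = FALSE); emit(f)
  }

  if ("ad" %in% stages) {
    need("training", "ad"); need("application_curated", "ad")
    X <- state$training$values
    subsets <- list()
    if ("full" %in% config$ad_subsets)
      subsets$full <- colnames(X)
    if ("regression" %in% config$ad_subsets && !is.null(state$regressor))
      subsets$regression <- state$regressor$selected_variables
    if ("classification" %in% config$ad_subsets &&
        length(state$classifiers))
      subsets$classification <-
        state$classifiers[[1L]]$selected_variables
    reports <- lapply(names(subsets), function(nm) {
      m <- build_leverage_model(X[, subsets[[nm]], drop = FALSE],
                                subset_name = nm)
      ad_assess(m, state$application_curated)
    })
    names(reports) <- names(subsets)
    state$ad_reports <- reports
    f_csv <- file.path(outdir, "ad_report.csv")
    f_json <- file.path(outdir, "ad_summary.json")
    write_ad_report(reports, f_csv, f_json); emit(f_csv); emit(f_json)
  }

  if ("evaluate" %in% stages) {
    need("regressor", "evaluate"); need("split", "evaluate")
    X <- state$training$values
    chem <- state$chemicals
    te <- state$split$test
    obs <- log10(chem$lc50)[te]
    prd <- predict_lc50(state$regressor, X[te, , drop = FALSE])
    eval_out <- list(
      regression = list(
        r_squared_test = r_squared(obs, prd),
        pearson_test = pearson(obs, prd),
        r_squared_train = state$regressor$train_score,
        cv_scores = state$regressor$cv_scores,
        cv_median = stats::median(unlist(state$regressor$cv_scores)),
        residuals = residual_summary(obs, prd)[
          c("fraction_within_band", "band", "quantiles")]))
    masses <- chem$monoisotopic_mass[te]
    state$comparisons <- list()
    for (nm in names(state$schemas)) {
      truth <- state$training_categories[[nm]][te]
      preds <- list(
        two_step = two_step_categorize(state$regressor,
                                       state$schemas[[nm]],
                                       X[te, , drop = FALSE], masses),
        direct = predict_category_direct(state$classifiers[[nm]],
                                         X[te, , drop = FALSE]))
      cmp <- compare_methods(truth, preds, state$schemas[[nm]])
      state$comparisons[[nm]] <- cmp
      f <- file.path(outdir, sprintf("comparison_%s.json", nm))
      write_comparison_report(cmp, f); emit(f)
      eval_out[[paste0("categories_", nm)]] <- list(
        misclassified = as.list(cmp$misclassified),
        accuracy = lapply(cmp$per_method, `[[`, "accuracy"),
        agreement_two_step_vs_direct = cmp$agreement["two_step", "direct"])
    }
    state$evaluation <- eval_out
    f <- file.path(outdir, "evaluation.json")
    jsonlite::write_json(eval_out, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE); emit(f)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("toxprio")),
    config = config, config_hash = config_hash(config), seed = seed,
    stages = stages,
    outputs = lapply(outputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(manifest, "state") <- state
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
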