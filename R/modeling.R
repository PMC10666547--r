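#' Random-forest QSAR modeling
#'
#' Two competing predictors are built from the curated descriptors:
#'
#' * a **regression** forest on log10 LC50 (mg/L), later thresholded into
#'   categories (the conventional two-step QSAR route), and
#' * a **direct classification** forest that predicts the toxicity category
#'   straight from descriptors.
#'
#' Both are tuned on a (number of trees, minimum leaf size) grid by k-fold
#' cross-validation with per-tree feature subsampling of floor(sqrt(p))
#' variables, then reduced to the variables whose out-of-bag importance
#' exceeds 1% of the largest, and refit on the full data.
#'
#' @name qsar-modeling
NULL

#' Default hyperparameter grids
#'
#' The regression grid spans 100-1000 trees (10 log-spaced values) and leaf
#' sizes 1-21 (step 2). The classification grid uses 20 steps over 200-2000
#' trees and 20 steps over leaf sizes 1-21 (rounded to unique integers).
#'
#' @return list with integer vectors `n_trees` and `min_leaf`.
#' @export
default_grid <- function(task = c("regression", "classification")) {
  task <- match.arg(task)
  if (task == "regression") {
    list(n_trees = unique(round(exp(seq(log(100), log(1000),
                                        length.out = 10L)))),
         min_leaf = seq(1L, 21L, by = 2L))
  } else {
    list(n_trees = unique(round(seq(200L, 2000L, length.out = 20L))),
         min_leaf = unique(round(seq(1L, 21L, length.out = 20L))))
  }
}

#' Split chemicals into training and test sets
#'
#' @param n number of chemicals.
#' @param frac training fraction (default 0.9); the training size is
#'   `round(frac * n)`.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test` (disjoint, covering
#'   `1:n`).
#' @export
split_train_test <- function(n, frac = 0.9, seed = 1L) {
  if (n < 2L) stop("need at least 2 chemicals to split")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  n_train <- round(frac * n)
  if (n_train < 1L || n_train >= n)
    stop("degenerate split: ", n_train, " train of ", n)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  list(train = train, test = setdiff(seq_len(n), train))
}

validate_xy <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("D", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete")
  X
}

ranger_fit <- function(X, y, task, n_trees, min_leaf, seed,
                       importance = "none") {
  if (task == "classification" && !is.factor(y)) y <- factor(y)
  df <- data.frame(..y = y, X, check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = "..y", data = df,
    num.trees = n_trees, min.node.size = min_leaf,
    mtry = max(1L, floor(sqrt(ncol(X)))),
    importance = importance, seed = seed, num.threads = 1L,
    verbose = FALSE)
}

score_predictions <- function(task, observed, predicted) {
  if (task == "regression") r_squared(observed, predicted)
  else mean(as.character(observed) == as.character(predicted))
}

#' Grid search with k-fold cross-validation
#'
#' Evaluates every (n_trees, min_leaf) cell by k-fold cross-validation
#' (mean R-squared for regression, mean accuracy for classification), picks
#' the best cell (ties: fewer trees, then larger leaves), refits it on the
#' full data and returns its out-of-bag variable importances.
#'
#' @param X numeric matrix of (curated, scaled) descriptors.
#' @param y numeric response (log10 LC50) or factor/character labels.
#' @param task `"regression"` or `"classification"`.
#' @param grid list with `n_trees` and `min_leaf` vectors; defaults to
#'   [default_grid()] for the task.
#' @param folds number of CV folds (default 3).
#' @param seed integer seed controlling fold assignment and all forests.
#' @param importance out-of-bag importance type at the best cell:
#'   `"permutation"` (default) or `"impurity"`.
#' @return list with `best` (n_trees, min_leaf), `cv_table` (one row per
#'   cell with the per-fold and mean scores), `importances` (named vector)
#'   and `best_fit` (the refit ranger object).
#' @export
grid_search <- function(X, y, task = c("regression", "classification"),
                        grid = NULL, folds = 3L, seed = 1L,
                        importance = c("permutation", "impurity")) {
  task <- match.arg(task)
  importance <- match.arg(importance)
  X <- validate_xy(X, y)
  if (is.null(grid)) grid <- default_grid(task)
  stopifnot(length(grid$n_trees) >= 1L, length(grid$min_leaf) >= 1L,
            all(grid$n_trees >= 1L), all(grid$min_leaf >= 1L), folds >= 2L)
  if (task == "classification") y <- factor(y)

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), nrow(X)))
  if (task == "classification") {
    for (f in seq_len(folds)) {
      if (nlevels(droplevels(y[fold_id == f])) < 2L)
        stop("fold ", f, " contains a single class; cannot cross-validate")
    }
  }

  cells <- expand.grid(n_trees = grid$n_trees, min_leaf = grid$min_leaf,
                       KEEP.OUT.ATTRS = FALSE)
  scores <- matrix(NA_real_, nrow(cells), folds)
  for (i in seq_len(nrow(cells))) {
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- ranger_fit(X[tr, , drop = FALSE], y[tr], task,
                        cells$n_trees[i], cells$min_leaf[i],
                        seed = seed + f)
      # explicit seed: ranger breaks classification vote ties randomly
      pred <- stats::predict(fit,
                             data.frame(X[!tr, , drop = FALSE],
                                        check.names = FALSE),
                             num.threads = 1L,
                             seed = seed + f)$predictions
      scores[i, f] <- score_predictions(task, y[!tr], pred)
    }
  }
  mean_score <- rowMeans(scores)
  # ties: fewer trees, then larger min_leaf (parsimony)
  ord <- order(-mean_score, cells$n_trees, -cells$min_leaf)
  best_i <- ord[1L]
  best <- list(n_trees = cells$n_trees[best_i],
               min_leaf = cells$min_leaf[best_i])

  best_fit <- ranger_fit(X, y, task, best$n_trees, best$min_leaf,
                         seed = seed, importance = importance)
  imp <- best_fit$variable.importance
  imp[imp < 0] <- 0  # permutation importance can go slightly negative

  cv_table <- cbind(cells, scores, mean = mean_score)
  names(cv_table)[2L + seq_len(folds)] <- paste0("fold", seq_len(folds))
  list(best = best, cv_table = cv_table,
       cv_scores = scores[best_i, ], importances = imp, best_fit = best_fit)
}

#' Select variables by relative importance
#'
#' Divides every importance by the largest one and keeps the variables
#' contributing strictly more than `threshold` (default 1%).
#'
#' @param importances named numeric vector of nonnegative importances.
#' @param threshold relative-importance cutoff (default 0.01).
#' @return character vector of selected variable names (input order).
#' @export
select_by_relative_importance <- function(importances, threshold = 0.01) {
  if (!length(importances) || all(importances <= 0))
    stop("all importances are zero; nothing to select")
  names(importances)[importances / max(importances) > threshold]
}

#' Fit the final model on selected variables
#'
#' Refits the forest at the chosen hyperparameters on the supplied data
#' restricted to the selected variables, recording the training score
#' (R-squared or accuracy) and the out-of-bag score.
#'
#' @param X descriptor matrix containing at least the selected variables.
#' @param y response (numeric log10 LC50) or labels.
#' @param selected_variables character vector of descriptor names.
#' @param hyperparams list with `n_trees` and `min_leaf`.
#' @param task `"regression"` or `"classification"`.
#' @param seed integer seed.
#' @param schema optional `toxicity_schema` recorded with classification
#'   models (labels of the prediction).
#' @param cv_scores optional per-fold CV scores to carry along.
#' @param importance importance type stored on the final fit.
#' @return a `trained_model`.
#' @export
fit_final <- function(X, y, selected_variables, hyperparams,
                      task = c("regression", "classification"), seed = 1L,
                      schema = NULL, cv_scores = NULL,
                      importance = c("permutation", "impurity")) {
  task <- match.arg(task)
  importance <- match.arg(importance)
  X <- validate_xy(X, y)
  miss <- setdiff(selected_variables, colnames(X))
  if (length(miss))
    stop("selected variables missing from X: ", paste(miss, collapse = ", "))
  Xs <- X[, selected_variables, drop = FALSE]
  if (task == "classification") y <- factor(y)
  fit <- ranger_fit(Xs, y, task, hyperparams$n_trees, hyperparams$min_leaf,
                    seed = seed, importance = importance)
  train_pred <- stats::predict(
    fit, data.frame(Xs, check.names = FALSE), num.threads = 1L,
    seed = seed)$predictions
  oob_score <- if (task == "regression") fit$r.squared
               else 1 - fit$prediction.error
  structure(list(task = task, selected_variables = selected_variables,
                 hyperparams = hyperparams,
                 importances = fit$variable.importance,
                 cv_scores = cv_scores,
                 train_score = score_predictions(task, y, train_pred),
                 oob_score = oob_score, seed = seed, schema = schema,
                 ensemble = fit),
            class = "trained_model")
}

#' Train a predictor end to end
#'
#' Convenience wrapper: grid search, >threshold relative-importance variable
#' selection, final refit on the full supplied data with the selected
#' variables.
#'
#' @inheritParams grid_search
#' @param importance_threshold relative-importance cutoff (default 0.01).
#' @param schema recorded with classification models.
#' @return a `trained_model` whose `tuning` element holds the grid-search
#'   result.
#' @export
train_model <- function(X, y, task = c("regression", "classification"),
                        grid = NULL, folds = 3L, seed = 1L,
                        importance = c("permutation", "impurity"),
                        importance_threshold = 0.01, schema = NULL) {
  task <- match.arg(task)
  importance <- match.arg(importance)
  gs <- grid_search(X, y, task, grid, folds, seed, importance)
  selected <- select_by_relative_importance(gs$importances,
                                            importance_threshold)
  model <- fit_final(X, y, selected, gs$best, task, seed, schema,
                     cv_scores = gs$cv_scores, importance = importance)
  model$tuning <- gs[c("best", "cv_table")]
  model
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model (", x$task, "): ", length(x$selected_variables),
      " variables, ", x$hyperparams$n_trees, " trees, min leaf ",
      x$hyperparams$min_leaf, "\n  train score ",
      format(x$train_score, digits = 3), ", OOB score ",
      format(x$oob_score, digits = 3), "\n", sep = "")
  invisible(x)
}

model_matrix <- function(model, X) {
  X <- as.matrix(X)
  miss <- setdiff(model$selected_variables, colnames(X))
  if (length(miss))
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "))
  X[, model$selected_variables, drop = FALSE]
}

#' Predict log10 LC50 with a regression model
#'
#' @param model a `trained_model` with task `"regression"`.
#' @param X descriptor matrix containing the model's selected variables.
#' @return numeric vector of predicted log10 LC50 (mg/L), one per row.
#' @export
predict_lc50 <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  if (model$task != "regression") stop("model is not a regression model")
  Xs <- model_matrix(model, X)
  stats::predict(model$ensemble, data.frame(Xs, check.names = FALSE),
                 num.threads = 1L, seed = model$seed)$predictions
}

#' Predict toxicity categories directly from descriptors
#'
#' @param model a `trained_model` with task `"classification"`.
#' @param X descriptor matrix containing the model's selected variables.
#' @return character vector of category labels.
#' @export
predict_category_direct <- function(model, X) {
  stopifnot(inherits(model, "trained_model"))
  if (model$task != "classification") stop("model is not a classifier")
  Xs <- model_matrix(model, X)
  # explicit seed: ranger breaks classification vote ties randomly
  as.character(stats::predict(
    model$ensemble, data.frame(Xs, check.names = FALSE),
    num.threads = 1L, seed = model$seed)$predictions)
}

#' Two-step categorization: regression then threshold
#'
#' Predicts log10 LC50 with the regression model, converts back to mg/L and
#' applies the schema: GHS thresholds for a GHS schema, nearest-centroid
#' assignment on (predicted log LC50, mass) for a k-means schema.
#'
#' @param regressor a regression `trained_model`.
#' @param schema a `toxicity_schema`.
#' @param X descriptor matrix.
#' @param masses monoisotopic masses (Da), required for k-means schemas.
#' @return character vector of category labels.
#' @export
two_step_categorize <- function(regressor, schema, X, masses = NULL) {
  stopifnot(inherits(schema, "toxicity_schema"))
  pred_log <- predict_lc50(regressor, X)
  if (schema$provenance == "ghs") return(assign_ghs(10^pred_log))
  if (is.null(masses))
    stop("monoisotopic masses are required for a k-means schema")
  if (length(masses) != length(pred_log))
    stop("masses must match the number of rows of X")
  assign_kmeans(schema, cbind(pred_log, masses))
}

#' Persist / restore a trained model
#'
#' The fitted ensemble is stored with `saveRDS`; a JSON sidecar next to it
#' records the task, hyperparameters, selected variables, scores and seed
#' so runs can be audited without loading the binary.
#'
#' @param model a `trained_model`.
#' @param path output `.rds` path (sidecar gets `.json` appended).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  side <- list(task = model$task, hyperparams = model$hyperparams,
               selected_variables = model$selected_variables,
               train_score = model$train_score, oob_score = model$oob_score,
               cv_scores = model$cv_scores, seed = model$seed,
               schema_labels = model$schema$labels,
               package_version = as.character(utils::packageVersion("toxprio")))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "trained_model"))
  model
}
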