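#' Descriptor curation
#'
#' Curation removes descriptors that cannot be trusted or carry no usable
#' signal before any model sees them. Four filters run in a fixed order:
#'
#' 1. *Replicate stability*: descriptors whose values differ between
#'    replicate calculations of the same chemicals (non-converged structure
#'    optimizations) are dropped.
#' 2. *Missing values*: descriptors with more than `max_missing` missing in
#'    the training table are dropped; remaining missing cells are imputed
#'    with the training-column median.
#' 3. *Max-scaling + variance filter*: each column is divided by its maximum
#'    absolute training value, then columns are kept according to their
#'    scaled sample variance relative to `var_threshold`.
#' 4. *Cross-set ratio filter*: descriptors whose maximum magnitude in the
#'    application set exceeds `ratio_threshold` times the training scaling
#'    factor are dropped from both sets.
#'
#' Each removal is attributed to the first filter that triggers it.
#'
#' @name curation
NULL

#' Detect replicate-unstable descriptors
#'
#' A descriptor is unstable if, for any chemical, the spread of its values
#' across the three replicate calculations is too large: the max pairwise
#' deviation exceeds `rel_tol` relative to the maximum absolute value across
#' replicates, or exceeds `abs_tol` when that maximum is zero.
#'
#' @param replicates list of exactly three `descriptor_table`s sharing
#'   identical chemicals and descriptor names.
#' @param rel_tol relative tolerance (default 1e-6).
#' @param abs_tol absolute tolerance used where all replicate values are 0.
#' @return character vector of unstable descriptor names.
#' @export
replicate_stability <- function(replicates, rel_tol = 1e-6, abs_tol = 1e-9) {
  if (length(replicates) != 3L) stop("exactly three replicates required")
  lapply(replicates, function(r) stopifnot(inherits(r, "descriptor_table")))
  ids <- chemical_ids(replicates[[1L]])
  nms <- descriptor_names(replicates[[1L]])
  for (r in replicates[-1L]) {
    if (!identical(chemical_ids(r), ids))
      stop("replicates do not share the same chemicals")
    if (!identical(descriptor_names(r), nms))
      stop("replicates do not share the same descriptors")
  }
  v1 <- replicates[[1L]]$values
  v2 <- replicates[[2L]]$values
  v3 <- replicates[[3L]]$values
  hi <- pmax(v1, v2, v3, na.rm = FALSE)
  lo <- pmin(v1, v2, v3, na.rm = FALSE)
  spread <- hi - lo
  scale <- pmax(abs(v1), abs(v2), abs(v3))
  # relative criterion where the scale is nonzero, absolute where it is 0
  bad <- ifelse(scale > 0, spread > rel_tol * scale, spread > abs_tol)
  bad[is.na(bad)] <- FALSE  # missing cells cannot witness instability
  nms[apply(bad, 2L, any)]
}

#' Fit max-scaling factors on a training table
#'
#' The scaling factor of a descriptor is the maximum *absolute* value of its
#' column over the training set, so that scaled training values lie in
#' \[-1, 1\]. All-zero columns get factor 0 and are flagged for removal.
#'
#' @param training a `descriptor_table`.
#' @return a list with `factors` (named numeric vector) and `zero_columns`
#'   (names of constant-zero descriptors).
#' @export
fit_scaling <- function(training) {
  stopifnot(inherits(training, "descriptor_table"))
  if (nrow(training$values) < 1L) stop("training table is empty")
  factors <- apply(abs(training$values), 2L, max, na.rm = TRUE)
  factors[!is.finite(factors)] <- 0  # all-missing column
  list(factors = factors, zero_columns = names(factors)[factors == 0])
}

#' Apply training scaling factors to a table
#'
#' Training-set factors are applied unchanged to application sets, so scaled
#' application values may exceed 1 in magnitude. Missing cells stay missing.
#'
#' @param table a `descriptor_table`.
#' @param factors named numeric vector covering all columns of `table`.
#' @return a scaled `descriptor_table`.
#' @export
apply_scaling <- function(table, factors) {
  stopifnot(inherits(table, "descriptor_table"))
  nms <- descriptor_names(table)
  missing <- setdiff(nms, names(factors))
  if (length(missing))
    stop("no scaling factor for: ", paste(missing, collapse = ", "))
  f <- factors[nms]
  if (any(f == 0))
    stop("scaling factor 0 for retained column(s): ",
         paste(nms[f == 0], collapse = ", "))
  descriptor_table(sweep(table$values, 2L, f, "/"),
                   chemicals = table$chemicals,
                   replicate_id = table$replicate_id)
}

#' Variance filter on a scaled table
#'
#' Computes the sample variance (n - 1 denominator) of every scaled column
#' and keeps descriptors on one side of `threshold`. The default keeps
#' columns with variance strictly below the threshold; set
#' `keep = "above"` for conventional low-variance pruning instead.
#'
#' @param scaled a scaled `descriptor_table`.
#' @param threshold variance threshold (default 0.1).
#' @param keep `"below"` (keep var < threshold, the default) or `"above"`
#'   (keep var >= threshold).
#' @return character vector of kept descriptor names.
#' @export
variance_filter <- function(scaled, threshold = 0.1,
                            keep = c("below", "above")) {
  stopifnot(inherits(scaled, "descriptor_table"))
  keep <- match.arg(keep)
  if (nrow(scaled$values) < 2L) stop("variance needs at least 2 chemicals")
  v <- apply(scaled$values, 2L, stats::var, na.rm = TRUE)
  nms <- descriptor_names(scaled)
  if (keep == "below") nms[v < threshold] else nms[v >= threshold]
}

#' Cross-set ratio filter
#'
#' A descriptor is unstable across data sets when its maximum magnitude in
#' the application set is more than `ratio_threshold` times its training
#' scaling factor; such descriptors are removed from both sets. A training
#' factor of 0 with any nonzero application value also triggers removal.
#'
#' @param train_factors named numeric vector of training scaling factors.
#' @param app_table the (unscaled) application `descriptor_table`.
#' @param ratio_threshold removal threshold on the max-abs ratio (default 100).
#' @return character vector of removed descriptor names.
#' @export
ratio_filter <- function(train_factors, app_table, ratio_threshold = 100) {
  stopifnot(inherits(app_table, "descriptor_table"))
  shared <- intersect(names(train_factors), descriptor_names(app_table))
  app_max <- apply(abs(app_table$values[, shared, drop = FALSE]), 2L, max,
                   na.rm = TRUE)
  app_max[!is.finite(app_max)] <- 0
  f <- train_factors[shared]
  removed <- ifelse(f == 0, app_max > 0, app_max / f > ratio_threshold)
  shared[removed]
}

impute_median <- function(values, medians) {
  for (j in seq_len(ncol(values))) {
    nas <- is.na(values[, j])
    if (any(nas)) values[nas, j] <- medians[j]
  }
  values
}

#' Curate training replicates and an application table
#'
#' Runs the full curation cascade (see [curation]) and returns the curated
#' training table (replicate 1 after filtering and imputation, scaled), the
#' curated application table (scaled with *training* factors), and a
#' `curation_report` partitioning every original descriptor into kept /
#' removed-by-reason sets.
#'
#' @param training_replicates list of three replicate `descriptor_table`s.
#' @param application application `descriptor_table` sharing descriptor names.
#' @param rel_tol,abs_tol replicate-stability tolerances.
#' @param max_missing maximum tolerated fraction of missing values per
#'   descriptor (default 0.1) before removal.
#' @param var_threshold,var_keep variance-filter parameters (see
#'   [variance_filter()]).
#' @param ratio_threshold cross-set ratio threshold (default 100).
#' @return list with elements `training`, `application` (both scaled
#'   `descriptor_table`s over the identical final descriptor set) and
#'   `report` (class `curation_report`).
#' @export
curate <- function(training_replicates, application,
                   rel_tol = 1e-6, abs_tol = 1e-9,
                   max_missing = 0.1,
                   var_threshold = 0.1, var_keep = "below",
                   ratio_threshold = 100) {
  stopifnot(inherits(application, "descriptor_table"))
  train <- training_replicates[[1L]]
  all_names <- descriptor_names(train)
  if (!setequal(all_names, descriptor_names(application)))
    stop("curation stage 'input': application descriptors differ from training")

  # 1. replicate stability
  unstable <- tryCatch(
    replicate_stability(training_replicates, rel_tol, abs_tol),
    error = function(e) stop("curation stage 'stability': ",
                             conditionMessage(e), call. = FALSE))
  keep <- setdiff(all_names, unstable)

  # 2. missing values: remove heavily missing columns, impute the rest
  tv <- train$values[, keep, drop = FALSE]
  miss_frac <- colMeans(is.na(tv))
  too_missing <- keep[miss_frac > max_missing]
  keep <- setdiff(keep, too_missing)
  tv <- train$values[, keep, drop = FALSE]
  medians <- apply(tv, 2L, stats::median, na.rm = TRUE)
  tv <- impute_median(tv, medians)
  train_imputed <- descriptor_table(tv, chemicals = train$chemicals)

  # 3. scaling + variance filter (constant-zero columns removed here)
  sc <- fit_scaling(train_imputed)
  zero_removed <- sc$zero_columns
  keep <- setdiff(keep, zero_removed)
  train_scaled <- apply_scaling(subset_descriptors(train_imputed, keep),
                                sc$factors)
  kept_var <- tryCatch(
    variance_filter(train_scaled, var_threshold, var_keep),
    error = function(e) stop("curation stage 'variance': ",
                             conditionMessage(e), call. = FALSE))
  var_removed <- setdiff(keep, kept_var)
  keep <- kept_var

  # 4. cross-set ratio filter (on unscaled application values)
  ratio_removed <- ratio_filter(sc$factors[keep], application, ratio_threshold)
  keep <- setdiff(keep, ratio_removed)

  factors <- sc$factors[keep]
  training_out <- apply_scaling(subset_descriptors(train_imputed, keep),
                                factors)
  app_vals <- application$values[, keep, drop = FALSE]
  app_vals <- impute_median(app_vals, medians[keep])
  app_out <- apply_scaling(
    descriptor_table(app_vals, chemicals = application$chemicals), factors)

  report <- structure(list(
    removed_unstable_replicate = unstable,
    removed_missing = too_missing,
    removed_variance = c(zero_removed, var_removed),
    removed_ratio = ratio_removed,
    scaling_factors = as.list(factors),
    kept = keep,
    imputation_medians = as.list(medians[keep]),
    params = list(rel_tol = rel_tol, abs_tol = abs_tol,
                  max_missing = max_missing, var_threshold = var_threshold,
                  var_keep = var_keep, ratio_threshold = ratio_threshold)),
    class = "curation_report")

  list(training = training_out, application = app_out, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("curation_report\n",
      "  kept:              ", length(x$kept), "\n",
      "  removed unstable:  ", length(x$removed_unstable_replicate), "\n",
      "  removed missing:   ", length(x$removed_missing), "\n",
      "  removed variance:  ", length(x$removed_variance), "\n",
      "  removed ratio:     ", length(x$removed_ratio), "\n", sep = "")
  invisible(x)
}

#' Serialize a curation report to JSON
#'
#' @param report a `curation_report`.
#' @param path output path.
#' @export
write_curation_report <- function(report, path) {
  stopifnot(inherits(report, "curation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' PCA scores for chemical-space coverage
#'
#' Mean-centers the columns of a curated matrix and returns the scores on
#' the leading principal components together with the fraction of variance
#' each explains. Used to visualise how well an application set is covered
#' by the training chemical space.
#'
#' @param matrix numeric matrix without missing values (chemicals x
#'   descriptors), typically the curated, scaled values.
#' @param n_components number of components (default 2).
#' @return list with `scores` (n x n_components matrix) and
#'   `explained_variance` (fractions, non-increasing).
#' @export
pca_scores <- function(matrix, n_components = 2L) {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix)) stop("matrix contains missing values")
  if (n_components > min(dim(matrix)))
    stop("n_components (", n_components, ") exceeds min(n, p) = ",
         min(dim(matrix)))
  p <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  evar <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = evar[seq_len(n_components)])
}
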