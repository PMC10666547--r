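#' Evaluation of category predictions and regression outputs
#'
#' Confusion matrices and misclassification counts for the two
#' categorization routes, the usual regression scores (R-squared, Pearson
#' correlation, residual bands), and the fraction of chemicals on which two
#' methods agree.
#'
#' @name evaluation
NULL

#' Confusion matrix and misclassification count
#'
#' @param true,predicted equal-length label vectors; every label must occur
#'   in `schema$labels` (or in `labels` if given directly).
#' @param schema a `toxicity_schema`, or a character vector of labels fixing
#'   the row/column order.
#' @return list with `confusion` (k x k integer matrix, rows = true,
#'   columns = predicted), `misclassified` (n - trace), `accuracy`, and
#'   `recall` (per true category; NaN where a category is absent).
#' @export
confusion <- function(true, predicted, schema) {
  labels <- if (inherits(schema, "toxicity_schema")) schema$labels
            else as.character(schema)
  if (length(true) != length(predicted))
    stop("label vectors differ in length")
  unknown <- setdiff(unique(c(true, predicted)), labels)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  tab <- table(factor(true, levels = labels),
               factor(predicted, levels = labels))
  cm <- matrix(as.integer(tab), nrow = length(labels),
               dimnames = list(true = labels, predicted = labels))
  n <- length(true)
  correct <- sum(diag(cm))
  list(confusion = cm, misclassified = n - correct, accuracy = correct / n,
       recall = diag(cm) / rowSums(cm))
}

#' Coefficient of determination
#'
#' R-squared = 1 - SS_res / SS_tot of `predicted` against `observed`.
#'
#' @param observed,predicted equal-length numeric vectors; `observed` must
#'   not be constant.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("vectors differ in length")
  if (length(observed) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values are constant")
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length, non-constant numeric vectors.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has no defined correlation")
  stats::cor(x, y, method = "pearson")
}

#' Residual summary for a regression model
#'
#' @param observed,predicted equal-length numeric vectors (log10 LC50).
#' @param band half-width of the acceptance band in log units (default 1).
#' @param probs quantiles of the residual distribution to report.
#' @return list with `fraction_within_band`, `band`, `quantiles`, and the
#'   raw `residuals` (observed - predicted).
#' @export
residual_summary <- function(observed, predicted, band = 1.0,
                             probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  if (length(observed) != length(predicted))
    stop("vectors differ in length")
  res <- observed - predicted
  list(fraction_within_band = mean(abs(res) <= band), band = band,
       quantiles = stats::quantile(res, probs), residuals = res)
}

#' Agreement fraction between two label vectors
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return fraction of positions with identical labels.
#' @export
agreement_fraction <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  mean(as.character(labels_a) == as.character(labels_b))
}

#' Compare two categorization methods against true labels
#'
#' @param true true category labels.
#' @param predictions named list of predicted label vectors (one per
#'   method).
#' @param schema schema or label vector fixing category order.
#' @return a `comparison_report`: per-method confusion results plus the
#'   pairwise agreement fractions between methods, and the ratio of
#'   misclassification counts relative to the best method.
#' @export
compare_methods <- function(true, predictions, schema) {
  stopifnot(is.list(predictions), length(predictions) >= 1L,
            !is.null(names(predictions)))
  per_method <- lapply(predictions, confusion, true = true, schema = schema)
  mis <- vapply(per_method, `[[`, integer(1L), "misclassified")
  m <- length(predictions)
  agreement <- matrix(1, m, m,
                      dimnames = list(names(predictions), names(predictions)))
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      a <- agreement_fraction(predictions[[i]], predictions[[j]])
      agreement[i, j] <- agreement[j, i] <- a
    }
  }
  denom <- if (any(mis > 0)) min(mis[mis > 0]) else NA_real_
  structure(list(per_method = per_method, misclassified = mis,
                 misclassification_ratio = mis / denom,
                 agreement = agreement, n = length(true)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report over", x$n, "chemicals\n")
  for (nm in names(x$per_method)) {
    pm <- x$per_method[[nm]]
    cat("  ", nm, ": accuracy ", format(pm$accuracy, digits = 3),
        ", misclassified ", pm$misclassified, "\n", sep = "")
  }
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @export
write_comparison_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  out <- list(
    n = report$n,
    methods = lapply(names(report$per_method), function(nm) {
      pm <- report$per_method[[nm]]
      list(method = nm, accuracy = pm$accuracy,
           misclassified = pm$misclassified,
           confusion = as.data.frame(pm$confusion),
           recall = as.list(pm$recall))
    }),
    agreement = as.data.frame(report$agreement))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
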