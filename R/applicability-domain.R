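#' Leverage-based applicability domain
#'
#' The applicability domain (AD) of a QSAR model is the region of
#' descriptor space adequately represented by its training set. It is
#' assessed here through the leverage
#' \deqn{h_{ii} = x_i^\top (X^\top X)^{-} x_i}
#' where X is the training matrix restricted to a named descriptor subset
#' and x_i the query chemical's descriptor vector in the same (scaled)
#' space. A chemical is in-domain when its leverage does not exceed the
#' warning threshold, by default h* = 3 p / n capped at 1.
#'
#' When p >= n (e.g. the full curated descriptor space) X'X is singular and
#' the ordinary inverse does not exist; a Moore-Penrose generalized inverse
#' with a singular-value cutoff is used instead, and the report flags this
#' regime.
#'
#' @name applicability-domain
NULL

#' Build a leverage model for one descriptor subspace
#'
#' @param X_train numeric training matrix (n x p), already scaled; columns
#'   named.
#' @param subset_name label for the descriptor subspace (e.g. `"full"`,
#'   `"regression"`, `"classification"`).
#' @param threshold in-domain cutoff on leverage; default `3 * p / n`
#'   capped at 1.
#' @param rcond singular-value cutoff for the generalized inverse of X'X,
#'   relative to its largest singular value (default 1e-10).
#' @return a `leverage_model`.
#' @export
build_leverage_model <- function(X_train, subset_name = "subset",
                                 threshold = NULL, rcond = 1e-10) {
  X_train <- as.matrix(X_train)
  if (!nrow(X_train) || !ncol(X_train)) stop("empty training matrix")
  if (anyNA(X_train)) stop("training matrix contains missing values")
  n <- nrow(X_train); p <- ncol(X_train)
  xtx <- crossprod(X_train)
  ginv <- MASS::ginv(xtx, tol = rcond)
  ginv <- (ginv + t(ginv)) / 2  # enforce symmetry
  if (is.null(threshold)) threshold <- min(1, 3 * p / n)
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(X = X_train, pseudo_inverse = ginv,
                 subset_name = subset_name, threshold = threshold,
                 n = n, p = p, rank = qr(X_train)$rank,
                 singular = p >= n, rcond = rcond),
            class = "leverage_model")
}

#' @export
print.leverage_model <- function(x, ...) {
  cat("leverage_model '", x$subset_name, "': n = ", x$n, ", p = ", x$p,
      ", threshold h* = ", format(x$threshold, digits = 4), "\n", sep = "")
  if (x$singular)
    cat("  note: p >= n; leverages use a generalized inverse of X'X\n")
  invisible(x)
}

#' Leverage of query chemicals
#'
#' @param model a `leverage_model`.
#' @param x a descriptor vector of length p, or an m x p matrix (same
#'   column scaling as the training matrix).
#' @return numeric leverage(s), one per query row; always >= 0.
#' @export
leverage <- function(model, x) {
  stopifnot(inherits(model, "leverage_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$p)
    stop("descriptor vector length ", ncol(x), " does not match p = ",
         model$p)
  h <- rowSums((x %*% model$pseudo_inverse) * x)
  pmax(h, 0)
}

#' Assess the applicability domain of a table of chemicals
#'
#' @param model a `leverage_model`.
#' @param table a `descriptor_table` (or plain matrix with named columns)
#'   containing the model's descriptor columns, scaled as the training set.
#' @return a data.frame of class `ad_report` with columns `id`, `subset`,
#'   `leverage`, `in_domain`; attributes carry the threshold and counts.
#' @export
ad_assess <- function(model, table) {
  stopifnot(inherits(model, "leverage_model"))
  vals <- if (inherits(table, "descriptor_table")) table$values else
    as.matrix(table)
  cols <- colnames(model$X)
  miss <- setdiff(cols, colnames(vals))
  if (length(miss))
    stop("table lacks descriptor column(s): ", paste(miss, collapse = ", "))
  vals <- vals[, cols, drop = FALSE]
  h <- leverage(model, vals)
  ids <- rownames(vals)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(vals)))
  out <- data.frame(id = ids, subset = model$subset_name, leverage = h,
                    in_domain = h <= model$threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- model$threshold
  attr(out, "singular") <- model$singular
  attr(out, "counts") <- c(in_domain = sum(out$in_domain),
                           out_of_domain = sum(!out$in_domain))
  class(out) <- c("ad_report", class(out))
  out
}

#' Compare applicability domains across descriptor subspaces
#'
#' @param reports list of `ad_report`s over the identical chemicals (same
#'   ids, same order) from different descriptor subsets.
#' @return list with `counts` (data.frame: subset, n_in, n_out) and
#'   `agreement` (pairwise fraction of chemicals with matching in/out
#'   flags).
#' @export
ad_compare <- function(reports) {
  if (length(reports) < 2L) stop("need at least two reports to compare")
  lapply(reports, function(r) stopifnot(inherits(r, "ad_report")))
  ids <- reports[[1L]]$id
  for (r in reports[-1L])
    if (!identical(r$id, ids)) stop("reports cover different chemical sets")
  subsets <- vapply(reports, function(r) r$subset[1L], character(1L))
  counts <- data.frame(subset = subsets,
                       n_in = vapply(reports, function(r) sum(r$in_domain),
                                     integer(1L)),
                       n_out = vapply(reports, function(r) sum(!r$in_domain),
                                      integer(1L)),
                       stringsAsFactors = FALSE)
  m <- length(reports)
  agreement <- matrix(1, m, m, dimnames = list(subsets, subsets))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      a <- mean(reports[[i]]$in_domain == reports[[j]]$in_domain)
      agreement[i, j] <- agreement[j, i] <- a
    }
  }
  list(counts = counts, agreement = agreement)
}

#' Write an AD report (rows) and summary (JSON)
#'
#' @param reports list of `ad_report`s over identical chemicals.
#' @param csv_path per-chemical CSV output (one leverage + flag pair per
#'   subset).
#' @param json_path summary JSON output (counts, thresholds, pairwise
#'   agreement, generalized-inverse flags).
#' @export
write_ad_report <- function(reports, csv_path, json_path = NULL) {
  if (inherits(reports, "ad_report")) reports <- list(reports)
  wide <- data.frame(id = reports[[1L]]$id, stringsAsFactors = FALSE)
  for (r in reports) {
    nm <- r$subset[1L]
    wide[[paste0("leverage_", nm)]] <- r$leverage
    wide[[paste0("in_domain_", nm)]] <- r$in_domain
  }
  utils::write.csv(wide, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summary <- list(
      subsets = lapply(reports, function(r) list(
        subset = r$subset[1L], threshold = attr(r, "threshold"),
        generalized_inverse = isTRUE(attr(r, "singular")),
        n_in = sum(r$in_domain), n_out = sum(!r$in_domain))),
      agreement = if (length(reports) >= 2L)
        as.data.frame(ad_compare(reports)$agreement) else NULL)
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv_path)
}
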