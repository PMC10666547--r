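#' Toxicity category schemas
#'
#' Two ways of turning an acute fish toxicity measurement (96 h LC50) into
#' an ordered hazard category:
#'
#' * **GHS**: the fixed regulatory thresholds for short-term (acute) aquatic
#'   hazard — acute 1 (LC50 <= 1 mg/L), acute 2 (1 < LC50 <= 10 mg/L),
#'   acute 3 (LC50 > 10 mg/L).
#' * **k-means**: four data-driven categories obtained by clustering
#'   chemicals in the (log10 LC50, monoisotopic mass) plane, stabilised by
#'   bootstrapping the clustering and keeping the modal centroid set.
#'
#' @name toxicity-categories
NULL

.GHS_LABELS <- c("acute 1", "acute 2", "acute 3")
.GHS_THRESHOLDS_MG_L <- c(1, 10)

.KMEANS_LABELS_4 <- c("high toxicity", "moderate toxicity",
                      "low toxicity", "very low toxicity")

#' Convert a concentration to log10(mg/L)
#'
#' @param value positive concentration value(s).
#' @param unit one of `"g/L"`, `"mg/L"`, `"ug/L"` (accepted spelling of
#'   micrograms per litre; `"μg/L"` also works), `"ng/L"`.
#' @return log10 of the concentration in mg/L.
#' @examples
#' to_log_mg_per_l(0.95, "ug/L")  # -3.02 (2 d.p.)
#' @export
to_log_mg_per_l <- function(value, unit = "mg/L") {
  if (any(!is.finite(value)) || any(value <= 0))
    stop("concentration must be positive and finite")
  unit <- rep_len(as.character(unit), length(value))
  unit[unit == "μg/L" | unit == "µg/L"] <- "ug/L"
  scale <- c("g/L" = 1e3, "mg/L" = 1, "ug/L" = 1e-3, "ng/L" = 1e-6)[unit]
  if (anyNA(scale)) stop("unknown unit: ",
                         paste(unique(unit[is.na(scale)]), collapse = ", "))
  log10(value * unname(scale))
}

#' The built-in GHS acute aquatic hazard schema
#'
#' @return a `toxicity_schema` with labels acute 1/2/3 and thresholds at
#'   1 and 10 mg/L.
#' @export
ghs_schema <- function() {
  structure(list(provenance = "ghs", labels = .GHS_LABELS,
                 thresholds_mg_l = .GHS_THRESHOLDS_MG_L),
            class = "toxicity_schema")
}

#' Assign GHS acute aquatic hazard categories
#'
#' Boundaries are inclusive on the more-toxic side: LC50 of exactly 1 mg/L
#' is acute 1 and exactly 10 mg/L is acute 2.
#'
#' @param lc50 positive LC50 value(s) in mg/L.
#' @return character vector of labels among `"acute 1"`, `"acute 2"`,
#'   `"acute 3"`.
#' @export
assign_ghs <- function(lc50) {
  if (any(!is.finite(lc50)) || any(lc50 <= 0))
    stop("lc50 must be positive and finite")
  ifelse(lc50 <= 1, .GHS_LABELS[1L],
         ifelse(lc50 <= 10, .GHS_LABELS[2L], .GHS_LABELS[3L]))
}

## ---- k-means internals -----------------------------------------------------

# k-means++ initial centers followed by Lloyd iterations, best of `restarts`
kmeanspp_fit <- function(x, k, restarts = 25L, iter_max = 300L, tol = 1e-6) {
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1L, ] <- x[sample.int(n, 1L), ]
    if (k > 1L) {
      d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
      for (j in 2:k) {
        if (all(d2 == 0)) idx <- sample.int(n, 1L)
        else idx <- sample.int(n, 1L, prob = d2)
        centers[j, ] <- x[idx, ]
        d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                           byrow = TRUE))^2))
      }
    }
    # resamples can repeat points; nudge coincident centers apart
    if (anyDuplicated(centers))
      centers <- centers + stats::rnorm(length(centers), sd = 1e-9)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss - tol)
      best <- fit
  }
  best
}

# order centroids ascending by first coordinate (log LC50), ties by second
align_centroids <- function(centers) {
  ord <- order(centers[, 1L], centers[, 2L])
  centers[ord, , drop = FALSE]
}

#' Modal centroid set over bootstrap iterations
#'
#' Each iteration's aligned centroid set is rounded to `rounding` decimals;
#' the most frequent rounded set defines an equivalence class, and the
#' element-wise mean of the *unrounded* members of that class is returned.
#' Frequency ties go to the class seen earliest.
#'
#' @param centroid_sets list of k x 2 centroid matrices, all aligned to a
#'   common label order.
#' @param rounding decimals used to group near-identical sets (default 2).
#' @return k x 2 matrix of modal centroids.
#' @export
select_modal_centroids <- function(centroid_sets, rounding = 2L) {
  if (!length(centroid_sets)) stop("no centroid sets supplied")
  keys <- vapply(centroid_sets, function(m)
    paste(sprintf(paste0("%.", rounding, "f"), round(m, rounding)),
          collapse = "|"), character(1L))
  counts <- table(keys)
  winners <- names(counts)[counts == max(counts)]
  # earliest-iteration tie-break
  first_seen <- vapply(winners, function(k) which(keys == k)[1L], integer(1L))
  modal_key <- winners[which.min(first_seen)]
  members <- centroid_sets[keys == modal_key]
  Reduce(`+`, members) / length(members)
}

#' Fit a bootstrapped k-means toxicity categorizer
#'
#' Points (log10 LC50 in mg/L, monoisotopic mass in Da) are split into a
#' training and a holdout fraction, standardized with the training mean and
#' standard deviation, and clustered. The training points are resampled with
#' replacement `n_boot` times; each resample is clustered with k-means
#' (k-means++ seeding, multiple restarts) and its centroids aligned by
#' ascending log-LC50 coordinate. The modal centroid set over all
#' iterations becomes the final model. Labels are attached most-toxic-first:
#' the centroid with the lowest log-LC50 coordinate is `"high toxicity"`.
#'
#' `holdout_agreement` is the fraction of holdout points whose assignment
#' under the final (modal) centroids matches their assignment under a
#' single k-means fit to the full training split — a stability measure for
#' the bootstrap consensus.
#'
#' @param points numeric matrix or data.frame with two columns:
#'   log10 LC50 (mg/L) and monoisotopic mass (Da).
#' @param k number of clusters (default 4).
#' @param n_boot bootstrap iterations (default 500).
#' @param train_frac training fraction for the split (default 0.9).
#' @param seed integer seed driving the split, the resamples and all k-means
#'   restarts.
#' @param labels category labels, most toxic first; defaults to the built-in
#'   four labels when `k = 4`, otherwise `"category 1"..k`.
#' @param restarts,iter_max,tol k-means controls.
#' @param rounding modal-set rounding, in decimals of the standardized
#'   coordinates (default 2).
#' @return a `kmeans_categorizer` (also a `toxicity_schema`) with the
#'   standardization parameters, aligned centroids (standardized space),
#'   labels and `holdout_agreement`.
#' @export
fit_kmeans_categorizer <- function(points, k = 4L, n_boot = 500L,
                                   train_frac = 0.9, seed = 1L,
                                   labels = NULL, restarts = 25L,
                                   iter_max = 300L, tol = 1e-6,
                                   rounding = 2L) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns (log LC50, mass)")
  if (anyNA(points)) stop("points contain missing values")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  n_distinct <- nrow(unique(points))
  if (k > n_distinct)
    stop("k (", k, ") exceeds number of distinct points (", n_distinct, ")")
  if (is.null(labels)) {
    labels <- if (k == 4L) .KMEANS_LABELS_4 else paste("category", seq_len(k))
  }
  if (length(labels) != k) stop("need exactly k labels")

  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n <- nrow(points)
  n_train <- round(train_frac * n)
  if (n_train < k || n_train >= n) stop("degenerate train/holdout split")
  train_idx <- sample.int(n, n_train)
  train <- points[train_idx, , drop = FALSE]
  holdout <- points[-train_idx, , drop = FALSE]

  mu <- unname(colMeans(train))
  sdv <- unname(apply(train, 2L, stats::sd))
  if (any(sdv == 0)) sdv[sdv == 0] <- 1  # degenerate coordinate: leave as-is
  z_train <- scale(train, center = mu, scale = sdv)

  sets <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    boot <- z_train[sample.int(n_train, n_train, replace = TRUE), ,
                    drop = FALSE]
    fit <- kmeanspp_fit(boot, k, restarts, iter_max, tol)
    sets[[b]] <- align_centroids(fit$centers)
  }
  centroids <- select_modal_centroids(sets, rounding)
  dimnames(centroids) <- NULL

  ref_fit <- kmeanspp_fit(z_train, k, restarts, iter_max, tol)
  ref_centroids <- align_centroids(ref_fit$centers)
  dimnames(ref_centroids) <- NULL

  obj <- structure(list(
    provenance = "kmeans", labels = labels, k = k,
    centroids = centroids, feature_means = mu, feature_sds = sdv,
    n_boot = n_boot, train_frac = train_frac, seed = seed,
    rounding = rounding, holdout_agreement = NA_real_),
    class = c("kmeans_categorizer", "toxicity_schema"))

  if (nrow(holdout)) {
    final_lab <- assign_kmeans(obj, holdout)
    ref_obj <- obj
    ref_obj$centroids <- ref_centroids
    ref_lab <- assign_kmeans(ref_obj, holdout)
    obj$holdout_agreement <- mean(final_lab == ref_lab)
  }
  obj
}

#' Assign k-means toxicity categories
#'
#' Standardizes each point with the categorizer's stored training mean/sd
#' and returns the label of the nearest centroid (Euclidean distance; exact
#' ties go to the lower centroid index, i.e. the more toxic label).
#'
#' @param categorizer a fitted `kmeans_categorizer`.
#' @param points matrix/data.frame with columns (log10 LC50 mg/L, mass Da),
#'   or a length-2 vector for a single chemical.
#' @return character vector of labels.
#' @export
assign_kmeans <- function(categorizer, points) {
  if (!inherits(categorizer, "kmeans_categorizer") ||
      is.null(categorizer$centroids))
    stop("categorizer is not a fitted kmeans_categorizer")
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  z <- scale(points, center = categorizer$feature_means,
             scale = categorizer$feature_sds)
  cen <- categorizer$centroids
  d2 <- outer(rowSums(z^2), rep(1, nrow(cen))) -
    2 * z %*% t(cen) + outer(rep(1, nrow(z)), rowSums(cen^2))
  categorizer$labels[apply(d2, 1L, which.min)]
}

#' Assign categories under either schema
#'
#' @param schema a `toxicity_schema` (GHS or k-means).
#' @param lc50_mg_l LC50 values in mg/L.
#' @param mass_da monoisotopic masses in Da (required for k-means schemas).
#' @return character vector of labels.
#' @export
assign_category <- function(schema, lc50_mg_l, mass_da = NULL) {
  stopifnot(inherits(schema, "toxicity_schema"))
  if (schema$provenance == "ghs") return(assign_ghs(lc50_mg_l))
  if (is.null(mass_da))
    stop("monoisotopic masses are required for a k-means schema")
  assign_kmeans(schema, cbind(log10(lc50_mg_l), mass_da))
}

#' @export
print.toxicity_schema <- function(x, ...) {
  cat("toxicity_schema (", x$provenance, "): ",
      paste(x$labels, collapse = " > "), "\n", sep = "")
  if (x$provenance == "kmeans") {
    cat("  k = ", x$k, ", n_boot = ", x$n_boot,
        ", holdout agreement = ", format(x$holdout_agreement, digits = 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialize / restore a toxicity schema as JSON
#'
#' Everything needed to reapply a schema in a later session (labels,
#' centroids, standardization parameters, seed, bootstrap count) round-trips
#' through a plain JSON file.
#'
#' @param schema a `toxicity_schema`.
#' @param path output path.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "toxicity_schema"))
  x <- unclass(schema)
  if (!is.null(x$centroids)) x$centroids <- as.data.frame(x$centroids)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_schema
#' @return `read_schema` returns the restored `toxicity_schema`.
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$provenance, "ghs")) return(ghs_schema())
  x$centroids <- as.matrix(x$centroids)
  dimnames(x$centroids) <- NULL
  x$feature_means <- as.numeric(x$feature_means)
  x$feature_sds <- as.numeric(x$feature_sds)
  structure(x, class = c("kmeans_categorizer", "toxicity_schema"))
}

## RNG bookkeeping: fits are deterministic under their seed without
## clobbering the caller's random stream.
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
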