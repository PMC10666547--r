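make_reps <- function(base, r2 = base, r3 = base) {
  lapply(list(r1 = base, r2 = r2, r3 = r3), function(v)
    tiny_table(v))
}

test_that("replicate stability flags only descriptors exceeding the relative tolerance", {
  base <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
  reps <- make_reps(base)
  expect_identical(replicate_stability(reps), character(0))

  r2 <- base; r2[1, "b"] <- base[1, "b"] * 1.5
  expect_identical(replicate_stability(make_reps(base, r2 = r2)), "b")

  r2 <- base; r2[1, "b"] <- base[1, "b"] * (1 + 1e-9)
  expect_identical(replicate_stability(make_reps(base, r2 = r2)),
                   character(0))

  bad <- tiny_table(base[, 1, drop = FALSE])
  expect_error(replicate_stability(list(reps[[1]], reps[[2]], bad)),
               "descriptors")
})

test_that("scaling uses the max absolute training value and round-trips", {
  tab <- tiny_table(cbind(a = c(5, 10), b = c(-4, 2), c = c(0, 0)))
  sc <- fit_scaling(tab)
  expect_equal(sc$factors, c(a = 10, b = 4, c = 0))
  expect_identical(sc$zero_columns, "c")

  keep <- subset_descriptors(tab, c("a", "b"))
  scaled <- apply_scaling(keep, sc$factors)
  expect_equal(scaled$values[, "a"], c(C01 = 0.5, C02 = 1.0))
  # application values above the training max scale past 1
  app <- tiny_table(cbind(a = 150, b = 1), ids = "X")
  expect_equal(apply_scaling(app, sc$factors)$values[1, "a"], 15)
  # descale recovers the original
  expect_equal(sweep(scaled$values, 2, sc$factors[c("a", "b")], "*"),
               keep$values)
  expect_error(apply_scaling(tab, sc$factors), "factor 0")
})

test_that("variance filter keeps var < threshold with strict inequality", {
  # scaled column (0, 1, 0, 1): sample variance 1/3 >= 0.1 -> removed
  tab <- tiny_table(cbind(flat = c(0.5, 0.5, 0.5, 0.5),
                          alt = c(0, 1, 0, 1)))
  expect_equal(stats::var(c(0, 1, 0, 1)), 1 / 3)
  expect_identical(variance_filter(tab), "flat")
  # exactly at the threshold -> removed (strict <)
  at <- tiny_table(cbind(edge = c(0, 0.31622776601683794,
                                  -0.31622776601683794)))
  expect_equal(stats::var(at$values[, "edge"]), 0.1, tolerance = 1e-12)
  expect_identical(variance_filter(at, threshold = 0.1), character(0))
  # direction switch
  expect_identical(variance_filter(tab, keep = "above"), "alt")
  expect_error(variance_filter(tiny_table(cbind(a = 1))), "at least 2")
})

test_that("ratio filter removes descriptors exploding in the application set", {
  app <- tiny_table(cbind(a = c(150, 10), b = c(99, 1), c = c(3, 1)))
  removed <- ratio_filter(c(a = 1, b = 1, c = 0), app)
  expect_setequal(removed, c("a", "c"))  # c: zero-denominator rule
})

test_that("the curation cascade partitions descriptors by first-triggering filter", {
  fx <- make_fixture("curation6")
  cur <- curate(fx$replicates, fx$application)
  rep <- cur$report
  expect_identical(sort(rep$kept), sort(fx$expected$kept))
  expect_identical(rep$removed_unstable_replicate,
                   fx$expected$removed_unstable)
  expect_identical(rep$removed_variance, fx$expected$removed_variance)
  expect_identical(rep$removed_ratio, fx$expected$removed_ratio)
  # bookkeeping: partition of the original descriptor set
  all_names <- colnames(fx$replicates[[1]]$values)
  parts <- list(rep$kept, rep$removed_unstable_replicate,
                rep$removed_missing, rep$removed_variance,
                rep$removed_ratio)
  expect_equal(sum(lengths(parts)), length(all_names))
  expect_setequal(unlist(parts), all_names)
  # identical final columns, same order, in both outputs
  expect_identical(colnames(cur$training$values),
                   colnames(cur$application$values))
  # curation is idempotent
  cur2 <- curate(list(cur$training, cur$training, cur$training),
                 cur$application)
  expect_equal(cur2$training$values, cur$training$values)
  expect_equal(cur2$application$values, cur$application$values)
  expect_identical(cur2$report$kept, rep$kept)
})

test_that("curation report serializes to JSON", {
  fx <- make_fixture("curation6")
  cur <- curate(fx$replicates, fx$application)
  f <- withr::local_tempfile(fileext = ".json")
  write_curation_report(cur$report, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(back$kept, cur$report$kept)
  expect_identical(back$removed_ratio, cur$report$removed_ratio)
})

test_that("PCA scores are centered and match an eigendecomposition oracle", {
  set.seed(42)
  X <- matrix(rnorm(20), 5, 4)
  res <- pca_scores(X, n_components = 2)
  expect_equal(colMeans(res$scores), c(PC1 = 0, PC2 = 0), tolerance = 1e-12)
  expect_true(all(diff(res$explained_variance) <= 1e-12))

  # independent oracle: eigendecomposition of the covariance matrix
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  oracle_scores <- Xc %*% eg$vectors[, 1:2]
  for (k in 1:2) {  # sign of each component is arbitrary
    expect_equal(min(max(abs(res$scores[, k] - oracle_scores[, k])),
                     max(abs(res$scores[, k] + oracle_scores[, k]))),
                 0, tolerance = 1e-10)
  }
  expect_equal(res$explained_variance,
               (eg$values / sum(eg$values))[1:2], tolerance = 1e-10)

  # collinear data: first component explains everything
  line <- cbind(1:6, 2 * (1:6))
  expect_equal(pca_scores(line, 2)$explained_variance[1], 1,
               tolerance = 1e-12)
  expect_error(pca_scores(X, 5), "exceeds")
})
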