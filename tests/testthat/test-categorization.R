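test_that("concentration units convert to log10(mg/L)", {
  expect_equal(round(to_log_mg_per_l(0.95, "ug/L"), 2), -3.02)
  expect_equal(to_log_mg_per_l(1, "mg/L"), 0)
  expect_equal(to_log_mg_per_l(1, "g/L"), 3)
  expect_equal(to_log_mg_per_l(1, "ng/L"), -6)
  expect_equal(to_log_mg_per_l(0.95, "μg/L"),
               to_log_mg_per_l(0.95, "ug/L"))
  expect_error(to_log_mg_per_l(0), "positive")
  expect_error(to_log_mg_per_l(1, "mol/L"), "unknown unit")
})

test_that("GHS boundaries are inclusive on the more-toxic side and partition (0, Inf)", {
  expect_identical(assign_ghs(0.5), "acute 1")
  expect_identical(assign_ghs(1.0), "acute 1")
  expect_identical(assign_ghs(1.0000001), "acute 2")
  expect_identical(assign_ghs(10.0), "acute 2")
  expect_identical(assign_ghs(10.000001), "acute 3")
  # every positive value receives exactly one label
  grid <- 10^seq(-6, 6, length.out = 200)
  labs <- assign_ghs(grid)
  expect_true(all(labs %in% c("acute 1", "acute 2", "acute 3")))
  # monotone: decreasing LC50 never moves toward a less toxic category
  ord <- match(labs, c("acute 1", "acute 2", "acute 3"))
  expect_true(all(diff(ord) >= 0))
  expect_error(assign_ghs(-1), "positive")
})

test_that("modal centroid selection groups by rounding and breaks ties by earliest iteration", {
  a <- matrix(c(0, 0, 1, 1), 2, 2)
  b <- a + 0.001          # same rounded (2 d.p.) class as a
  z <- matrix(c(5, 5, 6, 6), 2, 2)
  expect_equal(select_modal_centroids(rep(list(a), 500)), a)
  expect_equal(select_modal_centroids(c(rep(list(a), 499), list(z))), a)
  # winner is the mean of the unrounded members of the winning class
  expect_equal(select_modal_centroids(list(a, b, z)), (a + b) / 2)
  # exact frequency tie: class seen first wins
  expect_equal(select_modal_centroids(list(z, a)), z)
  expect_error(select_modal_centroids(list()), "no centroid")
})

test_that("k-means categorizer is deterministic, ordered by toxicity, and exact on degenerate k", {
  fx <- make_fixture("blobs4")
  km1 <- fit_kmeans_categorizer(fx$points, k = 4, n_boot = 25, seed = 9)
  km2 <- fit_kmeans_categorizer(fx$points, k = 4, n_boot = 25, seed = 9)
  expect_identical(km1$centroids, km2$centroids)  # bitwise under same seed
  # centroid order: ascending log LC50; first label is "high toxicity"
  expect_true(all(diff(km1$centroids[, 1]) > 0))
  expect_identical(km1$labels[1], "high toxicity")

  # k = 1: the single centroid is the mean of the (standardized) training set
  km <- fit_kmeans_categorizer(fx$points[1:50, ], k = 1, n_boot = 5,
                               seed = 2, train_frac = 0.8)
  expect_equal(dim(km$centroids), c(1L, 2L))
  expect_error(fit_kmeans_categorizer(fx$points[1:3, ], k = 5, n_boot = 2,
                                      seed = 1),
               "distinct")
})

test_that("assignment standardizes, picks the nearest centroid, and breaks ties low", {
  fx <- make_fixture("blobs4")
  km <- fit_kmeans_categorizer(fx$points, k = 4, n_boot = 25, seed = 9)
  # a point placed exactly at a (destandardized) centroid gets its label
  for (i in 1:4) {
    raw <- km$centroids[i, ] * km$feature_sds + km$feature_means
    expect_identical(assign_kmeans(km, raw), km$labels[i])
  }
  # equidistant point between centroids 1 and 2 -> lower index wins
  mid_std <- (km$centroids[1, ] + km$centroids[2, ]) / 2
  mid_raw <- mid_std * km$feature_sds + km$feature_means
  expect_identical(assign_kmeans(km, mid_raw), km$labels[1])
  expect_error(assign_kmeans(structure(list(), class = "kmeans_categorizer"),
                             c(0, 100)),
               "not a fitted")
})

test_that("schemas round-trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  write_schema(ghs_schema(), f)
  expect_identical(read_schema(f), ghs_schema())

  fx <- make_fixture("blobs4")
  km <- fit_kmeans_categorizer(fx$points, k = 4, n_boot = 10, seed = 5)
  write_schema(km, f)
  back <- read_schema(f)
  expect_equal(back$centroids, km$centroids)
  expect_equal(back$feature_means, km$feature_means)
  expect_identical(back$labels, km$labels)
  pts <- fx$points[seq(1, 400, by = 20), ]
  expect_identical(assign_kmeans(back, pts), assign_kmeans(km, pts))
})

test_that("assign_category dispatches on schema provenance", {
  expect_identical(assign_category(ghs_schema(), c(0.5, 5, 50)),
                   c("acute 1", "acute 2", "acute 3"))
  fx <- make_fixture("blobs4")
  km <- fit_kmeans_categorizer(fx$points, k = 4, n_boot = 10, seed = 5)
  expect_error(assign_category(km, 1), "masses")
  expect_identical(assign_category(km, 10^fx$points[1, 1],
                                   fx$points[1, 2]),
                   assign_kmeans(km, fx$points[1, , drop = FALSE]))
})
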