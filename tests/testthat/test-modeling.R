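test_that("train/test split is disjoint, covering, sized by round(frac*n), reproducible", {
  sp <- split_train_test(10, 0.9, seed = 3)
  expect_length(sp$train, 9L)
  expect_length(sp$test, 1L)
  expect_setequal(c(sp$train, sp$test), 1:10)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(sp, split_train_test(10, 0.9, seed = 3))
  expect_false(identical(sp, split_train_test(10, 0.9, seed = 4)))
  expect_error(split_train_test(1), "at least 2")
  expect_error(split_train_test(5, 0.01), "degenerate")
})

test_that("default grids span the documented hyperparameter ranges", {
  gr <- default_grid("regression")
  expect_equal(range(gr$n_trees), c(100, 1000))
  expect_equal(range(gr$min_leaf), c(1, 21))
  gc <- default_grid("classification")
  expect_equal(range(gc$n_trees), c(200, 2000))
  expect_equal(length(gc$n_trees), 20L)
  expect_equal(range(gc$min_leaf), c(1, 21))
})

test_that("grid search returns the single cell of a 1x1 grid with OOB importances", {
  tr <- small_training()
  gs <- grid_search(tr$X, tr$y, "regression",
                    grid = list(n_trees = 80L, min_leaf = 5L), seed = 7)
  expect_equal(gs$best, list(n_trees = 80L, min_leaf = 5L))
  expect_length(gs$cv_scores, 3L)
  expect_length(gs$importances, ncol(tr$X))
  expect_true(all(gs$importances >= 0))
  expect_equal(nrow(gs$cv_table), 1L)
})

test_that("grid search rejects folds containing a single class", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(rep("pos", 9), "neg")
  expect_error(grid_search(X, y, "classification",
                           grid = list(n_trees = 50L, min_leaf = 1L),
                           folds = 3, seed = 1),
               "single class")
})

test_that("relative-importance selection divides by the largest and is scale-free", {
  imp <- c(a = 0.50, b = 0.30, c = 0.004)
  expect_identical(select_by_relative_importance(imp), c("a", "b"))
  # scale invariance
  expect_identical(select_by_relative_importance(imp * 1000),
                   select_by_relative_importance(imp))
  # all equal -> all selected; exact threshold -> excluded (strict >)
  expect_identical(select_by_relative_importance(c(x = 2, y = 2)),
                   c("x", "y"))
  expect_identical(select_by_relative_importance(c(x = 1, y = 0.01)), "x")
  expect_error(select_by_relative_importance(c(a = 0, b = 0)), "zero")
})

test_that("final fits are deterministic under seed and validate their columns", {
  tr <- small_training()
  m1 <- fit_final(tr$X, tr$y, colnames(tr$X)[1:10], quick_hp, "regression",
                  seed = 5)
  m2 <- fit_final(tr$X, tr$y, colnames(tr$X)[1:10], quick_hp, "regression",
                  seed = 5)
  expect_identical(predict_lc50(m1, tr$X), predict_lc50(m2, tr$X))
  expect_error(fit_final(tr$X, tr$y, c("D001", "nope"), quick_hp,
                         "regression"),
               "nope")
  expect_error(predict_lc50(m1, tr$X[, -1]), "D001")
})

test_that("tree-ensemble predictions stay within the training response range", {
  tr <- small_training()
  m <- fit_final(tr$X, tr$y, colnames(tr$X), quick_hp, "regression",
                 seed = 5)
  cfg_far <- generator_config(n_chemicals = 50, n_descriptors = 30,
                              response = "smooth", shift_sd = 20, seed = 77)
  far <- generate_application(cfg_far, n_application = 50)
  pred <- predict_lc50(m, far$table$values)
  expect_true(all(pred >= min(tr$y) - 1e-9))
  expect_true(all(pred <= max(tr$y) + 1e-9))
})

test_that("a noise-free smooth response trains better than it cross-validates", {
  cfg <- generator_config(n_chemicals = 150, n_descriptors = 30,
                          noise_sd = 0, response = "smooth", seed = 21)
  tr <- generate_training(cfg)
  gs <- grid_search(tr$replicates[[1]]$values, tr$chemicals$log_lc50,
                    "regression", grid = list(n_trees = 150L, min_leaf = 3L),
                    seed = 21)
  m <- fit_final(tr$replicates[[1]]$values, tr$chemicals$log_lc50,
                 colnames(tr$replicates[[1]]$values), gs$best, "regression",
                 seed = 21, cv_scores = gs$cv_scores)
  expect_gte(m$train_score, mean(gs$cv_scores))
  expect_gt(m$train_score, 0.8)
})

test_that("direct classification preserves schema labels and degenerates gracefully", {
  tr <- small_training()
  labs <- assign_ghs(10^tr$y)
  m <- fit_final(tr$X, labs, colnames(tr$X), quick_hp, "classification",
                 seed = 3, schema = ghs_schema())
  pred <- predict_category_direct(m, tr$X)
  expect_true(all(pred %in% ghs_schema()$labels))
  # single-label training data always predicts that label
  one <- fit_final(tr$X[1:30, ], rep("acute 2", 30), colnames(tr$X),
                   quick_hp, "classification", seed = 3)
  expect_identical(unique(predict_category_direct(one, tr$X)), "acute 2")
})

test_that("two-step categorization composes regression with the schema", {
  tr <- small_training()
  m <- fit_final(tr$X, tr$y, colnames(tr$X), quick_hp, "regression",
                 seed = 5)
  pred_log <- predict_lc50(m, tr$X)
  expect_identical(two_step_categorize(m, ghs_schema(), tr$X),
                   assign_ghs(10^pred_log))
  # k-means schema requires masses
  fx <- make_fixture("blobs4")
  km <- fit_kmeans_categorizer(fx$points, k = 4, n_boot = 10, seed = 5)
  expect_error(two_step_categorize(m, km, tr$X), "masses")
  masses <- tr$chemicals$monoisotopic_mass
  expect_identical(two_step_categorize(m, km, tr$X, masses),
                   assign_kmeans(km, cbind(pred_log, masses)))
})

test_that("models persist to rds with a JSON sidecar", {
  tr <- small_training()
  m <- fit_final(tr$X, tr$y, colnames(tr$X)[1:8], quick_hp, "regression",
                 seed = 5)
  f <- withr::local_tempfile(fileext = ".rds")
  write_model(m, f)
  expect_true(file.exists(paste0(f, ".json")))
  back <- read_model(f)
  expect_identical(predict_lc50(back, tr$X), predict_lc50(m, tr$X))
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_identical(side$task, "regression")
  expect_identical(side$selected_variables, m$selected_variables)
})
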