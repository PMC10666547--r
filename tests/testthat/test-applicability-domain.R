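test_that("leverage reproduces the explicit hat-matrix formula", {
  m <- build_leverage_model(diag(2), "id")
  expect_equal(m$pseudo_inverse, diag(2))
  expect_equal(leverage(m, c(1, 0)), 1.0)
  expect_equal(leverage(m, c(0, 0)), 0.0)
  expect_error(leverage(m, c(1, 0, 0)), "does not match")
  expect_error(build_leverage_model(matrix(numeric(0), 0, 0)), "empty")
})

test_that("leverage matches a brute-force dense-inverse oracle on random full-rank matrices", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(6:20, 1); p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    mod <- build_leverage_model(X, "rand")
    x <- rnorm(p)
    oracle <- drop(t(x) %*% solve(crossprod(X)) %*% x)
    expect_equal(leverage(mod, x), oracle, tolerance = 1e-10)
    # hat-matrix trace: training leverages sum to rank(X)
    expect_equal(sum(leverage(mod, X)), qr(X)$rank, tolerance = 1e-8)
    expect_true(all(leverage(mod, X) >= 0 & leverage(mod, X) <= 1 + 1e-12))
  }
})

test_that("rank-deficient training matrices build via the generalized inverse", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(0, 1, 0, 1))
  mod <- build_leverage_model(X, "dup")
  expect_equal(mod$rank, 2L)
  expect_equal(sum(leverage(mod, X)), 2, tolerance = 1e-8)
  # p >= n regime flagged
  wide <- matrix(rnorm(12), 2, 6)
  expect_true(build_leverage_model(wide, "wide")$singular)
})

test_that("leverage is invariant under orthogonal rotation of descriptor space", {
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  m1 <- build_leverage_model(X, "raw")
  m2 <- build_leverage_model(X %*% Q, "rot")
  x <- rnorm(3)
  expect_equal(leverage(m1, x), leverage(m2, drop(x %*% Q)),
               tolerance = 1e-10)
})

test_that("duplicating a training row never increases any leverage", {
  set.seed(6)
  X <- matrix(rnorm(24), 8, 3)
  m1 <- build_leverage_model(X, "base")
  m2 <- build_leverage_model(rbind(X, X[3, ]), "dup")
  probes <- rbind(X, diag(3), matrix(rnorm(9), 3, 3))
  expect_true(all(leverage(m2, probes) <= leverage(m1, probes) + 1e-12))
})

test_that("AD assessment applies the threshold and default h* = 3p/n", {
  set.seed(7)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  mod <- build_leverage_model(X, "full")
  expect_equal(mod$threshold, 0.6)  # 3 * 2 / 10
  rep <- ad_assess(mod, X)
  expect_identical(rep$in_domain, rep$leverage <= 0.6)
  expect_equal(mean(rep$leverage), mod$rank / nrow(X), tolerance = 1e-8)
  # a duplicated training row is in-domain for full-rank X
  expect_true(ad_assess(mod, X[3, , drop = FALSE])$in_domain)
  expect_error(ad_assess(mod, X[, 1, drop = FALSE]), "lacks")
})

test_that("AD comparison counts and agreement match a hand-enumerated fixture", {
  fx <- make_fixture("ad5")
  reports <- lapply(names(fx$subsets), function(nm) {
    ad_assess(build_leverage_model(fx$training[, fx$subsets[[nm]],
                                               drop = FALSE], nm),
              fx$query)
  })
  cmp <- ad_compare(reports)
  expect_equal(cmp$counts$n_in + cmp$counts$n_out, rep(5L, 3))
  # enumerate flags by hand via the explicit formula, per subset
  for (i in seq_along(fx$subsets)) {
    cols <- fx$subsets[[i]]
    Xi <- fx$training[, cols, drop = FALSE]
    G <- solve(crossprod(Xi))
    h <- apply(fx$query[, cols, drop = FALSE], 1,
               function(v) drop(t(v) %*% G %*% v))
    flags <- h <= min(1, 3 * length(cols) / nrow(Xi))
    expect_equal(reports[[i]]$in_domain, unname(flags))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(cmp$agreement[i, j],
                 mean(reports[[i]]$in_domain == reports[[j]]$in_domain))
  }
  # identical subsets agree perfectly
  cmp2 <- ad_compare(list(reports[[1]], reports[[1]]))
  expect_equal(unname(cmp2$agreement), matrix(1, 2, 2))
  scrambled <- reports[[2]]
  scrambled$id <- rev(scrambled$id)
  expect_error(ad_compare(list(reports[[1]], scrambled)),
               "different chemical sets")
})

test_that("shifted application chemicals fall outside the full-space domain", {
  flagged <- sapply(1:5, function(s) {
    cfg <- generator_config(n_chemicals = 120, n_descriptors = 40,
                            shift_sd = 10, seed = s)
    tr <- generate_training(cfg)
    app <- generate_application(cfg)
    cur <- curate(tr$replicates, app$table)
    mod <- build_leverage_model(cur$training$values, "full")
    rep <- ad_assess(mod, cur$application)
    mean(!rep$in_domain[app$shifted])
  })
  expect_true(all(flagged >= 0.9))
})

test_that("AD reports serialize to CSV and JSON", {
  fx <- make_fixture("ad5")
  reports <- lapply(names(fx$subsets), function(nm)
    ad_assess(build_leverage_model(fx$training[, fx$subsets[[nm]],
                                               drop = FALSE], nm),
              fx$query))
  f_csv <- withr::local_tempfile(fileext = ".csv")
  f_json <- withr::local_tempfile(fileext = ".json")
  write_ad_report(reports, f_csv, f_json)
  wide <- utils::read.csv(f_csv)
  expect_equal(nrow(wide), 5L)
  expect_true(all(c("leverage_full", "in_domain_regression") %in%
                    names(wide)))
  summ <- jsonlite::read_json(f_json, simplifyVector = TRUE)
  expect_equal(nrow(summ$subsets), 3L)
})
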