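#' Synthetic descriptor data sets
#'
#' Generates data with the structure of a real descriptor-based toxicity
#' study, so every pipeline stage can be exercised without external
#' downloads: a wide numeric descriptor matrix built from correlated latent
#' blocks (heavy-tailed, as real count/fragment descriptors are), replicate
#' calculation noise with a configurable fraction of unstable descriptors,
#' a skewed log10 LC50 response spanning roughly -3 to +5 log(mg/L),
#' monoisotopic masses in a configurable range, and an application set half
#' of which sits deliberately outside the training chemical space.
#'
#' @name synthetic-data
NULL

#' Generator configuration
#'
#' @param n_chemicals number of training chemicals (default 400).
#' @param n_descriptors number of descriptors (default 200).
#' @param n_latent number of latent factors / correlated blocks (default 10).
#' @param noise_sd standard deviation of the measurement noise on the
#'   response, log10(mg/L) units (default 0.3, the order of intra-source
#'   replicate variability of 96 h LC50 assays).
#' @param response `"smooth"` (sum of ridge functions of the signal
#'   descriptors) or `"discontinuous"` (thresholded latent score mapped to
#'   category-specific mean log LC50).
#' @param category_spread within-category standard deviation of log10 LC50
#'   for the discontinuous response (default 1.2). Calibrated jointly with
#'   `category_means` so the marginal log LC50 distribution spans roughly
#'   -3 to +5 log(mg/L), as pooled experimental acute fish toxicity sets
#'   do; a hazard category collapses a wide slice of the concentration
#'   scale, so this spread is large by construction.
#' @param signal_decay geometric decay of the signal-descriptor weights
#'   (default 0.7): importance is concentrated in the leading descriptors,
#'   as observed importance profiles of descriptor-based toxicity models
#'   are.
#' @param mass_range monoisotopic mass range in Da (default 50-1000).
#' @param unstable_fraction fraction of descriptors given large replicate
#'   jitter (default 0.05).
#' @param shift_sd latent-space shift, in training-sd units, applied to the
#'   out-of-domain half of the application set (default 10).
#' @param n_signal number of descriptors that carry the response signal
#'   (default 8).
#' @param category_means mean log10 LC50 per category for the
#'   discontinuous response; the defaults sit at the centres of the two
#'   bounded GHS bins and symmetrically below the first threshold.
#' @param category_weights mixture weights of the categories (default
#'   equal).
#' @param seed integer seed; every generator output is a pure function of
#'   the config including this seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_chemicals = 400L, n_descriptors = 200L,
                             n_latent = 10L, noise_sd = 0.3,
                             response = c("smooth", "discontinuous"),
                             mass_range = c(50, 1000),
                             unstable_fraction = 0.05, shift_sd = 10,
                             n_signal = 8L, signal_decay = 0.7,
                             category_means = c(-0.5, 0.5, 1.5),
                             category_spread = 1.2,
                             category_weights = c(1, 1, 1) / 3,
                             seed = 1L) {
  response <- match.arg(response)
  stopifnot(n_latent <= n_descriptors, noise_sd >= 0,
            length(mass_range) == 2L, all(mass_range > 0),
            mass_range[1L] < mass_range[2L],
            unstable_fraction >= 0, unstable_fraction <= 1,
            n_signal <= n_descriptors, signal_decay > 0, signal_decay <= 1,
            category_spread >= 0,
            length(category_means) == length(category_weights),
            all(category_weights > 0))
  structure(list(n_chemicals = as.integer(n_chemicals),
                 n_descriptors = as.integer(n_descriptors),
                 n_latent = as.integer(n_latent), noise_sd = noise_sd,
                 response = response, mass_range = mass_range,
                 unstable_fraction = unstable_fraction, shift_sd = shift_sd,
                 n_signal = as.integer(n_signal),
                 signal_decay = signal_decay,
                 category_means = category_means,
                 category_spread = category_spread,
                 category_weights = category_weights / sum(category_weights),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# latent structure shared by the training and application sets: drawn at the
# start of the seeded stream so both generators agree on it
.generator_structure <- function(config) {
  L <- config$n_latent; p <- config$n_descriptors
  block <- rep_len(seq_len(L), p)  # descriptor j belongs to block[j]
  W <- matrix(stats::rnorm(L * p, sd = 0.08), L, p)
  for (j in seq_len(p))
    W[block[j], j] <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.6, 1.4)
  signal <- seq_len(config$n_signal)  # one per block while blocks last
  shift_dir <- stats::rnorm(L)
  shift_dir <- shift_dir / sqrt(sum(shift_dir^2))
  list(W = W, block = block, signal = signal, shift_dir = shift_dir)
}

# monoisotopic masses correlated with the molecular-size latent (real
# descriptors encode size), near-uniform over mass_range marginally
.draw_masses <- function(Z, config) {
  u <- stats::pnorm(0.8 * Z[, ncol(Z)] + 0.6 * stats::rnorm(nrow(Z)))
  config$mass_range[1L] + diff(config$mass_range) * u
}

# heavy-tailed latent draws (t with 4 df, unit variance) emulate the skewed,
# outlier-rich distributions of real count/fragment descriptors
.draw_latent <- function(n, L) {
  matrix(stats::rt(n * L, df = 4) / sqrt(2), n, L)
}

.descriptor_values <- function(Z, structure_) {
  X <- Z %*% structure_$W
  # descriptors are computed quantities: only small numerical jitter
  X + matrix(stats::rnorm(length(X), sd = 0.05), nrow(X), ncol(X))
}

.response_from_X <- function(X, config) {
  S <- X[, seq_len(config$n_signal), drop = FALSE]
  w <- config$signal_decay^(seq_len(config$n_signal) - 1L)
  if (config$response == "smooth") {
    fns <- list(tanh, function(v) sin(v), function(v) v / (1 + abs(v)),
                function(v) pmin(pmax(v, -2), 2))
    raw <- 0
    for (k in seq_len(ncol(S)))
      raw <- raw + w[k] * fns[[(k - 1L) %% 4L + 1L]](S[, k])
    z <- (raw - mean(raw)) / stats::sd(raw)
    # mild right skew, located so the bulk spans about -3..+5 log(mg/L)
    y_mean <- 0.6 + 1.4 * z + 0.2 * (z^2 - 1)
    list(y = y_mean + stats::rnorm(length(y_mean), sd = config$noise_sd),
         category = NULL)
  } else {
    score <- as.vector(S %*% w)
    score <- (score - mean(score)) / stats::sd(score)
    # empirical quantile thresholds: category sizes honour the weights
    # regardless of the score's (heavy-tailed) shape
    qs <- cumsum(config$category_weights)
    cuts <- stats::quantile(score, qs[-length(qs)], names = FALSE)
    cat_idx <- findInterval(score, cuts) + 1L
    y_mean <- config$category_means[cat_idx]
    sd_y <- sqrt(config$category_spread^2 + config$noise_sd^2)
    list(y = y_mean + stats::rnorm(length(y_mean), sd = sd_y),
         category = cat_idx)
  }
}

#' Generate a synthetic training set
#'
#' @param config a [generator_config()].
#' @return list with `replicates` (three `descriptor_table`s; replicates 2
#'   and 3 carry tiny jitter except for the designated unstable
#'   descriptors), `chemicals` (data.frame with id, monoisotopic_mass, lc50
#'   in mg/L, log_lc50, and true_category for discontinuous responses), and
#'   `unstable_descriptors` (names of the large-jitter columns).
#' @export
generate_training <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  st <- .generator_structure(config)

  n <- config$n_chemicals; p <- config$n_descriptors
  Z <- .draw_latent(n, config$n_latent)
  X <- .descriptor_values(Z, st)
  colnames(X) <- sprintf("D%03d", seq_len(p))
  ids <- sprintf("CHEM%04d", seq_len(n))
  rownames(X) <- ids

  resp <- .response_from_X(X, config)
  masses <- .draw_masses(Z, config)
  chem <- data.frame(id = ids, monoisotopic_mass = masses,
                     log_lc50 = resp$y, lc50 = 10^resp$y,
                     stringsAsFactors = FALSE)
  if (!is.null(resp$category))
    chem$true_category <- .GHS_LABELS[resp$category]

  n_unstable <- round(config$unstable_fraction * p)
  unstable <- sort(sample.int(p, n_unstable))
  jitter_small <- matrix(stats::runif(n * p, -1e-8, 1e-8), n, p)
  reps <- list(descriptor_table(X, chemicals = chem, replicate_id = 1L))
  for (r in 2:3) {
    eps <- matrix(stats::runif(n * p, -1e-8, 1e-8), n, p)
    if (n_unstable)
      eps[, unstable] <- matrix(
        sample(c(-1, 1), n * n_unstable, replace = TRUE) *
          stats::runif(n * n_unstable, 0.2, 0.6), n, n_unstable)
    reps[[r]] <- descriptor_table(X * (1 + eps), chemicals = chem,
                                  replicate_id = r)
  }
  list(replicates = reps, chemicals = chem,
       unstable_descriptors = colnames(X)[unstable])
}

#' Generate a synthetic application set
#'
#' Half of the chemicals are drawn from the training descriptor
#' distribution; the other half are shifted by `shift_sd` training-sd units
#' along a fixed random direction in latent space, so they sit outside the
#' training chemical space by construction.
#'
#' @param config the same [generator_config()] used for the training set.
#' @param n_application number of application chemicals (default
#'   `config$n_chemicals`).
#' @param shift_sd override of `config$shift_sd`.
#' @return list with `table` (a `descriptor_table` with mass metadata) and
#'   `shifted` (logical vector marking the out-of-domain half).
#' @export
generate_application <- function(config, n_application = NULL,
                                 shift_sd = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(n_application)) n_application <- config$n_chemicals
  if (is.null(shift_sd)) shift_sd <- config$shift_sd
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  st <- .generator_structure(config)  # same structure as the training set
  set.seed(config$seed + 777L)

  n <- n_application
  Z <- .draw_latent(n, config$n_latent)
  shifted <- seq_len(n) > n / 2
  Z[shifted, ] <- Z[shifted, , drop = FALSE] +
    matrix(shift_sd * st$shift_dir, sum(shifted), config$n_latent,
           byrow = TRUE)
  X <- .descriptor_values(Z, st)
  colnames(X) <- sprintf("D%03d", seq_len(config$n_descriptors))
  ids <- sprintf("APP%04d", seq_len(n))
  rownames(X) <- ids
  masses <- .draw_masses(Z, config)
  chem <- data.frame(id = ids, monoisotopic_mass = masses,
                     stringsAsFactors = FALSE)
  list(table = descriptor_table(X, chemicals = chem), shifted = shifted)
}

#' Built-in deterministic fixtures
#'
#' Small, fully deterministic data sets used by the unit tests and examples:
#'
#' * `"curation6"` — 10 chemicals x 6 descriptors in triplicate plus an
#'   application table, built so that curation removes exactly one
#'   descriptor per filter (replicate-unstable, high scaled variance,
#'   cross-set ratio) and keeps the remaining three.
#' * `"blobs4"` — 400 points in the (log10 LC50, monoisotopic mass) plane
#'   drawn from 4 well-separated Gaussian components (sd = 5% of the
#'   between-center separation per coordinate), with true memberships.
#' * `"ad5"` — an 8-chemical training matrix over 4 descriptors, 5 query
#'   chemicals, and 3 named descriptor subsets for AD comparison.
#'
#' @param name one of `"curation6"`, `"blobs4"`, `"ad5"`.
#' @return the fixture (a list; contents depend on the fixture).
#' @export
make_fixture <- function(name) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  switch(name,
    curation6 = .fixture_curation6(),
    blobs4 = .fixture_blobs4(),
    ad5 = .fixture_ad5(),
    stop("unknown fixture: ", name))
}

.fixture_curation6 <- function() {
  set.seed(1106L)
  n <- 10L
  ids <- sprintf("FIX%02d", seq_len(n))
  # three keepers: modest spread around a nonzero level -> tiny scaled
  # variance; one high-variance column (alternating 0/10 -> scaled var 5/18);
  # one replicate-unstable column; one column exploding in the application set
  keep1 <- 10 + stats::runif(n, -0.5, 0.5)
  keep2 <- -5 + stats::runif(n, -0.3, 0.3)
  keep3 <- 100 + stats::runif(n, -2, 2)
  unstable <- 3 + stats::runif(n, -0.1, 0.1)
  highvar <- rep(c(0, 10), 5L)
  ratio <- 1 + stats::runif(n, 0, 1)
  X <- cbind(d_keep1 = keep1, d_keep2 = keep2, d_keep3 = keep3,
             d_unstable = unstable, d_highvar = highvar, d_ratio = ratio)
  rownames(X) <- ids
  chem <- data.frame(id = ids,
                     monoisotopic_mass = seq(100, 550, length.out = n),
                     lc50 = 10^seq(-2, 3, length.out = n),
                     stringsAsFactors = FALSE)
  r2 <- X; r3 <- X
  r2[1L, "d_unstable"] <- X[1L, "d_unstable"] * 1.5  # 50% replicate jump
  app_X <- X
  rownames(app_X) <- sprintf("APPFIX%02d", seq_len(n))
  app_X[, "d_ratio"] <- 500  # ratio 500 / max(train) >> 100
  app_chem <- data.frame(id = rownames(app_X),
                         monoisotopic_mass = seq(120, 600, length.out = n),
                         stringsAsFactors = FALSE)
  list(replicates = list(descriptor_table(X, chemicals = chem,
                                          replicate_id = 1L),
                         descriptor_table(r2, chemicals = chem,
                                          replicate_id = 2L),
                         descriptor_table(r3, chemicals = chem,
                                          replicate_id = 3L)),
       application = descriptor_table(app_X, chemicals = app_chem),
       expected = list(kept = c("d_keep1", "d_keep2", "d_keep3"),
                       removed_unstable = "d_unstable",
                       removed_variance = "d_highvar",
                       removed_ratio = "d_ratio"))
}

.fixture_blobs4 <- function() {
  set.seed(404L)
  centers <- cbind(log_lc50 = c(-2, 0, 2, 4),
                   mass = c(150, 400, 650, 900))
  # sd = 5% of the smallest between-center separation per coordinate
  sds <- c(0.05 * 2, 0.05 * 250)
  n_per <- 100L
  pts <- do.call(rbind, lapply(1:4, function(k)
    cbind(stats::rnorm(n_per, centers[k, 1L], sds[1L]),
          stats::rnorm(n_per, centers[k, 2L], sds[2L]))))
  colnames(pts) <- c("log_lc50", "mass")
  list(points = pts, membership = rep(1:4, each = n_per), centers = centers,
       sds = sds)
}

.fixture_ad5 <- function() {
  set.seed(505L)
  train <- matrix(stats::rnorm(8L * 4L), 8L, 4L,
                  dimnames = list(sprintf("TRN%02d", 1:8),
                                  paste0("d", 1:4)))
  query <- rbind(train[1L, ],                      # a training row: in-domain
                 matrix(stats::rnorm(2L * 4L, sd = 0.5), 2L, 4L),
                 matrix(stats::rnorm(2L * 4L, mean = 6), 2L, 4L))  # far out
  rownames(query) <- sprintf("QRY%02d", 1:5)
  colnames(query) <- paste0("d", 1:4)
  list(training = train, query = query,
       subsets = list(full = paste0("d", 1:4),
                      regression = c("d1", "d2"),
                      classification = c("d2", "d3", "d4")))
}
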