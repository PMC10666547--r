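# small shared builders for the unit tests

tiny_table <- function(values, ids = sprintf("C%02d", seq_len(nrow(values))),
                       ...) {
  descriptor_table(values, ids = ids, ...)
}

# a small training set with a learnable smooth response, for modeling tests
small_training <- function(seed = 11L, n = 120L, p = 30L) {
  cfg <- generator_config(n_chemicals = n, n_descriptors = p,
                          response = "smooth", seed = seed)
  tr <- generate_training(cfg)
  list(X = tr$replicates[[1L]]$values, y = tr$chemicals$log_lc50,
       chemicals = tr$chemicals, config = cfg)
}

quick_hp <- list(n_trees = 100L, min_leaf = 5L)
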