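# Small cohort specs used across test files.  Kept tiny so individual
# tests run in milliseconds; study-scale runs live in test-acceptance.R.

tiny_spec <- function(seed = 7, effect_table = list(), ...) {
  synth_spec(grid_shape = c(12, 10, 8), n_regions = 8,
             group_sizes = c(`0` = 3, `3` = 3, `10` = 3, `30` = 3),
             n_acquisitions = 40, baseline_len = 15,
             effect_table = effect_table, seed = seed, ...)
}

tiny_windows <- function() scan_windows(c(0, 15), c(15, 40))

# An activation map built directly from a category array, bypassing
# voxel_test, for count-oracle tests.
fake_map <- function(category, alpha = 0.05) {
  structure(list(percent_change = array(0, dim(category)),
                 p_value = array(0.5, dim(category)),
                 category = category, alpha = alpha, statistic = "welch",
                 windows = scan_windows()),
            class = "activation_map")
}

regions_with_tag_local <- function(table, tag) {
  phmriVoA:::regions_with_tag(table, tag)
}

# Brute-force BH step-up scan (independent of stats::p.adjust).
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0L
  for (i in seq_len(m)) if (p[ord[i]] <= q * i / m) k <- i
  pass <- rep(FALSE, m)
  if (k > 0L) pass[ord[seq_len(k)]] <- TRUE
  pass
}
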