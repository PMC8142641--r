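const_series <- function(baseline, stimulation, nb = 6, ns = 8) {
  x <- array(baseline, c(3, 3, 2, nb + ns))
  x[, , , (nb + 1):(nb + ns)] <- stimulation
  bold_series(x, "const", 0)
}
cube_atlas <- function() atlas_volume(array(1L, c(3, 3, 2)))

test_that("percent change matches its closed form", {
  w <- scan_windows(c(0, 6), c(6, 14))
  pc <- percent_change(const_series(100, 102), cube_atlas(), w)
  expect_equal(unique(as.vector(pc)), 2)
  pc <- percent_change(const_series(100, 95), cube_atlas(), w)
  expect_equal(unique(as.vector(pc)), -5)
  bad <- const_series(0, 5)
  expect_error(percent_change(bad, cube_atlas(), w), "nonpositive baseline")
})

test_that("noise-free synthetic amplitudes are recovered exactly", {
  eff <- list(`2` = dose_profile(c(`0` = 0, `3` = 1, `10` = 3, `30` = 1),
                                 affected_fraction = 1))
  spec <- tiny_spec(effect_table = eff, noise_sd = 1e-9, drift_slope = 0)
  at <- build_atlas(spec)
  s <- simulate_phmri_subject(at$atlas, at$table, spec, "10", seed = 2)
  pc <- percent_change(s, at$atlas, tiny_windows())
  vox <- at$atlas$labels == 2L
  expect_equal(as.vector(pc[vox]), rep(3, sum(vox)), tolerance = 1e-6)
  m <- voxel_test(s, at$atlas, tiny_windows(), detrend = FALSE)
  expect_true(all(m$category[vox] == 1L))
  expect_lt(max(m$p_value[vox]), 1e-12)
})

test_that("negating deviations from baseline swaps positive and negative", {
  spec <- tiny_spec(seed = 5,
                    effect_table = list(`4` = dose_profile(
                      c(`0` = 0, `3` = 0.5, `10` = 1.5, `30` = 0.5))))
  at <- build_atlas(spec)
  s <- simulate_phmri_subject(at$atlas, at$table, spec, "10", seed = 4)
  m1 <- voxel_test(s, at$atlas, tiny_windows(), detrend = FALSE)
  s2 <- s; s2$data <- 2 * spec$baseline_level - s$data  # reflect about baseline
  m2 <- voxel_test(s2, at$atlas, tiny_windows(), detrend = FALSE)
  expect_identical(sum(m1$category == 1L, na.rm = TRUE),
                   sum(m2$category == 2L, na.rm = TRUE))
  expect_identical(sum(m1$category == 2L, na.rm = TRUE),
                   sum(m2$category == 1L, na.rm = TRUE))
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
})

test_that("adding a constant leaves categories unchanged", {
  spec <- tiny_spec(seed = 9)
  at <- build_atlas(spec)
  s <- simulate_phmri_subject(at$atlas, at$table, spec, "3", seed = 11)
  m1 <- voxel_test(s, at$atlas, tiny_windows())
  s2 <- s; s2$data <- s$data + 50
  m2 <- voxel_test(s2, at$atlas, tiny_windows())
  expect_identical(m1$category, m2$category)
})

test_that("raising alpha never shrinks the flagged sets", {
  spec <- tiny_spec(seed = 13)
  at <- build_atlas(spec)
  s <- simulate_phmri_subject(at$atlas, at$table, spec, "30", seed = 17)
  m_lo <- voxel_test(s, at$atlas, tiny_windows(), alpha = 0.01)
  m_hi <- voxel_test(s, at$atlas, tiny_windows(), alpha = 0.10)
  c_lo <- region_counts(m_lo, at$atlas, at$table)
  c_hi <- region_counts(m_hi, at$atlas, at$table)
  expect_true(all(c_hi$n_positive >= c_lo$n_positive))
  expect_true(all(c_hi$n_negative >= c_lo$n_negative))
})

test_that("region counts match a brute-force per-voxel recount", {
  spec <- tiny_spec()
  at <- build_atlas(spec)
  set.seed(123)
  for (rep in 1:5) {
    cat3 <- array(NA_integer_, dim(at$atlas$labels))
    inb <- at$atlas$labels > 0L
    cat3[inb] <- sample(0:2, sum(inb), replace = TRUE)
    rc <- region_counts(fake_map(cat3), at$atlas, at$table)
    for (i in seq_len(nrow(rc))) {
      sel <- at$atlas$labels == rc$region_id[i]
      expect_identical(rc$n_positive[i], sum(cat3[sel] == 1L))
      expect_identical(rc$n_negative[i], sum(cat3[sel] == 2L))
      expect_identical(rc$n_total[i], sum(sel))
    }
    # conservation
    expect_identical(sum(rc$n_total), sum(inb))
  }
})

test_that("regions with no voxels yield zero rows, not missing rows", {
  at <- build_atlas(tiny_spec())
  tab2 <- region_table(c(at$table$region_id, 99L), c(at$table$name, "ghost"),
                       c(at$table$macro_region, "hindbrain"),
                       c(at$table$systems, "other"))
  cat3 <- array(NA_integer_, dim(at$atlas$labels))
  cat3[at$atlas$labels > 0L] <- 1L
  rc <- region_counts(fake_map(cat3), at$atlas, tab2)
  ghost <- rc[rc$region_id == 99L, ]
  expect_identical(ghost$n_total, 0L)
  expect_identical(ghost$n_positive, 0L)
})

test_that("group medians follow the stated conventions and an oracle", {
  voa <- data.frame(subject_id = sprintf("s%d", 1:5),
                    group = c("0", "0", "0", "3", "3"),
                    region_id = 1L,
                    n_positive = c(1L, 2L, 3L, 2L, 4L),
                    n_negative = 0L, n_total = 10L)
  gm <- group_medians(voa)
  expect_equal(gm$median_positive[gm$group == "0"], 2)
  expect_equal(gm$median_positive[gm$group == "3"], 3)  # mean-of-middle

  spec <- tiny_spec(seed = 41, effect_table = effect_table_inverted_u(c(2, 6)))
  coh <- make_cohort(spec, "phmri")
  voa2 <- cohort_voa(coh, windows = tiny_windows())
  gm2 <- group_medians(voa2)
  for (i in sample(nrow(gm2), 10)) {
    sel <- voa2$region_id == gm2$region_id[i] & voa2$group == gm2$group[i]
    expect_equal(gm2$median_positive[i], median(voa2$n_positive[sel]))
    expect_equal(gm2$median_negative[i], median(voa2$n_negative[sel]))
  }
})
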