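test_that("build_atlas partitions the grid into the requested regions", {
  spec2 <- synth_spec(grid_shape = c(4, 4, 4), n_regions = 2,
                      group_sizes = c(`0` = 1, `3` = 1, `10` = 1, `30` = 1))
  at <- build_atlas(spec2)
  labs <- at$atlas$labels
  expect_setequal(setdiff(unique(as.vector(labs)), 0L), 1:2)
  expect_true(all(table(labs[labs > 0]) > 0))
  # regions are disjoint by construction: every voxel carries one label
  expect_equal(sum(labs == 1) + sum(labs == 2), sum(labs > 0))
})

test_that("default 138-region atlas gives every region at least 8 voxels", {
  at <- build_atlas(synth_spec())
  sizes <- table(at$atlas$labels[at$atlas$labels > 0])
  expect_length(sizes, 138L)
  expect_true(all(sizes >= 8))
  # macro-regions occupy contiguous slabs along the rostral-caudal axis
  rc_extent <- function(ids) {
    range(which(apply(at$atlas$labels, 1, function(sl) any(sl %in% ids))))
  }
  fb <- rc_extent(at$table$region_id[at$table$macro_region == "forebrain"])
  hb <- rc_extent(at$table$region_id[at$table$macro_region == "hindbrain"])
  expect_lt(fb[2], hb[2])
  expect_lte(fb[1], hb[1])
})

test_that("atlas construction is deterministic and validates grid size", {
  s <- tiny_spec()
  expect_identical(build_atlas(s)$atlas$labels, build_atlas(s)$atlas$labels)
  expect_error(build_atlas(synth_spec(grid_shape = c(5, 5, 4), n_regions = 50,
                                      group_sizes = c(`0` = 1, `3` = 1,
                                                      `10` = 1, `30` = 1))),
               "too small")
})

test_that("noise-free phMRI subjects carry exactly the configured step", {
  eff <- list(`3` = dose_profile(c(`0` = 0, `3` = 1, `10` = 5, `30` = 1),
                                 affected_fraction = 1))
  spec <- tiny_spec(effect_table = eff, noise_sd = 1e-9, drift_slope = 0)
  at <- build_atlas(spec)
  s <- simulate_phmri_subject(at$atlas, at$table, spec, "10", seed = 1)
  flat <- matrix(s$data, prod(spec$grid_shape), spec$n_acquisitions)
  vox <- which(as.vector(at$atlas$labels) == 3L)
  base_mean <- rowMeans(flat[vox, 1:15, drop = FALSE])
  stim_mean <- rowMeans(flat[vox, 16:40, drop = FALSE])
  expect_equal(stim_mean, 1.05 * base_mean, tolerance = 1e-6)
  # locality: unseeded regions do not shift
  vox0 <- which(as.vector(at$atlas$labels) == 1L)
  expect_equal(rowMeans(flat[vox0, 16:40, drop = FALSE]),
               rowMeans(flat[vox0, 1:15, drop = FALSE]), tolerance = 1e-6)
  expect_error(simulate_phmri_subject(at$atlas, at$table, spec, "99", 1),
               "unknown dose")
})

test_that("an all-null subject flags about alpha of its voxels", {
  spec <- synth_spec(seed = 21)  # default grid, no effects
  at <- build_atlas(spec)
  s <- simulate_phmri_subject(at$atlas, at$table, spec, "0", seed = 5)
  m <- voxel_test(s, at$atlas)
  frac <- mean(m$category[!is.na(m$category)] != 0L)
  n <- sum(!is.na(m$category))
  expect_gt(n, 1e4)
  ci <- 0.05 + c(-1, 1) * qnorm(0.995) * sqrt(0.05 * 0.95 / n)
  expect_gt(frac, ci[1]); expect_lt(frac, ci[2])
})

test_that("resting-state block correlations are recovered in sample", {
  # zero off-diagonal coupling: mean |r| between systems stays small
  null_block <- matrix(0, 5, 5, dimnames = list(phmriVoA:::SYSTEM_TAGS,
                                                phmriVoA:::SYSTEM_TAGS))
  diag(null_block) <- 0.5
  spec0 <- tiny_spec(rs_block_corr = list(vehicle = null_block,
                                          CBD = null_block),
                     rs_n_acquisitions = 300)
  at <- build_atlas(spec0)
  s <- simulate_rsfc_subject(at$atlas, at$table, spec0, "vehicle", seed = 3)
  ts <- region_timeseries(s, at$atlas, at$table)
  sys <- spec0$system_tags
  r <- cor(t(ts))
  between <- r[outer(sys, sys, "!=")]
  expect_lt(mean(abs(between)), 0.12)

  # a 0.6 ARAS-olfactory block in one group is recovered across seeds
  blk <- null_block; blk["ARAS", "olfactory"] <- blk["olfactory", "ARAS"] <- 0.6
  spec1 <- tiny_spec(rs_block_corr = list(vehicle = null_block, CBD = blk),
                     rs_voxel_sd = 1e-6)
  at1 <- build_atlas(spec1)
  pair_r <- vapply(derive_seeds(99, 40), function(sd) {
    s1 <- simulate_rsfc_subject(at1$atlas, at1$table, spec1, "CBD", seed = sd)
    ts1 <- region_timeseries(s1, at1$atlas, at1$table)
    r1 <- cor(t(ts1))
    mean(r1[sys == "ARAS", sys == "olfactory"])
  }, 0)
  expect_equal(mean(pair_r), 0.6, tolerance = 0.05)
})

test_that("identical spec and seed reproduce subjects bit for bit", {
  spec <- tiny_spec(seed = 31)
  at <- build_atlas(spec)
  a <- simulate_phmri_subject(at$atlas, at$table, spec, "3", seed = 8)
  b <- simulate_phmri_subject(at$atlas, at$table, spec, "3", seed = 8)
  expect_identical(a$data, b$data)
  r1 <- simulate_rsfc_subject(at$atlas, at$table, spec, "CBD", seed = 8)
  r2 <- simulate_rsfc_subject(at$atlas, at$table, spec, "CBD", seed = 8)
  expect_identical(r1$data, r2$data)
  c1 <- make_cohort(spec, "phmri"); c2 <- make_cohort(spec, "phmri")
  expect_identical(lapply(c1$subjects, `[[`, "data"),
                   lapply(c2$subjects, `[[`, "data"))
})

test_that("make_cohort sizes follow the group design", {
  spec <- tiny_spec()
  spec$group_sizes <- c(`0` = 8L, `3` = 6L, `10` = 5L, `30` = 7L)
  spec$grid_shape <- c(12L, 10L, 8L)
  coh <- make_cohort(spec, "phmri")
  expect_length(coh$subjects, 26L)
  grp <- vapply(coh$subjects, `[[`, "", "group")
  expect_equal(as.integer(table(grp)[c("0", "3", "10", "30")]),
               c(8L, 6L, 5L, 7L))
  rs <- make_cohort(tiny_spec(), "rsfc")
  expect_length(rs$subjects, 20L)
  expect_length(make_cohort(tiny_spec(), "phmri")$ground_truth$effects, 0L)
})

test_that("a non-PSD block design is rejected with the offending block named", {
  bad <- matrix(0.9, 5, 5, dimnames = list(phmriVoA:::SYSTEM_TAGS,
                                           phmriVoA:::SYSTEM_TAGS))
  diag(bad) <- 0.1  # within-system far below between-system: impossible
  spec <- tiny_spec(rs_block_corr = list(vehicle = bad, CBD = bad))
  at <- build_atlas(spec)
  expect_error(simulate_rsfc_subject(at$atlas, at$table, spec, "vehicle", 1),
               "positive-semidefinite")
})
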