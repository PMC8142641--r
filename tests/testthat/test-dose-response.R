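test_that("kruskal_wallis handles degenerate and shifted data", {
  expect_equal(kruskal_wallis(rep(4, 10), rep(1:2, 5)),
               list(H = 0, p = 1, df = 1L, method = "chisq"))
  set.seed(2)
  # shifting the largest group far from the rest drives H to its ceiling
  # for a single-group separation (p of order 1e-3 at these group sizes)
  x <- c(rnorm(8) + 50, rnorm(6), rnorm(5), rnorm(7))
  g <- rep(c("0", "3", "10", "30"), c(8, 6, 5, 7))
  kt <- kruskal_wallis(x, g)
  expect_lt(kt$p, 0.01)
  kp <- kruskal_wallis(x, g, method = "permutation", n_perm = 2e4, seed = 5)
  expect_lt(kp$p, 0.01)
  expect_lt(abs(kt$p - kp$p), 0.005)
})

test_that("kruskal_wallis is invariant to joint label permutation", {
  set.seed(3)
  x <- rnorm(20); g <- rep(letters[1:4], 5)
  perm <- sample(20)
  a <- kruskal_wallis(x, g); b <- kruskal_wallis(x[perm], g[perm])
  expect_equal(a$H, b$H); expect_equal(a$p, b$p)
})

test_that("chi-square p tracks the permutation p at small n", {
  # light version of the agreement study (the full 100-dataset study runs
  # in the acceptance suite); tolerance covers the chi-square
  # approximation bias at n = 16 plus Monte-Carlo error
  set.seed(11)
  for (i in 1:10) {
    g <- rep(1:4, each = 4)
    x <- rnorm(16) + rep(runif(4, -1, 1), each = 4)
    pc <- kruskal_wallis(x, g)$p
    pp <- kruskal_wallis(x, g, method = "permutation", n_perm = 1e4,
                         seed = i)$p
    expect_lt(abs(pc - pp), 0.08)
  }
})

test_that("bh_fdr reproduces the step-up rule and its realized threshold", {
  r <- bh_fdr(0.03, q = 0.05)
  expect_true(r$pass); expect_equal(r$threshold, 0.03)
  r <- bh_fdr(rep(0.04, 138), q = 0.05)
  expect_true(all(r$pass)); expect_equal(r$threshold, 0.04)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:200) {
    m <- sample(1:60, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)  # mix of null-ish and signal-ish
    r <- bh_fdr(p, q = 0.05)
    expect_identical(r$pass, bh_oracle(p, 0.05))
    if (any(r$pass)) expect_equal(r$threshold, max(p[r$pass]))
    else expect_true(is.na(r$threshold))
  }
})

test_that("omega squared matches a direct ANOVA decomposition and clips", {
  set.seed(13)
  x <- c(rnorm(8, 0), rnorm(6, 0.5), rnorm(5, 3), rnorm(7, 0.5))
  g <- factor(rep(1:4, c(8, 6, 5, 7)))
  tab <- anova(aov(x ~ g))
  ssb <- tab["g", "Sum Sq"]; ssw <- tab["Residuals", "Sum Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  direct <- (ssb - 3 * msw) / (ssb + ssw + msw)
  expect_equal(omega_squared(x, g), direct, tolerance = 1e-12)
  # identical group means with within-variance: clipped to 0
  y <- rep(c(-1, 1), 8); gy <- rep(1:4, each = 4)
  expect_equal(omega_squared(y, gy), 0)
  # scale invariance
  expect_equal(omega_squared(3 * x, g), omega_squared(x, g))
  expect_warning(o0 <- omega_squared(rep(2, 8), rep(1:2, 4)), "zero total variance")
  expect_equal(o0, 0)
})

test_that("shape classification follows the four-dose rule", {
  expect_equal(classify_shape(c(`0` = 2, `3` = 5, `10` = 20, `30` = 6)), "inverted-U")
  expect_equal(classify_shape(c(`0` = 20, `3` = 18, `10` = 3, `30` = 8)), "U")
  expect_equal(classify_shape(c(`0` = 5, `3` = 5, `10` = 5, `30` = 5)), "flat")
  expect_equal(classify_shape(c(`0` = 1, `3` = 3, `10` = 5, `30` = 7)), "monotonic")
  expect_equal(classify_shape(c(`0` = 9, `3` = 7, `10` = 5, `30` = 3)), "monotonic")
  # delta gates the separation
  expect_equal(classify_shape(c(`0` = 2, `3` = 5, `10` = 5.5, `30` = 5), delta = 1), "flat")
  # names are sorted numerically, not lexically
  expect_equal(classify_shape(c(`10` = 20, `0` = 2, `30` = 6, `3` = 5)), "inverted-U")
  expect_error(classify_shape(c(`0` = 1, `3` = 2, `10` = 3)), "four doses")
})

test_that("region_dose_stats ranks by p and flags consistently", {
  spec <- tiny_spec(seed = 19, effect_table = effect_table_inverted_u(c(3, 7)))
  coh <- make_cohort(spec, "phmri")
  voa <- cohort_voa(coh, windows = tiny_windows())
  st <- region_dose_stats(voa, coh$table)
  expect_identical(nrow(st), 8L)
  expect_false(is.unsorted(st$p))
  thr <- attr(st, "fdr_threshold")
  if (!is.na(thr)) expect_identical(st$fdr_pass, st$p <= thr)
  else expect_false(any(st$fdr_pass))
  expect_true(all(st$omega2 >= 0 & st$omega2 <= 1))
})

test_that("macro aggregation reduces to the single region it selects", {
  spec <- tiny_spec(seed = 23)
  coh <- make_cohort(spec, "phmri")
  voa <- cohort_voa(coh, windows = tiny_windows())
  # restrict the table to make 'olfactory' a single region
  tab <- coh$table
  only <- phmriVoA:::regions_with_tag(tab, "olfactory")
  expect_length(only, 1L)
  ms <- macro_aggregate(voa, tab, "olfactory")
  gm <- group_medians(voa[voa$region_id == only, ])
  expect_equal(ms$summary$mean_median,
               gm$median_positive[match(ms$summary$dose, gm$group)])
  # permuting region order leaves the summary unchanged
  voa_perm <- voa[rev(seq_len(nrow(voa))), ]
  ms2 <- macro_aggregate(voa_perm, tab, "forebrain")
  ms1 <- macro_aggregate(voa, tab, "forebrain")
  expect_equal(ms1$summary, ms2$summary)
  expect_error(macro_aggregate(voa, tab, "nosuchtag"), "matches no regions")
})

test_that("time-course comparison separates offset groups, not identical ones", {
  spec <- tiny_spec(seed = 29, noise_sd = 1)
  at <- build_atlas(spec)
  mk <- function(id, group, offset = 0, seed) {
    s <- simulate_phmri_subject(at$atlas, at$table, spec, group, seed,
                                subject_id = id)
    s$data <- s$data + offset
    s
  }
  seeds <- derive_seeds(77, 8)
  same <- c(lapply(1:4, function(i) mk(paste0("a", i), "0", 0, seeds[i])),
            lapply(1:4, function(i) mk(paste0("b", i), "3", 0, seeds[i])))
  tc0 <- timecourse_compare(same, at$atlas, at$table, "forebrain",
                            groups = c("0", "3"))
  expect_equal(tc0$F, 0, tolerance = 1e-9)
  expect_gt(tc0$p, 0.999)
  expect_identical(tc0$df1, 1L)
  off <- c(lapply(1:4, function(i) mk(paste0("a", i), "0", 0, seeds[i])),
           lapply(1:4, function(i) mk(paste0("b", i), "3", 25, seeds[i + 4])))
  tc1 <- timecourse_compare(off, at$atlas, at$table, "forebrain",
                            groups = c("0", "3"))
  expect_lt(tc1$p, 1e-6)
  expect_match(tc1$direction, "3 > 0")
  # scaling all signals scales traces but leaves F and p unchanged
  sc <- lapply(off, function(s) { s$data <- 2 * s$data; s })
  tc2 <- timecourse_compare(sc, at$atlas, at$table, "forebrain",
                            groups = c("0", "3"))
  expect_equal(tc2$F, tc1$F, tolerance = 1e-9)
  expect_equal(tc2$p, tc1$p, tolerance = 1e-9)
  expect_equal(max(abs(tc2$traces$mean_signal - 2 * tc1$traces$mean_signal)), 0,
               tolerance = 1e-9)
})
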