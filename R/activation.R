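# Flatten the in-brain voxels of a series to a voxels x acquisitions matrix.
mask_matrix <- function(series, atlas) {
  check_shapes(series, atlas)
  mask <- which(as.vector(atlas$labels) > 0L)
  d <- dim(series$data)
  list(mask = mask,
       x = matrix(series$data, prod(d[1:3]), d[4])[mask, , drop = FALSE])
}

# Remove a linear drift estimated on the baseline window of the brain-mean
# trace.  The drift confound is modelled as shared across voxels, so the
# brain mean estimates it with negligible noise; per-voxel baseline-only
# fits would extrapolate into the stimulation window with enough slope
# error to distort the voxel tests.
detrend_baseline <- function(x, idx_baseline) {
  gm <- colMeans(x)
  t_all <- seq_len(ncol(x)) - 1
  fit <- lm(gm[idx_baseline] ~ t_all[idx_baseline])
  b <- coef(fit)
  drift <- b[[2]] * t_all  # keep the intercept: levels stay interpretable
  x - rep(drift, each = nrow(x))
}

#' Per-voxel percent signal change between scan windows
#'
#' For every in-brain voxel, computes
#' `100 * (mean(stimulation) - mean(baseline)) / mean(baseline)`,
#' the standard phMRI percent-signal-change measure relative to the
#' pre-injection baseline.
#'
#' @param series a [bold_series()].
#' @param atlas an [atlas_volume()]; the brain mask is the union of its
#'   positive labels.
#' @param windows a [scan_windows()].
#' @return 3D numeric array of percent changes, `NA` outside the mask.
#' @export
#' @examples
#' a <- atlas_volume(array(1L, c(2, 2, 1)))
#' x <- array(100, c(2, 2, 1, 10)); x[, , , 6:10] <- 102
#' s <- bold_series(x, "demo", group = 0)
#' percent_change(s, a, scan_windows(c(0, 5), c(5, 10)))[1, 1, 1]  # +2
percent_change <- function(series, atlas, windows = scan_windows()) {
  mm <- mask_matrix(series, atlas)
  idx <- validate_windows(windows, dim(series$data)[4])
  mb <- rowMeans(mm$x[, idx$baseline, drop = FALSE])
  if (any(mb <= 0)) {
    bad <- mm$mask[mb <= 0]
    stop("nonpositive baseline mean at in-mask voxel(s): ",
         paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" ... (%d total)", length(bad)) else "")
  }
  ms <- rowMeans(mm$x[, idx$stimulation, drop = FALSE])
  out <- array(NA_real_, dim = dim(series$data)[1:3])
  out[mm$mask] <- 100 * (ms - mb) / mb
  out
}

# Vectorised two-sample statistics over voxel rows. Returns two-sided p.
voxel_two_sample_p <- function(xb, xs, statistic) {
  n1 <- ncol(xb); n2 <- ncol(xs)
  m1 <- rowMeans(xb); m2 <- rowMeans(xs)
  switch(statistic,
    welch = {
      v1 <- rowSums((xb - m1)^2) / (n1 - 1)
      v2 <- rowSums((xs - m2)^2) / (n2 - 1)
      se2 <- v1 / n1 + v2 / n2
      tt <- (m2 - m1) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
      p <- 2 * pt(-abs(tt), df)
      p[se2 == 0] <- ifelse(m2[se2 == 0] == m1[se2 == 0], 1, 0)
      p
    },
    student = {
      sp2 <- (rowSums((xb - m1)^2) + rowSums((xs - m2)^2)) / (n1 + n2 - 2)
      tt <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
      p <- 2 * pt(-abs(tt), n1 + n2 - 2)
      p[sp2 == 0] <- ifelse(m2[sp2 == 0] == m1[sp2 == 0], 1, 0)
      p
    },
    wilcoxon = {
      # normal-approximation rank-sum with tie correction, per voxel
      n <- n1 + n2
      xall <- cbind(xb, xs)
      apply(xall, 1L, function(row) {
        r <- rank(row)
        w <- sum(r[(n1 + 1):n]) - n2 * (n2 + 1) / 2
        ties <- table(row)
        cf <- sum(ties^3 - ties) / (n * (n - 1))
        s2 <- n1 * n2 / 12 * (n + 1 - cf)
        if (s2 == 0) return(1)
        2 * pnorm(-abs((w - n1 * n2 / 2) / sqrt(s2)))
      })
    },
    stop("unknown statistic '", statistic, "'"))
}

#' Voxel-wise positive/negative BOLD activation test
#'
#' Compares each in-brain voxel's stimulation-window samples against its
#' baseline-window samples with a two-sample test (Welch t by default) and
#' categorises the voxel as positively activated, negatively activated, or
#' unchanged. The voxel-level alpha is uncorrected: multiplicity control
#' happens at the region level (FDR over regions), mirroring the two-tier
#' structure of volume-of-activation analyses. An optional linear detrend,
#' fitted on the baseline window of the brain-mean trace, is removed from
#' the whole series first.
#'
#' @inheritParams percent_change
#' @param alpha per-voxel significance level (default 0.05).
#' @param detrend remove the baseline-fitted linear drift first?
#' @param statistic `"welch"` (default), `"student"`, or `"wilcoxon"`.
#' @return An object of class `activation_map`: list with 3D arrays
#'   `percent_change`, `p_value`, `category` (codes 0 none / 1 positive /
#'   2 negative; `NA` outside the mask), plus `alpha`, `statistic`,
#'   `windows`.
#' @export
voxel_test <- function(series, atlas, windows = scan_windows(), alpha = 0.05,
                       detrend = TRUE,
                       statistic = c("welch", "student", "wilcoxon")) {
  statistic <- match.arg(statistic)
  mm <- mask_matrix(series, atlas)
  idx <- validate_windows(windows, dim(series$data)[4])
  x <- mm$x
  if (detrend) x <- detrend_baseline(x, idx$baseline)
  xb <- x[, idx$baseline, drop = FALSE]
  xs <- x[, idx$stimulation, drop = FALSE]
  mb <- rowMeans(xb)
  if (any(mb <= 0))
    stop("nonpositive baseline mean at in-mask voxel(s): ",
         paste(head(mm$mask[mb <= 0], 10L), collapse = ", "))
  pc <- 100 * (rowMeans(xs) - mb) / mb
  p <- voxel_two_sample_p(xb, xs, statistic)
  cat_codes <- ifelse(p < alpha, ifelse(pc > 0, 1L, 2L), 0L)
  shape3 <- dim(series$data)[1:3]
  wrap <- function(v, fill) { a <- array(fill, shape3); a[mm$mask] <- v; a }
  structure(list(percent_change = wrap(pc, NA_real_),
                 p_value = wrap(p, NA_real_),
                 category = wrap(cat_codes, NA_integer_),
                 alpha = alpha, statistic = statistic, windows = windows),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  tab <- table(factor(as.vector(x$category), levels = 0:2,
                      labels = c("none", "positive", "negative")))
  cat(sprintf("Activation map (%s, alpha %g): %d+ / %d- / %d unchanged of %d in-brain voxels\n",
              x$statistic, x$alpha, tab[["positive"]], tab[["negative"]],
              tab[["none"]], sum(tab)))
  invisible(x)
}

#' Write an activation category map as NIfTI-1
#'
#' Codes: 0 none, 1 positive, 2 negative; background voxels are written
#' as 0.
#'
#' @param map an `activation_map`.
#' @param path output path.
#' @export
write_activation_map <- function(map, path) {
  cat3 <- map$category
  cat3[is.na(cat3)] <- 0L
  RNifti::writeNifti(RNifti::asNifti(cat3, datatype = "int16"), path)
  invisible(path)
}

#' Per-region volume-of-activation counts
#'
#' Counts positively and negatively activated voxels in every atlas
#' region. Regions with no in-mask voxels get zero rows, not missing rows.
#'
#' @param map an `activation_map` from [voxel_test()].
#' @param atlas the [atlas_volume()] the map was computed against.
#' @param table a [region_table()]; its ids define the output rows.
#' @param subject_id,group carried into the output for bookkeeping.
#' @return A `region_voa` data frame: `subject_id`, `group`, `region_id`,
#'   `n_positive`, `n_negative`, `n_total`.
#' @export
region_counts <- function(map, atlas, table, subject_id = NA_character_,
                          group = NA) {
  if (!all(dim(map$category) == dim(atlas$labels)))
    stop(sprintf("map shape %s does not match atlas shape %s",
                 paste(dim(map$category), collapse = "x"),
                 paste(dim(atlas$labels), collapse = "x")))
  lab <- as.vector(atlas$labels)
  cat3 <- as.vector(map$category)
  keep <- lab > 0L & !is.na(cat3)
  ids <- table$region_id
  f <- factor(lab[keep], levels = ids)
  n_total <- as.integer(base::table(f))
  n_pos <- as.integer(base::table(f[cat3[keep] == 1L]))
  n_neg <- as.integer(base::table(f[cat3[keep] == 2L]))
  structure(data.frame(subject_id = subject_id, group = group,
                       region_id = ids, n_positive = n_pos,
                       n_negative = n_neg, n_total = n_total,
                       stringsAsFactors = FALSE),
            class = c("region_voa", "data.frame"))
}

#' Volume-of-activation counts for a whole cohort
#'
#' Runs [voxel_test()] and [region_counts()] on every subject.
#'
#' @param cohort a `phmri_cohort` from [make_cohort()] (phMRI mode), or a
#'   list of [bold_series()] plus explicit `atlas`/`table`.
#' @param atlas,table override the cohort's own (optional).
#' @inheritParams voxel_test
#' @return A long `region_voa` data frame over all subjects.
#' @export
cohort_voa <- function(cohort, atlas = cohort$atlas, table = cohort$table,
                       windows = scan_windows(), alpha = 0.05, detrend = TRUE,
                       statistic = "welch") {
  subjects <- if (inherits(cohort, "phmri_cohort")) cohort$subjects else cohort
  out <- lapply(subjects, function(s) {
    m <- voxel_test(s, atlas, windows, alpha = alpha, detrend = detrend,
                    statistic = statistic)
    region_counts(m, atlas, table, subject_id = s$subject_id, group = s$group)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  structure(res, class = c("region_voa", "data.frame"))
}

#' Group medians of volume-of-activation counts
#'
#' The sample median (mean-of-middle convention for even group sizes) of
#' per-subject voxel counts, per region and dose, separately for positive
#' and negative counts.
#'
#' @param voa long `region_voa` data frame (e.g. from [cohort_voa()]).
#' @return Data frame `region_id`, `group`, `median_positive`,
#'   `median_negative`, `n_subjects`.
#' @export
group_medians <- function(voa) {
  stopifnot(all(c("region_id", "group", "n_positive", "n_negative") %in% names(voa)))
  if (anyNA(voa$group)) stop("every subject must be assigned to a dose group")
  split_by <- interaction(voa$region_id, voa$group, drop = FALSE)
  agg <- function(col) as.vector(tapply(voa[[col]], split_by, median))
  key <- expand.grid(region_id = sort(unique(voa$region_id)),
                     group = unique(voa$group))
  lev <- levels(split_by)
  ord <- match(paste(key$region_id, key$group, sep = "."), lev)
  n_by <- as.vector(tapply(voa$n_positive, split_by, length))
  if (any(is.na(n_by[ord])) || any(n_by[ord] == 0))
    stop("empty dose group in VoA table")
  data.frame(region_id = key$region_id, group = key$group,
             median_positive = agg("n_positive")[ord],
             median_negative = agg("n_negative")[ord],
             n_subjects = n_by[ord])
}

#' Write per-subject VoA counts as TSV
#'
#' Columns: `subject_id region_id n_positive n_negative n_total`.
#' @param voa a `region_voa` data frame.
#' @param path output path.
#' @export
write_voa <- function(voa, path) {
  write_tsv(voa[, c("subject_id", "region_id", "n_positive", "n_negative",
                    "n_total")], path)
}
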