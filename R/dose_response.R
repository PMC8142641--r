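# Tie-corrected Kruskal-Wallis H for fixed data; used by the permutation
# route (the chi-square route delegates to stats::kruskal.test).
kw_statistic <- function(r, g_index, n_per, tie_term) {
  sums <- vapply(split(r, g_index), sum, 0)
  h <- 12 / (length(r) * (length(r) + 1)) * sum(sums^2 / n_per) -
    3 * (length(r) + 1)
  h / tie_term
}

#' Kruskal-Wallis test across dose groups
#'
#' Omnibus k-group comparison of per-subject voxel counts (or any
#' samples). The default p-value comes from the tie-corrected chi-square
#' approximation with `k - 1` degrees of freedom (via
#' [stats::kruskal.test()]); `method = "permutation"` instead estimates p
#' by Monte-Carlo relabelling, useful as an exact reference at small n.
#' When all observations are identical there is no rank variation and the
#' test returns `H = 0`, `p = 1`.
#'
#' @param x numeric observations.
#' @param g group labels, same length as `x`; at least 2 nonempty groups.
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed seed for the permutation draw.
#' @return List with `H`, `p`, `df`, `method`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
kruskal_wallis <- function(x, g, method = c("chisq", "permutation"),
                           n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) < 1L)) stop("every group needs at least 1 observation")
  if (length(x) != length(g)) stop("x and g lengths differ")
  k <- nlevels(g)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = k - 1L, method = method))
  if (method == "chisq") {
    kt <- kruskal.test(x, g)
    return(list(H = unname(kt$statistic), p = unname(kt$p.value),
                df = unname(kt$parameter), method = method))
  }
  n <- length(x)
  r <- rank(x)
  ties <- base::table(x)
  tie_term <- 1 - sum(ties^3 - ties) / (n^3 - n)
  n_per <- tabulate(g)
  g_index <- as.integer(g)
  h_obs <- kw_statistic(r, g_index, n_per, tie_term)
  h_perm <- with_seed(seed, {
    # relabelling is equivalent to permuting the rank vector over fixed
    # group blocks; vectorised via rowsum over all permutations at once
    R <- vapply(seq_len(n_perm), function(i) r[sample.int(n)], numeric(n))
    S <- rowsum(R, g_index)
    (12 / (n * (n + 1)) * colSums(S^2 / n_per) - 3 * (n + 1)) / tie_term
  })
  p <- (1 + sum(h_perm >= h_obs - 1e-12)) / (n_perm + 1)
  list(H = h_obs, p = p, df = k - 1L, method = method)
}

#' Benjamini-Hochberg FDR over regions
#'
#' Step-up procedure at rate `q`. The realized threshold — the largest p
#' among passing regions, i.e. the number reported in the
#' "significance level for FDR was p <= x" style — accompanies the flags;
#' it is `NA` when nothing passes.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q false-discovery rate (default 0.05).
#' @return List with logical `pass`, `threshold`, and `q`.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.2, 0.8), q = 0.05)
bh_fdr <- function(p, q = 0.05) {
  if (length(p) < 1L) stop("need at least one p-value")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  pass <- p.adjust(p, method = "BH") <= q
  threshold <- if (any(pass)) max(p[pass]) else NA_real_
  list(pass = pass, threshold = threshold, q = q)
}

#' Omega-squared effect size for a k-group comparison
#'
#' Classical one-way ANOVA decomposition of the raw observations:
#' `omega^2 = (SS_between - (k-1) MS_within) / (SS_total + MS_within)`,
#' clipped to `[0, 1]` (small-sample estimates can fall below zero when
#' group means are close). Zero total variance is degenerate and returns
#' 0 with a warning.
#'
#' @inheritParams kruskal_wallis
#' @return Effect size in `[0, 1]`.
#' @export
omega_squared <- function(x, g) {
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (length(x) != length(g)) stop("x and g lengths differ")
  n <- length(x); k <- nlevels(g)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  n_per <- tabulate(g)
  ss_b <- sum(n_per * (means - gm)^2)
  ss_t <- sum((x - gm)^2)
  if (ss_t == 0) {
    warning("zero total variance; omega-squared undefined, returning 0")
    return(0)
  }
  ms_w <- (ss_t - ss_b) / (n - k)
  min(1, max(0, (ss_b - (k - 1) * ms_w) / (ss_t + ms_w)))
}

#' Classify the dose-response shape of four-group medians
#'
#' With doses in increasing order (vehicle, low, mid, high; 0/3/10/30 in
#' the reference design), labels:
#' \describe{
#'   \item{inverted-U}{the mid dose exceeds vehicle, low and high, each by
#'     at least `delta` — effect maximal at an intermediate dose.}
#'   \item{U}{among the active doses the mid dose is the minimum and the
#'     low dose the maximum, each margin at least `delta`.}
#'   \item{monotonic}{values strictly ordered across all four doses
#'     (either direction) by at least `delta` per step.}
#'   \item{flat}{anything else.}
#' }
#' The default `delta` of 1 reflects integer voxel counts.
#'
#' @param medians numeric of length 4, named by dose; ordered by numeric
#'   dose internally when the names parse as numbers.
#' @param delta minimum separation.
#' @return One of `"inverted-U"`, `"U"`, `"monotonic"`, `"flat"`.
#' @export
#' @examples
#' classify_shape(c(`0` = 2, `3` = 5, `10` = 20, `30` = 6))   # inverted-U
#' classify_shape(c(`0` = 20, `3` = 18, `10` = 3, `30` = 8))  # U
classify_shape <- function(medians, delta = 1) {
  if (length(medians) != 4L || anyNA(medians))
    stop("medians must be defined for all four doses")
  if (!is.null(names(medians)) &&
      !anyNA(suppressWarnings(as.numeric(names(medians))))) {
    medians <- medians[order(as.numeric(names(medians)))]
  }
  v <- unname(medians)  # vehicle, low, mid, high
  active <- v[2:4]
  if (v[3] - max(v[c(1, 2, 4)]) >= delta) return("inverted-U")
  if (min(active[-2]) - active[2] >= delta &&
      active[1] - max(active[-1]) >= delta) return("U")
  d <- diff(v)
  if (all(d >= delta) || all(d <= -delta)) return("monotonic")
  "flat"
}

#' Region-level dose-response statistics table
#'
#' The computation behind a ranked volume-of-activation table: for every
#' region, per-dose medians of the chosen count, a Kruskal-Wallis H and p
#' across doses, an omega-squared effect size, Benjamini-Hochberg FDR
#' flags over all regions with the realized threshold, and a
#' dose-response shape label from the medians. Regions are ranked by p.
#'
#' @param voa long `region_voa` data frame (see [cohort_voa()]).
#' @param table a [region_table()].
#' @param measure `"positive"` or `"negative"` counts.
#' @param q FDR rate over regions (default 0.05).
#' @param delta shape-classification separation (default 1 voxel).
#' @return A `dose_stats` data frame with columns `rank region_id name
#'   median_<dose>... H p fdr_pass omega2 shape`, plus attributes
#'   `fdr_threshold`, `q`, `measure`.
#' @export
region_dose_stats <- function(voa, table, measure = c("positive", "negative"),
                              q = 0.05, delta = 1) {
  measure <- match.arg(measure)
  col <- paste0("n_", measure)
  if (anyNA(voa$group)) stop("every subject must carry a dose group")
  doses <- unique(as.character(voa$group))
  doses <- doses[order(suppressWarnings(as.numeric(doses)))]
  ids <- table$region_id
  med <- matrix(NA_real_, length(ids), length(doses),
                dimnames = list(NULL, doses))
  H <- p <- om <- numeric(length(ids))
  shape <- character(length(ids))
  for (i in seq_along(ids)) {
    sub <- voa[voa$region_id == ids[i], ]
    x <- sub[[col]]
    g <- as.character(sub$group)
    med[i, ] <- vapply(doses, function(d) median(x[g == d]), 0)
    kt <- kruskal_wallis(x, g)
    H[i] <- kt$H; p[i] <- kt$p
    om[i] <- suppressWarnings(omega_squared(x, g))
    shape[i] <- if (length(doses) == 4L) {
      classify_shape(setNames(med[i, ], doses), delta = delta)
    } else NA_character_
  }
  fdr <- bh_fdr(p, q = q)
  out <- data.frame(region_id = ids, name = table$name,
                    stringsAsFactors = FALSE)
  for (d in doses) out[[paste0("median_", d)]] <- med[, d]
  out$H <- H; out$p <- p; out$fdr_pass <- fdr$pass
  out$omega2 <- om; out$shape <- shape
  out <- out[order(out$p, out$region_id), ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("dose_stats", "data.frame"),
            fdr_threshold = fdr$threshold, q = q, measure = measure)
}

#' @export
print.dose_stats <- function(x, n = 10L, ...) {
  thr <- attr(x, "fdr_threshold")
  cat(sprintf("Region dose-response statistics (%s BOLD): %d regions, %d pass FDR (q = %g%s)\n",
              attr(x, "measure"), nrow(x), sum(x$fdr_pass), attr(x, "q"),
              if (is.na(thr)) "" else sprintf(", realized threshold p <= %.4g", thr)))
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... %d more regions\n", nrow(x) - n))
  invisible(x)
}

#' Write a ranked dose-response table as TSV
#' @param stats a `dose_stats` data frame.
#' @param path output path.
#' @export
write_dose_stats <- function(stats, path) write_tsv(as.data.frame(stats), path)

#' Macro-region (or system) aggregation of VoA counts
#'
#' Summarises a set of regions selected by macro-region name or system tag:
#' the per-dose mean of the selected regions' group medians ("average
#' median voxels"), and pairwise two-sided Mann-Whitney comparisons between
#' doses on per-subject counts averaged over the selected regions. Pairwise
#' p-values are uncorrected by default.
#'
#' @param voa long `region_voa` data frame.
#' @param table a [region_table()].
#' @param selection macro-region name (`"forebrain"`, ...) or system tag
#'   (`"ARAS"`, ...).
#' @param measure `"positive"` or `"negative"`.
#' @param p_adjust optional multiplicity correction for the pairwise
#'   p-values (a [stats::p.adjust()] method; `"none"` default).
#' @return A `macro_summary`: list with `summary` (dose, mean_median,
#'   n_regions), `pairwise` (dose_a, dose_b, p, direction), `selection`.
#' @export
macro_aggregate <- function(voa, table, selection,
                            measure = c("positive", "negative"),
                            p_adjust = "none") {
  measure <- match.arg(measure)
  col <- paste0("n_", measure)
  ids <- regions_with_tag(table, selection)
  if (!length(ids)) stop("selection '", selection, "' matches no regions")
  sub <- voa[voa$region_id %in% ids, ]
  doses <- unique(as.character(sub$group))
  doses <- doses[order(suppressWarnings(as.numeric(doses)))]
  # mean over selected regions of the per-dose medians
  gm <- group_medians(sub)
  mm <- tapply(gm[[paste0("median_", measure)]], as.character(gm$group), mean)
  summary <- data.frame(dose = doses, mean_median = as.vector(mm[doses]),
                        n_regions = length(ids))
  # per-subject mean count across the selected regions
  per_sub <- tapply(sub[[col]], sub$subject_id, mean)
  sub_group <- tapply(as.character(sub$group), sub$subject_id,
                      function(g) g[1])
  pairs <- utils::combn(doses, 2L)
  pw <- data.frame(dose_a = pairs[1, ], dose_b = pairs[2, ],
                   p = NA_real_, direction = "", stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    xa <- per_sub[sub_group == pairs[1, j]]
    xb <- per_sub[sub_group == pairs[2, j]]
    wt <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
    pw$p[j] <- wt$p.value
    pw$direction[j] <- if (median(xb) > median(xa)) {
      sprintf("%s > %s", pairs[2, j], pairs[1, j])
    } else if (median(xb) < median(xa)) {
      sprintf("%s < %s", pairs[2, j], pairs[1, j])
    } else "tie"
  }
  pw$p <- p.adjust(pw$p, method = p_adjust)
  structure(list(summary = summary, pairwise = pw, selection = selection,
                 measure = measure),
            class = "macro_summary")
}

#' @export
print.macro_summary <- function(x, ...) {
  cat(sprintf("Macro summary for '%s' (%s BOLD, %d regions)\n",
              x$selection, x$measure, x$summary$n_regions[1]))
  print(x$summary, digits = 4)
  cat("Pairwise dose comparisons (Mann-Whitney):\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}

#' Region-set time-course comparison between two groups
#'
#' For each subject, the acquisition-wise mean BOLD signal over all voxels
#' of a region set (e.g. every area comprising the ARAS); then a two-factor
#' fixed-effects ANOVA (treatment x acquisition, with interaction) on the
#' subject-level traces. The treatment main effect has 1 df; its F, degrees
#' of freedom, p, and direction are reported.
#'
#' @param cohort a `phmri_cohort` or list of [bold_series()].
#' @param atlas,table as in [cohort_voa()].
#' @param selection macro-region name, system tag, or integer vector of
#'   region ids.
#' @param groups exactly two group labels to compare (default: the two
#'   groups present).
#' @return A `timecourse_result`: list with `traces` (subject, group,
#'   acquisition, mean_signal), `F`, `df1`, `df2`, `p`, `direction`.
#' @export
timecourse_compare <- function(cohort, atlas = cohort$atlas,
                               table = cohort$table, selection, groups = NULL) {
  subjects <- if (inherits(cohort, "phmri_cohort")) cohort$subjects else cohort
  ids <- if (is.numeric(selection)) as.integer(selection)
         else regions_with_tag(table, selection)
  if (!length(ids)) stop("region selection is empty")
  grp <- vapply(subjects, function(s) as.character(s$group), "")
  if (is.null(groups)) groups <- unique(grp)
  groups <- as.character(groups)
  if (length(groups) != 2L) stop("exactly two groups are required")
  keep <- grp %in% groups
  if (!any(grp == groups[1]) || !any(grp == groups[2]))
    stop("both groups must be present in the cohort")
  subjects <- subjects[keep]; grp <- grp[keep]
  lab <- as.vector(atlas$labels)
  vox <- which(lab %in% ids)
  if (!length(vox)) stop("region selection is empty after masking")
  traces <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    check_shapes(s, atlas)
    d <- dim(s$data)
    x <- matrix(s$data, prod(d[1:3]), d[4])[vox, , drop = FALSE]
    data.frame(subject = s$subject_id, group = unname(grp[i]),
               acquisition = seq_len(d[4]) - 1L,
               mean_signal = unname(colMeans(x)), stringsAsFactors = FALSE)
  })
  traces <- do.call(rbind, traces)
  traces$group <- factor(traces$group, levels = groups)
  fit <- aov(mean_signal ~ group * factor(acquisition), data = traces)
  tab <- anova(fit)
  i_g <- match("group", rownames(tab))
  i_r <- match("Residuals", rownames(tab))
  m <- tapply(traces$mean_signal, traces$group, mean)
  direction <- if (m[2] > m[1]) sprintf("%s > %s", groups[2], groups[1])
               else if (m[2] < m[1]) sprintf("%s < %s", groups[2], groups[1])
               else "tie"
  structure(list(traces = traces, F = tab[i_g, "F value"],
                 df1 = tab[i_g, "Df"], df2 = tab[i_r, "Df"],
                 p = tab[i_g, "Pr(>F)"], direction = direction,
                 selection = selection, groups = groups),
            class = "timecourse_result")
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat(sprintf("Time-course comparison (%s vs %s): F(%d,%d) = %.3f, p = %.4g; %s\n",
              x$groups[1], x$groups[2], x$df1, x$df2, x$F, x$p, x$direction))
  invisible(x)
}

#' Write group-mean time courses as TSV (`group acquisition mean_signal`)
#' @param tc a `timecourse_result`.
#' @param path output path.
#' @export
write_timecourse <- function(tc, path) {
  agg <- aggregate(mean_signal ~ group + acquisition, data = tc$traces, FUN = mean)
  agg <- agg[order(agg$group, agg$acquisition), c("group", "acquisition", "mean_signal")]
  write_tsv(agg, path)
}
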