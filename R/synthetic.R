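#' Dose-response effect profile for one atlas region
#'
#' Describes the percent-signal-change effect a region carries at each
#' dose. Amplitudes are signed percent signal change relative to the
#' baseline level (negative = negative BOLD). The shape label is derived
#' from the amplitude magnitudes with [classify_shape()] (detection counts
#' respond to effect magnitude regardless of sign), unless given
#' explicitly.
#'
#' Amplitudes are conveniently stated in a noise-relative unit: with the
#' default baseline level 100 and noise SD 2, one unit = 0.5% signal
#' change = 0.25 noise SDs per acquisition, giving roughly 30% per-voxel
#' detection power at the default windows; 3 units give ~99%.
#'
#' @param amplitudes named numeric, dose (as character) -> percent signal
#'   change.
#' @param affected_fraction fraction of the region's voxels carrying the
#'   effect, in `[0, 1]`.
#' @param shape_label optional explicit label; must be consistent with the
#'   amplitudes under the [classify_shape()] rule.
#' @param delta separation (in percent signal change) used when deriving
#'   the label; default 1e-8 (any nonzero difference counts).
#' @return An object of class `dose_profile`.
#' @export
#' @examples
#' dose_profile(c(`0` = 0, `3` = 0.5, `10` = 1.5, `30` = 0.5))
dose_profile <- function(amplitudes, affected_fraction = 0.3,
                         shape_label = NULL, delta = 1e-8) {
  stopifnot(is.numeric(amplitudes), !is.null(names(amplitudes)))
  if (affected_fraction < 0 || affected_fraction > 1)
    stop("affected_fraction must be in [0, 1]")
  derived <- if (length(amplitudes) == 4L) {
    classify_shape(abs(amplitudes), delta = delta)
  } else NULL
  if (is.null(shape_label)) {
    if (is.null(derived))
      stop("shape_label must be given explicitly unless exactly 4 doses are defined")
    shape_label <- derived
  } else if (!is.null(derived) && !identical(shape_label, derived)) {
    stop(sprintf("shape_label '%s' inconsistent with amplitudes (rule gives '%s')",
                 shape_label, derived))
  }
  structure(list(amplitudes = amplitudes,
                 affected_fraction = affected_fraction,
                 shape_label = shape_label),
            class = "dose_profile")
}

#' Specification of a synthetic phMRI / resting-state cohort
#'
#' Bundles every parameter of the synthetic study: atlas geometry, group
#' sizes, scan lengths, noise and drift, per-region dose effects, and the
#' resting-state block-correlation design. Defaults emulate the awake-mouse
#' CBD study design this package validates against: four phMRI dose groups
#' of 8/6/5/7 animals (0, 3, 10, 30 mg/kg), 150 acquisitions with a
#' 50-acquisition baseline, a 138-region parcellation split into
#' forebrain/midbrain/hindbrain with olfactory, prefrontal, ARAS and
#' cerebellum system tags, and two resting-state groups of 10 scanned for
#' 200 acquisitions.
#'
#' @param grid_shape voxel counts per axis; the first axis is
#'   rostral-caudal. A one-voxel background shell surrounds the brain.
#' @param n_regions number of atlas regions (default 138).
#' @param macro_assignment character vector, length `n_regions`, of
#'   forebrain/midbrain/hindbrain; `NULL` for the default split
#'   (regions 1-55 forebrain, 56-83 midbrain, 84-138 hindbrain).
#' @param system_tags character vector, length `n_regions`, of primary
#'   system tags; `NULL` for the default (olfactory 1-12, prefrontal
#'   13-22, ARAS 84-95, cerebellum 96-107, other elsewhere).
#' @param group_sizes named integer vector, dose (mg/kg) -> number of
#'   subjects.
#' @param n_acquisitions phMRI scan length (default 150).
#' @param baseline_len number of baseline acquisitions (default 50).
#' @param baseline_level in-brain baseline signal level.
#' @param noise_sd per-acquisition Gaussian noise SD, signal units.
#' @param drift_slope linear drift, signal units per acquisition, shared
#'   by all in-brain voxels of a subject.
#' @param effect_table named list, region id (as character) ->
#'   [dose_profile()]; empty list for a null cohort.
#' @param rs_group_sizes named integer vector for the resting-state arm.
#' @param rs_n_acquisitions resting-state scan length (default 200).
#' @param rs_block_corr named list, group -> 5x5 system correlation matrix
#'   (dimnames from the system tags; diagonal = within-system
#'   correlation); `NULL` for the default design (see
#'   [rs_block_corr_default()]).
#' @param rs_voxel_sd SD of voxel-level noise added around each region's
#'   resting-state series.
#' @param seed root seed; every random draw in the cohort derives from it.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(grid_shape = c(32L, 32L, 14L),
                       n_regions = 138L,
                       macro_assignment = NULL,
                       system_tags = NULL,
                       group_sizes = c(`0` = 8L, `3` = 6L, `10` = 5L, `30` = 7L),
                       n_acquisitions = 150L,
                       baseline_len = 50L,
                       baseline_level = 100,
                       noise_sd = 2,
                       drift_slope = 0.02,
                       effect_table = list(),
                       rs_group_sizes = c(vehicle = 10L, CBD = 10L),
                       rs_n_acquisitions = 200L,
                       rs_block_corr = NULL,
                       rs_voxel_sd = 1,
                       seed = 1L) {
  n_regions <- as.integer(n_regions)
  if (is.null(macro_assignment)) {
    splits <- default_macro_split(n_regions)
    macro_assignment <- rep(MACRO_REGIONS, splits)
  }
  if (is.null(system_tags)) system_tags <- default_system_tags(n_regions, macro_assignment)
  stopifnot(length(macro_assignment) == n_regions,
            length(system_tags) == n_regions,
            all(macro_assignment %in% MACRO_REGIONS),
            all(system_tags %in% SYSTEM_TAGS))
  if (is.null(rs_block_corr)) rs_block_corr <- rs_block_corr_default(names(rs_group_sizes))
  if (baseline_len >= n_acquisitions)
    stop("baseline_len must be smaller than n_acquisitions")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (length(effect_table)) {
    stopifnot(all(vapply(effect_table, inherits, TRUE, "dose_profile")))
    ids <- as.integer(names(effect_table))
    if (any(is.na(ids)) || any(ids < 1L) || any(ids > n_regions))
      stop("effect_table names must be region ids in 1..n_regions")
    doses <- names(group_sizes)
    ok <- vapply(effect_table,
                 function(p) all(doses %in% names(p$amplitudes)), TRUE)
    if (!all(ok))
      stop("every dose profile must define an amplitude for each configured dose")
  }
  for (g in names(rs_group_sizes)) {
    B <- rs_block_corr[[g]]
    if (is.null(B) || !all(dim(B) == c(5L, 5L)) || any(abs(B) > 1))
      stop("rs_block_corr must give, per group, a 5x5 system matrix with entries in [-1, 1]")
    if (max(abs(B - t(B))) > 1e-12) stop("rs_block_corr matrices must be symmetric")
  }
  structure(list(grid_shape = as.integer(grid_shape), n_regions = n_regions,
                 macro_assignment = macro_assignment, system_tags = system_tags,
                 group_sizes = group_sizes,
                 n_acquisitions = as.integer(n_acquisitions),
                 baseline_len = as.integer(baseline_len),
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 drift_slope = drift_slope, effect_table = effect_table,
                 rs_group_sizes = rs_group_sizes,
                 rs_n_acquisitions = as.integer(rs_n_acquisitions),
                 rs_block_corr = rs_block_corr, rs_voxel_sd = rs_voxel_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

default_macro_split <- function(n_regions) {
  # forebrain-heavy split mirroring a whole-brain parcellation
  fb <- round(n_regions * 55 / 138)
  mb <- round(n_regions * 28 / 138)
  c(fb, mb, n_regions - fb - mb)
}

default_system_tags <- function(n_regions, macro_assignment) {
  tags <- rep("other", n_regions)
  fb <- which(macro_assignment == "forebrain")
  hb <- which(macro_assignment == "hindbrain")
  take <- function(idx, n) idx[seq_len(min(n, length(idx)))]
  tags[take(fb, round(n_regions * 12 / 138))] <- "olfactory"
  fb_rest <- setdiff(fb, which(tags == "olfactory"))
  tags[take(fb_rest, round(n_regions * 10 / 138))] <- "prefrontal"
  tags[take(hb, round(n_regions * 12 / 138))] <- "ARAS"
  hb_rest <- setdiff(hb, which(tags == "ARAS"))
  tags[take(hb_rest, round(n_regions * 12 / 138))] <- "cerebellum"
  tags
}

#' Default resting-state block-correlation design
#'
#' The first group ("vehicle") has uniform inter-system coupling 0.40 and
#' within-system coupling 0.80. The second ("CBD") keeps that structure
#' but decouples the ARAS from every system except the prefrontal cortex
#' (coupling 0.10) while hypercoupling it to the olfactory system (0.65) —
#' the qualitative pattern of ARAS uncoupling with selective olfactory
#' hyperconnectivity. Both matrices yield positive-definite region
#' covariances.
#'
#' @param groups character vector of (exactly two) group labels; the
#'   second receives the ARAS-perturbed design.
#' @return Named list of 5x5 matrices with system-tag dimnames.
#' @export
rs_block_corr_default <- function(groups = c("vehicle", "CBD")) {
  base <- matrix(0.40, 5, 5, dimnames = list(SYSTEM_TAGS, SYSTEM_TAGS))
  diag(base) <- 0.80
  pert <- base
  pert["ARAS", ] <- pert[, "ARAS"] <- 0.10
  pert["ARAS", "olfactory"] <- pert["olfactory", "ARAS"] <- 0.65
  pert["ARAS", "prefrontal"] <- pert["prefrontal", "ARAS"] <- 0.40
  pert["ARAS", "ARAS"] <- 0.80
  out <- list(base, pert)[seq_along(groups)]
  names(out) <- groups
  if (length(groups) == 1L) out[[1]] <- base
  out
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %s grid, %d regions, seed %d\n",
              paste(x$grid_shape, collapse = "x"), x$n_regions, x$seed))
  cat(sprintf("  phMRI: %d acquisitions (%d baseline), groups [%s], %d effect regions\n",
              x$n_acquisitions, x$baseline_len,
              paste(sprintf("%s mg/kg n=%d", names(x$group_sizes), x$group_sizes),
                    collapse = ", "),
              length(x$effect_table)))
  cat(sprintf("  rsFC: %d acquisitions, groups [%s]\n", x$rs_n_acquisitions,
              paste(sprintf("%s n=%d", names(x$rs_group_sizes), x$rs_group_sizes),
                    collapse = ", ")))
  invisible(x)
}

#' Build a labelled atlas volume from a cohort spec
#'
#' Partitions the in-brain voxels (everything inside a one-voxel background
#' shell) into `n_regions` near-equal contiguous parcels ordered along the
#' rostral-caudal axis, so the macro-regions occupy contiguous slabs:
#' forebrain rostral, midbrain middle, hindbrain caudal. Deterministic
#' given the spec.
#'
#' @param spec a [synth_spec()].
#' @return `list(atlas = atlas_volume, table = region_table)`.
#' @export
#' @examples
#' at <- build_atlas(synth_spec(grid_shape = c(12, 10, 8), n_regions = 10))
#' table(at$atlas$labels > 0)
build_atlas <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  g <- spec$grid_shape
  labels <- array(0L, dim = g)
  # one-voxel background shell when the grid affords it; small grids are
  # all brain
  margin <- if (all(g >= 3L) && prod(g - 2L) >= 8L * spec$n_regions) 1L else 0L
  inner <- lapply(g, function(n) (1L + margin):(n - margin))
  n_in <- prod(g - 2L * margin)
  if (n_in < 8L * spec$n_regions)
    stop(sprintf("grid too small for %d regions: %d in-brain voxels < %d required (8 per region)",
                 spec$n_regions, n_in, 8L * spec$n_regions))
  # voxel order: rostral-caudal axis slowest, so consecutive parcels tile
  # the brain front to back
  coords <- expand.grid(x = inner[[1]], y = inner[[2]], z = inner[[3]])
  coords <- coords[order(coords$x, coords$y, coords$z), ]
  sizes <- rep(n_in %/% spec$n_regions, spec$n_regions)
  extra <- n_in %% spec$n_regions
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  lab_seq <- rep.int(seq_len(spec$n_regions), sizes)
  labels[cbind(coords$x, coords$y, coords$z)] <- lab_seq
  table <- region_table(
    region_id = seq_len(spec$n_regions),
    name = sprintf("%s_%03d", spec$macro_assignment, seq_len(spec$n_regions)),
    macro_region = spec$macro_assignment,
    systems = spec$system_tags)
  list(atlas = atlas_volume(labels), table = table)
}

# Root streams: 1 = affected-voxel selection, 2 = phMRI subjects,
# 3 = rsFC subjects.  Documented so a cohort is a pure function of seed.
cohort_roots <- function(spec) derive_seeds(spec$seed, 3L)

# Deterministic affected-voxel subsets per effect region (shared by all
# subjects of a cohort, like a fixed anatomical effect site).
affected_voxels <- function(atlas, spec) {
  roots <- cohort_roots(spec)
  ids <- names(spec$effect_table)
  if (!length(ids)) return(list())
  seeds <- derive_seeds(roots[1], length(ids))
  out <- vector("list", length(ids)); names(out) <- ids
  lab <- as.vector(atlas$labels)
  for (i in seq_along(ids)) {
    vox <- which(lab == as.integer(ids[i]))
    prof <- spec$effect_table[[i]]
    k <- round(prof$affected_fraction * length(vox))
    out[[i]] <- if (k > 0L) with_seed(seeds[i], sort(sample(vox, k))) else integer(0)
  }
  out
}

#' Simulate one phMRI subject
#'
#' In-brain voxels start at the baseline level; voxels in the affected
#' subset of each effect region step by the region's dose amplitude
#' (percent of baseline) from acquisition `baseline_len` onward (no
#' hemodynamic ramp — the analysis quantifies window means, not response
#' dynamics). I.i.d. Gaussian noise and a linear drift shared by all
#' in-brain voxels are added; background voxels stay at zero.
#'
#' @param atlas,table from [build_atlas()].
#' @param spec a [synth_spec()].
#' @param dose one of the configured doses (matched by name).
#' @param seed integer seed for this subject.
#' @param subject_id identifier.
#' @return A [bold_series()] with `group` set to the dose.
#' @export
simulate_phmri_subject <- function(atlas, table, spec, dose, seed,
                                   subject_id = sprintf("sub_d%s_s%d", dose, seed)) {
  stopifnot(inherits(spec, "synth_spec"))
  dose <- as.character(dose)
  if (!dose %in% names(spec$group_sizes))
    stop("unknown dose '", dose, "'; configured doses: ",
         paste(names(spec$group_sizes), collapse = ", "))
  lab <- as.vector(atlas$labels)
  mask <- which(lab > 0L)
  n_t <- spec$n_acquisitions
  sig <- matrix(spec$baseline_level, length(mask), n_t)
  stim_cols <- (spec$baseline_len + 1L):n_t
  aff <- affected_voxels(atlas, spec)
  for (id in names(aff)) {
    amp <- spec$effect_table[[id]]$amplitudes[[dose]]
    if (amp == 0 || !length(aff[[id]])) next
    rows <- match(aff[[id]], mask)
    sig[rows, stim_cols] <- sig[rows, stim_cols] + spec$baseline_level * amp / 100
  }
  drift <- spec$drift_slope * (seq_len(n_t) - 1L)
  sig <- sig + rep(drift, each = length(mask))
  sig <- sig + with_seed(seed, matrix(rnorm(length(sig), sd = spec$noise_sd),
                                      nrow(sig), ncol(sig)))
  data <- array(0, dim = c(spec$grid_shape, n_t))
  flat <- matrix(data, prod(spec$grid_shape), n_t)
  flat[mask, ] <- sig
  data <- array(flat, dim = c(spec$grid_shape, n_t))
  bold_series(data, subject_id = subject_id, group = dose, tr = 6)
}

# Factor (138 x 138) such that t(F) %*% F = region covariance; eigen-based
# so positive semidefinite boundaries are handled.
rs_region_factor <- function(spec, group) {
  B <- spec$rs_block_corr[[group]]
  if (is.null(B)) stop("no rs_block_corr entry for group '", group, "'")
  sys <- match(spec$system_tags, SYSTEM_TAGS)
  S <- B[sys, sys]
  diag(S) <- 1
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    v <- abs(e$vectors[, which.min(e$values)])
    load <- tapply(v, spec$system_tags, sum)
    worst <- names(sort(load, decreasing = TRUE))[1:2]
    stop(sprintf("rs_block_corr for group '%s' yields a non-positive-semidefinite region covariance (min eigenvalue %.3g); offending block: %s-%s",
                 group, min(e$values), worst[1], worst[2]))
  }
  t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
}

#' Simulate one resting-state subject
#'
#' Region-mean series are drawn from a multivariate normal whose
#' between-system correlations follow the spec's block design for the
#' subject's group; each voxel's series is its region's series plus
#' independent voxel noise, then shifted to the baseline level.
#'
#' @inheritParams simulate_phmri_subject
#' @param group one of the configured resting-state group labels.
#' @return A [bold_series()] with `group` set to the label.
#' @export
simulate_rsfc_subject <- function(atlas, table, spec, group, seed,
                                  subject_id = sprintf("sub_%s_s%d", group, seed)) {
  stopifnot(inherits(spec, "synth_spec"))
  group <- as.character(group)
  if (!group %in% names(spec$rs_group_sizes))
    stop("unknown resting-state group '", group, "'")
  Fm <- rs_region_factor(spec, group)
  n_t <- spec$rs_n_acquisitions
  lab <- as.vector(atlas$labels)
  mask <- which(lab > 0L)
  sig <- with_seed(seed, {
    region_ts <- matrix(rnorm(n_t * spec$n_regions), n_t) %*% Fm  # T x regions
    v <- t(region_ts[, lab[mask], drop = FALSE])                  # voxels x T
    v + matrix(rnorm(length(mask) * n_t, sd = spec$rs_voxel_sd),
               length(mask), n_t)
  })
  sig <- sig + spec$baseline_level
  flat <- matrix(0, prod(spec$grid_shape), n_t)
  flat[mask, ] <- sig
  bold_series(array(flat, dim = c(spec$grid_shape, n_t)),
              subject_id = subject_id, group = group, tr = 1)
}

#' Generate a full synthetic cohort
#'
#' One subject per group slot, all randomness derived from the spec's root
#' seed (identical spec + seed gives a bit-identical cohort). The returned
#' ground-truth record lists every seeded effect region with its profile
#' and affected voxels (phMRI mode) or the block-correlation design (rsFC
#' mode), for use by validation code.
#'
#' @param spec a [synth_spec()].
#' @param mode `"phmri"` (dose groups, step effects) or `"rsfc"`
#'   (resting-state correlation structure).
#' @return An object of class `phmri_cohort`: list with `subjects` (list of
#'   [bold_series()]), `atlas`, `table`, `spec`, `mode`, `ground_truth`.
#' @export
#' @examples
#' spec <- synth_spec(grid_shape = c(10, 8, 6), n_regions = 6,
#'                    group_sizes = c(`0` = 2, `3` = 2, `10` = 2, `30` = 2),
#'                    n_acquisitions = 20, baseline_len = 8, seed = 7)
#' coh <- make_cohort(spec, "phmri")
#' length(coh$subjects)
make_cohort <- function(spec, mode = c("phmri", "rsfc")) {
  mode <- match.arg(mode)
  at <- build_atlas(spec)
  roots <- cohort_roots(spec)
  if (mode == "phmri") {
    doses <- names(spec$group_sizes)
    n_sub <- sum(spec$group_sizes)
    seeds <- derive_seeds(roots[2], n_sub)
    assign_dose <- rep(doses, spec$group_sizes)
    subjects <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      subjects[[i]] <- simulate_phmri_subject(
        at$atlas, at$table, spec, assign_dose[i], seeds[i],
        subject_id = sprintf("S%02d_d%s", i, assign_dose[i]))
    }
    gt <- list(effects = spec$effect_table,
               affected_voxels = affected_voxels(at$atlas, spec))
  } else {
    groups <- names(spec$rs_group_sizes)
    n_sub <- sum(spec$rs_group_sizes)
    seeds <- derive_seeds(roots[3], n_sub)
    assign_grp <- rep(groups, spec$rs_group_sizes)
    subjects <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      subjects[[i]] <- simulate_rsfc_subject(
        at$atlas, at$table, spec, assign_grp[i], seeds[i],
        subject_id = sprintf("R%02d_%s", i, assign_grp[i]))
    }
    gt <- list(rs_block_corr = spec$rs_block_corr)
  }
  names(subjects) <- vapply(subjects, function(s) s$subject_id, "")
  structure(list(subjects = subjects, atlas = at$atlas, table = at$table,
                 spec = spec, mode = mode, ground_truth = gt),
            class = "phmri_cohort")
}

#' @export
print.phmri_cohort <- function(x, ...) {
  cat(sprintf("Synthetic %s cohort: %d subjects, %d regions, seed %d\n",
              x$mode, length(x$subjects), x$spec$n_regions, x$spec$seed))
  invisible(x)
}

#' Canonical inverted-U effect table
#'
#' Seeds `regions` with an inverted-U dose-response: amplitude
#' `3 * unit_pct` percent signal change at the intermediate (most
#' effective) dose and `1 * unit_pct` at the other active doses, zero at
#' vehicle. With the default noise parameters `unit_pct = 0.5` is one
#' noise-relative unit (see [dose_profile()]).
#'
#' @param regions integer region ids to seed.
#' @param doses dose names in increasing order; the second-highest is the
#'   peak.
#' @param unit_pct percent signal change per unit.
#' @param affected_fraction fraction of region voxels carrying the effect.
#' @return Named list of [dose_profile()] suitable for `synth_spec()`.
#' @export
effect_table_inverted_u <- function(regions,
                                    doses = c("0", "3", "10", "30"),
                                    unit_pct = 0.5,
                                    affected_fraction = 0.3) {
  amps <- setNames(c(0, 1, 3, 1) * unit_pct, doses)
  profs <- lapply(regions, function(r) dose_profile(amps, affected_fraction))
  names(profs) <- as.character(regions)
  profs
}
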