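#' Scan windows for phMRI analysis
#'
#' Defines the baseline (pre-injection) and stimulation (post-injection)
#' acquisition windows. Acquisition indices are 0-based and ranges are
#' half-open, matching scanner acquisition numbering: the defaults
#' `[0, 50)` and `[50, 150)` correspond to a 5 min baseline followed by a
#' 10 min stimulation window in a 150-acquisition run.
#'
#' @param baseline integer vector `c(start, end)`, half-open 0-based range.
#' @param stimulation integer vector `c(start, end)`, half-open 0-based range.
#' @return An object of class `scan_windows`.
#' @export
#' @examples
#' w <- scan_windows()          # [0,50) baseline, [50,150) stimulation
#' scan_windows(c(0, 20), c(20, 60))
scan_windows <- function(baseline = c(0L, 50L), stimulation = c(50L, 150L)) {
  stopifnot(length(baseline) == 2L, length(stimulation) == 2L)
  baseline <- as.integer(baseline); stimulation <- as.integer(stimulation)
  if (baseline[1] < 0L || baseline[1] >= baseline[2])
    stop("baseline window must be a nonempty half-open range with start >= 0")
  if (stimulation[1] >= stimulation[2])
    stop("stimulation window must be a nonempty half-open range")
  if (stimulation[1] < baseline[2])
    stop("windows must be disjoint and in order (baseline before stimulation)")
  structure(list(baseline = baseline, stimulation = stimulation),
            class = "scan_windows")
}

# Validate windows against a series length; returns 1-based column indices.
validate_windows <- function(windows, n_t) {
  stopifnot(inherits(windows, "scan_windows"))
  if (windows$stimulation[2] > n_t)
    stop(sprintf("scan windows extend to acquisition %d but the series has only %d acquisitions",
                 windows$stimulation[2], n_t))
  if (diff(windows$baseline) < 2L || diff(windows$stimulation) < 2L)
    stop("each window must contain at least 2 acquisitions")
  list(baseline = (windows$baseline[1] + 1L):windows$baseline[2],
       stimulation = (windows$stimulation[1] + 1L):windows$stimulation[2])
}

#' @export
print.scan_windows <- function(x, ...) {
  cat(sprintf("Scan windows (0-based, half-open): baseline [%d, %d), stimulation [%d, %d)\n",
              x$baseline[1], x$baseline[2], x$stimulation[1], x$stimulation[2]))
  invisible(x)
}

#' Construct a BOLD series object
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param subject_id subject identifier.
#' @param group dose (mg/kg) or group label.
#' @param tr repetition time in seconds.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, subject_id, group, tr = 6) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (dim(data)[4] < 2L) stop("a BOLD series needs at least 2 acquisitions")
  structure(list(data = data, subject_id = as.character(subject_id),
                 group = group, tr = tr),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD series '%s' (group %s): %dx%dx%d voxels, %d acquisitions, TR %gs\n",
              x$subject_id, format(x$group), d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Construct an atlas volume object
#'
#' @param labels 3D integer array of region labels; 0 is background.
#' @param voxel_size numeric length-3, mm per axis.
#' @param rostral_caudal_axis which spatial axis (1-3) runs rostral to
#'   caudal; carried with the volume so macro-region polarization along
#'   the neuraxis stays geometrically meaningful.
#' @return An object of class `atlas_volume`.
#' @export
atlas_volume <- function(labels, voxel_size = c(0.1875, 0.1875, 0.75),
                         rostral_caudal_axis = 1L) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("atlas labels must be nonnegative (0 = background)")
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 rostral_caudal_axis = as.integer(rostral_caudal_axis)),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Atlas volume: %dx%dx%d voxels, %d regions, rostral-caudal axis %d\n",
              d[1], d[2], d[3], length(setdiff(unique(as.vector(x$labels)), 0L)),
              x$rostral_caudal_axis))
  invisible(x)
}

MACRO_REGIONS <- c("forebrain", "midbrain", "hindbrain")
SYSTEM_TAGS <- c("olfactory", "prefrontal", "ARAS", "cerebellum", "other")

#' Construct and validate a region lookup table
#'
#' @param region_id unique positive integer region ids.
#' @param name region names.
#' @param macro_region one of forebrain / midbrain / hindbrain per region.
#' @param systems character vector of semicolon-delimited system tags
#'   (subset of olfactory, prefrontal, ARAS, cerebellum, other), or a list
#'   of character vectors.
#' @return A `region_table` data frame.
#' @export
region_table <- function(region_id, name, macro_region, systems) {
  region_id <- as.integer(region_id)
  if (anyDuplicated(region_id)) stop("region ids must be unique")
  if (any(region_id <= 0L)) stop("region ids must be positive")
  if (!all(macro_region %in% MACRO_REGIONS))
    stop("macro_region must be one of: ", paste(MACRO_REGIONS, collapse = ", "))
  if (is.list(systems)) systems <- vapply(systems, paste, "", collapse = ";")
  parsed <- strsplit(systems, ";", fixed = TRUE)
  bad <- !vapply(parsed, function(s) all(s %in% SYSTEM_TAGS), TRUE)
  if (any(bad))
    stop("unknown system tag(s) in regions: ",
         paste(region_id[bad], collapse = ", "))
  structure(data.frame(region_id = region_id, name = as.character(name),
                       macro_region = as.character(macro_region),
                       systems = as.character(systems),
                       stringsAsFactors = FALSE),
            class = c("region_table", "data.frame"))
}

# Region ids in a table carrying a macro-region name or system tag.
regions_with_tag <- function(table, tag) {
  hit <- table$macro_region == tag |
    vapply(strsplit(table$systems, ";", fixed = TRUE),
           function(s) tag %in% s, TRUE)
  table$region_id[hit]
}

#' Write / read a 4D BOLD series as NIfTI-1
#'
#' Signal is stored as 32-bit floating point; a write-then-read round trip
#' reproduces values to single precision.
#'
#' @param series a `bold_series`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param subject_id,group,tr metadata to attach on read (NIfTI-1 does not
#'   carry them).
#' @return `read_series` returns a `bold_series`; `write_series` returns
#'   `path` invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  RNifti::writeNifti(RNifti::asNifti(series$data, datatype = "float"), path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path, subject_id = basename(path), group = NA, tr = 6) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  if (length(dim(a)) != 4L)
    stop(sprintf("expected a 4D series, got %d dimensions in %s",
                 length(dim(a)), path))
  bold_series(a, subject_id = subject_id, group = group, tr = tr)
}

#' Write / read an atlas volume with its sidecar region table
#'
#' Labels are stored as NIfTI-1 integers (exact round trip); region
#' metadata lives in a tab-separated sidecar with columns
#' `region_id name macro_region systems` (systems semicolon-delimited).
#' On read, every positive label in the volume must appear in the table.
#'
#' @param atlas an `atlas_volume`.
#' @param table a `region_table`.
#' @param path NIfTI path for the labels.
#' @param table_path TSV path for the region table.
#' @return `read_atlas` returns `list(atlas, table)`.
#' @export
write_atlas <- function(atlas, table, path, table_path) {
  stopifnot(inherits(atlas, "atlas_volume"), inherits(table, "region_table"))
  RNifti::writeNifti(RNifti::asNifti(atlas$labels, datatype = "int32"), path)
  write_region_table(table, table_path)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path, table_path) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(img), dim = dim(img))
  if (length(dim(labels)) != 3L)
    stop("expected a 3D label volume, got ", length(dim(labels)), " dimensions")
  table <- read_region_table(table_path)
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, table$region_id)
  if (length(missing))
    stop("atlas labels absent from region table: ",
         paste(sort(missing), collapse = ", "))
  pix <- RNifti::pixdim(img)
  list(atlas = atlas_volume(labels, voxel_size = pix[seq_len(3)]),
       table = table)
}

#' @rdname write_atlas
#' @export
write_region_table <- function(table, table_path) {
  write_tsv(as.data.frame(table), table_path)
}

#' @rdname write_atlas
#' @export
read_region_table <- function(table_path) {
  if (!file.exists(table_path)) stop("no such file: ", table_path)
  df <- read.delim(table_path, stringsAsFactors = FALSE)
  need <- c("region_id", "name", "macro_region", "systems")
  if (!all(need %in% names(df)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  region_table(df$region_id, df$name, df$macro_region, df$systems)
}

# All tabular outputs share one TSV dialect so reruns are byte-identical.
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Require that a series and atlas agree spatially.
check_shapes <- function(series, atlas) {
  ds <- dim(series$data)[1:3]; da <- dim(atlas$labels)
  if (!all(ds == da))
    stop(sprintf("series spatial shape %s does not match atlas shape %s",
                 paste(ds, collapse = "x"), paste(da, collapse = "x")))
  invisible(TRUE)
}
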