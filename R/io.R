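#' Read a 4D NIfTI volume
#'
#' Loads a 4D time-series volume. The sampling frequency is taken as
#' 1/TR from the NIfTI header (`pixdim[4]`); a missing or non-positive TR
#' falls back to `default_fs` (10 Hz by default, a typical MREG rate).
#'
#' @param path NIfTI file (.nii or .nii.gz) with 4 dimensions.
#' @param default_fs fallback sampling frequency in Hz.
#' @param mask optional 3D mask array attached to the volume.
#' @return A [voxel_volume].
#' @export
read_volume_4d <- function(path, default_fs = default_config()$fs,
                           mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D NIfTI, got ", length(d), "D: ", path)
  # header read straight from the file: the in-memory image normalizes a
  # zero TR to 1, hiding exactly the TR-less case the fallback is for
  pd <- RNifti::niftiHeader(path)$pixdim
  tr <- pd[5]
  fs <- if (is.finite(tr) && tr > 0) 1 / tr else default_fs
  voxel_volume(array(as.numeric(img), d), fs = fs,
               voxel_size_mm = abs(pd[2]), mask = mask,
               meta = list(source = path))
}

#' Write a 4D volume as NIfTI
#'
#' @param vol a [voxel_volume].
#' @param path destination (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(rep(vol$voxel_size_mm, 3), 1 / vol$fs)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a biometric or statistic map as NIfTI
#'
#' `NaN` outside the mask is preserved. For a [stat_map] the corrected-p
#' volume is written (use `field = "t"` for the statistic volume).
#'
#' @param map a [biometric_map] or [stat_map].
#' @param path destination (.nii or .nii.gz).
#' @param field for stat maps, which volume to write (`"p"` or `"t"`).
#' @param mask optional 3D mask; must match the map's spatial shape.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, field = c("p", "t"), mask = NULL) {
  if (inherits(map, "biometric_map")) {
    values <- map$values
    vox <- map$voxel_size_mm
  } else if (inherits(map, "stat_map")) {
    field <- match.arg(field)
    values <- map[[field]]
    vox <- map$voxel_size_mm
  } else stop("`map` must be a biometric_map or stat_map")
  if (!is.null(mask) && !identical(dim(mask), dim(values)))
    stop("mask shape does not match map shape")
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep(vox, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D map or mask from NIfTI
#'
#' @param path NIfTI file with 3 dimensions.
#' @param as_mask coerce to logical (any nonzero is inside)?
#' @return 3D array (logical if `as_mask`).
#' @export
read_map_3d <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { img <- img[, , , 1]; d <- d[1:3] }
  if (length(d) != 3L)
    stop("expected a 3D NIfTI, got ", length(d), "D: ", path)
  a <- array(as.numeric(img), d)
  if (as_mask) array(is.finite(a) & a != 0, d) else a
}

# required / known columns per table kind
.table_schemas <- list(
  physio = list(required = c("time_s", "amplitude")),
  motion = list(required = c("t", "abs_mm", "rel_mm")),
  design = list(required = c("subject_id", "group", "age", "sex"),
                optional = "medication")
)

#' Read a typed CSV table
#'
#' Three schemas are understood: `physio` (columns `time_s`, `amplitude`;
#' a PPG or end-tidal CO2 trace), `motion` (`t`, `abs_mm`, `rel_mm`;
#' per-timepoint absolute and relative displacement) and `design`
#' (`subject_id`, `group`, `age`, `sex`, optional `medication`).
#'
#' @param path CSV file with a header row.
#' @param schema one of `"physio"`, `"motion"`, `"design"`.
#' @return data.frame in file row order, with class `motion_trace` attached
#'   for the motion schema.
#' @export
read_table <- function(path, schema = c("physio", "motion", "design")) {
  schema <- match.arg(schema)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- .table_schemas[[schema]]$required
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("table ", path, " is missing required column(s) for schema '",
         schema, "': ", paste(miss, collapse = ", "))
  if (schema == "motion") class(df) <- c("motion_trace", class(df))
  if (schema == "design") validate_design(df, min_per_group = 1)
  df
}

#' Construct a motion trace in memory
#'
#' @param abs_mm,rel_mm per-timepoint absolute and relative displacement
#'   (mm), equal lengths, nonnegative.
#' @return data.frame of class `motion_trace`.
#' @export
motion_trace <- function(abs_mm, rel_mm) {
  if (length(abs_mm) != length(rel_mm)) stop("trace lengths differ")
  if (!length(abs_mm)) stop("empty motion trace")
  if (any(abs_mm < 0) || any(rel_mm < 0))
    stop("displacements must be nonnegative")
  df <- data.frame(t = seq_along(abs_mm), abs_mm = abs_mm, rel_mm = rel_mm)
  class(df) <- c("motion_trace", class(df))
  df
}
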