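#' Construct a 4D voxel time-series volume
#'
#' The unit every subject-level stage consumes: a 4D array (x, y, z, t) of
#' signal values in arbitrary units, with its sampling frequency, isotropic
#' voxel edge length and an optional analysis mask.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param fs sampling frequency in Hz (> 0).
#' @param voxel_size_mm isotropic voxel edge length in mm.
#' @param mask optional 3D logical (or 0/1) array matching the spatial grid;
#'   any nonzero value counts as inside.
#' @param meta free-form provenance list.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, fs, voxel_size_mm = 3, mask = NULL,
                         meta = list()) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (dim(data)[4] < 2L)
    stop("time axis must have length >= 2")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)[1:3]))
      stop("mask shape ", paste(dim(mask), collapse = "x"),
           " does not match spatial grid ",
           paste(dim(data)[1:3], collapse = "x"))
    mask <- array(mask != 0, dim(data)[1:3])
  }
  structure(list(data = data, fs = fs, voxel_size_mm = voxel_size_mm,
                 mask = mask, meta = meta),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_volume> %dx%dx%d grid, %d timepoints @ %g Hz, %g mm voxels\n",
              d[1], d[2], d[3], d[4], x$fs, x$voxel_size_mm))
  if (!is.null(x$mask))
    cat(sprintf("  mask: %d voxels inside\n", sum(x$mask)))
  invisible(x)
}

#' Construct a one-sided power spectrum
#'
#' @param freqs strictly increasing bin frequencies (Hz).
#' @param power nonnegative power values (arbitrary units), same length.
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power) {
  if (length(freqs) != length(power))
    stop("freqs and power lengths differ")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (any(power < -1e-12, na.rm = TRUE)) stop("power must be nonnegative")
  structure(list(freqs = freqs, power = pmax(power, 0)),
            class = "power_spectrum")
}

#' Construct a frequency band
#'
#' A closed interval \[lo, hi\] in Hz. The canonical bands are VLF
#' (0.008--0.1 Hz, vasomotor waves), the subject-specific respiratory and
#' cardiac bands (peak +- 0.05 Hz) and the full band (0.008--5 Hz).
#'
#' @param lo,hi band edges in Hz, `0 <= lo < hi`.
#' @param label one of `"VLF"`, `"respiratory"`, `"cardiac"`, `"fullband"`,
#'   or any descriptive string.
#' @param fs optional sampling frequency; when given, `hi <= fs/2` is
#'   enforced.
#' @return An object of class `frequency_band`.
#' @export
frequency_band <- function(lo, hi, label = "band", fs = NULL) {
  if (!(lo >= 0 && lo < hi)) stop("need 0 <= lo < hi")
  if (!is.null(fs) && hi > fs / 2 + 1e-12)
    stop(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz", hi, fs / 2))
  structure(list(lo = lo, hi = hi, label = label),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<frequency_band> %s: [%g, %g] Hz\n", x$label, x$lo, x$hi))
  invisible(x)
}

#' Construct a 3D biometric map
#'
#' One scalar pulsation biometric per voxel: CV (coefficient of variation of
#' the band-filtered signal), SP (band spectral power) or SE (normalized
#' spectral entropy).
#'
#' @param values 3D numeric array; `NaN`/`NA` marks undefined voxels.
#' @param kind one of `"CV"`, `"SP"`, `"SE"`.
#' @param band the [frequency_band] the map was computed over (optional for
#'   SE which uses the full band).
#' @param voxel_size_mm isotropic voxel edge (mm).
#' @param meta provenance list.
#' @return An object of class `biometric_map`.
#' @export
biometric_map <- function(values, kind = c("CV", "SP", "SE"), band = NULL,
                          voxel_size_mm = 3, meta = list()) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  ok <- values[is.finite(values)]
  if (kind %in% c("CV", "SP") && any(ok < -1e-9))
    stop(kind, " map must be nonnegative where defined")
  if (kind == "SE" && length(ok) && (min(ok) < -1e-9 || max(ok) > 1 + 1e-9))
    stop("SE map must lie in [0, 1] where defined")
  structure(list(values = values, kind = kind, band = band,
                 voxel_size_mm = voxel_size_mm, meta = meta),
            class = "biometric_map")
}

#' @export
print.biometric_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<biometric_map> %s, %dx%dx%d, %d defined voxels\n",
              x$kind, d[1], d[2], d[3], sum(is.finite(x$values))))
  invisible(x)
}

#' Validate a cohort design table
#'
#' @param design data.frame with columns `subject_id`, `group`, `age`,
#'   `sex` (0/1) and optionally `medication` (0/1).
#' @param min_per_group minimum group size usable for inference.
#' @return the design, invisibly, with `group` as factor.
#' @export
validate_design <- function(design, min_per_group = 2) {
  req <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyNA(design$group)) stop("design has missing group labels")
  design$group <- factor(design$group)
  n <- table(design$group)
  if (any(n < min_per_group))
    stop("each group needs >= ", min_per_group, " subjects; got: ",
         paste(sprintf("%s=%d", names(n), n), collapse = ", "))
  invisible(design)
}

#' Construct a statistic map from permutation inference
#'
#' @param t 3D array of voxel-wise contrast t statistics.
#' @param p 3D array of FWE-corrected p values in \[0, 1\].
#' @param contrast description of the tested contrast.
#' @param n_perm number of permutations used.
#' @param seed RNG seed used.
#' @param mask 3D logical analysis mask.
#' @param voxel_size_mm voxel edge (mm).
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(t, p, contrast = "", n_perm = NA_integer_,
                     seed = NA_integer_, mask = NULL, voxel_size_mm = 3) {
  if (!identical(dim(t), dim(p))) stop("t and p shapes differ")
  pin <- p[is.finite(p)]
  if (length(pin) && (min(pin) < 0 || max(pin) > 1))
    stop("p values must lie in [0, 1]")
  structure(list(t = t, p = p, contrast = contrast, n_perm = n_perm,
                 seed = seed, mask = mask, voxel_size_mm = voxel_size_mm),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> contrast %s, %d permutations, %d voxels p<0.05\n",
              x$contrast, x$n_perm, sum(x$p < 0.05, na.rm = TRUE)))
  invisible(x)
}
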