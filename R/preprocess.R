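#' Motion quality-control thresholds
#'
#' The four-layer exclusion rule for head motion plus the respiratory-band
#' overlap rule: any absolute displacement over 1.5 mm (half the voxel
#' size), any relative displacement over 0.5 mm, mean absolute over 0.6 mm,
#' mean relative over 0.07 mm; and a respiratory peak whose +-`band_halfwidth`
#' band would overlap the VLF upper edge (`vlf_hi`).
#'
#' @param max_abs,max_rel,max_mean_abs,max_mean_rel displacement limits (mm).
#' @param vlf_hi upper VLF band edge (Hz).
#' @param band_halfwidth cardiorespiratory band half-width (Hz).
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_abs = 1.5, max_rel = 0.5, max_mean_abs = 0.6,
                          max_mean_rel = 0.07, vlf_hi = 0.1,
                          band_halfwidth = 0.05) {
  vals <- c(max_abs, max_rel, max_mean_abs, max_mean_rel, vlf_hi,
            band_halfwidth)
  if (any(vals <= 0)) stop("all QC thresholds must be > 0")
  structure(list(max_abs = max_abs, max_rel = max_rel,
                 max_mean_abs = max_mean_abs, max_mean_rel = max_mean_rel,
                 vlf_hi = vlf_hi, band_halfwidth = band_halfwidth),
            class = "qc_thresholds")
}

# zero-phase frequency-domain filter: keeps bins whose (folded, one-sided)
# frequency satisfies `keep`, applied per column of an N x V matrix
.fft_filter_mat <- function(mat, fs, keep) {
  n <- nrow(mat)
  f <- (seq_len(n) - 1) * fs / n
  f1 <- pmin(f, fs - f)          # one-sided frequency of each DFT bin
  w <- as.numeric(keep(f1))
  Re(mvfft(mvfft(mat) * w, inverse = TRUE)) / n
}

#' Trim initial frames and high-pass filter
#'
#' Drops the first `n_trim` frames (T1-relaxation transient), then removes
#' frequency content below `cutoff` per voxel with a zero-phase
#' frequency-domain filter (bins below the cutoff, including DC, are
#' zeroed). The pre-filter per-voxel temporal mean is retained in
#' `meta$voxel_mean` for later reinjection; the returned data are
#' zero-mean per voxel.
#'
#' @param vol a [voxel_volume].
#' @param n_trim frames to drop from the start.
#' @param cutoff high-pass cutoff (Hz).
#' @return a [voxel_volume] with `n - n_trim` frames.
#' @export
trim_and_highpass <- function(vol, n_trim = 180, cutoff = 0.008) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  if (d[4] <= n_trim + 2)
    stop("series too short: ", d[4], " frames, need > ", n_trim + 2)
  keep_t <- (n_trim + 1):d[4]
  n <- length(keep_t)
  V <- prod(d[1:3])
  mat <- matrix(vol$data, V, d[4])[, keep_t, drop = FALSE]
  vmean <- rowMeans(mat)
  filt <- .fft_filter_mat(t(mat), vol$fs, function(f) f >= cutoff)
  meta <- vol$meta
  meta$voxel_mean <- array(vmean, d[1:3])
  meta$highpass_hz <- cutoff
  voxel_volume(array(t(filt), c(d[1:3], n)), fs = vol$fs,
               voxel_size_mm = vol$voxel_size_mm, mask = vol$mask,
               meta = meta)
}

# one-axis Gaussian convolution matrix with renormalized truncated rows
.gauss_band <- function(n, sd_vox) {
  if (sd_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sd_vox))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- exp(-((j - i)^2) / (2 * sd_vox^2))
    K[i, j] <- w / sum(w)
  }
  K
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable 3D Gaussian smoothing with
#' `sd = fwhm / (2*sqrt(2*log(2)))` converted to voxels via the voxel edge
#' length. Boundaries use the renormalized truncated kernel (no
#' wraparound). `fwhm_mm = 0` is a no-op.
#'
#' @param vol a [voxel_volume].
#' @param fwhm_mm kernel full width at half maximum (mm).
#' @return smoothed [voxel_volume].
#' @export
spatial_smooth <- function(vol, fwhm_mm = 5) {
  stopifnot(inherits(vol, "voxel_volume"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(vol)
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vol$voxel_size_mm
  d <- dim(vol$data)
  a <- vol$data
  # axis 1
  a <- array(.gauss_band(d[1], sd_vox) %*% matrix(a, d[1]), d)
  # axis 2
  a <- aperm(a, c(2, 1, 3, 4))
  a <- array(.gauss_band(d[2], sd_vox) %*% matrix(a, d[2]), d[c(2, 1, 3, 4)])
  a <- aperm(a, c(2, 1, 3, 4))
  # axis 3
  a <- aperm(a, c(3, 1, 2, 4))
  a <- array(.gauss_band(d[3], sd_vox) %*% matrix(a, d[3]), d[c(3, 1, 2, 4)])
  a <- aperm(a, c(2, 3, 1, 4))
  voxel_volume(a, fs = vol$fs, voxel_size_mm = vol$voxel_size_mm,
               mask = vol$mask, meta = vol$meta)
}

#' Optional MAD-based despiking
#'
#' Clips per-voxel samples further than `k` median absolute deviations from
#' the voxel median to the clip boundary. Off by default in the pipeline:
#' synthetic data are spike-free; enable for spiky acquisitions.
#'
#' @param vol a [voxel_volume].
#' @param k clip threshold in MAD units.
#' @return clipped [voxel_volume].
#' @export
despike_mad <- function(vol, k = 6) {
  stopifnot(inherits(vol, "voxel_volume"), k > 0)
  d <- dim(vol$data)
  mat <- matrix(vol$data, prod(d[1:3]), d[4])
  med <- apply(mat, 1, median)
  madv <- apply(abs(mat - med), 1, median) * 1.4826
  lo <- med - k * madv
  hi <- med + k * madv
  mat <- pmin(pmax(mat, lo), hi)
  voxel_volume(array(mat, d), fs = vol$fs,
               voxel_size_mm = vol$voxel_size_mm, mask = vol$mask,
               meta = vol$meta)
}

#' Motion QC verdict
#'
#' Fails when any of the four layer rules is violated (strict inequalities:
#' "exceeding" / "over"); all violated rules are listed.
#'
#' @param trace a [motion_trace] (columns `abs_mm`, `rel_mm`).
#' @param thr a [qc_thresholds].
#' @return list with `pass` (logical) and `reasons` (character).
#' @export
motion_qc <- function(trace, thr = qc_thresholds()) {
  if (!all(c("abs_mm", "rel_mm") %in% names(trace)))
    stop("trace must have abs_mm and rel_mm columns")
  if (!nrow(trace)) stop("empty motion trace")
  if (any(trace$abs_mm < 0) || any(trace$rel_mm < 0))
    stop("displacements must be nonnegative")
  reasons <- character(0)
  if (max(trace$abs_mm) > thr$max_abs)  reasons <- c(reasons, "max_abs")
  if (max(trace$rel_mm) > thr$max_rel)  reasons <- c(reasons, "max_rel")
  if (mean(trace$abs_mm) > thr$max_mean_abs)
    reasons <- c(reasons, "mean_abs")
  if (mean(trace$rel_mm) > thr$max_mean_rel)
    reasons <- c(reasons, "mean_rel")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Respiratory-band overlap QC
#'
#' A subject whose respiratory band (peak +- half-width) would overlap the
#' VLF band is excluded: fail iff
#' `resp_peak_hz - band_halfwidth < vlf_hi` (strict).
#'
#' @param resp_peak_hz estimated respiratory peak frequency (Hz).
#' @param thr a [qc_thresholds].
#' @return list with `pass` and `reasons`.
#' @export
respiratory_overlap_qc <- function(resp_peak_hz, thr = qc_thresholds()) {
  if (resp_peak_hz <= 0) stop("resp_peak_hz must be > 0")
  # small tolerance so exact boundary values (e.g. 0.15 - 0.05 vs 0.10)
  # are not misclassified by floating-point rounding
  fail <- (resp_peak_hz - thr$band_halfwidth) < thr$vlf_hi - 1e-9
  list(pass = !fail,
       reasons = if (fail) "respiratory_vlf_overlap" else character(0))
}
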