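#' Band-pass filter with mean reinjection
#'
#' Zero-phase frequency-domain band-pass (bins outside `[lo, hi]` and DC
#' zeroed), after which the full-band per-voxel temporal mean is added
#' back -- filtering demeans the signal, and the pulsation biometrics need
#' the physiological baseline in the denominator. The reinjected mean is
#' `meta$voxel_mean` when the volume came through [trim_and_highpass()]
#' (the stored pre-filter mean), otherwise the volume's own temporal mean.
#'
#' @param vol a [voxel_volume].
#' @param band a [frequency_band] within `(0, fs/2)`.
#' @return a [voxel_volume] of class `c("filtered_volume", "voxel_volume")`
#'   whose per-voxel temporal mean equals the reinjected mean.
#' @export
bandpass_with_mean <- function(vol, band) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(band, "frequency_band"))
  if (band$hi > vol$fs / 2 + 1e-12)
    stop(sprintf("band [%g, %g] exceeds Nyquist %g Hz",
                 band$lo, band$hi, vol$fs / 2))
  d <- dim(vol$data)
  V <- prod(d[1:3])
  mat <- t(matrix(vol$data, V, d[4]))       # n x V
  vmean <- vol$meta$voxel_mean
  if (is.null(vmean)) vmean <- array(colMeans(mat), d[1:3])
  filt <- .fft_filter_mat(mat, vol$fs,
                          function(f) f >= band$lo & f <= band$hi & f > 0)
  filt <- filt + rep(as.vector(vmean), each = d[4])
  meta <- vol$meta
  meta$voxel_mean <- vmean
  meta$band <- band
  out <- voxel_volume(array(t(filt), d), fs = vol$fs,
                      voxel_size_mm = vol$voxel_size_mm, mask = vol$mask,
                      meta = meta)
  class(out) <- c("filtered_volume", class(out))
  out
}

#' Voxel-wise coefficient of variation map
#'
#' `CV_v = SD(series_v) / mean(series_v)` on the band-filtered,
#' mean-reinjected data; sample SD (`N - 1` denominator). Voxels whose
#' mean magnitude falls below `eps` times the global signal scale are set
#' `NaN` and counted in `meta$n_undefined` rather than raising an error.
#'
#' @param fvol a filtered volume from [bandpass_with_mean()] (any
#'   [voxel_volume] is accepted).
#' @param eps relative near-zero-mean guard.
#' @return a [biometric_map] of kind `"CV"`.
#' @export
cv_map <- function(fvol, eps = 1e-9) {
  stopifnot(inherits(fvol, "voxel_volume"))
  d <- dim(fvol$data)
  V <- prod(d[1:3])
  mat <- matrix(fvol$data, V, d[4])
  m <- rowMeans(mat)
  s <- sqrt(rowSums((mat - m)^2) / (d[4] - 1))
  scale <- mean(abs(m))
  bad <- abs(m) < eps * max(scale, .Machine$double.eps)
  cv <- s / m
  cv[bad] <- NaN
  if (!is.null(fvol$mask)) cv[!as.vector(fvol$mask)] <- NA_real_
  biometric_map(array(cv, d[1:3]), kind = "CV", band = fvol$meta$band,
                voxel_size_mm = fvol$voxel_size_mm,
                meta = list(n_undefined = sum(bad)))
}

# indices of spectrum bins inside a closed band
.band_bins <- function(freqs, band) {
  which(freqs >= band$lo & freqs <= band$hi)
}

#' Voxel-wise band spectral power map
#'
#' `SP_v = sum of periodogram power over bins whose frequency lies in the
#' (closed) band`.
#'
#' @param specvol a `spectrum_volume` from [spectrum_volume()].
#' @param band a [frequency_band] within the bin support.
#' @return a [biometric_map] of kind `"SP"`.
#' @export
sp_map <- function(specvol, band) {
  stopifnot(inherits(specvol, "spectrum_volume"),
            inherits(band, "frequency_band"))
  sel <- .band_bins(specvol$freqs, band)
  if (!length(sel))
    stop(sprintf("band [%g, %g] Hz contains no spectrum bins",
                 band$lo, band$hi))
  d <- dim(specvol$power)
  pw <- matrix(specvol$power, prod(d[1:3]), d[4])
  sp <- rowSums(pw[, sel, drop = FALSE])
  biometric_map(array(sp, d[1:3]), kind = "SP", band = band,
                voxel_size_mm = specvol$voxel_size_mm)
}

#' Voxel-wise spectral entropy map
#'
#' Shannon entropy of the normalized power distribution over the full-band
#' bins (default 0.008--5 Hz, i.e. above the high-pass cutoff and up to the
#' usable bandwidth), normalized by `log(B)` so that `SE` lies in
#' `[0, 1]`: 0 when all power sits in one bin, 1 for a perfectly flat
#' spectrum. Set `normalize = FALSE` for raw entropy in nats. Voxels with
#' zero in-band power become `NaN` and are counted in `meta$n_undefined`.
#'
#' @param specvol a `spectrum_volume`.
#' @param fullband the [frequency_band] of bins entering the entropy.
#' @param normalize divide by `log(B)`?
#' @return a [biometric_map] of kind `"SE"`.
#' @export
se_map <- function(specvol, fullband = frequency_band(0.008, 5, "fullband"),
                   normalize = TRUE) {
  stopifnot(inherits(specvol, "spectrum_volume"))
  fb <- fullband
  if (fb$hi > max(specvol$freqs)) fb <- frequency_band(fb$lo,
                                                       max(specvol$freqs),
                                                       fb$label)
  sel <- .band_bins(specvol$freqs, fb)
  if (length(sel) < 2) stop("need >= 2 bins inside the full band")
  d <- dim(specvol$power)
  pw <- matrix(specvol$power, prod(d[1:3]), d[4])[, sel, drop = FALSE]
  tot <- rowSums(pw)
  p <- pw / tot
  h <- -rowSums(ifelse(p > 0, p * log(p), 0))
  if (normalize) h <- h / log(length(sel))
  h[!is.finite(tot) | tot <= 0] <- NaN
  n_undef <- sum(is.finite(tot) & tot <= 0)
  h <- pmin(pmax(h, 0), if (normalize) 1 else Inf)
  biometric_map(array(h, d[1:3]), kind = "SE", band = fb,
                voxel_size_mm = specvol$voxel_size_mm,
                meta = list(n_undefined = n_undef,
                            normalized = normalize))
}

#' Background spectral power (peaks removed)
#'
#' Spectral power summed over bins farther than `exclusion_halfwidth` from
#' every listed peak frequency. Harmonics and artifact lines must be listed
#' explicitly by the caller. Used on phantom spectra to quantify the
#' nonprincipal (background) power distribution.
#'
#' @param spectrum a [power_spectrum].
#' @param principal_peaks numeric vector of peak frequencies (Hz); may be
#'   empty, in which case the full SP is returned.
#' @param exclusion_halfwidth half-width removed around each peak (Hz);
#'   default matches the pulsation-band half-width.
#' @return scalar background SP.
#' @export
background_sp <- function(spectrum, principal_peaks = numeric(0),
                          exclusion_halfwidth = 0.05) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  keep <- rep(TRUE, length(spectrum$freqs))
  for (pk in principal_peaks)
    keep <- keep & abs(spectrum$freqs - pk) > exclusion_halfwidth
  if (!any(keep))
    stop("peak exclusion removes every spectrum bin")
  sum(spectrum$power[keep])
}

#' Convert a voxel count to a reported volume
#'
#' `n * edge^3 / 1000` cubic centimetres, rounded to reporting precision:
#' whole cm^3 at or above 1, one decimal below 1. With 3 mm voxels,
#' 16,099 voxels -> 435 cm^3 and 28 voxels -> 0.8 cm^3.
#'
#' @param n_voxels nonnegative voxel count.
#' @param voxel_edge_mm isotropic voxel edge (mm).
#' @param rounded apply the reporting rounding? `FALSE` returns the exact
#'   volume.
#' @return volume in cm^3.
#' @export
voxels_to_volume_cm3 <- function(n_voxels, voxel_edge_mm = 3,
                                 rounded = TRUE) {
  if (any(n_voxels < 0)) stop("voxel count must be nonnegative")
  v <- n_voxels * voxel_edge_mm^3 / 1000
  if (!rounded) return(v)
  ifelse(v >= 1, round(v), round(v, 1))
}

#' Subject-level biometric pipeline
#'
#' Convenience wrapper running the full per-subject stage on a (raw)
#' volume: trim + high-pass, optional smoothing, then for each requested
#' band a CV and SP map, plus the full-band SE map.
#'
#' @param vol a raw [voxel_volume].
#' @param bands named list of [frequency_band]s for CV/SP.
#' @param n_trim,highpass_hz,fwhm_mm preprocessing settings (fwhm 0 skips
#'   smoothing).
#' @param fullband band for SE.
#' @return nested list: `cv[[band]]`, `sp[[band]]`, `se`.
#' @export
subject_biometrics <- function(vol, bands, n_trim = 180,
                               highpass_hz = 0.008, fwhm_mm = 0,
                               fullband = frequency_band(0.008, 5,
                                                         "fullband")) {
  pre <- trim_and_highpass(vol, n_trim = n_trim, cutoff = highpass_hz)
  if (fwhm_mm > 0) pre <- spatial_smooth(pre, fwhm_mm)
  sv <- spectrum_volume(pre)
  cv <- lapply(bands, function(b) cv_map(bandpass_with_mean(pre, b)))
  sp <- lapply(bands, function(b) sp_map(sv, b))
  list(cv = cv, sp = sp, se = se_map(sv, fullband))
}

#' Phantom biometrics across flow states
#'
#' Applies the full-band CV/SP/SE computation to each flow-state volume
#' inside the water ROI and summarizes with per-state medians and their
#' ratios to the first (baseline) state.
#'
#' @param volumes named list of per-state [voxel_volume]s (baseline first).
#' @param roi_mask 3D logical water-channel mask.
#' @param fullband analysis band.
#' @param peaks optional named list (per state) of peak frequencies to
#'   exclude for background SP; states without an entry use none.
#' @param exclusion_halfwidth peak-removal half-width (Hz).
#' @return data.frame with one row per state: median CV, SP, SE, background
#'   SP and each metric's ratio to the baseline state.
#' @export
phantom_biometrics <- function(volumes, roi_mask,
                               fullband = frequency_band(0.008, 5,
                                                         "fullband"),
                               peaks = NULL,
                               exclusion_halfwidth = 0.05) {
  roi_idx <- which(as.vector(roi_mask))
  rows <- lapply(names(volumes), function(nm) {
    vol <- volumes[[nm]]
    pre <- trim_and_highpass(vol, n_trim = 0,
                             cutoff = min(fullband$lo, 0.008))
    sv <- spectrum_volume(pre)
    fb <- frequency_band(fullband$lo, min(fullband$hi, vol$fs / 2),
                         fullband$label)
    cvv <- as.vector(cv_map(bandpass_with_mean(pre, fb))$values)[roi_idx]
    spv <- as.vector(sp_map(sv, fb)$values)[roi_idx]
    sev <- as.vector(se_map(sv, fb)$values)[roi_idx]
    pw <- matrix(sv$power, length(as.vector(roi_mask)), length(sv$freqs))
    sel <- .band_bins(sv$freqs, fb)
    pks <- if (!is.null(peaks) && nm %in% names(peaks)) peaks[[nm]]
           else numeric(0)
    bsp <- apply(pw[roi_idx, sel, drop = FALSE], 1, function(p)
      background_sp(power_spectrum(sv$freqs[sel], p), pks,
                    exclusion_halfwidth))
    data.frame(state = nm, median_cv = median(cvv, na.rm = TRUE),
               median_sp = median(spv, na.rm = TRUE),
               median_se = median(sev, na.rm = TRUE),
               median_background_sp = median(bsp, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$cv_ratio <- out$median_cv / out$median_cv[1]
  out$sp_ratio <- out$median_sp / out$median_sp[1]
  out$background_sp_ratio <- out$median_background_sp /
    out$median_background_sp[1]
  out
}
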