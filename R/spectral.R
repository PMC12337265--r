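#' One-sided periodogram
#'
#' `P_k = |X_k|^2 / N` over `k = 0..floor(N/2)` with a rectangular window.
#' Under this convention a unit-amplitude sinusoid at an exact bin places
#' `N/4` in that bin, and Parseval reads
#' `sum(s^2) = P_0 + 2*sum(P_mid) + P_Nyq` (Nyquist term for even `N`).
#'
#' @param series numeric vector, length >= 4.
#' @param fs sampling frequency (Hz).
#' @return a [power_spectrum] with bins at `k * fs / N`.
#' @export
periodogram <- function(series, fs) {
  n <- length(series)
  if (n < 4) stop("series must have length >= 4")
  X <- fft(series)
  k <- 0:(n %/% 2)
  power_spectrum(freqs = k * fs / n, power = Mod(X[k + 1])^2 / n)
}

#' Voxel-wise spectrum volume
#'
#' The [periodogram] of every voxel's series, on one shared bin grid.
#' Voxels outside the volume's mask are skipped (all-`NA` spectra).
#'
#' @param vol a [voxel_volume] (already preprocessed/high-passed).
#' @return list of class `spectrum_volume` with `freqs` and a 4D `power`
#'   array (x, y, z, bin).
#' @export
spectrum_volume <- function(vol) {
  stopifnot(inherits(vol, "voxel_volume"))
  d <- dim(vol$data)
  n <- d[4]
  if (n < 4) stop("need >= 4 timepoints")
  V <- prod(d[1:3])
  mat <- t(matrix(vol$data, V, n))          # n x V
  X <- mvfft(mat)
  k <- 0:(n %/% 2)
  pw <- t(Mod(X[k + 1, , drop = FALSE])^2 / n)   # V x bins
  if (!is.null(vol$mask)) pw[!as.vector(vol$mask), ] <- NA_real_
  structure(list(freqs = k * vol$fs / n,
                 power = array(pw, c(d[1:3], length(k))),
                 fs = vol$fs, n_time = n,
                 voxel_size_mm = vol$voxel_size_mm, mask = vol$mask),
            class = "spectrum_volume")
}

#' Mean spectrum over a region of interest
#'
#' @param sv a `spectrum_volume`.
#' @param roi 3D logical array.
#' @return a [power_spectrum], the ROI-mean power per bin.
#' @export
roi_mean_spectrum <- function(sv, roi) {
  stopifnot(inherits(sv, "spectrum_volume"))
  if (!identical(dim(roi), dim(sv$power)[1:3])) stop("ROI shape mismatch")
  pw <- matrix(sv$power, prod(dim(roi)), length(sv$freqs))
  m <- colMeans(pw[as.vector(roi != 0), , drop = FALSE], na.rm = TRUE)
  power_spectrum(sv$freqs, m)
}

#' Detect the dominant spectral peak in a search band
#'
#' Frequency of the maximal power bin inside the (closed) search band; ties
#' break toward the lower frequency. Invariant to overall spectrum scaling.
#'
#' @param spectrum a [power_spectrum].
#' @param search a [frequency_band] giving the search window.
#' @return peak frequency (Hz).
#' @export
detect_peak <- function(spectrum, search) {
  stopifnot(inherits(spectrum, "power_spectrum"),
            inherits(search, "frequency_band"))
  sel <- which(spectrum$freqs >= search$lo & spectrum$freqs <= search$hi)
  if (!length(sel))
    stop(sprintf("search band [%g, %g] Hz contains no spectrum bins",
                 search$lo, search$hi))
  spectrum$freqs[sel[which.max(spectrum$power[sel])]]
}

#' Build a pulsation band around a detected peak
#'
#' The subject-specific cardiorespiratory band: `half_width` Hz on both
#' sides of the principal peak (total range `2 * half_width`).
#'
#' @param peak_hz peak frequency (Hz).
#' @param half_width band half-width (Hz).
#' @param label band label.
#' @param fs optional sampling frequency; enforces the upper edge below
#'   Nyquist.
#' @return a [frequency_band] `[peak - half_width, peak + half_width]`.
#' @export
band_from_peak <- function(peak_hz, half_width = 0.05, label = "band",
                           fs = NULL) {
  if (peak_hz - half_width <= 0)
    stop("band lower edge would reach 0 Hz (peak too low)")
  frequency_band(peak_hz - half_width, peak_hz + half_width,
                 label = label, fs = fs)
}

#' Short-time spectrogram
#'
#' Periodograms on sliding windows (default 10 s, half-overlapping),
#' columns time-ordered.
#'
#' @param series numeric vector.
#' @param fs sampling frequency (Hz).
#' @param window_s window length (s); `window_s * fs >= 8`.
#' @param overlap_frac fractional overlap between consecutive windows.
#' @return list with `freqs`, `times` (window centers, s) and `power`
#'   (bins x windows matrix).
#' @export
spectrogram <- function(series, fs, window_s = 10, overlap_frac = 0.5) {
  nw <- round(window_s * fs)
  if (nw < 8) stop("window too short: need window_s * fs >= 8")
  if (length(series) < nw) stop("series shorter than one window")
  hop <- max(1L, round(nw * (1 - overlap_frac)))
  starts <- seq(1L, length(series) - nw + 1L, by = hop)
  k <- 0:(nw %/% 2)
  pw <- vapply(starts, function(s0) {
    X <- fft(series[s0:(s0 + nw - 1L)])
    Mod(X[k + 1])^2 / nw
  }, numeric(length(k)))
  list(freqs = k * fs / nw,
       times = (starts - 1 + nw / 2) / fs,
       power = matrix(pw, nrow = length(k)))
}

#' Resolve subject pulsation bands from spectra
#'
#' Detects the respiratory and cardiac peaks in a spectrum (a physiological
#' trace's periodogram, or an ROI-mean voxel spectrum) and returns the
#' peak +- half-width bands.
#'
#' @param spectrum a [power_spectrum].
#' @param search list with `respiratory` and `cardiac` `c(lo, hi)` windows.
#' @param half_width band half-width (Hz).
#' @param fs optional sampling frequency for Nyquist checking.
#' @return list with `respiratory` and `cardiac` entries, each holding
#'   `peak_hz` and `band`.
#' @export
resolve_bands <- function(spectrum,
                          search = default_config()$peak_search,
                          half_width = default_config()$band_halfwidth,
                          fs = NULL) {
  out <- lapply(names(search), function(nm) {
    sb <- frequency_band(search[[nm]][1], search[[nm]][2], label = nm)
    pk <- detect_peak(spectrum, sb)
    list(peak_hz = pk,
         band = band_from_peak(pk, half_width, label = nm, fs = fs))
  })
  names(out) <- names(search)
  out
}
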