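#' Default analysis configuration
#'
#' All tunable constants in one list: band edges, the half-width used to
#' build subject-specific cardiorespiratory bands, motion-QC thresholds,
#' peak-search windows and permutation settings. Values mirror a 10 Hz,
#' 3 mm isotropic MREG acquisition.
#'
#' @return nested list of settings.
#' @export
default_config <- function() {
  list(
    fs = 10,                 # Hz, fallback when a file carries no TR
    voxel_size_mm = 3,
    bands = list(
      vlf      = c(0.008, 0.1),
      fullband = c(0.008, 5)
    ),
    band_halfwidth = 0.05,   # Hz on both sides of a cardiorespiratory peak
    peak_search = list(
      respiratory = c(0.12, 0.6),
      cardiac     = c(0.6, 1.8)
    ),
    qc = list(
      max_abs = 1.5, max_rel = 0.5,       # mm, any-timepoint thresholds
      max_mean_abs = 0.6, max_mean_rel = 0.07,
      vlf_hi = 0.1
    ),
    preprocess = list(n_trim = 180, highpass_hz = 0.008, fwhm_mm = 5),
    permutation = list(n_perm = 10000, n_perm_test = 250, alpha = 0.05),
    tfce = list(H = 2, E = 0.5, n_steps = 100, connectivity = 26)
  )
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path YAML file; keys override [default_config()] entries.
#' @return merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}
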