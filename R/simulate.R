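#' Specification for one simulated MREG-like subject
#'
#' Defines a per-voxel signal of the form
#' `s_v(t) = m * (1 + sum_b a_bv * sin(2*pi*f_b*t + phi_bv)) + eps(t)`,
#' `eps ~ N(0, sd^2)` i.i.d.: a baseline mean plus one sinusoid per
#' physiological band (VLF vasomotor, respiratory, cardiac) with relative
#' amplitude `a` expressed as a fraction of the mean, and white noise.
#' Effect regions are voxel-index boxes whose band amplitude is multiplied,
#' emulating a localized group difference.
#'
#' @param grid spatial grid dimensions, length 3.
#' @param fs sampling frequency (Hz).
#' @param duration_s scan length (s); default 300 s matches a 5-min analysed
#'   segment.
#' @param baseline mean signal level `m` (arbitrary units).
#' @param bands named list; each element `list(freq = Hz, amp = fraction)`.
#' @param regions list of `list(box = list(x = c(lo, hi), y = ..., z = ...),
#'   band = name, multiplier = k)` (inclusive 1-based index ranges).
#' @param noise_sd additive white-noise SD (signal units).
#' @param phase `"random"` (per-voxel uniform phases, decorrelates voxels)
#'   or `"coherent"` (all phases 0, for closed-form checks).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @return An object of class `subject_sim_spec`.
#' @export
subject_sim_spec <- function(grid = c(12, 12, 12), fs = 10, duration_s = 300,
                             baseline = 100,
                             bands = list(
                               vlf         = list(freq = 0.05, amp = 0.05),
                               respiratory = list(freq = 0.30, amp = 0.05),
                               cardiac     = list(freq = 1.00, amp = 0.10)),
                             regions = list(), noise_sd = 1,
                             phase = c("random", "coherent"), seed = NULL) {
  phase <- match.arg(phase)
  stopifnot(length(grid) == 3, all(grid >= 1), fs > 0, duration_s > 0,
            baseline != 0, noise_sd >= 0)
  for (b in bands) {
    if (b$amp < 0) stop("relative amplitudes must be >= 0")
    if (b$freq >= fs / 2)
      stop(sprintf(
        "band frequency %g Hz is at/above Nyquist (%g Hz): aliasing; ",
        b$freq, fs / 2),
        "the subject generator refuses super-Nyquist components")
  }
  for (r in regions) {
    if (!r$band %in% names(bands)) stop("region band '", r$band, "' unknown")
    for (ax in 1:3) {
      rng <- r$box[[ax]]
      if (rng[1] < 1 || rng[2] > grid[ax] || rng[1] > rng[2])
        stop("effect region box exceeds the grid")
    }
  }
  structure(list(grid = grid, fs = fs, duration_s = duration_s,
                 baseline = baseline, bands = bands, regions = regions,
                 noise_sd = noise_sd, phase = phase, seed = seed),
            class = "subject_sim_spec")
}

# per-band 3D relative-amplitude arrays implied by a spec
.amplitude_arrays <- function(spec) {
  out <- lapply(spec$bands, function(b) array(b$amp, spec$grid))
  for (r in spec$regions) {
    bx <- lapply(r$box, function(v) v[1]:v[2])
    out[[r$band]][bx[[1]], bx[[2]], bx[[3]]] <-
      out[[r$band]][bx[[1]], bx[[2]], bx[[3]]] * r$multiplier
  }
  out
}

#' Simulate one subject volume with known ground truth
#'
#' @param spec a [subject_sim_spec].
#' @return list with `volume` (a [voxel_volume]) and `truth`, a data.frame of
#'   every voxel's per-band relative amplitude.
#' @export
simulate_subject <- function(spec) {
  stopifnot(inherits(spec, "subject_sim_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs)
    V <- prod(spec$grid)
    tt <- (seq_len(n) - 1) / spec$fs
    amps <- .amplitude_arrays(spec)
    mat <- matrix(spec$baseline, V, n)
    for (bn in names(spec$bands)) {
      f <- spec$bands[[bn]]$freq
      a <- as.vector(amps[[bn]]) * spec$baseline
      phi <- if (spec$phase == "random") runif(V, 0, 2 * pi) else rep(0, V)
      s1 <- sin(2 * pi * f * tt)
      c1 <- cos(2 * pi * f * tt)
      mat <- mat + outer(a * cos(phi), s1) + outer(a * sin(phi), c1)
    }
    if (spec$noise_sd > 0)
      mat <- mat + matrix(rnorm(V * n, 0, spec$noise_sd), V, n)
    vol <- voxel_volume(array(mat, c(spec$grid, n)), fs = spec$fs,
                        meta = list(sim_spec = spec))
    idx <- expand.grid(x = seq_len(spec$grid[1]), y = seq_len(spec$grid[2]),
                       z = seq_len(spec$grid[3]))
    truth <- do.call(rbind, lapply(names(amps), function(bn)
      cbind(idx, band = bn, rel_amplitude = as.vector(amps[[bn]]))))
    list(volume = vol, truth = truth)
  })
}

#' Simulate a multi-group cohort
#'
#' Each group has its own [subject_sim_spec] template. Subjects get
#' independent seeds derived from the master seed, ages and sex drawn from
#' configured distributions, and a per-subject lognormal amplitude factor
#' (inter-individual pulsation-strength variation) applied to every band.
#'
#' @param group_specs named list of [subject_sim_spec] templates (>= 2).
#' @param n_per_group integer vector, one per group (recycled); each >= 2.
#' @param seed master seed.
#' @param age_mean,age_sd age distribution (years), truncated to 18--70.
#' @param sex_p probability of sex code 1.
#' @param amp_jitter_sd SD of the per-subject log amplitude factor; 0 for
#'   identical subjects.
#' @param transform optional function applied to each subject's
#'   [voxel_volume] immediately (e.g. a map-computing pipeline); its result
#'   is stored instead of the raw volume, keeping memory flat.
#' @return list with `subjects` (list, grouped order), `design` (data.frame:
#'   subject_id, group, age, sex), and `truth` (per-group per-band amplitude
#'   arrays; see [cohort_effect_mask()]).
#' @export
simulate_cohort <- function(group_specs, n_per_group, seed = NULL,
                            age_mean = 30, age_sd = 8, sex_p = 0.5,
                            amp_jitter_sd = 0.1, transform = NULL) {
  if (length(group_specs) < 2) stop("need >= 2 groups")
  if (is.null(names(group_specs)) || any(names(group_specs) == ""))
    stop("group_specs must be a named list")
  n_per_group <- rep_len(as.integer(n_per_group), length(group_specs))
  if (any(n_per_group < 2)) stop("each group needs n >= 2 subjects")
  total <- sum(n_per_group)
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, total)
    ages <- pmin(70, pmax(18, round(rnorm(total, age_mean, age_sd))))
    sexes <- rbinom(total, 1, sex_p)
    jit <- if (amp_jitter_sd > 0) exp(rnorm(total, 0, amp_jitter_sd))
           else rep(1, total)
    subjects <- vector("list", total)
    design <- data.frame(subject_id = sprintf("S%03d", seq_len(total)),
                         group = rep(names(group_specs), n_per_group),
                         age = ages, sex = sexes,
                         stringsAsFactors = FALSE)
    k <- 0L
    for (g in seq_along(group_specs)) {
      for (j in seq_len(n_per_group[g])) {
        k <- k + 1L
        sp <- group_specs[[g]]
        sp$bands <- lapply(sp$bands, function(b) {
          b$amp <- b$amp * jit[k]; b
        })
        sp$seed <- sub_seeds[k]
        sub <- simulate_subject(sp)
        subjects[[k]] <- if (is.null(transform)) sub$volume
                         else transform(sub$volume)
      }
    }
    truth <- lapply(group_specs, .amplitude_arrays)
    list(subjects = subjects, design = design, truth = truth)
  })
}

#' True between-group effect mask
#'
#' Voxels whose ground-truth relative amplitude in `band` differs between
#' two simulated groups.
#'
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param group_a,group_b group names.
#' @param band band name.
#' @return 3D logical array.
#' @export
cohort_effect_mask <- function(truth, group_a, group_b, band) {
  a <- truth[[group_a]][[band]]
  b <- truth[[group_b]][[band]]
  a != b
}

#' Specification for a pulsatile-flow phantom recording
#'
#' Emulates a water-channel phantom scanned under an inactive pump and a
#' series of pulsatile flow states. Each flow state injects, inside the
#' water ROI, a principal sinusoid at the pump frequency, a first-degree
#' harmonic, a scanner helium-pump artifact line at 1.0 Hz (present in
#' every state, baseline included), and state-dependent broadband power
#' standing in for heterodynes/turbulence. Components above Nyquist are
#' folded to `|f - fs*round(f/fs)|`, reproducing the aliasing a 10 Hz
#' acquisition shows for fast flow.
#'
#' Default amplitudes rise monotonically with flow speed and are placed in
#' the signal-to-noise regime where the ROI-median spectral-power and CV
#' ratios to baseline are of the order observed for 7/14/21 cm/s pulsatile
#' flow (see the methods vignette for the derivation).
#'
#' @param grid spatial grid, length 3.
#' @param fs sampling frequency (Hz).
#' @param samples_per_state steady-state timepoints per flow state.
#' @param baseline mean signal level.
#' @param noise_sd white-noise SD everywhere.
#' @param roi voxel-index box (inclusive ranges) of the water channel.
#' @param states data.frame with columns `label`, `freq` (Hz, NA for the
#'   inactive-pump baseline), `amp`, `harmonic_amp`, `broadband_sd`
#'   (signal units), ordered by nominal flow speed.
#' @param artifact_hz,artifact_amp helium-pump line frequency and amplitude.
#' @param seed RNG seed.
#' @return An object of class `phantom_sim_spec`.
#' @export
phantom_sim_spec <- function(grid = c(12, 12, 12), fs = 10,
                             samples_per_state = 462, baseline = 100,
                             noise_sd = 1,
                             roi = list(x = c(3, 10), y = c(3, 10),
                                        z = c(2, 10)),
                             states = data.frame(
                               label = c("baseline", "7cm/s", "14cm/s",
                                         "21cm/s"),
                               freq = c(NA, 1.47, 2.93, 4.4),
                               amp = c(0, 5.10, 6.93, 7.35),
                               harmonic_amp = c(0, 1.02, 1.39, 1.47),
                               broadband_sd = c(0, 1.77, 2.65, 3.44),
                               stringsAsFactors = FALSE),
                             artifact_hz = 1.0, artifact_amp = 0.8,
                             seed = NULL) {
  stopifnot(length(grid) == 3, fs > 0, samples_per_state >= 8)
  nroi <- prod(vapply(roi, function(v) v[2] - v[1] + 1, 0))
  if (nroi < 1) stop("empty phantom ROI")
  for (ax in 1:3) {
    if (roi[[ax]][1] < 1 || roi[[ax]][2] > grid[ax])
      stop("ROI exceeds the grid")
  }
  fl <- states$freq[!is.na(states$freq)]
  if (any(fl <= 0)) stop("principal frequencies must be > 0")
  structure(list(grid = grid, fs = fs,
                 samples_per_state = samples_per_state, baseline = baseline,
                 noise_sd = noise_sd, roi = roi, states = states,
                 artifact_hz = artifact_hz, artifact_amp = artifact_amp,
                 seed = seed),
            class = "phantom_sim_spec")
}

#' Fold a frequency into the sampled band
#'
#' Alias of `f` under sampling at `fs`: `|f - fs * round(f / fs)|`.
#'
#' @param f frequency (Hz), possibly above Nyquist.
#' @param fs sampling frequency (Hz).
#' @return folded frequency in `[0, fs/2]`.
#' @export
alias_frequency <- function(f, fs) abs(f - fs * round(f / fs))

#' Simulate a pulsatile-flow phantom recording
#'
#' @param spec a [phantom_sim_spec].
#' @return list with `volumes` (named list of [voxel_volume], one per
#'   state), `roi_mask` (3D logical array) and `truth` (state table with the
#'   effective, possibly folded, component frequencies).
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$samples_per_state
    V <- prod(spec$grid)
    tt <- (seq_len(n) - 1) / spec$fs
    roi_mask <- array(FALSE, spec$grid)
    bx <- lapply(spec$roi, function(v) v[1]:v[2])
    roi_mask[bx[[1]], bx[[2]], bx[[3]]] <- TRUE
    roi_idx <- which(roi_mask)
    nroi <- length(roi_idx)
    add_line <- function(mat, f, amp) {
      fa <- alias_frequency(f, spec$fs)
      phi <- runif(nroi, 0, 2 * pi)
      s1 <- sin(2 * pi * fa * tt); c1 <- cos(2 * pi * fa * tt)
      mat[roi_idx, ] <- mat[roi_idx, ] +
        outer(amp * cos(phi), s1) + outer(amp * sin(phi), c1)
      mat
    }
    volumes <- list()
    truth <- list()
    for (i in seq_len(nrow(spec$states))) {
      st <- spec$states[i, ]
      mat <- matrix(spec$baseline, V, n) +
        matrix(rnorm(V * n, 0, spec$noise_sd), V, n)
      comps <- data.frame(component = "artifact", freq = spec$artifact_hz,
                          effective_freq = alias_frequency(spec$artifact_hz,
                                                           spec$fs),
                          amp = spec$artifact_amp)
      mat <- add_line(mat, spec$artifact_hz, spec$artifact_amp)
      if (!is.na(st$freq)) {
        mat <- add_line(mat, st$freq, st$amp)
        mat <- add_line(mat, 2 * st$freq, st$harmonic_amp)
        comps <- rbind(comps,
          data.frame(component = c("principal", "harmonic"),
                     freq = c(st$freq, 2 * st$freq),
                     effective_freq = alias_frequency(c(st$freq, 2 * st$freq),
                                                      spec$fs),
                     amp = c(st$amp, st$harmonic_amp)))
        if (st$broadband_sd > 0)
          mat[roi_idx, ] <- mat[roi_idx, ] +
            matrix(rnorm(nroi * n, 0, st$broadband_sd), nroi, n)
      }
      volumes[[st$label]] <- voxel_volume(array(mat, c(spec$grid, n)),
                                          fs = spec$fs, mask = roi_mask)
      truth[[st$label]] <- comps
    }
    list(volumes = volumes, roi_mask = roi_mask, truth = truth)
  })
}

#' Specification for a synthetic photoplethysmogram
#'
#' A pulse train: an asymmetric template (steep systolic upstroke, slower
#' decay) placed at beat times whose intervals are
#' `RR_i ~ N(mean_rr, rr_jitter_sd^2)` truncated positive.
#'
#' @param mean_rr mean beat-to-beat interval (s); must exceed 3x the jitter
#'   SD.
#' @param rr_jitter_sd beat-to-beat SD (s).
#' @param fs sampling frequency (Hz), >= 50 for slope-detection fidelity.
#' @param duration_s recording length (s).
#' @param seed RNG seed.
#' @return An object of class `ppg_sim_spec`.
#' @export
ppg_sim_spec <- function(mean_rr = 1.0, rr_jitter_sd = 0.03, fs = 100,
                         duration_s = 300, seed = NULL) {
  if (fs < 50) stop("fs must be >= 50 Hz")
  if (!(mean_rr > 3 * rr_jitter_sd))
    stop("mean_rr must exceed 3x rr_jitter_sd")
  if (duration_s < 10) stop("duration must be >= 10 s")
  structure(list(mean_rr = mean_rr, rr_jitter_sd = rr_jitter_sd, fs = fs,
                 duration_s = duration_s, seed = seed),
            class = "ppg_sim_spec")
}

# systolic pulse template on the sampling grid: half-cosine upstroke over
# `rise` seconds, exponential decay thereafter, tapered to 0 at the end
.ppg_template <- function(fs, rise = 0.08, tau = 0.12, length_s = 0.45) {
  tt <- seq(0, length_s, by = 1 / fs)
  p <- ifelse(tt <= rise, (1 - cos(pi * tt / rise)) / 2,
              exp(-(tt - rise) / tau))
  ramp <- pmin(1, (length_s - tt) / 0.1)
  p * pmax(ramp, 0)
}

#' Simulate a photoplethysmogram with known beat times
#'
#' Reported `beat_times` are the instants of maximal template upslope (the
#' fiducial a maximal-slope beat detector estimates), snapped to the sample
#' grid.
#'
#' @param spec a [ppg_sim_spec].
#' @return list with `time`, `signal`, `beat_times` (s), `rr` (s) and
#'   `true_rmssd` (s).
#' @export
simulate_ppg <- function(spec) {
  stopifnot(inherits(spec, "ppg_sim_spec"))
  with_seed(spec$seed, {
    fs <- spec$fs
    tpl <- .ppg_template(fs)
    slope_off <- which.max(diff(tpl))  # samples from onset to max upslope
    n <- round(spec$duration_s * fs)
    sig <- numeric(n)
    onsets <- numeric(0)
    t0 <- 0.2
    while (TRUE) {
      i0 <- round(t0 * fs) + 1L
      if (i0 + length(tpl) - 1L > n) break
      sig[i0:(i0 + length(tpl) - 1L)] <-
        sig[i0:(i0 + length(tpl) - 1L)] + tpl
      onsets <- c(onsets, (i0 - 1L) / fs)
      repeat {  # truncated-positive RR draw; never emit a nonpositive RR
        rr <- rnorm(1, spec$mean_rr, spec$rr_jitter_sd)
        if (rr > 0.25 * spec$mean_rr) break
      }
      t0 <- t0 + rr
    }
    beat_times <- onsets + slope_off / fs
    rr <- diff(beat_times)
    list(time = (seq_len(n) - 1) / fs, signal = sig,
         beat_times = beat_times, rr = rr,
         true_rmssd = if (length(rr) >= 2) rmssd(rr) else NA_real_)
  })
}
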