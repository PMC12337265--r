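#' Detect heart beats in a PPG trace by maximal slope
#'
#' Candidate pulses are peaks of a moving-average-smoothed signal with a
#' refractory period (default 0.3 s, a ~200 bpm physiological ceiling);
#' within each pulse's rising limb (preceding trough to peak) the beat
#' fiducial is the sample of maximal first difference of the raw signal.
#'
#' @param signal numeric PPG samples.
#' @param fs sampling frequency (Hz), >= 50.
#' @param smooth_s moving-average width for candidate detection (s).
#' @param refractory_s minimum inter-beat spacing (s).
#' @param min_prominence peak height threshold as a fraction of the
#'   smoothed signal's amplitude range above its median.
#' @return numeric beat times (s); empty with a warning for a flat signal.
#' @export
detect_beats <- function(signal, fs, smooth_s = 0.1, refractory_s = 0.3,
                         min_prominence = 0.3) {
  if (fs < 50) stop("fs must be >= 50 Hz")
  n <- length(signal)
  if (n < 10 * fs) stop("need >= 10 s of signal")
  rng <- diff(range(signal))
  if (rng < .Machine$double.eps^0.5 * max(1, abs(signal[1]))) {
    warning("flat signal: no beats detected")
    return(numeric(0))
  }
  w <- max(1L, round(smooth_s * fs))
  sm <- as.numeric(stats::filter(signal, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- signal[is.na(sm)]
  thr <- median(sm) + min_prominence * (max(sm) - median(sm))
  refr <- round(refractory_s * fs)
  # local maxima of the smoothed trace above threshold
  isel <- which(sm > thr)
  isel <- isel[isel > 1 & isel < n]
  isel <- isel[sm[isel] >= sm[isel - 1] & sm[isel] >= sm[isel + 1]]
  if (!length(isel)) {
    warning("no pulse candidates above threshold")
    return(numeric(0))
  }
  peaks <- integer(0)
  last <- -Inf
  for (i in isel) {
    if (i - last >= refr) {
      peaks <- c(peaks, i)
      last <- i
    } else if (sm[i] > sm[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i    # keep the taller of clashing candidates
      last <- i
    }
  }
  ds <- diff(signal)
  beats <- vapply(seq_along(peaks), function(k) {
    i1 <- peaks[k]
    i0 <- if (k == 1) max(1L, i1 - refr) else peaks[k - 1]
    # preceding trough on the raw trace
    tr <- i0 + which.min(signal[i0:i1]) - 1L
    if (tr >= i1) tr <- max(1L, i1 - 1L)
    tr + which.max(ds[tr:(i1 - 1L)]) - 1
  }, 0)
  (beats - 1) / fs
}

#' Root mean square of successive RR differences
#'
#' `RMSSD = sqrt( (1/(N-1)) * sum_i (RR_{i+1} - RR_i)^2 )` with `N` the
#' number of intervals; a time-domain heart-rate-variability index of
#' parasympathetic tone. Invariant to a constant shift of all intervals
#' and linear in their scale.
#'
#' @param rr numeric RR intervals (s), `N >= 2`.
#' @return RMSSD (s).
#' @export
rmssd <- function(rr) {
  n <- length(rr)
  if (n < 2) stop("need >= 2 RR intervals")
  sqrt(sum(diff(rr)^2) / (n - 1))
}

#' Beat-detection quality control (5% error rule)
#'
#' Matches detected to reference beats greedily within `tolerance_s`;
#' `error rate = (misses + false detections) / #reference`. Fails iff the
#' rate exceeds `max_error` (strictly; exactly 5% passes).
#'
#' @param detected,reference numeric beat times (s); reference nonempty.
#' @param tolerance_s matching tolerance (s).
#' @param max_error exclusion threshold.
#' @return list with `pass`, `error_rate`, `n_miss`, `n_extra`.
#' @export
hrv_qc <- function(detected, reference, tolerance_s = 0.05,
                   max_error = 0.05) {
  if (!length(reference)) stop("empty reference beat set")
  used <- rep(FALSE, length(detected))
  n_miss <- 0L
  for (r in reference) {
    dist <- abs(detected - r)
    dist[used] <- Inf
    j <- if (length(dist)) which.min(dist) else integer(0)
    if (!length(j) || dist[j] > tolerance_s) n_miss <- n_miss + 1L
    else used[j] <- TRUE
  }
  n_extra <- sum(!used)
  rate <- (n_miss + n_extra) / length(reference)
  list(pass = rate <= max_error, error_rate = rate,
       n_miss = n_miss, n_extra = n_extra)
}

#' Medication effect on RMSSD (general linear model)
#'
#' OLS fit `rmssd ~ medication + age + sex`; returns the medication
#' coefficient with its normal-theory 95% CI and the model R^2.
#'
#' @param rmssd_values numeric response.
#' @param medication,age,sex predictors (binary, years, binary).
#' @param conf_level CI coverage.
#' @return list with `estimate`, `ci` (length 2), `r_squared`, `p_value`
#'   and the fitted `model`.
#' @export
medication_model <- function(rmssd_values, medication, age, sex,
                             conf_level = 0.95) {
  df <- data.frame(rmssd = rmssd_values, medication = medication,
                   age = age, sex = sex)
  if (nrow(df) < 5)
    stop("need n > number of predictors + 1 (n >= 5)")
  X <- cbind(1, df$medication, df$age, df$sex)
  if (qr(X)$rank < ncol(X)) stop("singular design")
  fit <- lm(rmssd ~ medication + age + sex, data = df)
  sm <- summary(fit)
  ci <- confint(fit, "medication", level = conf_level)
  list(estimate = unname(coef(fit)["medication"]),
       ci = as.numeric(ci), r_squared = sm$r.squared,
       p_value = sm$coefficients["medication", "Pr(>|t|)"],
       model = fit)
}
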