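test_that("band-pass keeps in-band content, kills out-of-band, reinjects the mean", {
  n <- 1000; fs <- 10; tt <- (0:(n - 1)) / fs
  band <- frequency_band(0.95, 1.05, "cardiac")
  mk <- function(s) voxel_volume(array(rep(s, each = 4), c(2, 2, 1, n)), fs)

  # 1.0 Hz is an exact bin inside the band: the series passes unchanged
  inb <- 100 + 4 * sin(2 * pi * 1.0 * tt)
  fv <- bandpass_with_mean(mk(inb), band)
  expect_equal(fv$data[1, 1, 1, ], inb, tolerance = 1e-8)
  expect_equal(mean(fv$data[1, 1, 1, ]), 100, tolerance = 1e-8)

  outb <- 100 + 4 * sin(2 * pi * 3.0 * tt)
  fv2 <- bandpass_with_mean(mk(outb), band)
  expect_lt(max(abs(fv2$data[1, 1, 1, ] - 100)), 0.05)

  # reinjection contract on arbitrary data
  vol <- tiny_volume(grid = c(3, 3, 1), n = 512, seed = 8)
  fv3 <- bandpass_with_mean(vol, band)
  expect_equal(apply(fv3$data, 1:3, mean), apply(vol$data, 1:3, mean),
               tolerance = 1e-9)
  # volumes through trim_and_highpass reinject the stored pre-filter mean
  pre <- trim_and_highpass(vol, n_trim = 0)
  fv4 <- bandpass_with_mean(pre, band)
  expect_equal(apply(fv4$data, 1:3, mean), pre$meta$voxel_mean,
               tolerance = 1e-9)
  expect_error(bandpass_with_mean(vol, frequency_band(4, 6, "bad")),
               "Nyquist")
})

test_that("CV maps implement SD/mean with the n-1 denominator", {
  v <- c(8, 12, 8, 12)
  vol <- voxel_volume(array(v, c(1, 1, 1, 4)), fs = 10)
  cv <- cv_map(vol)
  expect_equal(cv$values[1, 1, 1], sqrt(16 / 3) / 10, tolerance = 1e-12)

  const <- voxel_volume(array(5, c(1, 1, 1, 10)), fs = 10)
  expect_equal(cv_map(const)$values[1, 1, 1], 0)

  # mean 100, amplitude 10 sinusoid over integer cycles -> (A/sqrt(2))/m
  n <- 3000; tt <- (0:(n - 1)) / 10
  s <- 100 + 10 * sin(2 * pi * 1 * tt)
  cv2 <- cv_map(voxel_volume(array(s, c(1, 1, 1, n)), fs = 10))
  expect_equal(cv2$values[1, 1, 1], 0.0707, tolerance = 1e-3)

  # near-zero mean voxels become NaN and are counted, not thrown
  z <- voxel_volume(array(rbind(rep(0, 8), 100 + rnorm(8)), c(2, 1, 1, 8)),
                    fs = 10)
  cvz <- cv_map(z)
  expect_true(is.nan(cvz$values[1, 1, 1]))
  expect_equal(cvz$meta$n_undefined, 1)
})

test_that("SP maps sum band bins under the shared convention", {
  n <- 512; fs <- 10; tt <- (0:(n - 1)) / fs
  f0 <- 51 * fs / n                       # exact bin, 0.996 Hz
  vol <- voxel_volume(array(sin(2 * pi * f0 * tt), c(1, 1, 1, n)), fs)
  sv <- spectrum_volume(vol)
  sp <- sp_map(sv, frequency_band(0.95, 1.05, "cardiac"))
  expect_equal(sp$values[1, 1, 1], n / 4, tolerance = 1e-8)
  expect_equal(sp_map(spectrum_volume(
    voxel_volume(array(0 * tt, c(1, 1, 1, n)), fs)),
    frequency_band(0.95, 1.05, "c"))$values[1, 1, 1], 0)
  expect_error(sp_map(sv, frequency_band(1.001e-4, 2e-4, "empty")),
               "no spectrum bins")
})

test_that("spectral entropy hits its closed-form anchors", {
  mkspec <- function(pw) structure(
    list(freqs = seq(0.0195, 5, length.out = length(pw)),
         power = array(pw, c(1, 1, 1, length(pw))), fs = 10,
         n_time = 2 * length(pw), voxel_size_mm = 3, mask = NULL),
    class = "spectrum_volume")
  one <- c(1, rep(0, 255))
  expect_equal(se_map(mkspec(one))$values[1, 1, 1], 0)
  expect_equal(se_map(mkspec(rep(1, 256)))$values[1, 1, 1], 1)
  two <- c(rep(0, 254), 1, 1)
  expect_equal(se_map(mkspec(two))$values[1, 1, 1], log(2) / log(256),
               tolerance = 1e-12)
  # raw-entropy mode
  expect_equal(se_map(mkspec(two), normalize = FALSE)$values[1, 1, 1],
               log(2), tolerance = 1e-12)
  # all-zero power -> NaN + QC count
  sez <- se_map(mkspec(rep(0, 256)))
  expect_true(is.nan(sez$values[1, 1, 1]))
  expect_equal(sez$meta$n_undefined, 1)
})

test_that("background SP removes listed peaks and their surroundings", {
  freqs <- seq(0.1, 5, by = 0.1)
  flat <- rep(2, length(freqs))
  pk <- flat; pk[20] <- 1000                  # peak at 2.0 Hz
  ps <- power_spectrum(freqs, pk)
  expect_equal(background_sp(ps), sum(pk))    # no peaks listed -> full SP
  bg <- background_sp(ps, principal_peaks = 2.0, exclusion_halfwidth = 0.05)
  expect_equal(bg, 2 * (length(freqs) - 1))
  expect_error(background_sp(ps, principal_peaks = 2.5,
                             exclusion_halfwidth = 10), "every spectrum bin")
})

test_that("voxel counts convert to reported cm^3 volumes", {
  expect_equal(voxels_to_volume_cm3(16099), 435)
  expect_equal(voxels_to_volume_cm3(579), 16)
  expect_equal(voxels_to_volume_cm3(0), 0)
  expect_equal(voxels_to_volume_cm3(28), 0.8)
  expect_equal(voxels_to_volume_cm3(16099, rounded = FALSE), 434.673)
  expect_error(voxels_to_volume_cm3(-1), "nonnegative")
})

test_that("CV and SP increase with in-band amplitude; SE falls as one band dominates", {
  n <- 1000; fs <- 10; tt <- (0:(n - 1)) / fs
  band <- frequency_band(0.95, 1.05, "cardiac")
  amps <- c(0.05, 0.1, 0.2)
  cvs <- sps <- ses <- numeric(3)
  set.seed(17)
  noise <- rnorm(n, 0, 0.5)
  for (i in seq_along(amps)) {
    s <- 100 * (1 + amps[i] * sin(2 * pi * 1 * tt)) + noise
    vol <- voxel_volume(array(s, c(1, 1, 1, n)), fs)
    pre <- trim_and_highpass(vol, n_trim = 0)
    sv <- spectrum_volume(pre)
    cvs[i] <- cv_map(bandpass_with_mean(pre, band))$values[1]
    sps[i] <- sp_map(sv, band)$values[1]
    ses[i] <- se_map(sv)$values[1]
  }
  expect_true(all(diff(cvs) > 0))
  expect_true(all(diff(sps) > 0))
  expect_true(all(diff(ses) < 0))
})

test_that("CV and SP measure the same variance (Parseval link)", {
  n <- 1200; fs <- 10; tt <- (0:(n - 1)) / fs
  f0 <- 120 * fs / n                       # exact bin at 1.0 Hz
  s <- 50 + 5 * sin(2 * pi * f0 * tt + 0.7)
  vol <- voxel_volume(array(s, c(1, 1, 1, n)), fs)
  pre <- trim_and_highpass(vol, n_trim = 0)
  cv <- cv_map(bandpass_with_mean(pre, frequency_band(0.95, 1.05, "c")))
  sp <- sp_map(spectrum_volume(pre), frequency_band(0.95, 1.05, "c"))
  lhs <- cv$values[1]^2 * 50^2 * (n - 1)
  expect_equal(lhs, 2 * sp$values[1], tolerance = 1e-6)
})
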