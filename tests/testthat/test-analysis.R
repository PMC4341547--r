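test_that("Welch estimate recovers sine power and white-noise flatness", {
  fs <- 250
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * tt)
  ps <- welch_psd(x, fs)
  expect_equal(ps$freq[which.max(ps$power)], 10, tolerance = 1e-9)
  expect_equal(sum(ps$power) * ps$df, 0.5, tolerance = 0.02)

  set.seed(41)
  v <- 2.3
  w <- rnorm(fs * 60, sd = sqrt(v))
  pw <- welch_psd(w, fs)
  # flat density ~ v / Nyquist, checked in two bands
  expect_equal(mean(pw$power[pw$freq > 10 & pw$freq < 50]), v / (fs / 2),
               tolerance = 0.1)
  expect_equal(mean(pw$power[pw$freq > 70 & pw$freq < 120]), v / (fs / 2),
               tolerance = 0.1)
  # Parseval: integrated PSD matches the series variance within 2%
  expect_equal(sum(pw$power) * pw$df, var(w), tolerance = 0.02)

  # constant series: mean removal leaves zero power
  pc <- welch_psd(rep(4.2, 1000), fs)
  expect_lt(sum(pc$power), 1e-20)
  expect_error(welch_psd(rnorm(100), fs), "shorter")
})

test_that("Welch agrees with the base-R periodogram on a shared window", {
  # cross-check against stats::spec.pgram with an identical taperless,
  # single-segment configuration
  fs <- 100
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = 0.7), 400))
  ours <- .welch_matrix(matrix(x, 1), fs, window_s = 4, overlap = 0)
  ref <- spec.pgram(ts(x, frequency = fs), taper = 0, detrend = TRUE,
                    fast = FALSE, plot = FALSE)
  # compare band-averaged densities (windowing differs only by the Hann
  # taper's leakage): spec.pgram returns density/frequency in spectrum
  # convention (two-sided x 1), rescale to one-sided per Hz
  ours_band <- mean(ours$power[ours$freq > 5 & ours$freq < 20])
  ref_band <- mean(2 * ref$spec[ref$freq > 5 & ref$freq < 20])
  expect_equal(ours_band, ref_band, tolerance = 0.25)
})

test_that("grid averaging is linear and unit-area normalization holds", {
  fs <- 250
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 9 * tt) + 0.3 * sin(2 * pi * 21 * tt)
  X <- rbind(x, x, x)
  rec <- structure(list(
    fields = list(h_e = X), times = list(h_e = tt), fs = fs,
    protocol = constant_protocol(0, 10)), class = "recording")
  ga <- grid_average_psd(rec, "P")
  expect_equal(sum(ga$power_norm) * ga$df, 1, tolerance = 1e-6)
  single <- welch_psd(x, fs)
  expect_equal(ga$power, single$power, tolerance = 1e-12)
  # power ratio of an amplitude-doubled copy is 4
  rec2 <- rec
  rec2$fields$h_e <- cbind(X, 2 * X)
  rec2$times$h_e <- c(tt, 10 + tt)
  rec2$protocol <- protocol(c(0, 10), c(10, 20), c(0, 0), c(0, 0),
                            plateaus = list(A = c(0, 10), B = c(10, 20)))
  expect_equal(total_power_ratio(rec2, "A", "B"), 4, tolerance = 1e-9)
  expect_equal(total_power_ratio(rec2, "A", "A"), 1)
})

test_that("burst-peak detection segments, selects minima and censors", {
  fs <- 250
  tt <- seq(0, 8, by = 1 / fs)
  x <- rep(0.2, length(tt))
  dip <- function(x, t0, depth) {
    sel <- abs(tt - t0) < 0.15
    x[sel] <- pmin(x[sel], depth + 2 * abs(tt[sel] - t0))
    x
  }
  x <- dip(x, 1.0, 0.01); x <- dip(x, 3.2, 0.02); x <- dip(x, 5.4, 0.015)
  pk <- detect_burst_peaks(x, tt, threshold = 0.05, min_ibi_s = 1.0)
  expect_equal(pk, c(1.0, 3.2, 5.4), tolerance = 1e-9)
  expect_equal(diff(pk), c(2.2, 2.2), tolerance = 1e-9)

  # double-dipping half a second apart merges to the deeper peak
  y <- rep(0.2, length(tt))
  y <- dip(y, 2.0, 0.005); y <- dip(y, 2.5, 0.03)
  pk2 <- detect_burst_peaks(y, tt, 0.05, 1.0)
  expect_equal(pk2, 2.0)

  expect_equal(detect_burst_peaks(rep(0.2, 100), seq_len(100) / fs),
               numeric(0))

  # idempotence: re-detecting on a reconstruction of retained peaks
  z <- rep(0.2, length(tt))
  for (t0 in pk) z <- dip(z, t0, 0.01)
  expect_equal(detect_burst_peaks(z, tt, 0.05, 1.0), pk, tolerance = 1e-9)
})

test_that("threshold regions are nested as the threshold rises", {
  # the below-threshold set grows monotonically with the threshold, so
  # every region found at a lower threshold lies inside a region found at
  # a higher one (regions can merge, so the count itself is not monotone)
  set.seed(43)
  tt <- seq(0, 30, by = 0.004)
  x <- 0.1 + 0.08 * sin(2 * pi * 0.4 * tt) + 0.02 * rnorm(length(tt))
  below <- function(th) x <= th
  ths <- c(0.02, 0.05, 0.08, 0.12)
  for (j in seq_len(length(ths) - 1))
    expect_true(all(below(ths[j + 1])[below(ths[j])]))
  # and detected peaks at the lower threshold all lie inside regions of
  # the higher threshold
  pk_lo <- detect_burst_peaks(x, tt, threshold = 0.05, min_ibi_s = 0)
  hi <- below(0.08)
  expect_true(all(hi[match(pk_lo, tt)]))
})

test_that("grid IBI statistics pool per-point intervals", {
  fs <- 250
  tt <- seq(0, 20 - 1 / fs, by = 1 / fs)
  # periodic dips with period 2.5 s, identical at every point
  x <- 0.8 + 0.75 * cos(2 * pi * tt / 2.5)
  X <- rbind(x, x, x, x)
  p <- bf_params
  rec <- structure(list(
    fields = list(C_e = X), times = list(C_e = tt), fs = fs,
    params = p, protocol = constant_protocol(0, 20)), class = "recording")
  st <- ibi_statistics(rec, threshold = 0.05, mode = "absolute")
  expect_equal(st$mean, 2.5, tolerance = 1e-3)
  expect_equal(st$sd, 0, tolerance = 1e-6)
  expect_equal(st$points_bursting, 1)
  # normalized mode applies the threshold on C_e H_e directly
  st2 <- ibi_statistics(rec, threshold = 0.05 / unname(p$Gamma0["ee"]),
                        mode = "normalized")
  expect_equal(st2$mean, st$mean)
})

test_that("correlation length tracks pattern scale", {
  g <- grid_spec(48)
  xs <- (0:47)
  set.seed(44)
  broad <- as.numeric(outer(sin(2 * pi * xs / 48), cos(2 * pi * xs / 48)))
  narrow <- as.numeric(outer(sin(2 * pi * xs * 6 / 48),
                             cos(2 * pi * xs * 6 / 48)))
  expect_gt(correlation_length(broad, g), correlation_length(narrow, g))
})

test_that("patch masks cover the right area with a closed boundary", {
  g <- grid_spec(128)
  m <- patch_mask(g, center_cm = c(6.4, 6.4), radius_cm = 4,
                  inside = 1.25, outside = 0.175)
  expect_equal(m[.point_index_test(g, 64, 64)], 1.25)
  expect_equal(m[.point_index_test(g, 64 + 40, 64)], 1.25)  # boundary inside
  expect_equal(m[.point_index_test(g, 64 + 41, 64)], 0.175)
  expect_equal(m[.point_index_test(g, 127, 127)], 0.175)
  expect_equal(mean(m == 1.25), pi * 40^2 / (128 * 128), tolerance = 0.01)
  expect_error(patch_mask(grid_spec(16), c(0.8, 0.8), radius_cm = 2),
               "fit")
})
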