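test_that("paradigm validates windows and sample counts", {
  p <- paradigm()
  expect_equal(p$n_samples, 12000)
  expect_equal(p$n_trials, 44L)
  expect_error(paradigm(20, 600, 44, list(c(1, 0, 2), c(2, 1, 3))),
               "must not overlap")
  expect_error(paradigm(20, 600, 44, list(c(1, -1, 2))), "active windows")
  expect_error(paradigm(1.5, 601, 1), "integer sample count")
})

test_that("boxcar timecourses are zero outside the window with per-trial amplitudes", {
  p <- paradigm()
  set.seed(1)
  q <- boxcar_timecourse(p, 1, 31, 3)
  expect_length(q, 12000)
  expect_identical(which(q != 0), 1:1200)          # 0 < t < 2 s at 600 Hz
  expect_equal(sum(q[1201:12000] == 0), 10800)
  q2 <- boxcar_timecourse(p, 2, 31, 3)
  expect_identical(which(q2 != 0), 6001:7200)      # 10 < t < 12 s
  # amplitude_sd = 0: active-segment SD matches the mean amplitude
  sds <- replicate(20, sd(boxcar_timecourse(p, 1, 31, 0)[1:1200]))
  expect_true(all(abs(sds - 31) < 4 * 31 / sqrt(2 * 1200)))
  # across 44 trials the mean per-trial amplitude concentrates near 31
  set.seed(2)
  means <- replicate(30, mean(replicate(44, sd(boxcar_timecourse(p, 1, 31, 3)[1:1200]))))
  expect_true(mean(means >= 29 & means <= 33) >= 0.95)
  expect_error(boxcar_timecourse(p, 1, 31, -1), "amplitude_sd")
  expect_error(boxcar_timecourse(p, 3, 31, 3), "no active window")
})

test_that("simulated datasets obey additivity, rank structure and SNR scaling", {
  geo <- small_geometry(12)
  p <- paradigm(2, 300, 2, active_windows = list(c(1, 0, 0.5)))
  src <- surface_dipole(geo$source_surface, c(0, 0.01, 0.08), 0.3)
  d0 <- simulate_dataset(list(src), p, geo$head, geo$sensors,
                         noise_model("gaussian", 1e-9), seed = 9)
  d1 <- simulate_dataset(list(src), p, geo$head, geo$sensors,
                         noise_model("gaussian", 10), seed = 9)
  d2 <- simulate_dataset(list(src), p, geo$head, geo$sensors,
                         noise_model("gaussian", 20), seed = 9)
  # shared seed: the noise term is sample-exact additive and linear
  expect_equal(d2$data - d0$data, 2 * (d1$data - d0$data),
               tolerance = 1e-12)
  # single source, (near) zero noise: rank 1 across channels when active
  X <- d0$data[1, , 1:150]
  svs <- svd(X)$d
  expect_lt(svs[2] / svs[1], 1e-4)
  # zero-amplitude source: pure noise with the injected SD
  z <- surface_dipole(geo$source_surface, c(0, 0.01, 0.08), 0.3,
                      amplitude_mean = 0, amplitude_sd = 0)
  dn <- simulate_dataset(list(z), paradigm(2, 300, 10,
                                           active_windows = list(c(1, 0, 0.5))),
                         geo$head, geo$sensors, noise_model("gaussian", 36),
                         seed = 4)
  expect_equal(sd(dn$data), 36e-15, tolerance = 0.02)
  # 8 fT vs 36 fT noise: amplitude ratio 4.5 by construction
  dn8 <- simulate_dataset(list(z), paradigm(2, 300, 10,
                                            active_windows = list(c(1, 0, 0.5))),
                          geo$head, geo$sensors, noise_model("gaussian", 8),
                          seed = 4)
  expect_equal(sd(dn$data) / sd(dn8$data), 4.5, tolerance = 0.02)
  # bit reproducibility
  expect_identical(d1$data,
                   simulate_dataset(list(src), p, geo$head, geo$sensors,
                                    noise_model("gaussian", 10), seed = 9)$data)
})

test_that("phase-randomised surrogates preserve spectra and covariance but scramble time", {
  rec <- ar_noise_record(10, 6000, seed = 2)
  sur <- phase_randomized_surrogate(rec, 6000, seed = 1)
  a_in <- abs(mvfft(t(rec))); a_out <- abs(mvfft(t(sur)))
  expect_lt(max(abs(a_in - a_out) / pmax(a_in, max(a_in) * 1e-12)), 1e-10)
  # per-channel variance preserved (Parseval)
  expect_equal(rowMeans(sur^2), rowMeans(rec^2), tolerance = 1e-10)
  # shared-phase scheme preserves the zero-lag covariance
  C_in <- tcrossprod(rec) / 6000
  C_mc <- Reduce(`+`, lapply(1:10, function(i)
    tcrossprod(phase_randomized_surrogate(rec, 6000, seed = i)) / 6000)) / 10
  expect_lt(norm(C_in - C_mc, "F") / norm(C_in, "F"), 0.03)
  # waveform differs from the input
  expect_gt(max(abs(sur - rec)), sd(rec))
  # two surrogates with different seeds are essentially uncorrelated
  long <- ar_noise_record(2, 1e5, seed = 3)
  s1 <- phase_randomized_surrogate(long, 1e5, seed = 11)
  s2 <- phase_randomized_surrogate(long, 1e5, seed = 22)
  expect_lt(abs(cor(s1[1, ], s2[1, ])), 0.05)
  expect_error(phase_randomized_surrogate(rbind(rep(1, 100), rnorm(100))),
               "zero-variance")
  expect_error(phase_randomized_surrogate(rec, 7000), "shorter")
})

test_that("surrogate noise drives simulate_dataset with matched channel count", {
  geo <- small_geometry(10)
  rec <- ar_noise_record(10, 1200, seed = 5)
  p <- paradigm(2, 300, 3, active_windows = list(c(1, 0, 0.5)))
  src <- surface_dipole(geo$source_surface, c(0, 0.01, 0.08), 0.3)
  ds <- simulate_dataset(list(src), p, geo$head, geo$sensors,
                         noise_model("surrogate", surrogate_record = rec),
                         seed = 2)
  expect_true(all(is.finite(ds$data)))
  bad <- ar_noise_record(7, 1200, seed = 5)
  expect_error(simulate_dataset(list(src), p, geo$head, geo$sensors,
                                noise_model("surrogate", surrogate_record = bad),
                                seed = 2), "channel count")
})

test_that("band-pass keeps passband tones and rejects stopband tones", {
  geo <- small_geometry(5)
  p <- paradigm(4, 600, 1, active_windows = list(c(1, 0, 2)))
  tt <- (0:(2400 - 1)) / 600
  mk <- function(f) {
    d <- array(rep(sin(2 * pi * f * tt), each = 5), c(1, 5, 2400))
    structure(list(data = d, paradigm = p, sensors = geo$sensors, seed = 1L),
              class = "sensor_dataset")
  }
  in_band <- bandpass(mk(20), 13, 30)
  expect_equal(max(abs(in_band$data[1, 1, 600:1800])), 1, tolerance = 0.05)
  stop_band <- bandpass(mk(50), 13, 30)
  expect_lt(max(abs(stop_band$data[1, 1, 600:1800])), 10^(-20 / 20))
  zero <- mk(20); zero$data[] <- 0
  expect_equal(max(abs(bandpass(zero, 13, 30)$data)), 0)
  expect_error(bandpass(mk(20), 200, 400), "Nyquist")
})

test_that("the exact-distribution covariance sampler matches brute force in expectation", {
  geo <- small_geometry(16)
  set.seed(3)
  fx <- fixture_pair(geo, d = 0.02, seed = 3)
  par <- paradigm(2, 60, 6, active_windows = list(c(1, 0, 0.2), c(2, 1, 1.2)))
  B <- cbind(forward_field(fx$s1, geo$head, geo$sensors),
             forward_field(fx$s2, geo$head, geo$sensors))
  nsd <- 50e-15
  nmc <- 120
  acc_f <- acc_b <- 0
  for (i in seq_len(nmc)) {
    f <- sample_window_covariances(B, par, 31, 3, nsd, seed = i)
    acc_f <- acc_f + f$C1$matrix / nmc
    ds <- simulate_dataset(list(fx$s1, fx$s2), par, geo$head, geo$sensors,
                           noise_model("gaussian", 50), seed = i)
    acc_b <- acc_b + estimate_covariance(ds, cov_window(c(0, 1)))$matrix / nmc
  }
  th <- 0.2 * (31^2 + 3^2) * 1e-18 * tcrossprod(B[, 1]) + diag(nsd^2, 16)
  expect_lt(norm(acc_f - th, "F") / norm(th, "F"), 0.05)
  expect_lt(norm(acc_b - th, "F") / norm(th, "F"), 0.05)
  expect_lt(norm(acc_f - acc_b, "F") / norm(th, "F"), 0.06)
  # pooled consistency: N1*C1 + N2*C2 = N*C
  f <- sample_window_covariances(B, par, 31, 3, nsd, seed = 1)
  expect_equal(f$N1 * f$C1$matrix + f$N2 * f$C2$matrix, f$N * f$C$matrix,
               tolerance = 1e-12)
  # determinism
  g <- sample_window_covariances(B, par, 31, 3, nsd, seed = 1)
  expect_identical(f$C$matrix, g$C$matrix)
})
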