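# Simulation of epoched sensor data: boxcar-gated stochastic dipole
# timecourses, Gaussian or phase-randomised surrogate sensor noise, and an
# exact-distribution sampler for window covariances used by the resolution
# study.

#' Trial paradigm
#'
#' Describes the trial structure: length, sampling rate, trial count and the
#' active window of each source. The default mirrors a sequential two-digit
#' design: source 1 active 0-2 s, source 2 active 10-12 s, 20 s trials at
#' 600 Hz, 44 trials.
#'
#' @param trial_length seconds.
#' @param sampling_rate Hz.
#' @param n_trials number of trials.
#' @param active_windows list of `c(source_index, start_s, end_s)` triples;
#'   windows must lie in `[0, trial_length)` and windows of distinct sources
#'   must not overlap.
#' @return object of class `paradigm`.
#' @export
paradigm <- function(trial_length = 20, sampling_rate = 600, n_trials = 44,
                     active_windows = list(c(1, 0, 2), c(2, 10, 12))) {
  if (trial_length <= 0 || sampling_rate <= 0 || n_trials < 1)
    stop("trial_length, sampling_rate and n_trials must be positive")
  ns <- trial_length * sampling_rate
  if (abs(ns - round(ns)) > 1e-9)
    stop("trial_length x sampling_rate must be an integer sample count")
  aw <- lapply(active_windows, as.numeric)
  for (w in aw) {
    if (length(w) != 3L) stop("each active window is c(source, start, end)")
    if (w[2] < 0 || w[3] > trial_length || w[2] >= w[3])
      stop("active windows must satisfy 0 <= start < end <= trial_length")
  }
  if (length(aw) > 1) {
    for (i in seq_along(aw)) for (j in seq_along(aw)) {
      if (i < j && aw[[i]][1] != aw[[j]][1] &&
          aw[[i]][2] < aw[[j]][3] && aw[[j]][2] < aw[[i]][3])
        stop("active windows of distinct sources must not overlap")
    }
  }
  structure(list(trial_length = trial_length, sampling_rate = sampling_rate,
                 n_trials = as.integer(n_trials), active_windows = aw,
                 n_samples = as.integer(round(ns))),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat("<paradigm>", x$n_trials, "trials of", x$trial_length, "s at",
      x$sampling_rate, "Hz\n")
  invisible(x)
}

active_window_for <- function(paradigm, source_index) {
  for (w in paradigm$active_windows) if (w[1] == source_index) return(w[2:3])
  NULL
}

#' Sensor noise model
#'
#' Either uncorrelated Gaussian noise of a given per-sample amplitude, or
#' phase-randomised surrogates of a supplied multichannel record (preserving
#' its spectra and spatial covariance).
#'
#' @param kind `"gaussian"` or `"surrogate"`.
#' @param gaussian_amplitude per-sample, per-channel noise standard
#'   deviation in femtotesla (gaussian kind).
#' @param surrogate_record channels x samples matrix in tesla (surrogate
#'   kind).
#' @return object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian", "surrogate"),
                        gaussian_amplitude = 21, surrogate_record = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian") {
    if (!is.numeric(gaussian_amplitude) || gaussian_amplitude <= 0)
      stop("gaussian_amplitude must be positive (fT)")
  } else {
    if (is.null(surrogate_record)) stop("surrogate kind needs surrogate_record")
    surrogate_record <- as.matrix(surrogate_record)
    if (nrow(surrogate_record) < 2L)
      stop("surrogate_record needs at least 2 channels")
  }
  structure(list(kind = kind, gaussian_amplitude = gaussian_amplitude,
                 surrogate_record = surrogate_record),
            class = "noise_model")
}

#' Boxcar-gated stochastic dipole timecourse for one trial
#'
#' Inside the source's active window the timecourse is white Gaussian noise
#' whose standard deviation is drawn once per trial from
#' `Normal(amplitude_mean, amplitude_sd)` truncated at zero; outside the
#' window it is exactly zero. Draws use the current RNG state.
#'
#' @param paradigm a [paradigm()].
#' @param source_index which source's active window to use.
#' @param amplitude_mean,amplitude_sd nAm; see [dipole_source()].
#' @return numeric vector of length `paradigm$n_samples`, in nAm.
#' @export
boxcar_timecourse <- function(paradigm, source_index, amplitude_mean = 31,
                              amplitude_sd = 3) {
  if (amplitude_sd < 0) stop("amplitude_sd must be non-negative")
  w <- active_window_for(paradigm, source_index)
  if (is.null(w)) stop("source ", source_index, " has no active window")
  fs <- paradigm$sampling_rate
  idx <- (floor(w[1] * fs) + 1L):(floor(w[2] * fs))
  amp <- -1
  while (amp < 0) amp <- rnorm(1, amplitude_mean, amplitude_sd)
  q <- numeric(paradigm$n_samples)
  q[idx] <- rnorm(length(idx), 0, amp)
  q
}

#' Simulate an epoched sensor dataset
#'
#' Each trial is the sum over sources of (lead field) x (boxcar timecourse)
#' plus an independent noise realisation. Source randomness and noise
#' randomness are drawn from two seed-derived streams so that datasets that
#' share a seed but differ in noise amplitude share both their source
#' signals and their underlying standard-normal noise draws.
#'
#' @param sources list of [dipole_source()] objects.
#' @param paradigm a [paradigm()]; sources are matched to active windows by
#'   list position.
#' @param head a [head_model()].
#' @param sensors a [sensor_array()].
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @return object of class `sensor_dataset` with fields `data` (array,
#'   trials x channels x samples, tesla), `paradigm`, `sensors`, `seed`.
#' @export
simulate_dataset <- function(sources, paradigm, head, sensors, noise,
                             seed = 1L) {
  nc <- nrow(sensors$positions)
  if (noise$kind == "surrogate" && nrow(noise$surrogate_record) != nc)
    stop("surrogate record channel count does not match the sensor array")
  B <- vapply(sources, function(s) forward_field(s, head, sensors),
              numeric(nc))                      # nc x nsrc, T/(A m)
  nt <- paradigm$n_trials; ns <- paradigm$n_samples
  dat <- array(0, dim = c(nt, nc, ns))
  # stream 1: source timecourses for all trials
  set.seed(derive_seed(seed, 1L))
  Q <- vector("list", nt)
  for (tr in seq_len(nt)) {
    Q[[tr]] <- vapply(seq_along(sources), function(i)
      boxcar_timecourse(paradigm, i, sources[[i]]$amplitude_mean,
                        sources[[i]]$amplitude_sd), numeric(ns)) # ns x nsrc, nAm
  }
  # stream 2: noise
  set.seed(derive_seed(seed, 2L))
  for (tr in seq_len(nt)) {
    sig <- B %*% t(Q[[tr]] * NAM)               # nc x ns
    if (noise$kind == "gaussian") {
      sig <- sig + (noise$gaussian_amplitude * FT) * matrix(rnorm(nc * ns), nc, ns)
    } else {
      sig <- sig + phase_randomized_surrogate(noise$surrogate_record, ns)
    }
    dat[tr, , ] <- sig
  }
  structure(list(data = dat, paradigm = paradigm, sensors = sensors,
                 seed = as.integer(seed)),
            class = "sensor_dataset")
}

#' @export
print.sensor_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat("<sensor_dataset>", d[1], "trials x", d[2], "channels x", d[3],
      "samples at", x$paradigm$sampling_rate, "Hz\n")
  invisible(x)
}

# deterministic seed derivation, kept below 2^31
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  s <- 0
  for (k in ks) s <- (s * 69069 + (as.numeric(k) %% 2147483647)) %% 2147483647
  as.integer(s)
}

#' Multivariate phase-randomised surrogate
#'
#' Adds one common random phase per frequency bin to every channel's Fourier
#' transform (Hermitian symmetry enforced), which preserves each channel's
#' amplitude spectrum exactly and, because the phase offset is shared,
#' preserves all cross-spectra and hence the zero-lag covariance, while
#' scrambling the waveform. Used to generate arbitrarily many noise
#' realisations from one measured interference record.
#'
#' @param record channels x samples matrix; must have at least 2 channels
#'   and non-zero variance in every channel.
#' @param n_samples_out number of output samples (<= record length).
#' @param seed optional integer seed for the phase draws (`NULL` uses the
#'   current RNG state).
#' @return channels x `n_samples_out` matrix.
#' @export
phase_randomized_surrogate <- function(record, n_samples_out = ncol(record),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(derive_seed(seed, 5L))
  record <- as.matrix(record)
  nch <- nrow(record); n <- ncol(record)
  if (nch < 2L) stop("record needs at least 2 channels")
  if (n_samples_out > n) stop("record is shorter than n_samples_out")
  v <- apply(record, 1, stats::var)
  if (any(v == 0)) stop("record contains a constant (zero-variance) channel")
  X <- mvfft(t(record))                          # n x nch spectra
  nfree <- if (n %% 2L == 0L) n / 2L - 1L else (n - 1L) / 2L
  rot <- rep(1 + 0i, n)
  if (nfree > 0L) {
    ph <- exp(1i * runif(nfree, 0, 2 * pi))
    rot[2:(nfree + 1L)] <- ph
    rot[n:(n - nfree + 1L)] <- Conj(ph)          # Hermitian symmetry
  }
  # DC (and Nyquist for even n) stay real and untouched
  Y <- X * rot
  out <- t(Re(mvfft(Y, inverse = TRUE) / n))
  out[, seq_len(n_samples_out), drop = FALSE]
}

#' Spatially mixed AR(1) noise record
#'
#' Generates a correlated multichannel noise fixture: independent AR(1)
#' processes mixed through a random spatial matrix. Stands in for a measured
#' interference record when exercising the surrogate pipeline.
#'
#' @param n_channels,n_samples dimensions.
#' @param ar AR(1) coefficient.
#' @param amplitude overall scale (tesla).
#' @param seed integer seed.
#' @return channels x samples matrix.
#' @export
ar_noise_record <- function(n_channels = 10, n_samples = 6000, ar = 0.9,
                            amplitude = 50e-15, seed = 1L) {
  set.seed(derive_seed(seed, 7L))
  innov <- matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
  x <- t(apply(innov, 1, function(e)
    as.numeric(stats::filter(e, ar, method = "recursive"))))
  M <- matrix(rnorm(n_channels^2, sd = 1 / sqrt(n_channels)), n_channels)
  diag(M) <- diag(M) + 1
  y <- M %*% x
  y * amplitude / sd(as.numeric(y))
}

#' Exact-distribution window covariance sampler
#'
#' Draws the three segment sample-covariance matrices (first half-trial,
#' second half-trial, and their pooled union) of an Eq-6 style two-source
#' dataset with i.i.d. Gaussian sensor noise, *without* forming the sensor
#' time series. Writing a window's data as `M = B Q + E` (lead fields `B`,
#' simulated source timecourses `Q`, white noise `E`), the uncentered sample
#' scatter `M M'` equals in distribution
#' `(B R' + Z)(B R' + Z)' + W` where `R'R = Q Q'`, `Z` is channels x
#' n-sources i.i.d. `N(0, sigma^2)` and `W ~ Wishart(N - n_sources,
#' sigma^2 I)`; this is the orthogonal decomposition of `E` along the row
#' space of `Q` and is exact by the rotational invariance of the Gaussian.
#' Source timecourses (per-trial amplitude draws included) are simulated in
#' full.
#'
#' @param B channels x n_sources lead-field matrix (T per A m).
#' @param paradigm a [paradigm()] whose active windows fall in the half
#'   trials `[0, T/2)` and `[T/2, T)`.
#' @param amplitude_mean,amplitude_sd per-trial source strength model, nAm
#'   (recycled over sources).
#' @param noise_sd per-sample noise SD in tesla.
#' @param seed integer seed.
#' @return list with covariance matrices `C1`, `C2`, `C`
#'   ([covariance_matrix()] objects) and their raw sample counts `N1`,
#'   `N2`, `N`.
#' @export
sample_window_covariances <- function(B, paradigm, amplitude_mean = 31,
                                      amplitude_sd = 3, noise_sd = 21e-15,
                                      seed = 1L) {
  B <- as.matrix(B)
  nsrc <- ncol(B); nc <- nrow(B)
  fs <- paradigm$sampling_rate
  half <- paradigm$n_samples %/% 2L
  Nh <- half * paradigm$n_trials
  amplitude_mean <- rep_len(amplitude_mean, nsrc)
  amplitude_sd <- rep_len(amplitude_sd, nsrc)
  set.seed(derive_seed(seed, 3L))
  # accumulate per-window source Gram matrices Q Q' (in (A m)^2)
  G <- list(matrix(0, nsrc, nsrc), matrix(0, nsrc, nsrc))
  for (tr in seq_len(paradigm$n_trials)) {
    for (i in seq_len(nsrc)) {
      w <- active_window_for(paradigm, i)
      if (is.null(w)) next
      idx0 <- floor(w[1] * fs); idx1 <- floor(w[2] * fs)
      nact <- idx1 - idx0
      amp <- -1
      while (amp < 0) amp <- rnorm(1, amplitude_mean[i], amplitude_sd[i])
      q <- rnorm(nact, 0, amp) * NAM
      wh <- if (idx0 < half) 1L else 2L         # windows must not straddle
      G[[wh]][i, i] <- G[[wh]][i, i] + sum(q^2)
    }
  }
  s2 <- noise_sd^2
  S <- vector("list", 2L)
  for (wh in 1:2) {
    eg <- eigen(G[[wh]], symmetric = TRUE)
    Rt <- t(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))) # R' sym sqrt
    Z <- matrix(rnorm(nc * nsrc, 0, noise_sd), nc, nsrc)
    A <- B %*% Rt + Z
    W <- rWishart(1, Nh - nsrc, diag(s2, nc))[, , 1]
    S[[wh]] <- tcrossprod(A) + W
  }
  w1 <- cov_window(c(0, paradigm$trial_length / 2))
  w2 <- cov_window(c(paradigm$trial_length / 2, paradigm$trial_length))
  wf <- cov_window(c(0, paradigm$trial_length))
  list(C1 = covariance_matrix(S[[1]] / Nh, Nh, w1),
       C2 = covariance_matrix(S[[2]] / Nh, Nh, w2),
       C  = covariance_matrix((S[[1]] + S[[2]]) / (2 * Nh), 2 * Nh, wf),
       N1 = Nh, N2 = Nh, N = 2 * Nh)
}
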