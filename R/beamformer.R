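# LCMV beamformer: covariance estimation, weights, pseudo-z / pseudo-t
# statistics and the three covariance-segmentation imaging strategies.

#' Covariance window
#'
#' @param time_interval `c(start_s, end_s)` within the trial.
#' @param band optional `c(low_Hz, high_Hz)` band-pass applied before
#'   covariance estimation; `NULL` means broadband.
#' @return object of class `cov_window`.
#' @export
cov_window <- function(time_interval, band = NULL) {
  time_interval <- as.numeric(time_interval)
  if (length(time_interval) != 2L || time_interval[1] >= time_interval[2])
    stop("time_interval must be c(start, end) with start < end")
  if (!is.null(band)) {
    band <- as.numeric(band)
    if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
      stop("band must be c(low, high) with 0 < low < high")
  }
  structure(list(time_interval = time_interval, band = band),
            class = "cov_window")
}

#' Covariance matrix container
#'
#' @param matrix channels x channels matrix, tesla^2.
#' @param n_samples effective sample count used to estimate it.
#' @param window the [cov_window()] it came from (provenance).
#' @return object of class `covariance_matrix`.
#' @export
covariance_matrix <- function(matrix, n_samples, window = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != ncol(matrix)) stop("covariance must be square")
  if (max(abs(matrix - t(matrix))) > 1e-12 * max(abs(matrix)))
    stop("covariance must be symmetric")
  structure(list(matrix = (matrix + t(matrix)) / 2,
                 n_samples = n_samples, window = window),
            class = "covariance_matrix")
}

#' @export
print.covariance_matrix <- function(x, ...) {
  cat("<covariance_matrix>", nrow(x$matrix), "x", ncol(x$matrix),
      "| n_samples =", format(x$n_samples), "\n")
  invisible(x)
}

#' Effective sample count of band-limited data
#'
#' Degrees of freedom available to estimate covariance from data of
#' bandwidth `bandwidth_hz` and total duration `duration_s`: `2 * BW * D`.
#'
#' @param bandwidth_hz signal bandwidth in Hz.
#' @param duration_s total data duration in seconds (all trials pooled).
#' @return effective sample count.
#' @export
effective_samples <- function(bandwidth_hz, duration_s) {
  2 * bandwidth_hz * duration_s
}

#' Estimate a window covariance from an epoched dataset
#'
#' Optionally band-passes the data, then pools the window's samples across
#' all trials into an uncentered sample covariance (all simulated processes
#' are zero mean; set `center = TRUE` to subtract the pooled channel means).
#' `n_samples` records `2 * BW * duration` when a band is given, else the
#' raw pooled sample count.
#'
#' @param dataset a `sensor_dataset`.
#' @param window a [cov_window()].
#' @param center subtract pooled channel means first?
#' @return a [covariance_matrix()].
#' @export
estimate_covariance <- function(dataset, window, center = FALSE) {
  iv <- window$time_interval
  fs <- dataset$paradigm$sampling_rate
  if (iv[1] < 0 || iv[2] > dataset$paradigm$trial_length)
    stop("window exceeds the trial bounds")
  idx <- (floor(iv[1] * fs) + 1L):floor(iv[2] * fs)
  if (length(idx) < 2L) stop("window contains fewer than 2 samples")
  d <- dataset$data
  if (!is.null(window$band)) {
    co <- butter_coef(window$band[1], window$band[2], fs)
  }
  nc <- dim(d)[2]
  S <- matrix(0, nc, nc)
  mu <- numeric(nc)
  ntot <- 0L
  for (tr in seq_len(dim(d)[1])) {
    X <- d[tr, , ]                               # nc x ns
    if (!is.null(window$band)) X <- t(filtfilt_mat(co$b, co$a, t(X)))
    X <- X[, idx, drop = FALSE]
    S <- S + tcrossprod(X)
    mu <- mu + rowSums(X)
    ntot <- ntot + length(idx)
  }
  C <- S / ntot
  if (center) {
    mu <- mu / ntot
    C <- C - tcrossprod(mu)
  }
  neff <- if (is.null(window$band)) ntot else
    effective_samples(diff(window$band),
                      diff(iv) * dataset$paradigm$n_trials)
  covariance_matrix(C, neff, window)
}

cov_mat <- function(C) if (inherits(C, "covariance_matrix")) C$matrix else as.matrix(C)

#' LCMV beamformer weights
#'
#' Computes `w = C^-1 l / (l' C^-1 l)`: the unit-gain spatial filter with
#' minimum projected power. Optional diagonal loading (`regularisation` as a
#' fraction of the mean sensor variance) stabilises ill-conditioned
#' covariances.
#'
#' @param C a [covariance_matrix()] or plain matrix.
#' @param leadfield per-channel forward field of the target (non-zero).
#' @param regularisation diagonal loading fraction (default 0).
#' @return object of class `weights_vector` with elements `weights`,
#'   `leadfield`, `covariance_provenance`.
#' @export
lcmv_weights <- function(C, leadfield, regularisation = 0) {
  M <- cov_mat(C)
  l <- as.numeric(leadfield)
  if (length(l) != nrow(M)) stop("leadfield length must match covariance dimension")
  if (sqrt(sum(l^2)) == 0) stop("leadfield must be non-zero")
  if (regularisation > 0) M <- M + diag(regularisation * mean(diag(M)), nrow(M))
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance is singular; use diagonal loading (regularisation > 0) or more data")
  Cl <- backsolve(ch, forwardsolve(t(ch), l))
  w <- Cl / sum(l * Cl)
  structure(list(weights = w, leadfield = l,
                 covariance_provenance = if (inherits(C, "covariance_matrix")) C$window else NULL),
            class = "weights_vector")
}

wvec <- function(w) if (inherits(w, "weights_vector")) w$weights else as.numeric(w)

#' Pseudo-z statistic
#'
#' Projected source power normalised by projected sensor-noise power,
#' `z = w'Cw / (v^2 w'w)`, assuming uncorrelated sensor noise of equal
#' per-channel variance `v^2`. Removes the depth bias of raw projected
#' power.
#'
#' @param w a `weights_vector` (or numeric weights).
#' @param C covariance used in the numerator.
#' @param noise_variance `v^2`, tesla^2 per sample.
#' @return scalar pseudo-z.
#' @export
pseudo_z <- function(w, C, noise_variance) {
  if (noise_variance <= 0) stop("noise_variance must be positive")
  w <- wvec(w)
  if (sum(w^2) == 0) stop("weights are zero")
  M <- cov_mat(C)
  as.numeric(w %*% M %*% w) / (noise_variance * sum(w^2))
}

#' Pseudo-t statistic
#'
#' Noise-normalised active-minus-control projected power,
#' `T = (w'C_a w - w'C_c w) / (2 w'w)`; the `w'w` denominator removes the
#' bias towards the centre of the head.
#'
#' @param w a `weights_vector` (or numeric weights).
#' @param C_active,C_control covariances of the active and control windows.
#' @return scalar pseudo-t.
#' @export
pseudo_t <- function(w, C_active, C_control) {
  w <- wvec(w)
  Ca <- cov_mat(C_active); Cc <- cov_mat(C_control)
  if (length(w) != nrow(Ca) || length(w) != nrow(Cc))
    stop("dimension mismatch between weights and covariances")
  (as.numeric(w %*% Ca %*% w) - as.numeric(w %*% Cc %*% w)) / (2 * sum(w^2))
}

#' Source image container
#'
#' @param values one statistic value per scan point (finite).
#' @param scan_points n x 3 matrix of scan locations, metres.
#' @param statistic_kind `"pseudo_z"` or `"pseudo_t"`.
#' @param s optional 1-D coordinate along a scan line (metres).
#' @return object of class `source_image`.
#' @export
source_image <- function(values, scan_points, statistic_kind = "pseudo_z",
                         s = NULL) {
  values <- as.numeric(values)
  scan_points <- rbind3(scan_points)
  if (length(values) != nrow(scan_points))
    stop("one value per scan point required")
  if (!all(is.finite(values))) stop("image values must be finite")
  structure(list(values = values, scan_points = scan_points,
                 statistic_kind = statistic_kind, s = s),
            class = "source_image")
}

#' @export
print.source_image <- function(x, ...) {
  cat("<source_image>", x$statistic_kind, "at", length(x$values),
      "scan points; max =", signif(max(x$values), 4), "\n")
  invisible(x)
}

# Shared imaging core. For each scan point, builds the tangential 2-column
# lead field L, the weight covariance solve, and maximises the requested
# statistic over orientation in the tangent plane (generalised 2x2
# eigenproblem), or evaluates a fixed orientation.
#   Cw: weight covariance; num: list of numerator covariance matrices (for
#   pseudo_z) or list(active=, control=) (pseudo_t); returns values.
scan_statistic <- function(points, head, sensors, Cw, num, noise_variance,
                           statistic = c("pseudo_z", "pseudo_t"),
                           orientation = "optimal", regularisation = 0) {
  statistic <- match.arg(statistic)
  points <- rbind3(points)
  M <- cov_mat(Cw)
  if (regularisation > 0) M <- M + diag(regularisation * mean(diag(M)), nrow(M))
  ch <- tryCatch(chol(M), error = function(e)
    stop("covariance is singular; use diagonal loading (regularisation > 0) or more data"))
  fixed <- is.numeric(orientation)
  vals <- numeric(nrow(points))
  for (k in seq_len(nrow(points))) {
    lf <- leadfield_scan(points[k, ], head, sensors)
    L <- lf$L                                            # nc x rank
    M1 <- backsolve(ch, forwardsolve(t(ch), L))          # C^-1 L
    Bm <- crossprod(M1)                                  # L'C^-2L
    if (statistic == "pseudo_z") {
      G <- crossprod(M1, cov_mat(num[[1]])) %*% M1
      den <- noise_variance * Bm
    } else {
      G <- (crossprod(M1, cov_mat(num$active)) %*% M1 -
              crossprod(M1, cov_mat(num$control)) %*% M1)
      den <- 2 * Bm
    }
    if (fixed) {
      u <- as.numeric(crossprod(lf$V, orientation))      # visible component
      if (sqrt(sum(u^2)) < 1e-12)
        stop("fixed orientation is externally silent at a scan point")
      vals[k] <- as.numeric(u %*% G %*% u) / as.numeric(u %*% den %*% u)
    } else {
      vals[k] <- max_gen_eig(G, den)
    }
  }
  vals
}

# largest generalised eigenvalue of the symmetric pencil (G, D), D > 0
max_gen_eig <- function(G, D) {
  ch <- chol((D + t(D)) / 2)
  Y <- backsolve(ch, t(G), transpose = TRUE)             # R^-T G'
  K <- backsolve(ch, t(Y), transpose = TRUE)             # R^-T G R^-1 (sym)
  max(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# images from precomputed covariances: common to the simulated, fast-path
# and analytic routes
images_from_cov <- function(C, C1, C2, points, head, sensors, method,
                            noise_variance, orientation = "optimal",
                            regularisation = 0, s = NULL) {
  method <- as.integer(method)
  if (!method %in% 1:3) stop("method must be 1, 2 or 3")
  im <- function(Cw, Cn) {
    v <- scan_statistic(points, head, sensors, Cw, list(Cn), noise_variance,
                        "pseudo_z", orientation, regularisation)
    source_image(v, points, "pseudo_z", s = s)
  }
  switch(method,
         list(im(C, C)),                 # 1: single weights, single image
         list(im(C, C1), im(C, C2)),     # 2: single weights, two images
         list(im(C1, C1), im(C2, C2)))   # 3: two weights, two images
}

#' Beamformer images by covariance-segmentation method
#'
#' Builds the segment covariances `C1` (first half-trial), `C2` (second
#' half-trial) and `C` (all data) and reconstructs the scan points with one
#' of three strategies: (1) single weights from `C`, single image; (2)
#' single weights from `C`, two images with `C1`/`C2` numerators; (3)
#' independent weights from `C1` and `C2`, one image each. Method 3 removes
#' the temporally separated source from each weight computation, which is
#' what sharpens the spatial filter.
#'
#' @param dataset a `sensor_dataset`.
#' @param scan_points n x 3 matrix of scan locations.
#' @param head a [head_model()].
#' @param sensors a [sensor_array()].
#' @param method 1, 2 or 3.
#' @param noise_variance sensor noise variance `v^2` (tesla^2 per sample).
#' @param windows list with elements `full`, `w1`, `w2` ([cov_window()]s);
#'   default splits the trial into halves, broadband.
#' @param orientation `"optimal"` (maximise the statistic in the tangent
#'   plane per point) or a fixed 3-vector.
#' @param regularisation diagonal loading fraction.
#' @return list of one ([method 1]) or two `source_image`s.
#' @export
method_images <- function(dataset, scan_points, head, sensors, method,
                          noise_variance, windows = NULL,
                          orientation = "optimal", regularisation = 0) {
  tl <- dataset$paradigm$trial_length
  if (is.null(windows))
    windows <- list(full = cov_window(c(0, tl)),
                    w1 = cov_window(c(0, tl / 2)),
                    w2 = cov_window(c(tl / 2, tl)))
  C  <- estimate_covariance(dataset, windows$full)
  C1 <- estimate_covariance(dataset, windows$w1)
  C2 <- estimate_covariance(dataset, windows$w2)
  images_from_cov(C, C1, C2, scan_points, head, sensors, method,
                  noise_variance, orientation, regularisation)
}
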