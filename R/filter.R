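# Zero-phase band-pass filtering. Design is delegated to signal::butter;
# the forward-backward application runs in compiled code over all channels
# of a trial at once.

# zero-phase forward-backward IIR on columns of X, with odd reflection
# padding to suppress edge transients
filtfilt_mat <- function(b, a, X, pad = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(pad)) pad <- min(n - 1L, max(300L, 9L * (length(a) - 1L)))
  top <- 2 * matrix(X[1L, ], pad, ncol(X), byrow = TRUE) -
    X[seq(pad + 1L, 2L), , drop = FALSE]
  bot <- 2 * matrix(X[n, ], pad, ncol(X), byrow = TRUE) -
    X[seq(n - 1L, n - pad), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  Y <- iir_filter_mat(b, a, Xp)
  Y <- iir_filter_mat(b, a, Y[nrow(Y):1L, , drop = FALSE])
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[seq(pad + 1L, pad + n), , drop = FALSE]
}

butter_coef <- function(low, high, fs, order = 4L) {
  ny <- fs / 2
  if (!(low > 0 && low < high && high < ny))
    stop("band must satisfy 0 < low < high < Nyquist (", ny, " Hz)")
  bf <- signal::butter(order, c(low, high) / ny, type = "pass")
  list(b = bf$b, a = bf$a)
}

#' Zero-phase band-pass filter an epoched dataset
#'
#' Applies a 4th-order Butterworth band-pass forwards and backwards (zero
#' phase, so boxcar timing is preserved) to every channel of every trial.
#'
#' @param dataset a `sensor_dataset` from [simulate_dataset()].
#' @param low,high band edges in Hz; `0 < low < high < Nyquist`.
#' @param order filter order before the forward-backward pass.
#' @return a `sensor_dataset` with filtered data.
#' @export
bandpass <- function(dataset, low, high, order = 4L) {
  co <- butter_coef(low, high, dataset$paradigm$sampling_rate, order)
  d <- dataset$data
  for (tr in seq_len(dim(d)[1])) {
    d[tr, , ] <- t(filtfilt_mat(co$b, co$a, t(d[tr, , ])))
  }
  out <- dataset
  out$data <- d
  out$band <- c(low, high)
  out
}
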