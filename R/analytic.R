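# Closed-form (infinite-data) beamformer images from exact model
# covariances: the oracle the finite-data simulations converge to.

#' Exact covariance specification
#'
#' Describes the population covariance implied by uncorrelated boxcar
#' sources plus white sensor noise: `C = v^2 I + sum_i duty_i s_i^2 l_i
#' l_i'`, where `s_i^2` is the per-sample source variance inside its active
#' window and `duty_i` the fraction of the covariance window during which
#' source i is active.
#'
#' @param lead_fields list of per-channel lead-field vectors (T per A m).
#' @param source_variances per-source within-window variance in (nAm)^2;
#'   for a per-trial amplitude model `Normal(m, sd)` this is `m^2 + sd^2`.
#' @param duty_cycles per-source fraction of the covariance window the
#'   source is active, in `[0, 1]`.
#' @param noise_variance `v^2`, tesla^2 per channel per sample.
#' @return object of class `exact_cov_spec`.
#' @export
exact_cov_spec <- function(lead_fields, source_variances, duty_cycles,
                           noise_variance) {
  if (!is.list(lead_fields)) lead_fields <- list(lead_fields)
  k <- length(lead_fields)
  source_variances <- rep_len(as.numeric(source_variances), k)
  duty_cycles <- rep_len(as.numeric(duty_cycles), k)
  if (any(duty_cycles < 0 | duty_cycles > 1))
    stop("duty cycles must lie in [0, 1]")
  if (any(source_variances < 0)) stop("source variances must be >= 0")
  if (noise_variance <= 0) stop("noise_variance must be positive")
  structure(list(lead_fields = lapply(lead_fields, as.numeric),
                 source_variances = source_variances,
                 duty_cycles = duty_cycles, noise_variance = noise_variance),
            class = "exact_cov_spec")
}

#' Exact (infinite-data) covariance matrix
#'
#' @param spec an [exact_cov_spec()].
#' @return a [covariance_matrix()] with `n_samples = Inf`.
#' @export
exact_covariance <- function(spec) {
  nc <- length(spec$lead_fields[[1]])
  C <- diag(spec$noise_variance, nc)
  for (i in seq_along(spec$lead_fields)) {
    l <- spec$lead_fields[[i]]
    C <- C + spec$duty_cycles[i] * spec$source_variances[i] * NAM^2 *
      tcrossprod(l)
  }
  covariance_matrix(C, Inf)
}

# Woodbury inverse of v^2 I + L S L' (alternative route; must agree with a
# direct solve to 1e-10 — checked in the test suite)
exact_covariance_inverse <- function(spec) {
  nc <- length(spec$lead_fields[[1]])
  act <- which(spec$duty_cycles * spec$source_variances > 0)
  v2 <- spec$noise_variance
  if (!length(act)) return(diag(1 / v2, nc))
  L <- vapply(spec$lead_fields[act], identity, numeric(nc))
  s <- spec$duty_cycles[act] * spec$source_variances[act] * NAM^2
  K <- diag(1 / s, length(act)) + crossprod(L) / v2
  diag(1 / v2, nc) - (L %*% solve(K, t(L))) / v2^2
}

#' Analytic beamformer line profile
#'
#' Infinite-data pseudo-z image for method 1 (weights and numerator from
#' the full exact covariance, both sources present) or method 3 (per-source
#' exact covariances for both weights and numerator, composite image list).
#'
#' @param sources list of two [dipole_source()] objects.
#' @param head a [head_model()].
#' @param sensors a [sensor_array()].
#' @param method 1 or 3.
#' @param noise_variance `v^2`, tesla^2 per sample.
#' @param duty_full duty cycle of each source over the full trial
#'   (default 0.1: 2 s of 20 s).
#' @param duty_half duty cycle over its own half trial (default 0.2).
#' @param points scan points (n x 3); typically from [line_points()].
#' @param orientation `"optimal"` or fixed 3-vector.
#' @param s optional line coordinate to attach to the images.
#' @return list of one (method 1) or two (method 3) `source_image`s.
#' @export
analytic_profile <- function(sources, head, sensors, method, noise_variance,
                             points, duty_full = 0.1, duty_half = 0.2,
                             orientation = "optimal", s = NULL) {
  method <- as.integer(method)
  if (!method %in% c(1L, 3L)) stop("analytic profiles cover methods 1 and 3")
  lf <- lapply(sources, function(src) forward_field(src, head, sensors))
  sv <- vapply(sources, function(src)
    src$amplitude_mean^2 + src$amplitude_sd^2, numeric(1))
  if (method == 1L) {
    spec <- exact_cov_spec(lf, sv, duty_full, noise_variance)
    C <- exact_covariance(spec)
    images_from_cov(C, C, C, points, head, sensors, 1L, noise_variance,
                    orientation, s = s)
  } else {
    C1 <- exact_covariance(exact_cov_spec(lf[1], sv[1], duty_half, noise_variance))
    C2 <- exact_covariance(exact_cov_spec(lf[2], sv[2], duty_half, noise_variance))
    images_from_cov(NULL, C1, C2, points, head, sensors, 3L, noise_variance,
                    orientation, s = s)
  }
}
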