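# Current-dipole forward model in spherically symmetric conductors
# (Sarvas closed form). Fields are in tesla per unit dipole moment (A m).

#' Construct a dipole source
#'
#' @param position 3-vector, metres.
#' @param orientation unit 3-vector (normalised here if slightly off).
#' @param amplitude_mean mean source strength across trials, nAm.
#' @param amplitude_sd across-trial standard deviation of strength, nAm.
#' @return object of class `dipole_source`.
#' @export
dipole_source <- function(position, orientation, amplitude_mean = 31,
                          amplitude_sd = 3) {
  position <- as.numeric(position); orientation <- as.numeric(orientation)
  if (length(position) != 3L || length(orientation) != 3L)
    stop("position and orientation must be 3-vectors")
  nrm <- sqrt(sum(orientation^2))
  if (nrm < 1e-12) stop("orientation must be non-zero")
  if (amplitude_sd < 0) stop("amplitude_sd must be non-negative")
  structure(list(position = position, orientation = orientation / nrm,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd),
            class = "dipole_source")
}

#' Tangential dipole on a source surface
#'
#' Convenience constructor: place a dipole on `surface` (radially projecting
#' `position` first) with a tangential orientation at angle `azimuth`.
#'
#' @inheritParams dipole_source
#' @param surface an [ellipsoid_surface()].
#' @param azimuth radians within the tangent plane.
#' @export
surface_dipole <- function(surface, position, azimuth = 0,
                           amplitude_mean = 31, amplitude_sd = 3) {
  p <- as.numeric(project_to_ellipsoid(surface, position))
  dipole_source(p, tangential_orientation(surface, p, azimuth),
                amplitude_mean, amplitude_sd)
}

# Sarvas formula, vectorised over channels with per-channel sphere centers.
# rs: channels x 3 sensor positions; os: channels x 3 orientations;
# centers: channels x 3; r0 source position (3); q dipole moment (3, A m).
sarvas_field <- function(rs, os, centers, r0, q) {
  r <- rs - centers                               # sensor rel. center
  rr0 <- matrix(r0, nrow(rs), 3, byrow = TRUE) - centers  # source rel. center
  a <- r - rr0
  an <- sqrt(rowSums(a^2))
  rn <- sqrt(rowSums(r^2))
  adotr <- rowSums(a * r)
  FF <- an * (rn * an + rn^2 - rowSums(rr0 * r))
  if (any(!is.finite(FF) | FF <= 0))
    stop("degenerate source-sensor geometry (F <= 0) for channel ",
         which(!is.finite(FF) | FF <= 0)[1])
  # grad F
  gF <- (an^2 / rn + adotr / an + 2 * an + 2 * rn) * r -
    (an + 2 * rn + adotr / an) * rr0
  qxr0 <- cbind(q[2] * rr0[, 3] - q[3] * rr0[, 2],
                q[3] * rr0[, 1] - q[1] * rr0[, 3],
                q[1] * rr0[, 2] - q[2] * rr0[, 1])
  B <- (MU0 / (4 * pi * FF^2)) * (FF * qxr0 - rowSums(qxr0 * r) * gF)
  rowSums(B * os)
}

#' Forward field (lead field) of a dipole
#'
#' Projects the external magnetic field of a current dipole in a spherical
#' conductor onto each channel's sensing orientation. In `local_spheres`
#' mode every channel uses its own fitted sphere centre. The result is
#' linear in the dipole moment; `moment` defaults to 1 A m so the return
#' value is the lead-field vector in T / (A m).
#'
#' @param source a [dipole_source()] (or a list with `position`,
#'   `orientation`).
#' @param head a [head_model()].
#' @param sensors a [sensor_array()].
#' @param moment dipole moment in A m multiplying the unit orientation.
#' @return numeric vector, one value per channel (tesla).
#' @export
forward_field <- function(source, head, sensors, moment = 1) {
  centers <- head_centers(head, sensors)
  r0 <- source$position
  d <- sqrt(rowSums(sweep(centers, 2, r0, FUN = function(a, b) b - a)^2))
  # in single-sphere mode the sphere is the conductor boundary; in local
  # mode the per-channel radii are approximations retained for provenance
  # and far-side sources legitimately fall outside them
  bad <- if (head$mode == "single_sphere")
    which(d < 1e-9 | d >= head$sphere_radii[ch_index(head, sensors)])
  else which(d < 1e-9)
  if (length(bad))
    stop("source lies at or outside the conductor sphere for channel ",
         sensors$names[bad[1]])
  q <- source$orientation * moment
  sarvas_field(sensors$positions, sensors$orientations, centers, r0, q)
}

head_centers <- function(head, sensors) {
  nc <- nrow(sensors$positions)
  if (head$mode == "single_sphere")
    matrix(head$sphere_centers[1, ], nc, 3, byrow = TRUE)
  else {
    if (nrow(head$sphere_centers) != nc)
      stop("local_spheres head model needs exactly one center per channel")
    head$sphere_centers
  }
}

ch_index <- function(head, sensors) {
  if (head$mode == "single_sphere") rep(1L, nrow(sensors$positions))
  else seq_len(nrow(sensors$positions))
}

# Full lead-field matrix for a scan point: columns are the fields of unit
# dipoles along x, y, z. In a single-sphere conductor the radial moment
# component is externally silent, so the matrix has (numerical) rank 2
# there; with local spheres it is full rank but strongly anisotropic.
leadfield_xyz <- function(point, head, sensors) {
  centers <- head_centers(head, sensors)
  vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(e)
    sarvas_field(sensors$positions, sensors$orientations, centers, point, e),
    numeric(nrow(sensors$positions)))
}

# visible-subspace factorisation of the lead field at a scan point:
# L = (U D) V' with silent directions (singular value below tol * largest)
# removed. Orientations u map to subspace coordinates c = V'u.
leadfield_scan <- function(point, head, sensors, tol = 1e-7) {
  L3 <- leadfield_xyz(point, head, sensors)
  sv <- svd(L3)
  keep <- sv$d > tol * sv$d[1]
  list(L = sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep)),
       V = sv$v[, keep, drop = FALSE])
}
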