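# Shared fixtures: small geometries and an independent re-implementation of
# the spherical-conductor dipole field used as a forward-model oracle.

small_geometry <- function(n_channels = 40) {
  default_geometry(n_channels = n_channels)
}

# Independent scalar implementation of the closed-form conductor field,
# written straight from the published formula with explicit component
# algebra (no shared code with the package's vectorised version).
oracle_dipole_field <- function(sensor, orient, center, r0, q) {
  r <- sensor - center
  r0 <- r0 - center
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2)); R <- sqrt(sum(r^2))
  FF <- a * (R * a + R^2 - sum(r0 * r))
  dF <- (a^2 / R + sum(a_vec * r) / a + 2 * a + 2 * R) * r -
    (a + 2 * R + sum(a_vec * r) / a) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  B <- (1e-7 / FF^2) * (FF * qxr0 - sum(qxr0 * r) * dF)
  sum(B * orient)
}

# Magnetic scalar potential outside a spherical conductor; the field is
# -mu0 * grad(U). Used as a formula-independent numerical-gradient oracle.
oracle_potential <- function(rvec, center, r0, q) {
  r <- rvec - center
  r0 <- r0 - center
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2)); R <- sqrt(sum(r^2))
  FF <- a * (R * a + R^2 - sum(r0 * r))
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  -sum(qxr0 * r) / (4 * pi * FF)
}

oracle_field_numgrad <- function(sensor, orient, center, r0, q, h = 1e-6) {
  g <- vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    # five-point central difference
    (-oracle_potential(sensor + 2 * e, center, r0, q) +
       8 * oracle_potential(sensor + e, center, r0, q) -
       8 * oracle_potential(sensor - e, center, r0, q) +
       oracle_potential(sensor - 2 * e, center, r0, q)) / (12 * h)
  }, numeric(1))
  -4 * pi * 1e-7 * sum(g * orient)
}

# deterministic two-source placement on the default study surface
fixture_pair <- function(geo, d = 0.012, seed = 13) {
  set.seed(seed)
  mid <- as.numeric(sample_ellipsoid(geo$source_surface, 1, upper = TRUE))
  tdir <- tangential_orientation(geo$source_surface, mid, runif(1, 0, 2 * pi))
  az <- runif(2, 0, 2 * pi)
  pp <- megres:::place_pair(geo$source_surface, mid, tdir, d)
  list(s1 = surface_dipole(geo$source_surface, pp$a, az[1]),
       s2 = surface_dipole(geo$source_surface, pp$b, az[2]),
       mid = mid, tdir = tdir, az = az)
}

# line-profile images from precomputed covariances with line metadata
profile_images <- function(cov, srcs, geo, method, noise_variance,
                           margin = 0.01, step = 5e-4) {
  lp <- line_points(srcs$s1$position, srcs$s2$position, margin, step)
  imgs <- megres:::images_from_cov(cov$C, cov$C1, cov$C2, lp$points,
                                   geo$head, geo$sensors, method,
                                   noise_variance, "optimal", s = lp$s)
  lapply(imgs, function(im) {
    attr(im, "line") <- list(a = lp$a, dir = lp$dir)
    im
  })
}

IN_BAND <- sqrt(17 / 300)   # in-band amplitude fraction of a white source
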