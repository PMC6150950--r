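# Sensor-array and source-surface geometry. Coordinates are right handed,
# +z superior, metres throughout; interface units (nAm, fT) are converted at
# the boundary, never internally.

#' Construct a sensor array
#'
#' A `sensor_array` holds the measurement frame: one position and one unit
#' sensing orientation per channel. Sensors are modelled as point
#' magnetometers reading the field component along their orientation.
#'
#' @param positions numeric matrix, channels x 3, metres.
#' @param orientations numeric matrix, channels x 3; each row must have unit
#'   norm (tolerance 1e-12).
#' @param names optional character vector of channel labels.
#' @return An object of class `sensor_array` with elements `positions`,
#'   `orientations`, `names`.
#' @export
sensor_array <- function(positions, orientations, names = NULL) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (ncol(positions) != 3L || ncol(orientations) != 3L)
    stop("positions and orientations must be n x 3 matrices")
  n <- nrow(positions)
  if (n < 2L) stop("a sensor_array needs at least 2 channels")
  if (nrow(orientations) != n)
    stop("positions and orientations disagree on channel count")
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("orientation vectors must have unit norm (tolerance 1e-12)")
  if (anyDuplicated(round(positions, 12)))
    stop("sensor positions must be pairwise distinct")
  if (is.null(names)) names <- sprintf("MEG%03d", seq_len(n))
  structure(list(positions = positions, orientations = orientations,
                 names = as.character(names)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array> ", nrow(x$positions), " channels, radius range [",
      signif(min(sqrt(rowSums(x$positions^2))), 3), ", ",
      signif(max(sqrt(rowSums(x$positions^2))), 3), "] m\n", sep = "")
  invisible(x)
}

#' Synthetic helmet-like sensor array
#'
#' Places `n_channels` quasi-uniform point magnetometers on the upper cap of
#' a sphere of given radius using a golden-angle (Fibonacci) lattice, with
#' inward radial sensing orientations. This emulates the coverage and
#' sensor-scalp distance scale of a whole-head axial system; the seed only
#' sets a rigid rotation of the lattice about z, so arrays are deterministic
#' for a fixed seed.
#'
#' @param n_channels number of channels (>= 2).
#' @param radius sphere radius in metres; must exceed the largest semi-axis
#'   of any head surface used with the array.
#' @param coverage fraction of the full sphere's solid angle covered by the
#'   cap, measured from the +z pole (0.5 = upper hemisphere).
#' @param seed integer seed for the lattice rotation.
#' @return A [sensor_array()].
#' @export
make_helmet_array <- function(n_channels = 275, radius = 0.12,
                              coverage = 0.5, seed = 1L) {
  if (!is.numeric(n_channels) || n_channels < 2)
    stop("n_channels must be >= 2")
  if (!is.numeric(radius) || radius <= 0)
    stop("radius must be positive")
  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  n <- as.integer(n_channels)
  zmin <- 1 - 2 * coverage                  # cap area fraction (1 - cos)/2
  i <- seq_len(n)
  z <- 1 - (i - 0.5) / n * (1 - zmin)
  golden <- pi * (3 - sqrt(5))
  phi0 <- withr_seed(seed, runif(1, 0, 2 * pi))
  phi <- golden * i + phi0
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(r * cos(phi), r * sin(phi), z)
  ori <- -pos / radius                      # inward radial
  sensor_array(pos, ori)
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Construct an ellipsoid surface
#'
#' @param center 3-vector, metres.
#' @param semi_axes 3 strictly positive lengths, metres.
#' @param rotation orthonormal 3x3 matrix whose columns are the principal
#'   axes (default identity).
#' @return Object of class `ellipsoid_surface`.
#' @export
ellipsoid_surface <- function(center, semi_axes, rotation = diag(3)) {
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  rotation <- as.matrix(rotation)
  if (length(center) != 3L || length(semi_axes) != 3L)
    stop("center and semi_axes must have length 3")
  if (any(semi_axes <= 0)) stop("semi_axes must be strictly positive")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10)
    stop("rotation must be orthonormal (R'R = I to 1e-10)")
  structure(list(center = center, semi_axes = semi_axes, rotation = rotation),
            class = "ellipsoid_surface")
}

#' @export
print.ellipsoid_surface <- function(x, ...) {
  cat("<ellipsoid_surface> semi-axes (",
      paste(signif(x$semi_axes, 4), collapse = ", "), ") m, center (",
      paste(signif(x$center, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Implicit ellipsoid equation
#'
#' Returns `|diag(1/s) R' (x - c)|^2 - 1`, zero on the surface, negative
#' inside.
#'
#' @param surface an [ellipsoid_surface()].
#' @param points n x 3 matrix or 3-vector.
#' @return numeric vector of implicit values.
#' @export
ellipsoid_implicit <- function(surface, points) {
  p <- local_coords(surface, points)
  rowSums(sweep(p, 2, surface$semi_axes, "/")^2) - 1
}

local_coords <- function(surface, points) {
  points <- rbind3(points)
  sweep(points, 2, surface$center) %*% surface$rotation
}

rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), ncol = 3) else as.matrix(x)
}

#' Outward unit normal of an ellipsoid at surface points
#' @inheritParams ellipsoid_implicit
#' @return n x 3 matrix of unit normals.
#' @export
ellipsoid_normal <- function(surface, points) {
  p <- local_coords(surface, points)          # local frame
  g <- sweep(p, 2, surface$semi_axes^2, "/")  # gradient/2 in local frame
  g <- g %*% t(surface$rotation)
  g / sqrt(rowSums(g^2))
}

#' Radially project points onto an ellipsoid surface
#'
#' Projects along rays through the ellipsoid centre, which maps any nonzero
#' offset to a unique surface point.
#' @inheritParams ellipsoid_implicit
#' @return n x 3 matrix of surface points.
#' @export
project_to_ellipsoid <- function(surface, points) {
  p <- local_coords(surface, points)
  q <- sqrt(rowSums(sweep(p, 2, surface$semi_axes, "/")^2))
  if (any(q == 0)) stop("cannot project the ellipsoid centre")
  p <- p / q
  sweep(p %*% t(surface$rotation), 2, surface$center, "+")
}

#' Sample points on an ellipsoid surface
#'
#' Area-weighted rejection sampling (uniform with respect to surface area).
#'
#' @param surface an [ellipsoid_surface()].
#' @param n number of points.
#' @param upper if `TRUE`, restrict to points with positive local z (the
#'   part of the surface under a superior sensor cap).
#' @return n x 3 matrix of points satisfying the implicit equation.
#' @export
sample_ellipsoid <- function(surface, n, upper = FALSE) {
  s <- surface$semi_axes
  out <- matrix(NA_real_, 0, 3)
  while (nrow(out) < n) {
    m <- 4L * (n - nrow(out)) + 8L
    u <- matrix(rnorm(3 * m), m, 3)
    u <- u / sqrt(rowSums(u^2))
    if (upper) u <- u[u[, 3] > 0, , drop = FALSE]
    if (!nrow(u)) next
    p <- sweep(u, 2, s, "*")
    # area element relative weight for rejection
    w <- sqrt(rowSums(sweep(u, 2, c(s[2] * s[3], s[1] * s[3], s[1] * s[2]), "*")^2))
    keep <- runif(nrow(u)) < w / max(s[2] * s[3], s[1] * s[3], s[1] * s[2])
    p <- p[keep, , drop = FALSE]
    out <- rbind(out, p)
  }
  out <- out[seq_len(n), , drop = FALSE]
  sweep(out %*% t(surface$rotation), 2, surface$center, "+")
}

#' Least-squares ellipsoid fit
#'
#' Fits a general quadric to a point cloud by algebraic least squares
#' (smallest singular vector of the design matrix) and extracts centre,
#' semi-axes and principal frame.
#'
#' @param points n x 3 matrix, n >= 9, not coplanar.
#' @return An [ellipsoid_surface()] with attribute `"fit"`, a list holding
#'   the RMS implicit-equation residual and the point count.
#' @export
fit_ellipsoid <- function(points) {
  points <- rbind3(points)
  if (nrow(points) < 9L) stop("fit_ellipsoid needs at least 9 points")
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  # centre/scale for conditioning
  mu <- colMeans(points); sc <- max(apply(points, 2, function(v) diff(range(v))), 1e-12)
  xs <- (x - mu[1]) / sc; ys <- (y - mu[2]) / sc; zs <- (z - mu[3]) / sc
  D <- cbind(xs^2, ys^2, zs^2, 2 * xs * ys, 2 * xs * zs, 2 * ys * zs,
             2 * xs, 2 * ys, 2 * zs, 1)
  sv <- svd(D)
  v <- sv$v[, ncol(sv$v)]
  A <- matrix(c(v[1], v[4], v[5],
                v[4], v[2], v[6],
                v[5], v[6], v[3]), 3, 3)
  b <- v[7:9]
  ev0 <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (any(abs(ev0) < 1e-10 * max(abs(ev0))) || abs(det(A)) < 1e-300)
    stop("degenerate point cloud: quadric fit is not an ellipsoid (coplanar or rank-deficient)")
  ctr_s <- -solve(A, b)
  k <- as.numeric(ctr_s %*% A %*% ctr_s) - v[10]
  ev <- eigen(A / k, symmetric = TRUE)
  if (any(ev$values <= 0))
    stop("degenerate point cloud: fitted quadric is not positive definite (not an ellipsoid)")
  semi <- sc / sqrt(ev$values)
  R <- ev$vectors
  if (det(R) < 0) R[, 3] <- -R[, 3]
  # sort axes descending for a canonical frame
  o <- order(semi, decreasing = TRUE)
  semi <- semi[o]; R <- R[, o, drop = FALSE]
  if (det(R) < 0) R[, 3] <- -R[, 3]
  surf <- ellipsoid_surface(mu + sc * ctr_s, semi, R)
  res <- ellipsoid_implicit(surf, points)
  attr(surf, "fit") <- list(rms_residual = sqrt(mean(res^2)), n_points = nrow(points))
  surf
}

#' Shrink an ellipsoid surface to a given depth
#'
#' Reduces every semi-axis by `depth`, keeping centre and orientation. Used
#' to place simulated sources at a uniform depth beneath the brain surface
#' so that all placements see comparable sensor-level SNR.
#'
#' @param surface an [ellipsoid_surface()].
#' @param depth metres; must be smaller than the smallest semi-axis.
#' @return the shrunken [ellipsoid_surface()].
#' @export
shrink_surface <- function(surface, depth) {
  if (depth < 0) stop("depth must be non-negative")
  if (depth >= min(surface$semi_axes))
    stop("depth must be smaller than the smallest semi-axis")
  ellipsoid_surface(surface$center, surface$semi_axes - depth, surface$rotation)
}

#' Tangential source orientation at a surface point
#'
#' Returns a unit vector in the plane tangential to the surface at `point`,
#' at angle `azimuth` within that plane. Simulated dipoles are tangential
#' because the radial component of a primary current is externally silent in
#' a spherical conductor.
#'
#' @param surface an [ellipsoid_surface()].
#' @param point 3-vector on the surface (implicit residual < 1e-6).
#' @param azimuth radians; rotation within the tangent plane.
#' @return unit 3-vector orthogonal to the outward normal.
#' @export
tangential_orientation <- function(surface, point, azimuth = 0) {
  point <- as.numeric(point)
  if (abs(ellipsoid_implicit(surface, point)) > 1e-6)
    stop("point does not lie on the surface (implicit residual > 1e-6)")
  n <- as.numeric(ellipsoid_normal(surface, point))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- cross3(ref, n); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)
  cos(azimuth) * e1 + sin(azimuth) * e2
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Conductor head model
#'
#' Either one global sphere or one fitted sphere per channel ("multiple
#' local spheres"). Radii are retained for provenance and range checking;
#' the external field of a spherical conductor does not depend on them.
#'
#' @param mode `"single_sphere"` or `"local_spheres"`.
#' @param sphere_centers 3-vector (single) or channels x 3 matrix (local).
#' @param sphere_radii numeric scalar or per-channel vector.
#' @return object of class `head_model`.
#' @export
head_model <- function(mode = c("single_sphere", "local_spheres"),
                       sphere_centers, sphere_radii) {
  mode <- match.arg(mode)
  centers <- rbind3(sphere_centers)
  radii <- as.numeric(sphere_radii)
  if (mode == "single_sphere" && nrow(centers) != 1L)
    stop("single_sphere mode takes exactly one center")
  if (length(radii) == 1L) radii <- rep(radii, nrow(centers))
  if (length(radii) != nrow(centers))
    stop("sphere_radii must match the number of centers")
  structure(list(mode = mode, sphere_centers = centers, sphere_radii = radii),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("<head_model> mode =", x$mode, "with", nrow(x$sphere_centers),
      "sphere(s)\n")
  invisible(x)
}

# linear least-squares sphere fit: |x|^2 = 2 c.x + (r^2 - |c|^2)
fit_sphere <- function(points) {
  points <- rbind3(points)
  if (nrow(points) < 4L) stop("sphere fit needs at least 4 points")
  A <- cbind(2 * points, 1)
  rhs <- rowSums(points^2)
  sol <- qr.solve(A, rhs)
  ctr <- sol[1:3]
  r2 <- sol[4] + sum(ctr^2)
  if (r2 <= 0) stop("degenerate sphere fit")
  list(center = ctr, radius = sqrt(r2))
}

#' Fit a conductor model to a head surface
#'
#' In `local_spheres` mode a sphere is least-squares fitted, for every
#' channel, to the patch of the head surface within `patch_radius` of the
#' surface point closest to that channel; in `single_sphere` mode one sphere
#' is fitted to the whole surface.
#'
#' @param head_surface an [ellipsoid_surface()] describing the scalp/brain
#'   boundary used for conductor fitting.
#' @param sensors a [sensor_array()].
#' @param patch_radius metres (default 0.04).
#' @param mode `"local_spheres"` (default) or `"single_sphere"`.
#' @param n_surface_points number of quasi-uniform surface samples used for
#'   the fits.
#' @return a [head_model()].
#' @export
fit_local_spheres <- function(head_surface, sensors, patch_radius = 0.04,
                              mode = c("local_spheres", "single_sphere"),
                              n_surface_points = 1500L) {
  mode <- match.arg(mode)
  if (patch_radius <= 0) stop("patch_radius must be positive")
  # deterministic quasi-uniform samples: golden lattice on the unit sphere
  n <- as.integer(n_surface_points)
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- pi * (3 - sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(r * cos(phi), r * sin(phi), z)
  pts <- sweep(sweep(u, 2, head_surface$semi_axes, "*") %*%
                 t(head_surface$rotation), 2, head_surface$center, "+")
  if (mode == "single_sphere") {
    f <- fit_sphere(pts)
    return(head_model("single_sphere", f$center, f$radius))
  }
  nc <- nrow(sensors$positions)
  centers <- matrix(NA_real_, nc, 3)
  radii <- numeric(nc)
  for (ch in seq_len(nc)) {
    d2 <- rowSums(sweep(pts, 2, sensors$positions[ch, ])^2)
    near <- pts[which.min(d2), ]
    patch <- pts[rowSums(sweep(pts, 2, near)^2) < patch_radius^2, , drop = FALSE]
    if (nrow(patch) < 4L)
      stop("patch for channel ", ch, " contains fewer than 4 surface points")
    f <- fit_sphere(patch)
    centers[ch, ] <- f$center
    radii[ch] <- f$radius
  }
  head_model("local_spheres", centers, radii)
}
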