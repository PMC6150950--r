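test_that("helmet arrays are valid, deterministic and reject bad input", {
  arr <- make_helmet_array(275, 0.12, 0.5, seed = 1)
  expect_equal(nrow(arr$positions), 275)
  expect_equal(sqrt(rowSums(arr$orientations^2)), rep(1, 275),
               tolerance = 1e-12)
  expect_true(all(arr$positions[, 3] > -1e-12))      # upper hemisphere
  expect_equal(sqrt(rowSums(arr$positions^2)), rep(0.12, 275))
  expect_identical(arr, make_helmet_array(275, 0.12, 0.5, seed = 1))
  expect_false(identical(arr$positions,
                         make_helmet_array(275, 0.12, 0.5, seed = 2)$positions))
  expect_silent(make_helmet_array(2, 0.1))
  expect_error(make_helmet_array(1, 0.1), "n_channels")
  expect_error(make_helmet_array(10, -1), "radius")
})

test_that("ellipsoid fitting recovers exact, spherical and jittered surfaces", {
  true <- ellipsoid_surface(c(0.01, -0.02, 0.03), c(0.09, 0.07, 0.06))
  set.seed(1)
  pts <- sample_ellipsoid(true, 400)
  fit <- fit_ellipsoid(pts)
  expect_equal(fit$center, true$center, tolerance = 1e-6)
  expect_equal(sort(fit$semi_axes), sort(true$semi_axes), tolerance = 1e-6)
  expect_lt(attr(fit, "fit")$rms_residual, 1e-8)

  sph <- ellipsoid_surface(c(0, 0, 0), c(0.08, 0.08, 0.08))
  fs <- fit_ellipsoid(sample_ellipsoid(sph, 200))
  expect_equal(fs$semi_axes, rep(0.08, 3), tolerance = 1e-6)

  set.seed(2)
  noisy <- pts + matrix(rnorm(length(pts), sd = 1e-3), ncol = 3)
  fn <- fit_ellipsoid(noisy)
  expect_lt(max(abs(fn$center - true$center)), 2e-3)
  expect_lt(max(abs(sort(fn$semi_axes) - sort(true$semi_axes))), 2e-3)

  flat <- cbind(runif(20), runif(20), 0)            # coplanar
  expect_error(fit_ellipsoid(flat), "degenerate")
  expect_error(fit_ellipsoid(pts[1:5, ]), "at least 9")
})

test_that("shrink_surface reduces each semi-axis by the depth", {
  s <- ellipsoid_surface(c(0, 0, 0), c(0.09, 0.07, 0.06))
  expect_equal(shrink_surface(s, 0.015)$semi_axes, c(0.075, 0.055, 0.045))
  expect_equal(shrink_surface(s, 0)$semi_axes, s$semi_axes)
  expect_error(shrink_surface(s, 0.07), "smaller than the smallest semi-axis")
})

test_that("tangential orientations are unit, orthogonal to the normal and antiperiodic", {
  surf <- ellipsoid_surface(c(0, 0, 0), c(0.075, 0.055, 0.05))
  set.seed(3)
  pts <- sample_ellipsoid(surf, 100)
  for (i in seq_len(20)) {
    az <- runif(1, 0, 2 * pi)
    o <- tangential_orientation(surf, pts[i, ], az)
    n <- as.numeric(ellipsoid_normal(surf, pts[i, ]))
    expect_equal(sum(o^2), 1, tolerance = 1e-12)
    expect_lt(abs(sum(o * n)), 1e-10)
    expect_equal(tangential_orientation(surf, pts[i, ], az + pi), -o,
                 tolerance = 1e-12)
  }
  # sphere north pole, azimuth 0 -> horizontal vector
  sph <- ellipsoid_surface(c(0, 0, 0), c(0.08, 0.08, 0.08))
  o <- tangential_orientation(sph, c(0, 0, 0.08), 0)
  expect_lt(abs(o[3]), 1e-12)
  expect_error(tangential_orientation(surf, c(0, 0, 0.2), 0), "surface")
})

test_that("local sphere fitting reduces to the global sphere on a spherical head", {
  sph <- ellipsoid_surface(c(0.005, -0.01, 0.02), c(0.08, 0.08, 0.08))
  sens <- make_helmet_array(30, 0.12)
  hm <- fit_local_spheres(sph, sens)
  expect_equal(nrow(hm$sphere_centers), 30)
  expect_lt(max(abs(sweep(hm$sphere_centers, 2, sph$center))), 1e-6)
  hs <- fit_local_spheres(sph, sens, mode = "single_sphere")
  expect_equal(as.numeric(hs$sphere_centers), sph$center, tolerance = 1e-6)
  expect_equal(hs$sphere_radii[1], 0.08, tolerance = 1e-6)
  # ellipsoidal head -> centers vary across channels
  ell <- ellipsoid_surface(c(0, 0, 0), c(0.09, 0.07, 0.065))
  hm2 <- fit_local_spheres(ell, sens)
  expect_gt(max(apply(hm2$sphere_centers, 2, sd)), 1e-3)
})

test_that("radial dipoles are externally silent in every head-model mode", {
  geo <- small_geometry()
  hs <- fit_local_spheres(geo$head_surface, geo$sensors, mode = "single_sphere")
  set.seed(4)
  pts <- sample_ellipsoid(geo$source_surface, 50)
  for (i in seq_len(nrow(pts))) {
    rad <- pts[i, ] - as.numeric(hs$sphere_centers)
    rad <- rad / sqrt(sum(rad^2))
    lf <- forward_field(dipole_source(pts[i, ], rad), hs, geo$sensors)
    expect_lt(max(abs(lf)), 1e-20)
  }
  # local spheres: radial w.r.t. each channel's own center is silent per channel
  ctr <- geo$head$sphere_centers[1, ]
  p <- pts[1, ]
  rad <- p - ctr; rad <- rad / sqrt(sum(rad^2))
  l <- forward_field(dipole_source(p, rad), geo$head, geo$sensors)
  expect_lt(abs(l[1]), 1e-20)
})

test_that("forward fields are linear, antisymmetric and decay with depth", {
  geo <- small_geometry()
  src <- surface_dipole(geo$source_surface, c(0.01, 0.02, 0.07), 0.7)
  l1 <- forward_field(src, geo$head, geo$sensors)
  expect_equal(forward_field(src, geo$head, geo$sensors, moment = 2), 2 * l1)
  flip <- dipole_source(src$position, -src$orientation)
  expect_equal(forward_field(flip, geo$head, geo$sensors), -l1)
  # monotone decay moving the same tangential dipole deeper
  hs <- fit_local_spheres(geo$head_surface, geo$sensors, mode = "single_sphere")
  p0 <- as.numeric(project_to_ellipsoid(geo$source_surface, c(0.0, 0.01, 0.08)))
  u <- p0 / sqrt(sum(p0^2))
  o <- tangential_orientation(geo$source_surface, p0, 0.3)
  depths <- seq(0.9, 0.4, by = -0.1)
  mags <- vapply(depths, function(k)
    abs(forward_field(dipole_source(k * sqrt(sum(p0^2)) * u, o), hs,
                      geo$sensors)[5]), numeric(1))
  expect_true(all(diff(mags) < 0))
  expect_error(forward_field(dipole_source(c(0.2, 0, 0), c(0, 0, 1)), hs,
                             geo$sensors), "outside the conductor")
  expect_error(forward_field(dipole_source(as.numeric(hs$sphere_centers),
                                           c(0, 0, 1)), hs, geo$sensors),
               "channel")
})

test_that("the conductor field matches two independent oracles", {
  center <- c(0, 0, 0)
  hm <- head_model("single_sphere", center, 0.09)
  sens <- make_helmet_array(12, 0.12, seed = 5)
  set.seed(6)
  r0 <- c(0.02, -0.01, 0.045)
  q <- c(3e-9, 5e-9, -2e-9)      # arbitrary moment, A m
  src <- dipole_source(r0, q / sqrt(sum(q^2)))
  lf <- forward_field(src, hm, sens, moment = sqrt(sum(q^2)))
  for (i in seq_len(12)) {
    # independent closed-form re-implementation: 1e-12 relative
    o1 <- oracle_dipole_field(sens$positions[i, ], sens$orientations[i, ],
                              center, r0, q)
    expect_equal(lf[i], o1, tolerance = 1e-12)
    # numerical gradient of the scalar potential: formula-independent
    o2 <- oracle_field_numgrad(sens$positions[i, ], sens$orientations[i, ],
                               center, r0, q)
    expect_equal(lf[i], o2, tolerance = 1e-6)
  }
})

test_that("surface invariants hold over many random draws", {
  surf <- ellipsoid_surface(c(0.01, 0, 0.01), c(0.07, 0.06, 0.05),
                            rotation = {
                              th <- 0.4
                              rbind(c(cos(th), -sin(th), 0),
                                    c(sin(th), cos(th), 0), c(0, 0, 1))
                            })
  set.seed(7)
  pts <- sample_ellipsoid(surf, 2000)
  expect_lt(max(abs(ellipsoid_implicit(surf, pts))), 1e-9)
  prj <- project_to_ellipsoid(surf, pts * 1.3)
  expect_lt(max(abs(ellipsoid_implicit(surf, prj))), 1e-9)
  nrm <- ellipsoid_normal(surf, pts)
  expect_equal(rowSums(nrm^2), rep(1, 2000), tolerance = 1e-12)
})

test_that("sensor arrays round-trip through the JSON sidecar", {
  arr <- make_helmet_array(20, 0.11, seed = 3)
  path <- tempfile(fileext = ".json")
  write_sensor_array(arr, path)
  back <- read_sensor_array(path)
  expect_equal(back$positions, arr$positions, ignore_attr = TRUE)
  expect_equal(back$orientations, arr$orientations, ignore_attr = TRUE)
  expect_identical(back$names, arr$names)
})
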