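test_that("line scan points have the stated count, order and geometry", {
  a <- c(0, 0, 0.05); b <- c(0.03, 0, 0.05)
  lp <- line_points(a, b, margin = 0.005, step = 5e-4)
  expect_equal(nrow(lp$points), 81)              # 30 mm + 2 x 5 mm at 0.5 mm
  expect_equal(lp$s[1], -0.005)
  expect_true(all(diff(lp$s) > 0))
  expect_equal(lp$points[11, ], a, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(line_points(a, a + 1e-5, step = 5e-4), "coincide")
  expect_error(line_points(a, b, step = -1), "step")
})

test_that("line profiles locate an analytic single-source maximum", {
  geo <- small_geometry(40)
  fx <- fixture_pair(geo, d = 0.02, seed = 51)
  v2 <- (21e-15)^2
  img <- line_profile(function(p)
    analytic_profile(list(fx$s1), geo$head, geo$sensors, 1, v2, p,
                     duty_full = 0.1)[[1]],
    fx$s1$position, fx$s2$position, margin = 0.005, step = 5e-4)
  expect_equal(img$s[which.max(img$values)], 0, tolerance = 1e-3)
})

test_that("the dip criterion resolves separated peaks and rejects merged ones", {
  s <- seq(0, 0.03, by = 5e-4)
  line <- list(a = c(0, 0, 0), dir = c(1, 0, 0))
  mk <- function(v) {
    img <- source_image(v, cbind(s, 0, 0), s = s)
    attr(img, "line") <- line
    img
  }
  exp_loc <- rbind(c(0.005, 0, 0), c(0.025, 0, 0))
  # two sharp peaks with a deep valley
  v <- exp(-(s - 0.005)^2 / 2e-6) + exp(-(s - 0.025)^2 / 2e-6)
  expect_true(is_resolved(mk(v), resolution_criterion(0.8), exp_loc)$resolved)
  # one broad bump
  v1 <- exp(-(s - 0.015)^2 / 2e-4)
  chk <- is_resolved(mk(v1), resolution_criterion(0.8), exp_loc)
  expect_false(chk$resolved)
  expect_match(chk$reason, "fewer than 2")
  # boundary case: dip exactly 80% of the peak is resolved (inclusive)
  g1 <- exp(-(s - 0.005)^2 / 2e-6); g2 <- exp(-(s - 0.025)^2 / 2e-6)
  v2 <- pmax(g1, g2, 0.8)
  expect_true(is_resolved(mk(v2), resolution_criterion(0.8), exp_loc)$resolved)
  v3 <- pmax(g1, g2, 0.8001)
  expect_false(is_resolved(mk(v3), resolution_criterion(0.8), exp_loc)$resolved)
  # sidelobe guard: both top maxima near one source -> not resolved
  v4 <- exp(-(s - 0.004)^2 / 2e-6) + 0.9 * exp(-(s - 0.007)^2 / 2e-6)
  expect_false(is_resolved(mk(v4), resolution_criterion(0.8), exp_loc)$resolved)
  # monotone in the dip ratio
  for (r in c(0.5, 0.7, 0.9)) {
    lo <- is_resolved(mk(v2), resolution_criterion(r), exp_loc)$resolved
    hi <- is_resolved(mk(v2), resolution_criterion(min(r + 0.09, 0.99)),
                      exp_loc)$resolved
    expect_true(!lo || hi)
  }
  # two images are composited by pointwise maximum
  va <- exp(-(s - 0.005)^2 / 2e-6)
  vb <- exp(-(s - 0.025)^2 / 2e-6)
  expect_true(is_resolved(list(mk(va), mk(vb)), resolution_criterion(0.8),
                          exp_loc)$resolved)
  expect_error(resolution_criterion(1.2), "dip_ratio")
})

test_that("a high-amplitude low-noise pair resolves down to the lattice floor", {
  geo <- small_geometry(60)
  cfg <- study_config(n_repeats = 1, d_start = 0.02, d_step = 1e-3,
                      methods = 3, seed = 2, amplitude_mean = 500,
                      amplitude_sd = 1, geometry = geo, n_trials = 44)
  cfg$noise_ft <- 2       # near-noiseless relative to a 500 nAm source
  d <- min_resolvable_distance(cfg, method = 3, repeat_index = 1)
  expect_lte(d, 2 * cfg$d_step * 1e3)
})

test_that("an impossibly strict criterion stops at the starting distance", {
  geo <- small_geometry(60)
  cfg <- study_config(n_repeats = 1, d_start = 0.02, d_step = 1e-3,
                      methods = 3, seed = 2, dip_ratio = 1e-6,
                      geometry = geo)
  expect_error(min_resolvable_distance(cfg, 3, 1), "d_start")
})

test_that("small studies run, pair methods and reproduce bit-identically", {
  cfg <- study_config(n_repeats = 2, methods = c(1, 3), seed = 3)
  res <- resolution_study(cfg)
  expect_s3_class(res, "resolution_result")
  expect_equal(nrow(res$table), 4)
  expect_true(all(res$table$min_distance_mm > 0))
  expect_equal(sort(unique(res$table$method)), c(1, 3))
  res2 <- resolution_study(cfg)
  expect_identical(res$table, res2$table)
  # serialisation round-trip
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_study_tsv(res, tsv); write_study_json(res, js)
  back <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(back$min_distance_mm, res$table$min_distance_mm)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$summary$mean_mm,
               res$summary$mean_mm, tolerance = 1e-12)
})

test_that("lower noise never worsens the minimum resolvable distance on shared seeds", {
  worse <- 0
  for (r in 1:10) {
    cfg_hi <- study_config(n_repeats = 1, methods = 3, seed = 600 + r,
                           snr_condition = "high", d_start = 0.02)
    cfg_lo <- cfg_hi; cfg_lo$noise_ft <- 36
    d_hi <- min_resolvable_distance(cfg_hi, 3, 1)
    d_lo <- tryCatch(min_resolvable_distance(cfg_lo, 3, 1),
                     error = function(e) NA)
    if (!is.na(d_lo) && d_hi > d_lo) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("method ordering holds in the mean over a shared-seed study", {
  cfg <- study_config(n_repeats = 8, methods = c(1, 2, 3), seed = 5)
  res <- resolution_study(cfg)
  m <- res$summary$mean_mm[match(1:3, res$summary$method)]
  expect_lte(m[3], m[2] + 1e-9)
  expect_lte(m[2], m[1] + 1e-9)
})

test_that("peak coordinate statistics match the closed-form paired t-test", {
  set.seed(8)
  A <- cbind(rnorm(8, 0, 1e-4), rnorm(8, 0, 1e-4), rnorm(8, 0, 1e-4))
  expect_error(peak_coordinate_stats(A[1:3, ], A), "equal run counts")
  # identical peaks: mean separation 0, p = 0.5
  st <- peak_coordinate_stats(A, A)
  expect_equal(st$mean_separation, 0)
  expect_equal(st$p, 0.5)
  # constant +3.5 mm z offset with 0.7 mm jitter over 8 runs
  set.seed(9)
  jit <- rnorm(8, 0, 7e-4)
  B <- A; B[, 3] <- A[, 3] + 3.5e-3 + jit
  st <- peak_coordinate_stats(A, B, axis = 3, direction = "greater")
  d <- B[, 3] - A[, 3]
  t_ref <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(st$t, t_ref, tolerance = 1e-12)
  expect_equal(st$p, pt(t_ref, 7, lower.tail = FALSE), tolerance = 1e-12)
  expect_lt(st$p, 0.01)
  # flipping the prespecified direction complements the p-value
  st2 <- peak_coordinate_stats(A, B, axis = 3, direction = "less")
  expect_equal(st$p + st2$p, 1, tolerance = 1e-12)
})

test_that("digit distance metrics separate corresponding from alternate references", {
  set.seed(10)
  ref <- rbind(c(0, 0, 0.05), c(0, 0, 0.058))
  runs <- 6
  mp <- array(NA_real_, c(runs, 2, 3))
  for (r in 1:runs) for (d in 1:2)
    mp[r, d, ] <- ref[d, ] + rnorm(3, 0, 5e-4)
  dm <- digit_distance_metrics(mp, ref)
  expect_true(all(dm$corresponding < dm$alternate))
  expect_lt(dm$p, 0.01)
  # swapped references reverse the direction
  dm2 <- digit_distance_metrics(mp, ref[2:1, ])
  expect_gt(dm2$p, 0.95)
  # offset geometry: difference of means approximates the offset projection
  expect_equal(dm$mean_alternate - dm$mean_corresponding,
               sqrt(sum((ref[1, ] - ref[2, ])^2)), tolerance = 0.15)
  expect_error(digit_distance_metrics(mp[, 1, , drop = FALSE], ref), "2 digits|runs x 2")
})
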