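# Two-peak resolvability: the 80%-dip criterion, the minimum-resolvable-
# distance search, the repeated resolution study and the peak-coordinate
# statistics used when comparing digit representations.

#' Resolvability criterion
#'
#' Two image peaks count as resolved when the local minimum between them is
#' at most `dip_ratio` times the larger peak height (inclusive).
#'
#' @param dip_ratio fraction in (0, 1); default 0.8.
#' @return object of class `resolution_criterion`.
#' @export
resolution_criterion <- function(dip_ratio = 0.8) {
  if (!(dip_ratio > 0 && dip_ratio < 1)) stop("dip_ratio must lie in (0, 1)")
  structure(list(dip_ratio = dip_ratio), class = "resolution_criterion")
}

#' Scan points along the line joining two sources
#'
#' Evenly spaced points from `margin` before `a` to `margin` beyond `b`
#' along the `a` to `b` direction, ordered by position. The line coordinate
#' `s` is zero at `a`.
#'
#' @param a,b 3-vectors (metres); must not coincide.
#' @param margin metres beyond each endpoint (default 0.01).
#' @param step spacing in metres (default 5e-4).
#' @return list with `points` (n x 3), `s` (line coordinate), `a`, `dir`.
#' @export
line_points <- function(a, b, margin = 0.01, step = 5e-4) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (step <= 0) stop("step must be positive")
  if (margin < 0) stop("margin must be non-negative")
  d <- sqrt(sum((b - a)^2))
  if (d < step) stop("endpoints coincide (separation below one step)")
  dir <- (b - a) / d
  s <- seq(-margin, d + margin, by = step)
  pts <- matrix(a, length(s), 3, byrow = TRUE) + outer(s, dir)
  list(points = pts, s = s, a = a, dir = dir)
}

#' One-dimensional beamformer image along a source-pair line
#'
#' @param image_fn function taking an n x 3 matrix of scan points and
#'   returning one image value per point (or a `source_image`).
#' @inheritParams line_points
#' @param statistic_kind label stored on the image.
#' @return a `source_image` with the line coordinate in `$s` and the line
#'   geometry in `attr(, "line")`.
#' @export
line_profile <- function(image_fn, a, b, margin = 0.01, step = 5e-4,
                         statistic_kind = "pseudo_z") {
  lp <- line_points(a, b, margin, step)
  v <- image_fn(lp$points)
  if (inherits(v, "source_image")) v <- v$values
  img <- source_image(v, lp$points, statistic_kind, s = lp$s)
  attr(img, "line") <- list(a = lp$a, dir = lp$dir)
  img
}

# interior local maxima indices (strict rise, non-strict fall handles flats)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

project_on_line <- function(img, x) {
  ln <- attr(img, "line")
  if (is.null(ln)) stop("profile carries no line geometry")
  sum((as.numeric(x) - ln$a) * ln$dir)
}

#' Apply the dip criterion to one or two line profiles
#'
#' Two-image methods are reduced to a single composite profile by pointwise
#' maximum; the two highest local maxima are then located, each is required
#' to lie nearer its own expected source than the other's, and the pair is
#' resolved when the minimum of the composite between the peaks is at most
#' `dip_ratio` of the larger peak height.
#'
#' @param profiles a `source_image` or list of one/two sharing scan points.
#' @param criterion a [resolution_criterion()].
#' @param expected_locations 2 x 3 matrix (or list of two 3-vectors) of the
#'   true source positions.
#' @return list with `resolved` (logical) and diagnostics: `peak_s`,
#'   `peak_heights`, `dip_value`, `dip_fraction`, `reason`.
#' @export
is_resolved <- function(profiles, criterion = resolution_criterion(),
                        expected_locations) {
  if (inherits(profiles, "source_image")) profiles <- list(profiles)
  s <- profiles[[1]]$s
  for (p in profiles) if (!identical(p$s, s))
    stop("profiles must share scan points")
  v <- Reduce(pmax, lapply(profiles, `[[`, "values"))
  exp_loc <- rbind3(if (is.list(expected_locations))
    do.call(rbind, expected_locations) else expected_locations)
  se <- sort(c(project_on_line(profiles[[1]], exp_loc[1, ]),
               project_on_line(profiles[[1]], exp_loc[2, ])))
  out <- function(res, reason, ps = NULL, ph = NULL, dip = NA_real_)
    list(resolved = res, peak_s = ps, peak_heights = ph, dip_value = dip,
         dip_fraction = if (is.na(dip) || is.null(ph)) NA_real_ else dip / max(ph),
         reason = reason)
  mx <- local_maxima(v)
  if (length(mx) < 2L) return(out(FALSE, "fewer than 2 local maxima"))
  top <- mx[order(v[mx], decreasing = TRUE)[1:2]]
  top <- sort(top)
  ps <- s[top]; ph <- v[top]
  near <- abs(ps[1] - se[1]) < abs(ps[1] - se[2]) &&
    abs(ps[2] - se[2]) < abs(ps[2] - se[1])
  if (!near) return(out(FALSE, "peaks not adjacent to the expected sources",
                        ps, ph))
  dip <- min(v[top[1]:top[2]])
  res <- dip <= criterion$dip_ratio * max(ph)
  out(res, if (res) "dip criterion met" else "dip above threshold", ps, ph, dip)
}

snr_noise_ft <- c(low = 36, medium = 21, high = 8)

#' Resolution-study configuration
#'
#' Bundles the geometry, paradigm, noise condition and search schedule of
#' the two-source minimum-separation study. Defaults reproduce the headline
#' simulation: 275-channel helmet of radius 12 cm, head ellipsoid with
#' semi-axes (9, 7, 6.5) cm shrunk by 1.5 cm, 31 +/- 3 nAm boxcar sources,
#' 44 trials of 20 s at 600 Hz, d from 30 mm in 0.5 mm steps, 80% dip.
#'
#' @param n_repeats number of random source-pair placements.
#' @param d_start,d_step starting separation and lattice step, metres.
#' @param snr_condition `"low"`, `"medium"` or `"high"` (36 / 21 / 8 fT
#'   per-sample Gaussian sensor noise).
#' @param methods subset of `c(1, 2, 3)`.
#' @param seed master seed; every random draw in the study derives from it.
#' @param search `"sequential"` (reduce d by d_step until the first
#'   failure) or `"bisection"` (same lattice, assumes monotonicity).
#' @param dip_ratio dip criterion fraction.
#' @param margin,profile_step line-profile geometry, metres.
#' @param amplitude_mean,amplitude_sd source strength model, nAm
#'   (broadband; the in-band fraction enters the band-limited covariance).
#' @param trial_length,sampling_rate,n_trials paradigm scale.
#' @param band analysis band for covariance estimation, Hz (default beta,
#'   `c(13, 30)`); `NULL` for broadband. Band-limited covariance is
#'   simulated through the degrees-of-freedom equivalence: white data at an
#'   effective sampling rate of `2 * BW` Hz (so a 10 s half-window of 44
#'   trials carries `2 * BW * 10 * 44` effective samples) with the source
#'   scaled to its in-band amplitude fraction `sqrt(BW / (fs/2))`. Noise
#'   amplitudes are per-sample SDs within the band.
#' @param orientation scan orientation mode for imaging.
#' @param retry_cap placements re-drawn per repeat before giving up.
#' @param geometry optional list(sensors, head_surface, source_surface,
#'   head) overriding [default_geometry()].
#' @return object of class `study_config`.
#' @export
study_config <- function(n_repeats = 50, d_start = 0.030, d_step = 5e-4,
                         snr_condition = c("medium", "low", "high"),
                         methods = c(1, 2, 3), seed = 1L,
                         search = c("bisection", "sequential"),
                         dip_ratio = 0.8, margin = 0.01, profile_step = 5e-4,
                         amplitude_mean = 31, amplitude_sd = 3,
                         trial_length = 20, sampling_rate = 600,
                         n_trials = 44, band = c(13, 30),
                         orientation = "optimal",
                         retry_cap = 10L, geometry = NULL) {
  snr_condition <- match.arg(snr_condition)
  search <- match.arg(search)
  if (!(d_start > d_step && d_step > 0))
    stop("need d_start > d_step > 0")
  if (!all(methods %in% 1:3)) stop("methods must be a subset of 1:3")
  if (is.null(geometry)) geometry <- default_geometry()
  if (is.null(band)) {
    paradigm_eff <- paradigm(trial_length, sampling_rate, n_trials)
    amp_scale <- 1
  } else {
    bw <- diff(as.numeric(band))
    if (bw <= 0 || band[2] >= sampling_rate / 2)
      stop("band must lie inside (0, Nyquist)")
    paradigm_eff <- paradigm(trial_length, 2 * bw, n_trials)
    amp_scale <- sqrt(bw / (sampling_rate / 2))
  }
  structure(list(n_repeats = as.integer(n_repeats), d_start = d_start,
                 d_step = d_step, snr_condition = snr_condition,
                 noise_ft = unname(snr_noise_ft[snr_condition]),
                 methods = as.integer(methods), seed = as.integer(seed),
                 search = search, criterion = resolution_criterion(dip_ratio),
                 margin = margin, profile_step = profile_step,
                 amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
                 paradigm = paradigm(trial_length, sampling_rate, n_trials),
                 band = band, paradigm_eff = paradigm_eff,
                 amp_scale = amp_scale,
                 orientation = orientation, retry_cap = as.integer(retry_cap),
                 geometry = geometry),
            class = "study_config")
}

#' Default study geometry
#'
#' 275-channel helmet on a 12 cm upper hemisphere, head ellipsoid with
#' semi-axes (0.09, 0.07, 0.065) m at the origin, source surface shrunk by
#' 1.5 cm, and a multiple-local-spheres conductor model fitted to the head
#' surface.
#'
#' @param n_channels,helmet_radius,coverage helmet parameters.
#' @param semi_axes head ellipsoid semi-axes, metres.
#' @param depth source-surface shrink depth, metres.
#' @param head_mode `"local_spheres"` or `"single_sphere"`.
#' @return list with `sensors`, `head_surface`, `source_surface`, `head`.
#' @export
default_geometry <- function(n_channels = 275, helmet_radius = 0.12,
                             coverage = 0.5,
                             semi_axes = c(0.09, 0.07, 0.065),
                             depth = 0.015,
                             head_mode = c("local_spheres", "single_sphere")) {
  head_mode <- match.arg(head_mode)
  sensors <- make_helmet_array(n_channels, helmet_radius, coverage, seed = 1L)
  head_surface <- ellipsoid_surface(c(0, 0, 0), semi_axes)
  source_surface <- shrink_surface(head_surface, depth)
  head <- fit_local_spheres(head_surface, sensors, mode = head_mode)
  list(sensors = sensors, head_surface = head_surface,
       source_surface = source_surface, head = head)
}

# symmetric pair on the surface: chord distance d about midpoint along tdir
place_pair <- function(surface, midpoint, tdir, d) {
  p <- function(s) as.numeric(project_to_ellipsoid(surface, midpoint + s * tdir))
  f <- function(s) sqrt(sum((p(s) - p(-s))^2)) - d
  hi <- d
  while (f(hi) < 0 && hi < 0.3) hi <- hi * 1.5
  if (f(hi) < 0) stop("cannot place sources ", d, " m apart on the surface")
  s <- stats::uniroot(f, c(d / 8, hi), tol = 1e-9)$root
  list(a = p(-s), b = p(s))
}

# One study repeat: shared placement, shared per-d covariance draws, one
# minimum distance per method. Covariances and profiles are cached on the
# d lattice so methods probing the same d reuse identical data.
study_repeat <- function(cfg, rep_idx) {
  geo <- cfg$geometry
  noise_sd <- cfg$noise_ft * FT
  v2 <- noise_sd^2
  k_start <- round(cfg$d_start / cfg$d_step)
  for (attempt in seq_len(cfg$retry_cap)) {
    set.seed(derive_seed(cfg$seed, rep_idx, attempt, 11L))
    # placements cover the whole source surface; pairs that cannot be
    # resolved even at d_start (e.g. far below the helmet rim) fail the
    # search precondition and are re-drawn, up to retry_cap
    midpoint <- as.numeric(sample_ellipsoid(geo$source_surface, 1))
    tdir <- tangential_orientation(geo$source_surface, midpoint,
                                   runif(1, 0, 2 * pi))
    az <- runif(2, 0, 2 * pi)
    cache <- new.env(parent = emptyenv())
    eval_d <- function(k) {
      key <- sprintf("d%d", k)
      if (!is.null(cache[[key]])) return(cache[[key]])
      d <- k * cfg$d_step
      pp <- place_pair(geo$source_surface, midpoint, tdir, d)
      srcs <- list(surface_dipole(geo$source_surface, pp$a, az[1],
                                  cfg$amplitude_mean, cfg$amplitude_sd),
                   surface_dipole(geo$source_surface, pp$b, az[2],
                                  cfg$amplitude_mean, cfg$amplitude_sd))
      B <- vapply(srcs, function(s) forward_field(s, geo$head, geo$sensors),
                  numeric(nrow(geo$sensors$positions)))
      cov <- sample_window_covariances(B, cfg$paradigm_eff,
                                       cfg$amplitude_mean * cfg$amp_scale,
                                       cfg$amplitude_sd * cfg$amp_scale,
                                       noise_sd,
                                       seed = derive_seed(cfg$seed, rep_idx, 17L, k))
      lp <- line_points(srcs[[1]]$position, srcs[[2]]$position,
                        cfg$margin, cfg$profile_step)
      cache[[key]] <- list(srcs = srcs, cov = cov, lp = lp)
      cache[[key]]
    }
    resolved_at <- function(k, method) {
      key <- sprintf("r%d_%d", k, method)
      if (!is.null(cache[[key]])) return(cache[[key]])
      e <- eval_d(k)
      imgs <- images_from_cov(e$cov$C, e$cov$C1, e$cov$C2, e$lp$points,
                              geo$head, geo$sensors, method, v2,
                              cfg$orientation, s = e$lp$s)
      imgs <- lapply(imgs, function(im) {
        attr(im, "line") <- list(a = e$lp$a, dir = e$lp$dir); im
      })
      chk <- is_resolved(imgs, cfg$criterion,
                         rbind(e$srcs[[1]]$position, e$srcs[[2]]$position))
      cache[[key]] <- chk$resolved
      chk$resolved
    }
    ok_start <- all(vapply(cfg$methods, function(m) resolved_at(k_start, m),
                           logical(1)))
    if (!ok_start) next
    dist <- vapply(cfg$methods, function(m) {
      if (cfg$search == "sequential") {
        k <- k_start
        while (k > 1L && resolved_at(k - 1L, m)) k <- k - 1L
        k * cfg$d_step
      } else {
        lo <- 0L; hi <- k_start                  # hi resolved, lo not
        while (hi - lo > 1L) {
          mid <- (hi + lo) %/% 2L
          if (resolved_at(mid, m)) hi <- mid else lo <- mid
        }
        hi * cfg$d_step
      }
    }, numeric(1))
    return(list(distances = dist, methods = cfg$methods,
                midpoint = midpoint, attempt = attempt))
  }
  stop("repeat ", rep_idx, ": no placement resolved at d_start after ",
       cfg$retry_cap, " attempts; increase d_start")
}

#' Minimum resolvable source separation for one placement
#'
#' Starting from `d_start`, the separation is reduced on the `d_step`
#' lattice (sequentially or by bisection); for each separation a fresh
#' covariance realisation is drawn with the sources moved symmetrically
#' about the placement midpoint along the surface, imaged, and tested with
#' the dip criterion. Returns the smallest separation still resolved.
#'
#' @param config a [study_config()].
#' @param method 1, 2 or 3.
#' @param repeat_index which placement stream to use (>= 1).
#' @return distance in mm.
#' @export
min_resolvable_distance <- function(config, method = 1, repeat_index = 1) {
  cfg <- config
  cfg$methods <- as.integer(method)
  r <- study_repeat(cfg, repeat_index)
  unname(r$distances[1] * 1e3)
}

#' Run the repeated two-source resolution study
#'
#' For each repeat a random source pair is placed on the source surface
#' (random tangential azimuths), and the minimum resolvable separation is
#' found independently for each beamformer method on shared placement and
#' noise streams, so method comparisons are paired. Summaries and paired
#' t-tests between methods are attached.
#'
#' @param config a [study_config()].
#' @param progress print one line per repeat?
#' @return object of class `resolution_result`: `table` (one row per repeat
#'   x method), `summary` (per-method mean/SD in mm), `tests` (paired
#'   t-tests between method pairs), `config`.
#' @export
resolution_study <- function(config, progress = FALSE) {
  rows <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    rep_res <- study_repeat(config, r)
    rows[[r]] <- data.frame(repeat_index = r, method = rep_res$methods,
                            min_distance_mm = rep_res$distances * 1e3,
                            attempt = rep_res$attempt)
    if (progress)
      message(sprintf("repeat %d/%d: %s", r, config$n_repeats,
                      paste(sprintf("m%d=%.1fmm", rep_res$methods,
                                    rep_res$distances * 1e3), collapse = " ")))
  }
  tab <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(tab, tab$method), function(g)
    data.frame(method = g$method[1], mean_mm = mean(g$min_distance_mm),
               sd_mm = sd(g$min_distance_mm), n = nrow(g))))
  tests <- NULL
  ms <- sort(unique(tab$method))
  if (length(ms) > 1 && config$n_repeats > 1) {
    pairs <- utils::combn(ms, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      da <- tab$min_distance_mm[tab$method == a]
      db <- tab$min_distance_mm[tab$method == b]
      tt <- paired_t(da, db)
      data.frame(method_a = a, method_b = b, mean_diff_mm = tt$mean,
                 t = tt$t, p_two_sided = tt$p_two,
                 p_one_sided_a_greater = tt$p_greater)
    }))
  }
  structure(list(table = tab, summary = sm, tests = tests, config = config),
            class = "resolution_result")
}

#' @export
print.resolution_result <- function(x, ...) {
  cat("<resolution_result>", x$config$n_repeats, "repeats,",
      x$config$snr_condition, "SNR\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# paired t with degenerate-case handling (zero-variance differences)
paired_t <- function(a, b, mu = 0) {
  d <- a - b
  n <- length(d)
  if (n < 2L) stop("paired test needs at least 2 runs")
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    if (m == mu) return(list(mean = m, t = 0, p_two = 1, p_greater = 0.5))
    t <- sign(m - mu) * Inf
    return(list(mean = m, t = t, p_two = 0,
                p_greater = if (m > mu) 0 else 1))
  }
  t <- (m - mu) / (s / sqrt(n))
  list(mean = m, t = t, p_two = 2 * stats::pt(-abs(t), n - 1),
       p_greater = stats::pt(t, n - 1, lower.tail = FALSE))
}

#' Paired statistics of peak coordinates along one axis
#'
#' One-sided paired t-test of whether the `peaksB` coordinates exceed (or
#' fall below) the `peaksA` coordinates along the chosen axis, as used to
#' test a superior shift of one digit representation over another.
#'
#' @param peaksA,peaksB runs x 3 matrices of peak coordinates (metres or
#'   mm; units propagate).
#' @param axis coordinate index (3 = z, foot-to-head).
#' @param direction `"greater"` tests B > A along the axis, `"less"` the
#'   reverse.
#' @return list with `mean_separation`, `sd_separation`, `t`, `p`,
#'   `euclidean_separation` (distance of the mean peaks), `n`.
#' @export
peak_coordinate_stats <- function(peaksA, peaksB, axis = 3,
                                  direction = c("greater", "less")) {
  direction <- match.arg(direction)
  peaksA <- rbind3(peaksA); peaksB <- rbind3(peaksB)
  if (nrow(peaksA) != nrow(peaksB))
    stop("peak sets must have equal run counts")
  if (nrow(peaksA) < 2L) stop("need at least 2 runs")
  tt <- paired_t(peaksB[, axis], peaksA[, axis])
  p <- if (direction == "greater") tt$p_greater else 1 - tt$p_greater
  list(mean_separation = tt$mean,
       sd_separation = sd(peaksB[, axis] - peaksA[, axis]),
       t = tt$t, p = p,
       euclidean_separation = sqrt(sum((colMeans(peaksB) - colMeans(peaksA))^2)),
       n = nrow(peaksA))
}

#' Corresponding and alternate digit distances
#'
#' For each run and digit, the distance from the measured peak to the
#' same-digit reference peak ("corresponding") and to the other digit's
#' reference ("alternate"), pooled over digits, with a one-sided paired
#' t-test that corresponding < alternate.
#'
#' @param meg_peaks runs x 2 x 3 array (or list of 2 x 3 matrices), one
#'   peak per digit per run.
#' @param reference_peaks 2 x 3 matrix of reference (e.g. fMRI) peaks.
#' @return list with `corresponding`, `alternate` (runs x 2 matrices),
#'   their means, and `t`, `p` for corresponding < alternate.
#' @export
digit_distance_metrics <- function(meg_peaks, reference_peaks) {
  if (is.list(meg_peaks))
    meg_peaks <- aperm(simplify2array(meg_peaks), c(3, 1, 2))
  if (length(dim(meg_peaks)) != 3L || dim(meg_peaks)[2] != 2L)
    stop("meg_peaks must be runs x 2 digits x 3 coordinates")
  reference_peaks <- rbind3(reference_peaks)
  if (nrow(reference_peaks) != 2L) stop("two reference peaks required")
  nr <- dim(meg_peaks)[1]
  if (nr < 2L) stop("need at least 2 runs")
  dst <- function(r, d, ref) sqrt(sum((meg_peaks[r, d, ] - reference_peaks[ref, ])^2))
  corr <- alt <- matrix(NA_real_, nr, 2)
  for (r in seq_len(nr)) for (d in 1:2) {
    corr[r, d] <- dst(r, d, d)
    alt[r, d] <- dst(r, d, 3 - d)
  }
  tt <- paired_t(as.numeric(alt), as.numeric(corr))
  list(corresponding = corr, alternate = alt,
       mean_corresponding = mean(corr), mean_alternate = mean(alt),
       t = tt$t, p = tt$p_greater)
}
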