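# Serialisation: geometry sidecars (JSON), profiles and study tables (TSV),
# study summaries (JSON), volumetric images (NIfTI-1), experiment configs
# (YAML) and dataset containers (RDS with provenance attributes).

#' Write / read a sensor-array JSON sidecar
#'
#' Plain-text channel layout: name, position (m), orientation, one record
#' per channel.
#'
#' @param sensors a [sensor_array()].
#' @param path file path.
#' @return `read_sensor_array` returns a [sensor_array()].
#' @export
write_sensor_array <- function(sensors, path) {
  recs <- lapply(seq_along(sensors$names), function(i)
    list(name = sensors$names[i],
         position = as.numeric(sensors$positions[i, ]),
         orientation = as.numeric(sensors$orientations[i, ])))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensor_array
#' @export
read_sensor_array <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE)
  sensor_array(do.call(rbind, recs$position),
               do.call(rbind, recs$orientation), recs$name)
}

#' Write a line profile to TSV
#'
#' Columns: line coordinate `s_mm`, scan-point coordinates (m), statistic
#' value, one block per image (column `image`).
#'
#' @param profiles a `source_image` or list of them.
#' @param path file path.
#' @param extra named scalar columns replicated on every row (e.g.
#'   `resolved` flag, `analytic` flag).
#' @export
write_profile_tsv <- function(profiles, path, extra = list()) {
  if (inherits(profiles, "source_image")) profiles <- list(profiles)
  tabs <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    df <- data.frame(image = i,
                     s_mm = if (is.null(p$s)) NA_real_ else p$s * 1e3,
                     x = p$scan_points[, 1], y = p$scan_points[, 2],
                     z = p$scan_points[, 3], value = p$values,
                     statistic = p$statistic_kind)
    for (nm in names(extra)) df[[nm]] <- extra[[nm]]
    df
  })
  write.table(do.call(rbind, tabs), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write resolution-study outputs
#'
#' `write_study_tsv` writes one row per repeat x method;
#' `write_study_json` writes the summary (per-method means/SDs and paired
#' tests) plus config provenance (seed, SNR condition, schedule).
#'
#' @param result a `resolution_result`.
#' @param path file path.
#' @export
write_study_tsv <- function(result, path) {
  write.table(result$table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_study_tsv
#' @export
write_study_json <- function(result, path) {
  cfg <- result$config
  jsonlite::write_json(
    list(summary = result$summary, tests = result$tests,
         config = list(n_repeats = cfg$n_repeats, seed = cfg$seed,
                       snr_condition = cfg$snr_condition,
                       d_start_mm = cfg$d_start * 1e3,
                       d_step_mm = cfg$d_step * 1e3,
                       dip_ratio = cfg$criterion$dip_ratio,
                       methods = cfg$methods, search = cfg$search)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export a gridded source image as NIfTI-1
#'
#' @param image a `source_image` whose points came from [make_scan_grid()].
#' @param grid the grid used to build it.
#' @param path output path (`.nii` / `.nii.gz`).
#' @export
write_image_nifti <- function(image, grid, path) {
  vol <- array(image$values, dim = grid$dims)
  img <- RNifti::asNifti(vol)
  sp <- grid$spacing * 1e3                      # mm
  or <- grid$origin * 1e3
  xf <- rbind(cbind(diag(sp, 3), or), c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a dataset container
#'
#' RDS container holding the epoched array plus provenance (seed and a hash
#' of the generating configuration).
#'
#' @param dataset a `sensor_dataset`.
#' @param path file path (`.rds`).
#' @param config optional generating configuration stored alongside.
#' @export
write_dataset <- function(dataset, path, config = NULL) {
  attr(dataset, "config") <- config
  attr(dataset, "config_hash") <- config_hash(config)
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) readRDS(path)

#' Export single trials as TSV
#'
#' @param dataset a `sensor_dataset`.
#' @param path file path.
#' @param trials which trials to export.
#' @export
write_trials_tsv <- function(dataset, path, trials = 1L) {
  fs <- dataset$paradigm$sampling_rate
  rows <- lapply(trials, function(tr) {
    X <- dataset$data[tr, , ]
    df <- as.data.frame(t(X))
    names(df) <- dataset$sensors$names
    cbind(trial = tr, time_s = (seq_len(ncol(X)) - 1) / fs, df)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

# stable hash of a configuration list (content-based, no external deps)
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  txt <- paste(deparse(config), collapse = "")
  # polynomial rolling hash over the serialised text (stays inside 2^31)
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Experiment configuration
#'
#' Reads, validates and normalises a YAML experiment configuration; every
#' block is optional and falls back to the package defaults (the headline
#' study conditions).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list merged over the file contents.
#' @return a validated configuration list with a `study_config` in
#'   `$study`, geometry in `$geometry`, and the raw list in `$raw`.
#' @export
load_experiment_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- modifyList(raw, overrides)
  g <- raw$geometry
  geometry <- default_geometry(
    n_channels = g$n_channels %||% 275,
    helmet_radius = g$helmet_radius %||% 0.12,
    coverage = g$coverage %||% 0.5,
    semi_axes = unlist(g$semi_axes) %||% c(0.09, 0.07, 0.065),
    depth = g$depth %||% 0.015,
    head_mode = g$head_mode %||% "local_spheres")
  st <- raw$study
  pz <- raw$paradigm
  bad <- setdiff(names(raw), c("geometry", "study", "paradigm", "noise",
                               "output", "seed"))
  if (length(bad)) stop("unknown config block: ", bad[1])
  study <- study_config(
    n_repeats = st$n_repeats %||% 50,
    d_start = st$d_start %||% 0.030,
    d_step = st$d_step %||% 5e-4,
    snr_condition = raw$noise$snr_condition %||% "medium",
    methods = unlist(st$methods) %||% c(1, 2, 3),
    seed = raw$seed %||% 1L,
    search = st$search %||% "bisection",
    dip_ratio = st$dip_ratio %||% 0.8,
    amplitude_mean = pz$amplitude_mean %||% 31,
    amplitude_sd = pz$amplitude_sd %||% 3,
    trial_length = pz$trial_length %||% 20,
    sampling_rate = pz$sampling_rate %||% 600,
    n_trials = pz$n_trials %||% 44,
    retry_cap = st$retry_cap %||% 10L,
    geometry = geometry)
  list(study = study, geometry = geometry, seed = raw$seed %||% 1L,
       output = raw$output, raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
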