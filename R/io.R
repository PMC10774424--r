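#' Write a behavioral session to disk
#'
#' Tracking goes to a comma-separated table with header
#' `t,x,y,heading_deg` (units s, cm, cm, deg); the trial schedule,
#' ground-truth bouts, and session metadata go to a JSON sidecar
#' (`<path>.json`).
#'
#' @param session A `behavior_session`.
#' @param path CSV path for the tracking table.
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "behavior_session"))
  if (is.null(session$tracking)) {
    abort("session has no tracking table (simulated with include_tracking = FALSE)")
  }
  readr::write_csv(session$tracking, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(fish_id = session$fish_id,
         condition_label = session$condition_label,
         washout_h = session$washout_h,
         seed = session$seed,
         sample_rate_hz = session$protocol$sample_rate_hz,
         trials = session$trials,
         truth_bouts = session$bouts),
    sidecar, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(path, sidecar))
}

#' Read a behavioral session written by [write_session()]
#'
#' @param path CSV path of the tracking table (JSON sidecar expected at
#'   `<path>.json`).
#' @param protocol Optional [behavior_protocol()] to attach; defaults to the
#'   standard protocol with the sidecar's sample rate.
#' @return A `behavior_session` (without generator parameters).
#' @export
read_session <- function(path, protocol = NULL) {
  tracking <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trials <- as_tibble(meta$trials)
  bouts <- as_tibble(meta$truth_bouts)
  if (is.null(protocol)) {
    protocol <- behavior_protocol(sample_rate_hz = meta$sample_rate_hz)
  }
  structure(
    list(fish_id = meta$fish_id,
         condition_label = meta$condition_label,
         washout_h = if (is.null(meta$washout_h)) NA_real_
                     else meta$washout_h,
         seed = meta$seed,
         protocol = protocol,
         params = NULL,
         trials = trials,
         tracking = as_tibble(tracking),
         bouts = bouts),
    class = "behavior_session"
  )
}

#' Write unit traces as a long comma-separated table
#'
#' Columns `unit_id, t, f`; the block schedule goes to a JSON sidecar and
#' ground-truth unit parameters (synthetic data only) to
#' `<path>.truth.json`.
#'
#' @param population A `unit_population`.
#' @param path CSV path.
#' @return Invisibly, the paths written.
#' @export
write_traces <- function(population, path) {
  stopifnot(inherits(population, "unit_population"))
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(t = population$frames$t),
                     as_tibble(population$f)),
    -"t", names_to = "unit_id", values_to = "f")
  readr::write_csv(select(long, "unit_id", "t", "f"), path)
  jsonlite::write_json(population$schedule, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(population$units, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(path, paste0(path, ".json"), paste0(path, ".truth.json")))
}

#' Read unit traces written by [write_traces()]
#'
#' @param path CSV path.
#' @param protocol An [imaging_protocol()].
#' @return A `unit_population` (truth parameters attached when the sidecar
#'   exists).
#' @export
read_traces <- function(path, protocol = imaging_protocol()) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  schedule <- as_tibble(jsonlite::read_json(paste0(path, ".json"),
                                            simplifyVector = TRUE))
  truth_path <- paste0(path, ".truth.json")
  units <- if (file.exists(truth_path)) {
    as_tibble(jsonlite::read_json(truth_path, simplifyVector = TRUE))
  } else {
    tibble(unit_id = unique(long$unit_id))
  }
  wide <- tidyr::pivot_wider(long, names_from = "unit_id",
                             values_from = "f")
  f <- as.matrix(wide[, setdiff(names(wide), "t")])
  pop <- simulate_skeleton_population(f, schedule, protocol)
  pop$units <- units
  pop
}

# rebuild the frames annotation for a trace matrix aligned to a schedule
simulate_skeleton_population <- function(f, schedule, protocol) {
  nf_trial <- as.integer(round(protocol$trial_s * protocol$frame_rate_hz))
  n_frames <- nrow(f)
  stopifnot(n_frames == nrow(schedule) * nf_trial)
  f_pre <- as.integer(round(protocol$static_pre_s * protocol$frame_rate_hz))
  f_mot <- as.integer(round(protocol$motion_s * protocol$frame_rate_hz))
  frame0 <- seq_len(n_frames) - 1
  ti <- frame0 %/% nf_trial + 1L
  fit <- frame0 %% nf_trial
  frames <- tibble(
    frame = frame0,
    t = frame0 / protocol$frame_rate_hz,
    block = schedule$block[ti],
    block_label = schedule$block_label[ti],
    trial = schedule$trial[ti],
    frame_in_trial = fit,
    phase = ifelse(fit < f_pre, "pre",
                   ifelse(fit < f_pre + f_mot, "motion", "post")),
    stimulus = schedule$stimulus[ti],
    washout_min = schedule$washout_min[ti] +
      fit / protocol$frame_rate_hz / 60
  )
  structure(list(f = f, frames = frames, units = NULL, schedule = schedule,
                 protocol = protocol, seed = NA_integer_),
            class = "unit_population")
}

#' Convert a unit population to a long segmented tibble
#'
#' One row per unit and frame, with all trial annotations; the input format
#' of [trial_responses()] and [trial_average()].
#'
#' @param population A `unit_population`.
#' @param units Optional subset of unit ids.
#' @return A long tibble (`unit_id`, `t`, `f`, plus annotations).
#' @export
population_frames <- function(population, units = NULL) {
  ids <- colnames(population$f)
  if (!is.null(units)) ids <- intersect(ids, units)
  purrr::map_dfr(ids, function(u) {
    mutate(population$frames, unit_id = u, f = population$f[, u])
  }) |>
    select("unit_id", "t", "f", dplyr::everything())
}

#' Read or write protocol and parameter configuration as YAML
#'
#' @param config A named list (e.g. `list(protocol = behavior_protocol(),
#'   params = fish_params())`); classed objects are stored as plain lists
#'   with a `class` field and restored on read.
#' @param path YAML file path.
#' @return `write_config`: invisibly, the path. `read_config`: the list with
#'   classes restored.
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    if (inherits(x, c("behavior_protocol", "fish_params",
                      "imaging_protocol", "unit_params"))) {
      out <- lapply(unclass(x), strip)
      out$.class <- class(x)[1]
      out
    } else if (is.data.frame(x)) {
      c(as.list(x), list(.df = TRUE))
    } else if (is.list(x)) {
      lapply(x, strip)
    } else {
      x
    }
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  restore <- function(x) {
    if (!is.list(x)) return(x)
    if (isTRUE(x$.df)) {
      return(as_tibble(x[setdiff(names(x), ".df")]))
    }
    cls <- x$.class
    x <- lapply(x[setdiff(names(x), ".class")], restore)
    if (!is.null(cls)) {
      ctor <- switch(cls,
                     behavior_protocol = behavior_protocol,
                     fish_params = fish_params,
                     imaging_protocol = imaging_protocol,
                     unit_params = unit_params,
                     NULL)
      if (!is.null(ctor)) {
        keep <- intersect(names(x), names(formals(ctor)))
        return(do.call(ctor, x[keep]))
      }
    }
    x
  }
  restore(yaml::read_yaml(path))
}

#' Tidy per-fish metrics table
#'
#' Long format (`fish_id, condition, metric, value`) for export.
#'
#' @param perf Per-fish summary rows from [session_performance()].
#' @return A long tibble.
#' @export
tidy_metrics <- function(perf) {
  tidyr::pivot_longer(
    perf,
    dplyr::where(is.numeric) & !dplyr::any_of("washout_h"),
    names_to = "metric", values_to = "value") |>
    select("fish_id", "condition", "metric", "value")
}
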