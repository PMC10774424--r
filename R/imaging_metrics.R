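#' Segment a fluorescence trace into trials
#'
#' Aligns a 1 Hz trace to a block/stimulus schedule, annotating every frame
#' with its trial, within-trial frame index (0-based; frame `k` covers
#' `[k, k+1)` s, motion starts at trial frame 10 under the default protocol),
#' phase, block, stimulus, and washout time. Traces shorter than the schedule
#' are rejected; frames beyond the schedule are dropped.
#'
#' @param trace A data frame with columns `t` (seconds) and `f`
#'   (fluorescence), optionally `unit_id`.
#' @param schedule Schedule from [build_block_schedule()].
#' @param protocol An [imaging_protocol()].
#' @return A tibble with the trace columns plus `trial`, `frame_in_trial`,
#'   `phase`, `block`, `block_label`, `stimulus`, `washout_min`.
#' @export
segment_trials <- function(trace, schedule, protocol = imaging_protocol()) {
  stopifnot(is.data.frame(trace), all(c("t", "f") %in% names(trace)))
  nf_trial <- as.integer(round(protocol$trial_s * protocol$frame_rate_hz))
  n_needed <- nrow(schedule) * nf_trial
  n_per_unit <- if ("unit_id" %in% names(trace)) {
    min(table(trace$unit_id))
  } else {
    nrow(trace)
  }
  if (n_per_unit < n_needed) {
    abort(sprintf("trace has %d frames per unit but the schedule needs %d",
                  n_per_unit, n_needed))
  }
  f_pre <- as.integer(round(protocol$static_pre_s * protocol$frame_rate_hz))
  f_mot <- as.integer(round(protocol$motion_s * protocol$frame_rate_hz))
  idx_of <- function(t) as.integer(floor(t * protocol$frame_rate_hz))
  out <- trace |>
    mutate(.frame = idx_of(.data$t)) |>
    filter(.data$.frame < n_needed)
  ti <- out$.frame %/% nf_trial + 1L
  fit <- out$.frame %% nf_trial
  out |>
    mutate(trial = schedule$trial[ti],
           frame_in_trial = fit,
           phase = ifelse(fit < f_pre, "pre",
                          ifelse(fit < f_pre + f_mot, "motion", "post")),
           block = schedule$block[ti],
           block_label = schedule$block_label[ti],
           stimulus = schedule$stimulus[ti],
           washout_min = schedule$washout_min[ti] +
             fit / protocol$frame_rate_hz / 60) |>
    select(-".frame")
}

#' Baseline-subtracted trial response (C - C0)
#'
#' The trial's baseline `C0` is the mean fluorescence over the pre-motion
#' static frames; the response is the per-frame difference `C - C0` and its
#' scalar average over the averaging window. No division is performed
#' anywhere, so a zero baseline is valid input (the reason this metric is
#' used instead of dC/C0).
#'
#' @param frames_f Numeric vector of one trial's fluorescence frames in
#'   within-trial order.
#' @param n_baseline Number of pre-motion baseline frames. Default 10.
#' @param window `"trial"` (average over the entire trial, default) or
#'   `"motion"` (motion-window frames only).
#' @param n_motion Number of motion frames (used for `window = "motion"`).
#'   Default 30.
#' @return A list with `c0`, `c_minus_c0` (vector), and `trial_mean`. The
#'   mean of `c_minus_c0` over the baseline window is exactly 0.
#' @examples
#' compute_trial_response(c(rep(100, 10), rep(150, 30), rep(100, 20)))
#' @export
compute_trial_response <- function(frames_f, n_baseline = 10,
                                   window = c("trial", "motion"),
                                   n_motion = 30) {
  window <- match.arg(window)
  if (length(frames_f) < n_baseline) {
    abort(sprintf("need at least %d baseline frames", n_baseline))
  }
  c0 <- mean(frames_f[seq_len(n_baseline)])
  cmc0 <- frames_f - c0
  win <- if (window == "motion") {
    cmc0[(n_baseline + 1):min(length(cmc0), n_baseline + n_motion)]
  } else {
    cmc0
  }
  list(c0 = c0, c_minus_c0 = cmc0, trial_mean = mean(win))
}

#' Per-trial response summaries for segmented traces
#'
#' Applies the C - C0 metric to every (unit, trial) of a segmented trace
#' table: per-trial baseline `c0`, scalar `trial_mean` over the averaging
#' window, and the trial's maximum per-frame C - C0 (used by
#' [filter_fittable()]).
#'
#' @param segmented Output of [segment_trials()] (must contain `f`,
#'   `frame_in_trial`, `phase`, `trial`; `unit_id` optional).
#' @param window Averaging window, `"trial"` (entire trial, default) or
#'   `"motion"`.
#' @return A tibble with one row per unit and trial: `unit_id`, `trial`,
#'   `block`, `block_label`, `stimulus`, `washout_min` (value at trial
#'   start), `c0`, `trial_mean`, `max_cmc0`.
#' @export
trial_responses <- function(segmented, window = c("trial", "motion")) {
  window <- match.arg(window)
  if (!"unit_id" %in% names(segmented)) segmented$unit_id <- "u1"
  segmented |>
    group_by(.data$unit_id, .data$trial) |>
    arrange(.data$frame_in_trial, .by_group = TRUE) |>
    summarise(
      block = .data$block[1],
      block_label = .data$block_label[1],
      stimulus = .data$stimulus[1],
      washout_min = .data$washout_min[1],
      c0 = mean(.data$f[.data$phase == "pre"]),
      trial_mean = if (window == "motion") {
        mean(.data$f[.data$phase == "motion"]) -
          mean(.data$f[.data$phase == "pre"])
      } else {
        mean(.data$f) - mean(.data$f[.data$phase == "pre"])
      },
      max_cmc0 = max(.data$f) - mean(.data$f[.data$phase == "pre"]),
      .groups = "drop"
    ) |>
    arrange(.data$unit_id, .data$trial)
}

#' Per-unit responsiveness index series
#'
#' Normalizes each unit's per-trial average C - C0 by the unit's own maximum
#' absolute trial mean across all of its trials (the whole multi-hour
#' experiment), preserving sign. A unit with a net increase in responsiveness
#' thus peaks at exactly +1, and a net-decreasing (suppressed) unit at
#' exactly -1; all values lie in [-1, 1]. All-zero units are flagged
#' unresponsive and left at zero.
#'
#' @param responses Trial-response tibble from [trial_responses()] (needs
#'   `unit_id`, `trial`, `trial_mean`).
#' @return The input with columns `responsiveness` (normalized, in [-1, 1]),
#'   `net_sign` (sign of the summed trial means, per unit), and `unresponsive`
#'   (logical, per unit).
#' @examples
#' r <- tibble::tibble(unit_id = "u1", trial = 1:3, trial_mean = c(2, 4, -1))
#' responsiveness_index(r)$responsiveness  # 0.5, 1, -0.25
#' @export
responsiveness_index <- function(responses) {
  responses |>
    group_by(.data$unit_id) |>
    mutate(
      .max_abs = max(abs(.data$trial_mean)),
      responsiveness = if_else(.data$.max_abs > 0,
                               .data$trial_mean / .data$.max_abs, 0),
      net_sign = sign(sum(.data$trial_mean)),
      unresponsive = .data$.max_abs == 0
    ) |>
    ungroup() |>
    select(-".max_abs")
}

#' Per-unit direction-selectivity index series
#'
#' Matches subsequent trial pairs in which gratings moved first leftward,
#' then rightward (adjacent left-then-right pairs in schedule order,
#' skipping non-conforming adjacencies), takes the difference of the two
#' trials' average responses, and normalizes by the unit's maximum absolute
#' pair difference across the whole experiment. The result ranges from -1
#' (rightward-selective) to +1 (leftward-selective). Units whose schedule
#' holds no such pair return an empty series (flagged via the `n_pairs`
#' attribute of 0 rows).
#'
#' @param responses Trial-response tibble from [trial_responses()] (needs
#'   `unit_id`, `trial`, `stimulus`, `trial_mean`).
#' @return A tibble with one row per unit and pair: `unit_id`, `pair`,
#'   `trial_left`, `trial_right`, `block`, `block_label`, `washout_min`,
#'   `diff_raw`, `dsi`.
#' @examples
#' r <- tibble::tibble(unit_id = "u1", trial = 1:4,
#'                     stimulus = c("left", "right", "left", "right"),
#'                     trial_mean = c(2, 0, -2, 2),
#'                     block = 1, block_label = "baseline", washout_min = 0)
#' dsi_series(r)$dsi  # 0.5, -1
#' @export
dsi_series <- function(responses) {
  if (!"block" %in% names(responses)) responses$block <- NA_integer_
  if (!"block_label" %in% names(responses)) {
    responses$block_label <- NA_character_
  }
  if (!"washout_min" %in% names(responses)) {
    responses$washout_min <- NA_real_
  }
  out <- responses |>
    group_by(.data$unit_id) |>
    arrange(.data$trial, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      is_pair <- d$stimulus[-nrow(d)] == "left" & d$stimulus[-1] == "right"
      i <- which(is_pair)
      # non-overlapping pairs in schedule order
      if (length(i) > 1) {
        keep <- rep(TRUE, length(i))
        last <- -1L
        for (k in seq_along(i)) {
          if (i[k] <= last) keep[k] <- FALSE else last <- i[k] + 1L
        }
        i <- i[keep]
      }
      if (length(i) == 0) {
        return(tibble(pair = integer(), trial_left = integer(),
                      trial_right = integer(), block = integer(),
                      block_label = character(), washout_min = numeric(),
                      diff_raw = numeric(), dsi = numeric()))
      }
      diff_raw <- d$trial_mean[i] - d$trial_mean[i + 1]
      max_abs <- max(abs(diff_raw))
      tibble(pair = seq_along(i),
             trial_left = d$trial[i],
             trial_right = d$trial[i + 1],
             block = d$block[i],
             block_label = d$block_label[i],
             washout_min = d$washout_min[i],
             diff_raw = diff_raw,
             dsi = if (max_abs > 0) diff_raw / max_abs else rep(0, length(i)))
    }) |>
    ungroup()
  out
}

#' Filter units eligible for kinetics fitting
#'
#' Keeps units whose maximum per-frame C - C0 anywhere in the experiment
#' strictly exceeds the threshold (default 100 fluorescence units).
#'
#' @param responses Trial-response tibble from [trial_responses()] (needs
#'   `unit_id`, `max_cmc0`).
#' @param threshold Fluorescence threshold; strict `>`. Default 100.
#' @return A tibble `unit_id, max_cmc0, fittable`; filter on `fittable` or
#'   use `fittable_units()` for the kept ids.
#' @export
filter_fittable <- function(responses, threshold = 100) {
  responses |>
    group_by(.data$unit_id) |>
    summarise(max_cmc0 = max(.data$max_cmc0), .groups = "drop") |>
    mutate(fittable = .data$max_cmc0 > threshold)
}

#' @rdname filter_fittable
#' @export
fittable_units <- function(responses, threshold = 100) {
  ff <- filter_fittable(responses, threshold)
  ff$unit_id[ff$fittable]
}

#' Trial-averaged response of a unit
#'
#' Averages the per-frame C - C0 across a chosen subset of trials (typically
#' the preferred-direction trials of one block set), for kinetics fitting and
#' trial-average plots.
#'
#' @param segmented Segmented trace table ([segment_trials()]) for one or
#'   more units.
#' @param unit One `unit_id` (required if several are present).
#' @param trials Optional vector of trial numbers to include; defaults to
#'   all.
#' @param stimulus Optional stimulus filter (`"left"`/`"right"`).
#' @param n_baseline Baseline frames per trial. Default 10.
#' @return A tibble `frame_in_trial, phase, mean_cmc0, n_trials`.
#' @export
trial_average <- function(segmented, unit = NULL, trials = NULL,
                          stimulus = NULL, n_baseline = 10) {
  d <- segmented
  if (!"unit_id" %in% names(d)) d$unit_id <- "u1"
  if (!is.null(unit)) d <- filter(d, .data$unit_id == unit)
  if (length(unique(d$unit_id)) != 1) {
    abort("trial_average needs exactly one unit; pass `unit`")
  }
  if (!is.null(trials)) d <- filter(d, .data$trial %in% trials)
  if (!is.null(stimulus)) {
    stim <- stimulus
    d <- filter(d, .data$stimulus == stim)
  }
  d <- d |>
    group_by(.data$trial) |>
    arrange(.data$frame_in_trial, .by_group = TRUE) |>
    mutate(cmc0 = .data$f -
             mean(.data$f[.data$frame_in_trial < n_baseline])) |>
    ungroup()
  d |>
    group_by(.data$frame_in_trial, .data$phase) |>
    summarise(mean_cmc0 = mean(.data$cmc0),
              n_trials = dplyr::n(), .groups = "drop") |>
    arrange(.data$frame_in_trial)
}
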