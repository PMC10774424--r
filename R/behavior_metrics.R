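#' Turn-angle probability distribution
#'
#' Normalized histogram of signed bout turn angles over `[-180, 180)` with
#' left-closed, right-open bins. With zero bouts an empty-distribution marker
#' is returned (`n_bouts = 0`, zero rows) rather than NaNs.
#'
#' @param bouts Bout tibble with a `turn_angle_deg` column.
#' @param bin_width_deg Bin width in degrees. Default 5.
#' @return A tibble of class `turn_distribution` with columns `bin_left`,
#'   `bin_right`, `bin_mid` (degrees) and `probability`, and attribute
#'   `n_bouts`. Probabilities sum to 1 when any bout exists.
#' @examples
#' turn_distribution(tibble::tibble(turn_angle_deg = c(30, 30, -30, 0)),
#'                   bin_width_deg = 20)
#' @export
turn_distribution <- function(bouts, bin_width_deg = 5) {
  stopifnot(bin_width_deg > 0)
  edges <- seq(-180, 180, by = bin_width_deg)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  if (nrow(bouts) == 0) {
    out <- tibble(bin_left = numeric(), bin_right = numeric(),
                  bin_mid = numeric(), probability = numeric())
    attr(out, "n_bouts") <- 0L
    class(out) <- c("turn_distribution", class(out))
    return(out)
  }
  a <- pmin(pmax(bouts$turn_angle_deg, -180), 180 - 1e-9)
  counts <- tabulate(findInterval(a, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1)
  out <- tibble(bin_left = edges[-length(edges)],
                bin_right = edges[-1],
                bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
                probability = counts / sum(counts))
  attr(out, "n_bouts") <- nrow(bouts)
  class(out) <- c("turn_distribution", class(out))
  out
}

#' Proportion of correct turns
#'
#' A turn bout is "correct" when the sign of its turn angle matches the
#' stimulus direction (positive = leftward). Bouts with `|angle| <=
#' forward_band_deg` are counted as forward swims and excluded from the
#' denominator, as are exact-zero angles. The caller restricts `bouts` to
#' motion-phase bouts of one lateral stimulus (see [annotate_bouts()]).
#'
#' @param bouts Bout tibble with `turn_angle_deg`.
#' @param stimulus_label `"left"` or `"right"`.
#' @param forward_band_deg Half-width of the forward band in degrees.
#'   Default 10.
#' @return A one-row tibble: `n_correct`, `n_turns`, `proportion_correct`
#'   (`NA` when the denominator is empty).
#' @examples
#' b <- tibble::tibble(turn_angle_deg = c(20, 25, -18, 30))
#' proportion_correct(b, "left")
#' @export
proportion_correct <- function(bouts, stimulus_label = c("left", "right"),
                               forward_band_deg = 10) {
  stimulus_label <- match.arg(stimulus_label)
  ang <- bouts$turn_angle_deg
  turns <- ang[abs(ang) > forward_band_deg]
  stim_sign <- if (stimulus_label == "left") 1 else -1
  n_turns <- length(turns)
  n_correct <- sum(sign(turns) == stim_sign)
  tibble(n_correct = n_correct,
         n_turns = n_turns,
         proportion_correct = if (n_turns == 0) NA_real_
                              else n_correct / n_turns)
}

#' Bout frequency over a time window
#'
#' @param bouts Bout tibble with `t_on`.
#' @param window Numeric length-2 `c(t0, t1)` in seconds; only bouts with
#'   `t0 <= t_on < t1` are counted. Defaults to the span implied by the bouts
#'   themselves being pre-windowed, in which case `duration_s` must be given.
#' @param duration_s Total observed duration in seconds (overrides `window`
#'   width when the bouts are already restricted to the epoch of interest).
#' @return Frequency in Hz.
#' @examples
#' bout_frequency(tibble::tibble(t_on = runif(30, 0, 60)), window = c(0, 60))
#' @export
bout_frequency <- function(bouts, window = NULL, duration_s = NULL) {
  if (!is.null(window)) {
    stopifnot(length(window) == 2, diff(window) > 0)
    n <- sum(bouts$t_on >= window[1] & bouts$t_on < window[2])
    return(n / diff(window))
  }
  stopifnot(!is.null(duration_s), duration_s > 0)
  nrow(bouts) / duration_s
}

#' Cumulative turn angle over aligned trials
#'
#' For each fish, bouts of trials with the given stimulus are laid on a common
#' trial clock (time since trial start) and their signed turn angles are
#' accumulated across the session; the group summary is the median and
#' quartiles across fish on a common time grid.
#'
#' @param sessions A list of `behavior_session` objects, or a list of lists
#'   with elements `bouts` (annotated, see [annotate_bouts()]) and `fish_id`.
#' @param stimulus_label Stimulus to align on.
#' @param bin_s Time resolution of the common grid, seconds. Default 0.5.
#' @param use_truth Use ground-truth bouts (`TRUE`, default) or re-detect from
#'   tracking.
#' @return A list with `per_fish` (tibble `fish_id, t, cum_angle_deg`) and
#'   `summary` (tibble `t, median, q25, q75`).
#' @export
cumulative_turn_angle <- function(sessions, stimulus_label,
                                  bin_s = 0.5, use_truth = TRUE) {
  per_fish <- purrr::map_dfr(sessions, function(s) {
    b <- session_bouts(s, use_truth)
    b <- filter(b, .data$stimulus == stimulus_label)
    trial_s <- s$protocol$pre_static_s + s$protocol$motion_s +
      s$protocol$post_static_s
    grid <- seq(0, trial_s, by = bin_s)
    if (nrow(b) == 0) {
      return(tibble(fish_id = s$fish_id, t = grid, cum_angle_deg = 0))
    }
    tt <- b$t_on - s$trials$t_start[match(b$trial, s$trials$trial)]
    csum <- vapply(grid, function(g) sum(b$turn_angle_deg[tt < g]),
                   numeric(1))
    tibble(fish_id = s$fish_id, t = grid, cum_angle_deg = csum)
  })
  summary <- per_fish |>
    group_by(.data$t) |>
    summarise(median = stats::median(.data$cum_angle_deg),
              q25 = stats::quantile(.data$cum_angle_deg, 0.25, names = FALSE),
              q75 = stats::quantile(.data$cum_angle_deg, 0.75, names = FALSE),
              .groups = "drop")
  list(per_fish = per_fish, summary = summary)
}

#' Performance as a function of time during visual stimulation
#'
#' Pools motion-phase turn bouts by time since motion onset into half-open
#' bins `[k*bin_s, (k+1)*bin_s)`, computes per-fish proportion correct per
#' bin, and summarizes across fish with median and quartiles. Empty bins
#' propagate `NA` (no interpolation).
#'
#' @inheritParams cumulative_turn_angle
#' @param bin_s Bin width in seconds. Default 1.
#' @param forward_band_deg Forward-band half-width, degrees. Default 10.
#' @return A list with `per_fish` (tibble `fish_id, bin, t_mid,
#'   proportion_correct, n_turns`) and `summary` (tibble `bin, t_mid, median,
#'   q25, q75, n_fish`).
#' @export
performance_vs_time <- function(sessions, bin_s = 1, forward_band_deg = 10,
                                use_truth = TRUE) {
  stopifnot(bin_s > 0)
  per_fish <- purrr::map_dfr(sessions, function(s) {
    b <- session_bouts(s, use_truth)
    b <- filter(b, .data$phase == "motion",
                .data$stimulus %in% c("left", "right"),
                abs(.data$turn_angle_deg) > forward_band_deg)
    motion_s <- s$protocol$motion_s
    bins <- seq_len(ceiling(motion_s / bin_s)) - 1
    if (nrow(b) == 0) {
      return(tibble(fish_id = s$fish_id, bin = bins,
                    t_mid = (bins + 0.5) * bin_s,
                    proportion_correct = NA_real_, n_turns = 0L))
    }
    b$bin <- floor(b$t_since_motion_on / bin_s)
    b$correct <- sign(b$turn_angle_deg) ==
      if_else(b$stimulus == "left", 1, -1)
    agg <- b |>
      group_by(.data$bin) |>
      summarise(proportion_correct = mean(.data$correct),
                n_turns = dplyr::n(), .groups = "drop")
    out <- tibble(fish_id = s$fish_id, bin = bins,
                  t_mid = (bins + 0.5) * bin_s)
    left_join(out, agg, by = "bin") |>
      mutate(n_turns = if_else(is.na(.data$n_turns), 0L,
                               as.integer(.data$n_turns)))
  })
  summary <- per_fish |>
    group_by(.data$bin, .data$t_mid) |>
    summarise(median = stats::median(.data$proportion_correct, na.rm = TRUE),
              q25 = stats::quantile(.data$proportion_correct, 0.25,
                                    na.rm = TRUE, names = FALSE),
              q75 = stats::quantile(.data$proportion_correct, 0.75,
                                    na.rm = TRUE, names = FALSE),
              n_fish = sum(!is.na(.data$proportion_correct)),
              .groups = "drop")
  summary$median[summary$n_fish == 0] <- NA_real_
  list(per_fish = per_fish, summary = summary)
}

#' Performance as a function of trial ordinal
#'
#' Proportion of correct motion-phase turns per stimulus-set ordinal across
#' fish (all sessions must share the schedule length), summarized as median
#' and quartiles.
#'
#' @inheritParams performance_vs_time
#' @return A list with `per_fish` (tibble `fish_id, set, proportion_correct,
#'   n_turns`) and `summary` (tibble `set, median, q25, q75, n_fish`).
#' @export
performance_vs_trial <- function(sessions, forward_band_deg = 10,
                                 use_truth = TRUE) {
  n_sets <- vapply(sessions, function(s) s$protocol$n_sets, integer(1))
  if (length(unique(n_sets)) != 1) {
    abort("sessions must share the same schedule length")
  }
  per_fish <- purrr::map_dfr(sessions, function(s) {
    b <- session_bouts(s, use_truth)
    b <- filter(b, .data$phase == "motion",
                .data$stimulus %in% c("left", "right"),
                abs(.data$turn_angle_deg) > forward_band_deg)
    b$set <- s$trials$set[match(b$trial, s$trials$trial)]
    b$correct <- sign(b$turn_angle_deg) ==
      if_else(b$stimulus == "left", 1, -1)
    out <- tibble(fish_id = s$fish_id, set = seq_len(s$protocol$n_sets))
    agg <- b |>
      group_by(.data$set) |>
      summarise(proportion_correct = mean(.data$correct),
                n_turns = dplyr::n(), .groups = "drop")
    left_join(out, agg, by = "set") |>
      mutate(n_turns = if_else(is.na(.data$n_turns), 0L,
                               as.integer(.data$n_turns)))
  })
  summary <- per_fish |>
    group_by(.data$set) |>
    summarise(median = stats::median(.data$proportion_correct, na.rm = TRUE),
              q25 = stats::quantile(.data$proportion_correct, 0.25,
                                    na.rm = TRUE, names = FALSE),
              q75 = stats::quantile(.data$proportion_correct, 0.75,
                                    na.rm = TRUE, names = FALSE),
              n_fish = sum(!is.na(.data$proportion_correct)),
              .groups = "drop")
  list(per_fish = per_fish, summary = summary)
}

#' Per-fish behavioral summary metrics
#'
#' Runs the full behavioral pipeline on one session: proportion correct over
#' lateral motion-phase bouts, bout rates in no-motion and motion windows, and
#' bout counts. By default bouts come from [detect_bouts()] on the tracking
#' table (the end-to-end path); `use_truth = TRUE` uses ground-truth bouts.
#'
#' @param session A `behavior_session`.
#' @param forward_band_deg Forward-band half-width in degrees. Default 10.
#' @param use_truth Use ground-truth bouts instead of detection.
#'   Default `FALSE`.
#' @return A one-row tibble: `fish_id`, `condition`, `washout_h`,
#'   `proportion_correct`, `n_turns`, `bout_rate_stim_hz`,
#'   `bout_rate_nostim_hz`, `n_bouts`.
#' @export
session_performance <- function(session, forward_band_deg = 10,
                                use_truth = FALSE) {
  b <- session_bouts(session, use_truth)
  lat <- filter(b, .data$phase == "motion",
                .data$stimulus %in% c("left", "right"))
  ang <- lat$turn_angle_deg
  turns <- ang[abs(ang) > forward_band_deg]
  correct <- sign(turns) == if_else(
    lat$stimulus[abs(ang) > forward_band_deg] == "left", 1, -1)
  p <- session$protocol
  motion_s <- sum(session$trials$stimulus != "none") * p$motion_s
  nostim_s <- sum(session$trials$stimulus == "none") *
    (p$pre_static_s + p$motion_s + p$post_static_s)
  n_motion <- sum(b$phase == "motion" & b$stimulus != "none", na.rm = TRUE)
  n_nostim <- sum(b$stimulus == "none", na.rm = TRUE)
  tibble(
    fish_id = session$fish_id,
    condition = session$condition_label,
    washout_h = session$washout_h,
    proportion_correct = if (length(turns) == 0) NA_real_
                         else mean(correct),
    n_turns = length(turns),
    bout_rate_stim_hz = if (motion_s > 0) n_motion / motion_s else NA_real_,
    bout_rate_nostim_hz = if (nostim_s > 0) n_nostim / nostim_s
                          else NA_real_,
    n_bouts = nrow(b)
  )
}

# bouts for analysis: ground truth or detected-from-tracking, annotated
session_bouts <- function(session, use_truth = TRUE) {
  b <- if (use_truth) {
    session$bouts
  } else {
    if (is.null(session$tracking)) {
      abort("session has no tracking; use use_truth = TRUE")
    }
    detect_bouts(session$tracking)
  }
  if (!all(c("trial", "stimulus", "phase", "t_since_motion_on") %in% names(b))) {
    b <- annotate_bouts(b, session$trials)
  } else if (!"t_since_motion_on" %in% names(b)) {
    b <- annotate_bouts(b[, c("t_on", "duration", "turn_angle_deg",
                              "displacement_cm")], session$trials)
  }
  b
}
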