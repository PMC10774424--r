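#' Detect swim bouts in a tracking time series
#'
#' Finds contiguous epochs in which the smoothed angular speed (deg/s) or the
#' smoothed translational speed (cm/s) exceeds its threshold, merges epochs
#' separated by less than `merge_gap_s`, discards epochs shorter than
#' `min_duration_s`, and reports each surviving epoch as one bout. The bout's
#' turn angle is the heading change from just before to just after the epoch
#' (padded by `pad_s` so the ramp tails are included).
#'
#' @param tracking A data frame with columns `t`, `x`, `y`, `heading_deg`
#'   sampled uniformly (tolerance 1e-6 s); non-uniform time bases are rejected.
#' @param ang_speed_deg_s Angular-speed threshold, deg/s. Default 30.
#' @param speed_cm_s Translational-speed threshold, cm/s. Default 1.
#' @param smooth_n Boxcar width (samples) applied to both speed traces before
#'   thresholding. Default 3.
#' @param min_duration_s Minimum epoch duration, seconds. Default 0.03.
#' @param merge_gap_s Epochs closer than this are merged, seconds.
#'   Default 0.02.
#' @param pad_s Padding (seconds) added on both sides when measuring the
#'   heading change and displacement. Default 0.03.
#'
#' @return A tibble of bouts: `t_on`, `duration`, `turn_angle_deg`,
#'   `displacement_cm` (zero rows if nothing crosses threshold).
#' @examples
#' s <- simulate_session(behavior_protocol(n_sets = 1), fish_params(), seed = 1)
#' detect_bouts(s$tracking)
#' @export
detect_bouts <- function(tracking,
                         ang_speed_deg_s = 30,
                         speed_cm_s = 1,
                         smooth_n = 3,
                         min_duration_s = 0.03,
                         merge_gap_s = 0.02,
                         pad_s = 0.03) {
  stopifnot(is.data.frame(tracking),
            all(c("t", "x", "y", "heading_deg") %in% names(tracking)))
  t <- tracking$t
  if (length(t) < 3) abort("tracking too short for bout detection")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6) {
    abort("tracking must be uniformly sampled")
  }
  dt <- stats::median(dt)
  fs <- 1 / dt

  ang_speed <- c(0, abs(diff(tracking$heading_deg))) * fs
  trans_speed <- c(0, sqrt(diff(tracking$x)^2 + diff(tracking$y)^2)) * fs
  boxcar <- function(v, k) {
    if (k <= 1) return(v)
    as.numeric(stats::filter(v, rep(1 / k, k), sides = 2)) |>
      (\(z) {z[is.na(z)] <- 0; z})()
  }
  active <- boxcar(ang_speed, smooth_n) > ang_speed_deg_s |
    boxcar(trans_speed, smooth_n) > speed_cm_s

  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  on <- which(r$values)
  if (length(on) == 0) {
    return(tibble(t_on = numeric(), duration = numeric(),
                  turn_angle_deg = numeric(), displacement_cm = numeric()))
  }
  ep <- tibble(i0 = starts[on], i1 = ends[on])
  # merge epochs separated by small gaps
  gap_n <- round(merge_gap_s * fs)
  if (nrow(ep) > 1) {
    gap <- ep$i0[-1] - ep$i1[-nrow(ep)] - 1
    grp <- cumsum(c(1, as.integer(gap > gap_n)))
    ep <- tibble(
      i0 = tapply(ep$i0, grp, min)[as.character(unique(grp))],
      i1 = tapply(ep$i1, grp, max)[as.character(unique(grp))]
    )
  }
  ep <- ep[(ep$i1 - ep$i0 + 1) >= max(1, round(min_duration_s * fs)), ]
  if (nrow(ep) == 0) {
    return(tibble(t_on = numeric(), duration = numeric(),
                  turn_angle_deg = numeric(), displacement_cm = numeric()))
  }
  pad <- round(pad_s * fs)
  a <- pmax(ep$i0 - pad, 1)
  b <- pmin(ep$i1 + pad, length(t))
  tibble(
    t_on = t[ep$i0],
    duration = (ep$i1 - ep$i0 + 1) * dt,
    turn_angle_deg = tracking$heading_deg[b] - tracking$heading_deg[a],
    displacement_cm = sqrt((tracking$x[b] - tracking$x[a])^2 +
                             (tracking$y[b] - tracking$y[a])^2)
  )
}

#' Match detected bouts against ground truth
#'
#' Greedy one-to-one matching of detected to true bout onsets within a time
#' tolerance; reports recall, precision, and the matched pairs.
#'
#' @param detected,truth Bout tibbles with columns `t_on` and
#'   `turn_angle_deg`.
#' @param tol_s Onset tolerance in seconds. Default 0.1.
#' @return A list with `recall`, `precision`, `n_matched`, and a tibble
#'   `pairs` (`t_on_true`, `t_on_det`, `angle_true`, `angle_det`).
#' @export
match_bouts <- function(detected, truth, tol_s = 0.1) {
  if (nrow(truth) == 0) {
    return(list(recall = NA_real_,
                precision = if (nrow(detected) == 0) NA_real_ else 0,
                n_matched = 0L,
                pairs = tibble(t_on_true = numeric(), t_on_det = numeric(),
                               angle_true = numeric(), angle_det = numeric())))
  }
  used <- rep(FALSE, nrow(detected))
  m_true <- integer(0)
  m_det <- integer(0)
  for (i in seq_len(nrow(truth))) {
    d <- abs(detected$t_on - truth$t_on[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      m_true <- c(m_true, i)
      m_det <- c(m_det, j)
    }
  }
  list(
    recall = length(m_true) / nrow(truth),
    precision = if (nrow(detected) == 0) NA_real_
                else length(m_det) / nrow(detected),
    n_matched = length(m_true),
    pairs = tibble(t_on_true = truth$t_on[m_true],
                   t_on_det = detected$t_on[m_det],
                   angle_true = truth$turn_angle_deg[m_true],
                   angle_det = detected$turn_angle_deg[m_det])
  )
}

#' Annotate bouts with their trial, stimulus, and phase
#'
#' Joins a bout table to a trial schedule by onset time, adding `trial`,
#' `stimulus`, `phase` (`pre`/`motion`/`post`), and `t_since_motion_on`
#' (seconds from motion onset; `NA` outside the trial's motion-capable span).
#'
#' @param bouts Bout tibble with a `t_on` column.
#' @param trials Trial schedule from [build_trial_schedule()].
#' @return The bout tibble with annotation columns added.
#' @export
annotate_bouts <- function(bouts, trials) {
  if (nrow(bouts) == 0) {
    return(mutate(bouts, trial = integer(), stimulus = character(),
                  phase = character(), t_since_motion_on = numeric()))
  }
  idx <- findInterval(bouts$t_on, trials$t_start)
  idx[idx < 1] <- NA_integer_
  ok <- !is.na(idx) & bouts$t_on < trials$t_end[pmax(idx, 1)]
  idx[!ok] <- NA_integer_
  phase <- rep(NA_character_, nrow(bouts))
  tmo <- trials$t_motion_on[idx]
  tmf <- trials$t_motion_off[idx]
  phase[!is.na(idx)] <- ifelse(bouts$t_on[!is.na(idx)] < tmo[!is.na(idx)],
                               "pre",
                               ifelse(bouts$t_on[!is.na(idx)] <
                                        tmf[!is.na(idx)], "motion", "post"))
  mutate(bouts,
         trial = trials$trial[idx],
         stimulus = trials$stimulus[idx],
         phase = phase,
         t_since_motion_on = .data$t_on - tmo)
}
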