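#' Evidence-accumulator trace
#'
#' Solves `dE/dt = (s(t) - E) / tau` where `s(t)` is 1 inside the given motion
#' windows and 0 elsewhere, with `E(0) = 0`, using the exact piecewise
#' exponential solution. During a motion window starting at `t0` with
#' `E(t0) = 0` this reduces to `1 - exp(-(t - t0)/tau)`.
#'
#' @param times Numeric vector of query times (seconds), nondecreasing.
#' @param motion_windows Data frame with columns `t_on`, `t_off` giving
#'   non-overlapping, ordered windows where `s = 1`.
#' @param tau Accumulator time constant in seconds.
#' @return Numeric vector of `E` values at `times`.
#' @export
evidence_trace <- function(times, motion_windows, tau) {
  stopifnot(tau > 0, !is.unsorted(times))
  brk <- sort(unique(c(0, motion_windows$t_on, motion_windows$t_off, Inf)))
  e <- numeric(length(times))
  e0 <- 0
  t0 <- 0
  for (i in seq_len(length(brk) - 1)) {
    a <- brk[i]
    b <- brk[i + 1]
    s <- as.numeric(any(motion_windows$t_on <= a & motion_windows$t_off > a))
    sel <- times >= a & times < b
    if (any(sel)) {
      e[sel] <- s + (e0 - s) * exp(-(times[sel] - a) / tau)
    }
    if (is.finite(b)) e0 <- s + (e0 - s) * exp(-(b - a) / tau)
    if (all(times < b)) break
  }
  e
}

#' Simulate one closed-loop behavioral session
#'
#' Agent-based simulation of a freely swimming larva under the optomotor
#' protocol. Bout onsets follow an inhomogeneous renewal process (exponential
#' inter-bout intervals plus a refractory period) whose rate is the
#' phase-dependent base rate times an anesthesia gain `g(t)`. Each bout draws a
#' signed turn angle from a forward/turn mixture; under lateral motion the turn
#' component matches the stimulus with probability
#' `0.5 + (p_correct - 0.5) * E(t)` where `E` is the evidence accumulator (see
#' [evidence_trace()]), and the turn-mixture weight itself scales with `E`.
#' Heading and position are integrated into 100 Hz tracking, each bout
#' depositing its turn angle and forward displacement over a smooth 150 ms
#' ramp. The closed loop is emulated: the stimulus is defined in the fish
#' frame, so heading changes do not alter the stimulus. Positive angles are
#' leftward (counter-clockwise) turns.
#'
#' @param protocol A [behavior_protocol()].
#' @param params A [fish_params()].
#' @param condition_label Rearing/treatment condition passed to
#'   [apply_washout_modulation()].
#' @param washout_h Washout duration (hours) for tricaine conditions.
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @param fish_id Identifier stored in the session.
#' @param include_tracking If `FALSE`, skip synthesizing the 100 Hz tracking
#'   table (bout-level analyses only); ground-truth bouts are always recorded.
#' @param gain_fun Optional override of the anesthesia gain as a function of
#'   time (seconds) returning values in `[0, 1]`; defaults to the condition's
#'   own gain (1 except for `acute_tricaine`, which recovers as
#'   `1 - exp(-t / tau_rec_min)` from session start).
#'
#' @return An object of class `behavior_session`: a list with `fish_id`,
#'   `condition_label`, `washout_h`, `seed`, `protocol`, `params` (after
#'   condition modulation), `trials` (the schedule), `tracking` (tibble
#'   `t, x, y, heading_deg` or `NULL`), and `bouts` (ground-truth bout tibble
#'   with `t_on`, `duration`, `turn_angle_deg`, `displacement_cm`, `trial`,
#'   `stimulus`, `phase`).
#' @examples
#' s <- simulate_session(behavior_protocol(n_sets = 2), fish_params(), seed = 1)
#' nrow(s$bouts)
#' @export
simulate_session <- function(protocol = behavior_protocol(),
                             params = fish_params(),
                             condition_label = "control",
                             washout_h = NA_real_,
                             seed = 1,
                             fish_id = "fish1",
                             include_tracking = TRUE,
                             gain_fun = NULL) {
  stopifnot(inherits(protocol, "behavior_protocol"),
            inherits(params, "fish_params"))
  params <- apply_washout_modulation(params, condition_label, washout_h)
  local_rng(seed)
  trials <- build_trial_schedule_impl(protocol)
  trial_s <- protocol$pre_static_s + protocol$motion_s + protocol$post_static_s
  t_total <- nrow(trials) * trial_s
  if (is.null(gain_fun)) {
    gain_fun <- if (identical(condition_label, "acute_tricaine")) {
      function(t) acute_recovery_gain(t / 60, params$tau_rec_min)
    } else {
      function(t) rep(1, length(t))
    }
  }

  onsets <- draw_bout_onsets(trials, protocol, params, gain_fun, t_total)
  bouts <- draw_bout_angles(onsets, trials, protocol, params)

  tracking <- NULL
  if (include_tracking && t_total > 0) {
    tracking <- render_tracking(bouts, protocol, params, t_total)
  }

  structure(
    list(fish_id = fish_id,
         condition_label = condition_label,
         washout_h = washout_h,
         seed = as.integer(seed),
         protocol = protocol,
         params = params,
         trials = trials,
         tracking = tracking,
         bouts = bouts),
    class = "behavior_session"
  )
}

#' @export
print.behavior_session <- function(x, ...) {
  cat(sprintf("<behavior_session> %s (%s%s): %d trials, %d bouts, seed %d\n",
              x$fish_id, x$condition_label,
              if (!is.na(x$washout_h)) sprintf(", washout %g h", x$washout_h)
              else "",
              nrow(x$trials), nrow(x$bouts), x$seed))
  invisible(x)
}

# schedule construction from the current RNG stream (no re-seeding)
build_trial_schedule_impl <- function(protocol) {
  n_cond <- length(protocol$conditions)
  if (protocol$n_sets == 0) {
    return(tibble(trial = integer(), set = integer(), stimulus = character(),
                  t_start = numeric(), t_motion_on = numeric(),
                  t_motion_off = numeric(), t_end = numeric()))
  }
  stim <- unlist(lapply(seq_len(protocol$n_sets), function(s) {
    protocol$conditions[sample.int(n_cond)]
  }))
  trial_s <- protocol$pre_static_s + protocol$motion_s + protocol$post_static_s
  n <- protocol$n_sets * n_cond
  t0 <- (seq_len(n) - 1) * trial_s
  tibble(trial = seq_len(n),
         set = rep(seq_len(protocol$n_sets), each = n_cond),
         stimulus = stim,
         t_start = t0,
         t_motion_on = t0 + protocol$pre_static_s,
         t_motion_off = t0 + protocol$pre_static_s + protocol$motion_s,
         t_end = t0 + trial_s)
}

# Inhomogeneous renewal process by thinning. The post-refractory hazard is
# r/(1 - refractory * r) so that the realized bout rate equals the nominal
# rate r despite the dead time.
draw_bout_onsets <- function(trials, protocol, params, gain_fun, t_total) {
  trial_s <- protocol$pre_static_s + protocol$motion_s + protocol$post_static_s
  base_rate_at <- function(t) {
    idx <- pmin(floor(t / trial_s) + 1, nrow(trials))
    tt <- t - trials$t_start[idx]
    in_motion <- trials$stimulus[idx] != "none" &
      tt >= protocol$pre_static_s &
      tt < protocol$pre_static_s + protocol$motion_s
    ifelse(in_motion, params$rate_stim_hz, params$rate_nostim_hz)
  }
  hazard <- function(r) {
    excl <- params$refractory_s * r
    if (any(excl >= 1)) abort("bout rate too high for the refractory period")
    r / (1 - excl)
  }
  r_max <- max(params$rate_stim_hz, params$rate_nostim_hz)
  if (r_max <= 0 || nrow(trials) == 0) return(numeric(0))
  lam_max <- hazard(r_max)
  onsets <- numeric(0)
  t_cur <- 0
  repeat {
    t_cur <- t_cur + rexp(1, lam_max)
    if (t_cur >= t_total) break
    lam <- hazard(base_rate_at(t_cur) * gain_fun(t_cur))
    if (runif(1) < lam / lam_max) {
      onsets <- c(onsets, t_cur)
      t_cur <- t_cur + params$refractory_s
    }
  }
  onsets
}

draw_bout_angles <- function(onsets, trials, protocol, params) {
  empty <- tibble(t_on = numeric(), duration = numeric(),
                  turn_angle_deg = numeric(), displacement_cm = numeric(),
                  trial = integer(), stimulus = character(),
                  phase = character())
  if (length(onsets) == 0) return(empty)
  trial_s <- protocol$pre_static_s + protocol$motion_s + protocol$post_static_s
  idx <- pmin(floor(onsets / trial_s) + 1, nrow(trials))
  tt <- onsets - trials$t_start[idx]
  phase <- ifelse(tt < protocol$pre_static_s, "pre",
                  ifelse(tt < protocol$pre_static_s + protocol$motion_s,
                         "motion", "post"))
  stimulus <- trials$stimulus[idx]
  lateral <- stimulus %in% c("left", "right") & phase == "motion"

  motion_windows <- trials[trials$stimulus %in% c("left", "right"),
                           c("t_motion_on", "t_motion_off")]
  names(motion_windows) <- c("t_on", "t_off")
  e <- evidence_trace(onsets, motion_windows, params$tau_int_s)
  e[!lateral] <- 0

  # per-set asymptotic accuracy, optionally relaxing from a first-trial value
  p_asym <- rep(params$p_correct, length(onsets))
  if (!is.na(params$first_trial_accuracy)) {
    k <- trials$set[idx]
    p_asym <- params$p_correct -
      (params$p_correct - params$first_trial_accuracy) *
      exp(-(k - 1) / params$trial_transient_tau)
  }
  p_eff <- 0.5 + (p_asym - 0.5) * e
  w_turn <- params$w_turn_nostim +
    (params$w_turn_stim - params$w_turn_nostim) * e

  n <- length(onsets)
  is_turn <- runif(n) < w_turn
  mag <- abs(rnorm(n, params$mu_turn_deg, params$sigma_turn_deg))
  correct <- runif(n) < p_eff
  stim_sign <- ifelse(stimulus == "left", 1,
                      ifelse(stimulus == "right", -1, 0))
  turn_sign <- ifelse(lateral,
                      ifelse(correct, stim_sign, -stim_sign),
                      sample(c(-1, 1), n, replace = TRUE))
  angle <- ifelse(is_turn, turn_sign * mag, rnorm(n, 0, params$sigma_forward_deg))

  tibble(t_on = onsets,
         duration = params$bout_ramp_s,
         turn_angle_deg = angle,
         displacement_cm = params$displacement_cm,
         trial = trials$trial[idx],
         stimulus = stimulus,
         phase = phase)
}

# smoothstep ramp used as the bout waveform
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

render_tracking <- function(bouts, protocol, params, t_total) {
  fs <- protocol$sample_rate_hz
  n <- round(t_total * fs)
  t <- (seq_len(n) - 1) / fs
  n_ramp <- max(2L, round(params$bout_ramp_s * fs))
  dhead <- numeric(n)
  dx <- numeric(n)
  dy <- numeric(n)
  if (nrow(bouts) > 0) {
    step <- diff(smoothstep(seq(0, 1, length.out = n_ramp + 1)))
    i0 <- floor(bouts$t_on * fs) + 1
    samp <- rep(i0, each = n_ramp) + rep(seq_len(n_ramp) - 1, nrow(bouts))
    keep <- samp <= n
    w <- rep(step, nrow(bouts))
    ang <- rep(bouts$turn_angle_deg, each = n_ramp)
    disp <- rep(bouts$displacement_cm, each = n_ramp)
    dhead_add <- (ang * w)[keep]
    samp <- samp[keep]
    samp_u <- sort(unique(samp))
    dhead[samp_u] <- rowsum(dhead_add, samp)[, 1]
    # displacement is deposited along the heading at bout onset
    head_pre <- cumsum(dhead)
    h_onset <- rep(ifelse(i0 > 1, head_pre[pmax(i0 - 1, 1)], 0),
                   each = n_ramp)[keep]
    ddisp <- (disp * w)[keep]
    dx[samp_u] <- rowsum(ddisp * cospi(h_onset / 180), samp)[, 1]
    dy[samp_u] <- rowsum(ddisp * sinpi(h_onset / 180), samp)[, 1]
  }
  tibble(
    t = t,
    x = cumsum(dx) + rnorm(n, 0, params$pos_noise_cm),
    y = cumsum(dy) + rnorm(n, 0, params$pos_noise_cm),
    heading_deg = cumsum(dhead) + rnorm(n, 0, params$heading_noise_deg)
  )
}

#' Simulate a cohort of behavioral sessions
#'
#' Convenience wrapper running [simulate_session()] for `n_fish` fish with
#' per-fish seeds derived from `seed`.
#'
#' @inheritParams simulate_session
#' @param n_fish Number of fish.
#' @param seed Base seed; fish `i` uses `seed + i - 1`.
#' @return A list of `behavior_session` objects.
#' @export
simulate_cohort <- function(n_fish,
                            protocol = behavior_protocol(),
                            params = fish_params(),
                            condition_label = "control",
                            washout_h = NA_real_,
                            seed = 1,
                            include_tracking = TRUE) {
  lapply(seq_len(n_fish), function(i) {
    simulate_session(protocol, params, condition_label, washout_h,
                     seed = seed + i - 1,
                     fish_id = sprintf("fish%03d", i),
                     include_tracking = include_tracking)
  })
}
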