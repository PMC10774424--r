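# Small fixtures built in code.

# Tracking with hand-injected bouts, constructed independently of the
# simulator (linear deposition ramp, not the simulator's smoothstep), so it
# can serve as a detection oracle.
make_tracking_with_bouts <- function(angles, onsets, total_s = 30,
                                     fs = 100, ramp_s = 0.15,
                                     disp_cm = 0.2) {
  n <- total_s * fs
  dhead <- numeric(n)
  dpos <- numeric(n)
  n_ramp <- round(ramp_s * fs)
  for (k in seq_along(angles)) {
    i0 <- round(onsets[k] * fs) + 1
    idx <- i0:(i0 + n_ramp - 1)
    dhead[idx] <- dhead[idx] + angles[k] / n_ramp
    dpos[idx] <- dpos[idx] + disp_cm / n_ramp
  }
  heading <- cumsum(dhead)
  tibble::tibble(
    t = (seq_len(n) - 1) / fs,
    x = cumsum(dpos * cospi(heading / 180)),
    y = cumsum(dpos * sinpi(heading / 180)),
    heading_deg = heading
  )
}

flat_tracking <- function(total_s = 10, fs = 100) {
  n <- total_s * fs
  tibble::tibble(t = (seq_len(n) - 1) / fs, x = 0, y = 0, heading_deg = 0)
}

# minimal session object for metric functions that only need
# protocol/trials/bouts
fake_session <- function(bouts, protocol = behavior_protocol(n_sets = 1),
                         trials = NULL, fish_id = "f1") {
  if (is.null(trials)) {
    trials <- build_trial_schedule(protocol, seed = 1)
  }
  structure(list(fish_id = fish_id, condition_label = "control",
                 washout_h = NA_real_, seed = 1L, protocol = protocol,
                 params = fish_params(), trials = trials, tracking = NULL,
                 bouts = bouts),
            class = "behavior_session")
}

noiseless_fish <- function(...) {
  fish_params(heading_noise_deg = 0, pos_noise_cm = 0, ...)
}

# one-left-trial-then-one-right-trial imaging trace built by hand:
# baseline-level frames with a boxcar response added during chosen motion
# windows
boxcar_trace <- function(schedule, protocol = imaging_protocol(),
                         left_amp = 50, right_amp = 0, baseline = 100) {
  nf <- protocol$trial_s * protocol$frame_rate_hz
  f <- unlist(lapply(seq_len(nrow(schedule)), function(i) {
    amp <- if (schedule$stimulus[i] == "left") left_amp else right_amp
    c(rep(baseline, 10), rep(baseline + amp, 30), rep(baseline, 20))
  }))
  tibble::tibble(t = seq_along(f) - 1, f = f)
}
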