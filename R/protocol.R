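#' Behavioral stimulation protocol
#'
#' Describes one free-swimming optomotor trial and the session built from it.
#' Each trial is a static-grating period, a moving-grating period, and a second
#' static period; a session is `n_sets` sets in which every stimulus condition
#' appears exactly once in randomized order.
#'
#' @param pre_static_s Seconds of static grating before motion. Default 5.
#' @param motion_s Seconds of grating motion. Default 10.
#' @param post_static_s Seconds of static grating after motion. Default 5.
#' @param grating_speed_cm_s Grating speed during motion, cm/s. Default 1.
#' @param spatial_period_cm Grating spatial period, cm. Default 1.
#' @param n_sets Number of stimulus sets per session. Default 30.
#' @param conditions Character vector of stimulus labels presented within each
#'   set. Default `c("none", "forward", "backward", "left", "right")`.
#' @param sample_rate_hz Tracking sample rate, Hz. Default 100.
#'
#' @return An object of class `behavior_protocol` (a named list).
#' @examples
#' p <- behavior_protocol()
#' p$motion_s
#' @export
behavior_protocol <- function(pre_static_s = 5,
                              motion_s = 10,
                              post_static_s = 5,
                              grating_speed_cm_s = 1,
                              spatial_period_cm = 1,
                              n_sets = 30,
                              conditions = c("none", "forward", "backward",
                                             "left", "right"),
                              sample_rate_hz = 100) {
  stopifnot(pre_static_s > 0, motion_s > 0, post_static_s > 0,
            sample_rate_hz > 0, grating_speed_cm_s > 0,
            spatial_period_cm > 0, n_sets >= 0,
            length(conditions) >= 1, !anyDuplicated(conditions))
  structure(
    list(pre_static_s = pre_static_s,
         motion_s = motion_s,
         post_static_s = post_static_s,
         grating_speed_cm_s = grating_speed_cm_s,
         spatial_period_cm = spatial_period_cm,
         n_sets = as.integer(n_sets),
         conditions = conditions,
         sample_rate_hz = sample_rate_hz),
    class = "behavior_protocol"
  )
}

#' @export
print.behavior_protocol <- function(x, ...) {
  cat("<behavior_protocol>\n")
  cat(sprintf("  trial: %g s static + %g s motion (%g cm/s) + %g s static\n",
              x$pre_static_s, x$motion_s, x$grating_speed_cm_s,
              x$post_static_s))
  cat(sprintf("  %d sets x {%s}, tracking at %g Hz\n",
              x$n_sets, paste(x$conditions, collapse = ", "),
              x$sample_rate_hz))
  invisible(x)
}

#' Virtual-fish behavioral parameters
#'
#' Parameters of the closed-loop swimming model. Bouts are generated by a
#' renewal process (exponential inter-bout intervals plus a refractory period)
#' whose rate depends on whether gratings are moving and on an anesthesia gain.
#' Each bout draws a signed turn angle from a forward/turn mixture; during
#' leftward or rightward motion the turn component matches the stimulus
#' direction with probability `0.5 + (p_correct - 0.5) * E(t)`, where the
#' evidence accumulator `E` relaxes toward 1 during motion with time constant
#' `tau_int_s`.
#'
#' @param rate_nostim_hz Bout rate without grating motion, Hz. Default 0.5.
#' @param rate_stim_hz Bout rate during grating motion, Hz. Default 1.
#' @param p_correct Asymptotic probability that a turn bout matches the
#'   stimulus direction. Default 0.967.
#' @param sigma_forward_deg SD of the forward-bout angle component, degrees.
#' @param mu_turn_deg,sigma_turn_deg Mean and SD of the (folded-normal)
#'   turn-bout angle magnitude, degrees.
#' @param w_turn_nostim Turn-bout mixture weight without directed motion.
#' @param w_turn_stim Asymptotic turn-bout weight under lateral motion; the
#'   instantaneous weight is `w_turn_nostim + (w_turn_stim - w_turn_nostim) *
#'   E(t)`, so fish swim mostly forward until evidence has accumulated.
#' @param tau_int_s Evidence-accumulator time constant, seconds.
#' @param tau_rec_min Bout-rate recovery time constant after acute anesthesia,
#'   minutes. Default 25.
#' @param washout_accuracy_curve Data frame with columns `washout_h` and
#'   `accuracy`: asymptotic turn accuracy as a function of washout duration for
#'   anesthesia-reared fish. Must be nondecreasing in duration.
#' @param rate_cap_fraction Maximum bout-rate fraction (relative to control)
#'   for anesthesia-reared fish. Default 0.5.
#' @param refractory_s Post-bout refractory period, seconds. Default 0.2.
#' @param bout_ramp_s Duration over which a bout deposits its heading change
#'   and displacement, seconds. Default 0.15.
#' @param displacement_cm Forward displacement per bout, cm. Default 0.2.
#' @param heading_noise_deg,pos_noise_cm Per-sample tracking noise SDs.
#' @param first_trial_accuracy Turn accuracy at the first lateral trial, or
#'   `NA` for no trial transient. With a value, per-trial asymptotic accuracy
#'   relaxes from it toward `p_correct` with scale `trial_transient_tau`.
#' @param trial_transient_tau E-folding scale (in trials) of the first-trials
#'   transient. Default 1.5 (roughly a 3-trial transient).
#'
#' @return An object of class `fish_params` (a named list).
#' @examples
#' fp <- fish_params()
#' fp$p_correct
#' @export
fish_params <- function(rate_nostim_hz = 0.5,
                        rate_stim_hz = 1.0,
                        p_correct = 0.967,
                        sigma_forward_deg = 3.5,
                        mu_turn_deg = 30,
                        sigma_turn_deg = 10,
                        w_turn_nostim = 0.3,
                        w_turn_stim = 0.8,
                        tau_int_s = 0.25,
                        tau_rec_min = 25,
                        washout_accuracy_curve = default_washout_curve(),
                        rate_cap_fraction = 0.5,
                        refractory_s = 0.2,
                        bout_ramp_s = 0.15,
                        displacement_cm = 0.2,
                        heading_noise_deg = 0.05,
                        pos_noise_cm = 0.002,
                        first_trial_accuracy = NA_real_,
                        trial_transient_tau = 1.5) {
  stopifnot(rate_nostim_hz >= 0, rate_stim_hz >= 0,
            p_correct >= 0.5, p_correct <= 1,
            tau_int_s > 0, tau_rec_min > 0,
            w_turn_nostim >= 0, w_turn_nostim <= 1,
            w_turn_stim >= 0, w_turn_stim <= 1,
            rate_cap_fraction > 0, rate_cap_fraction <= 1,
            refractory_s >= 0, bout_ramp_s > 0)
  wc <- as_tibble(washout_accuracy_curve)
  stopifnot(all(c("washout_h", "accuracy") %in% names(wc)))
  wc <- arrange(wc, .data$washout_h)
  if (any(diff(wc$accuracy) < 0)) {
    abort("washout_accuracy_curve must be nondecreasing in washout duration")
  }
  structure(
    list(rate_nostim_hz = rate_nostim_hz,
         rate_stim_hz = rate_stim_hz,
         p_correct = p_correct,
         sigma_forward_deg = sigma_forward_deg,
         mu_turn_deg = mu_turn_deg,
         sigma_turn_deg = sigma_turn_deg,
         w_turn_nostim = w_turn_nostim,
         w_turn_stim = w_turn_stim,
         tau_int_s = tau_int_s,
         tau_rec_min = tau_rec_min,
         washout_accuracy_curve = wc,
         rate_cap_fraction = rate_cap_fraction,
         refractory_s = refractory_s,
         bout_ramp_s = bout_ramp_s,
         displacement_cm = displacement_cm,
         heading_noise_deg = heading_noise_deg,
         pos_noise_cm = pos_noise_cm,
         first_trial_accuracy = first_trial_accuracy,
         trial_transient_tau = trial_transient_tau),
    class = "fish_params"
  )
}

#' Default washout-accuracy anchors for anesthesia-reared fish
#'
#' Asymptotic turn accuracy by washout duration: 55% immediately after washout
#' (0-1 h), 75% by 2 h, 89% by 6 h, and 93% by 24 h. Queries between anchors
#' are linearly interpolated; beyond 24 h the curve stays at its last value.
#'
#' @return A tibble with columns `washout_h` and `accuracy`.
#' @export
default_washout_curve <- function() {
  tibble(washout_h = c(0, 1, 2, 6, 24),
         accuracy  = c(0.55, 0.55, 0.75, 0.89, 0.93))
}

#' @export
print.fish_params <- function(x, ...) {
  cat("<fish_params>\n")
  cat(sprintf("  bout rate %g Hz (no stim) / %g Hz (motion); p_correct %.3f\n",
              x$rate_nostim_hz, x$rate_stim_hz, x$p_correct))
  cat(sprintf("  turn mixture: w %g -> %g, |N(%g, %g)| deg; tau_int %g s\n",
              x$w_turn_nostim, x$w_turn_stim, x$mu_turn_deg,
              x$sigma_turn_deg, x$tau_int_s))
  invisible(x)
}

#' Imaging stimulation protocol
#'
#' One imaging trial lasts 60 s at 1 Hz: 10 s static grating, 30 s leftward or
#' rightward motion, 20 s static. Frame `k` covers time `[k, k+1)` s within the
#' trial (0-based), so motion starts at trial frame 10. Recording blocks are
#' one hour long and hold an integer number of trials.
#'
#' @param frame_rate_hz Acquisition frame rate, Hz. Default 1.
#' @param static_pre_s,motion_s,static_post_s Trial phase durations, seconds.
#' @param block_length_h Length of one recording block, hours. Default 1.
#'
#' @return An object of class `imaging_protocol` (a named list) with derived
#'   fields `trial_s` and `trials_per_block`.
#' @export
imaging_protocol <- function(frame_rate_hz = 1,
                             static_pre_s = 10,
                             motion_s = 30,
                             static_post_s = 20,
                             block_length_h = 1) {
  stopifnot(frame_rate_hz > 0, static_pre_s > 0, motion_s > 0,
            static_post_s > 0, block_length_h > 0)
  trial_s <- static_pre_s + motion_s + static_post_s
  n_trials <- block_length_h * 3600 / trial_s
  if (abs(n_trials - round(n_trials)) > 1e-9) {
    abort("block length must hold an integer number of trials")
  }
  structure(
    list(frame_rate_hz = frame_rate_hz,
         static_pre_s = static_pre_s,
         motion_s = motion_s,
         static_post_s = static_post_s,
         block_length_h = block_length_h,
         trial_s = trial_s,
         trials_per_block = as.integer(round(n_trials))),
    class = "imaging_protocol"
  )
}

#' @export
print.imaging_protocol <- function(x, ...) {
  cat("<imaging_protocol>\n")
  cat(sprintf("  trial: %g s pre + %g s motion + %g s post at %g Hz\n",
              x$static_pre_s, x$motion_s, x$static_post_s, x$frame_rate_hz))
  cat(sprintf("  blocks of %g h = %d trials\n",
              x$block_length_h, x$trials_per_block))
  invisible(x)
}

#' Parameters of one synthetic imaging unit
#'
#' A unit is a small cluster of 1-5 similarly tuned neurons. Its stimulus drive
#' rises toward `amplitude` with time constant `tau_on_s` during motion in its
#' preferred direction(s) and decays with `tau_off_s` after motion offset; the
#' drive is low-pass filtered by a calcium-indicator kernel (single-exponential
#' decay, GCaMP6s-like) before noise is added. During anesthesia the response
#' gain is zero; during washout it follows a logistic in time with midpoint
#' `recovery_x0_min` and time constant `recovery_k_min`.
#'
#' @param unit_id Unit identifier.
#' @param region One of `"tectum"`, `"pretectum"`, `"hindbrain"`.
#' @param tuning One of `"left_selective"`, `"right_selective"`,
#'   `"motion_selective"`, `"suppressed"`.
#' @param amplitude Asymptotic drive, fluorescence units. Default 300.
#' @param tau_on_s Onset time constant, seconds. Values below the frame
#'   interval are allowed but flagged sub-frame (unrecoverable at 1 Hz).
#' @param tau_off_s Offset decay constant, seconds.
#' @param recovery_x0_min Logistic midpoint of the washout gain, minutes after
#'   washout start.
#' @param recovery_k_min Logistic time constant of the washout gain, minutes.
#' @param baseline_f Baseline fluorescence. Default 50.
#' @param noise_sd Per-frame Gaussian noise SD, fluorescence units.
#' @param flicker_sd SD of an optional multiplicative background flicker
#'   applied during anesthesia blocks (stimulus-uncorrelated). Default 0.
#' @param indicator_tau_s Calcium-indicator decay constant, seconds.
#'   Default 1.8.
#' @param n_neurons Number of neurons in the unit (1-5), metadata and movie
#'   rendering only.
#'
#' @return An object of class `unit_params` (a named list) with a logical
#'   `sub_frame` flag.
#' @export
unit_params <- function(unit_id = "u1",
                        region = c("tectum", "pretectum", "hindbrain"),
                        tuning = c("left_selective", "right_selective",
                                   "motion_selective", "suppressed"),
                        amplitude = 300,
                        tau_on_s = 1.5,
                        tau_off_s = 8,
                        recovery_x0_min = 60,
                        recovery_k_min = 12,
                        baseline_f = 50,
                        noise_sd = 10,
                        flicker_sd = 0,
                        indicator_tau_s = 1.8,
                        n_neurons = 3) {
  region <- match.arg(region)
  tuning <- match.arg(tuning)
  stopifnot(amplitude >= 0, tau_on_s > 0, tau_off_s > 0,
            recovery_k_min > 0, noise_sd >= 0, flicker_sd >= 0,
            indicator_tau_s > 0, n_neurons >= 1, n_neurons <= 5)
  structure(
    list(unit_id = unit_id, region = region, tuning = tuning,
         amplitude = amplitude, tau_on_s = tau_on_s, tau_off_s = tau_off_s,
         recovery_x0_min = recovery_x0_min, recovery_k_min = recovery_k_min,
         baseline_f = baseline_f, noise_sd = noise_sd,
         flicker_sd = flicker_sd, indicator_tau_s = indicator_tau_s,
         n_neurons = as.integer(n_neurons),
         sub_frame = tau_on_s < 1),
    class = "unit_params"
  )
}

#' @export
print.unit_params <- function(x, ...) {
  cat(sprintf("<unit_params> %s: %s %s, amp %g, tau_on %g s, tau_off %g s%s\n",
              x$unit_id, x$region, x$tuning, x$amplitude, x$tau_on_s,
              x$tau_off_s,
              if (x$sub_frame) " [sub-frame, unrecoverable at 1 Hz]" else ""))
  invisible(x)
}
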