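#' Interpolate asymptotic turn accuracy at a washout duration
#'
#' Linear interpolation between the anchors of a washout-accuracy curve;
#' queries beyond the last anchor return the last value.
#'
#' @param curve Data frame with columns `washout_h`, `accuracy`.
#' @param washout_h Washout duration in hours (>= 0).
#' @return Accuracy as a fraction.
#' @export
washout_accuracy <- function(curve, washout_h) {
  if (any(washout_h < 0)) abort("washout_h must be >= 0")
  approx(curve$washout_h, curve$accuracy, xout = washout_h, rule = 2)$y
}

#' Apply rearing/treatment condition and washout duration to fish parameters
#'
#' Specializes a [fish_params()] object for a rearing or treatment condition:
#' * `control`: returned unchanged.
#' * `dark`: asymptotic accuracy 0.949, with a ~3-trial transient starting at
#'   0.94 on the first lateral trial.
#' * `strobe`: asymptotic accuracy 0.95.
#' * `tricaine_reared`: accuracy interpolated from the washout-accuracy curve
#'   at `washout_h`; bout rates capped at `rate_cap_fraction` of control.
#' * `acute_tricaine`: rates recover within-session as
#'   `1 - exp(-t / tau_rec_min)` from washout at session start (applied by
#'   [simulate_session()]); accuracy unchanged.
#'
#' @param params A [fish_params()].
#' @param condition_label One of `control`, `dark`, `strobe`,
#'   `tricaine_reared`, `acute_tricaine`.
#' @param washout_h Washout duration in hours; required (>= 0) for
#'   `tricaine_reared`.
#' @return A modified `fish_params` object with an added `condition_label`
#'   field.
#' @examples
#' fp <- apply_washout_modulation(fish_params(), "tricaine_reared", washout_h = 24)
#' fp$p_correct   # 0.93
#' @export
apply_washout_modulation <- function(params,
                                     condition_label = c("control", "dark",
                                                         "strobe",
                                                         "tricaine_reared",
                                                         "acute_tricaine"),
                                     washout_h = NA_real_) {
  stopifnot(inherits(params, "fish_params"))
  condition_label <- match.arg(condition_label)
  out <- params
  if (condition_label == "dark") {
    out$p_correct <- 0.949
    out$first_trial_accuracy <- 0.94
  } else if (condition_label == "strobe") {
    out$p_correct <- 0.95
  } else if (condition_label == "tricaine_reared") {
    if (is.na(washout_h)) abort("washout_h is required for tricaine_reared")
    if (washout_h < 0) abort("washout_h must be >= 0")
    out$p_correct <- washout_accuracy(params$washout_accuracy_curve, washout_h)
    out$rate_nostim_hz <- params$rate_nostim_hz * params$rate_cap_fraction
    out$rate_stim_hz <- params$rate_stim_hz * params$rate_cap_fraction
  }
  out$condition_label <- condition_label
  out
}

#' Anesthesia bout-rate gain during acute recovery
#'
#' Fraction of the pre-anesthesia bout rate recovered `t_min` minutes after
#' acute anesthetic washout: `1 - exp(-t_min / tau_rec_min)`.
#'
#' @param t_min Minutes since washout (vectorized); values < 0 return 0.
#' @param tau_rec_min Recovery time constant in minutes. Default 25.
#' @return Gain in `[0, 1]`.
#' @export
acute_recovery_gain <- function(t_min, tau_rec_min = 25) {
  ifelse(t_min <= 0, 0, 1 - exp(-t_min / tau_rec_min))
}
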