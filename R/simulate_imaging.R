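#' Draw a synthetic imaging-unit population
#'
#' Samples per-unit parameters for a population imaged across an
#' anesthesia/washout experiment. Tunings are drawn from a categorical mix,
#' amplitudes from a log-normal scaled so that most responsive units exceed
#' the fittable threshold (max C - C0 > 100) while `frac_weak` do not, onset
#' constants log-uniform on 0.2-3 s, offset constants log-uniform on 2-20 s,
#' and washout-recovery midpoints normal around `x0_mean_min` (45 min for
#' acute, 90 min for anesthesia-reared experiments by default).
#'
#' @param n_units Number of units.
#' @param experiment `"acute"` or `"lifetime"`; sets the default recovery
#'   midpoint mean.
#' @param seed Integer seed.
#' @param tuning_probs Named probabilities for `left_selective`,
#'   `right_selective`, `motion_selective`, `suppressed`.
#' @param x0_mean_min,x0_sd_min Mean and SD of the logistic recovery midpoint,
#'   minutes. `x0_mean_min = NULL` uses 45 (acute) or 90 (lifetime).
#' @param k_mean_min,k_sd_min Mean and SD of the logistic time constant,
#'   minutes.
#' @param amp_meanlog,amp_sdlog Log-normal amplitude parameters.
#' @param frac_weak Fraction of units given sub-threshold amplitudes.
#' @param baseline_f,noise_sd,flicker_sd,indicator_tau_s Shared trace
#'   parameters (see [unit_params()]).
#' @return A tibble with one row per unit and the columns of [unit_params()].
#' @export
sample_unit_population <- function(n_units,
                                   experiment = c("acute", "lifetime"),
                                   seed = 1,
                                   tuning_probs = c(left_selective = 0.35,
                                                    right_selective = 0.35,
                                                    motion_selective = 0.2,
                                                    suppressed = 0.1),
                                   x0_mean_min = NULL,
                                   x0_sd_min = 15,
                                   k_mean_min = 12,
                                   k_sd_min = 3,
                                   amp_meanlog = log(300),
                                   amp_sdlog = 0.4,
                                   frac_weak = 0.15,
                                   baseline_f = 50,
                                   noise_sd = 10,
                                   flicker_sd = 0,
                                   indicator_tau_s = 1.8) {
  experiment <- match.arg(experiment)
  if (is.null(x0_mean_min)) {
    x0_mean_min <- if (experiment == "acute") 45 else 90
  }
  local_rng(seed)
  tuning <- sample(names(tuning_probs), n_units, replace = TRUE,
                   prob = tuning_probs)
  amp <- stats::rlnorm(n_units, amp_meanlog, amp_sdlog)
  weak <- runif(n_units) < frac_weak
  amp[weak] <- runif(sum(weak), 20, 80)
  tibble(
    unit_id = sprintf("u%03d", seq_len(n_units)),
    region = sample(c("tectum", "pretectum", "hindbrain"), n_units,
                    replace = TRUE),
    tuning = tuning,
    amplitude = amp,
    tau_on_s = exp(runif(n_units, log(0.2), log(3))),
    tau_off_s = exp(runif(n_units, log(2), log(20))),
    recovery_x0_min = pmax(5, rnorm(n_units, x0_mean_min, x0_sd_min)),
    recovery_k_min = pmax(2, rnorm(n_units, k_mean_min, k_sd_min)),
    baseline_f = baseline_f,
    noise_sd = noise_sd,
    flicker_sd = flicker_sd,
    indicator_tau_s = indicator_tau_s,
    n_neurons = sample(1:5, n_units, replace = TRUE)
  )
}

# Exact affine per-frame propagation of the two-state model
#   drive:      tau_d * d' = u - d   (tau_d = tau_on while input active,
#                                     tau_off otherwise)
#   indicator:  tau_k * F' = d - F
# over one trial with input pattern u_j = g_j * a (g_j in {0, 1}).
# The state (d, F) and per-frame frame-averaged outputs are affine in
# (d0, F0, a); coefficients are propagated as n x 3 matrices so an entire
# unit population is handled at once.
trial_filter_coefs <- function(tau_on, tau_off, tau_k, g, delta = 1) {
  n <- length(tau_on)
  nf <- length(g)
  tau_k <- ifelse(abs(tau_on - tau_k) < 1e-8, tau_k * (1 + 1e-6), tau_k)
  tau_k <- ifelse(abs(tau_off - tau_k) < 1e-8, tau_k * (1 + 1e-6), tau_k)
  Sd <- cbind(rep(1, n), 0, 0)
  Sf <- cbind(rep(0, n), 1, 0)
  W1 <- matrix(0, n, nf)
  W2 <- matrix(0, n, nf)
  W3 <- matrix(0, n, nf)
  e2 <- exp(-delta / tau_k)
  mk <- (tau_k / delta) * (1 - e2)
  for (j in seq_len(nf)) {
    tau <- if (g[j] > 0) tau_on else tau_off
    U <- cbind(rep(0, n), 0, g[j])
    alpha <- exp(-delta / tau)
    gam <- tau / (tau - tau_k)
    mt <- (tau / delta) * (1 - alpha)
    Beta <- gam * (Sd - U)
    Cc <- Sf - U - Beta
    Wj <- U + Beta * mt + Cc * mk
    W1[, j] <- Wj[, 1]
    W2[, j] <- Wj[, 2]
    W3[, j] <- Wj[, 3]
    Sd <- U + (Sd - U) * alpha
    Sf <- U + Beta * alpha + Cc * e2
  }
  list(W1 = W1, W2 = W2, W3 = W3, Ad = Sd, Af = Sf)
}

#' Simulate a population of trial-structured fluorescence units
#'
#' Generates 1 Hz fluorescence traces for all units of a population over a
#' multi-hour block schedule. Each unit's stimulus drive rises toward its
#' (signed) amplitude with `tau_on_s` during motion in its preferred
#' direction(s) and decays with `tau_off_s` otherwise; the drive is filtered
#' by the calcium-indicator kernel (single-exponential, `indicator_tau_s`),
#' and the filtered response is multiplied by an anesthesia gain that is 1 in
#' baseline blocks, exactly 0 in tricaine blocks, and a logistic
#' `1 / (1 + exp(-(t - x0)/k))` in washout time. Fluorescence is the gained
#' response plus `baseline_f` and Gaussian noise; frame `k` reports the
#' within-frame time average of the model over `[k, k+1)` s. Drive and
#' indicator state carry over between trials (slow offsets bleed into the next
#' trial's baseline, as in slow-indicator recordings).
#'
#' @param units Tibble of unit parameters (see [sample_unit_population()]),
#'   or a list of [unit_params()] objects.
#' @param schedule Block/stimulus schedule from [build_block_schedule()].
#' @param protocol An [imaging_protocol()].
#' @param seed Integer seed (noise only; the schedule carries its own seed).
#' @param gain_fun Optional override: function of washout minutes (vector) and
#'   the unit-parameter tibble returning a gain matrix (frames x units); used
#'   for robustness checks with non-logistic recoveries.
#'
#' @return An object of class `unit_population`: list with `f` (frames x
#'   units matrix of fluorescence, columns named by `unit_id`), `frames`
#'   (tibble `frame`, `t`, `block`, `block_label`, `trial`, `frame_in_trial`,
#'   `phase`, `stimulus`, `washout_min`), `units` (the parameter tibble),
#'   `schedule`, `protocol`, `seed`.
#' @export
simulate_unit_population <- function(units,
                                     schedule,
                                     protocol = imaging_protocol(),
                                     seed = 1,
                                     gain_fun = NULL) {
  units <- as_unit_tibble(units)
  local_rng(seed)
  fr <- protocol$frame_rate_hz
  delta <- 1 / fr
  nf_trial <- as.integer(round(protocol$trial_s * fr))
  n_units <- nrow(units)
  n_trials <- nrow(schedule)
  n_frames <- n_trials * nf_trial

  f_pre <- as.integer(round(protocol$static_pre_s * fr))
  f_mot <- as.integer(round(protocol$motion_s * fr))
  g_active <- c(rep(0, f_pre), rep(1, f_mot),
                rep(0, nf_trial - f_pre - f_mot))
  g_idle <- rep(0, nf_trial)

  coef_act <- trial_filter_coefs(units$tau_on_s, units$tau_off_s,
                                 units$indicator_tau_s, g_active, delta)
  coef_idle <- trial_filter_coefs(units$tau_on_s, units$tau_off_s,
                                  units$indicator_tau_s, g_idle, delta)

  a_signed <- ifelse(units$tuning == "suppressed",
                     -units$amplitude, units$amplitude)
  active_on <- list(
    left = units$tuning %in% c("left_selective", "motion_selective",
                               "suppressed"),
    right = units$tuning %in% c("right_selective", "motion_selective",
                                "suppressed")
  )

  eval_trial <- function(coefs, d0, F0) {
    # returns list(y = n_units x nf_trial, d1, F1)
    y <- coefs$W1 * d0 + coefs$W2 * F0 + coefs$W3 * a_signed
    d1 <- coefs$Ad[, 1] * d0 + coefs$Ad[, 2] * F0 + coefs$Ad[, 3] * a_signed
    F1 <- coefs$Af[, 1] * d0 + coefs$Af[, 2] * F0 + coefs$Af[, 3] * a_signed
    list(y = y, d1 = d1, F1 = F1)
  }

  Y <- matrix(0, n_frames, n_units)
  d <- numeric(n_units)
  Fst <- numeric(n_units)
  for (i in seq_len(n_trials)) {
    act <- active_on[[schedule$stimulus[i]]]
    ea <- eval_trial(coef_act, d, Fst)
    ei <- eval_trial(coef_idle, d, Fst)
    y <- ei$y
    y[act, ] <- ea$y[act, ]
    d <- ifelse(act, ea$d1, ei$d1)
    Fst <- ifelse(act, ea$F1, ei$F1)
    rows <- ((i - 1) * nf_trial + 1):(i * nf_trial)
    Y[rows, ] <- t(y)
  }

  frame0 <- seq_len(n_frames) - 1
  trial_of_frame <- rep(seq_len(n_trials), each = nf_trial)
  fit <- rep(seq_len(nf_trial) - 1L, n_trials)
  phase <- ifelse(fit < f_pre, "pre",
                  ifelse(fit < f_pre + f_mot, "motion", "post"))
  frames <- tibble(
    frame = frame0,
    t = frame0 * delta,
    block = schedule$block[trial_of_frame],
    block_label = schedule$block_label[trial_of_frame],
    trial = schedule$trial[trial_of_frame],
    frame_in_trial = fit,
    phase = phase,
    stimulus = schedule$stimulus[trial_of_frame],
    washout_min = schedule$washout_min[trial_of_frame] + fit * delta / 60
  )

  if (is.null(gain_fun)) {
    G <- matrix(0, n_frames, n_units)
    G[frames$block_label == "baseline", ] <- 1
    wf <- startsWith(frames$block_label, "washout")
    if (any(wf)) {
      wm <- frames$washout_min[wf]
      G[wf, ] <- stats::plogis(
        (matrix(wm, sum(wf), n_units) -
           matrix(units$recovery_x0_min, sum(wf), n_units, byrow = TRUE)) /
          matrix(units$recovery_k_min, sum(wf), n_units, byrow = TRUE))
    }
  } else {
    G <- gain_fun(frames$washout_min, units)
    stopifnot(identical(dim(G), c(n_frames, n_units)))
  }

  f <- matrix(rep(units$baseline_f, each = n_frames), n_frames, n_units) +
    G * Y +
    matrix(rnorm(n_frames * n_units), n_frames, n_units) *
      matrix(units$noise_sd, n_frames, n_units, byrow = TRUE)
  tric <- frames$block_label == "tricaine"
  if (any(units$flicker_sd > 0) && any(tric)) {
    f[tric, ] <- f[tric, ] +
      matrix(rnorm(sum(tric) * n_units), sum(tric), n_units) *
      matrix(units$baseline_f * units$flicker_sd, sum(tric), n_units,
             byrow = TRUE)
  }
  colnames(f) <- units$unit_id

  structure(
    list(f = f, frames = frames, units = units, schedule = schedule,
         protocol = protocol, seed = as.integer(seed)),
    class = "unit_population"
  )
}

#' @export
print.unit_population <- function(x, ...) {
  cat(sprintf("<unit_population> %d units x %d frames (%s)\n",
              ncol(x$f), nrow(x$f),
              paste(unique(x$frames$block_label), collapse = " > ")))
  invisible(x)
}

#' Simulate one unit's fluorescence trace
#'
#' Single-unit convenience wrapper around [simulate_unit_population()].
#'
#' @param params A [unit_params()] object (or one-row tibble).
#' @inheritParams simulate_unit_population
#' @return A tibble `unit_id, t, f, block, block_label, trial,
#'   frame_in_trial, phase, stimulus, washout_min` with the unit parameters in
#'   attribute `"truth"`. Units with `tau_on_s` below the frame interval carry
#'   a `"sub_frame"` attribute (allowed, but unrecoverable at this frame
#'   rate).
#' @examples
#' sched <- build_block_schedule("acute", 1, seed = 1)
#' tr <- simulate_unit_trace(unit_params(noise_sd = 0), sched, seed = 1)
#' head(tr)
#' @export
simulate_unit_trace <- function(params,
                                schedule,
                                protocol = imaging_protocol(),
                                seed = 1,
                                gain_fun = NULL) {
  units <- as_unit_tibble(params)
  stopifnot(nrow(units) == 1)
  pop <- simulate_unit_population(units, schedule, protocol, seed, gain_fun)
  out <- mutate(pop$frames, unit_id = units$unit_id, f = pop$f[, 1])
  out <- select(out, "unit_id", "t", "f", dplyr::everything())
  attr(out, "truth") <- units
  sub_frame <- units$tau_on_s < 1 / protocol$frame_rate_hz
  attr(out, "sub_frame") <- sub_frame
  if (sub_frame) {
    warn(sprintf("tau_on_s = %g s is below the %g s frame interval: sub-frame, unrecoverable",
                 units$tau_on_s, 1 / protocol$frame_rate_hz))
  }
  out
}

as_unit_tibble <- function(units) {
  if (inherits(units, "unit_params")) {
    units <- list(units)
  }
  if (is.list(units) && !is.data.frame(units) &&
      all(vapply(units, inherits, logical(1), "unit_params"))) {
    units <- purrr::map_dfr(units, function(u) {
      as_tibble(u[setdiff(names(u), "sub_frame")])
    })
  }
  units <- as_tibble(units)
  needed <- c("unit_id", "tuning", "amplitude", "tau_on_s", "tau_off_s",
              "baseline_f", "noise_sd", "indicator_tau_s")
  missing <- setdiff(needed, names(units))
  if (length(missing) > 0) {
    abort(paste("missing unit parameter columns:",
                paste(missing, collapse = ", ")))
  }
  if (!"recovery_x0_min" %in% names(units)) units$recovery_x0_min <- 60
  if (!"recovery_k_min" %in% names(units)) units$recovery_k_min <- 12
  if (!"flicker_sd" %in% names(units)) units$flicker_sd <- 0
  if (!"n_neurons" %in% names(units)) units$n_neurons <- 1L
  if (!"region" %in% names(units)) units$region <- "tectum"
  units
}
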