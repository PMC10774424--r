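#' Build a randomized behavioral trial schedule
#'
#' Produces `n_sets` sets of trials; within each set every stimulus condition
#' appears exactly once, in an order shuffled by `seed`. Phase boundary times
#' follow the protocol's pre-static / motion / post-static durations and tile
#' the session without gaps.
#'
#' @param protocol A [behavior_protocol()].
#' @param seed Integer seed; the same seed always yields the same schedule.
#'
#' @return A tibble with one row per trial: `trial`, `set`, `stimulus`,
#'   `t_start`, `t_motion_on`, `t_motion_off`, `t_end` (seconds).
#' @examples
#' sched <- build_trial_schedule(behavior_protocol(), seed = 1)
#' nrow(sched)
#' @export
build_trial_schedule <- function(protocol = behavior_protocol(), seed = 1) {
  stopifnot(inherits(protocol, "behavior_protocol"))
  n_cond <- length(protocol$conditions)
  if (protocol$n_sets == 0) {
    return(tibble(trial = integer(), set = integer(), stimulus = character(),
                  t_start = numeric(), t_motion_on = numeric(),
                  t_motion_off = numeric(), t_end = numeric()))
  }
  rng <- local_rng(seed)
  stim <- unlist(lapply(seq_len(protocol$n_sets), function(s) {
    protocol$conditions[sample.int(n_cond)]
  }))
  trial_s <- protocol$pre_static_s + protocol$motion_s + protocol$post_static_s
  n <- protocol$n_sets * n_cond
  t0 <- (seq_len(n) - 1) * trial_s
  tibble(
    trial = seq_len(n),
    set = rep(seq_len(protocol$n_sets), each = n_cond),
    stimulus = stim,
    t_start = t0,
    t_motion_on = t0 + protocol$pre_static_s,
    t_motion_off = t0 + protocol$pre_static_s + protocol$motion_s,
    t_end = t0 + trial_s
  )
}

#' Build an imaging block and stimulus schedule
#'
#' Lays out hour-long recording blocks for the two anesthesia experiments:
#' `"acute"` starts with a baseline (awake) block followed by one tricaine
#' block and `n_washout_blocks` washout blocks; `"lifetime"` (anesthesia-reared
#' fish) starts directly in tricaine followed by washout blocks. Per-trial
#' left/right stimulus labels are randomized, but every block is guaranteed to
#' contain at least one adjacent left-then-right trial pair so that
#' direction-selectivity pairing is always possible.
#'
#' @param experiment `"acute"` or `"lifetime"`.
#' @param n_washout_blocks Number of washout blocks (>= 1).
#' @param protocol An [imaging_protocol()].
#' @param seed Integer seed.
#'
#' @return A tibble with one row per trial: `block`, `block_label`, `trial`
#'   (global 1-based index), `trial_in_block`, `stimulus`, `t_start` (seconds
#'   from experiment start), `washout_min` (minutes since washout start at the
#'   trial's onset; negative before washout).
#' @export
build_block_schedule <- function(experiment = c("acute", "lifetime"),
                                 n_washout_blocks = 3,
                                 protocol = imaging_protocol(),
                                 seed = 1) {
  experiment <- match.arg(experiment)
  stopifnot(n_washout_blocks >= 1)
  labels <- c(if (experiment == "acute") "baseline", "tricaine",
              paste0("washout_", seq_len(n_washout_blocks)))
  rng <- local_rng(seed)
  npb <- protocol$trials_per_block
  stim <- unlist(lapply(seq_along(labels), function(b) {
    s <- sample(c("left", "right"), npb, replace = TRUE)
    # guarantee an adjacent left-then-right pair in every block
    if (!any(s[-npb] == "left" & s[-1] == "right")) {
      s[1] <- "left"
      s[2] <- "right"
    }
    s
  }))
  n <- length(stim)
  t0 <- (seq_len(n) - 1) * protocol$trial_s
  washout_start_s <- (match(TRUE, startsWith(labels, "washout")) - 1) *
    protocol$block_length_h * 3600
  tibble(
    block = rep(seq_along(labels), each = npb),
    block_label = rep(labels, each = npb),
    trial = seq_len(n),
    trial_in_block = rep(seq_len(npb), times = length(labels)),
    stimulus = stim,
    t_start = t0,
    washout_min = (t0 - washout_start_s) / 60
  )
}

# All randomness in a simulator flows from one integer seed through R's RNG.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  set.seed(as.integer(seed))
  invisible(seed)
}
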