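test_that("turn distributions are counting-exact and normalized", {
  td <- turn_distribution(tibble::tibble(turn_angle_deg = c(30, 30, -30, 0)),
                          bin_width_deg = 20)
  expect_equal(td$probability[td$bin_left == 20], 0.5)
  expect_equal(td$probability[td$bin_left == -40], 0.25)
  expect_equal(td$probability[td$bin_left == 0], 0.25)
  expect_equal(sum(td$probability), 1, tolerance = 1e-12)

  # degenerate: all bouts exactly 0 degrees
  td0 <- turn_distribution(tibble::tibble(turn_angle_deg = rep(0, 7)))
  expect_equal(td0$probability[td0$bin_left <= 0 & td0$bin_right > 0], 1)

  # empty marker, not NaNs
  tde <- turn_distribution(tibble::tibble(turn_angle_deg = numeric()))
  expect_equal(nrow(tde), 0)
  expect_equal(attr(tde, "n_bouts"), 0L)

  # normalization holds for arbitrary samples
  set.seed(1)
  for (i in 1:5) {
    td <- turn_distribution(
      tibble::tibble(turn_angle_deg = runif(50, -180, 180)))
    expect_equal(sum(td$probability), 1, tolerance = 1e-12)
  }
})

test_that("proportion correct follows the sign convention and counts", {
  b <- tibble::tibble(turn_angle_deg = c(20, -20))
  expect_equal(proportion_correct(b, "left")$n_correct, 1)
  expect_equal(proportion_correct(b, "right")$n_correct, 1)
  # 96 of 100 sign-matching turn bouts
  b2 <- tibble::tibble(turn_angle_deg = c(rep(25, 96), rep(-25, 4)))
  expect_equal(proportion_correct(b2, "left")$proportion_correct, 0.96)
  # forward band excluded; empty denominator -> NA marker
  b3 <- tibble::tibble(turn_angle_deg = c(3, -7, 0, 9))
  res <- proportion_correct(b3, "right")
  expect_equal(res$n_turns, 0)
  expect_true(is.na(res$proportion_correct))
})

test_that("bout frequency is count over duration", {
  expect_equal(
    bout_frequency(tibble::tibble(t_on = seq(1, 59, by = 2)),
                   window = c(0, 60)), 0.5)
  expect_equal(
    bout_frequency(tibble::tibble(t_on = numeric()), window = c(0, 10)), 0)
  expect_equal(
    bout_frequency(tibble::tibble(t_on = 1:30), duration_s = 60), 0.5)
})

test_that("cumulative turn angle is a prefix sum with correct group bands", {
  prot <- behavior_protocol(n_sets = 1, conditions = "left")
  trials <- build_trial_schedule(prot, 1)
  b <- tibble::tibble(t_on = c(6, 9, 12), duration = 0.15,
                      turn_angle_deg = c(10, 10, -5),
                      displacement_cm = 0.2, trial = 1L,
                      stimulus = "left",
                      phase = c("motion", "motion", "post"))
  s <- fake_session(b, prot, trials)
  out <- cumulative_turn_angle(list(s), "left", bin_s = 1)
  v <- out$per_fish$cum_angle_deg
  tt <- out$per_fish$t
  expect_equal(v[tt == 6], 0)     # before first bout
  expect_equal(v[tt == 7], 10)
  expect_equal(v[tt == 10], 20)
  expect_equal(v[tt == 13], 15)
  # no bouts -> identically zero
  s0 <- fake_session(b[0, ], prot, trials)
  out0 <- cumulative_turn_angle(list(s0), "left")
  expect_true(all(out0$per_fish$cum_angle_deg == 0))
})

test_that("cumulative angle sign tracks the generator bias", {
  mk <- function(cond, seeds) {
    lapply(seeds, function(i) {
      simulate_session(behavior_protocol(n_sets = 6, conditions = cond),
                       fish_params(p_correct = 0.95), seed = i,
                       include_tracking = FALSE, fish_id = paste0("f", i))
    })
  }
  left <- cumulative_turn_angle(mk("left", 1:6), "left")
  right <- cumulative_turn_angle(mk("right", 1:6), "right")
  expect_gt(tail(left$summary$median, 1), 0)
  expect_lt(tail(right$summary$median, 1), 0)
  none <- cumulative_turn_angle(mk("none", 1:8), "none")
  last <- tail(none$summary, 1)
  expect_lte(last$q25, 0)
  expect_gte(last$q75, 0)
})

test_that("within-stimulus performance rises with a slow accumulator", {
  sess <- lapply(1:10, function(i) {
    simulate_session(behavior_protocol(n_sets = 12,
                                       conditions = c("left", "right")),
                     fish_params(p_correct = 0.967, tau_int_s = 2),
                     seed = 100 + i, include_tracking = FALSE,
                     fish_id = paste0("f", i))
  })
  curve <- performance_vs_time(sess)
  med <- curve$summary$median
  expect_lt(med[1], tail(med, 1))
  ct <- suppressWarnings(
    stats::cor.test(curve$summary$t_mid, med, method = "spearman",
                    alternative = "greater"))
  expect_lt(ct$p.value, 0.01)
})

test_that("an instantaneous accumulator gives a flat curve at p_target", {
  sess <- lapply(1:10, function(i) {
    simulate_session(behavior_protocol(n_sets = 12,
                                       conditions = c("left", "right")),
                     fish_params(p_correct = 0.9, tau_int_s = 1e-6),
                     seed = 200 + i, include_tracking = FALSE,
                     fish_id = paste0("f", i))
  })
  curve <- performance_vs_time(sess)
  expect_true(all(abs(curve$summary$median - 0.9) < 0.08))
})

test_that("empty time bins propagate NA instead of being interpolated", {
  s <- simulate_session(behavior_protocol(n_sets = 2), noiseless_fish(),
                        seed = 3, gain_fun = function(t) rep(0, length(t)))
  curve <- performance_vs_time(list(s))
  expect_true(all(is.na(curve$summary$median)))
})

test_that("per-trial performance shows transients only when generated", {
  mk <- function(first, seeds) {
    lapply(seeds, function(i) {
      simulate_session(
        behavior_protocol(n_sets = 10, conditions = c("left", "right")),
        fish_params(p_correct = 0.95, first_trial_accuracy = first),
        seed = 300 + i, include_tracking = FALSE, fish_id = paste0("f", i))
    })
  }
  # strong transient: early sets worse than late sets
  tr <- performance_vs_trial(mk(0.6, 1:10))
  expect_lt(tr$summary$median[1], mean(tr$summary$median[5:10]))
  # stationary generator: no comparable gap
  st <- performance_vs_trial(mk(NA_real_, 1:10))
  expect_lt(abs(st$summary$median[1] - mean(st$summary$median[5:10])), 0.1)
  # single fish, single-set schedule -> one-point curve
  one <- performance_vs_trial(list(
    simulate_session(behavior_protocol(n_sets = 1,
                                       conditions = c("left", "right")),
                     fish_params(), seed = 4, include_tracking = FALSE)))
  expect_equal(nrow(one$summary), 1)
})
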