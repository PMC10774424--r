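test_that("unit traces are reproducible and block-structured", {
  sched <- build_block_schedule("acute", 1, seed = 2)
  u <- unit_params()
  a <- simulate_unit_trace(u, sched, seed = 5)
  b <- simulate_unit_trace(u, sched, seed = 5)
  expect_identical(a$f, b$f)
  expect_equal(nrow(a), nrow(sched) * 60)
  expect_equal(unique(a$block_label),
               c("baseline", "tricaine", "washout_1"))
})

test_that("zero gain leaves baseline plus noise only", {
  sched <- build_block_schedule("acute", 1, seed = 1)
  u <- unit_params(noise_sd = 5)
  pop <- simulate_unit_population(
    list(u), sched, seed = 1,
    gain_fun = function(wm, units) matrix(0, length(wm), nrow(units)))
  f <- pop$f[, 1]
  seg <- segment_trials(tibble::tibble(t = pop$frames$t, f = f), sched)
  resp <- trial_responses(seg, window = "motion")
  # motion-window C-C0 is centred on zero
  ci <- qt(0.995, nrow(resp) - 1) * sd(resp$trial_mean) / sqrt(nrow(resp))
  expect_lt(abs(mean(resp$trial_mean)), ci)
  expect_lt(abs(mean(f) - u$baseline_f), 1)
})

test_that("a noiseless selective unit ignores the non-preferred direction", {
  sched <- build_block_schedule("acute", 1, seed = 3)
  u <- unit_params(noise_sd = 0, tau_off_s = 1, indicator_tau_s = 1)
  tr <- simulate_unit_trace(u, sched, seed = 1)
  resp <- trial_responses(segment_trials(tr, sched), window = "motion")
  base <- resp[resp$block_label == "baseline", ]
  right_first <- base$trial[base$stimulus == "right" &
                              !dplyr::lag(base$stimulus == "left",
                                          default = FALSE)]
  # right trials not preceded by a left trial have exactly zero response
  iso <- base[base$stimulus == "right" &
                c("x", base$stimulus[-nrow(base)]) != "left", ]
  expect_true(all(abs(iso$trial_mean) < 1e-9))
  expect_true(all(base$trial_mean[base$stimulus == "left"] > 50))
})

test_that("the drive follows its closed-form exponential rise", {
  # near-instantaneous indicator exposes the drive itself; frame values are
  # within-frame averages of amplitude * (1 - exp(-t/tau_on))
  sched <- single_block_schedule(2)
  u <- unit_params(noise_sd = 0, tau_on_s = 2, tau_off_s = 40,
                   amplitude = 100, baseline_f = 0,
                   indicator_tau_s = 1e-4)
  tr <- suppressWarnings(simulate_unit_trace(u, sched, seed = 1))
  motion <- tr$f[tr$trial == 1 & tr$phase == "motion"]
  k <- seq_along(motion) - 1
  expected <- 100 * (1 - 2 * (exp(-k / 2) - exp(-(k + 1) / 2)))
  expect_equal(motion, expected, tolerance = 1e-3)
})

test_that("the exact propagator matches an independent ODE solver", {
  skip_if_not_installed("deSolve")
  prot <- imaging_protocol()
  sched <- single_block_schedule(1, prot)
  u <- unit_params(noise_sd = 0, tau_on_s = 1.3, tau_off_s = 7,
                   amplitude = 200, baseline_f = 0, indicator_tau_s = 1.8)
  tr <- simulate_unit_trace(u, sched, seed = 1)
  drive_in <- function(t) if (t >= 10 && t < 40) 200 else 0
  ode <- deSolve::ode(
    y = c(d = 0, F = 0), times = seq(0, 60, by = 0.01),
    func = function(t, y, p) {
      u_t <- drive_in(t)
      tau_d <- if (u_t != 0) 1.3 else 7
      list(c((u_t - y[1]) / tau_d, (y[1] - y[2]) / 1.8))
    }, parms = NULL, rtol = 1e-10, atol = 1e-10)
  fr_avg <- vapply(0:59, function(k) {
    mean(ode[ode[, "time"] >= k & ode[, "time"] < k + 1, "F"])
  }, numeric(1))
  expect_equal(tr$f, fr_avg, tolerance = 1e-3)
})

test_that("noiseless trial-averaged responses are stationary across trials", {
  sched <- single_block_schedule(8)
  u <- unit_params(noise_sd = 0, tau_off_s = 1, indicator_tau_s = 1)
  tr <- simulate_unit_trace(u, sched, seed = 1)
  left <- tr[tr$stimulus == "left" & tr$trial > 2, ]
  per_trial <- split(left$f - rep(tapply(left$f, left$trial, function(v) {
    mean(v[1:10])
  }), each = 60), left$trial)
  for (i in seq_along(per_trial)[-1]) {
    expect_equal(per_trial[[i]], per_trial[[1]], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("washout gain is nondecreasing and responses recover in time", {
  sched <- build_block_schedule("lifetime", 3, seed = 4)
  u <- unit_params(noise_sd = 0, tau_off_s = 2, recovery_x0_min = 60,
                   recovery_k_min = 10)
  tr <- simulate_unit_trace(u, sched, seed = 1)
  resp <- trial_responses(segment_trials(tr, sched), window = "motion")
  left <- resp[resp$stimulus == "left" &
                 startsWith(resp$block_label, "washout"), ]
  left <- left[order(left$washout_min), ]
  # responses rise monotonically (tiny numerical carryover tolerated)
  expect_true(all(diff(left$trial_mean) > -0.5))
  expect_lt(left$trial_mean[1], 0.2 * max(left$trial_mean))
  # tricaine block is silent
  expect_true(all(abs(
    resp$trial_mean[resp$block_label == "tricaine"]) < 1e-9))
})

test_that("movies render units that round-trip through ROI extraction", {
  sched <- single_block_schedule(2)
  units <- list(
    unit_params(unit_id = "a", tuning = "left_selective", noise_sd = 0),
    unit_params(unit_id = "b", tuning = "right_selective", noise_sd = 0))
  pop <- simulate_unit_population(units, sched, seed = 1)
  mv <- render_movie(pop, field_px = 32, roi_px = 8, pixel_noise_sd = 0,
                     seed = 2)
  tr <- extract_roi_traces(mv)
  # noiseless rendering is exactly proportional to the source
  expect_equal(cor(tr[, "a"], pop$f[, "a"]), 1, tolerance = 1e-12)
  expect_equal(cor(tr[, "b"], pop$f[, "b"]), 1, tolerance = 1e-12)
  # each ROI tracks its own source, not the other unit
  expect_gt(cor(tr[, "a"], pop$f[, "a"]), abs(cor(tr[, "a"], pop$f[, "b"])))
  expect_gt(cor(tr[, "b"], pop$f[, "b"]), abs(cor(tr[, "b"], pop$f[, "a"])))
})

test_that("degenerate movie inputs behave", {
  f0 <- matrix(numeric(0), nrow = 5, ncol = 0)
  mv <- render_movie(f = f0, field_px = 16, roi_px = 8,
                     pixel_noise_sd = 1, seed = 1)
  expect_equal(dim(mv$stack), c(16, 16, 5))
  expect_lt(abs(sd(mv$stack) - 1), 0.1)   # pure noise stack
  f2 <- matrix(1, 3, 5)
  expect_error(render_movie(f = f2, field_px = 8, roi_px = 8, seed = 1),
               "field too small")
})

test_that("sub-frame onset constants are flagged at generation", {
  sched <- single_block_schedule(1)
  expect_warning(
    simulate_unit_trace(unit_params(tau_on_s = 0.2), sched, seed = 1),
    "sub-frame")
})
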