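test_that("sessions are bit-reproducible under a fixed seed", {
  p <- behavior_protocol(n_sets = 2)
  a <- simulate_session(p, fish_params(), seed = 11)
  b <- simulate_session(p, fish_params(), seed = 11)
  expect_identical(a$trials, b$trials)
  expect_identical(a$bouts, b$bouts)
  expect_identical(a$tracking, b$tracking)
  expect_false(identical(
    a$bouts, simulate_session(p, fish_params(), seed = 12)$bouts))
})

test_that("zero anesthesia gain silences the fish completely", {
  s <- simulate_session(behavior_protocol(n_sets = 2), noiseless_fish(),
                        seed = 3, gain_fun = function(t) rep(0, length(t)))
  expect_equal(nrow(s$bouts), 0)
  expect_true(all(s$tracking$heading_deg == 0))
  expect_true(all(s$tracking$x == 0))
})

test_that("turn direction matches the stimulus at the binomial rate", {
  # near-instantaneous accumulator isolates the Bernoulli turn mechanism
  p_target <- 0.95
  prot <- behavior_protocol(n_sets = 30, conditions = "left")
  ang <- unlist(lapply(1:9, function(seed) {
    s <- simulate_session(prot,
                          fish_params(p_correct = p_target,
                                      tau_int_s = 1e-6),
                          seed = seed, include_tracking = FALSE)
    b <- s$bouts[s$bouts$phase == "motion", ]
    b$turn_angle_deg[abs(b$turn_angle_deg) > 10]
  }))
  expect_gt(length(ang), 2000)
  n_left <- sum(ang > 0)
  ci <- qbinom(c(0.005, 0.995), length(ang), p_target)
  expect_gte(n_left, ci[1])
  expect_lte(n_left, ci[2])
})

test_that("bout counts in motion windows match the renewal rate (Poisson check)", {
  # 30 forward trials x 10 s motion = 300 s at rate_stim 1 Hz
  prot <- behavior_protocol(n_sets = 30, conditions = "forward")
  s <- simulate_session(prot, fish_params(), seed = 7,
                        include_tracking = FALSE)
  n_motion <- sum(s$bouts$phase == "motion")
  ci <- qpois(c(0.005, 0.995), 300)
  expect_gte(n_motion, ci[1])
  expect_lte(n_motion, ci[2])
  # no-stimulus epochs at rate_nostim 0.5 Hz: 300 s static in same session
  n_static <- sum(s$bouts$phase != "motion")
  ci2 <- qpois(c(0.005, 0.995), 0.5 * 300)
  expect_gte(n_static, ci2[1])
  expect_lte(n_static, ci2[2])
})

test_that("the evidence accumulator matches its closed-form solution", {
  win <- tibble::tibble(t_on = 5, t_off = 15)
  tt <- seq(5, 14.99, by = 0.07)
  e <- evidence_trace(tt, win, tau = 2)
  expect_equal(e, 1 - exp(-(tt - 5) / 2), tolerance = 1e-12)
  # decay after offset
  t2 <- seq(15, 25, by = 0.11)
  e2 <- evidence_trace(t2, win, tau = 2)
  e_off <- 1 - exp(-10 / 2)
  expect_equal(e2, e_off * exp(-(t2 - 15) / 2), tolerance = 1e-12)
})

test_that("evidence accumulator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  win <- tibble::tibble(t_on = c(2, 12), t_off = c(7, 16))
  tau <- 1.7
  tt <- seq(0, 20, by = 0.25)
  ode <- deSolve::ode(
    y = c(E = 0), times = tt,
    func = function(t, y, p) {
      s <- as.numeric(any(win$t_on <= t & t < win$t_off))
      list((s - y) / tau)
    }, parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
  expect_equal(evidence_trace(tt, win, tau), unname(ode[, "E"]),
               tolerance = 1e-5)
})

test_that("left and right turns are exchangeable without directed motion", {
  prot <- behavior_protocol(n_sets = 6, conditions = "none")
  pass <- vapply(1:20, function(seed) {
    s <- simulate_session(prot, fish_params(), seed = 400 + seed,
                          include_tracking = FALSE)
    ang <- s$bouts$turn_angle_deg
    turns <- ang[abs(ang) > 10]
    stats::binom.test(sum(turns > 0), length(turns))$p.value > 0.01
  }, logical(1))
  expect_gte(sum(pass), 18)  # >= 95% of seeds at alpha = 0.01
})

test_that("acute anesthesia suppresses early-session bouts", {
  prot <- behavior_protocol(n_sets = 30, conditions = "forward")
  s <- simulate_session(prot, fish_params(), "acute_tricaine", seed = 5,
                        include_tracking = FALSE)
  t_half <- max(s$trials$t_end) / 2
  expect_lt(sum(s$bouts$t_on < t_half), sum(s$bouts$t_on >= t_half))
  expect_gt(nrow(s$bouts), 0)
})
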