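test_that("exponential recovery is exact on noiseless model data", {
  t <- seq(0, 150, by = 2.5)
  for (true in list(c(r_inf = 1, t0 = 0, tau = 25),
                    c(r_inf = 0.6, t0 = 12, tau = 40))) {
    r <- ifelse(t >= true["t0"],
                true["r_inf"] * (1 - exp(-(t - true["t0"]) / true["tau"])),
                0)
    f <- fit_exp_recovery(t, r)
    expect_true(f$converged)
    expect_equal(f$tau_min, unname(true["tau"]), tolerance = 1e-6)
    expect_equal(f$r_inf, unname(true["r_inf"]), tolerance = 1e-6)
  }
  # determinism
  r <- 1 - exp(-t / 25)
  expect_identical(fit_exp_recovery(t, r), fit_exp_recovery(t, r))
})

test_that("degenerate rate inputs do not fake convergence", {
  t <- seq(0, 100, by = 5)
  expect_false(fit_exp_recovery(t, rep(0, length(t)))$converged)
  expect_false(fit_exp_recovery(t, rep(0.7, length(t)))$converged)
})

test_that("noisy bout-rate recovery still finds the time constant", {
  t <- seq(0, 150, by = 5)
  taus <- vapply(1:15, function(seed) {
    set.seed(seed)
    r <- pmax(0, (1 - exp(-t / 25)) + rnorm(length(t), 0, 0.1))
    fit_exp_recovery(t, r)$tau_min
  }, numeric(1))
  expect_lt(abs(stats::median(taus) - 25) / 25, 0.1)
})

test_that("logistic recovery is exact on noiseless data and flags reversals", {
  t <- seq(0, 180, by = 3)
  v <- 0.9 / (1 + exp(-(t - 90) / 15))
  f <- fit_logistic_recovery(t, v)
  expect_true(f$converged)
  expect_equal(f$x0_min, 90, tolerance = 1e-6)
  expect_equal(f$k_min, 15, tolerance = 1e-6)
  expect_equal(f$amplitude, 0.9, tolerance = 1e-6)

  expect_false(fit_logistic_recovery(t, rep(0.4, length(t)))$converged)
  rev_fit <- fit_logistic_recovery(t, rev(v))
  expect_true("negative_slope" %in% rev_fit$flags)
  expect_false(rev_fit$converged)
})

test_that("onset/offset fits are exact on their own forward model", {
  prot <- imaging_protocol()
  sched <- single_block_schedule(4)
  u <- unit_params(noise_sd = 0, tau_on_s = 2, tau_off_s = 10,
                   amplitude = 300, baseline_f = 0)
  tr <- simulate_unit_trace(u, sched, seed = 1)
  avg <- trial_average(segment_trials(tr, sched), stimulus = "left")
  f <- fit_onset_offset(avg, prot)
  expect_true(f$converged)
  expect_lt(abs(f$tau_on_s - 2) / 2, 0.05)
  expect_lt(abs(f$tau_off_s - 10) / 10, 0.05)
})

test_that("sub-frame onset constants are flagged by the fitter", {
  sched <- single_block_schedule(4)
  u <- unit_params(noise_sd = 0, tau_on_s = 0.2, tau_off_s = 8,
                   amplitude = 300, baseline_f = 0)
  tr <- suppressWarnings(simulate_unit_trace(u, sched, seed = 1))
  avg <- trial_average(segment_trials(tr, sched), stimulus = "left")
  f <- fit_onset_offset(avg)
  expect_true(any(c("sub_frame", "unresolved") %in% f$flags))
})

test_that("the kernel-bias audit documents naive bias and corrected accuracy", {
  audit <- audit_kernel_bias(tau_on_grid = c(1, 3), tau_off_grid = c(5, 20),
                             n_trials = 4)
  corr <- audit[audit$corrected, ]
  naive <- audit[!audit$corrected, ]
  expect_true(all(corr$rel_err_on < 0.05))
  expect_true(all(corr$rel_err_off < 0.05))
  # the uncorrected fit inherits the indicator kernel's bias
  expect_gt(stats::median(naive$rel_err_on), 0.3)
  expect_gt(stats::median(naive$rel_err_on),
            stats::median(corr$rel_err_on))
})

test_that("population recovery fits order acute before lifetime onsets", {
  prot <- imaging_protocol()
  mk <- function(exper, x0_mean, seed) {
    sched <- build_block_schedule(exper, 3, prot, seed = seed)
    units <- sample_unit_population(
      6, exper, seed = seed,
      tuning_probs = c(left_selective = 1, right_selective = 0,
                       motion_selective = 0, suppressed = 0),
      x0_mean_min = x0_mean, frac_weak = 0)
    pop <- simulate_unit_population(units, sched, prot, seed = seed + 1)
    resp <- trial_responses(
      segment_trials(population_frames(pop), sched, prot),
      window = "motion")
    wash <- resp[startsWith(resp$block_label, "washout") &
                   resp$stimulus == "left", ]
    fit_population_recovery(wash, value = "trial_mean")
  }
  acute <- mk("acute", 45, 11)
  life <- mk("lifetime", 90, 12)
  expect_gt(acute$summary$n_converged, 3)
  expect_gt(life$summary$n_converged, 3)
  expect_lt(acute$summary$x0_median, life$summary$x0_median)
})

test_that("tidy and glance methods expose fit parameters", {
  t <- seq(0, 150, by = 5)
  f <- fit_exp_recovery(t, 1 - exp(-t / 25))
  expect_equal(tidy(f)$term, c("r_inf", "t0", "tau_min"))
  expect_true(glance(f)$converged)
  g <- fit_logistic_recovery(t, 1 / (1 + exp(-(t - 60) / 10)))
  expect_equal(nrow(tidy(g)), 3)
  expect_equal(glance(g)$nobs, length(t))
})
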