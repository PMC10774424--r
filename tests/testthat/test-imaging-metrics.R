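test_that("trial segmentation lays out frames, phases, and numbering", {
  sched <- build_block_schedule("acute", 1, seed = 1)
  tr <- tibble::tibble(t = 0:(nrow(sched) * 60 - 1), f = 0)
  seg <- segment_trials(tr, sched)
  expect_equal(length(unique(seg$trial)), 180)
  expect_equal(sum(seg$trial == 1), 60)
  # frame 10 is the first motion frame
  expect_equal(min(seg$frame_in_trial[seg$phase == "motion"]), 10)
  expect_equal(max(seg$frame_in_trial[seg$phase == "pre"]), 9)
  # concatenated blocks preserve global trial numbering
  expect_equal(unique(seg$trial[seg$block == 2]), 61:120)
  # short traces are rejected
  expect_error(segment_trials(tr[1:100, ], sched), "needs")
})

test_that("ROI extraction is the per-frame box mean", {
  stack <- array(7, c(4, 4, 3))
  rois <- tibble::tibble(unit_id = "u1", x0 = 0, y0 = 0, x1 = 2, y1 = 2)
  expect_equal(as.numeric(extract_roi_traces(stack, rois)), c(7, 7, 7))
  # 1x1 ROI is that pixel's series
  stack[2, 3, ] <- c(1, 2, 3)
  r1 <- tibble::tibble(unit_id = "px", x0 = 2, y0 = 1, x1 = 3, y1 = 2)
  expect_equal(as.numeric(extract_roi_traces(stack, r1)), c(1, 2, 3))
  # out-of-bounds rejected
  bad <- tibble::tibble(unit_id = "b", x0 = 2, y0 = 0, x1 = 5, y1 = 2)
  expect_error(extract_roi_traces(stack, bad), "bounds")
})

test_that("C - C0 subtracts the pre-motion baseline without division", {
  flat <- compute_trial_response(rep(42, 60))
  expect_true(all(flat$c_minus_c0 == 0))
  expect_equal(flat$trial_mean, 0)

  r <- compute_trial_response(c(rep(100, 10), rep(150, 30), rep(100, 20)))
  expect_equal(r$c0, 100)
  expect_equal(unique(r$c_minus_c0[11:40]), 50)
  expect_equal(r$trial_mean, 25)  # (0*10 + 50*30 + 0*20)/60
  rm <- compute_trial_response(c(rep(100, 10), rep(150, 30), rep(100, 20)),
                               window = "motion")
  expect_equal(rm$trial_mean, 50)

  # zero baseline is explicitly valid (the reason for C - C0 over dC/C0)
  z <- compute_trial_response(c(rep(0, 10), rep(80, 30), rep(0, 20)))
  expect_equal(z$c0, 0)
  expect_true(is.finite(z$trial_mean) && z$trial_mean > 0)
})

test_that("baseline-window mean of C - C0 is exactly zero for any trace", {
  set.seed(7)
  for (i in 1:10) {
    r <- compute_trial_response(rnorm(60, 50, 20))
    expect_equal(mean(r$c_minus_c0[1:10]), 0, tolerance = 1e-12)
  }
})

test_that("responsiveness normalizes to the per-unit max-absolute response", {
  r <- tibble::tibble(unit_id = "u1", trial = 1:3,
                      trial_mean = c(2, 4, -1))
  expect_equal(responsiveness_index(r)$responsiveness, c(0.5, 1, -0.25))

  pos <- tibble::tibble(unit_id = "u1", trial = 1:4,
                        trial_mean = c(1, 3, 2, 0.5))
  ri <- responsiveness_index(pos)
  expect_equal(max(ri$responsiveness), 1)
  expect_equal(unique(ri$net_sign), 1)

  neg <- tibble::tibble(unit_id = "u1", trial = 1:4,
                        trial_mean = c(-1, -3, 0, -0.5))
  rn <- responsiveness_index(neg)
  expect_equal(min(rn$responsiveness), -1)
  expect_equal(unique(rn$net_sign), -1)

  zero <- tibble::tibble(unit_id = "u1", trial = 1:3, trial_mean = 0)
  rz <- responsiveness_index(zero)
  expect_true(all(rz$unresponsive))
  expect_true(all(rz$responsiveness == 0))

  # bounds hold for arbitrary inputs, across units independently
  set.seed(3)
  big <- tibble::tibble(unit_id = rep(c("a", "b"), each = 20),
                        trial = rep(1:20, 2),
                        trial_mean = rnorm(40, 0, 50))
  rb <- responsiveness_index(big)
  expect_true(all(abs(rb$responsiveness) <= 1))
  expect_equal(as.numeric(tapply(abs(rb$responsiveness), rb$unit_id, max)),
               c(1, 1))
})

test_that("the DSI pairs left-then-right trials and normalizes to [-1, 1]", {
  base <- tibble::tibble(unit_id = "u1", trial = 1:4,
                         stimulus = c("left", "right", "left", "right"))
  # responds only on left trials -> +1 (leftward-selective)
  d1 <- dsi_series(dplyr::mutate(base, trial_mean = c(5, 0, 5, 0)))
  expect_equal(d1$dsi, c(1, 1))
  # responds only on right trials -> -1 (rightward-selective)
  d2 <- dsi_series(dplyr::mutate(base, trial_mean = c(0, 5, 0, 5)))
  expect_equal(d2$dsi, c(-1, -1))
  # pair diffs {2, -4} -> {0.5, -1}
  d3 <- dsi_series(dplyr::mutate(base, trial_mean = c(2, 0, 0, 4)))
  expect_equal(d3$dsi, c(0.5, -1))
  # equal responses -> 0
  d4 <- dsi_series(dplyr::mutate(base, trial_mean = c(3, 3, 3, 3)))
  expect_true(all(d4$dsi == 0))
  # no conforming pair -> empty, flagged by zero rows
  rr <- tibble::tibble(unit_id = "u1", trial = 1:3,
                       stimulus = c("right", "right", "left"),
                       trial_mean = c(1, 2, 3))
  expect_equal(nrow(dsi_series(rr)), 0)
  # non-conforming adjacencies are skipped, pairs never overlap
  seq5 <- tibble::tibble(unit_id = "u1", trial = 1:5,
                         stimulus = c("left", "left", "right", "right",
                                      "left"),
                         trial_mean = c(1, 4, 2, 0, 1))
  d5 <- dsi_series(seq5)
  expect_equal(d5$trial_left, 2)
  expect_equal(d5$trial_right, 3)
})

test_that("the fittable filter applies a strict threshold of 100", {
  r <- tibble::tibble(unit_id = c("hi", "lo", "edge"),
                      trial = 1,
                      max_cmc0 = c(150, 50, 100))
  ff <- filter_fittable(r)
  expect_true(ff$fittable[ff$unit_id == "hi"])
  expect_false(ff$fittable[ff$unit_id == "lo"])
  expect_false(ff$fittable[ff$unit_id == "edge"])  # strict inequality
  expect_equal(fittable_units(r), "hi")
})

test_that("trial averages recover a boxcar response", {
  sched <- single_block_schedule(6)
  tr <- boxcar_trace(sched, left_amp = 40)
  seg <- segment_trials(tr, sched)
  avg <- trial_average(seg, stimulus = "left")
  expect_equal(avg$mean_cmc0[avg$phase == "motion"], rep(40, 30))
  expect_equal(avg$mean_cmc0[avg$phase == "pre"], rep(0, 10))
  expect_equal(unique(avg$n_trials), 3)
})
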