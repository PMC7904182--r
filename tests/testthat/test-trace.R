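make_trace <- function(values, times = recording_times(), ...) {
  intensity_trace(times, rep_len(values, length(times)), ...)
}

test_that("windowed trapezoid integral matches closed forms", {
  # constant c over [560, 800] -> 240 c
  expect_equal(integrate_trace(make_trace(3), c(560, 800)), 720)
  expect_equal(integrate_trace(make_trace(1), c(560, 900)), 340)

  # triangle peak: piecewise-linear, trapezoid is exact
  tri <- intensity_trace(c(560, 600, 640), c(0, 2, 0))
  expect_equal(integrate_trace(tri, c(560, 640), allow_short = TRUE), 80)
  # window edge falls mid-segment: linear interpolation at the bound
  expect_equal(integrate_trace(tri, c(580, 640), allow_short = TRUE),
               80 - 0.5 * 20 * 1)
})

test_that("integral equals the dense-resampling oracle on random traces", {
  set.seed(11)
  for (rep in 1:5) {
    tt <- recording_times()
    vv <- runif(length(tt), 0.5, 5)
    tr <- intensity_trace(tt, vv)
    for (w in list(c(560, 800), c(600, 750), c(560, 695), c(696, 800))) {
      got <- integrate_trace(tr, w)
      exp_val <- oracle_integral(tt, vv, w)
      expect_equal(got, exp_val, tolerance = 1e-9)
    }
  }
})

test_that("integration is additive and invariant under grid refinement", {
  set.seed(12)
  tt <- recording_times()
  vv <- runif(length(tt), 0.5, 5)
  tr <- intensity_trace(tt, vv)
  ab <- integrate_trace(tr, c(560, 700))
  bc <- integrate_trace(tr, c(700, 900))
  ac <- integrate_trace(tr, c(560, 900))
  expect_equal(ab + bc, ac, tolerance = 1e-12)

  # refining the grid of a piecewise-linear trace leaves the integral fixed
  mid <- (tt[-1] + tt[-length(tt)]) / 2
  tt2 <- sort(c(tt, mid))
  tr2 <- intensity_trace(tt2, approx(tt, vv, xout = tt2)$y)
  expect_equal(integrate_trace(tr2, c(560, 900)),
               integrate_trace(tr, c(560, 900)), tolerance = 1e-9)
})

test_that("curve qualification and window guards are enforced", {
  short <- intensity_trace(seq(560, 600, 10), rep(1, 5))
  expect_error(integrate_trace(short, c(560, 600)), "fewer than 10")
  expect_equal(integrate_trace(short, c(560, 600), allow_short = TRUE), 40)
  expect_error(integrate_trace(make_trace(1), c(1000, 1100)),
               "outside the trace support")
  expect_error(integrate_trace(make_trace(1), c(800, 700)), "lower < upper")
  expect_warning(integrate_trace(make_trace(1), c(500, 800)),
                 "does not cover")
})

test_that("onset detection finds sustained rises and ignores flat traces", {
  expect_true(is.na(detect_onset(make_trace(1.0), 1.2)))
  # a single-sample blip does not satisfy min_run = 2
  tt <- seq(560, 700, 10)
  vv <- rep(1, length(tt)); vv[5] <- 2
  expect_true(is.na(detect_onset(intensity_trace(tt, vv), 1.2, min_run = 2)))
  expect_equal(detect_onset(intensity_trace(tt, vv), 1.2, min_run = 1),
               tt[5])
  vv[6] <- 2
  expect_equal(detect_onset(intensity_trace(tt, vv), 1.2, min_run = 2),
               tt[5])
})

test_that("detected calcium onsets track the generator ground truth", {
  for (s in 1:3) {
    co <- simulate_cohort(scenario_mec4d(seed = s, noise_sd = 0))
    for (cl in co$cells) {
      truth <- cl$truth$ca_onset
      det <- detect_onset(cl$ca, 1.2, min_run = 2)
      if (is.na(truth)) next
      expect_lte(abs(det - truth), 5)  # one sampling interval
    }
  }
})

test_that("swelling detection matches the programmed onset", {
  tt <- recording_times()
  expect_true(is.na(detect_swelling(tt, rep(10, length(tt)))))
  expect_error(detect_swelling(c(560, 570), c(0, 5)), "positive")
  for (s in 1:3) {
    co <- simulate_cohort(scenario_mec4d(seed = s, noise_sd = 0))
    for (cl in co$cells) {
      truth <- cl$truth$swelling_onset
      det <- detect_swelling(cl$radius$time, cl$radius$radius)
      if (is.na(truth)) expect_true(is.na(det))
      else expect_lte(det - truth, 5)  # within one sampling interval
    }
  }
})

test_that("mean swelling time of the default necrotic cohort sits near the
           695-min epoch boundary", {
  det <- c()
  for (s in 1:5) {
    co <- simulate_cohort(scenario_mec4d(seed = s, noise_sd = 0))
    for (cl in co$cells)
      det <- c(det, detect_swelling(cl$radius$time, cl$radius$radius))
  }
  expect_lt(abs(mean(det, na.rm = TRUE) - 695), 25)
})

test_that("peak metrics report programmed bumps", {
  expect_equal(nrow(peak_metrics(make_trace(1.0))), 0)

  p <- trace_params(peak_amplitudes = 3, peak_times = 620)
  tr <- simulate_ca_trace(p, recording_times())
  pm <- peak_metrics(tr, 1.2)
  expect_equal(nrow(pm), 1)
  expect_equal(pm$peak_value, 3.0)
  expect_equal(pm$peak_time, 620)
  expect_gt(pm$duration_min, 0)

  p3 <- trace_params(peak_amplitudes = c(3, 4, 2.5),
                     peak_times = c(600, 700, 800),
                     rise_width = 4, decay_width = 8)
  pm3 <- peak_metrics(simulate_ca_trace(p3, recording_times()), 1.2)
  expect_equal(nrow(pm3), 3)
})

test_that("cohort integral ratios follow the mean ratio definition", {
  r <- integral_ratio(c(2, 4, 6), c(2, 4, 6))
  expect_equal(r$ratio_pct, 100)
  expect_equal(integral_ratio(c(1, 2, 3), c(2, 4, 6))$ratio_pct, 50)
  expect_error(integral_ratio(numeric(0), 1:3), "nonempty")
  expect_error(integral_ratio(1:3, c(-2, 0, 2)), "positive")
})
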