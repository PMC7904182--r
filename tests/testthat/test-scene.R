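test_that("simulated calcium traces honor amplitude, cap and baseline", {
  tt <- recording_times()
  flat <- simulate_ca_trace(trace_params(), tt)
  expect_true(all(flat$values == 1))

  one <- simulate_ca_trace(trace_params(peak_amplitudes = 5,
                                        peak_times = 620), tt)
  expect_equal(max(one$values), 5.0)
  expect_lte(abs(one$times[which.max(one$values)] - 620), 2.5)
  # away from the peak the trace returns to baseline
  expect_lt(max(one$values[one$times > 800]), 1.01)

  capped <- simulate_ca_trace(trace_params(peak_amplitudes = 5,
                                           peak_times = 620,
                                           peak_cap = 1.2), tt)
  expect_lte(max(capped$values), 1.2)
  # the cap bounds the observed (noisy) signal too
  noisy <- simulate_ca_trace(trace_params(peak_amplitudes = 5,
                                          peak_times = 620, peak_cap = 1.2,
                                          noise_sd = 0.1, seed = 3), tt)
  expect_lte(max(noisy$values), 1.2)

  expect_error(simulate_ca_trace(trace_params(), c(560, 560, 570)),
               "strictly increasing")
  expect_error(trace_params(peak_amplitudes = 2, peak_times = 600,
                            rise_width = 0), "widths")
})

test_that("cells without calcium release never swell or expose PS", {
  cfg <- scenario_config("quiet", er_release_gain = 0, reuptake_block = 0,
                         noise_sd = 0, seed = 5)
  for (i in 1:4) {
    cell <- simulate_cell(cfg, i)
    expect_true(is.na(cell$truth$swelling_onset))
    expect_true(all(cell$ps$values == 1))
    expect_true(all(cell$radius$radius == cfg$cell_radius))
  }
})

test_that("event ordering Ca <= swelling <= PS holds in every swelling cell", {
  for (s in 1:5) {
    co <- simulate_cohort(scenario_mec4d(seed = s))
    tr <- co$truth[!is.na(co$truth$swelling_onset), ]
    expect_gt(nrow(tr), 0)
    expect_true(all(tr$ca_onset <= tr$swelling_onset))
    expect_true(all(tr$swelling_onset <= tr$ps_onset))
  }
})

test_that("the programmed log-linear coupling links the true integrals", {
  cfg <- scenario_mec4d(seed = 2, noise_sd = 0, n_cells = 6,
                        ps_coupling_slope = 1.4,
                        ps_coupling_intercept = 0.3)
  co <- simulate_cohort(cfg)
  tr <- co$truth[!is.na(co$truth$swelling_onset), ]
  expect_gte(nrow(tr), 3)
  expect_equal(log(tr$ps_integral),
               0.3 + 1.4 * log(tr$ca_integral), tolerance = 1e-9)
  # two cells whose integrated Ca differs k-fold have log PS integrals
  # differing by exactly slope * log k
  d_ps <- diff(log(tr$ps_integral))
  d_ca <- diff(log(tr$ca_integral))
  expect_equal(d_ps, 1.4 * d_ca, tolerance = 1e-9)
})

test_that("dantrolene-like dose reduction is monotone in every cell", {
  doses <- c(0, 1, 2, 3, 4)
  truths <- lapply(doses, function(d)
    simulate_cohort(scenario_dantrolene(d, seed = 9, noise_sd = 0))$truth)
  for (i in seq_len(nrow(truths[[1]]))) {
    ca <- vapply(truths, function(tt) tt$ca_integral[i], numeric(1))
    ps <- vapply(truths, function(tt) tt$ps_integral[i], numeric(1))
    expect_true(all(diff(ca) <= 1e-9))
    expect_true(all(diff(ps) <= 1e-9))
  }
})

test_that("cohort simulation is reproducible and validates its inputs", {
  cfgs <- list(scenario_mec4d(seed = 3), scenario_crt1(seed = 4))
  a <- simulate_cohort(cfgs)
  b <- simulate_cohort(cfgs)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)

  # every default trace qualifies for curve analysis (>= 10 points)
  pts <- table(a$traces$cell)
  expect_true(all(pts >= 10))

  expect_error(scenario_config("x", n_cells = 0), "at least 1")
  expect_error(simulate_cohort(list(scenario_mec4d(), scenario_mec4d())),
               "duplicate")
  expect_error(scenario_config("x", er_release_gain = -1), "nonnegative")
})

test_that("time-point dropout exercises the curve-qualification rule", {
  cfg <- scenario_mec4d(seed = 6, dropout_prob = 0.95)
  co <- simulate_cohort(cfg)
  n <- table(co$traces$cell)
  expect_true(any(n < 10))  # at least one cell fails the 10-point rule
  short <- names(n)[n < 10][1]
  d <- co$traces[co$traces$cell == short, ]
  tr <- intensity_trace(d$time_min, d$ca_r, cell = short)
  expect_error(integrate_trace(tr, c(560, 800)), "fewer than 10")
})

# ---- rendering round trips ------------------------------------------------

fake_cell <- function(times, ca, ps, radius, id = "fake") {
  list(ca = intensity_trace(times, rep_len(ca, length(times)), cell = id),
       ps = intensity_trace(times, rep_len(ps, length(times)), cell = id,
                            channel = "PS"),
       radius = data.frame(time = times, radius = rep_len(radius,
                                                          length(times))),
       truth = data.frame(scenario = "fake", cell = id))
}

test_that("render -> quantify recovers programmed ratios", {
  tt <- seq(560, 615, 5)
  # no enrichment: RPS comes back as exactly 1 up to rasterization noise
  plain <- fake_cell(tt, ca = 1, ps = 1, radius = 9)
  q <- quantify_stack(render_frames(list(plain), width = 96, height = 96))
  expect_equal(q$rps, rep(1, nrow(q)), tolerance = 1e-9)

  # programmed Ca_R = 2, PS plateau RPS = 3
  cell <- fake_cell(tt, ca = 2, ps = 3, radius = 9)
  q2 <- quantify_stack(render_frames(list(cell), width = 96, height = 96))
  expect_equal(q2$ca_r, rep(2, nrow(q2)), tolerance = 0.02)
  expect_equal(q2$rps, rep(3, nrow(q2)), tolerance = 0.02)
})

test_that("rendered cell geometry tracks the radius ground truth", {
  tt <- c(560, 565)
  cell <- fake_cell(tt, ca = 2, ps = 1, radius = c(8, 16))
  st <- render_frames(list(cell), width = 96, height = 96)
  # equivalent-disk radius from the bright (cell) pixels doubles
  r_eq <- vapply(1:2, function(ti)
    equivalent_radius(sum(st$ca[[ti]] > st$background_unit)), numeric(1))
  expect_equal(r_eq[2] / r_eq[1], 2, tolerance = 0.05)
  expect_equal(r_eq, c(8, 16), tolerance = 0.05)

  expect_error(render_frames(list(fake_cell(tt, 1, 1, radius = 60)),
                             width = 96, height = 96,
                             centers = cbind(10, 10)),
               "border")
})
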