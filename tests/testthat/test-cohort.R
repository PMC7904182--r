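test_that("reference normalization has the stated fixed points", {
  vals <- c(2, 3, 4, 0.9, 1.0, 1.1)
  cond <- rep(c("ref", "test"), each = 3)
  nn <- normalize_to_reference(vals, cond, "ref")
  expect_equal(nn$summary$mean[nn$summary$condition == "ref"], 1)

  # a test cohort at 29% of the reference mean normalizes to 0.29
  ref <- c(2, 3, 4)
  test <- rep(0.29 * mean(ref), 4)
  nn2 <- normalize_to_reference(c(ref, test),
                                rep(c("ref", "test"), c(3, 4)), "ref")
  expect_equal(nn2$summary$mean[nn2$summary$condition == "test"], 0.29)

  # scale invariance and idempotence
  nn3 <- normalize_to_reference(c(ref, test) * 7,
                                rep(c("ref", "test"), c(3, 4)), "ref")
  expect_equal(nn3$table$normalized, nn2$table$normalized)
  nn4 <- normalize_to_reference(nn2$table$normalized, nn2$table$condition,
                                "ref")
  expect_equal(nn4$table$normalized, nn2$table$normalized)

  expect_error(normalize_to_reference(1:3, c("a", "a", "b"), "zz"),
               "not present")
})

test_that("log-log regression recovers exact power laws", {
  x <- c(1, 2, 4, 8, 16, 32)
  y <- 2 * x^1.5
  fit <- log_integral_regression(x, y)
  expect_equal(fit$slope, 1.5, tolerance = 1e-12)
  expect_equal(fit$intercept, log(2), tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_identical(fit$r_squared, fit$r^2)

  # r is invariant under positive rescaling of either axis
  set.seed(21)
  x2 <- exp(rnorm(20)); y2 <- exp(1.2 * log(x2) + rnorm(20, 0, 0.3))
  f0 <- log_integral_regression(x2, y2)
  f1 <- log_integral_regression(5.3 * x2, 0.2 * y2)
  expect_equal(f1$r, f0$r, tolerance = 1e-12)
  expect_equal(f1$slope, f0$slope, tolerance = 1e-12)

  expect_error(log_integral_regression(c(1, -1, 2), c(1, 1, 1)),
               "log-transformed")
  expect_error(log_integral_regression(1:2, 1:2), "at least 3")
})

test_that("grouped count summaries follow the group-mean convention", {
  g <- grouped_count_summary(rep(2L, 30), 10)
  expect_equal(g$mean, 2)
  expect_equal(g$sem, 0)
  expect_equal(g$n_groups, 3)
  expect_false(g$partial_last_group)

  set.seed(31)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    counts <- sample(0:2, n, replace = TRUE)
    size <- sample(c(10, 15, 25), 1)
    g <- if (n %% size == 0) grouped_count_summary(counts, size)
         else suppressWarnings(grouped_count_summary(counts, size))
    o <- oracle_grouped_mean(counts, size)
    expect_equal(g$group_means, o$group_means)
    expect_equal(g$mean, o$mean)
  }
  expect_warning(grouped_count_summary(rep(1L, 25), 10), "partial")
  expect_error(grouped_count_summary(1:5, 0), "at least 1")
  expect_error(grouped_count_summary(c(1, 2.5), 10), "integers")
})

test_that("PS-positive fractions cover the boundary cases", {
  expect_equal(ps_positive_fraction(c(1, 1.1, 0.9), 1.5)$percentage, 0)
  expect_equal(ps_positive_fraction(c(2, 3, 4), 1.5)$percentage, 100)
  f <- ps_positive_fraction(c(1, 1, 2, 2), 1.5)
  expect_equal(f$percentage, 50)
  expect_equal(f$n_positive, 2)
})

test_that("dose-response tables normalize to vehicle and report monotonicity", {
  # noise-free dantrolene series: PS plateau never increases with dose
  doses <- c(0, 1, 2, 3, 4)
  rows <- do.call(rbind, lapply(doses, function(d) {
    tr <- simulate_cohort(scenario_dantrolene(d, seed = 13,
                                              noise_sd = 0))$truth
    data.frame(dose = d, rps = tr$ps_plateau)
  }))
  tab <- dose_response_table(rows$dose, rows$rps)
  expect_equal(tab$intensity$normalized_mean[tab$intensity$dose == 0], 1)
  expect_true(tab$monotone$non_increasing)

  # vehicle-only input collapses to a single normalized row
  solo <- dose_response_table(rep(0, 5), c(2, 3, 2, 3, 2))
  expect_equal(nrow(solo$intensity), 1)
  expect_equal(solo$intensity$normalized_mean, 1)

  expect_error(dose_response_table(c(1, 2), c(1, 1)), "vehicle")
})

test_that("thapsigargin-like reuptake block raises necrosis with dose", {
  swell_n <- vapply(c(0, 3, 6), function(d) {
    tr <- simulate_cohort(scenario_thapsigargin(d, seed = 17, noise_sd = 0,
                                                n_cells = 8))$truth
    sum(!is.na(tr$swelling_onset))
  }, numeric(1))
  expect_true(all(diff(swell_n) >= 0))
  expect_gt(swell_n[3], swell_n[1])
})
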