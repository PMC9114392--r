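test_that("transcriptional activity is the renilla/firefly ratio", {
  plate <- tibble::tibble(construct_id = "c1", replicate = 1:2,
                          renilla = c(500, 1000), firefly = c(1000, 2000))
  act <- transcriptional_activity(plate)
  expect_equal(act$activity, c(0.5, 0.5))
  # doubling both readouts leaves activity unchanged
  act2 <- transcriptional_activity(
    dplyr::mutate(plate, renilla = renilla * 2, firefly = firefly * 2))
  expect_equal(act2$activity, act$activity)
  expect_error(transcriptional_activity(
    tibble::tibble(renilla = 1, firefly = 0)), "firefly")
})

test_that("fold repression of transcriptional activity is a plain ratio", {
  # control activity 1.0, knock-down 0.5 -> 2.0-fold repression
  expect_equal(1.0 / 0.5, 2.0)
  summ <- reporter_summary(
    transcriptional_activity(tibble::tibble(
      construct_id = rep(c("ctrl", "kd"), each = 3),
      renilla = c(10, 11, 9, 5, 5.5, 4.5), firefly = rep(10, 6))))
  fold <- summ$mean_activity[summ$construct_id == "ctrl"] /
    summ$mean_activity[summ$construct_id == "kd"]
  expect_equal(fold, 2.0)
})

test_that("CPA activity divides test-PAS by SV40-PAS activity", {
  expect_equal(cpa_activity(0.60, 1.00)$value, 0.6)
  expect_equal(cpa_activity(c(1, 1.1, 0.9), c(1, 1.1, 0.9))$value, 1.0)
  # enhancer effect on CPA activity: 0.60 / 0.15 = 4-fold
  expect_equal(cpa_activity(0.60, 1)$value / cpa_activity(0.15, 1)$value,
               4.0)
  expect_error(cpa_activity(1, 1, test_context = "Penh-Pprom",
                            sv40_context = "Pprom"), "context")
  # delta-method sd shrinks with tighter replicates
  wide <- cpa_activity(c(0.5, 0.7, 0.6), c(1, 1.2, 0.8))
  tight <- cpa_activity(c(0.59, 0.61, 0.6), c(0.99, 1.01, 1))
  expect_lt(tight$sd, wide$sd)
})

test_that("read-through is downstream over upstream signal", {
  expect_equal(read_through_fraction(50, 100)$read_through, 0.5)
  rt <- read_through_fraction(0, 100)
  expect_equal(rt$read_through, 0)
  expect_true(rt$below_detection)
  # three-fold read-through difference
  expect_equal(read_through_fraction(15, 100)$read_through /
                 read_through_fraction(5, 100)$read_through, 3.0)
  expect_error(read_through_fraction(5, 0), "upstream")
})

test_that("fit_decay recovers exact geometric series and flags stability", {
  f <- fit_decay(tibble::tibble(t_hours = c(0, 1, 2),
                                abundance = c(1, 0.5, 0.25)))
  expect_equal(f$k, log(0.5), tolerance = 1e-9)
  expect_equal(f$half_life, 1.0, tolerance = 1e-9)
  expect_false(f$stable)

  const <- fit_decay(tibble::tibble(t_hours = c(0, 2, 4),
                                    abundance = c(1, 1, 1)))
  expect_equal(const$k, 0, tolerance = 1e-9)
  expect_true(const$stable)
  expect_equal(const$half_life, Inf)

  expect_error(fit_decay(tibble::tibble(t_hours = c(0, 1, 2),
                                        abundance = c(1, 0.5, 0))),
               "positive")
  expect_error(fit_decay(tibble::tibble(t_hours = c(0, 1),
                                        abundance = c(1, 0.5))),
               "3 timepoints")
})

test_that("fit_decay recovers k to 1e-6 relative error on noiseless input", {
  for (k in c(-0.1, -0.3466, -1.2)) {
    ser <- simulate_decay_series(k = k, timepoints = c(0, 1, 2, 4, 8),
                                 cv_noise = 0)
    f <- fit_decay(ser)
    expect_lt(abs(f$k - k) / abs(k), 1e-6)
  }
  # ln(0.5)/-0.3466 = 1.99985 ~ 2.0 h
  f2 <- fit_decay(simulate_decay_series(k = -0.3466,
                                        timepoints = c(0, 2, 4, 8)))
  expect_equal(f2$half_life, log(0.5) / -0.3466, tolerance = 1e-9)
  expect_equal(round(f2$half_life, 3), 2)
})

test_that("decay fits normalize to the t = 0 point and expose tidiers", {
  ser <- simulate_decay_series(k = -0.5, y0 = 250,
                               timepoints = c(0, 1, 3, 6))
  f <- fit_decay(ser)
  expect_equal(f$data$abundance[f$data$t_hours == 0], 1)
  expect_equal(f$k, -0.5, tolerance = 1e-8)
  td <- tidy(f)
  expect_equal(td$term, c("k", "half_life"))
  gl <- glance(f)
  expect_named(gl, c("k", "half_life", "stable", "sse", "converged", "n"))
  p <- autoplot(f)
  expect_s3_class(p, "ggplot")
})

test_that("fraction operations are scale invariant and bounded", {
  expect_equal(nascent_fraction(20, 100), 0.2)
  expect_equal(nascent_fraction(100, 100), 1.0)
  expect_equal(lu_fraction(30, 100), 0.3)
  expect_equal(lu_fraction(0, 50), 0)
  for (s in c(0.1, 3, 1e4)) {
    expect_equal(nascent_fraction(20 * s, 100 * s), 0.2)
    expect_equal(lu_fraction(30 * s, 100 * s), 0.3)
    expect_equal(read_through_fraction(50 * s, 100 * s)$read_through, 0.5)
    expect_equal(cpa_activity(0.6 * s, 1 * s)$value, 0.6)
  }
  expect_error(nascent_fraction(1, 0), "total")
  expect_error(lu_fraction(1, -1), "total")
})

test_that("screen hits band by significance and a 0.30 activity change", {
  ctrl <- c(0.59, 0.60, 0.61)
  strong <- classify_screen_hit(c(0.19, 0.20, 0.21), ctrl)
  expect_equal(as.character(strong$band), "strong")
  expect_equal(strong$delta, -0.40, tolerance = 1e-12)

  sig <- classify_screen_hit(c(0.44, 0.45, 0.46), ctrl)
  expect_equal(as.character(sig$band), "significant")

  none <- classify_screen_hit(ctrl, ctrl)
  expect_equal(as.character(none$band), "none")

  expect_error(classify_screen_hit(c(0.1, 0.2), ctrl), "3 replicates")

  # symmetric under swapping groups, apart from the sign of the change
  a <- classify_screen_hit(c(0.2, 0.22, 0.18), c(0.6, 0.58, 0.62))
  b <- classify_screen_hit(c(0.6, 0.58, 0.62), c(0.2, 0.22, 0.18))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$delta, -b$delta)
  expect_equal(as.character(a$band), as.character(b$band))
})
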