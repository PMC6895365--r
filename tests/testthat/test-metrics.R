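test_that("average acceleration is the 24-h epoch mean", {
  expect_equal(average_acceleration(rep(30, 17280)), 30)
  expect_equal(average_acceleration(c(rep(0, 8640), rep(100, 8640))), 50)
  set.seed(41)
  d <- generate_day(2)
  expect_equal(average_acceleration(d),
               sum(d$enmo_mg) / length(d$enmo_mg), tolerance = 1e-9)
  expect_error(average_acceleration(day_series(rep(1, 100))),
               "incomplete day")
})

test_that("intensity binning is half-open with an open-ended last bin", {
  b <- bin_intensity(rep(10, 17280), epoch_len_s = 5)
  expect_equal(b$time_min[1], 1440)
  expect_equal(sum(b$time_min), 1440)
  expect_true(all(b$time_min[-1] == 0))

  v <- rep(10, 17280); v[1] <- 25        # boundary value -> second bin
  b2 <- bin_intensity(v, epoch_len_s = 5)
  expect_equal(b2$time_min[2], 5 / 60)

  v[2] <- 5000                            # beyond the ceiling
  b3 <- bin_intensity(v, epoch_len_s = 5)
  expect_equal(b3$time_min[nrow(b3)], 5 / 60)
  expect_equal(b3$midpoint[nrow(b3)], 4012.5)
  expect_equal(sum(b3$time_min), 1440)

  # per-bin totals equal an independent histogram oracle
  set.seed(42)
  d <- generate_day(1.8)
  got <- bin_intensity(d)
  oracle <- tabulate(pmin(floor(d$enmo_mg / 25), 160) + 1L, 161) * 5 / 60
  expect_equal(got$time_min, oracle)
})

test_that("intensity gradient fits ln(time) on ln(midpoint)", {
  mid <- seq(12.5, 987.5, by = 25)
  exact <- data.frame(midpoint = mid, time_min = 1e4 * mid^(-2))
  fit <- intensity_gradient(exact)
  expect_equal(fit$slope, -2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_bins_used, 40L)

  flat <- data.frame(midpoint = mid, time_min = rep(36, 40))
  expect_equal(intensity_gradient(flat)$slope, 0, tolerance = 1e-12)

  # stochastic day against the closed-form OLS oracle
  d <- generate_day(2.5, seed = 17)
  bins <- bin_intensity(d)
  use <- bins$time_min > 0
  oracle <- ols_oracle(log(bins$midpoint[use]), log(bins$time_min[use]))
  got <- intensity_gradient(bins)
  expect_equal(got$slope, oracle$slope, tolerance = 1e-9)
  expect_equal(got$intercept, oracle$intercept, tolerance = 1e-9)
  expect_equal(got$r_squared, oracle$r_squared, tolerance = 1e-9)
  expect_lt(abs(got$slope - (-2.5)), 0.1)

  # empty bins are excluded; fewer than 3 non-empty bins is an error
  sparse <- data.frame(midpoint = mid[1:5], time_min = c(10, 0, 4, 0, 0))
  expect_error(intensity_gradient(sparse), "3 non-empty")
})

test_that("MX is the nearest-rank order statistic", {
  expect_equal(mx(rep(50, 17280), 60, epoch_len_s = 5), 50)
  v <- c(rep(300, 720), rep(20, 17280 - 720))
  expect_equal(mx(v, 60, epoch_len_s = 5), 300)   # 720 epochs = 60 min
  expect_equal(mx(v, 120, epoch_len_s = 5), 20)
  # a day whose 720th-largest epoch is 210 mg has M60 = 210
  day <- fixture_with_mx(c("60" = 210))
  expect_equal(sort(day$enmo_mg, decreasing = TRUE)[720], 210)
  expect_equal(mx(day, 60), 210)
  expect_error(mx(v, 1500, epoch_len_s = 5), "out of range")
  expect_error(mx(v, 0.07, epoch_len_s = 5), "divisible")
})

test_that("MX equals the brute-force threshold oracle and spans min/max", {
  set.seed(43)
  for (i in 1:5) {
    v <- random_day_values()
    for (X in c(5, 60, 480))
      expect_equal(mx(v, X, epoch_len_s = 5), mx_oracle(v, X, 5))
    expect_equal(mx(v, 1440, epoch_len_s = 5), min(v))
    expect_equal(mx(v, 5 / 60, epoch_len_s = 5), max(v))
  }
})

test_that("mx_suite is non-increasing and distribution-invariant", {
  set.seed(44)
  for (i in 1:20) {
    v <- random_day_values()
    s <- mx_suite(v, epoch_len_s = 5)
    expect_length(s, 8L)
    expect_named(s, c("m2", "m5", "m10", "m15", "m30", "m60", "m120",
                      "m480"))
    expect_true(all(diff(s) <= 0))
    p <- sample(v)   # permutation invariance of distributional metrics
    expect_identical(mx_suite(p, epoch_len_s = 5), s)
    expect_equal(average_acceleration(p), average_acceleration(v))
  }
  const <- mx_suite(rep(75, 17280), epoch_len_s = 5)
  expect_true(all(const == 75))
})

test_that("activity_profile averages per-day metrics over qualifying days", {
  d <- generate_day(2, seed = 45)
  two <- rbind(d, transform(d, time = time + 86400))
  attr(two, "epoch_len_s") <- 5L
  class(two) <- c("epoch_series", "data.frame")
  fit1 <- activity_profile(d)
  fit2 <- activity_profile(two)
  expect_equal(coef(fit2), coef(fit1))          # two identical days

  # participant mean of per-day MX values (three value levels per day so
  # the per-day gradient fit has enough non-empty bins)
  step_day <- function(top, date) {
    day_series(c(rep(top, 720), rep(40, 2000), rep(10, 17280 - 2720)),
               date = date)
  }
  dA <- step_day(100, "2023-05-01")
  dB <- step_day(200, "2023-05-02")
  expect_equal(mx(dA, 60), 100)
  both <- rbind(dA, dB)
  attr(both, "epoch_len_s") <- 5L
  class(both) <- c("epoch_series", "data.frame")
  expect_equal(coef(activity_profile(both))[["m60"]], 150)

  # constant metric across days averages to that constant
  expect_equal(coef(fit2)[["avg_accel_mg"]],
               average_acceleration(d))
})

test_that("weekday/weekend strata are unweighted within stratum", {
  set.seed(46)
  # Mon 2023-05-01 .. Sun 2023-05-07; weekend days generated less active
  days <- lapply(0:6, function(i)
    generate_day(if (i < 5) 1.8 else 2.6,
                 date = as.Date("2023-05-01") + i))
  s <- do.call(rbind, days)
  attr(s, "epoch_len_s") <- 5L
  class(s) <- c("epoch_series", "data.frame")
  all7 <- coef(activity_profile(s))
  wd <- coef(activity_profile(s, day_filter = "weekday"))
  we <- coef(activity_profile(s, day_filter = "weekend"))
  # pooled mean matches the all-day summary only under manual 5:2 weights
  expect_equal((5 * wd + 2 * we) / 7, all7, tolerance = 1e-12)
  expect_false(isTRUE(all.equal((wd + we) / 2, all7)))
  expect_error(activity_profile(day_series(rep(1, 17280)),
                                day_filter = "weekend"),
               "no qualifying days")
})

test_that("cohort_metrics builds one row per participant and guards epochs", {
  p1 <- included_participant(3, g = 1.8, seed = 47, id = "A")
  p2 <- included_participant(3, g = 2.4, seed = 48, id = "B")
  tab <- cohort_metrics(list(p1, p2), group = c("g1", "g2"))
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$id, c("A", "B"))
  expect_true(all(c("avg_accel_mg", "ig_slope", "ig_r2", "m60",
                    "m480") %in% names(tab)))
  expect_identical(mx_columns(tab),
                   c("m2", "m5", "m10", "m15", "m30", "m60", "m120",
                     "m480"))

  f1 <- activity_profile(p1)
  coarse <- generate_day(2, epoch_len_s = 60, seed = 49)
  f2 <- activity_profile(coarse)
  expect_error(cohort_metrics(list(f1, f2)), "epoch length")
  expect_silent(cohort_metrics(list(f1, f2), allow_mixed_epochs = TRUE))
})

test_that("excluded participants are refused by the fit", {
  npd <- 17280L
  vals <- matrix(100, 2, npd)
  p <- process_participant(multi_day_series(vals), id = "X",
                           detect = FALSE)
  expect_false(p$included)   # only 2 valid days
  expect_error(activity_profile(p), "excluded")
})
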