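# independent oracle for the epoch-only non-wear rule: literal scan over
# the 15-min clock blocks with the 60-min window centred on each
nonwear_oracle <- function(x, sd_mg = 13, range_mg = 50) {
  tt <- as.numeric(x$time)
  block <- floor(tt / 900)
  flags <- x$wear
  for (b in unique(block)) {
    centre <- (b + 0.5) * 900
    win <- x$enmo_mg[tt >= centre - 1800 & tt < centre + 1800]
    win <- win[is.finite(win)]
    bad <- !length(win) ||
      (all(win < sd_mg) && (max(win) - min(win)) < range_mg)
    if (bad) flags[block == b & flags == "W"] <- "N"
  }
  flags
}

test_that("non-wear detection flags flat spans and spares active data", {
  still <- day_series(rep(0, 17280))
  expect_true(all(detect_nonwear(still)$wear == "N"))

  active <- day_series(rep(c(0, 500), 8640))
  expect_true(all(detect_nonwear(active)$wear == "W"))

  short <- day_series(rep(0, 120))  # 10 min < one window
  expect_warning(out <- detect_nonwear(short), "shorter")
  expect_true(all(out$wear == "W"))
})

test_that("detection matches an independent window-scan oracle on an inserted gap", {
  set.seed(21)
  v <- runif(17280, 20, 400)                  # clearly worn background
  gap <- (8 * 720 + 1):(11 * 720)             # 3-h flat block, 08:00-11:00
  v[gap] <- 2
  day <- day_series(v)
  out <- detect_nonwear(day)
  expect_identical(out$wear, nonwear_oracle(day))
  flagged <- which(out$wear == "N")
  # detected span lies inside the inserted span; boundary attrition is at
  # most half a window plus one step on each side
  expect_true(all(flagged %in% gap))
  slack <- (30 + 15) * 60 / 5
  expect_lte(min(flagged) - min(gap), slack)
  expect_lte(max(gap) - max(flagged), slack)
})

test_that("raw-path detection uses pooled axis SDs and mean ranges", {
  n <- 17280
  v <- rep(1, n)
  day <- day_series(v)
  # still device: tiny per-epoch SDs, constant means -> non-wear
  still_stats <- data.frame(mean_x = rep(0, n), mean_y = 0, mean_z = 1000,
                            sd_x = 1, sd_y = 1, sd_z = 1)
  expect_true(all(detect_nonwear(day, axis_stats = still_stats)$wear == "N"))
  # one quiet axis only: criterion needs two of three
  active_stats <- still_stats
  active_stats$sd_x <- 60
  active_stats$sd_y <- 60
  expect_true(all(detect_nonwear(day, axis_stats = active_stats)$wear == "W"))
})

test_that("day validity uses a strict 16-h threshold on worn time", {
  npd <- 17280L
  worn_hours <- function(h) {
    k <- as.integer(h * 3600 / 5)
    wear <- c(rep("W", k), rep("N", npd - k))
    day_series(ifelse(wear == "W", 100, NA), wear = wear)
  }
  expect_false(day_validity(worn_hours(16.0))$valid)
  expect_true(day_validity(worn_hours(16.1))$valid)
  expect_true(day_validity(worn_hours(24))$valid)
  expect_equal(day_validity(worn_hours(16.0))$wear_hours, 16)
})

test_that("participant inclusion needs 3 valid days and full slot coverage", {
  npd <- 17280L
  full <- rep(100, npd)
  mk <- function(wear_rows) {
    vals <- matrix(100, nrow(wear_rows), npd)
    vals[wear_rows == "N"] <- NA
    multi_day_series(vals, wear_rows)
  }
  w_valid <- rep("W", npd)                      # 24 h worn
  w_invalid <- c(rep("W", npd / 2), rep("N", npd / 2))  # 12 h worn

  two_valid <- mk(rbind(w_valid, w_valid, w_invalid))
  expect_false(participant_inclusion(two_valid)$included)

  three_valid <- mk(rbind(w_valid, w_valid, w_valid))
  expect_true(participant_inclusion(three_valid)$included)

  # 3 valid days but one 15-min slot (12:00-12:15) never worn
  slot <- 48L * 180L + 1L    # 12:00 is the 49th 15-min slot; 180 epochs each
  w_hole <- w_valid
  w_hole[slot:(slot + 179)] <- "N"
  holey <- mk(rbind(w_hole, w_hole, w_hole))
  inc <- participant_inclusion(holey)
  expect_false(inc$included)
  expect_equal(sum(!inc$slot_coverage), 1L)
  expect_equal(inc$n_valid_days, 3L)            # days still valid

  seven <- mk(matrix("W", 7, npd))
  expect_true(participant_inclusion(seven)$included)
})

test_that("imputation replaces non-wear by time-of-day means of other days", {
  npd <- 17280L
  vals <- matrix(100, 2, npd)
  wear <- matrix("W", 2, npd)
  wear[2, 1000] <- "N"; vals[2, 1000] <- NA
  s <- impute_nonwear(multi_day_series(vals, wear))
  m <- matrix(s$enmo_mg, 2, npd, byrow = TRUE)
  expect_equal(m[2, 1000], 100)                     # single donor
  expect_equal(matrix(s$wear, 2, npd, byrow = TRUE)[2, 1000], "I")

  vals3 <- matrix(50, 3, npd)
  wear3 <- matrix("W", 3, npd)
  vals3[1, 7] <- 100; vals3[2, 7] <- 200
  wear3[3, 7] <- "N"; vals3[3, 7] <- NA
  s3 <- impute_nonwear(multi_day_series(vals3, wear3))
  expect_equal(matrix(s3$enmo_mg, 3, npd, byrow = TRUE)[3, 7], 150)

  # a clock position worn on no day is an error naming the position
  wearx <- matrix("W", 2, npd)
  wearx[, 50] <- "N"
  valsx <- matrix(10, 2, npd); valsx[, 50] <- NA
  expect_error(impute_nonwear(multi_day_series(valsx, wearx)), "00:04:05")
})

test_that("imputation equals a groupby-mean oracle, is idempotent, and preserves worn epochs", {
  set.seed(31)
  n_days <- 7L; npd <- 17280L
  vals <- matrix(runif(n_days * npd, 0, 300), n_days, npd)
  wear <- matrix("W", n_days, npd)
  gaps <- sample(n_days * npd, round(0.05 * n_days * npd))
  wear[gaps] <- "N"
  # keep every slot worn on at least one day
  covered <- colSums(wear == "W") > 0
  wear[1, !covered] <- "W"
  s <- multi_day_series(vals, wear)
  out <- impute_nonwear(s)
  expect_false(any(out$wear == "N"))
  # worn values untouched, total count conserved
  expect_identical(out$enmo_mg[s$wear == "W"], s$enmo_mg[s$wear == "W"])
  expect_equal(nrow(out), nrow(s))
  # per-slot imputed value equals the independent column-mean oracle
  vm <- matrix(out$enmo_mg, n_days, npd, byrow = TRUE)
  wm <- matrix(s$wear, n_days, npd, byrow = TRUE)
  for (j in sample(which(colSums(wm == "N") > 0), 50)) {
    donor_mean <- mean(vals[wm[, j] == "W", j])
    expect_equal(vm[wm[, j] == "N", j],
                 rep(donor_mean, sum(wm[, j] == "N")))
  }
  # idempotent
  again <- impute_nonwear(out)
  expect_identical(again$enmo_mg, out$enmo_mg)
  expect_identical(again$wear, out$wear)
  # a fully worn participant passes through unchanged
  clean <- multi_day_series(vals)
  expect_identical(impute_nonwear(clean)$enmo_mg, clean$enmo_mg)
})

test_that("process_participant pipelines detection, screening and imputation", {
  p <- included_participant(n_days = 3)
  expect_true(p$included)
  expect_equal(p$n_valid_days, 3L)
  expect_false(any(p$series$wear == "N"))
  qc <- tempfile(fileext = ".csv")
  write_qc_report(list(p), qc)
  got <- read.csv(qc)
  expect_equal(nrow(got), 3L)
  expect_true(all(c("id", "date", "wear_hours", "valid",
                    "pct_imputed") %in% names(got)))
})
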