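# shared fixture builders (all data generated in code; no stored files)

T0 <- function(date = "2023-05-01")
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC")

# one-day epoch_series from bare values (defaults: full 5-s day)
day_series <- function(values, epoch_len_s = 5L, wear = "W",
                       date = "2023-05-01") {
  epoch_series(T0(date) + (seq_along(values) - 1L) * epoch_len_s,
               values, wear, epoch_len_s)
}

# multi-day series: one wear/value matrix row per day (consecutive dates)
multi_day_series <- function(val_rows, wear_rows = NULL, epoch_len_s = 5L,
                             start_date = as.Date("2023-05-01")) {
  npd <- 86400L / epoch_len_s
  stopifnot(ncol(val_rows) == npd)
  if (is.null(wear_rows))
    wear_rows <- matrix("W", nrow(val_rows), npd)
  times <- T0(start_date) +
    (seq_len(nrow(val_rows) * npd) - 1L) * epoch_len_s
  epoch_series(times, as.numeric(t(val_rows)), as.character(t(wear_rows)),
               epoch_len_s)
}

# a cheap "random day": uniform epoch values (enough for order-statistic
# and permutation properties; the structured generator is tested separately)
random_day_values <- function(n = 17280L, max_mg = 2000)
  runif(n, 0, max_mg)

# independent brute-force MX oracle: the largest threshold c present in the
# value multiset with at least X minutes at or above it.  Works from the
# cumulative counts of the unique values, not from a rank index.
mx_oracle <- function(values, X_min, epoch_len_s) {
  cand <- sort(unique(values), decreasing = TRUE)
  cnt <- tabulate(match(values, cand), nbins = length(cand))
  minutes <- cumsum(cnt) * epoch_len_s / 60  # time at or above each value
  vapply(X_min, function(X) cand[which(minutes >= X)[1L]], numeric(1))
}

# independent OLS oracle from the closed-form normal equations
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = b, intercept = a, r_squared = r2)
}

# small included participant: n_days fully-worn generated days
included_participant <- function(n_days = 3, g = 2, seed = 42,
                                 id = "TP1") {
  set.seed(seed)
  days <- lapply(seq_len(n_days) - 1L, function(d)
    generate_day(g, date = as.Date("2023-05-01") + d))
  s <- do.call(rbind, days)
  attr(s, "epoch_len_s") <- 5L
  class(s) <- c("epoch_series", "data.frame")
  process_participant(s, id = id, detect = FALSE)
}
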