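# Synthetic epoch-level cohorts with known ("truth") volume and
# intensity-distribution slope.  Day construction: time per 25-mg
# intensity bin is allocated proportional to midpoint^(-g) (so the
# log-log slope of the intensity distribution is -g by construction),
# converted to whole epoch counts by largest-remainder rounding, and epoch
# values drawn uniformly within their bin.  The lowest-value epochs form a
# contiguous sleep block; the rest are shuffled across waking hours, which
# leaves all distributional metrics (average acceleration, intensity
# gradient, MX) invariant.

# round non-negative weights to integer counts summing to n, assigning the
# leftover to the largest fractional remainders (ties by index)
largest_remainder <- function(weights, n) {
  q <- weights / sum(weights) * n
  k <- floor(q)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(q - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}

#' Generate one synthetic day of epoch ENMO
#'
#' @param g power-law exponent (> 0) of the intensity distribution; the
#'   fitted intensity gradient of the day is approximately `-g`.
#' @param volume_mg optional target average acceleration; when given, the
#'   drawn values are rescaled to hit it exactly (the log-log slope is
#'   unchanged by a positive scale).
#' @param epoch_len_s epoch length in seconds (default 5).
#' @param sleep_hours length of the contiguous low-intensity block placed
#'   at the start of the day (default 8 h).
#' @param nonwear_gap_rate expected fraction of the day flagged non-wear,
#'   inserted as contiguous 1-h gaps at random waking positions (values
#'   are retained under the flag).
#' @param bin_width_mg,max_mg intensity-bin structure used for the
#'   allocation; values are drawn in `[0, max_mg)`.
#' @param date calendar date of the day.
#' @param seed optional seed (`set.seed` is called when non-`NULL`);
#'   otherwise the current RNG stream is used.
#' @return A one-day [epoch_series()].
#' @export
generate_day <- function(g, volume_mg = NULL, epoch_len_s = 5L,
                         sleep_hours = 8, nonwear_gap_rate = 0,
                         bin_width_mg = 25, max_mg = 1000,
                         date = as.Date("2023-05-01"), seed = NULL) {
  if (!is.finite(g) || g <= 0) stop("g must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  npd <- epochs_per_day(epoch_len_s)
  lower <- seq(0, max_mg - bin_width_mg, by = bin_width_mg)
  mid <- lower + bin_width_mg / 2
  # a single day cannot represent bins whose expected time is below one
  # epoch; drop them from the allocation before rounding, otherwise the
  # forced 0/1 counts in the sparse tail flatten the realised log-log slope
  w <- mid^(-g)
  keep <- w / sum(w) * npd >= 1
  lower <- lower[keep]; mid <- mid[keep]
  counts <- largest_remainder(mid^(-g), npd)
  vals <- unlist(lapply(seq_along(counts), function(i)
    stats::runif(counts[i], lower[i], lower[i] + bin_width_mg)))
  if (!is.null(volume_mg)) vals <- vals * (volume_mg / mean(vals))
  vals <- sort(vals)
  n_sleep <- as.integer(round(sleep_hours * 3600 / epoch_len_s))
  if (n_sleep > npd) stop("sleep_hours exceeds the day", call. = FALSE)
  sleep <- vals[seq_len(n_sleep)]
  wake <- vals[setdiff(seq_len(npd), seq_len(n_sleep))]
  out_vals <- c(sample(sleep), sample(wake))
  wear <- rep("W", npd)
  if (nonwear_gap_rate > 0) {
    per_gap <- as.integer(3600 / epoch_len_s)
    n_gaps <- max(1L, round(nonwear_gap_rate * 24))
    starts <- sample(seq.int(n_sleep + 1L, npd - per_gap), n_gaps)
    for (s in starts) wear[s:(s + per_gap - 1L)] <- "N"
  }
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  epoch_series(t0 + (seq_len(npd) - 1L) * epoch_len_s, out_vals, wear,
               epoch_len_s)
}

#' Generate a synthetic cohort
#'
#' Multi-day epoch series for `n_participants`, each with its own
#' power-law exponent and optional volume target, plus a truth table of
#' the generating parameters.  Deterministic for a fixed seed.
#'
#' @param n_participants,n_days cohort dimensions.
#' @param g per-participant exponents, recycled (default drawn uniformly
#'   in `[1.5, 3]`).
#' @param volume_mg optional per-participant volume targets, recycled.
#' @param epoch_len_s,sleep_hours,nonwear_gap_rate,bin_width_mg,max_mg
#'   passed to [generate_day()].
#' @param start_date date of each participant's first day (a Monday by
#'   default, so 7-day recordings split 5 weekdays : 2 weekend days).
#' @param seed RNG seed.
#' @param out_dir when given, one epoch CSV per participant
#'   (`<id>.csv`) and a `truth.csv` are written there.
#' @return List with `series` (named list of [epoch_series()]) and
#'   `truth` (data frame: `id`, `g`, `volume_target_mg`,
#'   `realized_volume_mg`).
#' @export
generate_cohort <- function(n_participants = 10, n_days = 7, g = NULL,
                            volume_mg = NULL, epoch_len_s = 5L,
                            sleep_hours = 8, nonwear_gap_rate = 0,
                            bin_width_mg = 25, max_mg = 1000,
                            start_date = as.Date("2023-05-01"),
                            seed = 1L, out_dir = NULL) {
  set.seed(seed)
  if (is.null(g)) g <- stats::runif(n_participants, 1.5, 3)
  g <- rep_len(g, n_participants)
  vol <- if (is.null(volume_mg)) rep(list(NULL), n_participants)
         else as.list(rep_len(volume_mg, n_participants))
  ids <- sprintf("P%03d", seq_len(n_participants))
  series <- vector("list", n_participants)
  realized <- numeric(n_participants)
  for (i in seq_len(n_participants)) {
    days <- lapply(seq_len(n_days) - 1L, function(d)
      generate_day(g[i], volume_mg = vol[[i]], epoch_len_s = epoch_len_s,
                   sleep_hours = sleep_hours,
                   nonwear_gap_rate = nonwear_gap_rate,
                   bin_width_mg = bin_width_mg, max_mg = max_mg,
                   date = start_date + d))
    joined <- do.call(rbind, days)
    attr(joined, "epoch_len_s") <- as.integer(epoch_len_s)
    class(joined) <- c("epoch_series", "data.frame")
    series[[i]] <- joined
    realized[i] <- mean(joined$enmo_mg)
  }
  names(series) <- ids
  truth <- data.frame(
    id = ids, g = g,
    volume_target_mg = vapply(vol, function(v) v %||% NA_real_,
                              numeric(1L)),
    realized_volume_mg = realized)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_participants))
      write_epoch_csv(series[[i]], file.path(out_dir,
                                             paste0(ids[i], ".csv")))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(series = series, truth = truth)
}

#' Construct a day with prescribed MX values
#'
#' Builds the stepwise epoch multiset whose nearest-rank MX equals each
#' requested target exactly: with durations `X_1 < ... < X_m` and ranks
#' `k_i = X_i * 60 / epoch_len_s`, epochs ranked `(k_(i-1), k_i]` take the
#' value `targets[X_i]`, and the remaining epochs take `fill`.
#'
#' @param targets named numeric vector, names = durations in minutes,
#'   values = desired MX in mg, non-increasing in duration.
#' @param epoch_len_s epoch length in seconds.
#' @param fill value of the epochs beyond the longest duration; defaults
#'   to half the smallest target (must not exceed the smallest target).
#' @param date calendar date.
#' @return A one-day [epoch_series()] with `mx(day, X) == targets[X]` for
#'   every requested duration.
#' @export
fixture_with_mx <- function(targets, epoch_len_s = 5L, fill = NULL,
                            date = as.Date("2023-05-01")) {
  X <- as.numeric(names(targets))
  if (anyNA(X) || any(X <= 0))
    stop("targets must be named by positive durations in minutes",
         call. = FALSE)
  ord <- order(X)
  X <- X[ord]; tv <- as.numeric(targets)[ord]
  if (any(diff(tv) > 0))
    stop("targets must be non-increasing in duration", call. = FALSE)
  npd <- epochs_per_day(epoch_len_s)
  k <- X * 60 / epoch_len_s
  if (any(k != round(k)) || max(k) > npd)
    stop("durations incompatible with the epoch grid", call. = FALSE)
  k <- as.integer(k)
  fill <- fill %||% (min(tv) / 2)
  if (fill > min(tv))
    stop("fill exceeds the smallest target", call. = FALSE)
  vals <- rep(fill, npd)
  prev <- 0L
  for (i in seq_along(k)) {
    vals[(prev + 1L):k[i]] <- tv[i]
    prev <- k[i]
  }
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  epoch_series(t0 + (seq_len(npd) - 1L) * epoch_len_s, vals, "W",
               epoch_len_s)
}

#' Generate a simple raw tri-axial signal
#'
#' A sinusoid on the z axis (riding on gravity) plus Gaussian noise on all
#' axes — just enough structure to exercise the ENMO and epoching path,
#' with no claim to biomechanical realism.
#'
#' @param duration_s signal length in seconds.
#' @param rate_hz sampling rate (default 100).
#' @param amp_g sinusoid amplitude in g.
#' @param freq_hz sinusoid frequency.
#' @param noise_g Gaussian noise SD in g.
#' @param start start instant.
#' @param seed optional seed.
#' @return Data frame `time`, `x`, `y`, `z` with attribute `rate_hz`.
#' @export
generate_raw_triaxial <- function(duration_s = 60, rate_hz = 100,
                                  amp_g = 0.2, freq_hz = 1,
                                  noise_g = 0.005,
                                  start = as.POSIXct(
                                    "2023-05-01 12:00:00", tz = "UTC"),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(duration_s * rate_hz)
  tt <- (seq_len(n) - 1L) / rate_hz
  out <- data.frame(
    time = start + tt,
    x = stats::rnorm(n, 0, noise_g),
    y = stats::rnorm(n, 0, noise_g),
    z = 1 + amp_g * sin(2 * pi * freq_hz * tt) +
      stats::rnorm(n, 0, noise_g))
  attr(out, "rate_hz") <- rate_hz
  out
}
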