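# --- per-day metric primitives ------------------------------------------

# extract the ENMO vector of one complete day, erroring on gaps
day_values <- function(day) {
  if (inherits(day, "epoch_series")) {
    len <- epoch_len(day)
    npd <- epochs_per_day(len)
    if (nrow(day) != npd)
      stop("incomplete day: ", nrow(day), " epochs, expected ", npd,
           call. = FALSE)
    v <- day$enmo_mg
  } else {
    v <- as.numeric(day)
  }
  if (anyNA(v))
    stop("day contains missing (non-imputed) epochs", call. = FALSE)
  v
}

#' Average acceleration of a day
#'
#' The arithmetic mean ENMO over the full 24-h (imputed) day, in mg; the
#' volume component of the activity profile.
#'
#' @param day a complete one-day [epoch_series()], or its numeric epoch
#'   values.
#' @return Mean acceleration in mg.
#' @export
average_acceleration <- function(day) mean(day_values(day))

#' Time accumulated per intensity bin
#'
#' Epochs are assigned to half-open intensity bins `[edge, edge + width)`
#' of uniform width, with a final open-ended bin `[max_edge, Inf)` whose
#' nominal midpoint is `max_edge + width/2`.  Bin times for a complete day
#' sum to 1440 min.
#'
#' @param day a complete one-day [epoch_series()] or numeric epoch values
#'   (then `epoch_len_s` must be given).
#' @param width_mg bin width in mg (default 25).
#' @param max_edge_mg lower edge of the open-ended final bin (default
#'   4000).
#' @param epoch_len_s epoch length in seconds, taken from the series when
#'   possible.
#' @return Data frame with `lower`, `upper`, `midpoint` (mg) and
#'   `time_min` per bin.
#' @export
bin_intensity <- function(day, width_mg = 25, max_edge_mg = 4000,
                          epoch_len_s = NULL) {
  if (inherits(day, "epoch_series") && is.null(epoch_len_s))
    epoch_len_s <- epoch_len(day)
  if (is.null(epoch_len_s))
    stop("epoch_len_s required for bare numeric input", call. = FALSE)
  v <- day_values(day)
  edges <- seq(0, max_edge_mg, by = width_mg)
  idx <- pmin(floor(v / width_mg), length(edges) - 1L) + 1L
  counts <- tabulate(idx, nbins = length(edges))
  data.frame(lower = edges,
             upper = c(edges[-1L], Inf),
             midpoint = edges + width_mg / 2,
             time_min = counts * epoch_len_s / 60)
}

#' Intensity gradient of a day
#'
#' Ordinary least-squares fit of `ln(time_min)` on `ln(midpoint_mg)` over
#' the non-empty intensity bins.  The slope is the intensity gradient: it
#' is negative for free-living data and more negative the steeper the
#' drop-off of time with intensity.
#'
#' @param bins a bin table from [bin_intensity()], or a one-day
#'   [epoch_series()] (binned with defaults first).
#' @return Object of class `gradient_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `n_bins_used`.
#' @export
intensity_gradient <- function(bins) {
  if (inherits(bins, "epoch_series")) bins <- bin_intensity(bins)
  use <- bins$time_min > 0
  if (sum(use) < 3L)
    stop("intensity gradient undefined: fewer than 3 non-empty bins",
         call. = FALSE)
  lx <- log(bins$midpoint[use])
  ly <- log(bins$time_min[use])
  fit <- stats::lm(ly ~ lx)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  out <- list(slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              r_squared = r2,
              n_bins_used = sum(use))
  class(out) <- "gradient_fit"
  out
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf(
    "<gradient_fit> slope %.3f, intercept %.3f, r2 %.3f (%d bins)\n",
    x$slope, x$intercept, x$r_squared, x$n_bins_used))
  invisible(x)
}

#' MX: acceleration above which the most active X minutes are accumulated
#'
#' The nearest-rank order statistic: with `k = X_min * 60 / epoch_len_s`,
#' MX is the k-th largest epoch value of the day, so at least X minutes of
#' the day are at or above the returned acceleration.  No interpolation is
#' used, so the verbal definition holds exactly on the discrete epoch
#' multiset.  M60 = 210 mg, say, means the most active accumulated 60 min
#' of the day were all spent above 210 mg.
#'
#' @param day a complete one-day [epoch_series()] or numeric epoch values
#'   (then `epoch_len_s` must be given).
#' @param X_min duration in minutes; `X_min * 60` must be divisible by the
#'   epoch length and at most 1440 min.
#' @param epoch_len_s epoch length in seconds.
#' @return Acceleration in mg.
#' @export
mx <- function(day, X_min, epoch_len_s = NULL) {
  if (inherits(day, "epoch_series") && is.null(epoch_len_s))
    epoch_len_s <- epoch_len(day)
  if (is.null(epoch_len_s))
    stop("epoch_len_s required for bare numeric input", call. = FALSE)
  v <- day_values(day)
  if (X_min <= 0 || X_min > 1440)
    stop("X_min out of range (0, 1440]", call. = FALSE)
  if ((X_min * 60) %% epoch_len_s != 0)
    stop("X_min * 60 not divisible by epoch_len_s", call. = FALSE)
  k <- as.integer(X_min * 60 / epoch_len_s)
  if (k > length(v))
    stop("day shorter than X_min", call. = FALSE)
  sort(v, decreasing = TRUE)[k]
}

#' MX metrics over a set of durations
#'
#' @inheritParams mx
#' @param durations durations in minutes; the default eight span 2 min to
#'   the most active third of the day (480 min).
#' @return Named numeric vector (`m2`, `m5`, ...), non-increasing in X.
#' @export
mx_suite <- function(day, durations = c(2, 5, 10, 15, 30, 60, 120, 480),
                     epoch_len_s = NULL) {
  if (inherits(day, "epoch_series") && is.null(epoch_len_s))
    epoch_len_s <- epoch_len(day)
  v <- day_values(day)
  sorted <- sort(v, decreasing = TRUE)
  out <- vapply(durations, function(X) {
    if (X <= 0 || X > 1440 || (X * 60) %% epoch_len_s != 0)
      stop("invalid duration ", X, call. = FALSE)
    k <- as.integer(X * 60 / epoch_len_s)
    if (k > length(sorted)) stop("day shorter than ", X, " min",
                                 call. = FALSE)
    sorted[k]
  }, numeric(1L))
  names(out) <- paste0("m", durations)
  out
}

# --- the participant-level fit ------------------------------------------

#' Fit a 24-h activity profile
#'
#' The central estimator of the package.  For each complete (imputed) day
#' it computes the analytical metrics — average acceleration (volume) and
#' intensity gradient (log-log slope of the intensity distribution) — and
#' the translational MX metrics, then averages each metric over the
#' qualifying days (unweighted), which is the participant-level profile.
#'
#' @param x a `participant_record` from [process_participant()] (must be
#'   included), or a complete [epoch_series()] spanning whole days with no
#'   missing values.
#' @param durations MX durations in minutes.
#' @param day_filter `"all"`, `"weekday"` (Mon-Fri) or `"weekend"`
#'   (Sat-Sun); days failing the filter or day validity are dropped.
#' @param width_mg,max_edge_mg intensity-bin settings, see
#'   [bin_intensity()].
#' @return Object of class `activity_profile`: list with `days` (per-day
#'   metric table), `participant` (named vector of day-averaged metrics),
#'   `durations`, `id`, `stratum`, `epoch_len_s`, `n_days`.
#' @examples
#' set.seed(1)
#' day <- generate_day(g = 2, seed = 1)
#' fit <- activity_profile(day)
#' coef(fit)
#' @export
activity_profile <- function(x, durations = c(2, 5, 10, 15, 30, 60, 120, 480),
                             day_filter = c("all", "weekday", "weekend"),
                             width_mg = 25, max_edge_mg = 4000) {
  day_filter <- match.arg(day_filter)
  id <- "P1"
  valid_dates <- NULL
  if (inherits(x, "participant_record")) {
    if (!x$included)
      stop("participant ", x$id, " is excluded by the validity criteria",
           call. = FALSE)
    id <- x$id
    valid_dates <- x$days$date[x$days$valid]
    x <- x$series
  }
  if (!inherits(x, "epoch_series"))
    stop("x must be a participant_record or epoch_series", call. = FALSE)
  len <- epoch_len(x)
  days <- split_days(x)
  dates <- as.Date(names(days))
  keep <- rep(TRUE, length(days))
  if (!is.null(valid_dates)) keep <- dates %in% valid_dates
  if (day_filter == "weekday") keep <- keep & format(dates, "%u") %in% as.character(1:5)
  if (day_filter == "weekend") keep <- keep & format(dates, "%u") %in% c("6", "7")
  if (!any(keep))
    stop("no qualifying days under day_filter = '", day_filter, "'",
         call. = FALSE)
  days <- days[keep]; dates <- dates[keep]
  per_day <- lapply(days, function(d) {
    v <- day_values(d)
    ig <- intensity_gradient(bin_intensity(v, width_mg = width_mg,
                                           max_edge_mg = max_edge_mg,
                                           epoch_len_s = len))
    c(avg_accel_mg = mean(v),
      ig_slope = ig$slope, ig_intercept = ig$intercept,
      ig_r2 = ig$r_squared,
      mx_suite(v, durations, epoch_len_s = len))
  })
  tab <- data.frame(date = dates, do.call(rbind, per_day),
                    row.names = NULL, check.names = FALSE)
  participant <- colMeans(tab[-1L])
  out <- list(days = tab, participant = participant,
              durations = durations, id = id, stratum = day_filter,
              epoch_len_s = len, n_days = nrow(tab))
  class(out) <- "activity_profile"
  out
}

#' @export
print.activity_profile <- function(x, digits = 1, ...) {
  cat(sprintf("<activity_profile> %s (%s): %d day(s), %d-s epochs\n",
              x$id, x$stratum, x$n_days, x$epoch_len_s))
  cat(sprintf("  average acceleration: %.*f mg\n", digits,
              x$participant[["avg_accel_mg"]]))
  cat(sprintf("  intensity gradient:   %.3f (r2 %.3f)\n",
              x$participant[["ig_slope"]], x$participant[["ig_r2"]]))
  mxv <- x$participant[paste0("m", x$durations)]
  cat("  MX (mg): ",
      paste(sprintf("M%d=%.*f", x$durations, digits, mxv),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.activity_profile <- function(object, ...) {
  structure(list(fit = object), class = "summary.activity_profile")
}

#' @export
print.summary.activity_profile <- function(x, ...) {
  print(x$fit)
  cat("per-day metrics:\n")
  print(x$fit$days, digits = 4)
  invisible(x)
}

#' @export
coef.activity_profile <- function(object, ...) object$participant

#' Radar plot of a fitted activity profile
#'
#' @param x an `activity_profile`.
#' @param spec a [radar_spec()]; defaults to the standard six-axis raw
#'   layout sized to this profile.
#' @param ... passed to [plot_mx_radar()].
#' @return The plotted coordinates, invisibly.
#' @export
plot.activity_profile <- function(x, spec = NULL, ...) {
  mxv <- x$participant[paste0("m", x$durations)]
  names(mxv) <- sub("^m", "", names(mxv))
  if (is.null(spec)) {
    axes <- intersect(c(480, 120, 60, 30, 15, 5), x$durations)
    spec <- radar_spec(axes = axes)
  }
  plot_mx_radar(setNames(list(mxv), x$id), spec = spec, ...)
}

# --- cohort assembly -----------------------------------------------------

#' Assemble a cohort metrics table
#'
#' One row per participant (and stratum): identifier, group label, average
#' acceleration, intensity-gradient fit and the MX vector — the table
#' consumed by the translation and radar functions.
#'
#' @param fits list of `activity_profile` objects (or of
#'   `participant_record`s, which are fitted first).
#' @param group optional character vector of group labels, recycled.
#' @param allow_mixed_epochs averaging over coarser epochs smooths out
#'   high-intensity activity, so profiles computed at different epoch
#'   lengths are not comparable and mixing them is refused unless this is
#'   set to `TRUE` explicitly.
#' @return Data frame with columns `id`, `group`, `stratum`,
#'   `avg_accel_mg`, `ig_slope`, `ig_intercept`, `ig_r2`, `m<X>`...
#' @export
cohort_metrics <- function(fits, group = NA_character_,
                           allow_mixed_epochs = FALSE) {
  fits <- lapply(fits, function(f)
    if (inherits(f, "participant_record")) activity_profile(f) else f)
  lens <- vapply(fits, function(f) f$epoch_len_s, numeric(1L))
  if (length(unique(lens)) > 1L && !allow_mixed_epochs)
    stop("epoch length differs between participants; metrics are not ",
         "comparable across epoch lengths (override with ",
         "allow_mixed_epochs = TRUE)", call. = FALSE)
  rows <- lapply(fits, function(f)
    data.frame(id = f$id, stratum = f$stratum,
               as.list(f$participant), check.names = FALSE))
  out <- do.call(rbind, rows)
  out <- cbind(out[1L], group = rep_len(group, nrow(out)),
               out[-1L])
  rownames(out) <- NULL
  out
}

#' Column names of the MX metrics in a cohort table
#' @param table a [cohort_metrics()] data frame.
#' @return Character vector like `c("m2", "m5", ...)`, ordered by
#'   increasing duration.
#' @export
mx_columns <- function(table) {
  nm <- grep("^m[0-9]+$", names(table), value = TRUE)
  nm[order(as.numeric(sub("^m", "", nm)))]
}
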