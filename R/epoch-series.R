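#' Epoch-level ENMO series
#'
#' An `epoch_series` is the package's universal intermediate: a data frame
#' with one row per fixed-length epoch, holding the epoch timestamp (start
#' instant, timezone-naive local clock stored as UTC), the mean ENMO of the
#' epoch in milli-gravitational units (mg), and a wear flag.
#'
#' Wear flags are single characters: `"W"` worn, `"N"` non-wear, `"I"`
#' imputed.  ENMO values must be non-negative and finite for worn and imputed
#' epochs; non-wear epochs may carry `NA` (they are replaced at imputation).
#'
#' @param time `POSIXct` epoch start instants, strictly increasing with a
#'   constant step equal to `epoch_len_s` seconds.
#' @param enmo_mg numeric epoch ENMO values (mg).
#' @param wear character wear flags in `c("W", "N", "I")`, recycled if
#'   length one.
#' @param epoch_len_s epoch length in seconds; must divide 86400 so that
#'   days slice reproducibly at midnight.
#' @return An object of class `epoch_series` (a data frame with columns
#'   `time`, `enmo_mg`, `wear` and attribute `epoch_len_s`).
#' @examples
#' t0 <- as.POSIXct("2023-05-01 00:00:00", tz = "UTC")
#' es <- epoch_series(t0 + seq(0, by = 5, length.out = 12),
#'                    enmo_mg = rep(30, 12))
#' epoch_len(es)
#' @export
epoch_series <- function(time, enmo_mg, wear = "W", epoch_len_s = 5L) {
  if (!inherits(time, "POSIXct"))
    stop("`time` must be POSIXct", call. = FALSE)
  n <- length(time)
  if (length(enmo_mg) != n)
    stop("`time` and `enmo_mg` lengths differ", call. = FALSE)
  if (length(wear) == 1L) wear <- rep(wear, n)
  if (length(wear) != n)
    stop("`wear` must have length 1 or length(time)", call. = FALSE)
  check_epoch_len(epoch_len_s)
  bad_flag <- which(!wear %in% c("W", "N", "I"))
  if (length(bad_flag))
    stop("invalid wear flag at row ", bad_flag[1L], call. = FALSE)
  if (n > 1L) {
    dt <- as.numeric(diff(as.numeric(time)))
    off <- which(abs(dt - epoch_len_s) > 1e-6)
    if (length(off))
      stop("timestamps not uniformly spaced at ", epoch_len_s,
           " s: first offending row ", off[1L] + 1L, call. = FALSE)
  }
  bad <- which(!is.finite(enmo_mg) & wear != "N")
  if (length(bad))
    stop("non-finite ENMO at row ", bad[1L], call. = FALSE)
  neg <- which(is.finite(enmo_mg) & enmo_mg < 0)
  if (length(neg))
    stop("negative ENMO at row ", neg[1L], call. = FALSE)
  out <- data.frame(time = time, enmo_mg = as.numeric(enmo_mg),
                    wear = wear, stringsAsFactors = FALSE)
  attr(out, "epoch_len_s") <- as.integer(epoch_len_s)
  class(out) <- c("epoch_series", "data.frame")
  out
}

check_epoch_len <- function(epoch_len_s) {
  if (length(epoch_len_s) != 1L || !is.finite(epoch_len_s) ||
      epoch_len_s <= 0 || 86400 %% epoch_len_s != 0)
    stop("`epoch_len_s` must be a positive divisor of 86400", call. = FALSE)
  invisible(epoch_len_s)
}

#' Epoch length of a series
#'
#' @param x an `epoch_series`.
#' @return Epoch length in seconds.
#' @export
epoch_len <- function(x) {
  len <- attr(x, "epoch_len_s")
  if (is.null(len)) stop("not an epoch_series: no epoch_len_s attribute",
                         call. = FALSE)
  len
}

#' Number of epochs in one full day
#' @param epoch_len_s epoch length in seconds.
#' @return `86400 / epoch_len_s`.
#' @export
epochs_per_day <- function(epoch_len_s) {
  check_epoch_len(epoch_len_s)
  as.integer(86400 / epoch_len_s)
}

# 0-based position of each epoch within its day (0 .. epochs_per_day - 1)
clock_index <- function(x) {
  len <- epoch_len(x)
  secs <- as.numeric(x$time) %% 86400
  as.integer(round(secs / len))
}

# calendar date (midnight-to-midnight, naive clock) of each epoch
epoch_date <- function(x) as.Date(x$time, tz = "UTC")

#' Split an epoch series into calendar days
#'
#' Days run midnight to midnight on the naive local clock.
#'
#' @param x an `epoch_series`.
#' @return Named list of `epoch_series`, one per calendar date present.
#' @export
split_days <- function(x) {
  d <- epoch_date(x)
  idx <- split(seq_len(nrow(x)), d)
  lapply(idx, function(i) {
    out <- x[i, , drop = FALSE]
    attr(out, "epoch_len_s") <- epoch_len(x)
    class(out) <- c("epoch_series", "data.frame")
    out
  })
}

#' Pad an epoch series to whole calendar days
#'
#' Missing epochs (before the first record, after the last, or in gaps in
#' the clock grid) are inserted as non-wear epochs with `NA` ENMO, so that
#' the padded series covers every day touched by the input from midnight to
#' midnight.  Required before day-level validity screening, where absent
#' data counts as not worn.
#'
#' @param x an `epoch_series`.
#' @return An `epoch_series` whose length is a multiple of
#'   [epochs_per_day()].
#' @export
pad_days <- function(x) {
  len <- epoch_len(x)
  d <- epoch_date(x)
  day0 <- as.POSIXct(paste(min(d), "00:00:00"), tz = "UTC")
  day_end <- as.POSIXct(paste(max(d) + 1L, "00:00:00"), tz = "UTC")
  grid <- seq(day0, day_end - len, by = len)
  pos <- match(round(as.numeric(x$time)), round(as.numeric(grid)))
  if (anyNA(pos))
    stop("epoch timestamps not aligned to the epoch grid", call. = FALSE)
  enmo <- rep(NA_real_, length(grid))
  wear <- rep("N", length(grid))
  enmo[pos] <- x$enmo_mg
  wear[pos] <- x$wear
  epoch_series(grid, enmo, wear, len)
}

#' @export
print.epoch_series <- function(x, ...) {
  len <- epoch_len(x)
  n <- nrow(x)
  cat(sprintf("<epoch_series> %d epochs of %d s (%.2f h), %s -> %s\n",
              n, len, n * len / 3600,
              format(x$time[1L]), format(x$time[n])))
  tab <- table(factor(x$wear, levels = c("W", "N", "I")))
  cat(sprintf("  wear: %d worn, %d non-wear, %d imputed\n",
              tab[["W"]], tab[["N"]], tab[["I"]]))
  worn <- x$enmo_mg[x$wear != "N"]
  if (length(worn))
    cat(sprintf("  ENMO (mg): mean %.1f, max %.1f\n",
                mean(worn), max(worn)))
  invisible(x)
}
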