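#' Per-sample ENMO from tri-axial acceleration
#'
#' ENMO (Euclidean norm minus one g) is the vector magnitude of the three
#' acceleration axes minus standard gravity, with negative values truncated
#' to zero, expressed in milli-gravitational units (mg).  Input axes are in
#' g and assumed autocalibrated; truncation is applied per sample, before
#' any epoch averaging.
#'
#' @param x,y,z numeric acceleration per axis in g, equal lengths.  `x` may
#'   instead be a data frame with columns `x`, `y`, `z` (and optionally
#'   `time`), in which case `y` and `z` are ignored.
#' @return Numeric vector of per-sample ENMO in mg.
#' @examples
#' compute_enmo(0, 0, 1)     # resting flat: 0 mg
#' compute_enmo(0, 0, 1.2)   # 200 mg
#' compute_enmo(0, 0, 0.9)   # truncated to 0 mg
#' @export
compute_enmo <- function(x, y = NULL, z = NULL) {
  if (is.data.frame(x)) {
    need <- c("x", "y", "z")
    if (!all(need %in% names(x)))
      stop("data frame input must have columns x, y, z", call. = FALSE)
    y <- x$y; z <- x$z; x <- x$x
  }
  if (length(y) != length(x) || length(z) != length(x))
    stop("axis vectors must have equal length", call. = FALSE)
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop("non-finite acceleration sample at row ", bad[1L], call. = FALSE)
  pmax(0, sqrt(x^2 + y^2 + z^2) - 1) * 1000
}

#' Aggregate a per-sample ENMO series into fixed epochs
#'
#' Samples are aligned to clock boundaries: the first epoch starts at the
#' first multiple of `epoch_len_s` seconds from midnight at or after the
#' first sample, and partial leading/trailing epochs are dropped.  Each
#' epoch value is the arithmetic mean of its samples, so day totals are
#' conserved for inputs that divide into whole epochs.
#'
#' @param time `POSIXct` sample instants, uniformly spaced at
#'   `1 / rate_hz` s.
#' @param enmo_mg per-sample ENMO (mg), e.g. from [compute_enmo()].
#' @param epoch_len_s epoch length in seconds (default 5).
#' @param rate_hz sampling rate; inferred from the timestamps when `NULL`.
#' @return An [epoch_series()] of epoch-mean ENMO, all flagged worn.
#' @export
aggregate_epochs <- function(time, enmo_mg, epoch_len_s = 5L,
                             rate_hz = NULL) {
  check_epoch_len(epoch_len_s)
  if (length(time) != length(enmo_mg))
    stop("`time` and `enmo_mg` lengths differ", call. = FALSE)
  tt <- as.numeric(time)
  if (is.null(rate_hz)) {
    if (length(tt) < 2L)
      stop("cannot infer rate_hz from fewer than two samples",
           call. = FALSE)
    rate_hz <- 1 / stats::median(diff(tt))
  }
  if (rate_hz <= 0) stop("rate_hz must be positive", call. = FALSE)
  if (epoch_len_s < 1 / rate_hz)
    stop("epoch shorter than one sample interval", call. = FALSE)
  step <- 1 / rate_hz
  dt <- diff(tt)
  off <- which(abs(dt - step) > step * 1e-3)
  if (length(off))
    stop("samples not uniformly spaced: first offending row ",
         off[1L] + 1L, call. = FALSE)
  # first clock-aligned epoch boundary at or after the first sample
  t0 <- ceiling((tt[1L] - 1e-9) / epoch_len_s) * epoch_len_s
  per <- as.integer(round(epoch_len_s * rate_hz))
  first <- which(tt >= t0 - 1e-9)[1L]
  n_ep <- (length(tt) - first + 1L) %/% per
  if (is.na(first) || n_ep < 1L)
    stop("input too short for a single aligned epoch", call. = FALSE)
  idx <- first:(first + n_ep * per - 1L)
  vals <- colMeans(matrix(enmo_mg[idx], nrow = per))
  starts <- as.POSIXct(t0 + (seq_len(n_ep) - 1L) * epoch_len_s,
                       origin = "1970-01-01", tz = "UTC")
  epoch_series(starts, vals, "W", epoch_len_s)
}

#' Read a raw tri-axial acceleration CSV
#'
#' Expects a header `timestamp,x,y,z` with ISO-8601 timestamps and axes in
#' g at a constant sampling rate.
#'
#' @param path CSV file path.
#' @param rate_hz declared sampling rate; validated against the timestamps.
#' @return Data frame with `time` (POSIXct) and `x`, `y`, `z` columns plus
#'   attribute `rate_hz`.
#' @export
read_raw_csv <- function(path, rate_hz = 100) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tm <- parse_iso_time(df$timestamp)
  dt <- diff(as.numeric(tm))
  step <- 1 / rate_hz
  off <- which(dt <= 0 | abs(dt - step) > step * 1e-3)
  if (length(off))
    stop("timestamps not increasing at 1/rate_hz: first offending row ",
         off[1L] + 1L, call. = FALSE)
  out <- data.frame(time = tm, x = df$x, y = df$y, z = df$z)
  attr(out, "rate_hz") <- rate_hz
  out
}

parse_iso_time <- function(s) {
  s <- sub("T", " ", s, fixed = TRUE)
  tm <- as.POSIXct(s, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  if (anyNA(tm))
    stop("unparseable timestamp at row ", which(is.na(tm))[1L],
         call. = FALSE)
  tm
}
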