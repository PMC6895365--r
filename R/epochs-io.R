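#' Read an epoch-level ENMO CSV
#'
#' Expects a header `timestamp,enmo_mg` with an optional `wear` column
#' (`W` worn, `N` non-wear, `I` imputed).  Timestamps must be ISO-8601,
#' strictly increasing at a constant spacing, which becomes the epoch
#' length.
#'
#' @param path CSV file path.
#' @param epoch_len_s expected epoch length in seconds; inferred from the
#'   timestamps when `NULL` and validated otherwise.
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path, epoch_len_s = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "enmo_mg")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tm <- parse_iso_time(df$timestamp)
  if (nrow(df) > 1L) {
    dt <- diff(as.numeric(tm))
    if (is.null(epoch_len_s)) {
      # modal spacing (smallest on ties), so a gap never inflates the
      # inferred epoch length
      tab <- table(round(dt, 6))
      epoch_len_s <- round(min(as.numeric(names(tab)[tab == max(tab)])))
    }
    off <- which(abs(dt - epoch_len_s) > 1e-6)
    if (length(off))
      stop("inconsistent epoch spacing: first offending row ",
           off[1L] + 1L, call. = FALSE)
  } else if (is.null(epoch_len_s)) {
    stop("epoch_len_s required for a single-row file", call. = FALSE)
  }
  wear <- if ("wear" %in% names(df)) df$wear else "W"
  epoch_series(tm, df$enmo_mg, wear, epoch_len_s)
}

#' Write an epoch series to CSV
#'
#' Values are written with full double precision so that
#' `read_epoch_csv(write_epoch_csv(x))` round-trips exactly for finite
#' values; the `wear` column is always included.
#'
#' @param x an [epoch_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(x, path) {
  stopifnot(inherits(x, "epoch_series"))
  df <- data.frame(
    timestamp = format(x$time, "%Y-%m-%dT%H:%M:%S"),
    enmo_mg = sprintf("%.17g", x$enmo_mg),
    wear = x$wear,
    stringsAsFactors = FALSE)
  df$enmo_mg[!is.finite(x$enmo_mg)] <- NA
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
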