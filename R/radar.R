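# Radar ("spider") plots of MX activity profiles.  Axes are MX durations
# arranged clockwise from the top; polygon size on the short-duration axes
# (left of the plot) visualises the intensity gradient, overall size the
# volume.  Geometry lives in polar_map() so it is testable without a
# graphics device; rendering is deterministic given spec + data.

#' Declarative description of a radar plot
#'
#' @param axes ordered MX durations (minutes), placed clockwise from the
#'   top; default the six-axis layout `480, 120, 60, 30, 15, 5` (add 10
#'   and 2 for the eight-axis variant).  At least 3 distinct axes.
#' @param mode `"raw"` (radii in mg) or `"standardized"` (radii in SD
#'   units).
#' @param radial_max outer radius in mg for raw mode; `NULL` sizes it to
#'   the data (max over plotted vectors rounded up to a clean step).
#' @param z_range radial range in SD units for standardised mode.
#' @param reference_bands named numeric vector of dashed reference circles
#'   (mg in raw mode, SD units in standardised mode), e.g.
#'   `c(slow_walk = 90, brisk_walk = 200)`.
#' @return Object of class `radar_spec`.
#' @export
radar_spec <- function(axes = c(480, 120, 60, 30, 15, 5),
                       mode = c("raw", "standardized"),
                       radial_max = NULL, z_range = c(-2.5, 2.5),
                       reference_bands = NULL) {
  mode <- match.arg(mode)
  if (length(axes) < 3L || anyDuplicated(axes))
    stop("at least 3 distinct axes required", call. = FALSE)
  if (!is.null(radial_max) && radial_max <= 0)
    stop("radial_max must be positive", call. = FALSE)
  if (diff(z_range) <= 0) stop("z_range must be increasing", call. = FALSE)
  structure(list(axes = axes, mode = mode, radial_max = radial_max,
                 z_range = z_range, reference_bands = reference_bands),
            class = "radar_spec")
}

# pull the value for each spec axis out of a (possibly "m"-prefixed) vector
axis_values <- function(spec, mx_vector) {
  nm <- names(mx_vector)
  keys <- as.character(spec$axes)
  v <- mx_vector[match(keys, nm)]
  alt <- mx_vector[match(paste0("m", keys), nm)]
  v[is.na(v)] <- alt[is.na(v)]
  if (anyNA(v))
    stop("missing axis value for M", keys[which(is.na(v))[1L]],
         call. = FALSE)
  stats::setNames(as.numeric(v), keys)
}

# unit radius for a value under the spec's scaling mode
unit_radius <- function(spec, values, radial_max) {
  if (spec$mode == "raw") {
    pmin(pmax(values / radial_max, 0), 1)
  } else {
    zr <- spec$z_range
    pmin(pmax((values - zr[1L]) / diff(zr), 0), 1)
  }
}

#' Map an MX vector to closed polar coordinates
#'
#' Axis k (0-based) sits at angle `pi/2 - 2*pi*k/K` — the first axis at
#' the top, subsequent axes clockwise.  Radii are scaled to `[0, 1]` by
#' `radial_max` (raw mode) or the spec's `z_range` (standardised mode) and
#' clipped; the first vertex is repeated so the polygon is closed.
#'
#' @param spec a [radar_spec()].
#' @param mx_vector named values, names either the durations (`"60"`) or
#'   metric columns (`"m60"`); must cover every axis.
#' @param radial_max overrides the spec's radial maximum (raw mode).
#' @return Data frame with `axis`, `angle_rad`, `radius`, `x`, `y`; the
#'   closing row repeats the first axis.
#' @export
polar_map <- function(spec, mx_vector, radial_max = NULL) {
  v <- axis_values(spec, mx_vector)
  K <- length(spec$axes)
  if (spec$mode == "raw") {
    radial_max <- radial_max %||% spec$radial_max %||% clean_max(v)
    if (radial_max <= 0) stop("radial_max must be positive", call. = FALSE)
  }
  ang <- pi / 2 - 2 * pi * (seq_len(K) - 1L) / K
  r <- unit_radius(spec, v, radial_max)
  out <- data.frame(axis = spec$axes, angle_rad = ang,
                    radius = unname(r),
                    x = unname(r * cos(ang)), y = unname(r * sin(ang)))
  rbind(out, out[1L, ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# smallest "clean" value at or above max(v): 1/2/2.5/5 x 10^k steps
clean_max <- function(v) {
  m <- max(v, na.rm = TRUE)
  if (m <= 0) return(1)
  p <- 10^floor(log10(m))
  for (mult in c(1, 2, 2.5, 5, 10)) if (m <= mult * p) return(mult * p)
  10 * p
}

axis_label <- function(d) ifelse(d == 480, "M1/3DAY", paste0("M", d))

radar_frame <- function(spec, radial_max, rings = 4L) {
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.45, 1.45), ylim = c(-1.3, 1.45),
                        asp = 1)
  th <- seq(0, 2 * pi, length.out = 241L)
  for (f in seq_len(rings) / rings)
    graphics::lines(f * cos(th), f * sin(th), col = "grey85")
  K <- length(spec$axes)
  ang <- pi / 2 - 2 * pi * (seq_len(K) - 1L) / K
  graphics::segments(0, 0, cos(ang), sin(ang), col = "grey85")
  graphics::text(1.18 * cos(ang), 1.18 * sin(ang),
                 axis_label(spec$axes), cex = 0.9)
  # radial tick labels on the vertical axis
  if (spec$mode == "raw") {
    at <- seq_len(rings) / rings
    graphics::text(0.06, at, sprintf("%g", at * radial_max),
                   cex = 0.6, col = "grey40", adj = 0)
  } else {
    zr <- spec$z_range
    at <- unit_radius(spec, pretty(zr, n = 4L), NULL)
    lab <- pretty(zr, n = 4L)
    keep <- at > 0 & at <= 1
    graphics::text(0.06, at[keep], sprintf("%g", lab[keep]),
                   cex = 0.6, col = "grey40", adj = 0)
  }
  # reference circles (e.g. walk bands, or the zero = cohort-mean circle)
  bands <- spec$reference_bands
  if (spec$mode == "standardized")
    bands <- c(bands, mean_z0 = 0)
  if (!is.null(bands)) {
    for (i in seq_along(bands)) {
      r <- unit_radius(spec, bands[[i]], radial_max)
      col <- if (names(bands)[i] == "mean_z0") "black" else "red"
      graphics::lines(r * cos(th), r * sin(th), lty = 2, col = col)
      graphics::text(-0.04, r + 0.035, names(bands)[i], cex = 0.6,
                     col = col, adj = 1)
    }
  }
  invisible(ang)
}

overlay_cols <- function(n) {
  base <- c("#1b6ca8", "#c0392b", "#27ae60", "#8e44ad", "#e67e22",
            "#16a085")
  rep_len(base, n)
}

#' Render a radar plot of one or more MX profiles
#'
#' Draws one closed polygon per profile with a legend, dashed reference
#' circles (walk bands in raw mode; the cohort-mean zero circle in
#' standardised mode), and optional per-group annotations.  When `file` is
#' given, PNG and PDF versions plus a companion CSV of the exact plotted
#' values are written next to it.
#'
#' @param vectors named list of MX vectors (see [polar_map()] for naming),
#'   one per overlay, or a single vector.
#' @param spec a [radar_spec()].
#' @param file output path without extension, or `NULL` to draw on the
#'   active device.
#' @param formats graphics formats when `file` is given.
#' @param annotations optional character vector (one per overlay) appended
#'   to the legend labels, e.g. average-acceleration / intensity-gradient
#'   summaries.
#' @param main plot title.
#' @return Invisibly, a list of the [polar_map()] coordinate tables.
#' @export
plot_mx_radar <- function(vectors, spec = radar_spec(), file = NULL,
                          formats = c("png", "pdf"), annotations = NULL,
                          main = NULL) {
  if (!is.list(vectors)) vectors <- list(profile = vectors)
  if (is.null(names(vectors)))
    names(vectors) <- paste0("group", seq_along(vectors))
  radial_max <- NULL
  if (spec$mode == "raw")
    radial_max <- spec$radial_max %||%
      clean_max(unlist(lapply(vectors, function(v) axis_values(spec, v))))
  maps <- lapply(vectors, polar_map, spec = spec, radial_max = radial_max)
  draw <- function() {
    graphics::par(mar = c(1, 1, 2, 1))
    radar_frame(spec, radial_max)
    cols <- overlay_cols(length(maps))
    for (i in seq_along(maps)) {
      m <- maps[[i]]
      graphics::polygon(m$x, m$y, border = cols[i],
                        col = grDevices::adjustcolor(cols[i], 0.15),
                        lwd = 2)
    }
    leg <- names(maps)
    if (!is.null(annotations))
      leg <- paste0(leg, " (", rep_len(annotations, length(leg)), ")")
    graphics::legend("bottomleft", legend = leg, col = cols, lwd = 2,
                     bty = "n", cex = 0.75)
    if (!is.null(main)) graphics::title(main)
  }
  render_to(file, formats, draw)
  if (!is.null(file)) write_radar_values(file, spec, vectors)
  invisible(maps)
}

#' Render a percentile-shaded radar plot
#'
#' The cohort's percentile polygons are filled light (lowest percentile)
#' to dark grey (highest); an optional individual profile is overlaid so
#' the percentile each of their MX metrics falls on can be read off.
#'
#' @param percentiles matrix from [cohort_percentiles()] (rows =
#'   increasing probabilities, columns covering every spec axis).
#' @param spec a [radar_spec()] in raw mode.
#' @param individual optional single MX vector to overlay.
#' @param file,formats,main as in [plot_mx_radar()].
#' @return Invisibly, the list of percentile [polar_map()] tables.
#' @export
plot_mx_percentiles <- function(percentiles, spec = radar_spec(),
                                individual = NULL, file = NULL,
                                formats = c("png", "pdf"), main = NULL) {
  if (is.null(rownames(percentiles)))
    stop("percentile matrix must have probability rownames", call. = FALSE)
  nall <- c(list(individual = individual)[!is.null(individual)],
            apply(percentiles, 1L, identity, simplify = FALSE))
  radial_max <- spec$radial_max %||%
    clean_max(unlist(lapply(nall, function(v) axis_values(spec, v))))
  np <- nrow(percentiles)
  maps <- lapply(seq_len(np), function(i)
    polar_map(spec, percentiles[i, ], radial_max = radial_max))
  names(maps) <- rownames(percentiles)
  greys <- grDevices::grey(seq(0.95, 0.35, length.out = np))
  draw <- function() {
    graphics::par(mar = c(1, 1, 2, 1))
    radar_frame(spec, radial_max)
    for (i in rev(seq_len(np))) {   # darkest (highest percentile) first
      m <- maps[[i]]
      graphics::polygon(m$x, m$y, border = "grey30", col = greys[i],
                        lwd = 0.5)
    }
    if (!is.null(individual)) {
      mi <- polar_map(spec, individual, radial_max = radial_max)
      graphics::polygon(mi$x, mi$y, border = "#c0392b", lwd = 2)
    }
    graphics::legend("bottomleft", legend = rev(rownames(percentiles)),
                     fill = rev(greys), bty = "n", cex = 0.7)
    if (!is.null(main)) graphics::title(main)
  }
  render_to(file, formats, draw)
  if (!is.null(file)) {
    vecs <- apply(percentiles, 1L, identity, simplify = FALSE)
    if (!is.null(individual)) vecs$individual <- individual
    write_radar_values(file, spec, vecs)
  }
  invisible(maps)
}

render_to <- function(file, formats, draw) {
  if (is.null(file)) { draw(); return(invisible(NULL)) }
  for (fmt in formats) {
    path <- paste0(file, ".", fmt)
    switch(fmt,
           png = grDevices::png(path, width = 1400, height = 1400,
                                res = 200),
           pdf = grDevices::pdf(path, width = 7, height = 7),
           svg = grDevices::svg(path, width = 7, height = 7),
           stop("unsupported format: ", fmt, call. = FALSE))
    tryCatch(draw(), finally = grDevices::dev.off())
  }
  invisible(NULL)
}

# companion table of the exact plotted values (one row per overlay)
write_radar_values <- function(file, spec, vectors) {
  rows <- t(vapply(vectors, function(v) axis_values(spec, v),
                   numeric(length(spec$axes))))
  df <- data.frame(label = rownames(rows), rows, check.names = FALSE)
  names(df)[-1L] <- paste0("m", spec$axes)
  utils::write.csv(df, paste0(file, "_values.csv"), row.names = FALSE)
  invisible(df)
}
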