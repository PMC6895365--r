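# Post-hoc translation of MX metrics: cut-points, percentiles, z-scores,
# tertile profiles and between-device harmonisation.  Cut-points are never
# applied before metric computation -- only here, at interpretation time.

#' Create a cut-point
#'
#' A labelled acceleration threshold (mg) used post-hoc to interpret an MX
#' value, e.g. a wrist MVPA cut-point of 200 mg.
#'
#' @param label short name.
#' @param threshold_mg positive acceleration threshold in mg.
#' @param note free-text provenance (population, wear site, source).
#' @return Object of class `cut_point`.
#' @export
cut_point <- function(label, threshold_mg, note = "") {
  if (!is.finite(threshold_mg) || threshold_mg <= 0)
    stop("threshold_mg must be positive", call. = FALSE)
  structure(list(label = label, threshold_mg = threshold_mg, note = note),
            class = "cut_point")
}

#' @export
print.cut_point <- function(x, ...) {
  cat(sprintf("<cut_point> %s: %g mg%s\n", x$label, x$threshold_mg,
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Load a cut-point registry
#'
#' Reads a YAML registry mapping labels to `{threshold_mg, population,
#' wear_site, source}`.  The bundled default registry ships wrist MVPA
#' cut-points at 200 and 250 mg and vigorous/very-vigorous thresholds at
#' 700 and 1200 mg.
#'
#' @param path YAML file; default the registry bundled with the package.
#' @return Named list of [cut_point()] objects.
#' @export
load_cutpoints <- function(path = system.file("extdata", "cutpoints.yml",
                                              package = "actiprofile")) {
  reg <- yaml::read_yaml(path)
  out <- lapply(names(reg), function(nm) {
    e <- reg[[nm]]
    note <- paste(Filter(nzchar, c(e$population, e$wear_site, e$source)),
                  collapse = "; ")
    cut_point(nm, e$threshold_mg, note)
  })
  names(out) <- names(reg)
  out
}

#' Does an MX value meet a cut-point?
#'
#' `TRUE` when the MX value is at or above the threshold: if M60 is at or
#' above an MVPA cut-point, the most active accumulated 60 min of the day
#' were all at MVPA intensity, i.e. the 60-min guideline is met under that
#' cut-point.  A profile exactly on the threshold counts as meeting it.
#'
#' @param mx_value_mg MX value(s) in mg.
#' @param cp a [cut_point()] or a bare threshold in mg.
#' @return Logical, `TRUE` where the cut-point is met.
#' @export
meets_cutpoint <- function(mx_value_mg, cp) {
  thr <- if (inherits(cp, "cut_point")) cp$threshold_mg else cp
  mx_value_mg >= thr
}

#' Cohort percentiles of the MX metrics
#'
#' Empirical quantiles (linear interpolation) of each requested metric
#' column across participants.
#'
#' @param table a [cohort_metrics()] data frame.
#' @param metrics metric column names; default all MX columns.
#' @param probs probabilities in `[0, 1]`.
#' @return Matrix, rows = probabilities, columns = metrics.
#' @export
cohort_percentiles <- function(table, metrics = mx_columns(table),
                               probs = c(.05, .25, .5, .75, .95)) {
  if (nrow(table) < 2L)
    stop("at least 2 participants required", call. = FALSE)
  out <- vapply(metrics, function(m)
    stats::quantile(table[[m]], probs = probs, type = 7, names = FALSE),
    numeric(length(probs)))
  out <- matrix(out, nrow = length(probs),
                dimnames = list(paste0("p", round(100 * probs, 1)), metrics))
  out
}

#' Percentile rank of an individual within a cohort
#'
#' Mid-rank definition: `100 * (#below + 0.5 * #equal) / n`, so ties are
#' handled symmetrically.
#'
#' @param value individual metric value(s).
#' @param table a [cohort_metrics()] data frame (or a numeric vector of
#'   cohort values).
#' @param metric metric column name when `table` is a data frame.
#' @return Percentile rank(s) in `(0, 100)`.
#' @export
percentile_of <- function(value, table, metric = NULL) {
  cohort <- if (is.data.frame(table)) {
    if (is.null(metric)) stop("metric required", call. = FALSE)
    table[[metric]]
  } else as.numeric(table)
  n <- length(cohort)
  if (!n) stop("empty cohort", call. = FALSE)
  vapply(value, function(v)
    100 * (sum(cohort < v) + 0.5 * sum(cohort == v)) / n, numeric(1L))
}

#' Standardise metric columns within a cohort
#'
#' Within-metric z-scores: `(v - mean) / sd` with the sample SD (n - 1),
#' so each transformed column has mean 0 and SD 1.  Used for the
#' standardised radar plots, where the zero circle marks the cohort mean.
#'
#' @param table a [cohort_metrics()] data frame.
#' @param metrics columns to standardise; default the MX columns plus the
#'   analytical metrics.
#' @return `table` with the chosen columns z-scored; the per-column means
#'   and SDs are kept in attributes `centre` and `scale`.
#' @export
standardize_metrics <- function(table,
                                metrics = c("avg_accel_mg", "ig_slope",
                                            mx_columns(table))) {
  if (nrow(table) < 2L)
    stop("at least 2 participants required", call. = FALSE)
  ctr <- numeric(0); scl <- numeric(0)
  for (m in metrics) {
    v <- table[[m]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-variance metric column: ", m, call. = FALSE)
    table[[m]] <- (v - mean(v)) / s
    ctr[m] <- mean(v); scl[m] <- s
  }
  attr(table, "centre") <- ctr
  attr(table, "scale") <- scl
  table
}

# stable tertile assignment: ranks <= ceil(n/3) low, <= ceil(2n/3) mid,
# rest high; ties broken by original row order
tertile_of <- function(v) {
  n <- length(v)
  r <- rank(v, ties.method = "first")
  cut1 <- ceiling(n / 3); cut2 <- ceiling(2 * n / 3)
  ifelse(r <= cut1, "low", ifelse(r <= cut2, "mid", "high"))
}

#' Mean MX profiles by intensity-gradient tertile at matched volume
#'
#' Restricts the cohort to the mid-tertile of the volume metric (so
#' groups share similar average acceleration), splits that subset into
#' tertiles of the intensity metric, and returns the mean MX vector per
#' group — the construction behind within-group comparisons of profiles
#' differing in intensity gradient but not volume.
#'
#' @param table a [cohort_metrics()] data frame with at least 9 rows.
#' @param volume_metric column used for the mid-tertile restriction.
#' @param split_metric column whose tertiles define the groups.
#' @return List with `groups` (matrix of group-mean MX vectors, rows
#'   `low`/`mid`/`high`), `sizes`, and `members` (row indices per group).
#' @export
tertile_profiles <- function(table, volume_metric = "avg_accel_mg",
                             split_metric = "ig_slope") {
  if (nrow(table) < 9L)
    stop("at least 9 participants required", call. = FALSE)
  mid <- which(tertile_of(table[[volume_metric]]) == "mid")
  grp <- tertile_of(table[[split_metric]][mid])
  mxc <- mx_columns(table)
  lev <- c("low", "mid", "high")
  if (any(vapply(lev, function(g) sum(grp == g), integer(1L)) < 1L))
    stop("empty tertile group", call. = FALSE)
  groups <- do.call(rbind, lapply(lev, function(g)
    colMeans(table[mid[grp == g], mxc, drop = FALSE])))
  rownames(groups) <- lev
  list(groups = groups,
       sizes = stats::setNames(vapply(lev, function(g) sum(grp == g),
                                      integer(1L)), lev),
       members = stats::setNames(lapply(lev, function(g) mid[grp == g]),
                                 lev))
}

#' Affine between-device harmonisation
#'
#' Applies `v' = scale * v + offset` uniformly, recording the transform in
#' attributes.  Accelerations from the ActiGraph run roughly 10% lower
#' than GENEActiv/Axivity at the same wear site, so an approximate preset
#' `scale = 1/0.9` is available via [actigraph_scale()].  Because MX
#' metrics are order statistics, harmonising epochs then computing MX
#' equals computing MX then harmonising (for positive scale).
#'
#' @param values_mg numeric accelerations in mg.
#' @param scale positive multiplicative factor.
#' @param offset additive term in mg.
#' @return Adjusted values with attributes `scale` and `offset`.
#' @export
harmonize <- function(values_mg, scale, offset = 0) {
  if (!is.finite(scale) || scale <= 0)
    stop("scale must be positive", call. = FALSE)
  out <- scale * values_mg + offset
  attr(out, "scale") <- scale
  attr(out, "offset") <- offset
  out
}

#' Approximate ActiGraph-to-GENEActiv scale factor
#'
#' ActiGraph accelerations are approximately 10% lower than
#' GENEActiv/Axivity; this preset (1/0.9) lifts ActiGraph values onto the
#' GENEActiv scale.  It is a ballpark correction, not a calibration.
#'
#' @return The scale factor, `1/0.9`.
#' @export
actigraph_scale <- function() 1 / 0.9

#' Evaluate a metrics table against a cut-point registry
#'
#' @param table a [cohort_metrics()] data frame.
#' @param cutpoints named list from [load_cutpoints()].
#' @param pairs named character vector mapping MX columns to cut-point
#'   labels, e.g. `c(m60 = "mvpa_200")`.
#' @return Data frame: `id` plus one logical column per pair, named
#'   `<metric>_meets_<label>`.
#' @export
translate_cohort <- function(table, cutpoints = load_cutpoints(),
                             pairs = c(m60 = "mvpa_200", m60 = "mvpa_250",
                                       m15 = "vig_700",
                                       m5 = "very_vig_1200")) {
  out <- data.frame(id = table$id)
  for (i in seq_along(pairs)) {
    m <- names(pairs)[i]; lab <- pairs[[i]]
    if (!m %in% names(table)) next
    cp <- cutpoints[[lab]]
    if (is.null(cp)) stop("unknown cut-point label: ", lab, call. = FALSE)
    out[[paste0(m, "_meets_", lab)]] <- meets_cutpoint(table[[m]], cp)
  }
  out
}
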