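# Heat-induced shrinkage analysis: percent-change trajectories, windowed
# shrink rates, and the pre-shrink dilution bookkeeping.

#' Tracked-object classes in shrinkage experiments
#'
#' Neighbour-class labels for shrinking droplets (a droplet shrinks more
#' slowly the more neighbours it has) plus the whole-network side length.
#'
#' @format Character vector.
#' @export
SHRINKAGE_CLASSES <- c("single", "pair", "layer1_center", "layer1_edge",
                       "layer8_center", "layer8_edge", "network_side")

#' A time series of droplet or network dimensions
#'
#' One tracked object: droplet diameters or network side lengths (um) at
#' strictly increasing time points, with its neighbour-class label and the
#' heating temperature.
#'
#' @param times_min Strictly increasing timestamps (min).
#' @param lengths_um Positive measurements (um), one per timestamp.
#' @param object_class One of [SHRINKAGE_CLASSES].
#' @param temperature_C Condition label (deg C), e.g. 36 or 43.
#' @return An object of class `shrinkage_series`.
#' @export
shrinkage_series <- function(times_min, lengths_um,
                             object_class = "single", temperature_C = NA) {
  object_class <- match.arg(object_class, SHRINKAGE_CLASSES)
  if (length(times_min) != length(lengths_um) || length(times_min) < 1L) {
    stop("times and lengths must be non-empty and of equal length")
  }
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (any(lengths_um <= 0)) stop("all lengths must be positive")
  structure(
    list(times_min = as.numeric(times_min),
         lengths_um = as.numeric(lengths_um),
         object_class = object_class,
         temperature_C = temperature_C),
    class = "shrinkage_series"
  )
}

#' Percent change relative to the initial length
#'
#' `100 * (L_t - L_0) / L_0` for every time point; the first element is
#' exactly 0 and the series is invariant under rescaling all lengths by a
#' constant.
#'
#' @param s A [shrinkage_series()].
#' @return Data frame with columns `time_min`, `pct_change`.
#' @examples
#' s <- shrinkage_series(c(0, 10, 20), c(100, 90, 80), "network_side", 43)
#' percent_change_series(s)
#' @export
percent_change_series <- function(s) {
  stopifnot(inherits(s, "shrinkage_series"))
  L0 <- s$lengths_um[1]
  if (L0 == 0) stop("initial length must be nonzero")
  data.frame(time_min = s$times_min,
             pct_change = 100 * (s$lengths_um - L0) / L0)
}

#' Windowed linear shrink rate
#'
#' Least-squares slope of length against time over a time window, with
#' intercept and residual standard error. A linear window slope is reported
#' rather than a fitted decay law, since shrinkage trajectories are
#' quantified empirically, not mechanistically.
#'
#' @param s A [shrinkage_series()].
#' @param window `c(t_min, t_max)` in minutes; defaults to the full series.
#' @return List with `slope_um_per_min`, `intercept_um`, `rse`, `n`.
#' @export
shrink_rate <- function(s, window = range(s$times_min)) {
  stopifnot(inherits(s, "shrinkage_series"), length(window) == 2L)
  keep <- s$times_min >= window[1] & s$times_min <= window[2]
  t <- s$times_min[keep]
  L <- s$lengths_um[keep]
  if (length(t) < 2L) stop("window must contain at least two points")
  if (length(unique(t)) < 2L) stop("cannot fit a rate to identical timestamps")
  fit <- stats::lm(L ~ t)
  # summary.lm warns on numerically perfect fits; a zero RSE is meaningful here
  s <- suppressWarnings(summary(fit)$sigma)
  list(slope_um_per_min = unname(stats::coef(fit)[2]),
       intercept_um = unname(stats::coef(fit)[1]),
       rse = s,
       n = length(t))
}

#' Concentration factor of isotropic droplet shrinkage
#'
#' When a droplet shrinks isotropically from diameter `d_initial` to
#' `d_final`, solute concentrations rise by `(d_initial / d_final)^3`. The
#' inverse is the pre-dilution to apply before printing so that target
#' concentrations are reached after shrinkage. Composes multiplicatively
#' over staged shrinkage.
#'
#' @param d_initial,d_final Positive diameters (any common unit).
#' @return Concentration multiplier (dimensionless).
#' @examples
#' dilution_factor(65, 50)  # ~2.2-fold concentration increase
#' @export
dilution_factor <- function(d_initial, d_final) {
  if (any(c(d_initial, d_final) <= 0)) stop("diameters must be positive")
  (d_initial / d_final)^3
}

#' Read a shrinkage measurement table
#'
#' CSV with columns `object_id`, `class`, `temperature_C`, `time_min`,
#' `length_um`; one row per measurement.
#'
#' @param path CSV path.
#' @return List of [shrinkage_series()], one per `object_id`.
#' @export
read_shrinkage_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("object_id", "class", "temperature_C", "time_min", "length_um")
  if (!all(need %in% names(df))) {
    stop(sprintf("shrinkage CSV must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  lapply(split(df, df$object_id), function(d) {
    d <- d[order(d$time_min), ]
    shrinkage_series(d$time_min, d$length_um, d$class[1], d$temperature_C[1])
  })
}

#' Per-class shrinkage summary
#'
#' Grouped summary over tracked objects: mean final percent change and mean
#' windowed rate per neighbour class and temperature.
#'
#' @param series_list List of [shrinkage_series()].
#' @param window Time window passed to [shrink_rate()]; default full range.
#' @return Data frame with one row per (class, temperature).
#' @export
shrinkage_summary <- function(series_list, window = NULL) {
  stopifnot(length(series_list) >= 1L)
  rows <- lapply(series_list, function(s) {
    pc <- percent_change_series(s)
    w <- window %||% range(s$times_min)
    r <- shrink_rate(s, w)
    data.frame(object_class = s$object_class,
               temperature_C = s$temperature_C,
               final_pct_change = pc$pct_change[nrow(pc)],
               slope_um_per_min = r$slope_um_per_min)
  })
  df <- do.call(rbind, rows)
  out <- stats::aggregate(cbind(final_pct_change, slope_um_per_min) ~
                     object_class + temperature_C, data = df, FUN = mean)
  out[order(out$object_class, out$temperature_C), , drop = FALSE]
}
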