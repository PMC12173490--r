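#' Observable time series
#'
#' A data frame with one row per sample and columns \code{t} (time),
#' \code{x, y, z} (centre of mass), \code{bax, bay, baz} (body axis unit
#' vector), \code{uax, uay, uaz} (bundle axis unit vector) and unwrapped
#' rotation phases \code{phi_body}, \code{phi_bundle} (radians).  Produced
#' by [run_schedule()] or [make_synthetic_trajectory()].
#'
#' @param df a data frame with the columns above.
#' @return the validated series.
#' @export
observable_series <- function(df) {
  need <- c("t", "x", "y", "z", "bax", "bay", "baz", "uax", "uay", "uaz",
            "phi_body", "phi_bundle")
  stopifnot(all(need %in% names(df)))
  if (any(diff(df$t) <= 0)) stop("time stamps must be strictly increasing")
  nb <- sqrt(df$bax^2 + df$bay^2 + df$baz^2)
  nu <- sqrt(df$uax^2 + df$uay^2 + df$uaz^2)
  if (any(abs(nb - 1) > 1e-6) || any(abs(nu - 1) > 1e-6))
    stop("axis columns must be unit vectors")
  df
}

#' Swimming speed from fixed-time displacements
#'
#' \eqn{v = |r(t_0 + \Delta t) - r(t_0)| / \Delta t} averaged over sliding
#' windows.  The default window is 22.8 tau (0.15 s), chosen so the
#' bacterium does not change its swimming direction within a run phase.
#'
#' @param series an [observable_series()].
#' @param window displacement window in the series' time units.
#' @return list with \code{mean}, \code{sd}, \code{n} and the per-window
#'   \code{samples}.
#' @export
swimming_speed <- function(series, window = 22.8) {
  t <- series$t
  if (window > (max(t) - min(t)) + 1e-12)
    stop("window exceeds the series time span")
  r <- as.matrix(series[, c("x", "y", "z")])
  v <- c()
  for (i in seq_along(t)) {
    j <- which(t >= t[i] + window - 1e-9)[1]
    if (is.na(j)) break
    v <- c(v, sqrt(sum((r[j, ] - r[i, ])^2)) / (t[j] - t[i]))
  }
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       n = length(v), samples = v)
}

#' Wobbling angle between body axis and bundle axis
#'
#' The angle between the body orientation vector and the bundle axis,
#' folded into [0, 90] degrees and sampled at a fixed interval
#' (default 0.3 tau).
#'
#' @param series an [observable_series()].
#' @param every sampling interval in the series' time units.
#' @return list with \code{mean}, \code{sd} (degrees) and the
#'   \code{samples}.
#' @export
wobbling_angle <- function(series, every = 0.3) {
  tgt <- seq(min(series$t), max(series$t), by = every)
  idx <- vapply(tgt, function(tt) which.min(abs(series$t - tt)), integer(1))
  idx <- unique(idx)
  b <- as.matrix(series[idx, c("bax", "bay", "baz")])
  u <- as.matrix(series[idx, c("uax", "uay", "uaz")])
  cang <- abs(rowSums(b * u))
  ang <- acos(pmin(1, cang)) * 180 / pi  # folded into [0, 90]
  list(mean = mean(ang), sd = if (length(ang) > 1) sd(ang) else 0,
       samples = ang)
}

#' Rotation frequency of the body or the bundle
#'
#' The unwrapped rotation phase about the respective axis divided by the
#' elapsed time.  Requires at least one full rotation in the window.
#'
#' @param series an [observable_series()].
#' @param component \code{"body"} or \code{"bundle"}.
#' @param us a [unit_system()] used for the Hz conversion (assumes the
#'   series time unit is tau).
#' @return list with \code{omega} (rotations per unit time, signed),
#'   \code{hz} (magnitude in Hz) and \code{rotations}.
#' @export
rotation_frequency <- function(series, component = c("body", "bundle"),
                               us = unit_system()) {
  component <- match.arg(component)
  phi <- series[[paste0("phi_", component)]]
  dt <- max(series$t) - min(series$t)
  rot <- (phi[length(phi)] - phi[1]) / (2 * pi)
  if (abs(rot) < 1)
    warning("less than one full rotation in the window")
  omega <- rot / dt
  list(omega = omega, hz = abs(to_SI(omega, "frequency", us)),
       rotations = rot)
}

#' Tumble angle per event
#'
#' The angle between the time-averaged body axis over a window before the
#' tumble start and after bundle re-formation.
#'
#' @param series an [observable_series()].
#' @param events data frame with columns \code{t_start} (tumble start) and
#'   \code{t_reform} (bundle re-formation time).
#' @param window averaging window in the series' time units.
#' @return list with per-event \code{angles} (degrees), \code{mean} and
#'   \code{sd}.
#' @export
tumble_angle <- function(series, events, window = 1) {
  mean_axis <- function(lo, hi) {
    sel <- series$t >= lo & series$t <= hi
    if (!any(sel)) stop("no samples in averaging window")
    a <- colMeans(series[sel, c("bax", "bay", "baz"), drop = FALSE])
    a / sqrt(sum(a^2))
  }
  ang <- vapply(seq_len(nrow(events)), function(k) {
    a1 <- mean_axis(events$t_start[k] - window, events$t_start[k])
    a2 <- mean_axis(events$t_reform[k], events$t_reform[k] + window)
    acos(max(-1, min(1, sum(a1 * a2)))) * 180 / pi
  }, numeric(1))
  list(angles = ang, mean = mean(ang),
       sd = if (length(ang) > 1) sd(ang) else 0)
}
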