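#' Reduced-scale swimmer fixture
#'
#' A geometrically similar swimmer with shortened flagella and a coarser
#' body mesh in a small periodic box with reduced fluid density, assembled
#' deterministically from the seed.  All structural invariants of the full
#' model hold (particle counts per segment, orthonormal triads, closed
#' mesh); the system is intended for integration smoke tests and
#' force/torque-free checks on a single CPU.
#'
#' @param n_flag number of flagella.
#' @param Ns segments per flagellum (>= 10).
#' @param seed integer seed.
#' @param ... further overrides passed to [mini_config()].
#' @return an \code{ecoli_sim}.
#' @export
make_mini_swimmer <- function(n_flag = 1L, Ns = 20L, seed = 1L, ...) {
  stopifnot(Ns >= 10)
  cfg <- mini_config(n_flag = n_flag, Ns = Ns, ...)
  cfg$seed <- as.integer(seed)
  assemble(cfg)
}

#' Synthetic observable trajectories with known ground truth
#'
#' Analytically constructed [observable_series()] for testing the analysis
#' operations:
#' \describe{
#'   \item{straight}{constant velocity \code{params$v} along
#'     \code{params$dir}; aligned constant axes.}
#'   \item{precessing}{body axis precessing about the bundle axis on a
#'     cone of half-angle \code{params$alpha_deg} at \code{params$omega}
#'     rotations per time unit.}
#'   \item{rotating}{fixed axes, body and bundle phases advancing at
#'     \code{params$omega_body}, \code{params$omega_bundle} rotations per
#'     time unit (opposite signs by default).}
#'   \item{tumbling}{body axis rotating by \code{params$beta_deg} between
#'     two run phases; the returned series has an \code{events} attribute
#'     with \code{t_start} and \code{t_reform}.}
#' }
#'
#' @param kind trajectory kind.
#' @param params named list of kind-specific parameters (see above);
#'   missing entries take defaults.
#' @param seed integer seed for the (small) added jitter.
#' @param tmax series duration; \code{dt} sampling interval.
#' @return an [observable_series()].
#' @export
make_synthetic_trajectory <- function(kind = c("straight", "precessing",
                                               "rotating", "tumbling"),
                                      params = list(), seed = 1L,
                                      tmax = 60, dt = 0.1) {
  kind <- match.arg(kind)
  t <- seq(0, tmax, by = dt)
  n <- length(t)
  p <- function(name, default) if (!is.null(params[[name]]))
    params[[name]] else default
  jitter_sd <- p("jitter", 0)
  dirv <- p("dir", c(1, 0, 0))
  dirv <- dirv / sqrt(sum(dirv^2))
  df <- data.frame(t = t, x = 0, y = 0, z = 0,
                   bax = dirv[1], bay = dirv[2], baz = dirv[3],
                   uax = dirv[1], uay = dirv[2], uaz = dirv[3],
                   phi_body = 0, phi_bundle = 0)
  if (kind == "straight") {
    v <- p("v", 0.077)
    df$x <- v * t * dirv[1]
    df$y <- v * t * dirv[2]
    df$z <- v * t * dirv[3]
  } else if (kind == "precessing") {
    alpha <- p("alpha_deg", 20) * pi / 180
    om <- p("omega", 1)
    phase <- 2 * pi * om * t
    # bundle axis fixed along x; body axis on a cone about it
    df$bax <- cos(alpha)
    df$bay <- sin(alpha) * cos(phase)
    df$baz <- sin(alpha) * sin(phase)
  } else if (kind == "rotating") {
    df$phi_body <- 2 * pi * p("omega_body", 0.22) * t
    df$phi_bundle <- -2 * pi * p("omega_bundle", 1) * t
  } else if (kind == "tumbling") {
    beta <- p("beta_deg", 60) * pi / 180
    t_start <- p("t_start", tmax / 3)
    t_reform <- p("t_reform", 2 * tmax / 3)
    frac <- pmin(1, pmax(0, (t - t_start) / (t_reform - t_start)))
    ang <- beta * frac
    df$bax <- cos(ang)
    df$bay <- sin(ang)
    df$baz <- 0
    df$uax <- df$bax
    df$uay <- df$bay
    attr(df, "events") <- data.frame(t_start = t_start,
                                     t_reform = t_reform)
  }
  if (jitter_sd > 0) {
    with_seed(seed, {
      for (col in c("x", "y", "z"))
        df[[col]] <- df[[col]] + rnorm(n, 0, jitter_sd)
    })
  }
  ev <- attr(df, "events")
  out <- observable_series(df)
  attr(out, "events") <- ev
  out
}
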