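#' DPD pair parameters
#'
#' Conservative amplitude, friction, weight-function exponent and cutoff of
#' one DPD pair class.  The random-force amplitude is tied to the friction
#' by the fluctuation-dissipation relation \eqn{\sigma^2 = 2\gamma k_BT}
#' with \eqn{w^D = (w^R)^2}.
#'
#' @param a conservative force amplitude (energy/length).
#' @param gamma dissipative friction (sqrt(mass energy)/length).
#' @param s exponent of the weight function \eqn{w^R = (1 - r/r_c)^s}.
#' @param rc cutoff radius.
#' @param kBT thermal energy.
#' @return list of class \code{dpd_params} including the derived
#'   \code{sigma}.
#' @export
dpd_params <- function(a, gamma, s, rc, kBT = 1) {
  stopifnot(rc > 0, gamma >= 0, kBT > 0)
  structure(list(a = a, gamma = gamma, s = s, rc = rc, kBT = kBT,
                 sigma = sqrt(2 * gamma * kBT)),
            class = "dpd_params")
}

#' DPD pair force (reference implementation)
#'
#' Sum of the conservative, dissipative and random forces on particle i
#' from particle j:
#' \deqn{F = a(1 - r/r_c)\hat r - \gamma w^R(r)^2 (\hat r \cdot v_{ij})
#'   \hat r + \sigma w^R(r) \xi_{ij} \hat r / \sqrt{\Delta t}.}
#' All terms vanish for \eqn{r \ge r_c}; the force is antisymmetric under
#' exchange of i and j (with the same symmetric variate \eqn{\xi}).
#'
#' @param ri,rj positions.
#' @param vi,vj velocities.
#' @param params a [dpd_params()].
#' @param xi symmetric standard-normal variate of the pair.
#' @param dt time step.
#' @return force vector on particle i.
#' @export
dpd_pair_force <- function(ri, rj, vi, vj, params, xi = 0, dt = 1) {
  rij <- ri - rj
  r <- sqrt(sum(rij^2))
  if (r == 0) stop("overlapping particles: rij = 0")
  if (r >= params$rc) return(c(0, 0, 0))
  e <- rij / r
  w <- (1 - r / params$rc)^params$s
  fc <- params$a * (1 - r / params$rc)
  fd <- -params$gamma * w^2 * sum(e * (vi - vj))
  fr <- params$sigma * w * xi / sqrt(dt)
  (fc + fd + fr) * e
}

#' Create a periodic DPD fluid box
#'
#' Deterministic pure-fluid fixture: uniformly random particle positions at
#' the requested number density and Maxwell-distributed velocities with the
#' centre-of-mass motion removed.  Fully reproducible from the seed.
#'
#' @param side box side length in bx (cubic box).
#' @param nd number density in bx^-3.
#' @param seed integer seed.
#' @param kBT thermal energy.
#' @param us a [unit_system()].
#' @return list of class \code{dpd_system} with raw-unit \code{pos},
#'   \code{vel}, \code{box}, \code{nd} and bookkeeping fields.
#' @export
make_fluid_box <- function(side = 1, nd = 2.16e3, seed = 1, kBT = 1,
                           us = unit_system()) {
  L <- bx_to_raw(side, us)
  n <- round(nd * side^3)
  with_seed(seed, {
    pos <- matrix(runif(3 * n, 0, L), n, 3)
    vel <- matrix(rnorm(3 * n, 0, sqrt(kBT)), n, 3)
  })
  vel <- sweep(vel, 2, colMeans(vel))
  structure(list(pos = pos, vel = vel, box = rep(L, 3), n = n,
                 nd = nd / us$bx_sim^3, kBT = kBT, step = 0, seed = seed),
            class = "dpd_system")
}

# run the RNG-dependent expression under a fixed seed without touching the
# caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Advance a pure DPD fluid
#'
#' Velocity-Verlet integration (dissipative force recomputed with the
#' half-step velocities) of a pure fluid box, optionally with the
#' periodic-Poiseuille body force \code{+/- fbody} along x in the two
#' z-halves of the box.  Binned velocity-profile and kinetic-temperature
#' statistics are accumulated after \code{burn} steps.
#'
#' @param system a \code{dpd_system} from [make_fluid_box()].
#' @param params fluid-fluid [dpd_params()] in raw units.
#' @param nsteps number of time steps.
#' @param dt time step (raw units).
#' @param fbody body-force magnitude per particle (raw units).
#' @param nbins number of z bins for profile/temperature statistics.
#' @param burn steps to skip before accumulating.
#' @param sample_every interval for the temperature time series (0 = off).
#' @return the system with advanced state and a \code{stats} field.
#' @export
fluid_run <- function(system, params, nsteps, dt, fbody = 0, nbins = 30,
                      burn = 0, sample_every = 0) {
  out <- cpp_fluid_run(system$pos, system$vel, system$box, params$a,
                       params$gamma, params$s, params$rc, params$kBT, dt,
                       as.integer(nsteps), system$seed, system$step, fbody,
                       as.integer(nbins), as.integer(burn),
                       as.integer(sample_every))
  system$pos <- out$pos
  system$vel <- out$vel
  system$step <- system$step + nsteps
  system$stats <- out[c("bin_n", "bin_vx", "bin_vx2", "bin_vy2", "bin_vz2",
                        "temperature_series")]
  system
}

#' Kinetic temperature of a DPD fluid
#'
#' Equilibrates the fluid, then estimates kBT from the velocity variances
#' about the (binned) mean flow, with a standard error from block
#' averaging of the temperature time series.
#'
#' @param system a \code{dpd_system}.
#' @param params fluid-fluid [dpd_params()] in raw units.
#' @param dt time step in raw units.
#' @param nsteps sampling steps.
#' @param burn equilibration steps.
#' @param nblocks number of blocks for the standard error.
#' @return list with \code{kBT}, \code{se} and the \code{series}.
#' @export
measure_temperature <- function(system, params, dt, nsteps = 4000,
                                burn = 1000, nblocks = 10) {
  system <- fluid_run(system, params, nsteps + burn, dt, burn = burn,
                      sample_every = 10)
  ser <- system$stats$temperature_series
  ser <- tail(ser, floor(nsteps / 10))
  bl <- split(ser, cut(seq_along(ser), nblocks, labels = FALSE))
  bm <- vapply(bl, mean, numeric(1))
  list(kBT = mean(bm), se = sd(bm) / sqrt(length(bm)), series = ser)
}

#' Dynamic shear viscosity of the DPD fluid
#'
#' Measures the viscosity with the periodic-Poiseuille method: opposite
#' body forces \code{+/- f} along x in the two z-halves of a periodic box
#' drive two counter-flowing parabolic profiles; the steady profile
#' \eqn{v_x(z) = (\rho f / 2\eta)\, z(w - z)} (w = half box height) is fit
#' by weighted least squares on the binned velocity, independently in
#' \code{nblocks} sequential blocks to give a standard error.
#'
#' @param params fluid-fluid [dpd_params()] in raw units (or bx units via
#'   \code{raw = FALSE}).
#' @param nd number density (raw units).
#' @param side box side (bx).
#' @param dt time step (raw units).
#' @param fbody body force per particle.
#' @param nsteps total sampling steps (after \code{burn}).
#' @param burn equilibration steps under the body force.
#' @param nblocks number of sampling blocks.
#' @param nbins profile bins.
#' @param seed integer seed.
#' @param method measurement protocol; periodic Poiseuille flow.
#' @param us a [unit_system()].
#' @return list with \code{eta} (raw units), \code{eta_bx}
#'   (sqrt(m kBT)/bx^2), \code{se}, per-block \code{blocks} and the last
#'   fitted \code{profile}.
#' @export
measure_viscosity <- function(params, nd, side = 1, dt, fbody = 0.7,
                              nsteps = 24000, burn = 4000, nblocks = 6,
                              nbins = 30, seed = 1,
                              method = c("periodic-poiseuille",
                                         "reverse-perturbation"),
                              us = unit_system()) {
  method <- match.arg(method)
  if (method == "reverse-perturbation")
    stop("reverse-perturbation measurement is not implemented; ",
         "use method = 'periodic-poiseuille'")
  if (bx_to_raw(side, us) < 4 * params$rc)
    stop("box side must be at least 4 cutoff radii")
  sys <- make_fluid_box(side, nd * us$bx_sim^3, seed, params$kBT, us)
  sys <- fluid_run(sys, params, burn, dt, fbody = fbody, nbins = nbins)
  per_block <- floor(nsteps / nblocks)
  etas <- numeric(nblocks)
  prof <- NULL
  for (b in seq_len(nblocks)) {
    sys <- fluid_run(sys, params, per_block, dt, fbody = fbody,
                     nbins = nbins)
    st <- sys$stats
    L <- sys$box[3]
    zc <- (seq_len(nbins) - 0.5) * L / nbins
    vbar <- st$bin_vx / pmax(st$bin_n, 1)
    w <- L / 2
    basis <- ifelse(zc < w, zc * (w - zc), -(zc - w) * (L - zc))
    wt <- st$bin_n
    C <- sum(wt * basis * vbar) / sum(wt * basis^2)
    etas[b] <- fbody * nd / (2 * C)
    prof <- data.frame(z = zc, vx = vbar, fit = C * basis)
  }
  list(eta = mean(etas), eta_bx = mean(etas) * us$bx_sim^2,
       se = sd(etas) / sqrt(nblocks), blocks = etas, profile = prof)
}
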