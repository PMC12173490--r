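#' Simulation unit system
#'
#' Defines the mapping between simulation units and SI.  The length scale is
#' the body major half-axis \code{bx} (9 in raw simulation units, 1.5 um),
#' the time scale is the bundle rotation period \code{tau} (132 raw units,
#' 6.7 ms, i.e. a bundle frequency of about 150 Hz), the energy scale is the
#' thermal energy \code{kBT} at 20 degrees C, and the particle mass is 1.
#'
#' @param bx_sim length of the body major half-axis in raw simulation units.
#' @param bx_SI the same length in metres.
#' @param tau_sim bundle rotation period in raw simulation units.
#' @param tau_SI the same time in seconds.
#' @param kBT energy scale in simulation units.
#' @param mass particle mass in simulation units.
#' @param temperature_C ambient temperature used to convert \code{kBT} to
#'   joules.
#' @return an object of class \code{unit_system}.
#' @examples
#' us <- unit_system()
#' to_SI(1, "time", us)        # one bundle rotation period in seconds
#' to_SI(300, "torque", us)    # motor torque of 300 kBT in N m
#' @export
unit_system <- function(bx_sim = 9, bx_SI = 1.5e-6, tau_sim = 132,
                        tau_SI = 6.7e-3, kBT = 1, mass = 1,
                        temperature_C = 20) {
  stopifnot(bx_sim > 0, bx_SI > 0, tau_sim > 0, tau_SI > 0, kBT > 0,
            mass > 0)
  structure(list(bx_sim = bx_sim, bx_SI = bx_SI, tau_sim = tau_sim,
                 tau_SI = tau_SI, kBT = kBT, mass = mass,
                 kBT_SI = 1.380649e-23 * (273.15 + temperature_C),
                 temperature_C = temperature_C),
            class = "unit_system")
}

unit_factor_SI <- function(what, us) {
  switch(what,
    length    = us$bx_SI,
    time      = us$tau_SI,
    velocity  = us$bx_SI / us$tau_SI,
    frequency = 1 / us$tau_SI,
    energy    = us$kBT_SI,
    torque    = us$kBT_SI,
    stop("unknown dimension tag: ", what))
}

#' Convert between simulation (bx, tau, kBT) units and SI
#'
#' Quantities are expressed in the scaled simulation units used throughout
#' the package interface: lengths in \code{bx}, times in \code{tau},
#' velocities in \code{bx/tau}, frequencies in \code{1/tau} (Hz after
#' conversion), energies and torques in \code{kBT}.
#'
#' @param x numeric vector of values.
#' @param what dimension tag, one of \code{"length"}, \code{"time"},
#'   \code{"velocity"}, \code{"frequency"}, \code{"energy"},
#'   \code{"torque"}.
#' @param us a [unit_system()].
#' @return numeric vector in SI units (\code{to_SI}) or simulation units
#'   (\code{from_SI}).
#' @export
to_SI <- function(x, what, us = unit_system()) {
  x * unit_factor_SI(what, us)
}

#' @rdname to_SI
#' @export
from_SI <- function(x, what, us = unit_system()) {
  x / unit_factor_SI(what, us)
}

#' Raw simulation-unit conversion helpers
#'
#' Raw units are the units the particle model actually integrates in
#' (\code{bx = 9}, \code{tau = 132}).  These helpers convert scaled
#' (bx/tau/kBT) interface values to raw values and back.
#'
#' @param x numeric values.
#' @param us a [unit_system()].
#' @return numeric values.
#' @keywords internal
bx_to_raw <- function(x, us = unit_system()) x * us$bx_sim
raw_to_bx <- function(x, us = unit_system()) x / us$bx_sim
tau_to_raw <- function(x, us = unit_system()) x * us$tau_sim
raw_to_tau <- function(x, us = unit_system()) x / us$tau_sim

#' Micrometre helpers for flagellum geometry
#'
#' Convert between micrometres and raw simulation length units (with the
#' default unit system, 1 um = 6 raw units).  Convenient for flagellum
#' dimensions, which the literature quotes in micrometres.
#'
#' @param x numeric values in micrometres (\code{um_to_raw}) or raw units
#'   (\code{raw_to_um}).
#' @param us a [unit_system()].
#' @return numeric values.
#' @export
um_to_raw <- function(x, us = unit_system()) x * 1e-6 / us$bx_SI * us$bx_sim

#' @rdname um_to_raw
#' @export
raw_to_um <- function(x, us = unit_system()) x * us$bx_SI / us$bx_sim * 1e6

#' Characteristic Reynolds number of the swimming bacterium
#'
#' Computed as \code{Re = bx * m * nd * v / eta} from raw-unit registry
#' values, with the swimming speed \code{v} and dynamic viscosity
#' \code{eta} taken from the configuration registry.  For the base
#' parameterization this is about 0.01, small enough that inertial effects
#' are negligible.
#'
#' @param config a [default_config()]-style configuration.
#' @param v swimming speed in raw units; default is the registry value
#'   \code{5.22e-3 sqrt(kBT/m)}.
#' @param eta dynamic viscosity in \code{sqrt(m kBT)/bx^2}; default is the
#'   registry value for the base fluid.
#' @return the Reynolds number (dimensionless).
#' @export
reynolds_number <- function(config = default_config(), v = 5.22e-3,
                            eta = 1225.53) {
  us <- config$units
  nd_raw <- config$dpd$nd / us$bx_sim^3
  eta_raw <- eta / us$bx_sim^2
  us$bx_sim * us$mass * nd_raw * v / eta_raw
}
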