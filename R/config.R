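#' Base simulation configuration
#'
#' Returns the validated parameter registry of the base five-flagella model:
#' a sphero-cylinder-like body (shape exponent 8.5, 3:1 aspect), flagella of
#' 76 octahedral segments forming three left-handed helical turns, a motor
#' torque of 300 kBT per flagellum, and the DPD fluid at number density
#' 2.16e3 bx^-3.  All entries are in scaled simulation units: lengths in bx,
#' times in tau, energies in kBT (see [unit_system()]).
#'
#' The full-scale domain (8.33 bx x 11.56 bx x 11.56 bx, about 2.4 million
#' fluid particles) is cluster-scale; reduced desk-scale systems for testing
#' are produced by [mini_config()] and the fixture generators.
#'
#' @return a nested list of class \code{ecoli_config}.
#' @examples
#' cfg <- default_config()
#' cfg$motor$torque       # 300 kBT
#' cfg$domain             # c(8.33, 11.56, 11.56) bx
#' @export
default_config <- function() {
  ell_um <- flagellum_spacing_um()
  cfg <- list(
    units = unit_system(),
    body = list(
      nu = 8.5, bx = 1, by = 1 / 3, bz = 1 / 3,
      n_vertices = 1278,
      mu0 = 8.1e4,      # shear modulus, kBT/bx^2
      kappa = 100,      # bending modulus, kBT
      ka = 4.05e4,      # global area constraint, kBT/bx^2
      kd = 8.1e4,       # local area constraint, kBT/bx^2
      kv = 3.65e5,      # volume constraint, kBT/bx^3
      x0 = 0.45         # spring extensibility
    ),
    flagella = list(
      n_flag = 5L,
      Ns = 76L,
      Omega_e = c(0.122, -0.027, -0.217),  # left-handed helix, rad/segment
      Kel = c(3e4, 3e4, 1e4),              # bend, bend, twist; kBT
      ell_um = ell_um,                     # backbone spacing, um
      helix = list(radius_um = 0.23, pitch_um = 2.56, turns = 3),
      spring_k = 2e3,                      # octahedron springs, kBT/len^2 raw
      ln_straight = 0L,                    # straight initial segments
      arrangement = "symmetric",
      arrangement_seed = 1L
    ),
    hook = list(k_run = 100, k_reverted = 500, stiffening = TRUE),
    motor = list(torque = 300),
    lj = list(eps = 1, sigma = 0.07),      # sigma in bx
    dpd = list(
      fluid = list(a = 540, gamma = 225, s = 0.15, rc = 0.11),
      coupling = list(a = 0, gamma = 360, s = 0.1, rc = 0.09),
      nd = 2.16e3,                         # number density, bx^-3
      kBT = 1
    ),
    domain = c(8.33, 11.56, 11.56),        # bx
    dt = 2.27e-5,                          # tau
    schedule = list(
      bundling = 10, run = 18.9, tumble = 12.6, cycles = 3L,
      reverted = 1L, polymorphic = TRUE, ramp = 0.76, stiffening = TRUE
    ),
    seed = 1L,
    cluster_scale = TRUE
  )
  class(cfg) <- "ecoli_config"
  validate_config(cfg)
  cfg
}

#' Backbone spacing of the flagellum model
#'
#' The backbone spacing is fixed by requiring that 76 segments trace the
#' three helical turns of the equilibrium flagellum (radius 0.23 um, pitch
#' 2.56 um), i.e. the contour length of three turns divided by the number
#' of segments.  The octahedron diagonal rest length equals the spacing and
#' the edge rest length is diagonal/sqrt(2) (regular octahedron).
#'
#' @param radius_um helix radius in micrometres.
#' @param pitch_um helix pitch in micrometres.
#' @param turns number of helical turns.
#' @param Ns number of segments.
#' @return backbone spacing in micrometres.
#' @export
flagellum_spacing_um <- function(radius_um = 0.23, pitch_um = 2.56,
                                 turns = 3, Ns = 76) {
  turns * sqrt((2 * pi * radius_um)^2 + pitch_um^2) / Ns
}

#' Validate a configuration
#'
#' Checks the registry invariants: extensibility in (0,1), at least two
#' flagellum segments, positive cutoffs and time step, and reverted-flagella
#' indices within 1..n_flag.
#'
#' @param cfg an \code{ecoli_config}.
#' @return the configuration, invisibly; errors on violation.
#' @export
validate_config <- function(cfg) {
  stopifnot(
    cfg$body$x0 > 0, cfg$body$x0 < 1,
    cfg$body$nu >= 2, cfg$body$bx >= cfg$body$by, cfg$body$by > 0,
    cfg$body$by == cfg$body$bz,
    cfg$flagella$Ns >= 2,
    cfg$dpd$fluid$rc > 0, cfg$dpd$coupling$rc > 0,
    cfg$dt > 0,
    all(cfg$schedule$reverted >= 1),
    all(cfg$schedule$reverted <= cfg$flagella$n_flag),
    all(cfg$domain > 0)
  )
  if (cfg$flagella$Kel[1] != cfg$flagella$Kel[2])
    stop("bending coefficients Kel1 and Kel2 must be equal")
  invisible(cfg)
}

#' Convert a configuration to raw simulation units
#'
#' Scaled interface units (bx, tau) map to the raw units the integrator
#' uses via bx = 9 and tau = 132.  Angular elastic coefficients (Kel,
#' Khook, torque) are energies per squared radian and are unchanged.
#'
#' @param cfg an \code{ecoli_config}.
#' @return a list of raw-unit parameters.
#' @export
config_raw <- function(cfg) {
  us <- cfg$units
  L <- us$bx_sim
  ell_raw <- um_to_raw(cfg$flagella$ell_um, us)
  list(
    body = list(
      nu = cfg$body$nu,
      bx = cfg$body$bx * L, by = cfg$body$by * L, bz = cfg$body$bz * L,
      n_vertices = cfg$body$n_vertices,
      mu0 = cfg$body$mu0 / L^2, kappa = cfg$body$kappa,
      ka = cfg$body$ka / L^2, kd = cfg$body$kd / L^2, kv = cfg$body$kv / L^3,
      x0 = cfg$body$x0
    ),
    flagella = list(
      n_flag = cfg$flagella$n_flag, Ns = cfg$flagella$Ns,
      Omega_e = cfg$flagella$Omega_e, Kel = cfg$flagella$Kel,
      ell = ell_raw, rd = ell_raw, re = ell_raw / sqrt(2),
      spring_k = cfg$flagella$spring_k,
      ln_straight = cfg$flagella$ln_straight,
      arrangement = cfg$flagella$arrangement,
      arrangement_seed = cfg$flagella$arrangement_seed
    ),
    hook = cfg$hook,
    motor = cfg$motor,
    lj = list(eps = cfg$lj$eps, sigma = cfg$lj$sigma * L),
    dpd = list(
      fluid = list(a = cfg$dpd$fluid$a / L, gamma = cfg$dpd$fluid$gamma / L,
                   s = cfg$dpd$fluid$s, rc = cfg$dpd$fluid$rc * L),
      coupling = list(a = cfg$dpd$coupling$a / L,
                      gamma = cfg$dpd$coupling$gamma / L,
                      s = cfg$dpd$coupling$s, rc = cfg$dpd$coupling$rc * L),
      nd = cfg$dpd$nd / L^3, kBT = cfg$dpd$kBT
    ),
    domain = cfg$domain * L,
    dt = tau_to_raw(cfg$dt, us),
    schedule = within_schedule_raw(cfg$schedule, us),
    seed = cfg$seed
  )
}

within_schedule_raw <- function(sch, us) {
  out <- sch
  for (f in c("bundling", "run", "tumble", "ramp"))
    out[[f]] <- tau_to_raw(sch[[f]], us)
  out
}

#' Reduced desk-scale configuration
#'
#' A geometrically similar, reduced system for single-CPU testing: a coarser
#' body mesh, shortened flagella, a (3 bx)^3 periodic box and an eight-fold
#' reduced fluid density.  Structural invariants of the full model (particle
#' counts per segment, triads, closed mesh) are preserved.
#'
#' @param n_flag number of flagella.
#' @param Ns segments per flagellum.
#' @param n_vertices body mesh vertex target.
#' @param box_bx cubic box side in bx.
#' @param nd_scale factor applied to the fluid number density.
#' @return an \code{ecoli_config}.
#' @export
mini_config <- function(n_flag = 1L, Ns = 20L, n_vertices = 162L,
                        box_bx = 3, nd_scale = 1 / 8) {
  cfg <- default_config()
  cfg$flagella$n_flag <- as.integer(n_flag)
  cfg$flagella$Ns <- as.integer(Ns)
  cfg$body$n_vertices <- as.integer(n_vertices)
  cfg$domain <- rep(box_bx, 3)
  cfg$dpd$nd <- cfg$dpd$nd * nd_scale
  # at reduced fluid density the dissipative damping of the driven
  # flagellum is weaker; a smaller step keeps the stiff octahedron
  # springs stable under the full motor torque
  cfg$dt <- cfg$dt / 4
  cfg$schedule$reverted <- 1L
  cfg$cluster_scale <- FALSE
  validate_config(cfg)
  cfg
}

#' Read / write configurations as YAML
#'
#' Configuration files use keys named after the model parameters; reading
#' merges the file over [default_config()] so partial files are valid.
#'
#' @param path file path.
#' @param cfg an \code{ecoli_config}.
#' @return \code{read_config} returns an \code{ecoli_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  cfg <- modify_list_deep(cfg, raw)
  class(cfg) <- "ecoli_config"
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  out <- cfg
  out$units <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
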