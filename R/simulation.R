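#' Assemble a swimmer in a DPD fluid
#'
#' Builds the body mesh, attaches the flagella in the requested arrangement
#' (symmetric: one polar flagellum plus the rest equally spaced on a
#' circumference near the rear pole; or seeded random placements over the
#' rear half or the whole body), and fills the periodic domain with fluid
#' particles at the configured number density, excluding the body interior.
#' Flagella are built in their relaxed helical shapes pointing rearward.
#'
#' @param config an \code{ecoli_config}.
#' @return an object of class \code{ecoli_sim} holding the global particle
#'   arrays, the component models and the phase state.
#' @export
assemble <- function(config) {
  validate_config(config)
  raw <- config_raw(config)
  shape <- body_shape(raw$body$nu, raw$body$bx, raw$body$by, raw$body$bz)
  mesh <- triangulate_body(shape, raw$body$n_vertices)
  center <- raw$domain / 2
  mesh$vertices <- sweep(mesh$vertices, 2, center, "+")
  mparams <- membrane_params(mesh, raw$body$mu0, raw$body$kappa,
                             raw$body$ka, raw$body$kd, raw$body$kv,
                             raw$body$x0)
  nflag <- raw$flagella$n_flag
  anchors_idx <- place_anchors(mesh, center, raw)
  # flagella chains; rear is +x
  chains <- list()
  anchors <- list()
  for (f in seq_len(nflag)) {
    v <- anchors_idx[f]
    nrm <- mesh$normals0[v, ]
    d <- 0.45 * nrm + c(1, 0, 0)
    d <- d / sqrt(sum(d^2))
    e1 <- pracma_cross(d, if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    e1 <- e1 / sqrt(sum(e1^2))
    frame <- cbind(e1, pracma_cross(d, e1), d)
    colnames(frame) <- NULL
    chains[[f]] <- build_flagellum(raw$flagella$Ns, raw$flagella$Omega_e,
                                   raw$flagella$ell,
                                   base = mesh$vertices[v, ], frame = frame,
                                   ln_straight = raw$flagella$ln_straight)
    anchors[[f]] <- make_anchor(mesh, v)
  }
  # fluid fill excluding the body interior
  nf <- round(raw$dpd$nd * prod(raw$domain))
  with_seed(raw$seed, {
    fpos <- matrix(runif(3 * nf), nf, 3) %*% diag(raw$domain)
    inside <- shape_implicit(shape, sweep(fpos, 2, center)) < 1
    while (any(inside)) {
      fpos[inside, ] <- matrix(runif(3 * sum(inside)), sum(inside), 3) %*%
        diag(raw$domain)
      inside <- shape_implicit(shape, sweep(fpos, 2, center)) < 1
    }
    fvel <- matrix(rnorm(3 * nf, 0, sqrt(raw$dpd$kBT)), nf, 3)
  })
  fvel <- sweep(fvel, 2, colMeans(fvel))
  nv <- nrow(mesh$vertices)
  body_rows <- nf + seq_len(nv)
  np_chain <- flagellum_particle_count(raw$flagella$Ns)
  flag_idx <- list()
  extra <- list()
  nxt <- nf + nv
  for (f in seq_len(nflag)) {
    idx <- c(body_rows[anchors_idx[f]], nxt + seq_len(np_chain - 1L))
    flag_idx[[f]] <- idx
    extra[[f]] <- chains[[f]]$pos[-1, , drop = FALSE]
    nxt <- nxt + np_chain - 1L
  }
  pos <- rbind(fpos, mesh$vertices, do.call(rbind, extra))
  vel <- matrix(0, nrow(pos), 3)
  vel[seq_len(nf), ] <- fvel
  type <- c(rep(0L, nf), rep(1L, nrow(pos) - nf))
  # LJ labels over swimmer rows
  sw_rows <- (nf + 1L):nrow(pos)
  isbody <- c(rep(1L, nv), rep(0L, nrow(pos) - nf - nv))
  fid <- integer(length(sw_rows))
  for (f in seq_len(nflag)) {
    fid[anchors_idx[f]] <- f
    fid[flag_idx[[f]][-1] - nf] <- f
  }
  # DPD pair table rows: fluid-fluid, fluid-swimmer, swimmer-swimmer (off)
  pf <- raw$dpd$fluid
  pc <- raw$dpd$coupling
  pars <- rbind(
    c(pf$a, pf$gamma, sqrt(2 * pf$gamma * raw$dpd$kBT), pf$s, pf$rc),
    c(pc$a, pc$gamma, sqrt(2 * pc$gamma * raw$dpd$kBT), pc$s, pc$rc),
    c(0, 0, 0, 0, -1))
  sim <- list(pos = pos, vel = vel, box = raw$domain, type = type, nf = nf,
              mesh = mesh, mparams = mparams, chains = chains,
              anchors = anchors, anchors_idx = anchors_idx,
              flag_idx = flag_idx, body_rows = body_rows,
              sw_rows = sw_rows, isbody = isbody, fid = fid,
              elasticity = rod_elasticity(raw$flagella$Kel[1],
                                          raw$flagella$Kel[2],
                                          raw$flagella$Kel[3],
                                          raw$flagella$spring_k),
              lj = raw$lj, dpd_pars = pars, dt = raw$dt,
              motor_sense = rep(1, nflag),
              hook_k = rep(raw$hook$k_run, nflag),
              phase = rep("bundling-run", nflag),
              time = 0, step = 0, raw = raw, config = config,
              forces = NULL)
  class(sim) <- "ecoli_sim"
  # build-time sanity: flagella must not interpenetrate the body
  lj0 <- lj_energy_forces(pos[sw_rows, , drop = FALSE], isbody, fid,
                          raw$lj$eps, raw$lj$sigma)
  if (!is.finite(lj0$energy))
    stop("flagella-body overlap that excluded volume cannot resolve")
  sim
}

place_anchors <- function(mesh, center, raw) {
  v <- sweep(mesh$vertices, 2, center)
  nflag <- raw$flagella$n_flag
  mode <- raw$flagella$arrangement
  if (mode == "symmetric") {
    polar <- which.max(v[, 1])
    if (nflag == 1L) return(polar)
    # circumference where the cross-section reaches 95% of its maximum
    xr <- raw$body$bx * (1 - 0.95^2)^(1 / raw$body$nu)
    rr <- 0.95 * raw$body$by
    ang <- seq(0, 2 * pi, length.out = nflag)[-nflag]
    idx <- polar
    for (a in ang) {
      tgt <- c(xr, rr * cos(a), rr * sin(a))
      ord <- order(colSums((t(v) - tgt)^2))
      cand <- ord[!(ord %in% idx)][1]
      idx <- c(idx, cand)
    }
    return(idx)
  }
  pool <- if (mode == "random-rear-half") which(v[, 1] > 0) else
    seq_len(nrow(v))
  if (mode != "random-rear-half" && mode != "random-whole-body")
    stop("unknown arrangement mode: ", mode)
  with_seed(raw$flagella$arrangement_seed, sample(pool, nflag))
}

#' Internal forces of the swimmer
#'
#' Sum of the membrane (bond, bending, constraint), rod elastic, hook,
#' motor + counter-torque and excluded-volume forces, scattered into the
#' global particle array.  These are the swimmer's own actuation and
#' elasticity; they sum to zero net force and zero net torque.
#'
#' @param sim an \code{ecoli_sim}.
#' @param pos optional global positions overriding \code{sim$pos}.
#' @return list with \code{forces} (global) and \code{energy}.
#' @export
swimmer_forces <- function(sim, pos = sim$pos) {
  F <- matrix(0, nrow(pos), 3)
  en <- 0
  bp <- pos[sim$body_rows, , drop = FALSE]
  mem <- membrane_energy_forces(sim$mesh, bp, sim$mparams)
  F[sim$body_rows, ] <- F[sim$body_rows, ] + mem$forces
  en <- en + mem$energy
  for (f in seq_along(sim$chains)) {
    idx <- sim$flag_idx[[f]]
    lpos <- pos[idx, , drop = FALSE]
    rod <- rod_energy_forces(sim$chains[[f]], sim$elasticity, lpos)
    F[idx, ] <- F[idx, ] + rod$forces
    en <- en + rod$energy
    ring_rows <- sim$body_rows[sim$anchors[[f]]$ring]
    if (sim$hook_k[f] > 0) {
      hk <- hook_energy_forces(pos[idx[1], ], pos[ring_rows, , drop = FALSE],
                               lpos[2, ], sim$hook_k[f])
      F[idx[1], ] <- F[idx[1], ] + hk$f_anchor
      F[ring_rows, ] <- F[ring_rows, ] + hk$f_ring
      F[idx[2], ] <- F[idx[2], ] + hk$f_first
      en <- en + hk$energy
    }
    Ns <- sim$chains[[f]]$Ns
    aux1 <- idx[aux_rows(Ns, 1L, 1:4)]
    axis <- lpos[2, ] - lpos[1, ]
    mf <- motor_forces(pos[aux1, , drop = FALSE],
                       pos[ring_rows, , drop = FALSE],
                       axis, sim$raw$motor$torque, sim$motor_sense[f])
    F[aux1, ] <- F[aux1, ] + mf$f_aux
    F[ring_rows, ] <- F[ring_rows, ] + mf$f_ring
  }
  lj <- lj_energy_forces(pos[sim$sw_rows, , drop = FALSE], sim$isbody,
                         sim$fid, sim$lj$eps, sim$lj$sigma)
  F[sim$sw_rows, ] <- F[sim$sw_rows, ] + lj$forces
  en <- en + lj$energy
  list(forces = F, energy = en)
}

#' Net force and torque of the swimmer's internal forces
#'
#' Diagnostic for the force-free and torque-free actuation: sums the
#' internal forces and their torques about the origin.  Both should vanish
#' to numerical precision.
#'
#' @param sim an \code{ecoli_sim}.
#' @return list with \code{force} and \code{torque} (length-3 vectors).
#' @export
net_force_torque <- function(sim) {
  F <- swimmer_forces(sim)$forces
  tq <- colSums(cbind(
    sim$pos[, 2] * F[, 3] - sim$pos[, 3] * F[, 2],
    sim$pos[, 3] * F[, 1] - sim$pos[, 1] * F[, 3],
    sim$pos[, 1] * F[, 2] - sim$pos[, 2] * F[, 1]))
  list(force = colSums(F), torque = tq)
}

total_forces <- function(sim, pos, vel, step) {
  dpd <- cpp_dpd_forces(pos, vel, sim$type, sim$box, sim$dpd_pars, sim$dt,
                        step, sim$raw$seed)
  dpd + swimmer_forces(sim, pos)$forces
}

#' Advance the full system one velocity-Verlet step
#'
#' Half kick, drift, force recomputation with half-step velocities
#' (so the dissipative force uses updated positions and velocities),
#' half kick.  All pair forces are antisymmetric, so total momentum is
#' conserved to machine precision.
#'
#' @param sim an \code{ecoli_sim}.
#' @return the advanced simulation object.
#' @export
simulation_step <- function(sim) {
  if (is.null(sim$forces))
    sim$forces <- total_forces(sim, sim$pos, sim$vel, sim$step)
  h <- 0.5 * sim$dt
  sim$vel <- sim$vel + h * sim$forces
  sim$pos <- sim$pos + sim$dt * sim$vel
  if (any(abs(sim$vel) > 1e3) || any(!is.finite(sim$vel)))
    stop("integrator instability: velocity overflow at step ", sim$step)
  sim$forces <- total_forces(sim, sim$pos, sim$vel, sim$step + 1)
  sim$vel <- sim$vel + h * sim$forces
  sim$step <- sim$step + 1L
  sim$time <- sim$time + sim$dt
  sim
}

#' Mean pairwise distance between flagellar mid-backbone particles
#'
#' The bundling metric: the bundle is considered tight when this distance
#' stays below \code{2 sigma_LJ + rd} for most of a sampling window.
#'
#' @param sim an \code{ecoli_sim}.
#' @return mean pairwise distance (raw units), or \code{NA} for fewer than
#'   two flagella.
#' @export
bundle_distance <- function(sim) {
  nfl <- length(sim$chains)
  if (nfl < 2) return(NA_real_)
  mids <- t(vapply(seq_len(nfl), function(f) {
    Ns <- sim$chains[[f]]$Ns
    sim$pos[sim$flag_idx[[f]][floor(Ns / 2) + 1L], ]
  }, numeric(3)))
  mean(dist(mids))
}

#' Execute a run/tumble schedule
#'
#' Alternates run and tumble phases after an initial bundling period.  At
#' each tumble start the pre-selected reverted flagella flip their motor
#' sense to clockwise, begin the polymorphic ramp towards the right-handed
#' state (if enabled) and stiffen their hooks (if enabled); at tumble end
#' all three revert.  The phase log records every event.
#'
#' @param sim an assembled \code{ecoli_sim}.
#' @param duration total simulated time in raw units (defaults to the full
#'   configured schedule).
#' @param out_every snapshot interval in steps.
#' @return list with the advanced \code{sim}, an observable \code{series}
#'   data frame and the \code{log} of phase events.
#' @export
run_schedule <- function(sim, duration = NULL, out_every = 50L) {
  sch <- sim$raw$schedule
  if (is.null(duration))
    duration <- sch$bundling + sch$cycles * (sch$run + sch$tumble)
  events <- schedule_events(sch)
  events <- events[events$time <= duration + 1e-12, , drop = FALSE]
  nsteps <- ceiling(duration / sim$dt)
  log <- data.frame(event = character(0), time = numeric(0),
                    flagella = character(0))
  ramps <- vector("list", length(sim$chains))
  obs <- list()
  prev <- NULL
  ev <- 1L
  for (s in seq_len(nsteps + 1L)) {
    # the extra iteration flushes events scheduled at the final time
    while (ev <= nrow(events) && events$time[ev] <= sim$time + 1e-12) {
      e <- events[ev, ]
      rev_idx <- sim$raw$schedule$reverted
      if (e$event == "tumble-start") {
        for (f in rev_idx) {
          sim$motor_sense[f] <- -1
          sim$phase[f] <- "reverted-tumble"
          sim$hook_k[f] <- hook_stiffness("tumble-reverted",
                                          sim$raw$hook$k_run,
                                          sim$raw$hook$k_reverted,
                                          sim$raw$schedule$stiffening)
          if (sim$raw$schedule$polymorphic)
            ramps[[f]] <- polymorphic_schedule(sim$raw$schedule$ramp,
                                               "to-right", sim$time)
        }
      } else if (e$event == "tumble-end") {
        for (f in rev_idx) {
          sim$motor_sense[f] <- 1
          sim$phase[f] <- "bundling-run"
          sim$hook_k[f] <- hook_stiffness("run", sim$raw$hook$k_run,
                                          sim$raw$hook$k_reverted,
                                          sim$raw$schedule$stiffening)
          if (sim$raw$schedule$polymorphic)
            ramps[[f]] <- polymorphic_schedule(sim$raw$schedule$ramp,
                                               "to-left", sim$time)
        }
      }
      log <- rbind(log, data.frame(event = e$event, time = sim$time,
                                   flagella = paste(rev_idx,
                                                    collapse = ",")))
      ev <- ev + 1L
    }
    if (s > nsteps) break
    for (f in seq_along(ramps)) {
      if (!is.null(ramps[[f]])) {
        sim$chains[[f]] <- polymorphic_step(sim$chains[[f]], ramps[[f]],
                                            sim$time)
        if (sim$time >= ramps[[f]]$start + ramps[[f]]$ramp)
          ramps[f] <- list(NULL)
      }
    }
    sim <- simulation_step(sim)
    if (s %% out_every == 0L || s == nsteps) {
      row <- observable_row(sim, prev)
      prev <- row
      obs[[length(obs) + 1L]] <- row$df
    }
  }
  list(sim = sim, series = do.call(rbind, obs), log = log)
}

schedule_events <- function(sch) {
  times <- c()
  events <- c()
  for (k in seq_len(sch$cycles)) {
    t0 <- sch$bundling + (k - 1) * (sch$run + sch$tumble) + sch$run
    times <- c(times, t0, t0 + sch$tumble)
    events <- c(events, "tumble-start", "tumble-end")
  }
  data.frame(event = events, time = times)
}

# one observable snapshot with sign/phase continuity relative to `prev`
observable_row <- function(sim, prev = NULL) {
  bp <- sim$pos[sim$body_rows, , drop = FALSE]
  com <- colMeans(bp)
  X <- sweep(bp, 2, com)
  ba <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)$vectors[, 1]
  ref_ba <- if (is.null(prev)) c(1, 0, 0) else
    c(prev$df$bax, prev$df$bay, prev$df$baz)
  if (sum(ba * ref_ba) < 0) ba <- -ba
  # bundle axis from pooled backbone particles of anti-clockwise flagella
  run_f <- which(sim$motor_sense > 0)
  if (length(run_f) == 0) run_f <- seq_along(sim$chains)
  bb <- do.call(rbind, lapply(run_f, function(f) {
    sim$pos[sim$flag_idx[[f]][seq_len(sim$chains[[f]]$Ns + 1L)], ,
            drop = FALSE]
  }))
  Y <- sweep(bb, 2, colMeans(bb))
  ua <- eigen(crossprod(Y) / nrow(Y), symmetric = TRUE)$vectors[, 1]
  ref_ua <- if (is.null(prev)) ba else c(prev$df$uax, prev$df$uay, prev$df$uaz)
  if (sum(ua * ref_ua) < 0) ua <- -ua
  # rotation markers: a body vertex about the body axis, a mid-backbone
  # auxiliary pair about the bundle axis
  mb <- bp[1, ] - com
  Ns <- sim$chains[[1]]$Ns
  i1 <- sim$flag_idx[[1]][aux_rows(Ns, floor(Ns / 2) + 1L, 1L)]
  i3 <- sim$flag_idx[[1]][aux_rows(Ns, floor(Ns / 2) + 1L, 3L)]
  mu <- sim$pos[i1, ] - sim$pos[i3, ]
  phi_body <- advance_phase(prev, "body", mb, ba)
  phi_bundle <- advance_phase(prev, "bundle", mu, ua)
  df <- data.frame(t = sim$time, x = com[1], y = com[2], z = com[3],
                   bax = ba[1], bay = ba[2], baz = ba[3],
                   uax = ua[1], uay = ua[2], uaz = ua[3],
                   phi_body = phi_body, phi_bundle = phi_bundle,
                   bundle_d = bundle_distance(sim))
  list(df = df, mb = mb, mu = mu)
}

advance_phase <- function(prev, which, marker, axis) {
  m <- marker - sum(marker * axis) * axis
  if (is.null(prev)) return(0)
  p <- if (which == "body") prev$mb else prev$mu
  p <- p - sum(p * axis) * axis
  dphi <- atan2(sum(axis * pracma_cross(p, m)), sum(p * m))
  prev$df[[paste0("phi_", which)]] + dphi
}
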