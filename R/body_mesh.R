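#' Superellipsoidal body shape
#'
#' The cell body surface is the superellipsoid
#' \deqn{(|x|/b_x)^\nu + (y/b_y)^2 + (z/b_z)^2 = 1,}
#' a sphero-cylinder-like shape for \eqn{\nu = 8.5} and a spheroid for
#' \eqn{\nu = 2}.  Axes may be given in any length unit; the mesh inherits
#' it.
#'
#' @param nu shape exponent, >= 2.
#' @param bx major half-axis.
#' @param by,bz minor half-axes (equal; surface of revolution).
#' @return an object of class \code{body_shape}.
#' @export
body_shape <- function(nu = 8.5, bx = 1, by = 1 / 3, bz = by) {
  if (by <= 0) stop("degenerate shape: by must be positive")
  stopifnot(nu >= 2, bx >= by, by == bz)
  structure(list(nu = nu, bx = bx, by = by, bz = bz), class = "body_shape")
}

shape_implicit <- function(shape, p) {
  (abs(p[, 1]) / shape$bx)^shape$nu + (p[, 2] / shape$by)^2 +
    (p[, 3] / shape$bz)^2
}

# project points radially (through the origin) onto the implicit surface
shape_project <- function(shape, p) {
  t <- rep(1, nrow(p))
  for (it in 1:100) {
    q <- p * t
    f <- shape_implicit(shape, q) - 1
    if (all(abs(f) < 1e-14)) break
    # df/dt
    df <- shape$nu * (abs(q[, 1]) / shape$bx)^shape$nu / t +
      2 * ((q[, 2] / shape$by)^2 + (q[, 3] / shape$bz)^2) / t
    df[df < 1e-30] <- 1e-30
    t <- t - f / df
  }
  p * t
}

#' Continuum surface area and volume of the body shape
#'
#' The enclosed volume has the closed form
#' \eqn{V = 2\pi b_y b_z b_x \nu/(\nu+1)}; the area is computed as a
#' surface of revolution by adaptive quadrature with the end-point
#' singularity removed by substitution, to a relative accuracy better than
#' 1e-6.
#'
#' @param shape a [body_shape()].
#' @return a list with elements \code{area} and \code{volume}.
#' @examples
#' shape_area_volume(body_shape(2, 1, 1, 1))          # sphere: 4 pi, 4 pi/3
#' shape_area_volume(body_shape(8.5, 1, 1/3))         # about (4.21, 0.62)
#' @export
shape_area_volume <- function(shape) {
  nu <- shape$nu; bx <- shape$bx; by <- shape$by
  volume <- 2 * pi * by * shape$bz * bx * nu / (nu + 1)
  # rho(u) = by sqrt(1 - u^nu), x = bx u, u = 1 - w^2
  f <- function(w) {
    u <- 1 - w^2
    s <- pmax(1 - u^nu, 0)
    rho <- by * sqrt(s)
    drdx <- ifelse(s > 0, -(by / bx) * nu * u^(nu - 1) / (2 * sqrt(s)), 0)
    2 * pi * rho * sqrt(1 + drdx^2) * bx * 2 * w
  }
  area <- 2 * integrate(f, 0, 1, rel.tol = 1e-10,
                        subdivisions = 2000L)$value
  list(area = area, volume = volume)
}

# ---- icosphere construction --------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(v, f) {
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  mid <- new.env()
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  getmid <- function(i, j) {
    k <- key(i, j)
    idx <- mid[[k]]
    if (is.null(idx)) {
      verts[[length(verts) + 1]] <<- (v[i, ] + v[j, ]) / 2
      idx <- length(verts)
      mid[[k]] <- idx
    }
    idx
  }
  nf <- matrix(0L, nrow(f) * 4, 3)
  r <- 1L
  for (t in seq_len(nrow(f))) {
    a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
    ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
    nf[r, ] <- c(a, ab, ca); nf[r + 1L, ] <- c(b, bc, ab)
    nf[r + 2L, ] <- c(c, ca, bc); nf[r + 3L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(vertices = do.call(rbind, verts), faces = nf)
}

mesh_edges <- function(faces) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# ordered one-ring (cyclic, consistent with outward face orientation)
mesh_rings <- function(nv, faces) {
  inc <- vector("list", nv)
  for (t in seq_len(nrow(faces))) {
    for (k in 1:3) inc[[faces[t, k]]] <- c(inc[[faces[t, k]]], t)
  }
  rings <- vector("list", nv)
  for (i in seq_len(nv)) {
    nxt <- integer(0)
    frm <- integer(0)
    for (t in inc[[i]]) {
      tri <- faces[t, ]
      k <- which(tri == i)
      a <- tri[(k %% 3) + 1]
      b <- tri[((k + 1) %% 3) + 1]
      frm <- c(frm, a)
      nxt <- c(nxt, b)
    }
    ring <- integer(length(frm))
    cur <- frm[1]
    for (k in seq_along(frm)) {
      ring[k] <- cur
      cur <- nxt[match(cur, frm)]
    }
    rings[[i]] <- ring
  }
  rings
}

#' Triangulate the body surface
#'
#' Subdivides an icosahedron (choosing the smallest subdivision level with
#' at least \code{target_vertices} vertices), projects vertices onto the
#' implicit surface, and applies tangential Lloyd-style relaxation to
#' near-uniform edge lengths.  All rest-state quantities of the membrane
#' model (edge rest lengths, face areas, dual-lattice vertex areas, unit
#' normals, spontaneous curvatures) are precomputed from the relaxed
#' geometry, so the constructed shape is the energy minimum.
#'
#' Relaxation runs in two phases: weighted Laplacian smoothing (stable,
#' removes the projection distortion) followed by edge-length equalization
#' restricted to fold-free moves, which brings the max/min edge ratio
#' below 3 even for the elongated sphero-cylinder-like shape.
#'
#' @param shape a [body_shape()].
#' @param target_vertices requested vertex count (>= 12); the actual count
#'   is the nearest admissible icosphere count above it.
#' @param smooth_iter,equalize_iter relaxation sweeps of the two phases.
#' @return an object of class \code{tri_mesh} with fields \code{vertices},
#'   \code{faces}, \code{edges}, \code{rings}, \code{l0}, \code{Am0},
#'   \code{A0}, \code{V0}, \code{H0}, \code{sigma0}, \code{normals0}.
#' @export
triangulate_body <- function(shape, target_vertices = 642,
                             smooth_iter = 150, equalize_iter = 800) {
  if (target_vertices < 12) stop("target_vertex_count must be >= 12")
  ico <- icosahedron()
  while (nrow(ico$vertices) < target_vertices)
    ico <- subdivide_mesh(ico$vertices, ico$faces)
  v <- shape_project(shape, ico$vertices *
                       max(shape$bx, shape$by, shape$bz))
  faces <- ico$faces
  edges <- mesh_edges(faces)
  rings <- mesh_rings(nrow(v), faces)
  ii <- c(edges[, 1], edges[, 2])
  jj <- c(edges[, 2], edges[, 1])
  mesh_quality <- function(v) {
    # returns min(signed orientation indicator, scaled min triangle height):
    # positive and O(1) for a well-formed outward-oriented mesh
    a <- v[faces[, 1], ]; b <- v[faces[, 2], ]; c <- v[faces[, 3], ]
    cr <- cbind((b[, 2] - a[, 2]) * (c[, 3] - a[, 3]) -
                  (b[, 3] - a[, 3]) * (c[, 2] - a[, 2]),
                (b[, 3] - a[, 3]) * (c[, 1] - a[, 1]) -
                  (b[, 1] - a[, 1]) * (c[, 3] - a[, 3]),
                (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
                  (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]))
    if (any(rowSums(cr * ((a + b + c) / 3)) <= 0)) return(-1)
    A2 <- sqrt(rowSums(cr^2))  # 2 x triangle area
    lmax2 <- pmax(rowSums((b - a)^2), rowSums((c - b)^2),
                  rowSums((a - c)^2))
    min(A2 / lmax2)  # ~ sin of the smallest-ish angle
  }
  for (it in seq_len(smooth_iter)) {
    d <- v[jj, ] - v[ii, ]
    w <- rowSums(d^2)
    v <- shape_project(shape, v + 0.4 * rowsum(d * w, ii) /
                         as.vector(rowsum(w, ii)))
  }
  step <- 0.15
  qmin <- 0.5 * mesh_quality(v)
  for (it in seq_len(equalize_iter)) {
    d <- v[jj, ] - v[ii, ]
    l <- sqrt(rowSums(d^2))
    f <- rowsum(d * (l - mean(l)) / l, ii)
    w <- l^2
    f <- f + 0.3 * rowsum(d * w, ii) / as.vector(rowsum(w, ii))
    cand <- shape_project(shape, v + step * f)
    if (mesh_quality(cand) > qmin) v <- cand else step <- step / 2
    if (step < 1e-4) break
  }
  geo <- cpp_mesh_geometry(v, rings)
  l0 <- sqrt(rowSums((v[edges[, 1], ] - v[edges[, 2], ])^2))
  av <- mesh_area_volume_points(v, faces)
  mesh <- list(vertices = v, faces = faces, edges = edges, rings = rings,
               l0 = l0, Am0 = av$Am, A0 = av$area, V0 = av$volume,
               H0 = geo$H, sigma0 = geo$sigma, normals0 = geo$normal,
               shape = shape)
  class(mesh) <- "tri_mesh"
  mesh
}

# areas/volume of a closed oriented triangle soup
mesh_area_volume_points <- function(v, faces) {
  a <- v[faces[, 1], , drop = FALSE]
  b <- v[faces[, 2], , drop = FALSE]
  c <- v[faces[, 3], , drop = FALSE]
  cr <- cbind((b[, 2] - a[, 2]) * (c[, 3] - a[, 3]) -
                (b[, 3] - a[, 3]) * (c[, 2] - a[, 2]),
              (b[, 3] - a[, 3]) * (c[, 1] - a[, 1]) -
                (b[, 1] - a[, 1]) * (c[, 3] - a[, 3]),
              (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
                (b[, 2] - a[, 2]) * (c[, 1] - a[, 1]))
  Am <- sqrt(rowSums(cr^2)) / 2
  vol <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
               a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
               a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  list(Am = Am, area = sum(Am), volume = vol)
}

#' Mesh area and enclosed volume
#' @param mesh a \code{tri_mesh}.
#' @param positions vertex positions (defaults to the rest positions).
#' @return list with \code{area}, \code{volume}, per-face \code{Am}.
#' @export
mesh_area_volume <- function(mesh, positions = mesh$vertices) {
  mesh_area_volume_points(positions, mesh$faces)
}

#' Per-vertex discrete geometry
#'
#' Dual-lattice vertex areas, outward unit normals and discrete mean
#' curvatures \eqn{H_i = n_i \cdot \sum_j \sigma_{ij} r_{ij} /
#' (\sigma_i r_{ij})} with cotangent dual-edge lengths.
#'
#' @param mesh a \code{tri_mesh}.
#' @param positions vertex positions.
#' @return list with \code{H}, \code{sigma}, \code{normal}.
#' @export
mesh_geometry <- function(mesh, positions = mesh$vertices) {
  cpp_mesh_geometry(positions, mesh$rings)
}

# ---- membrane parameters ------------------------------------------------

wlc_gprime <- function(x) (6 * x - 9 * x^2 + 4 * x^3) / (1 - x)^2

# energy of one WLC-POW bond of length l
wlc_pow_energy <- function(l, lmax, p, kp, kBT = 1) {
  x <- l / lmax
  kBT * lmax / (4 * p) * (3 * x^2 - 2 * x^3) / (1 - x) + kp / l
}

#' Shear modulus of a uniform triangular WLC-POW network
#'
#' Energy density of a flat hexagonal patch under affine simple shear
#' (area preserving, so constraint terms do not contribute), differentiated
#' numerically.  For a centrosymmetric triangular lattice the affine
#' deformation is the exact equilibrium at small strain.
#'
#' @param l0 edge rest length.
#' @param p persistence length.
#' @param x0 extensibility (rest length over maximum length).
#' @param kBT thermal energy.
#' @param gamma shear strain used for the second difference.
#' @return shear modulus in energy/length^2.
#' @export
patch_shear_modulus <- function(l0, p, x0 = 0.45, kBT = 1, gamma = 0.01) {
  lmax <- l0 / x0
  kp <- l0^2 * kBT * wlc_gprime(x0) / (4 * p)
  dirs <- rbind(c(1, 0), c(cos(pi / 3), sin(pi / 3)),
                c(cos(2 * pi / 3), sin(2 * pi / 3)))
  acell <- sqrt(3) / 2 * l0^2    # area per node; 3 bonds per node
  edens <- function(g) {
    Fm <- matrix(c(1, g, 0, 1), 2, 2, byrow = TRUE)
    b <- l0 * dirs %*% t(Fm)
    sum(wlc_pow_energy(sqrt(rowSums(b^2)), lmax, p, kp, kBT)) / acell
  }
  (edens(gamma) - 2 * edens(0) + edens(-gamma)) / gamma^2
}

#' Calibrate membrane spring parameters to a target shear modulus
#'
#' Chooses the persistence length \code{p} so the small-strain shear
#' modulus of the network equals \code{mu0}, and per-edge repulsion
#' coefficients \code{kp} so the net spring force vanishes at each edge's
#' rest length.  Both the WLC and the power-law term scale as 1/p, so a
#' single reference measurement fixes \code{p} exactly.
#'
#' @param mesh a \code{tri_mesh}.
#' @param mu0 target shear modulus (energy/length^2).
#' @param x0 extensibility.
#' @param kBT thermal energy.
#' @return list with \code{p}, per-edge \code{kp} and \code{lmax},
#'   \code{x0}, \code{mu} (the verified modulus).
#' @export
calibrate_springs <- function(mesh, mu0, x0 = 0.45, kBT = 1) {
  l0m <- mean(mesh$l0)
  p0 <- l0m
  mu_ref <- patch_shear_modulus(l0m, p0, x0, kBT)
  p <- p0 * mu_ref / mu0
  lmax <- mesh$l0 / x0
  kp <- mesh$l0^2 * kBT * wlc_gprime(x0) / (4 * p)
  list(p = p, kp = kp, lmax = lmax, x0 = x0,
       mu = patch_shear_modulus(l0m, p, x0, kBT))
}

#' Membrane parameter set
#'
#' Bundles the calibrated spring parameters with the bending modulus and
#' the area/volume constraint coefficients and targets.
#'
#' @param mesh a \code{tri_mesh}.
#' @param mu0 membrane shear modulus (energy/length^2).
#' @param kappa bending modulus (energy).
#' @param ka,kd,kv global-area, local-area and volume constraint
#'   coefficients.
#' @param x0 spring extensibility.
#' @param kBT thermal energy.
#' @return list of class \code{membrane_params}.
#' @export
membrane_params <- function(mesh, mu0, kappa, ka, kd, kv, x0 = 0.45,
                            kBT = 1) {
  cal <- calibrate_springs(mesh, mu0, x0, kBT)
  structure(c(cal, list(kappa = kappa, ka = ka, kd = kd, kv = kv,
                        kBT = kBT, A0 = mesh$A0, Am0 = mesh$Am0,
                        V0 = mesh$V0)),
            class = "membrane_params")
}

# ---- energies and forces ------------------------------------------------

#' Membrane energies and forces
#'
#' \code{bond_energy_forces} evaluates the worm-like-chain attraction with
#' the inverse-power (kp/l) repulsion per edge; \code{bending_energy_forces}
#' the discrete Helfrich bending energy on the cotangent dual lattice;
#' \code{constraint_energy_forces} the global-area, per-face local-area and
#' volume penalties; \code{membrane_energy_forces} their sum.  All forces
#' are exact gradients (analytic for bonds and constraints, dual-number
#' differentiation for bending).
#'
#' @param mesh a \code{tri_mesh}.
#' @param positions vertex positions.
#' @param params a [membrane_params()].
#' @param kappa bending modulus.
#' @param H0 per-vertex spontaneous curvature.
#' @return list with \code{energy} and \code{forces} (and for constraints
#'   \code{area}, \code{volume}).
#' @export
bond_energy_forces <- function(mesh, positions, params) {
  out <- cpp_mesh_bonds(positions, mesh$edges, params$lmax, params$kp,
                        params$p, params$kBT)
  if (out$bad_edge > 0)
    stop("overstretched edge ", out$bad_edge, " (", mesh$edges[out$bad_edge, 1],
         "-", mesh$edges[out$bad_edge, 2], "): length at or beyond maximum")
  out[c("energy", "forces")]
}

#' @rdname bond_energy_forces
#' @export
bending_energy_forces <- function(mesh, positions, kappa, H0 = mesh$H0) {
  cpp_mesh_bending(positions, mesh$rings, H0, kappa)
}

#' @rdname bond_energy_forces
#' @export
constraint_energy_forces <- function(mesh, positions, params) {
  av <- mesh_area_volume_points(positions, mesh$faces)
  if (av$volume <= 0) stop("inverted mesh: negative enclosed volume")
  cpp_mesh_constraints(positions, mesh$faces, params$ka, params$kd,
                       params$kv, params$A0, params$Am0, params$V0)
}

#' @rdname bond_energy_forces
#' @export
membrane_energy_forces <- function(mesh, positions, params) {
  b <- bond_energy_forces(mesh, positions, params)
  k <- bending_energy_forces(mesh, positions, params$kappa)
  c <- constraint_energy_forces(mesh, positions, params)
  list(energy = b$energy + k$energy + c$energy,
       forces = b$forces + k$forces + c$forces)
}
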