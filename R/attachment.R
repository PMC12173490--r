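#' Anchor of a flagellum on the body mesh
#'
#' The anchoring body vertex is identical to the first backbone particle of
#' the flagellum; the hook potential acts on the angles between the first
#' flagellum bond and the bonds from the anchor to its linked ring of body
#' vertices.
#'
#' @param mesh a \code{tri_mesh}.
#' @param vertex index of the anchoring vertex.
#' @return list of class \code{anchor} with the vertex index and its ring.
#' @export
make_anchor <- function(mesh, vertex) {
  stopifnot(vertex >= 1, vertex <= nrow(mesh$vertices))
  structure(list(vertex = as.integer(vertex),
                 ring = as.integer(mesh$rings[[vertex]])),
            class = "anchor")
}

#' Hook angle potential
#'
#' \deqn{U_{hook} = K_{hook} \sum_{j(i)} (\theta_j^{hook} - \pi/2)^2}
#' where \eqn{\theta_j^{hook}} is the angle between \eqn{r_j - r_i} (ring
#' bond) and \eqn{r_{2,0} - r_i} (first flagellum bond).  The preferred
#' angle \eqn{\pi/2} imposes a perpendicular orientation of the flagellum
#' with respect to the body surface.  Forces are exact gradients.
#'
#' @param ri anchor position (length 3).
#' @param ring_pos ring vertex positions (m x 3).
#' @param r2 position of the second backbone particle of the flagellum.
#' @param Khook hook stiffness (energy per squared radian).
#' @return list with \code{energy}, \code{f_anchor}, \code{f_ring},
#'   \code{f_first}.
#' @export
hook_energy_forces <- function(ri, ring_pos, r2, Khook) {
  if (sum((r2 - ri)^2) == 0) stop("coincident anchor and first bond point")
  if (any(rowSums(sweep(ring_pos, 2, ri)^2) == 0))
    stop("coincident anchor and ring vertex")
  if (Khook == 0) {
    m <- nrow(ring_pos)
    return(list(energy = 0, f_anchor = numeric(3),
                f_ring = matrix(0, m, 3), f_first = numeric(3)))
  }
  cpp_hook(ri, ring_pos, r2, Khook)
}

#' Hook stiffness by run/tumble phase
#'
#' During tumbles the hook of the reverted (clockwise-rotating) flagellum
#' is dynamically stiffened from the run value (100 kBT) to 500 kBT; all
#' other flagella keep the run value.  With stiffening disabled the run
#' value applies in every phase.
#'
#' @param phase one of \code{"run"}, \code{"tumble-reverted"},
#'   \code{"tumble-normal"}.
#' @param k_run hook stiffness in the run state.
#' @param k_reverted stiffened value for reverted flagella.
#' @param stiffening logical; disable to keep \code{k_run} throughout.
#' @return the hook stiffness (energy per squared radian).
#' @export
hook_stiffness <- function(phase, k_run = 100, k_reverted = 500,
                           stiffening = TRUE) {
  phase <- match.arg(phase, c("run", "tumble-reverted", "tumble-normal"))
  if (phase == "tumble-reverted" && stiffening) k_reverted else k_run
}

# forces on a set of points forming a pure couple with moment M:
# F_i = omega x d_i with omega solving (tr(S) I - S) omega = M,
# S = sum d d^T, d = points centered on their mean
couple_forces <- function(points, M) {
  d <- sweep(points, 2, colMeans(points))
  S <- crossprod(d)
  A <- diag(3) * sum(diag(S)) - S
  if (rcond(A) < 1e-12)
    stop("degenerate point set: cannot apply couple (points on the axis?)")
  om <- solve(A, M)
  t(apply(d, 1, function(r) pracma_cross(om, r)))
}

#' Motor torque and body counter-torque forces
#'
#' The motor applies a torque of magnitude \code{Tm} about the first
#' backbone bond direction to the four auxiliary particles of the first
#' flagellum segment, as a pure couple (zero net force, torque exactly
#' \code{Tm} along the axis).  The counter-torque \code{-Tm} is applied the
#' same way to the ring of body vertices linked to the anchor, so the
#' swimmer is exactly force-free and torque-free.
#'
#' @param aux_pos positions of the four first-segment auxiliary particles.
#' @param ring_pos positions of the anchor's ring of body vertices.
#' @param axis unit vector along the first backbone bond.
#' @param Tm torque magnitude (kBT per radian).
#' @param sense \code{+1} for anti-clockwise (run), \code{-1} for
#'   clockwise (tumble).
#' @return list with \code{f_aux} (4 x 3), \code{f_ring} (m x 3) and the
#'   applied \code{torque} vector.
#' @export
motor_forces <- function(aux_pos, ring_pos, axis, Tm, sense = 1) {
  axis <- axis / sqrt(sum(axis^2))
  M <- sense * Tm * axis
  list(f_aux = couple_forces(aux_pos, M),
       f_ring = couple_forces(ring_pos, -M),
       torque = M)
}

#' Excluded-volume (WCA) interactions
#'
#' Purely repulsive Lennard-Jones between particles of different flagella
#' and between flagella and body particles, cut off and shifted at
#' \eqn{2^{1/6}\sigma_{LJ}}.  Pairs within one flagellum and body-body
#' pairs are excluded; body anchors carry the flagellum id of their
#' flagellum so the bonded neighbourhood is excluded too.
#'
#' @param pos particle positions (n x 3).
#' @param isbody integer/logical vector: 1 for body particles.
#' @param fid flagellum id per particle (0 = none).
#' @param eps energy scale.
#' @param sigma repulsion length.
#' @return list with \code{energy} and \code{forces}.
#' @export
lj_energy_forces <- function(pos, isbody, fid, eps, sigma) {
  cpp_lj(pos, as.integer(isbody), as.integer(fid), eps, sigma)
}

#' Pairwise WCA energy of a single pair (reference implementation)
#' @param r scalar distance.
#' @param eps,sigma WCA parameters.
#' @return energy at distance r.
#' @export
wca_energy <- function(r, eps, sigma) {
  ifelse(r <= 2^(1 / 6) * sigma,
         4 * eps * ((sigma / r)^12 - (sigma / r)^6 + 0.25), 0)
}
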