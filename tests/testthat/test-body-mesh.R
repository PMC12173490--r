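test_that("quadrature area and volume match closed forms", {
  sph <- shape_area_volume(body_shape(2, 1, 1, 1))
  expect_equal(sph$area, 4 * pi, tolerance = 1e-8)
  expect_equal(sph$volume, 4 * pi / 3, tolerance = 1e-12)
  pro <- shape_area_volume(body_shape(2, 1, 1 / 3))
  expect_equal(pro$volume, 4 * pi / 27, tolerance = 1e-12)
})

test_that("the sphero-cylinder-like body has area 4.21 bx^2, volume 0.62 bx^3", {
  av <- shape_area_volume(body_shape(8.5, 1, 1 / 3))
  expect_equal(av$area, 4.21, tolerance = 0.02)
  expect_equal(av$volume, 0.62, tolerance = 0.02)
})

test_that("triangulation is closed, on-surface and near-uniform", {
  m <- fx_body_mesh()
  nv <- nrow(m$vertices)
  ne <- nrow(m$edges)
  nt <- nrow(m$faces)
  expect_identical(nv - ne + nt, 2L)  # Euler characteristic of a sphere
  dev <- abs(ecoliswim:::shape_implicit(m$shape, m$vertices) - 1)
  expect_lt(max(dev), 1e-8)
  expect_lt(max(m$l0) / min(m$l0), 3)
  expect_gt(min(m$Am0), 0)
  # dual areas tile the surface
  expect_equal(sum(m$sigma0), m$A0, tolerance = 1e-6)
})

test_that("unit-sphere mesh area approaches 4 pi", {
  ms <- triangulate_body(body_shape(2, 1, 1, 1), 642)
  expect_equal(mesh_area_volume(ms)$area, 4 * pi, tolerance = 0.01)
})

test_that("mesh area and volume agree with quadrature within 2%", {
  m <- fx_body_mesh()
  av <- mesh_area_volume(m)
  cont <- shape_area_volume(m$shape)
  expect_equal(av$area, cont$area, tolerance = 0.02)
  expect_equal(av$volume, cont$volume, tolerance = 0.02)
})

test_that("degenerate shapes are rejected", {
  expect_error(body_shape(8.5, 1, 0), "degenerate")
  expect_error(triangulate_body(body_shape(8.5, 1, 1 / 3), 6), ">= 12")
})

test_that("discrete mean curvature of a refined sphere is 2/R", {
  ms <- triangulate_body(body_shape(2, 1, 1, 1), 2562)
  H <- mesh_geometry(ms)$H
  expect_lt(max(abs(H - 2)), 0.02 * 2)
  # radius R = 3: curvature scales as 2/R
  ms3 <- triangulate_body(body_shape(2, 3, 3, 3), 642)
  H3 <- mesh_geometry(ms3)$H
  expect_equal(mean(H3), 2 / 3, tolerance = 0.02)
})

test_that("springs are force-free at rest length and diverge at full extension", {
  m <- fx_body_mesh()
  mp <- fx_mparams(m)
  b <- bond_energy_forces(m, m$vertices, mp)
  expect_lt(max(abs(b$forces)), 1e-9)
  # monotone divergence of the WLC term as x -> 1
  l0 <- mean(m$l0)
  u <- vapply(c(0.8, 0.9, 0.99, 0.999),
              function(x) ecoliswim:::wlc_pow_energy(x * l0 / 0.45,
                                                     l0 / 0.45, mp$p,
                                                     mp$kp[1]),
              numeric(1))
  expect_true(all(diff(u) > 0))
  expect_gt(u[4] / u[1], 50)
  # stretching beyond the maximum extension is an error naming the edge
  pos <- m$vertices
  e1 <- m$edges[1, ]
  dir <- pos[e1[2], ] - pos[e1[1], ]
  pos[e1[2], ] <- pos[e1[1], ] + dir * (mp$lmax[1] / m$l0[1]) * 1.01
  expect_error(bond_energy_forces(m, pos, mp), "overstretched")
})

test_that("spontaneous curvature from construction gives zero bending energy", {
  m <- fx_body_mesh()
  k <- bending_energy_forces(m, m$vertices, 100)
  expect_lt(abs(k$energy), 1e-12)
})

test_that("constraint energy vanishes at the target shape and follows the quadratic form", {
  ms <- triangulate_body(body_shape(2, 1, 1, 1), 162)
  mp <- fx_mparams(ms)
  cc <- constraint_energy_forces(ms, ms$vertices, mp)
  expect_lt(abs(cc$energy), 1e-12)
  expect_lt(max(abs(cc$forces)), 1e-9)
  # uniform 1% inflation: closed-form quadratic penalties
  s <- 1.01
  cc2 <- constraint_energy_forces(ms, ms$vertices * s, mp)
  A0 <- ms$A0; V0 <- ms$V0
  expected <- mp$ka * (A0 * s^2 - A0)^2 / (2 * A0) +
    sum(mp$kd * (ms$Am0 * s^2 - ms$Am0)^2 / (2 * ms$Am0)) +
    mp$kv * (V0 * s^3 - V0)^2 / (2 * V0)
  expect_equal(cc2$energy, expected, tolerance = 1e-8)
  # inverted meshes are rejected
  expect_error(constraint_energy_forces(ms, -ms$vertices, mp), "inverted")
})

test_that("all membrane forces are exact gradients (finite-difference oracle)", {
  m <- triangulate_body(body_shape(8.5, 1, 1 / 3), 162)
  mp <- fx_mparams(m)
  set.seed(7)
  pos <- m$vertices + matrix(rnorm(length(m$vertices), 0, 1e-4),
                             nrow(m$vertices))
  b <- bond_energy_forces(m, pos, mp)
  expect_lt(fd_force_error(function(p) bond_energy_forces(m, p, mp)$energy,
                           pos, b$forces), 1e-5)
  k <- bending_energy_forces(m, pos, mp$kappa)
  expect_lt(fd_force_error(
    function(p) bending_energy_forces(m, p, mp$kappa)$energy,
    pos, k$forces), 1e-5)
  cc <- constraint_energy_forces(m, pos, mp)
  expect_lt(fd_force_error(
    function(p) constraint_energy_forces(m, p, mp)$energy,
    pos, cc$forces), 1e-5)
})

test_that("membrane energy is invariant under rigid-body motion", {
  m <- fx_body_mesh()
  mp <- fx_mparams(m)
  e0 <- membrane_energy_forces(m, m$vertices, mp)$energy
  R <- ecoliswim:::rot_axis_angle(c(1, 2, 3), 0.7)
  pos <- sweep(m$vertices %*% t(R), 2, c(0.3, -1, 2), "+")
  e1 <- membrane_energy_forces(m, pos, mp)$energy
  expect_equal(e1, e0, tolerance = 1e-10)
})

test_that("spring calibration reproduces the target shear modulus and is linear", {
  m <- fx_body_mesh_raw()
  mu0 <- 8.1e4 / 81
  cal <- calibrate_springs(m, mu0)
  expect_equal(cal$mu, mu0, tolerance = 0.05)
  cal2 <- calibrate_springs(m, 2 * mu0)
  expect_equal(cal2$mu, 2 * mu0, tolerance = 0.05)
  expect_equal(cal2$mu / cal$mu, 2, tolerance = 0.05)
  # net spring force zero at rest length
  mp <- fx_mparams(m)
  expect_lt(max(abs(bond_energy_forces(m, m$vertices, mp)$forces)), 1e-9)
})

test_that("symplectic integration of the isolated membrane conserves energy", {
  m <- fx_body_mesh_raw()
  mp <- fx_mparams(m)
  set.seed(3)
  pos <- m$vertices
  vel <- matrix(rnorm(length(pos), 0, 0.05), nrow(pos))
  vel <- sweep(vel, 2, colMeans(vel))
  erest <- membrane_energy_forces(m, pos, mp)$energy
  out <- membrane_energy_forces(m, pos, mp)
  dt <- 2e-4
  e0 <- out$energy + 0.5 * sum(vel^2)
  for (s in seq_len(10000)) {
    vel <- vel + 0.5 * dt * out$forces
    pos <- pos + dt * vel
    out <- membrane_energy_forces(m, pos, mp)
    vel <- vel + 0.5 * dt * out$forces
  }
  e1 <- out$energy + 0.5 * sum(vel^2)
  # drift relative to the excitation energy above the rest state
  expect_lt(abs(e1 - e0) / (e0 - erest), 1e-4)
})
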