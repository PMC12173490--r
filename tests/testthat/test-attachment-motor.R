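# a symmetric ring of body vertices around an anchor at the origin, with
# the outward normal along +z
ring_fixture <- function(m = 6, r = 1) {
  ang <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  cbind(r * cos(ang), r * sin(ang), 0)
}

test_that("hook energy is minimal for a perpendicular first bond", {
  ring <- ring_fixture()
  ri <- c(0, 0, 0)
  h0 <- hook_energy_forces(ri, ring, c(0, 0, 0.5), 100)
  expect_lt(abs(h0$energy), 1e-20)
  expect_lt(max(abs(h0$f_first)), 1e-10)
  # tilted first bond: positive energy, restoring force
  h1 <- hook_energy_forces(ri, ring, c(0.3, 0, 0.5), 100)
  expect_gt(h1$energy, 0)
  expect_lt(h1$f_first[1], 0)  # pushes back towards the normal
})

test_that("a fully flexible hook exerts no forces", {
  ring <- ring_fixture()
  h <- hook_energy_forces(c(0, 0, 0), ring, c(0.4, 0.2, 0.3), 0)
  expect_identical(h$energy, 0)
  expect_identical(max(abs(h$f_ring)), 0)
})

test_that("hook forces are exact gradients and scale linearly with Khook", {
  ring <- ring_fixture(5, 0.8)
  set.seed(8)
  ring <- ring + matrix(rnorm(15, 0, 0.05), 5)
  ri <- c(0.02, -0.01, 0.03)
  r2 <- c(0.2, 0.1, 0.6)
  h <- hook_energy_forces(ri, ring, r2, 100)
  # finite differences on the first-bond endpoint and one ring vertex
  eps <- 1e-7
  for (c in 1:3) {
    r2p <- r2; r2p[c] <- r2p[c] + eps
    r2m <- r2; r2m[c] <- r2m[c] - eps
    fd <- -(hook_energy_forces(ri, ring, r2p, 100)$energy -
              hook_energy_forces(ri, ring, r2m, 100)$energy) / (2 * eps)
    expect_equal(fd, h$f_first[c], tolerance = 1e-6 * max(abs(h$f_first)))
  }
  h5 <- hook_energy_forces(ri, ring, r2, 500)
  expect_equal(h5$energy / h$energy, 5, tolerance = 1e-12)
  # small-deviation restoring torque is linear with slope ~ Khook
  t1 <- hook_energy_forces(c(0, 0, 0), ring_fixture(), c(0.01, 0, 1),
                           100)$energy
  t2 <- hook_energy_forces(c(0, 0, 0), ring_fixture(), c(0.02, 0, 1),
                           100)$energy
  expect_equal(t2 / t1, 4, tolerance = 0.01)
})

test_that("hook stiffness switches between run and tumble states", {
  expect_identical(hook_stiffness("run"), 100)
  expect_identical(hook_stiffness("tumble-reverted"), 500)
  expect_identical(hook_stiffness("tumble-normal"), 100)
  # stiffening disabled: unchanged across phases
  expect_identical(hook_stiffness("tumble-reverted", stiffening = FALSE),
                   100)
})

test_that("motor forces form torque-free, force-free couples", {
  set.seed(9)
  ell <- 0.7
  aux <- rbind(c(0.35, 0, 0.35), c(0, 0.35, 0.35), c(-0.35, 0, 0.35),
               c(0, -0.35, 0.35)) + matrix(rnorm(12, 0, 0.02), 4)
  ring <- ring_fixture(6, 1.2) + matrix(rnorm(18, 0, 0.02), 6)
  axis <- c(0.1, -0.05, 1)
  mf <- motor_forces(aux, ring, axis, 300, sense = 1)
  expect_lt(max(abs(colSums(mf$f_aux))), 1e-12)
  expect_lt(max(abs(colSums(mf$f_ring))), 1e-12)
  torque_about <- function(pts, F, o) {
    colSums(t(vapply(seq_len(nrow(pts)), function(i)
      ecoliswim:::pracma_cross(pts[i, ] - o, F[i, ]), numeric(3))))
  }
  axis_u <- axis / sqrt(sum(axis^2))
  taux <- torque_about(aux, mf$f_aux, c(0, 0, 0))
  expect_equal(sum(taux * axis_u), 300, tolerance = 1e-10)
  # motor + counter-torque cancel about any reference point
  for (o in list(c(0, 0, 0), c(5, -3, 2))) {
    tot <- torque_about(aux, mf$f_aux, o) + torque_about(ring, mf$f_ring, o)
    expect_lt(max(abs(tot)), 1e-10)
  }
  # clockwise sense flips the applied torque
  mr <- motor_forces(aux, ring, axis, 300, sense = -1)
  expect_equal(mr$f_aux, -mf$f_aux, tolerance = 1e-12)
  # collinear auxiliary particles cannot carry a couple
  degen <- cbind(0, 0, 1:4)
  expect_error(motor_forces(degen, ring, c(0, 0, 1), 300), "degenerate")
})

test_that("excluded-volume interaction is WCA: zero at cutoff, eps at sigma", {
  eps <- 1; sigma <- 0.63
  expect_equal(wca_energy(2^(1 / 6) * sigma, eps, sigma), 0,
               tolerance = 1e-14)
  expect_equal(wca_energy(sigma, eps, sigma), eps, tolerance = 1e-12)
  r <- seq(0.3, 1, length.out = 30) * sigma
  u <- wca_energy(r, eps, sigma)
  expect_true(all(diff(u) < 0))  # repulsion grows monotonically as r -> 0
  # pair kernel: two particles of different flagella
  pos <- rbind(c(0, 0, 0), c(sigma, 0, 0))
  lj <- lj_energy_forces(pos, c(0L, 0L), c(1L, 2L), eps, sigma)
  expect_equal(lj$energy, eps, tolerance = 1e-12)
  expect_equal(lj$forces[1, ], -lj$forces[2, ], tolerance = 1e-14)
  # exclusions: same flagellum and body-body pairs do not interact
  expect_identical(lj_energy_forces(pos, c(0L, 0L), c(1L, 1L), eps,
                                    sigma)$energy, 0)
  expect_identical(lj_energy_forces(pos, c(1L, 1L), c(0L, 0L), eps,
                                    sigma)$energy, 0)
})
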