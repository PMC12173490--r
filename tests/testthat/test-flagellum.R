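Om_left <- c(0.122, -0.027, -0.217)

test_that("a 76-segment chain has 381 particles and obeys the count formula", {
  expect_identical(flagellum_particle_count(76), 381L)
  ch <- fx_chain76()
  expect_identical(nrow(ch$pos), 381L)
  for (Ns in c(2, 10, 33))
    expect_identical(nrow(build_flagellum(Ns, c(0, 0, 0), 0.7)$pos),
                     5L * as.integer(Ns) + 1L)
})

test_that("zero strain targets build a straight rod of length Ns * ell", {
  ch <- build_flagellum(20, c(0, 0, 0), 0.7)
  bb <- ch$pos[1:21, ]
  expect_equal(sum(sqrt(rowSums(diff(bb)^2))), 20 * 0.7, tolerance = 1e-12)
  # straight along the anchor frame's e3: no transverse excursion
  expect_lt(max(abs(sweep(bb[, 1:2], 2, bb[1, 1:2]))), 1e-12)
})

test_that("triads are orthonormal, tangent-aligned and rotation-equivariant", {
  ch <- fx_chain76()
  tri <- compute_triads(ch)
  for (n in c(1, 30, 76)) {
    E <- matrix(tri[n, ], 3, 3)
    expect_lt(max(abs(crossprod(E) - diag(3))), 1e-10)
  }
  # e3 . b3 = |b3| by construction, also for perturbed chains
  set.seed(4)
  pos <- ch$pos + matrix(rnorm(length(ch$pos), 0, 1e-2), nrow(ch$pos))
  trip <- compute_triads(ch, pos)
  b3 <- pos[2:77, ] - pos[1:76, ]
  e3 <- trip[, 7:9]
  expect_lt(max(abs(rowSums(e3 * b3) - sqrt(rowSums(b3^2)))), 1e-12)
  # rigid rotation rotates all triads accordingly
  R <- ecoliswim:::rot_axis_angle(c(1, -1, 2), 1.1)
  trir <- compute_triads(ch, ch$pos %*% t(R))
  for (n in c(1, 40)) {
    E <- matrix(tri[n, ], 3, 3)
    Er <- matrix(trir[n, ], 3, 3)
    expect_equal(Er, R %*% E, tolerance = 1e-10)
  }
})

test_that("strain vector decomposition matches its defining cases", {
  A <- diag(3)
  expect_equal(strain_vector(A, A), c(0, 0, 0), tolerance = 1e-14)
  # pure twist about e3
  B <- A %*% ecoliswim:::rot_axis_angle(c(0, 0, 1), 0.3)
  expect_equal(strain_vector(A, B), c(0, 0, 0.3), tolerance = 1e-12)
  # pure bend about e1
  B <- ecoliswim:::rot_axis_angle(c(1, 0, 0), 0.25) %*% A
  expect_equal(strain_vector(A, B), c(0.25, 0, 0), tolerance = 1e-12)
  expect_error(
    strain_vector(A, diag(c(1, -1, -1))), "antiparallel")
})

test_that("built chains realize their strain targets exactly (round trip)", {
  ch <- fx_chain76()
  st <- strain_vectors(ch)
  expect_lt(max(abs(st - ch$Omega_e)), 1e-6)
  # also for a target set with a straight initial section
  ch2 <- build_flagellum(30, Om_left, 0.7, ln_straight = 10)
  st2 <- strain_vectors(ch2)
  expect_lt(max(abs(st2 - ch2$Omega_e)), 1e-6)
  expect_true(all(ch2$Omega_e[1:10, ] == 0))
})

test_that("rod energy vanishes at the built helix and grows quadratically in twist", {
  ch <- fx_chain76()
  el <- rod_elasticity()
  e0 <- rod_energy_forces(ch, el)
  expect_lt(abs(e0$energy), 1e-10)
  expect_lt(max(abs(e0$forces)), 1e-8)
  # twisting the last segment's auxiliary cross by d-phi about e3 costs
  # Kel3/2 d-phi^2
  ch3 <- build_flagellum(10, c(0, 0, 0), 0.7)
  dphi <- 0.02
  tri <- compute_triads(ch3)
  e3 <- tri[10, 7:9]
  R <- ecoliswim:::rot_axis_angle(e3, dphi)
  mid <- (ch3$pos[10, ] + ch3$pos[11, ]) / 2
  for (k in 1:4) {
    r <- ecoliswim:::aux_rows(10L, 10L, k)
    ch3$pos[r, ] <- mid + as.vector(R %*% (ch3$pos[r, ] - mid))
  }
  e1 <- rod_energy_forces(ch3, el)
  expect_equal(e1$elastic, 0.5 * el$Kel[3] * dphi^2, tolerance = 1e-6)
})

test_that("rod forces are exact gradients (finite-difference oracle)", {
  ch <- build_flagellum(12, Om_left, 0.7)
  el <- rod_elasticity()
  set.seed(5)
  pos <- ch$pos + matrix(rnorm(length(ch$pos), 0, 1e-3), nrow(ch$pos))
  out <- rod_energy_forces(ch, el, pos)
  expect_lt(fd_force_error(
    function(p) rod_energy_forces(ch, el, p)$energy, pos, out$forces),
    1e-5)
})

test_that("rod energy is invariant under rigid-body motion", {
  ch <- build_flagellum(15, Om_left, 0.7)
  el <- rod_elasticity()
  set.seed(6)
  pos <- ch$pos + matrix(rnorm(length(ch$pos), 0, 1e-2), nrow(ch$pos))
  e0 <- rod_energy_forces(ch, el, pos)$energy
  R <- ecoliswim:::rot_axis_angle(c(2, 1, -1), 0.9)
  e1 <- rod_energy_forces(ch, el,
                          sweep(pos %*% t(R), 2, c(1, 2, 3), "+"))$energy
  expect_equal(e1, e0, tolerance = 1e-10)
})

test_that("the minimized chain is the stated equilibrium helix", {
  ch <- fx_relaxed76()
  radius <- raw_to_um(ch$helix$radius)
  pitch <- raw_to_um(ch$helix$pitch)
  contour <- raw_to_um(ch$contour)
  expect_equal(radius, 0.23, tolerance = 0.02)
  expect_equal(pitch, 2.56, tolerance = 0.02)
  expect_equal(contour, 8.9, tolerance = 0.02)
  expect_equal(ch$helix$turns, 3, tolerance = 0.02)
  expect_identical(ch$helix$handedness, -1)  # left-handed
})

test_that("a perturbed chain relaxes back to the equilibrium helix", {
  ch <- fx_chain76()
  set.seed(11)
  ch$pos <- ch$pos + matrix(rnorm(length(ch$pos), 0, 5e-3), nrow(ch$pos))
  chr <- suppressWarnings(relax_flagellum(ch, rod_elasticity(),
                                          restarts = 3))
  ref <- fx_relaxed76()
  expect_equal(chr$helix$radius, ref$helix$radius, tolerance = 0.01)
  expect_equal(chr$helix$pitch, ref$helix$pitch, tolerance = 0.01)
})

test_that("discrete helix geometry matches the continuum closed form", {
  for (Ns in c(40, 76)) {
    ell <- 0.7
    ch <- relax_flagellum(build_flagellum(Ns, Om_left, ell),
                          rod_elasticity())
    kap <- sqrt(Om_left[1]^2 + Om_left[2]^2) / ell
    tau <- abs(Om_left[3]) / ell
    expect_equal(ch$helix$radius, kap / (kap^2 + tau^2), tolerance = 0.01)
    expect_equal(ch$helix$pitch, 2 * pi * tau / (kap^2 + tau^2),
                 tolerance = 0.01)
  }
})

test_that("sign-flipped bending targets build the mirror-image helix", {
  el <- rod_elasticity()
  chL <- fx_relaxed76()
  chR <- relax_flagellum(
    build_flagellum(76, c(-0.122, 0.027, -0.217), fx_chain76()$ell), el)
  expect_equal(chR$helix$radius, chL$helix$radius, tolerance = 1e-6)
  expect_equal(chR$helix$pitch, chL$helix$pitch, tolerance = 1e-6)
  expect_identical(chR$helix$handedness, -chL$helix$handedness)
  # the reflected left-handed chain is a zero-energy state of the
  # sign-flipped targets (mirror symmetry of the energy)
  mir <- chL$pos
  mir[, 3] <- -mir[, 3]
  chRm <- chR
  chRm$pos <- mir
  expect_lt(rod_energy_forces(chRm, el)$energy, 1e-8)
})

test_that("polymorphic ramp interpolates the bend targets linearly", {
  ch <- fx_chain76()
  sch <- polymorphic_schedule(ramp = 0.76 * 132, direction = "to-right",
                              start = 10)
  c0 <- polymorphic_step(ch, sch, 10)
  expect_equal(c0$Omega_e, ch$Omega_left)
  expect_identical(c0$state, "left")
  cm <- polymorphic_step(ch, sch, 10 + 0.38 * 132)
  expect_equal(max(abs(cm$Omega_e[, 1:2])), 0, tolerance = 1e-12)
  ce <- polymorphic_step(ch, sch, 10 + 0.76 * 132)
  expect_equal(ce$Omega_e[1, ], c(-0.122, 0.027, -0.217))
  expect_identical(ce$state, "right")
  # past the ramp the pure opposite state holds
  ce2 <- polymorphic_step(ch, sch, 10 + 2 * 0.76 * 132)
  expect_equal(ce2$Omega_e, ce$Omega_e)
  # reverse transformation uses the same linear ramp
  back <- polymorphic_schedule(ramp = 0.76 * 132, direction = "to-left",
                               start = 200)
  cb <- polymorphic_step(ce, back, 200 + 0.76 * 132)
  expect_equal(cb$Omega_e, ch$Omega_left)
})
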