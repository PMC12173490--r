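test_that("the default arrangement is one polar flagellum plus four at 90 degrees", {
  cfg <- mini_config(n_flag = 5, Ns = 12, n_vertices = 642)
  raw <- config_raw(cfg)
  mesh <- triangulate_body(body_shape(raw$body$nu, raw$body$bx,
                                      raw$body$by), raw$body$n_vertices)
  idx <- ecoliswim:::place_anchors(mesh, c(0, 0, 0), raw)
  expect_identical(length(unique(idx)), 5L)
  v <- mesh$vertices
  # first anchor at the rear pole
  expect_equal(unname(v[idx[1], 1]), max(v[, 1]), tolerance = 1e-9)
  # the other four are equally spaced in azimuth near the rear
  ang <- sort(atan2(v[idx[-1], 3], v[idx[-1], 2]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_equal(unname(gaps), rep(pi / 2, 4), tolerance = 0.15)
  expect_true(all(v[idx[-1], 1] > 0))  # rear half
})

test_that("random arrangements are seeded and constrained to their region", {
  cfg <- mini_config(n_flag = 3, Ns = 12)
  cfg$flagella$arrangement <- "random-rear-half"
  raw <- config_raw(cfg)
  mesh <- triangulate_body(body_shape(raw$body$nu, raw$body$bx,
                                      raw$body$by), raw$body$n_vertices)
  i1 <- ecoliswim:::place_anchors(mesh, c(0, 0, 0), raw)
  i2 <- ecoliswim:::place_anchors(mesh, c(0, 0, 0), raw)
  expect_identical(i1, i2)  # reproducible from the seed
  expect_true(all(mesh$vertices[i1, 1] > 0))
  raw$flagella$arrangement <- "random-whole-body"
  i3 <- ecoliswim:::place_anchors(mesh, c(0, 0, 0), raw)
  expect_identical(length(unique(i3)), 3L)
})

test_that("fluid fill matches density x volume and excludes the body", {
  sim <- fx_mini_sim()
  cfg <- sim$config
  expected <- round(config_raw(cfg)$dpd$nd * prod(config_raw(cfg)$domain))
  expect_identical(sim$nf, expected)
  # no fluid particle inside the body
  ctr <- config_raw(cfg)$domain / 2
  shp <- body_shape(cfg$body$nu, 9, 3)  # raw semi-axes
  f <- ecoliswim:::shape_implicit(shp,
                                  sweep(sim$pos[seq_len(sim$nf), ], 2, ctr))
  expect_true(all(f >= 1))
})

test_that("the full-scale configuration corresponds to ~2.4 million fluid particles", {
  cfg <- default_config()
  expect_true(cfg$cluster_scale)
  n <- cfg$dpd$nd * prod(cfg$domain)
  expect_equal(n, 2.4e6, tolerance = 0.01)
})

test_that("the assembled swimmer is force-free and torque-free", {
  sim <- fx_mini_sim()
  nft <- net_force_torque(sim)
  expect_lt(max(abs(nft$force)), 1e-8)
  expect_lt(max(abs(nft$torque)), 1e-8)
})

test_that("integration conserves momentum and stays stable", {
  sim <- fx_mini_sim()
  p0 <- colSums(sim$vel)
  for (k in 1:150) sim <- simulation_step(sim)
  expect_lt(max(abs(colSums(sim$vel) - p0)) / 150, 1e-10)
  expect_lt(max(abs(sim$vel)), 50)
  # still force/torque-free mid-run
  nft <- net_force_torque(sim)
  expect_lt(max(abs(nft$force)), 1e-8)
  expect_lt(max(abs(nft$torque)), 1e-7)
})

test_that("the phase log records every scheduled run/tumble transition", {
  cfg <- mini_config(n_flag = 2, Ns = 12)
  cfg$schedule$bundling <- 4e-4
  cfg$schedule$run <- 4e-4
  cfg$schedule$tumble <- 4e-4
  cfg$schedule$cycles <- 3L
  # a ramp much faster than the model's 0.76 tau is unstable (helicity
  # cannot change instantaneously); bookkeeping is tested without it
  cfg$schedule$polymorphic <- FALSE
  sim <- assemble(cfg)
  out <- run_schedule(sim, out_every = 40L)
  expect_identical(sum(out$log$event == "tumble-start"), 3L)
  expect_identical(sum(out$log$event == "tumble-end"), 3L)
  expect_true(all(diff(out$log$time) > 0))
  # after the final tumble-end all motors rotate anti-clockwise again
  expect_true(all(out$sim$motor_sense == 1))
  expect_true(all(out$sim$hook_k == 100))
  # the recorded series is a valid observable series
  expect_s3_class(observable_series(out$series), "data.frame")
})

test_that("tumble events flip motor sense, stiffen hooks and ramp targets", {
  cfg <- mini_config(n_flag = 2, Ns = 12)
  cfg$schedule$bundling <- 2e-4
  cfg$schedule$run <- 2e-4
  cfg$schedule$tumble <- 1
  cfg$schedule$cycles <- 1L
  cfg$schedule$ramp <- 0.76
  sim <- assemble(cfg)
  dur <- config_raw(cfg)$schedule$bundling +
    config_raw(cfg)$schedule$run + 40 * sim$dt
  out <- run_schedule(sim, duration = dur, out_every = 200L)
  expect_identical(out$sim$motor_sense[1], -1)
  expect_identical(out$sim$motor_sense[2], 1)
  expect_identical(out$sim$hook_k[1], 500)
  expect_identical(out$sim$hook_k[2], 100)
  # mid-ramp: bend targets shrunk in magnitude, twist unchanged
  om <- out$sim$chains[[1]]$Omega_e
  expect_lt(abs(om[1, 1]), 0.122)
  expect_identical(om[1, 3], -0.217)
  # two reverted flagella flip simultaneously
  cfg$schedule$reverted <- c(1L, 2L)
  sim2 <- assemble(cfg)
  out2 <- run_schedule(sim2, duration = dur, out_every = 200L)
  expect_identical(out2$sim$motor_sense, c(-1, -1))
})

test_that("controls: no polymorphic transformation and no hook stiffening", {
  cfg <- mini_config(n_flag = 2, Ns = 12)
  cfg$schedule$bundling <- 2e-4
  cfg$schedule$run <- 2e-4
  cfg$schedule$tumble <- 2e-4
  cfg$schedule$cycles <- 1L
  cfg$schedule$polymorphic <- FALSE
  cfg$schedule$stiffening <- FALSE
  sim <- assemble(cfg)
  om0 <- sim$chains[[1]]$Omega_e
  out <- run_schedule(sim, out_every = 60L)
  expect_identical(out$sim$chains[[1]]$Omega_e, om0)
  expect_true(all(out$sim$hook_k == 100))
})

test_that("without motor torque there is no directed swimming", {
  cfg <- mini_config(n_flag = 1, Ns = 12)
  cfg$motor$torque <- 0
  sim <- assemble(cfg)
  com0 <- colMeans(sim$pos[sim$body_rows, ])
  for (k in 1:150) sim <- simulation_step(sim)
  com1 <- colMeans(sim$pos[sim$body_rows, ])
  # displacement stays at the thermal-diffusion scale
  expect_lt(sqrt(sum((com1 - com0)^2)), 0.5)
})
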