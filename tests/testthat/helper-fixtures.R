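# cached fixtures shared across test files (built once per test run)
.fx <- new.env()

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_body_mesh <- function() fx("body642", function() {
  triangulate_body(body_shape(8.5, 1, 1 / 3), 642)
})

fx_body_mesh_raw <- function() fx("body162raw", function() {
  triangulate_body(body_shape(8.5, 9, 3), 162)
})

fx_mparams <- function(mesh) membrane_params(mesh, 8.1e4 / 81, 100,
                                             4.05e4 / 81, 8.1e4 / 81,
                                             3.65e5 / 729)

fx_chain76 <- function() fx("chain76", function() {
  build_flagellum(76, c(0.122, -0.027, -0.217), um_to_raw_test(0.1160419))
})

um_to_raw_test <- function(x) x * 6  # 1 um = 6 raw length units

fx_relaxed76 <- function() fx("relaxed76", function() {
  relax_flagellum(fx_chain76(), rod_elasticity())
})

fx_mini_sim <- function() fx("mini_sim", function() {
  make_mini_swimmer(n_flag = 2, Ns = 12, seed = 5)
})

# central finite-difference check of forces against an energy functional;
# returns the maximum error relative to the largest force component
fd_force_error <- function(energy_fn, pos, forces, n = 15, h = 1e-6,
                           seed = 42) {
  set.seed(seed)
  scale <- max(abs(forces))
  err <- 0
  for (k in seq_len(n)) {
    i <- sample(nrow(pos), 1)
    c <- sample(3, 1)
    pp <- pos
    pp[i, c] <- pp[i, c] + h
    ep <- energy_fn(pp)
    pp[i, c] <- pp[i, c] - 2 * h
    em <- energy_fn(pp)
    err <- max(err, abs((em - ep) / (2 * h) - forces[i, c]) / scale)
  }
  err
}
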