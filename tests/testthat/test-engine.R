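test_that("uniform fields have zero diffusion rate", {
  m <- generate_square(10, 1)
  r <- fvm_diffusion(m, rep(3.7, n_cells(m)), D = 25)
  expect_equal(max(abs(r)), 0, tolerance = 1e-12)
})

test_that("two-cell flux matches the hand-computed exchange", {
  m <- two_tri_mesh()
  # shared edge (0,0)-(1,1): length sqrt(2); centroids (2/3,1/3), (1/3,2/3):
  # distance sqrt(2)/3; areas 1/2 -> rate_1 = D/(1/2) * 3 * (u2 - u1)
  u <- c(1, 4)
  D <- 2.5
  r <- fvm_diffusion(m, u, D)
  expect_equal(r[1], D * 2 * 3 * (u[2] - u[1]), tolerance = 1e-12)
  expect_equal(r[2], -r[1], tolerance = 1e-12)
})

test_that("zero-flux diffusion conserves the area-weighted sum exactly", {
  m <- generate_square(10, 1)
  set.seed(3)
  u <- stats::runif(n_cells(m))
  r <- fvm_diffusion(m, u, 160)
  expect_lt(abs(sum(r * m$areas)) / sum(abs(u) * m$areas), 1e-12)
})

test_that("the discrete diffusion operator is negative semi-definite", {
  m <- generate_square(10, 1)
  set.seed(4)
  for (i in 1:20) {
    u <- stats::rnorm(n_cells(m))
    expect_lte(sum(u * fvm_diffusion(m, u, 25) * m$areas), 1e-12)
  }
})

test_that("one Heun step of scalar decay has the exact trapezoidal factor", {
  dt <- 0.002
  u1 <- heun_step(1, function(u) -u, dt, noise_sd = 0)
  expect_equal(u1, 1 - dt + dt^2 / 2, tolerance = 1e-15)
  # zero right-hand side leaves the state untouched
  expect_identical(heun_step(c(1, 2, 3), function(u) 0 * u, dt), c(1, 2, 3))
})

test_that("stochastic runs are bit-reproducible under a fixed seed", {
  m <- generate_square(20, 4)
  p <- bsw_preset("square")
  cfg <- integrator_config(t_per_day = 0.1)
  s1 <- simulate_bsw(p, m, cfg, days = 1, fgf = "none", seed = 11)
  s2 <- simulate_bsw(p, m, cfg, days = 1, fgf = "none", seed = 11)
  expect_identical(s1$S, s2$S)
  s3 <- simulate_bsw(p, m, cfg, days = 1, fgf = "none", seed = 12)
  expect_false(identical(s1$S, s3$S))
})

test_that("pure diffusion of a blob conserves mass and obeys the maximum principle", {
  m <- generate_square(40, 4)
  u0 <- numeric(n_cells(m)); u0[10] <- 5
  e <- finturing:::fvm_edges(m)
  u1 <- finturing:::cpp_diffuse(u0, 25, 0.002, 500, e$ei, e$ej, e$w, m$areas)
  expect_lt(abs(sum(u1 * m$areas) - sum(u0 * m$areas)) / sum(u0 * m$areas),
            1e-10)
  expect_lt(max(u1), max(u0))
  expect_gte(min(u1), -1e-12)
})

test_that("a stable parameter set stays at its homogeneous fixed point", {
  m <- generate_square(30, 5)
  # Sox9->Bmp loop only, no Sox9-Wnt loop: stable, not Turing
  p <- bsw_params(beta = 1, k2 = 1, k3 = 1, k4 = 2, k7 = 0, k5 = 0.1,
                  k9 = 0.1, alpha_B = 0.5, alpha_W = 0.5)
  cfg <- integrator_config(noise_sd = 0, t_per_day = 20)
  sim <- simulate_bsw(p, m, cfg, days = 1, fgf = "none", seed = 1)
  st <- steady_state(p, 0)
  expect_lt(max(abs(sim$S - st$S)), 1e-9)
  expect_lt(max(abs(sim$B - st$B)), 1e-9)
})

test_that("time steps beyond the stability bound are refused with a diagnosis", {
  m <- generate_square(20, 2)
  p <- bsw_preset("square")
  cfg <- integrator_config(dt = 0.05)
  expect_error(simulate_bsw(p, m, cfg, days = 1, fgf = "none"),
               "stability bound")
  expect_lt(dt_stability_bound(m, 160), 0.05)
})

test_that("growth runs remap all species onto each day's mesh", {
  dom <- small_fin_domain()
  p <- bsw_preset("fin")
  sim <- simulate_bsw(p, dom$growth_map, fin_config(), seed = 1)
  expect_length(sim$S, n_cells(dom$growth_map$meshes[[3]]))
  expect_true(all(is.finite(sim$S)))
  expect_equal(length(sim$snapshots), 3)
})
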