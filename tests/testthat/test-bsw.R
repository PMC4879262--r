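test_that("the origin is a fixed point without production", {
  p <- bsw_params(alpha_B = 0, alpha_W = 0)
  r <- reaction_rhs(0, 0, 0, p)
  expect_equal(unlist(r), c(dS = 0, dB = 0, dW = 0))
})

test_that("steady states satisfy the rate equations (residual oracle)", {
  p <- bsw_preset("fin")
  for (F in c(0, 0.3, 0.8)) {
    st <- steady_state(p, F)
    r <- reaction_rhs(st$S, st$B, st$W, p, F)
    expect_lt(max(abs(unlist(r))), 1e-12)
    expect_false(st$singular)
  }
})

test_that("steady states are linear in the production terms", {
  p <- bsw_preset("fin")
  st1 <- steady_state(p, 0.2)
  p2 <- p; p2$alpha_B <- 2 * p$alpha_B; p2$alpha_W <- 2 * p$alpha_W
  st2 <- steady_state(p2, 0.2)
  expect_equal(c(st2$S, st2$B, st2$W), 2 * c(st1$S, st1$B, st1$W),
               tolerance = 1e-12)
  p0 <- p; p0$alpha_B <- 0; p0$alpha_W <- 0
  st0 <- steady_state(p0, 0.2)
  expect_equal(c(st0$S, st0$B, st0$W), c(0, 0, 0), tolerance = 1e-12)
})

test_that("the square preset is singular and gets a finite minimum-norm state", {
  p <- bsw_preset("square", alpha_B = 0.1, alpha_W = 1.2)
  st <- steady_state(p, 0)
  expect_true(st$singular)
  expect_true(all(is.finite(c(st$S, st$B, st$W))))
  expect_lt(max(abs(c(st$S, st$B, st$W))), 100)
})

test_that("FGF modulation is monotone and trivial at F = 0", {
  p <- bsw_preset("fin")
  k0 <- modulated_params(p, 0)
  expect_equal(k0$k4_eff, 6)
  expect_equal(k0$k7_eff, 2.4)
  Fs <- seq(0, 1, by = 0.1)
  k <- modulated_params(p, Fs)
  expect_true(all(diff(k$k4_eff) < 0))
  expect_true(all(diff(k$k7_eff) > 0))
  expect_error(bsw_params(k_F = 1.2), "k_F")
})

test_that("a Sox9 pulse represses both ligands locally (sign check)", {
  p <- bsw_preset("fin")
  r0 <- reaction_rhs(0, 1, 1, p, 0.5)
  r1 <- reaction_rhs(1, 1, 1, p, 0.5)
  expect_lt(r1$dB, r0$dB)
  expect_lt(r1$dW, r0$dW)
  expect_equal(r1$dS, r0$dS)   # S does not feed back on itself
})

test_that("perturbations scale the printed parameters", {
  p <- bsw_preset("fin")
  bmp <- apply_perturbation(p, perturbation("bmp_inhibition"))
  expect_equal(bmp$params$k2, p$k2 * 0.8)
  wnt <- apply_perturbation(p, perturbation("wnt_inhibition"))
  expect_equal(wnt$params$alpha_W, 0.6)
  fgf <- apply_perturbation(p, perturbation("fgf_inhibition"))
  expect_equal(fgf$fgf_scale, 0.6)
  ctl <- apply_perturbation(p, perturbation("control"))
  expect_identical(unclass(ctl$params), unclass(p))
  expect_error(perturbation("bmp_inhibition", 1.5), "magnitude")
})

test_that("the FGF gradient on a strip decays with length sqrt(D_F/mu_F)", {
  m <- strip_mesh(300, 10, 5)
  fg <- fgf_gradient(m)
  x <- m$centroids[, 1]
  sel <- x > 20 & x < 200        # away from the source and the far wall
  fit <- stats::lm(log(fg$raw[sel]) ~ x[sel])
  ell <- -1 / stats::coef(fit)[2]
  expect_lt(abs(ell - sqrt(6000)) / sqrt(6000), 0.05)
  expect_equal(max(fg$F), 1)
  expect_gte(min(fg$F), 0)
})

test_that("the square-domain gradient is exp(-3x) at centroids", {
  m <- generate_square(50, 5)
  p <- bsw_preset("square")
  cfg <- integrator_config(noise_sd = 0, t_per_day = 0.002)
  sim <- simulate_bsw(p, m, cfg, days = 1, fgf = "exp3x", seed = 1)
  x <- m$centroids[, 1] / 50
  expect_equal(sim$F, exp(-3 * x), tolerance = 1e-12)
})

test_that("gradients require a distal-tagged source arc", {
  m <- two_tri_mesh()
  expect_error(fgf_gradient(m), "distal")
})
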