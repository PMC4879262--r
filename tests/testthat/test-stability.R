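test_that("without diffusion the growth rate is flat in k^2", {
  p <- bsw_preset("fin")
  A <- bsw_jacobian(p, 0.5)
  d <- dispersion(A, c(0, 0, 0), c(0, 0.01, 1, 100))
  expect_equal(diff(range(d$sigma_max)), 0, tolerance = 1e-9)
  expect_false(d$turing)
})

test_that("cubic eigenvalues agree with an independent characteristic-polynomial oracle", {
  set.seed(10)
  for (i in 1:25) {
    A <- matrix(stats::rnorm(9), 3, 3)
    D <- c(0, stats::runif(1, 1, 200), stats::runif(1, 1, 200))
    q <- stats::runif(1, 0, 1)
    M <- A - q * diag(D)
    # oracle: roots of det(lambda I - M) via polyroot
    cp <- c(-det(M),
            M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1] +
              M[1, 1] * M[3, 3] - M[1, 3] * M[3, 1] +
              M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2],
            -sum(diag(M)), 1)
    oracle <- max(Re(polyroot(cp)))
    d <- dispersion(A, D, c(0, q))
    expect_equal(d$sigma_max[d$k_squared == q], oracle, tolerance = 1e-9)
  }
})

test_that("pure decay without cross-loops is stable, not Turing", {
  p <- bsw_params(k2 = 0, k3 = 0, k4 = 0, k7 = 0, k5 = 0.2, k9 = 0.2)
  v <- is_turing(p)
  expect_false(v$turing)
  expect_lte(v$dispersion$sigma0, 1e-9)   # Sox9 itself has no decay term
  # a broken Sox9->Bmp loop can never be Turing (closed form agrees)
  p2 <- bsw_params(k2 = 1, k3 = 1, k4 = 0, k7 = 1)
  expect_false(closed_form_condition(p2))
  expect_false(is_turing(p2)$turing)
})

test_that("the square preset is Turing unstable and its verdict ignores production", {
  p <- bsw_preset("square", alpha_B = 0.3, alpha_W = 1.7)
  v <- is_turing(p)
  expect_true(v$turing)
  p2 <- bsw_preset("square", alpha_B = 1.4, alpha_W = 0.2)
  expect_identical(is_turing(p2)$turing, v$turing)
  expect_true(closed_form_condition(p))
})

test_that("the fin FGF path enters and exits the Turing space", {
  p <- bsw_preset("fin")
  v <- fgf_path_verdicts(p)
  expect_identical(rle(v$turing)$values, c(FALSE, TRUE, FALSE))
  vn <- fgf_path_verdicts(p, n_F = 21, method = "numeric")
  vc <- fgf_path_verdicts(p, n_F = 21, method = "closed_form")
  expect_identical(vn$turing, vc$turing)
  expect_true(check_fgf_traversal(p))
})

test_that("closed form and dispersion agree on random constrained points", {
  set.seed(99)
  n <- 200
  dis <- 0
  for (i in seq_len(n)) {
    p <- random_constrained_params()
    a <- closed_form_condition(p)
    b <- is_turing(p, n = 200)$turing
    if (a != b) dis <- dis + 1
  }
  expect_lt(dis / n, 0.005)
})

test_that("the verdict is invariant to a global time rescaling", {
  p <- bsw_preset("fin")
  for (F in c(0.3, 0.6)) {
    p2 <- p; p2$beta <- p$beta * 5
    # scaling beta rescales A; scaling D by the same factor rescales time
    A1 <- bsw_jacobian(p, F); A2 <- bsw_jacobian(p2, F)
    d1 <- dispersion(A1, c(0, 160, 25), c(0, 10^seq(-4, 1, length.out = 100)))
    d2 <- dispersion(A2, 5 * c(0, 160, 25),
                     c(0, 10^seq(-4, 1, length.out = 100)))
    expect_identical(d1$turing, d2$turing)
  }
})

test_that("growth rates stay bounded by the non-diffusive branch at large k^2", {
  p <- bsw_preset("fin")
  A <- bsw_jacobian(p, 0.5)
  d <- dispersion(A, c(0, 160, 25), c(0, 10, 100, 1000, 1e4))
  n <- length(d$sigma_max)
  # with D_S = 0 the surviving branch tends to the S-diagonal entry (0 here)
  expect_lt(d$sigma_max[n], d$sigma_max[n - 1])
  # the surviving S-branch decays toward the S-diagonal entry (0) as 1/k^2
  expect_lte(d$sigma_max[n], A[1, 1] + 1e-2)
})

test_that("region scans respect linearity and the k3 sweep shifts the path distally", {
  base <- bsw_preset("square")
  sc <- turing_region_scan(base, "alpha_B", "alpha_W", c(0, 2), c(0, 2), n = 5)
  expect_equal(length(unique(as.vector(sc$turing))), 1)   # uniform grid
  # halving k3 from the fin value moves the Turing interval of the F path
  # toward higher F (the distal edge)
  p <- bsw_preset("fin")
  p2 <- p; p2$k3 <- p$k3 / 2
  v1 <- fgf_path_verdicts(p)
  v2 <- fgf_path_verdicts(p2)
  enter1 <- v1$F[which(diff(v1$turing) == 1) + 1]
  enter2 <- v2$F[which(diff(v2$turing) == 1) + 1]
  expect_gt(enter2, enter1)
})
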