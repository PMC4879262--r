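test_that("segmentation finds nothing below threshold and everything at -Inf", {
  m <- generate_square(10, 1)
  expect_length(segment(rep(1, n_cells(m)), m, segment_rule(ref = 5)), 0)
  comps <- segment(rep(1, n_cells(m)), m, segment_rule(ref = -100, level = 0))
  expect_length(comps, 1)
  expect_length(comps[[1]], n_cells(m))
  expect_error(segment(rep(NA_real_, n_cells(m)), m), "NA")
})

test_that("two painted patches give two components with known cell counts", {
  m <- generate_square(20, 1)
  f <- numeric(n_cells(m))
  left <- which(m$centroids[, 1] < 3 & m$centroids[, 2] < 3)
  right <- which(m$centroids[, 1] > 17 & m$centroids[, 2] > 17)
  f[left] <- 1; f[right] <- 1
  comps <- segment(f, m, segment_rule(ref = 0, level = 0.5))
  expect_length(comps, 2)
  expect_setequal(unlist(comps), c(left, right))
})

test_that("raising the threshold never increases the segmented area", {
  m <- generate_square(30, 2)
  set.seed(5)
  f <- stats::rnorm(n_cells(m))
  areas <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(lev) {
    comps <- segment(f, m, segment_rule(ref = 0, level = lev, min_cells = 1))
    sum(m$areas[unlist(comps)])
  }, 0)
  expect_true(all(diff(areas) <= 1e-12))
})

test_that("radial bumps classify as spots and parallel bands as stripes", {
  m <- generate_square(60, 2)
  x <- m$centroids[, 1]; y <- m$centroids[, 2]
  centres <- as.matrix(expand.grid(c(10, 30, 50), c(10, 30, 50)))
  bumps <- Reduce(`+`, lapply(seq_len(nrow(centres)), function(i)
    exp(-((x - centres[i, 1])^2 + (y - centres[i, 2])^2) / 8)))
  cb <- classify(bumps, m, segment_rule(ref = 0, level = 0.5))
  expect_identical(cb$pattern_class, "spots")
  expect_lt(cb$median_elongation, 1.5)

  bands <- sin(2 * pi * x / 20)
  cs <- classify(bands, m, segment_rule(ref = 0, level = 0.5))
  expect_identical(cs$pattern_class, "stripes")
  expect_gt(cs$median_elongation, 2.5)

  blob <- exp(-((x - 30)^2 + (y - 30)^2) / 50)
  expect_identical(classify(blob, m, segment_rule(ref = 0))$pattern_class,
                   "mixed")
})

test_that("distal distances match the analytic point-segment distance", {
  m <- generate_square(20, 1)   # distal edge at x = 0
  f <- numeric(n_cells(m))
  cells <- which(abs(m$centroids[, 1] - 10.5) < 1 &
                   abs(m$centroids[, 2] - 10.5) < 1)
  f[cells] <- 1
  cl <- classify(f, m, segment_rule(ref = 0, level = 0.5))
  expect_equal(cl$components[[1]]$distal_distance,
               cl$components[[1]]$centroid[1], tolerance = 1e-9)
  # on-edge component
  f2 <- numeric(n_cells(m))
  f2[which(m$centroids[, 1] < 1 & abs(m$centroids[, 2] - 10) < 2)] <- 1
  cl2 <- classify(f2, m, segment_rule(ref = 0, level = 0.5))
  expect_lt(cl2$components[[1]]$distal_distance, 1)
})

test_that("metrics are invariant under rigid motions", {
  ser <- generate_fin_series(2, seed = 1)
  m <- triangulate(ser$outlines[[1]], 4)
  set.seed(8)
  f <- stats::rnorm(n_cells(m))
  cl <- classify(f, m, segment_rule(ref = 0, level = 0.3))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m2 <- m
  m2$vertices <- sweep(m$vertices %*% R, 2, c(5, -3), "+")
  m2$centroids <- sweep(m$centroids %*% R, 2, c(5, -3), "+")
  cl2 <- classify(f, m2, segment_rule(ref = 0, level = 0.3))
  expect_equal(cl2$n_components, cl$n_components)
  expect_equal(cl2$median_elongation, cl$median_elongation, tolerance = 1e-6)
  expect_equal(sort(cl2$areas), sort(cl$areas), tolerance = 1e-9)
})

test_that("phase overlap is +1 on itself and -1 on its mirror", {
  m <- generate_square(20, 2)
  set.seed(2)
  S <- stats::rnorm(n_cells(m))
  expect_equal(phase_overlap(S, S, m), 1, tolerance = 1e-12)
  expect_equal(phase_overlap(S, 5 - S, m), -1, tolerance = 1e-12)
  expect_error(phase_overlap(S, rep(1, n_cells(m)), m), "variance")
})

test_that("separation time finds the first arrival at the final count", {
  expect_equal(separation_time(c(1, 1, 4, 6, 6, 6), 1:6), 4)
  expect_equal(separation_time(c(6, 6, 6), 1:3), 1)
  expect_true(is.na(separation_time(c(0, 0, 0), 1:3)))
  # invariant to subsampling that preserves the transition
  expect_equal(separation_time(c(1, 4, 6, 6, 6), c(1, 3, 4, 5, 6)), 4)
})
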