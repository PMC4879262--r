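test_that("interpolating identical outlines returns identical outlines", {
  ser <- generate_fin_series(2, seed = 1)
  ol <- ser$outlines[[1]]
  ol2 <- ol; ol2$stage_time <- 2
  same <- structure(list(outlines = list(ol, ol2)), class = "outline_series")
  daily <- interpolate_series(same, 1)
  expect_length(daily$outlines, 3)
  for (o in daily$outlines)
    expect_equal(o$points, ol$points, tolerance = 1e-9)
})

test_that("midpoint of two scaled copies has the 1.5x area (shoelace oracle)", {
  spec <- growth_spec(length_factor = 2, anterior_factor = 2,
                      posterior_factor = 2)
  ser <- generate_fin_series(2, spec, seed = 1, jitter_sd = 0)
  half <- interpolate_series(ser, 0.5)
  a0 <- abs(polygon_area(ser$outlines[[1]]$points))
  amid <- abs(polygon_area(half$outlines[[2]]$points))
  expect_equal(amid, a0 * 1.5^2, tolerance = 0.01)
})

test_that("interpolation at daily resolution returns one outline per day", {
  ser <- generate_fin_series(6, seed = 1)
  sub <- structure(list(outlines = ser$outlines[c(1, 6)]),
                   class = "outline_series")
  daily <- interpolate_series(sub, 1)
  expect_length(daily$outlines, 6)
  expect_equal(vapply(daily$outlines, function(o) o$stage_time, 0), 0:5)
})

test_that("deforming a mesh onto its own outline is the identity", {
  ser <- generate_fin_series(2, seed = 1)
  m <- triangulate(ser$outlines[[1]], 5)
  pos <- deform_mesh(m, m$outline)
  expect_equal(pos, m$vertices, tolerance = 1e-9)
})

test_that("deformation to a scaled outline scales all triangle areas by s^2", {
  ser <- generate_fin_series(2, seed = 1, jitter_sd = 0)
  m <- triangulate(ser$outlines[[1]], 5)
  s <- 1.3
  target <- m$outline
  target$points <- target$points * s
  pos <- deform_mesh(m, target)
  t <- m$triangles
  newareas <- abs((pos[t[, 2], 1] - pos[t[, 1], 1]) *
                    (pos[t[, 3], 2] - pos[t[, 1], 2]) -
                    (pos[t[, 2], 2] - pos[t[, 1], 2]) *
                    (pos[t[, 3], 1] - pos[t[, 1], 1])) / 2
  expect_equal(newareas, m$areas * s^2, tolerance = 0.01)
})

test_that("deformation to a translated outline is a rigid translation (offset oracle)", {
  ser <- generate_fin_series(2, seed = 1)
  m <- triangulate(ser$outlines[[1]], 5)
  target <- m$outline
  target$points <- sweep(target$points, 2, c(3, -2), "+")
  pos <- deform_mesh(m, target)
  expect_equal(pos, sweep(m$vertices, 2, c(3, -2), "+"), tolerance = 1e-6)
})

test_that("transfer between identical meshes is the identity matrix", {
  m <- triangulate(generate_fin_series(2, seed = 1)$outlines[[1]], 6)
  T <- compute_transfer(m$vertices, m$triangles, m)
  expect_equal(Matrix::diag(T), rep(1, n_cells(m)), tolerance = 1e-9)
  expect_equal(max(abs(T - Matrix::Diagonal(n_cells(m)))), 0,
               tolerance = 1e-9)
})

test_that("exact clipping splits a bisected triangle 50/50", {
  src_v <- rbind(c(0, 0), c(1, 0), c(0, 1))
  src_t <- matrix(c(1, 2, 3), 1)
  dst <- trimesh(rbind(c(0, 0), c(1, 0), c(0, 1), c(0.5, 0.5)),
                 rbind(c(1, 2, 4), c(1, 4, 3)))
  T <- compute_transfer(src_v, src_t, dst)
  expect_equal(as.numeric(T[1, ]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("transfer rows sum to one on deformed growth intervals", {
  gm <- small_fin_domain()$growth_map
  for (T in gm$transfers)
    expect_lt(max(abs(Matrix::rowSums(T) - 1)), 1e-6)
})

test_that("remap preserves constants, bounds and mass", {
  src_v <- rbind(c(0, 0), c(1, 0), c(0, 1))
  src_t <- matrix(c(1, 2, 3), 1)
  dst <- trimesh(rbind(c(0, 0), c(1, 0), c(0, 1), c(0.5, 0.5)),
                 rbind(c(1, 2, 4), c(1, 4, 3)))
  T <- compute_transfer(src_v, src_t, dst)
  out <- remap(7.5, T, areas_old = 0.5)
  expect_equal(out, c(7.5, 7.5), tolerance = 1e-9)

  gm <- small_fin_domain()$growth_map
  T1 <- gm$transfers[[1]]
  set.seed(42)
  f <- stats::runif(n_cells(gm$meshes[[1]]), 0, 3)
  out <- remap(f, T1)
  mass_in <- sum(f * gm$meshes[[1]]$areas)
  mass_out <- sum(out * gm$meshes[[2]]$areas)
  expect_lt(abs(mass_out - mass_in) / mass_in, 1e-6)
  # no overshoot beyond the (dilution-scaled) input range
  expect_lte(max(out), max(f) + 1e-9)
  expect_gte(min(out), 0)
  expect_error(remap(c(f[-1], NaN), T1), "non-finite")
})

test_that("remap is linear and positivity-preserving on random fields", {
  gm <- small_fin_domain()$growth_map
  T1 <- gm$transfers[[1]]
  set.seed(1)
  f <- stats::runif(n_cells(gm$meshes[[1]]))
  g <- stats::runif(n_cells(gm$meshes[[1]]))
  lhs <- remap(2 * f + 3 * g, T1)
  rhs <- 2 * remap(f, T1) + 3 * remap(g, T1)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_true(all(remap(f, T1) >= 0))
})

test_that("virtual dye is conserved and static maps leave it unchanged", {
  dom <- small_fin_domain()
  fm <- virtual_fate_map(dom$growth_map, label = 1:5)
  drift <- abs(fm$total - fm$total[1]) / fm$total[1]
  expect_true(all(drift < 1e-6))
  expect_true(all(unlist(fm$dye) >= 0))
})

test_that("posterior dye displaces farther than anterior dye", {
  dom <- small_fin_domain()
  gm <- dom$growth_map
  m1 <- gm$meshes[[1]]
  # labels near the anterior and posterior base corners
  ant <- order(-m1$centroids[, 2] + m1$centroids[, 1])[1:4]
  post <- order(m1$centroids[, 2] + m1$centroids[, 1])[1:4]
  fa <- virtual_fate_map(gm, ant)
  fp <- virtual_fate_map(gm, post)
  disp <- function(fm) sqrt(sum((fm$centroid[nrow(fm$centroid), ] -
                                   fm$centroid[1, ])^2))
  expect_gt(disp(fp), disp(fa))
})
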