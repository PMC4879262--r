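test_that("isotropic growth produces scaled copies with squared area ratio", {
  spec <- growth_spec(length_factor = 1.2, anterior_factor = 1.2,
                      posterior_factor = 1.2)
  ser <- generate_fin_series(3, spec, seed = 1, jitter_sd = 0)
  a <- vapply(ser$outlines, function(o) abs(polygon_area(o$points)), 0)
  expect_equal(a[2] / a[1], 1.2^2, tolerance = 1e-10)
  expect_equal(a[3] / a[1], 1.2^4, tolerance = 1e-10)
  # scaled copies: points proportional
  expect_equal(ser$outlines[[2]]$points, 1.2 * ser$outlines[[1]]$points,
               tolerance = 1e-10)
})

test_that("fin series generation is deterministic under a fixed seed", {
  s1 <- generate_fin_series(4, seed = 7)
  s2 <- generate_fin_series(4, seed = 7)
  expect_identical(s1$outlines[[4]]$points, s2$outlines[[4]]$points)
  s3 <- generate_fin_series(4, seed = 8)
  expect_false(identical(s1$outlines[[4]]$points, s3$outlines[[4]]$points))
})

test_that("posterior boundary expands faster than anterior (brute-force displacement)", {
  ser <- generate_fin_series(4, seed = 2)
  # brute-force per-point displacement between consecutive stages, split by
  # the sign of the y coordinate (anterior > 0, posterior < 0)
  for (k in 1:3) {
    p0 <- ser$outlines[[k]]$points
    p1 <- ser$outlines[[k + 1]]$points
    disp <- sqrt(rowSums((p1 - p0)^2))
    post <- mean(disp[p0[, 2] < -1])
    ant <- mean(disp[p0[, 2] > 1])
    expect_gt(post, ant)
  }
})

test_that("series areas are non-decreasing and outlines simple", {
  ser <- generate_fin_series(6, seed = 1)
  a <- vapply(ser$outlines, function(o) abs(polygon_area(o$points)), 0)
  expect_true(all(diff(a) > 0))
  for (o in ser$outlines) expect_true(is_simple_polygon(o$points))
})

test_that("degenerate growth specs are rejected", {
  expect_error(growth_spec(anterior_factor = 1.3, posterior_factor = 1.1),
               "posterior")
  expect_error(generate_fin_series(1), "n_stages")
})

test_that("square mesh has the right area, tags and manifold structure", {
  m <- generate_square(1, 0.5)
  expect_gte(n_cells(m), 2)
  expect_equal(sum(m$areas), 1, tolerance = 0.005)
  # every interior edge has exactly two incident triangles (by construction
  # of the edge table: cell2 is NA only on the boundary)
  e <- m$edges
  expect_true(all(!is.na(e$cell1)))
  expect_true(all(table(c(e$cell1, e$cell2[!is.na(e$cell2)])) >= 1))
  expect_true(any(e$tag == "distal", na.rm = TRUE))
  # distal edges all on x = 0
  d <- which(!is.na(e$tag) & e$tag == "distal")
  expect_true(all(m$vertices[e$v1[d], 1] < 1e-9))
  expect_error(generate_square(1, 2), "degenerate")
})

test_that("square triangle count matches the structured-grid counting oracle", {
  m <- generate_square(200, 5)
  oracle <- 2 * (200 / 5)^2
  expect_lt(abs(n_cells(m) - oracle) / oracle, 0.2)
})

test_that("triangulation covers the outline area at all refinements (shoelace oracle)", {
  ser <- generate_fin_series(3, seed = 3)
  ol <- ser$outlines[[3]]
  shoelace <- abs(polygon_area(ol$points))
  errs <- vapply(c(8, 4), function(h) {
    m <- triangulate(ol, h)
    abs(sum(m$areas) - abs(polygon_area(m$outline$points))) /
      abs(polygon_area(m$outline$points))
  }, 0)
  expect_true(all(errs < 0.005))
  # resampled-outline area approaches the source polygon area
  m <- triangulate(ol, 4)
  expect_equal(sum(m$areas), shoelace, tolerance = 0.01)
})

test_that("triangulated fin meshes carry contiguous distal tags and good angles", {
  ser <- generate_fin_series(3, seed = 1)
  m <- triangulate(ser$outlines[[3]], 5)
  e <- m$edges
  boundary <- is.na(e$cell2)
  expect_true(all(!is.na(e$tag[boundary])))
  expect_true(any(e$tag[boundary] == "distal"))
  # distal boundary edges form one contiguous chain: vertex degree in the
  # distal subgraph is <= 2 and exactly two endpoints have degree 1
  d <- which(boundary & e$tag == "distal")
  deg <- table(c(e$v1[d], e$v2[d]))
  expect_true(all(deg <= 2))
  expect_equal(sum(deg == 1), 2)
  expect_gt(min(min_angles(m)), 20)
})

test_that("outline CSV round-trips points, tags and anchors", {
  ser <- generate_fin_series(2, seed = 5)
  ol <- ser$outlines[[1]]
  f <- tempfile(fileext = ".csv")
  write_outline_csv(ol, f)
  back <- read_outline_csv(f)
  expect_equal(back$points, ol$points, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$distal_arc, ol$distal_arc)
  expect_equal(back$anterior_anchor, ol$anterior_anchor)
})
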