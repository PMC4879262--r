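# shared fixtures, built in code

# unit square split along the diagonal: two right triangles
two_tri_mesh <- function() {
  trimesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
          rbind(c(1, 2, 3), c(1, 3, 4)))
}

# structured rectangular strip mesh with the x = 0 edge tagged distal
strip_mesh <- function(lx, ly, h) {
  nx <- max(2L, round(lx / h)); ny <- max(1L, round(ly / h))
  xs <- seq(0, lx, length.out = nx + 1); ys <- seq(0, ly, length.out = ny + 1)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  id <- function(i, j) (j - 1L) * (nx + 1L) + i
  tris <- matrix(0L, 2 * nx * ny, 3)
  k <- 1L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    tris[k, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)); k <- k + 1L
    tris[k, ] <- c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)); k <- k + 1L
  }
  tagger <- function(a, b) {
    if (grid[a, 1] < 1e-9 && grid[b, 1] < 1e-9) "distal" else "lateral"
  }
  trimesh(grid, tris, boundary_tags = tagger)
}

# small fin growth domain shared across experiment tests (cached)
small_fin_domain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fin_domain()
    cache
  }
})

# random constrained BSW parameter point (k5 = k9, D_S = 0)
random_constrained_params <- function() {
  bsw_params(beta = stats::runif(1, 0.5, 8),
             k2 = stats::runif(1, 0.1, 4), k3 = stats::runif(1, 0.1, 4),
             k4 = stats::runif(1, 0.1, 8), k7 = stats::runif(1, 0.1, 4),
             k5 = (k59 <- stats::runif(1, 0.05, 0.5)), k9 = k59)
}
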