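# Triangular meshes ------------------------------------------------------

#' Build a triangular mesh object
#'
#' Computes areas, centroids and the edge adjacency used by the finite-volume
#' operator. Interior edges store the shared-edge length and the distance
#' between the centroids of the two incident triangles; boundary edges carry
#' a tag (\code{distal} for the AER-analogue source arc, \code{lateral}
#' otherwise).
#'
#' @param vertices V x 2 coordinate matrix.
#' @param triangles T x 3 matrix of vertex indices (1-based).
#' @param boundary_tags optional named assignment of boundary edges: a
#'   function(v1, v2) -> tag, or a character tag applied to all boundary
#'   edges. Defaults to \code{"lateral"}.
#' @param boundary_param optional numeric vector, one entry per vertex:
#'   normalized arc-length position of boundary vertices on the source
#'   outline (NA for interior vertices). Used by mesh deformation.
#' @param outline the source \code{fin_outline}, if any.
#' @return an object of class \code{trimesh}.
#' @export
trimesh <- function(vertices, triangles, boundary_tags = "lateral",
                    boundary_param = NULL, outline = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  nt <- nrow(triangles)
  ax <- vertices[triangles[, 1], 1]; ay <- vertices[triangles[, 1], 2]
  bx <- vertices[triangles[, 2], 1]; by <- vertices[triangles[, 2], 2]
  cx <- vertices[triangles[, 3], 1]; cy <- vertices[triangles[, 3], 2]
  signed <- ((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
  flip <- signed < 0
  if (any(flip)) {   # enforce counter-clockwise orientation
    tmp <- triangles[flip, 2]
    triangles[flip, 2] <- triangles[flip, 3]
    triangles[flip, 3] <- tmp
    signed <- abs(signed)
  }
  if (any(signed <= 0)) stop("degenerate mesh: zero-area triangle")
  centroids <- cbind((ax + bx + cx) / 3, (ay + by + cy) / 3)

  # edge table: each triangle contributes 3 edges keyed by sorted vertex pair
  e1 <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  tri_of <- rep(seq_len(nt), 3)
  key_lo <- pmin(e1[, 1], e1[, 2])
  key_hi <- pmax(e1[, 1], e1[, 2])
  key <- paste(key_lo, key_hi)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  cnt <- tabulate(idx)
  if (any(cnt > 2)) stop("non-manifold mesh: edge shared by > 2 triangles")
  ne <- sum(first)
  c1 <- rep(NA_integer_, ne); c2 <- rep(NA_integer_, ne)
  ord <- order(idx)
  for (k in ord) {
    e <- idx[k]
    if (is.na(c1[e])) c1[e] <- tri_of[k] else c2[e] <- tri_of[k]
  }
  v1 <- key_lo[first]; v2 <- key_hi[first]
  elen <- sqrt(rowSums((vertices[v1, , drop = FALSE] -
                        vertices[v2, , drop = FALSE])^2))
  interior <- !is.na(c2)
  cdist <- rep(NA_real_, ne)
  cdist[interior] <- sqrt(rowSums((centroids[c1[interior], , drop = FALSE] -
                                   centroids[c2[interior], , drop = FALSE])^2))
  if (any(interior & cdist < 1e-12, na.rm = TRUE))
    stop("degenerate mesh: coincident centroids")
  tag <- rep(NA_character_, ne)
  if (is.function(boundary_tags)) {
    tag[!interior] <- mapply(boundary_tags, v1[!interior], v2[!interior])
  } else {
    tag[!interior] <- boundary_tags
  }
  structure(list(vertices = vertices, triangles = triangles,
                 areas = signed, centroids = centroids,
                 edges = data.frame(v1 = v1, v2 = v2, cell1 = c1, cell2 = c2,
                                    length = elen, cdist = cdist, tag = tag,
                                    stringsAsFactors = FALSE),
                 boundary_param = boundary_param, outline = outline),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d triangles, area %.3f, %d distal edges\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas),
              sum(x$edges$tag == "distal", na.rm = TRUE)))
  invisible(x)
}

#' Number of triangles of a mesh
#' @param mesh a \code{trimesh}.
#' @export
n_cells <- function(mesh) nrow(mesh$triangles)

# interior-edge arrays for the finite-volume kernels
fvm_edges <- function(mesh) {
  e <- mesh$edges
  i <- !is.na(e$cell2)
  list(ei = e$cell1[i], ej = e$cell2[i], w = e$length[i] / e$cdist[i])
}

#' Triangles adjacent to distal-tagged boundary edges
#' @param mesh a \code{trimesh}.
#' @return integer vector of triangle indices.
#' @export
distal_cells <- function(mesh) {
  e <- mesh$edges
  unique(e$cell1[!is.na(e$tag) & e$tag == "distal"])
}

#' Minimum interior angle of each triangle (degrees)
#' @param mesh a \code{trimesh}.
#' @export
min_angles <- function(mesh) {
  v <- mesh$vertices; t <- mesh$triangles
  ang <- function(p, q, r) {
    u <- q - p; w <- r - p
    acos(pmin(1, pmax(-1, rowSums(u * w) /
                        sqrt(rowSums(u^2) * rowSums(w^2))))) * 180 / pi
  }
  a <- v[t[, 1], , drop = FALSE]
  b <- v[t[, 2], , drop = FALSE]
  c <- v[t[, 3], , drop = FALSE]
  pmin(ang(a, b, c), ang(b, c, a), ang(c, a, b))
}

#' Generate a structured triangulated square domain
#'
#' The left edge (x = 0) is tagged \code{distal} so that a gradient source
#' placed there decays rightward, matching the square-domain simulations
#' where the morphogen profile is exp(-3x).
#'
#' @param side side length (model units).
#' @param resolution target edge length; must be smaller than \code{side}.
#' @export
generate_square <- function(side, resolution) {
  if (resolution >= side) stop("degenerate mesh: resolution >= side length")
  stopifnot(side > 0)
  n <- max(2L, round(side / resolution))
  xs <- seq(0, side, length.out = n + 1)
  grid <- as.matrix(expand.grid(x = xs, y = xs))
  id <- function(i, j) (j - 1L) * (n + 1L) + i   # column-major in x
  tris <- matrix(0L, 2 * n * n, 3)
  k <- 1L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    p00 <- id(i, j); p10 <- id(i + 1L, j)
    p01 <- id(i, j + 1L); p11 <- id(i + 1L, j + 1L)
    tris[k, ] <- c(p00, p10, p11); k <- k + 1L
    tris[k, ] <- c(p00, p11, p01); k <- k + 1L
  }
  tagger <- function(a, b) {
    if (grid[a, 1] < 1e-9 && grid[b, 1] < 1e-9) "distal" else "lateral"
  }
  trimesh(grid, tris, boundary_tags = tagger)
}

# distance from points to a closed polyline (minimum over segments)
dist_to_polyline <- function(pts, poly) {
  n <- nrow(poly)
  b <- poly[c(2:n, 1), , drop = FALSE]
  d2 <- rep(Inf, nrow(pts))
  for (s in seq_len(n)) {
    ex <- b[s, 1] - poly[s, 1]; ey <- b[s, 2] - poly[s, 2]
    L2 <- ex^2 + ey^2
    tt <- ((pts[, 1] - poly[s, 1]) * ex + (pts[, 2] - poly[s, 2]) * ey) /
      max(L2, 1e-300)
    tt <- pmin(1, pmax(0, tt))
    dx <- poly[s, 1] + tt * ex - pts[, 1]
    dy <- poly[s, 2] + tt * ey - pts[, 2]
    d2 <- pmin(d2, dx^2 + dy^2)
  }
  sqrt(d2)
}

#' Triangulate a fin-bud outline
#'
#' The boundary is resampled to the target edge length, interior points are
#' laid on a hexagonal lattice (clipped away from the boundary), and the
#' point set is Delaunay-triangulated; triangles outside the outline are
#' discarded. Boundary edges inherit distal/lateral tags from the outline's
#' distal arc, and boundary vertices store their normalized arc-length
#' position for later deformation.
#'
#' @param outline a \code{fin_outline} (simple, closed).
#' @param target_edge target edge length (model units).
#' @export
triangulate <- function(outline, target_edge) {
  ol <- resample_outline(outline, target_edge)
  bpts <- ol$points
  nb <- nrow(bpts)
  # normalized arc-length parameter of boundary points
  seg <- sqrt(rowSums((bpts[c(2:nb, 1), ] - bpts)^2))
  sfrac <- c(0, cumsum(seg))[1:nb] / sum(seg)
  # hexagonal interior lattice
  h <- target_edge
  xr <- range(bpts[, 1]); yr <- range(bpts[, 2])
  ys <- seq(yr[1], yr[2], by = h * sqrt(3) / 2)
  ipts <- do.call(rbind, lapply(seq_along(ys), function(r) {
    off <- if (r %% 2 == 0) h / 2 else 0
    xs <- seq(xr[1] + off, xr[2], by = h)
    cbind(xs, ys[r])
  }))
  keep <- cpp_point_in_poly(ipts, bpts) & dist_to_polyline(ipts, bpts) > 0.55 * h
  pts <- rbind(bpts, ipts[keep, , drop = FALSE])
  tris <- cpp_delaunay(pts)
  cen <- (pts[tris[, 1], ] + pts[tris[, 2], ] + pts[tris[, 3], ]) / 3
  inside <- cpp_point_in_poly(cen, bpts)
  tris <- tris[inside, , drop = FALSE]
  is_distal_pt <- rep(FALSE, nrow(pts))
  is_distal_pt[ol$distal_arc] <- TRUE
  tagger <- function(a, b) {
    if (a <= nb && b <= nb && is_distal_pt[a] && is_distal_pt[b])
      "distal" else "lateral"
  }
  bp <- rep(NA_real_, nrow(pts))
  bp[seq_len(nb)] <- sfrac
  m <- trimesh(pts, tris, boundary_tags = tagger, boundary_param = bp,
               outline = ol)
  poly_a <- abs(polygon_area(bpts))
  if (abs(sum(m$areas) - poly_a) / poly_a > 0.005)
    stop("meshing failure: mesh area deviates from outline area by > 0.5%")
  m
}
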