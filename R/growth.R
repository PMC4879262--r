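# Growth maps: interpolated shapes, mesh deformation, conservative transfer

# split an outline's boundary into the two anchor-to-anchor chains, each with
# normalized in-chain arc-length fractions. Chain 1 runs posterior -> anterior
# (through the distal arc), chain 2 anterior -> posterior (the base).
outline_chains <- function(ol) {
  n <- nrow(ol$points)
  fwd <- function(from, to) {
    if (from <= to) from:to else c(from:n, 1:to)
  }
  i1 <- fwd(ol$posterior_anchor, ol$anterior_anchor)
  i2 <- fwd(ol$anterior_anchor, ol$posterior_anchor)
  mk <- function(idx) {
    p <- ol$points[idx, , drop = FALSE]
    s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
    list(idx = idx, pts = p, frac = s / s[length(s)])
  }
  list(mk(i1), mk(i2))
}

# evaluate a chain polyline at given normalized fractions
eval_chain <- function(chain, fr) {
  cbind(stats::approx(chain$frac, chain$pts[, 1], xout = fr, rule = 2)$y,
        stats::approx(chain$frac, chain$pts[, 2], xout = fr, rule = 2)$y)
}

# match outline b onto outline a's points by anchored arc length: returns a
# matrix of positions on b corresponding 1:1 to a's points.
match_outline <- function(a, b) {
  ca <- outline_chains(a); cb <- outline_chains(b)
  out <- matrix(NA_real_, nrow(a$points), 2)
  for (k in 1:2) {
    pos <- eval_chain(cb[[k]], ca[[k]]$frac)
    out[ca[[k]]$idx, ] <- pos
  }
  out
}

#' Interpolate an outline series to fine temporal resolution
#'
#' Produces an outline at every multiple of \code{step_days} between the
#' first and last stage by linear interpolation of boundary points matched by
#' anchored, normalized arc length. Key-stage outlines are reproduced
#' exactly.
#'
#' @param series an \code{outline_series}.
#' @param step_days temporal resolution in days (default 1, as in the fin
#'   growth model).
#' @export
interpolate_series <- function(series, step_days = 1) {
  ols <- series$outlines
  stopifnot(length(ols) >= 2, step_days > 0)
  times <- vapply(ols, function(o) o$stage_time, 0)
  if (any(diff(times) <= 0)) stop("stage times must be strictly increasing")
  tout <- seq(times[1], times[length(times)], by = step_days)
  res <- vector("list", length(tout))
  for (q in seq_along(tout)) {
    t <- tout[q]
    k <- findInterval(t, times, rightmost.closed = TRUE)
    if (abs(t - times[k]) < 1e-9) { res[[q]] <- ols[[k]]; next }
    a <- ols[[k]]; b <- ols[[k + 1]]
    w <- (t - times[k]) / (times[k + 1] - times[k])
    pb <- match_outline(a, b)
    pts <- (1 - w) * a$points + w * pb
    res[[q]] <- fin_outline(pts, stage_time = t, distal_arc = a$distal_arc,
                            anterior_anchor = a$anterior_anchor,
                            posterior_anchor = a$posterior_anchor)
  }
  structure(list(outlines = res), class = "outline_series")
}

#' Deform a mesh to match a target outline
#'
#' Boundary vertices are mapped onto the target by anchored normalized arc
#' length; interior vertices follow by harmonic interpolation of the boundary
#' displacement (a graph-Laplacian Dirichlet solve), which keeps the convex
#' fin shapes free of inverted triangles.
#'
#' @param mesh a \code{trimesh} built by \code{\link{triangulate}} (it must
#'   carry its source outline and boundary parameters).
#' @param target the target \code{fin_outline}.
#' @return V x 2 matrix of new vertex positions.
#' @export
deform_mesh <- function(mesh, target) {
  if (is.null(mesh$outline) || is.null(mesh$boundary_param))
    stop("mesh carries no outline/boundary parameterization")
  ol <- mesh$outline
  nb <- sum(!is.na(mesh$boundary_param))
  nv <- nrow(mesh$vertices)
  newpos <- mesh$vertices
  # boundary vertices are the first nb vertices (triangulate() convention)
  ca <- outline_chains(ol); cb <- outline_chains(target)
  bidx <- seq_len(nb)
  mapped <- matrix(NA_real_, nb, 2)
  for (k in 1:2) {
    on_chain <- intersect(ca[[k]]$idx, bidx)
    fr <- ca[[k]]$frac[match(on_chain, ca[[k]]$idx)]
    mapped[on_chain, ] <- eval_chain(cb[[k]], fr)
  }
  disp <- mapped - mesh$vertices[bidx, , drop = FALSE]
  # harmonic extension of boundary displacement to interior vertices
  interior <- setdiff(seq_len(nv), bidx)
  if (length(interior)) {
    # cotangent-weighted Laplacian (FEM stiffness): reproduces affine
    # deformations exactly, so pure scalings and translations are lossless
    t <- mesh$triangles
    v <- mesh$vertices
    cot_at <- function(a, b, c) {   # cot of angle at vertex a
      u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
      w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
      rowSums(u * w) / abs(u[, 1] * w[, 2] - u[, 2] * w[, 1])
    }
    ei <- c(t[, 1], t[, 2], t[, 3])
    ej <- c(t[, 2], t[, 3], t[, 1])
    wt <- 0.5 * c(cot_at(t[, 3], t[, 1], t[, 2]),
                  cot_at(t[, 1], t[, 2], t[, 3]),
                  cot_at(t[, 2], t[, 3], t[, 1]))
    Wm <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = c(wt, wt),
                               dims = c(nv, nv))
    L <- Matrix::Diagonal(x = Matrix::rowSums(Wm)) - Wm
    Lii <- L[interior, interior, drop = FALSE]
    Lib <- L[interior, bidx, drop = FALSE]
    di <- as.matrix(Matrix::solve(Lii, -Lib %*% disp))
    newpos[interior, ] <- newpos[interior, , drop = FALSE] + di
  }
  newpos[bidx, ] <- mapped
  # reject inversions
  tr <- mesh$triangles
  s <- (newpos[tr[, 2], 1] - newpos[tr[, 1], 1]) *
    (newpos[tr[, 3], 2] - newpos[tr[, 1], 2]) -
    (newpos[tr[, 2], 2] - newpos[tr[, 1], 2]) *
    (newpos[tr[, 3], 1] - newpos[tr[, 1], 1])
  if (any(s <= 0)) stop("deformation inverted triangles; reduce the growth step")
  newpos
}

#' Conservative transfer matrix between overlapping meshes
#'
#' Entry (i, j) is the fraction of deformed-source triangle i's area that
#' overlaps target triangle j, computed by exact convex polygon clipping.
#' Rows are renormalized to sum to one over the covered region; overlaps
#' below 1e-12 of the triangle area are dropped first.
#'
#' @param src_vertices deformed source vertex positions (V x 2).
#' @param src_triangles source triangle index matrix.
#' @param dst the target \code{trimesh}.
#' @param coverage_tol maximum allowed relative symmetric-difference area.
#' @return a sparse row-stochastic \code{Matrix} (source x target), with the
#'   deformed source areas attached as attribute \code{"src_areas"}.
#' @export
compute_transfer <- function(src_vertices, src_triangles, dst,
                             coverage_tol = 0.01) {
  ov <- cpp_tri_overlap(src_vertices, src_triangles, dst$vertices,
                        dst$triangles)
  t <- src_triangles
  sa <- abs((src_vertices[t[, 2], 1] - src_vertices[t[, 1], 1]) *
              (src_vertices[t[, 3], 2] - src_vertices[t[, 1], 2]) -
              (src_vertices[t[, 2], 2] - src_vertices[t[, 1], 2]) *
              (src_vertices[t[, 3], 1] - src_vertices[t[, 1], 1])) / 2
  keep <- ov$area > 1e-12 * sa[ov$i]
  M <- Matrix::sparseMatrix(i = ov$i[keep], j = ov$j[keep], x = ov$area[keep],
                            dims = c(nrow(src_triangles), n_cells(dst)))
  covered <- sum(M)
  tot <- sum(sa)
  if (abs(covered - tot) / tot > coverage_tol)
    stop("transfer coverage mismatch: meshes do not overlap within tolerance")
  rs <- Matrix::rowSums(M)
  if (any(rs <= 0)) stop("transfer: uncovered source triangle")
  T <- Matrix::Diagonal(x = 1 / rs) %*% M
  attr(T, "src_areas") <- sa
  T
}

#' Remap a per-triangle concentration field through a transfer matrix
#'
#' Each source triangle's amount (concentration times its pre-deformation
#' area) rides with the tissue through the deformation and is split over the
#' target triangles by the row-stochastic transfer matrix; target
#' concentrations are the received amounts divided by the target areas.
#' Total amount is conserved exactly; on a growing interval concentrations
#' dilute by the local area expansion, and on conforming meshes of the same
#' region constants are preserved to clipping precision.
#'
#' @param field per-triangle concentrations on the source mesh.
#' @param transfer matrix from \code{\link{compute_transfer}}.
#' @param areas_old pre-deformation source areas; defaults to the
#'   \code{"orig_areas"} attribute attached by \code{\link{build_growth_map}}
#'   (falling back to the deformed areas, i.e. no dilution).
#' @param areas_new target triangle areas; defaults to the covered areas
#'   implied by the transfer geometry.
#' @export
remap <- function(field, transfer, areas_old = NULL, areas_new = NULL) {
  if (any(!is.finite(field))) stop("non-finite concentration entering remap")
  if (is.null(areas_old))
    areas_old <- attr(transfer, "orig_areas") %||% attr(transfer, "src_areas")
  amt <- as.numeric(Matrix::crossprod(transfer, field * areas_old))
  if (is.null(areas_new))
    areas_new <- attr(transfer, "dst_areas") %||%
      as.numeric(Matrix::crossprod(transfer, attr(transfer, "src_areas")))
  amt / areas_new
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a growth map from an outline series
#'
#' Interpolates the series to daily resolution, meshes every outline,
#' deforms each day's mesh onto the next day's outline and computes the
#' conservative triangle-overlap transfer matrices.
#'
#' @param series an \code{outline_series}.
#' @param target_edge mesh edge length (model units).
#' @param step_days temporal resolution (default 1 day).
#' @return an object of class \code{growth_map} with fields \code{meshes},
#'   \code{deformed} (vertex positions per interval) and \code{transfers}.
#' @export
build_growth_map <- function(series, target_edge, step_days = 1) {
  daily <- interpolate_series(series, step_days)
  ols <- daily$outlines
  meshes <- lapply(ols, triangulate, target_edge = target_edge)
  nint <- length(ols) - 1
  deformed <- vector("list", nint)
  transfers <- vector("list", nint)
  for (k in seq_len(nint)) {
    deformed[[k]] <- deform_mesh(meshes[[k]], ols[[k + 1]])
    tr <- compute_transfer(deformed[[k]], meshes[[k]]$triangles,
                           meshes[[k + 1]])
    attr(tr, "orig_areas") <- meshes[[k]]$areas
    attr(tr, "dst_areas") <- meshes[[k + 1]]$areas
    transfers[[k]] <- tr
  }
  structure(list(meshes = meshes, deformed = deformed, transfers = transfers,
                 times = vapply(ols, function(o) o$stage_time, 0)),
            class = "growth_map")
}

#' @export
print.growth_map <- function(x, ...) {
  cat(sprintf("growth_map: %d stages (days %.0f..%.0f), %d--%d triangles\n",
              length(x$meshes), x$times[1], x$times[length(x$times)],
              n_cells(x$meshes[[1]]), n_cells(x$meshes[[length(x$meshes)]])))
  invisible(x)
}

#' Virtual fate map
#'
#' Labels a set of triangles with a passive dye (concentration one) at the
#' first stage and advances it through the growth map's deformations and
#' transfers, with no diffusion or reaction.
#'
#' @param gm a \code{growth_map}.
#' @param label integer vector of triangle indices on the first mesh.
#' @return a list with per-stage dye fields, amount-weighted centroids and
#'   total dye amounts.
#' @export
virtual_fate_map <- function(gm, label) {
  stopifnot(length(label) >= 1)
  dye <- numeric(n_cells(gm$meshes[[1]]))
  dye[label] <- 1
  nst <- length(gm$meshes)
  fields <- vector("list", nst)
  cents <- matrix(NA_real_, nst, 2)
  totals <- numeric(nst)
  for (s in seq_len(nst)) {
    if (s > 1) dye <- remap(dye, gm$transfers[[s - 1]])
    fields[[s]] <- dye
    m <- gm$meshes[[s]]
    amt <- dye * m$areas
    totals[s] <- sum(amt)
    cents[s, ] <- colSums(m$centroids * amt) / sum(amt)
  }
  structure(list(dye = fields, centroid = cents, total = totals),
            class = "fate_map")
}
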