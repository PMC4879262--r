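# Pattern quantification --------------------------------------------------

#' Segmentation rule
#'
#' Triangles with \code{field - ref > level * max(field - ref)} form the
#' segmented set; connected components smaller than \code{min_cells}
#' triangles are discarded as noise. The reference is the homogeneous
#' steady state (or any fixed observation baseline); using the same
#' reference for a control/perturbed pair measures both runs on the same
#' scale.
#'
#' @param ref scalar or per-cell reference level.
#' @param level relative threshold in (0, 1) (default 0.5).
#' @param min_cells minimum component size in triangles (default 3).
#' @export
segment_rule <- function(ref = 0, level = 0.5, min_cells = 3) {
  structure(list(ref = ref, level = level, min_cells = min_cells),
            class = "segment_rule")
}

# connected components of a cell subset on the mesh adjacency graph
cell_components <- function(mesh, cells) {
  if (!length(cells)) return(list())
  e <- mesh$edges
  i <- !is.na(e$cell2)
  inset <- logical(n_cells(mesh))
  inset[cells] <- TRUE
  a <- e$cell1[i]; b <- e$cell2[i]
  keep <- inset[a] & inset[b]
  a <- a[keep]; b <- b[keep]
  # union-find
  parent <- seq_len(n_cells(mesh))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(cells, find, 0L)
  split(cells, roots)
}

#' Segment a field into high-expression components
#'
#' @param field per-triangle values (e.g. Sox9).
#' @param mesh a \code{trimesh}.
#' @param rule a \code{\link{segment_rule}}.
#' @return list of integer vectors (triangle indices per component).
#' @export
segment <- function(field, mesh, rule = segment_rule()) {
  if (all(is.na(field))) stop("all-NA field")
  excess <- field - rule$ref
  mx <- max(excess)
  if (mx <= 0) return(list())
  thr <- rule$level * mx
  cells <- which(excess > thr)
  comps <- cell_components(mesh, cells)
  comps[vapply(comps, length, 0L) >= rule$min_cells]
}

# area-weighted principal-axis elongation of a component
component_elongation <- function(mesh, cells) {
  a <- mesh$areas[cells]
  c <- mesh$centroids[cells, , drop = FALSE]
  mu <- colSums(c * a) / sum(a)
  d <- sweep(c, 2, mu)
  cov <- crossprod(d * a, d) / sum(a)
  # add each triangle's own second moment (disk of equal area) so that
  # few-triangle components have a finite, near-unity elongation
  self <- sum(a * a / (4 * pi)) / sum(a)
  cov <- cov + diag(self, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), 1e-300))
}

#' Classify a segmented pattern
#'
#' Computes per-component area, centroid, elongation (principal-axis s.d.
#' ratio, >= 1) and distance to the distal boundary, and assigns a pattern
#' class: \code{spots} (>= \code{min_spots} components, median elongation
#' below \code{stripe_elongation}), \code{stripes} (median elongation at or
#' above it), \code{mixed}, or \code{none}.
#'
#' @param field per-triangle values.
#' @param mesh a \code{trimesh}.
#' @param rule a \code{\link{segment_rule}}.
#' @param stripe_elongation elongation threshold separating stripes from
#'   spots (default 2.5).
#' @param min_spots minimum component count for the spot class (default 3).
#' @return object of class \code{pattern_summary}.
#' @export
classify <- function(field, mesh, rule = segment_rule(),
                     stripe_elongation = 2.5, min_spots = 3) {
  comps <- segment(field, mesh, rule)
  n <- length(comps)
  total_area <- sum(mesh$areas)
  if (n == 0) {
    return(structure(list(components = list(), n_components = 0L,
                          pattern_class = "none", median_elongation = NA_real_,
                          largest_area_fraction = 0, mean_distal_distance = NA_real_,
                          areas = numeric(0)), class = "pattern_summary"))
  }
  dseg <- distal_segments(mesh)
  comp_stats <- lapply(comps, function(cells) {
    a <- sum(mesh$areas[cells])
    mu <- colSums(mesh$centroids[cells, , drop = FALSE] * mesh$areas[cells]) / a
    el <- component_elongation(mesh, cells)
    dd <- if (nrow(dseg)) point_segments_distance(mu, dseg) else NA_real_
    list(cells = cells, area = a, centroid = mu, elongation = el,
         distal_distance = dd)
  })
  els <- vapply(comp_stats, function(s) s$elongation, 0)
  areas <- vapply(comp_stats, function(s) s$area, 0)
  med <- stats::median(els)
  cls <- if (med >= stripe_elongation) "stripes"
         else if (n >= min_spots) "spots" else "mixed"
  structure(list(components = comp_stats, n_components = n,
                 pattern_class = cls, median_elongation = med,
                 largest_area_fraction = max(areas) / total_area,
                 mean_distal_distance =
                   mean(vapply(comp_stats, function(s) s$distal_distance, 0)),
                 areas = areas),
            class = "pattern_summary")
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat(sprintf("pattern: %s, %d components, median elongation %.2f, largest area fraction %.3f, mean distal distance %.2f\n",
              x$pattern_class, x$n_components, x$median_elongation,
              x$largest_area_fraction, x$mean_distal_distance))
  invisible(x)
}

# distal boundary edges as segment coordinate matrix (x1 y1 x2 y2)
distal_segments <- function(mesh) {
  e <- mesh$edges
  d <- !is.na(e$tag) & e$tag == "distal"
  cbind(mesh$vertices[e$v1[d], 1], mesh$vertices[e$v1[d], 2],
        mesh$vertices[e$v2[d], 1], mesh$vertices[e$v2[d], 2])
}

point_segments_distance <- function(p, seg) {
  ex <- seg[, 3] - seg[, 1]; ey <- seg[, 4] - seg[, 2]
  L2 <- pmax(ex^2 + ey^2, 1e-300)
  t <- pmin(1, pmax(0, ((p[1] - seg[, 1]) * ex + (p[2] - seg[, 2]) * ey) / L2))
  min(sqrt((seg[, 1] + t * ex - p[1])^2 + (seg[, 2] + t * ey - p[2])^2))
}

#' Distance from each cell to the distal boundary
#' @param mesh a \code{trimesh}.
#' @export
cell_distal_distance <- function(mesh) {
  seg <- distal_segments(mesh)
  if (!nrow(seg)) stop("mesh has no distal-tagged edges")
  apply(mesh$centroids, 1, point_segments_distance, seg = seg)
}

#' Distal distances of pattern components
#'
#' @param summary a \code{pattern_summary}.
#' @return list with per-component distances and their mean/min/max.
#' @export
distal_distance <- function(summary) {
  d <- vapply(summary$components, function(s) s$distal_distance, 0)
  list(distances = d, mean = mean(d), min = suppressWarnings(min(d)),
       max = suppressWarnings(max(d)))
}

#' Area-weighted Pearson correlation between two fields
#'
#' Used to test the out-of-phase relationship between Sox9 and the ligands:
#' in a patterned fin, corr(S, B) and corr(S, W) are negative (ligand
#' expression gaps coincide with Sox9 spots).
#'
#' @param S,X per-triangle fields on the same mesh.
#' @param mesh a \code{trimesh}.
#' @param max_distal_distance restrict to triangles within this distance of
#'   the distal arc (default Inf: whole mesh).
#' @export
phase_overlap <- function(S, X, mesh, max_distal_distance = Inf) {
  sel <- rep(TRUE, n_cells(mesh))
  if (is.finite(max_distal_distance))
    sel <- cell_distal_distance(mesh) <= max_distal_distance
  a <- mesh$areas[sel]; s <- S[sel]; x <- X[sel]
  ms <- sum(a * s) / sum(a); mx <- sum(a * x) / sum(a)
  vs <- sum(a * (s - ms)^2); vx <- sum(a * (x - mx)^2)
  if (vs <= 0 || vx <= 0) stop("zero-variance field: no pattern to correlate")
  sum(a * (s - ms) * (x - mx)) / sqrt(vs * vx)
}

#' Time at which the component count reaches its final value
#'
#' Scans a trajectory of snapshots and returns the first time the segmented
#' component count equals its final value and remains there. Used for the
#' growth-versus-static comparison: growth accelerates the break-up of the
#' Sox9 band into separate spots.
#'
#' @param counts integer component counts per snapshot.
#' @param times snapshot times.
#' @return the separation time, or NA if the trajectory never patterns
#'   (final count 0).
#' @export
separation_time <- function(counts, times) {
  stopifnot(length(counts) == length(times), length(counts) >= 1)
  final <- counts[length(counts)]
  if (final == 0) return(NA_real_)
  stable_from <- length(counts)
  for (i in rev(seq_along(counts))) {
    if (counts[i] == final) stable_from <- i else break
  }
  times[stable_from]
}
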