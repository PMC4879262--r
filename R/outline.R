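# Synthetic fin-bud outlines ---------------------------------------------

#' Create a fin-bud outline
#'
#' An outline is a closed simple polyline with a tagged distal arc (the
#' AER-analogue margin where the FGF source sits) and two boundary landmarks
#' at the anterior and posterior base corners.
#'
#' @param points numeric matrix (n x 2) of boundary coordinates, ordered
#'   counter-clockwise, first point not repeated.
#' @param stage_time stage time in days.
#' @param distal_arc integer vector of point indices forming the contiguous
#'   distal (AER) arc.
#' @param anterior_anchor,posterior_anchor indices of the two base-corner
#'   landmarks; must lie outside the distal arc.
#' @return an object of class \code{fin_outline}.
#' @export
fin_outline <- function(points, stage_time = 0, distal_arc,
                        anterior_anchor, posterior_anchor) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 3)
  if (polygon_area(points) < 0) {
    n <- nrow(points)
    points <- points[n:1, , drop = FALSE]
    remap <- function(i) n + 1L - i
    distal_arc <- sort(remap(distal_arc))
    anterior_anchor <- remap(anterior_anchor)
    posterior_anchor <- remap(posterior_anchor)
  }
  if (length(distal_arc) < 1) stop("distal_arc must be non-empty")
  if (anterior_anchor %in% distal_arc || posterior_anchor %in% distal_arc)
    stop("anchors must lie outside the distal arc")
  if (anterior_anchor == posterior_anchor) stop("anchors must be distinct")
  if (!is_simple_polygon(points)) stop("invalid geometry: outline self-intersects")
  structure(list(points = points, stage_time = stage_time,
                 distal_arc = as.integer(distal_arc),
                 anterior_anchor = as.integer(anterior_anchor),
                 posterior_anchor = as.integer(posterior_anchor)),
            class = "fin_outline")
}

#' Shoelace area of a closed polygon
#' @param points n x 2 matrix, closed implicitly.
#' @return signed area (positive for counter-clockwise orientation).
#' @export
polygon_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# segment-pair intersection test for simplicity checking
is_simple_polygon <- function(points) {
  n <- nrow(points)
  a <- points
  b <- points[c(2:n, 1), , drop = FALSE]
  ccw <- function(p, q, r) {
    (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]) - (q[, 2] - p[, 2]) * (r[, 1] - p[, 1])
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]   # skip segments sharing a vertex
    if (!length(js)) next
    p1 <- a[rep(i, length(js)), , drop = FALSE]
    p2 <- b[rep(i, length(js)), , drop = FALSE]
    q1 <- a[js, , drop = FALSE]; q2 <- b[js, , drop = FALSE]
    d1 <- ccw(p1, p2, q1); d2 <- ccw(p1, p2, q2)
    d3 <- ccw(q1, q2, p1); d4 <- ccw(q1, q2, p2)
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

#' Growth specification for the synthetic fin-bud series
#'
#' Per-day multiplicative growth factors. The posterior factor must be at
#' least the anterior factor, reproducing the posterior-biased expansion of
#' the catshark pectoral fin bud.
#'
#' @param length_factor per-day growth of the proximodistal extent.
#' @param anterior_factor,posterior_factor per-day growth of the anterior and
#'   posterior half-widths.
#' @param length0,anterior0,posterior0 initial dimensions (model units).
#' @export
growth_spec <- function(length_factor = 1.18, anterior_factor = 1.08,
                        posterior_factor = 1.22, length0 = 40,
                        anterior0 = 25, posterior0 = 25) {
  if (posterior_factor < anterior_factor)
    stop("posterior growth factor must be >= anterior factor")
  stopifnot(length_factor > 0, anterior_factor > 0, length0 > 0)
  structure(list(length_factor = length_factor,
                 anterior_factor = anterior_factor,
                 posterior_factor = posterior_factor,
                 length0 = length0, anterior0 = anterior0,
                 posterior0 = posterior0), class = "growth_spec")
}

# one parametric fin-bud shape; base along x = 0, distal direction +x,
# anterior +y. Margin: x = L cos(phi), y = w(phi) sin(phi) with a smooth
# anterior/posterior width blend.
fin_shape <- function(L, wa, wp, n_margin = 96, n_base = 24, jitter = NULL) {
  phi <- seq(-pi / 2, pi / 2, length.out = n_margin)
  wblend <- wa * (1 + sin(phi)) / 2 + wp * (1 - sin(phi)) / 2
  x <- L * cos(phi)
  y <- wblend * sin(phi)
  if (!is.null(jitter)) {
    r <- 1 + jitter
    x <- x * r
    y <- y * r
  }
  # margin runs posterior corner -> apex -> anterior corner (CCW)
  margin <- cbind(x, y)
  base_y <- seq(wa, -wp, length.out = n_base + 2)[2:(n_base + 1)]
  base <- cbind(rep(0, n_base), base_y)
  pts <- rbind(margin, base)
  list(points = pts, posterior_corner = 1L, anterior_corner = n_margin,
       margin_idx = seq_len(n_margin))
}

#' Generate a synthetic growing fin-bud outline series
#'
#' Emulates the digitized stage-series of catshark pectoral fin buds: a
#' smooth bud with monotonically growing area, stronger posterior than
#' anterior expansion, and a tagged distal (AER) margin. One outline per
#' integer day.
#'
#' @param n_stages number of stages (>= 2), one day apart.
#' @param spec a \code{\link{growth_spec}}.
#' @param seed integer seed for the (small, smooth) boundary irregularity.
#' @param jitter_sd relative amplitude of the smooth boundary irregularity
#'   shared by all stages (0 disables it).
#' @param distal_fraction fraction of the outer margin (centred on the apex)
#'   tagged as the distal arc.
#' @return an object of class \code{outline_series}.
#' @export
generate_fin_series <- function(n_stages = 6, spec = growth_spec(), seed = 1,
                                jitter_sd = 0.01, distal_fraction = 0.8) {
  stopifnot(n_stages >= 2)
  n_margin <- 96L
  jitter <- NULL
  if (jitter_sd > 0) {
    set.seed(seed)
    # smooth periodic irregularity in the margin, shared across stages
    ph <- stats::runif(3, 0, 2 * pi)
    am <- stats::rnorm(3, 0, jitter_sd / sqrt(3))
    t <- seq(0, 1, length.out = n_margin)
    jitter <- am[1] * sin(2 * pi * t + ph[1]) +
      am[2] * sin(4 * pi * t + ph[2]) + am[3] * sin(6 * pi * t + ph[3])
  }
  outlines <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    g <- s - 1
    L <- spec$length0 * spec$length_factor^g
    wa <- spec$anterior0 * spec$anterior_factor^g
    wp <- spec$posterior0 * spec$posterior_factor^g
    sh <- fin_shape(L, wa, wp, n_margin = n_margin, jitter = jitter)
    k <- floor(n_margin * distal_fraction / 2)
    mid <- (n_margin + 1L) %/% 2L
    arc <- (mid - k):(mid + k)
    ol <- fin_outline(sh$points, stage_time = g, distal_arc = arc,
                      anterior_anchor = sh$anterior_corner,
                      posterior_anchor = sh$posterior_corner)
    outlines[[s]] <- ol
  }
  areas <- vapply(outlines, function(o) abs(polygon_area(o$points)), 0)
  if (any(diff(areas) < 0)) stop("invalid geometry: series area not non-decreasing")
  structure(list(outlines = outlines), class = "outline_series")
}

#' @export
print.outline_series <- function(x, ...) {
  areas <- vapply(x$outlines, function(o) abs(polygon_area(o$points)), 0)
  cat(sprintf("outline_series: %d stages, days %s, areas %s\n",
              length(x$outlines),
              paste(vapply(x$outlines, function(o) o$stage_time, 0),
                    collapse = ","),
              paste(sprintf("%.0f", areas), collapse = ",")))
  invisible(x)
}

#' Resample an outline to approximately uniform point spacing
#'
#' Periodic-spline resampling of the boundary polyline; distal-arc tags and
#' anchors are carried over to the nearest resampled points.
#'
#' @param outline a \code{fin_outline}.
#' @param spacing target distance between consecutive points (model units).
#' @export
resample_outline <- function(outline, spacing) {
  pts <- outline$points
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[c(2:n, 1), ] - pts)^2))
  s <- c(0, cumsum(seg))          # arc length at each point, length n+1
  total <- s[n + 1]
  m <- max(12L, round(total / spacing))
  snew <- seq(0, total, length.out = m + 1)[1:m]
  xs <- stats::approx(s, c(pts[, 1], pts[1, 1]), xout = snew)$y
  ys <- stats::approx(s, c(pts[, 2], pts[1, 2]), xout = snew)$y
  newpts <- cbind(xs, ys)
  near <- function(i) which.min((snew - s[i])^2)
  arc_pts <- s[outline$distal_arc]
  lo <- min(arc_pts); hi <- max(arc_pts)
  arc_new <- which(snew >= lo - 1e-9 & snew <= hi + 1e-9)
  fin_outline(newpts, stage_time = outline$stage_time,
              distal_arc = arc_new,
              anterior_anchor = near(outline$anterior_anchor),
              posterior_anchor = near(outline$posterior_anchor))
}

#' Read/write outlines as CSV
#'
#' CSV columns: \code{x}, \code{y}, \code{tag} (\code{distal} or
#' \code{lateral}), one row per boundary point in order; anchors are marked
#' with tags \code{anterior_anchor} / \code{posterior_anchor}.
#' @param outline a \code{fin_outline}.
#' @param path file path.
#' @export
write_outline_csv <- function(outline, path) {
  tag <- rep("lateral", nrow(outline$points))
  tag[outline$distal_arc] <- "distal"
  tag[outline$anterior_anchor] <- "anterior_anchor"
  tag[outline$posterior_anchor] <- "posterior_anchor"
  utils::write.csv(data.frame(x = outline$points[, 1],
                              y = outline$points[, 2], tag = tag),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_outline_csv
#' @param stage_time stage time assigned to the outline read from CSV.
#' @export
read_outline_csv <- function(path, stage_time = 0) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x", "y", "tag") %in% names(d)))
  fin_outline(cbind(d$x, d$y), stage_time = stage_time,
              distal_arc = which(d$tag == "distal"),
              anterior_anchor = which(d$tag == "anterior_anchor"),
              posterior_anchor = which(d$tag == "posterior_anchor"))
}
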