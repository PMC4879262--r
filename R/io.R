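# Mesh, field and configuration I/O --------------------------------------

#' Write a mesh as Gmsh MSH v2 ASCII
#'
#' Boundary edges are written as 2-node line elements with physical group 1
#' (\code{distal}) or 2 (\code{lateral}); triangles carry physical group 0.
#'
#' @param mesh a \code{trimesh}.
#' @param path output file.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
               "$PhysicalNames", "2",
               "1 1 \"distal\"", "1 2 \"lateral\"", "$EndPhysicalNames"), con)
  nv <- nrow(mesh$vertices)
  writeLines(c("$Nodes", as.character(nv)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(nv), mesh$vertices[, 1],
                     mesh$vertices[, 2]), con)
  writeLines("$EndNodes", con)
  e <- mesh$edges
  b <- which(is.na(e$cell2))
  nt <- nrow(mesh$triangles)
  writeLines(c("$Elements", as.character(length(b) + nt)), con)
  id <- 0L
  for (k in b) {
    id <- id + 1L
    grp <- if (!is.na(e$tag[k]) && e$tag[k] == "distal") 1L else 2L
    writeLines(sprintf("%d 1 2 %d %d %d %d", id, grp, grp, e$v1[k], e$v2[k]),
               con)
  }
  writeLines(sprintf("%d 2 2 0 0 %d %d %d", id + seq_len(nt),
                     mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH v2 ASCII mesh
#'
#' Supports the v2.2 ASCII dialect with 2-node line elements as tagged
#' boundary edges (physical group 1 = distal, 2 = lateral) and 3-node
#' triangles.
#'
#' @param path input file.
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("malformed MSH file: missing ", name)
    lines[(i0 + 1):(i1 - 1)]
  }
  fmt <- strsplit(sect("MeshFormat")[1], " ")[[1]]
  if (as.numeric(fmt[1]) >= 3)
    stop("unsupported MSH version ", fmt[1], ": convert to v2 ASCII")
  nd <- sect("Nodes")
  nv <- as.integer(nd[1])
  nodes <- do.call(rbind, lapply(strsplit(nd[-1], " +"), as.numeric))
  verts <- matrix(NA_real_, nv, 2)
  verts[nodes[, 1], ] <- nodes[, 2:3]
  el <- sect("Elements")
  rows <- lapply(strsplit(el[-1], " +"), as.integer)
  tris <- list(); btags <- list()
  for (r in rows) {
    type <- r[2]; ntags <- r[3]
    nn <- r[(4 + ntags):length(r)]
    if (type == 2) tris[[length(tris) + 1]] <- nn
    if (type == 1) btags[[length(btags) + 1]] <- c(nn, if (ntags >= 1) r[4] else 2L)
  }
  tris <- do.call(rbind, tris)
  tagmap <- new.env()
  for (b in btags) {
    key <- paste(min(b[1], b[2]), max(b[1], b[2]))
    assign(key, if (b[3] == 1L) "distal" else "lateral", envir = tagmap)
  }
  tagger <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    if (exists(key, envir = tagmap)) get(key, envir = tagmap) else "lateral"
  }
  trimesh(verts, tris, boundary_tags = tagger)
}

#' Write per-cell fields as a legacy VTK unstructured grid
#'
#' @param mesh a \code{trimesh}.
#' @param fields named list of per-triangle numeric vectors.
#' @param path output file.
#' @export
write_vtk <- function(mesh, fields, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "finturing fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$vertices[, 1], mesh$vertices[, 2]),
             con)
  writeLines(sprintf("CELLS %d %d", nt, 4 * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1,
                     mesh$triangles[, 2] - 1, mesh$triangles[, 3] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", nt), con)
  writeLines(rep("5", nt), con)
  writeLines(sprintf("CELL_DATA %d", nt), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(sprintf("%.17g", fields[[nm]]), con)
  }
  invisible(path)
}

#' Write/read field snapshots as long-format CSV
#'
#' Columns: \code{time}, \code{triangle_id}, \code{species}, \code{value}.
#'
#' @param snapshots list of snapshots (each with \code{time} and per-species
#'   vectors, as produced by \code{\link{simulate_bsw}}).
#' @param path file path.
#' @param species species to write.
#' @export
write_fields_csv <- function(snapshots, path, species = c("S", "B", "W")) {
  rows <- do.call(rbind, lapply(snapshots, function(sn) {
    do.call(rbind, lapply(species, function(sp) {
      data.frame(time = sn$time, triangle_id = seq_along(sn[[sp]]),
                 species = sp, value = sn[[sp]])
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fields_csv
#' @export
read_fields_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# -- run configuration ----------------------------------------------------

config_defaults <- function() {
  list(preset = "fin",
       params = NULL,
       integrator = list(dt = 0.002, noise_sd = 0.01, clip_negative = FALSE,
                         t_per_day = 1, snapshot_every = 0),
       domain = list(kind = "fin", target_edge = 2.5, n_stages = 6,
                     use_last = 3, side = 200, resolution = 7,
                     mesh_path = NULL),
       perturbation = list(kind = "control", magnitude = NULL),
       metrics = list(level = 0.5, min_cells = 3, stripe_elongation = 2.5,
                      min_spots = 3),
       seed = 1,
       days = 3)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON-like YAML) run configuration, rejects unknown keys,
#' fills defaults and returns the completed configuration; saving and
#' reloading the result is the identity.
#'
#' @param path YAML file.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- config_defaults()
  merged <- defaults
  check <- function(given, def, prefix = "") {
    unknown <- setdiff(names(given), names(def))
    if (length(unknown))
      stop("unknown configuration key: ", prefix, unknown[1])
  }
  check(raw, defaults)
  for (k in names(raw)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(raw[[k]])) {
      check(raw[[k]], defaults[[k]], paste0(k, "."))
      for (k2 in names(raw[[k]])) merged[[k]][k2] <- list(raw[[k]][[k2]])
    } else {
      merged[k] <- list(raw[[k]])
    }
  }
  if (!merged$preset %in% c("fin", "square"))
    stop("configuration error: preset must be 'fin' or 'square'")
  structure(merged, class = "run_config")
}

#' Save a run configuration with all defaults made explicit
#' @param config a \code{run_config} (or plain list).
#' @param path output YAML file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
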