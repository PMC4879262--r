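# Finite-volume reaction-diffusion engine --------------------------------

#' Finite-volume diffusion rate on a triangle mesh
#'
#' Two-point-flux approximation: the rate in cell i is
#' (D / area_i) * sum over interior edges of L_e (u_j - u_i) / d_ij, with
#' L_e the shared-edge length and d_ij the centroid distance. Boundary edges
#' contribute no flux (zero-flux condition), so the operator conserves the
#' area-integrated amount exactly.
#'
#' @param mesh a \code{trimesh}.
#' @param u per-triangle field.
#' @param D diffusion constant (model units^2 per time).
#' @export
fvm_diffusion <- function(mesh, u, D) {
  stopifnot(D >= 0, length(u) == n_cells(mesh), all(is.finite(u)))
  e <- fvm_edges(mesh)
  cpp_fvm_rate(u, D, e$ei, e$ej, e$w, mesh$areas)
}

#' Integrator configuration
#'
#' @param dt time step (default 0.002).
#' @param noise_sd multiplicative Gaussian noise s.d. per step (default 0.01,
#'   i.e. 1\%).
#' @param clip_negative clip negative concentrations after noise (default
#'   FALSE: the linear model admits negative values by construction).
#' @param t_per_day model time units per growth day (default 1; chosen so
#'   that patterns mature over a stage 29 to 31 window, see the vignette).
#' @param snapshot_every snapshot interval in steps (0: final state only).
#' @export
integrator_config <- function(dt = 0.002, noise_sd = 0.01,
                              clip_negative = FALSE, t_per_day = 1,
                              snapshot_every = 0) {
  stopifnot(dt > 0, noise_sd >= 0, noise_sd < 1, t_per_day > 0)
  structure(list(dt = dt, noise_sd = noise_sd,
                 clip_negative = clip_negative, t_per_day = t_per_day,
                 snapshot_every = as.integer(snapshot_every)),
            class = "integrator_config")
}

#' Explicit-diffusion stability bound for the time step
#'
#' Largest stable dt for the forward-Euler core of the Heun scheme,
#' min_i area_i / (D_max * sum_e L_e / d_e), with a safety factor.
#'
#' @param mesh a \code{trimesh}.
#' @param D_max largest diffusion constant integrated explicitly.
#' @param safety safety factor (default 0.9).
#' @export
dt_stability_bound <- function(mesh, D_max, safety = 0.9) {
  e <- mesh$edges
  i <- !is.na(e$cell2)
  w <- e$length[i] / e$cdist[i]
  acc <- numeric(n_cells(mesh))
  agg <- rowsum(c(w, w), c(e$cell1[i], e$cell2[i]))
  acc[as.integer(rownames(agg))] <- agg[, 1]
  safety * min(mesh$areas / pmax(D_max * acc, 1e-300))
}

#' One Heun (explicit trapezoidal) step, reference implementation
#'
#' Predictor u* = u + dt f(u); corrector u+ = u + dt/2 (f(u) + f(u*)); then
#' per-cell multiplicative noise u <- u (1 + sd N(0,1)). The compiled
#' integrator in \code{\link{simulate_bsw}} uses the identical scheme; this
#' reference version accepts an arbitrary right-hand side and is used for
#' verification.
#'
#' @param u state (vector or matrix, cells x species).
#' @param rhs function(u) returning rates of the same shape.
#' @param dt time step.
#' @param noise_sd multiplicative noise s.d. (0 disables noise).
#' @export
heun_step <- function(u, rhs, dt, noise_sd = 0) {
  f1 <- rhs(u)
  up <- u + dt * f1
  f2 <- rhs(up)
  out <- u + dt / 2 * (f1 + f2)
  if (noise_sd > 0) out <- out * (1 + noise_sd * stats::rnorm(length(out)))
  if (any(!is.finite(out)))
    stop("numerical instability: non-finite state after Heun step")
  out
}

#' Simulate the BSW system on a static mesh or a growth map
#'
#' Integrates the (optionally Fgf-modulated) linear BSW reaction-diffusion
#' system with the compiled finite-volume Heun scheme. On a growth map the
#' concentrations are remapped conservatively onto the next day's mesh at
#' every interval boundary and the Fgf gradient is recomputed on the new
#' geometry.
#'
#' @param params a \code{\link{bsw_params}} object.
#' @param domain a \code{trimesh} or a \code{growth_map}.
#' @param config an \code{\link{integrator_config}}.
#' @param days number of model days to simulate (static mesh only; a growth
#'   map fixes the number of intervals).
#' @param fgf \code{"gradient"} (steady-state distal-source gradient),
#'   \code{"exp3x"} (the square-domain profile exp(-3x) with x normalized to
#'   [0, 1]), \code{"none"} (F = 0), or a numeric per-cell field.
#' @param fgf_scale multiplier applied to the F field after normalization
#'   (Fgf inhibition lowers it below 1).
#' @param init optional list(S, B, W) initial fields; default is the
#'   per-cell steady state.
#' @param seed integer seed (set before the stochastic stream starts).
#' @return list with the final state, snapshots (per day), the mesh used at
#'   each snapshot, and the F field(s).
#' @export
simulate_bsw <- function(params, domain, config = integrator_config(),
                         days = 2, fgf = "gradient", fgf_scale = 1,
                         init = NULL, seed = 1) {
  set.seed(seed)
  growing <- inherits(domain, "growth_map")
  meshes <- if (growing) domain$meshes else list(domain)
  n_runs <- if (growing) length(meshes) else days
  steps_per_day <- max(1L, round(config$t_per_day / config$dt))
  pvec <- params_vector(params)
  fgf_field <- function(mesh) {
    if (is.numeric(fgf)) return(fgf * fgf_scale)
    switch(fgf,
           none = numeric(n_cells(mesh)),
           exp3x = {
             xr <- range(mesh$vertices[, 1])
             x <- (mesh$centroids[, 1] - xr[1]) / (xr[2] - xr[1])
             exp(-3 * x) * fgf_scale
           },
           gradient = fgf_gradient(mesh)$F * fgf_scale,
           stop("unknown fgf spec"))
  }
  mesh <- meshes[[1]]
  F <- fgf_field(mesh)
  bound <- dt_stability_bound(mesh, max(params$D_B, params$D_W))
  if (config$dt > bound)
    stop(sprintf("dt = %g exceeds the diffusion stability bound %.4g; reduce dt or coarsen the mesh",
                 config$dt, bound))
  if (is.null(init)) {
    # homogeneous steady state of the well-mixed (F = 0) system; for the
    # singular square preset this is the least-squares minimum-norm point
    st <- steady_state(params, 0)
    nc <- n_cells(mesh)
    S <- rep(st$S, nc); B <- rep(st$B, nc); W <- rep(st$W, nc)
  } else {
    S <- init$S; B <- init$B; W <- init$W
  }
  snaps <- list()
  e <- fvm_edges(mesh)
  for (k in seq_len(n_runs)) {
    run <- cpp_bsw_run(S, B, W, F, pvec, config$dt, steps_per_day,
                       config$noise_sd, config$clip_negative,
                       config$snapshot_every, e$ei, e$ej, e$w, mesh$areas,
                       params$D_B, params$D_W)
    if (!run$finite) stop("numerical instability in BSW integration")
    nlast <- length(run$S)
    for (q in seq_len(nlast)) {
      snaps[[length(snaps) + 1L]] <- list(
        time = (k - 1) * config$t_per_day + run$time[q],
        S = run$S[[q]], B = run$B[[q]], W = run$W[[q]],
        mesh_index = if (growing) k else 1L)
    }
    S <- run$S[[nlast]]; B <- run$B[[nlast]]; W <- run$W[[nlast]]
    if (growing && k < n_runs) {
      tr <- domain$transfers[[k]]
      S <- remap(S, tr); B <- remap(B, tr); W <- remap(W, tr)
      mesh <- meshes[[k + 1]]
      e <- fvm_edges(mesh)
      F <- fgf_field(mesh)
    }
  }
  list(S = S, B = B, W = W, F = F, mesh = mesh, snapshots = snaps,
       params = params, config = config, seed = seed)
}
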