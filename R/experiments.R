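# Scripted in-silico experiments -----------------------------------------

#' Default fin-bud simulation domain
#'
#' Builds the synthetic outline series and the growth map for the late
#' stages (the window in which the distal Sox9 row appears), plus the
#' final-stage static mesh used by the growth-versus-static comparison.
#'
#' @param target_edge mesh edge length (default 2.5 model units, about four
#'   cells per pattern wavelength of the fin parameter set).
#' @param n_stages total synthetic stages generated (default 6).
#' @param use_last number of late stages simulated on (default 3).
#' @param seed seed for the outline generator.
#' @param spec a \code{\link{growth_spec}}.
#' @export
fin_domain <- function(target_edge = 2.5, n_stages = 6, use_last = 3,
                       seed = 1, spec = growth_spec()) {
  series <- generate_fin_series(n_stages = n_stages, spec = spec, seed = seed)
  late <- series$outlines[(n_stages - use_last + 1):n_stages]
  for (k in seq_along(late)) late[[k]]$stage_time <- k - 1
  late_series <- structure(list(outlines = late), class = "outline_series")
  gm <- build_growth_map(late_series, target_edge = target_edge)
  list(series = late_series, growth_map = gm,
       final_mesh = gm$meshes[[length(gm$meshes)]])
}

#' Default integrator configuration for fin-bud meshes
#'
#' The fin parameter set patterns at a wavelength of about 10 model units,
#' so fin meshes are built at edge length 2.5 and stepped at dt = 0.001 to
#' respect the explicit-diffusion stability bound (the coarser square meshes
#' use the default dt = 0.002).
#'
#' @param dt time step.
#' @param t_per_day model time per growth day.
#' @param ... passed to \code{\link{integrator_config}}.
#' @export
fin_config <- function(dt = 0.001, t_per_day = 0.13, ...) {
  integrator_config(dt = dt, t_per_day = t_per_day, ...)
}

# homogeneous Sox9 observation baseline (well-mixed steady state of the
# control parameter set): perturbed and control runs are thresholded on the
# same fixed scale, as the paper's fixed colour scale does
reference_level <- function(params) steady_state(params, 0)$S

# run one simulation and classify its endpoint against a fixed reference
run_and_classify <- function(params, domain, config, seed, fgf = "gradient",
                             fgf_scale = 1, ref = NULL, days = 2,
                             level = 0.25) {
  sim <- simulate_bsw(params, domain, config, days = days, fgf = fgf,
                      fgf_scale = fgf_scale, seed = seed)
  if (is.null(ref)) ref <- reference_level(sim$params)
  summ <- classify(sim$S, sim$mesh, segment_rule(ref = ref, level = level))
  list(sim = sim, summary = summ)
}

#' Control fin simulation
#'
#' Simulates the FGF-modulated BSW system on the growing fin and checks the
#' three signatures of the normal phenotype: a spot-class pattern, spots at
#' an intermediate distance from the distal edge, and ligand fields
#' out-of-phase with Sox9.
#'
#' @param domain a \code{growth_map} or \code{trimesh} (see
#'   \code{\link{fin_domain}}).
#' @param params a \code{bsw_params} (default fin preset).
#' @param seeds integer vector of seeds.
#' @param config an \code{\link{integrator_config}}.
#' @param days simulated days on a static mesh.
#' @param phase_band restrict phase correlations to cells within this
#'   distance of the distal edge (default 30 model units, about three
#'   pattern wavelengths).
#' @return an experiment report (config echo, per-seed summaries, verdicts).
#' @export
run_control <- function(domain, params = bsw_preset("fin"), seeds = 1:3,
                        config = fin_config(), days = 3,
                        phase_band = 30) {
  if (!check_fgf_traversal(params))
    stop("parameter set fails the FGF-path sanity gate (no Turing-space traversal)")
  per_seed <- lapply(seeds, function(s) {
    r <- run_and_classify(params, domain, config, seed = s, days = days)
    dmax <- max(cell_distal_distance(r$sim$mesh))
    list(summary = r$summary,
         corr_SB = phase_overlap(r$sim$S, r$sim$B, r$sim$mesh, phase_band),
         corr_SW = phase_overlap(r$sim$S, r$sim$W, r$sim$mesh, phase_band),
         pd_extent = dmax, sim = r$sim)
  })
  verdicts <- list(
    spots = all(vapply(per_seed, function(x)
      x$summary$pattern_class == "spots", TRUE)),
    intermediate_distance = all(vapply(per_seed, function(x) {
      d <- x$summary$mean_distal_distance
      is.finite(d) && d > 0 && d < 0.5 * x$pd_extent
    }, TRUE)),
    out_of_phase = all(vapply(per_seed, function(x)
      x$corr_SB < 0 && x$corr_SW < 0, TRUE)))
  structure(list(kind = "control", params = params, seeds = seeds,
                 per_seed = per_seed, verdicts = verdicts),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment '%s' (%d seeds)\n", x$kind, length(x$seeds)))
  for (v in names(x$verdicts))
    cat(sprintf("  %-28s %s\n", v, ifelse(isTRUE(x$verdicts[[v]]), "PASS",
                                          format(x$verdicts[[v]]))))
  invisible(x)
}

#' Paired perturbation experiment
#'
#' Runs control and perturbed simulations with identical seeds (identical
#' noise streams) and evaluates the directional claims: Bmp inhibition
#' reduces component count and mean spot area; Wnt inhibition increases the
#' largest-component area fraction and the median elongation (fusion); Fgf
#' inhibition moves spots closer to the distal edge. Both arms are measured
#' against the control steady-state reference.
#'
#' @param domain as in \code{\link{run_control}}.
#' @param spec a \code{\link{perturbation}}.
#' @param params base parameters (default fin preset).
#' @param seeds paired seeds (default 1:5).
#' @param config integrator configuration; the default uses a shorter
#'   observation window than the control run (total model time 0.2), in
#'   which the steady-state baseline shifts induced by the perturbations are
#'   commensurate with the growing pattern amplitude.
#' @param days simulated days on a static mesh.
#' @param pass_fraction fraction of paired seeds that must agree (default
#'   0.8, i.e. 4 of 5).
#' @export
run_perturbation <- function(domain, spec, params = bsw_preset("fin"),
                             seeds = 1:5,
                             config = fin_config(t_per_day = 0.065),
                             days = 3, pass_fraction = 0.8) {
  pert <- apply_perturbation(params, spec)
  ref <- reference_level(params)
  pairs <- lapply(seeds, function(s) {
    ctl <- run_and_classify(params, domain, config, seed = s, ref = ref,
                            days = days)
    prt <- run_and_classify(pert$params, domain, config, seed = s, ref = ref,
                            fgf_scale = pert$fgf_scale, days = days)
    list(control = ctl$summary, perturbed = prt$summary)
  })
  delta <- function(f) vapply(pairs, function(p) f(p$perturbed) - f(p$control), 0)
  d_count <- delta(function(s) s$n_components)
  d_area <- delta(function(s) if (s$n_components) mean(s$areas) else 0)
  d_frac <- delta(function(s) s$largest_area_fraction)
  largest_elong <- function(s) {
    if (!s$n_components) return(0)
    s$components[[which.max(s$areas)]]$elongation
  }
  d_elong <- delta(largest_elong)
  d_dist <- delta(function(s) if (is.finite(s$mean_distal_distance))
    s$mean_distal_distance else NA_real_)
  frac_ok <- function(x) mean(x, na.rm = TRUE) >= pass_fraction
  verdicts <- switch(spec$kind,
    bmp_inhibition = list(
      fewer_components = frac_ok(d_count < 0),
      smaller_spots = frac_ok(d_area < 0)),
    wnt_inhibition = list(
      larger_fused_component = frac_ok(d_frac > 0),
      higher_elongation = frac_ok(d_elong > 0)),
    fgf_inhibition = list(
      spots_shift_distally = frac_ok(d_dist < 0)),
    control = list(null_effect = all(abs(d_count) == 0 & abs(d_area) < 1e-12)))
  structure(list(kind = spec$kind, magnitude = spec$magnitude,
                 params = params, seeds = seeds, pairs = pairs,
                 deltas = list(count = d_count, mean_area = d_area,
                               largest_fraction = d_frac,
                               elongation = d_elong, distal_distance = d_dist),
                 verdicts = verdicts),
            class = "experiment_report")
}

#' Square-domain production-ratio scan
#'
#' Simulates the square preset at several levels of the Wnt/Bmp production
#' ratio alpha_W / alpha_B (no FGF gradient) and summarizes the median
#' component elongation per level. With unequal productions the singular
#' square system drifts: the mean Sox9 level sinks below zero while the
#' pattern grows, so at a fixed observation contrast only the peaks of the
#' pattern remain positive -- isolated round spots. With balanced
#' productions the positive part of the field is a labyrinth of elongated
#' pieces. Each run is classified at the first snapshot whose spatial
#' standard deviation reaches \code{A_obs} (observation at fixed pattern
#' contrast), thresholding the positive part of the field (reference 0).
#'
#' @param side,resolution square-domain geometry (defaults 200 and 7).
#' @param ratios production ratios (>= 1), default c(1, 2, 4, 8, 12).
#' @param alpha_W fixed Wnt production (default 1.2; alpha_B = alpha_W /
#'   ratio, keeping both in the scanned [0, 2] range).
#' @param seeds seeds per level (default 1:5).
#' @param config integrator configuration.
#' @param t_total maximum simulated model time per run (default 16).
#' @param A_obs observation contrast: spatial s.d. of S at which the
#'   pattern is classified (default 50).
#' @param level,min_cells segmentation level (of the positive maximum) and
#'   minimum component size used for this experiment (defaults 0.1 and 6).
#' @export
run_alpha_scan <- function(side = 200, resolution = 7,
                           ratios = c(1, 2, 4, 8, 12), alpha_W = 1.2,
                           seeds = 1:5, config = integrator_config(),
                           t_total = 16, A_obs = 50, level = 0.1,
                           min_cells = 6) {
  mesh <- generate_square(side, resolution)
  cfg <- config
  cfg$t_per_day <- t_total
  cfg$snapshot_every <- 250L
  a <- mesh$areas
  wsd <- function(x) {
    m <- sum(x * a) / sum(a)
    sqrt(sum(a * (x - m)^2) / sum(a))
  }
  levels <- lapply(ratios, function(r) {
    p <- bsw_preset("square", alpha_B = alpha_W / r, alpha_W = alpha_W)
    per_seed <- lapply(seeds, function(s) {
      sim <- simulate_bsw(p, mesh, cfg, days = 1, fgf = "none", seed = s)
      sds <- vapply(sim$snapshots, function(sn) wsd(sn$S), 0)
      k <- which(sds >= A_obs)[1]
      if (is.na(k)) k <- length(sim$snapshots)
      classify(sim$snapshots[[k]]$S, mesh,
               segment_rule(ref = 0, level = level, min_cells = min_cells))
    })
    el <- vapply(per_seed, function(s)
      ifelse(is.na(s$median_elongation), NA_real_, s$median_elongation), 0)
    list(ratio = r, summaries = per_seed,
         median_elongation = stats::median(el, na.rm = TRUE),
         elongations = el,
         classes = vapply(per_seed, function(s) s$pattern_class, ""))
  })
  med <- vapply(levels, function(l) l$median_elongation, 0)
  pool <- do.call(rbind, lapply(levels, function(l)
    data.frame(ratio = l$ratio, elongation = l$elongations)))
  pool <- pool[is.finite(pool$elongation), ]
  tau <- suppressWarnings(stats::cor(pool$ratio, pool$elongation,
                                     method = "kendall"))
  verdicts <- list(
    elongation_decreases_with_ratio = all(diff(med) <= 0),
    elongation_trend_negative = is.finite(tau) && tau < 0,
    highest_ratio_spots =
      mean(levels[[length(levels)]]$classes == "spots") > 0.5,
    ratio_one_stripes =
      mean(levels[[1]]$classes %in% c("stripes", "mixed")) > 0.5)
  structure(list(kind = "alpha_scan", ratios = ratios, levels = levels,
                 median_elongation = med, kendall_tau = tau, seeds = seeds,
                 verdicts = verdicts),
            class = "experiment_report")
}

#' Growth-versus-static separation-time comparison
#'
#' Runs paired-seed simulations on the growing fin and on its final-stage
#' static mesh for the same total time and compares the time at which the
#' Sox9 pattern reaches its final component count. A run that never reaches
#' a stable patterned count is censored at +Inf, counting in favour of the
#' faster arm.
#'
#' @param dom a list as returned by \code{\link{fin_domain}}.
#' @param params base parameters (default fin preset).
#' @param seeds paired seeds (default 1:5).
#' @param config integrator configuration; snapshots are taken every
#'   \code{snapshot_steps} steps.
#' @param snapshot_steps snapshot interval in steps (default 100).
#' @export
run_growth_comparison <- function(dom, params = bsw_preset("fin"),
                                  seeds = 1:5, config = fin_config(),
                                  snapshot_steps = 100) {
  cfg <- config
  cfg$snapshot_every <- as.integer(snapshot_steps)
  gm <- dom$growth_map
  n_days <- length(gm$meshes)
  measure <- function(sim, meshes, refs) {
    counts <- vapply(sim$snapshots, function(sn) {
      m <- meshes[[sn$mesh_index]]
      length(segment(sn$S, m,
                     segment_rule(ref = refs[[sn$mesh_index]], level = 0.25)))
    }, 0L)
    times <- vapply(sim$snapshots, function(sn) sn$time, 0)
    st <- separation_time(counts, times)
    if (is.na(st)) Inf else st
  }
  g_meshes <- gm$meshes
  ref0 <- reference_level(params)
  g_refs <- lapply(g_meshes, function(m) ref0)
  s_mesh <- dom$final_mesh
  s_ref <- list(ref0)
  res <- lapply(seeds, function(s) {
    gsim <- simulate_bsw(params, gm, cfg, seed = s)
    ssim <- simulate_bsw(params, s_mesh, cfg, days = n_days, seed = s)
    c(growing = measure(gsim, g_meshes, g_refs),
      static = measure(ssim, list(s_mesh), s_ref))
  })
  tg <- vapply(res, `[[`, 0, "growing")
  ts <- vapply(res, `[[`, 0, "static")
  verdicts <- list(growth_separates_faster =
                     stats::median(tg) < stats::median(ts))
  structure(list(kind = "growth_comparison", seeds = seeds,
                 growing_times = tg, static_times = ts, verdicts = verdicts),
            class = "experiment_report")
}
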