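# The Bmp-Sox9-Wnt reaction system ---------------------------------------

#' BSW kinetic and diffusion parameters
#'
#' The linear BSW network: Bmp activates Sox9, Wnt represses Sox9, and Sox9
#' represses both ligands; only Bmp and Wnt diffuse. All parameters are
#' stored as magnitudes, the signs live in the equations:
#' \deqn{dS/dt = \beta (k_2 B - k_3 W)}
#' \deqn{dB/dt = \beta (-k_4 S - k_5 B + \alpha_B) + D_B \nabla^2 B}
#' \deqn{dW/dt = \beta (-k_7 S - k_9 W + \alpha_W) + D_W \nabla^2 W}
#' An FGF gradient F modulates the two Sox9-to-ligand couplings,
#' \eqn{k_4^{eff} = k_4 (1 - k_F F)} and \eqn{k_7^{eff} = k_7 / (1 - k_F F)},
#' so that rising F weakens Sox9's repression of Bmp and strengthens its
#' repression of Wnt; sweeping F from 0 to 1 carries the system into and out
#' of the Turing space (see \code{\link{is_turing}}).
#'
#' @param beta global rate coefficient (speed of pattern appearance).
#' @param k2 Bmp -> Sox9 activation.
#' @param k3 Wnt -| Sox9 repression.
#' @param k4 Sox9 -| Bmp repression (FGF-repressed).
#' @param k5,k9 Bmp and Wnt linear decay.
#' @param k7 Sox9 -| Wnt repression (FGF-boosted).
#' @param alpha_B,alpha_W constant production of Bmp and Wnt.
#' @param k_F FGF coupling constant (must be < 1).
#' @param D_S,D_B,D_W diffusion constants; Sox9 does not diffuse (D_S = 0).
#' @export
bsw_params <- function(beta = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 0.1, k7 = 1,
                       k9 = 0.1, alpha_B = 0, alpha_W = 0, k_F = 0,
                       D_S = 0, D_B = 160, D_W = 25) {
  vals <- c(beta = beta, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k7 = k7,
            k9 = k9, alpha_B = alpha_B, alpha_W = alpha_W, k_F = k_F,
            D_S = D_S, D_B = D_B, D_W = D_W)
  if (any(vals < 0)) stop("parameters are stored as magnitudes and must be >= 0")
  if (D_S != 0) stop("the BSW model assumes a non-diffusive Sox9 (D_S = 0)")
  if (k_F >= 1) stop("k_F must be < 1 (k4_eff would reach zero within F in [0,1])")
  structure(as.list(vals), class = "bsw_params")
}

#' @export
print.bsw_params <- function(x, ...) {
  cat("bsw_params:", paste(sprintf("%s=%g", names(unclass(x)), unlist(x)),
                           collapse = " "), "\n")
  invisible(x)
}

#' Named parameter presets
#'
#' \code{"fin"}: the fin-bud simulation set (beta = 8, Sox9-ligand couplings
#' k4 = 6 and k7 = 2.4, decays 0.1, k_F = 0.667, D_B = 160, D_W = 25,
#' alpha_B = 0.1, alpha_W = 1.2). The two Sox9-input magnitudes are assigned
#' as k2 = 3 (Bmp -> Sox9) and k3 = 1 (Wnt -| Sox9): this is the unique
#' assignment under which the FGF path crosses the Turing space (the package
#' verifies the crossing at load time via \code{\link{fgf_path_verdicts}}).
#' \code{"square"}: the square-domain set (all couplings 1, decays 0.1);
#' alpha_B and alpha_W are free in [0, 2] and set by the caller.
#'
#' @param name \code{"fin"} or \code{"square"}.
#' @param alpha_B,alpha_W production terms for the square preset.
#' @export
bsw_preset <- function(name = c("fin", "square"), alpha_B = NULL,
                       alpha_W = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    fin = bsw_params(beta = 8, k2 = 3, k3 = 1, k4 = 6, k5 = 0.1, k7 = 2.4,
                     k9 = 0.1, alpha_B = 0.1, alpha_W = 1.2, k_F = 0.667),
    square = bsw_params(beta = 1, k2 = 1, k3 = 1, k4 = 1, k5 = 0.1, k7 = 1,
                        k9 = 0.1, alpha_B = 1, alpha_W = 1, k_F = 0))
  if (!is.null(alpha_B)) p$alpha_B <- alpha_B
  if (!is.null(alpha_W)) p$alpha_W <- alpha_W
  p
}

# parameter vector for the compiled kernel:
# beta k2 k3 k4 k5 k7 k9 aB aW kF
params_vector <- function(p) {
  c(p$beta, p$k2, p$k3, p$k4, p$k5, p$k7, p$k9, p$alpha_B, p$alpha_W, p$k_F)
}

#' Effective FGF-modulated couplings
#'
#' @param params a \code{bsw_params}.
#' @param F_value FGF level(s) in [0, 1].
#' @return list with \code{k4_eff} (decreasing in F) and \code{k7_eff}
#'   (increasing in F); at F = 0 the base values are returned.
#' @export
modulated_params <- function(params, F_value) {
  stopifnot(all(F_value >= 0), all(F_value <= 1))
  m <- 1 - params$k_F * F_value
  if (any(m <= 0)) stop("k_F * F >= 1: re-tune k_F")
  list(k4_eff = params$k4 * m, k7_eff = params$k7 / m)
}

#' BSW reaction rates
#'
#' Evaluates the reaction part of the model (no diffusion) for per-cell
#' states, with optional per-cell FGF modulation.
#'
#' @param S,B,W per-cell concentrations.
#' @param params a \code{bsw_params}.
#' @param F per-cell FGF level, or NULL for the unmodulated system.
#' @return list of rates \code{dS}, \code{dB}, \code{dW}.
#' @export
reaction_rhs <- function(S, B, W, params, F = NULL) {
  if (is.null(F)) F <- rep(0, length(S))
  k <- modulated_params(params, F)
  b <- params$beta
  list(dS = b * (params$k2 * B - params$k3 * W),
       dB = b * (-k$k4_eff * S - params$k5 * B + params$alpha_B),
       dW = b * (-k$k7_eff * S - params$k9 * W + params$alpha_W))
}

#' Homogeneous steady state
#'
#' Solves the pointwise linear system reaction = 0 for each FGF level. Where
#' the reaction matrix is singular (the square preset has k2 k4 = k3 k7
#' exactly) the least-squares minimum-norm solution is returned and flagged;
#' with unequal productions such a system has no true steady state and the
#' mean Sox9 level drifts linearly, which is what converts the stripe
#' pattern into spots when Wnt production dominates.
#'
#' @param params a \code{bsw_params}.
#' @param F FGF level(s) in [0, 1] (vectorized).
#' @return list of vectors \code{S}, \code{B}, \code{W}, and logical
#'   \code{singular}.
#' @export
steady_state <- function(params, F = 0) {
  k <- modulated_params(params, F)
  n <- length(F)
  k4 <- rep_len(k$k4_eff, n); k7 <- rep_len(k$k7_eff, n)
  S <- B <- W <- numeric(n)
  sing <- logical(n)
  for (i in seq_len(n)) {
    A <- matrix(c(0, params$k2, -params$k3,
                  -k4[i], -params$k5, 0,
                  -k7[i], 0, -params$k9), 3, 3, byrow = TRUE)
    rhs <- c(0, -params$alpha_B, -params$alpha_W)
    if (abs(det(A)) > 1e-10 * max(abs(A))^3) {
      x <- solve(A, rhs)
    } else {
      sing[i] <- TRUE
      sv <- svd(A)
      d <- ifelse(sv$d > 1e-10 * max(sv$d), 1 / sv$d, 0)
      x <- sv$v %*% (d * crossprod(sv$u, rhs))      # minimum-norm least squares
    }
    S[i] <- x[1]; B[i] <- x[2]; W[i] <- x[3]
  }
  list(S = S, B = B, W = W, singular = sing)
}

#' Steady-state FGF gradient from the distal fin edge
#'
#' Solves 0 = alpha_F 1_source - mu_F F + D_F lap F with zero-flux
#' boundaries, the source supported on the triangles adjacent to
#' distal-tagged boundary edges, then min-max normalizes F to [0, 1]. The
#' decay length sqrt(D_F / mu_F) (about 77.5 model units at the defaults)
#' sets how deep FGF reaches into the fin.
#'
#' @param mesh a \code{trimesh} with a distal-tagged arc.
#' @param D_F,mu_F diffusion constant and decay rate (defaults 600, 0.1).
#' @param alpha_F source magnitude (immaterial after normalization).
#' @return list with the normalized field \code{F} and the raw solution.
#' @export
fgf_gradient <- function(mesh, D_F = 600, mu_F = 0.1, alpha_F = 1) {
  src_cells <- distal_cells(mesh)
  if (!length(src_cells)) stop("geometry error: mesh has no distal-tagged edges")
  nc <- n_cells(mesh)
  e <- fvm_edges(mesh)
  w <- e$w
  L <- Matrix::sparseMatrix(i = c(e$ei, e$ej, e$ei, e$ej),
                            j = c(e$ej, e$ei, e$ei, e$ej),
                            x = c(w, w, -w, -w), dims = c(nc, nc))
  # (mu_F * A - D_F * L_area) F = alpha_F * A * source
  Adiag <- Matrix::Diagonal(x = mesh$areas)
  src <- numeric(nc); src[src_cells] <- alpha_F
  M <- mu_F * Adiag - D_F * L
  Fraw <- as.numeric(Matrix::solve(M, mesh$areas * src))
  Fn <- (Fraw - min(Fraw)) / (max(Fraw) - min(Fraw))
  list(F = Fn, raw = Fraw, D_F = D_F, mu_F = mu_F)
}

#' Perturbation specifications
#'
#' \code{bmp_inhibition} scales the Bmp -> Sox9 transduction k2 down (the
#' LDN drug interferes with receptor binding; default 20\%),
#' \code{wnt_inhibition} scales the Wnt production alpha_W down (the C59
#' drug reduces Wnt secretion; default 50\%), and \code{fgf_inhibition}
#' scales the normalized FGF gradient down uniformly without reshaping it
#' (default 40\%). \code{control} leaves everything untouched.
#'
#' @param kind one of \code{"control"}, \code{"bmp_inhibition"},
#'   \code{"wnt_inhibition"}, \code{"fgf_inhibition"}.
#' @param magnitude fractional reduction in (0, 1]; defaults per kind.
#' @export
perturbation <- function(kind = c("control", "bmp_inhibition",
                                  "wnt_inhibition", "fgf_inhibition"),
                         magnitude = NULL) {
  kind <- match.arg(kind)
  if (is.null(magnitude))
    magnitude <- switch(kind, control = 0, bmp_inhibition = 0.2,
                        wnt_inhibition = 0.5, fgf_inhibition = 0.4)
  if (kind != "control" && (magnitude <= 0 || magnitude > 1))
    stop("perturbation magnitude must be in (0, 1]")
  structure(list(kind = kind, magnitude = magnitude), class = "perturbation")
}

#' Apply a perturbation to parameters and FGF scaling
#'
#' @param params a \code{bsw_params}.
#' @param spec a \code{\link{perturbation}}.
#' @return list with the perturbed \code{params} and the multiplicative
#'   \code{fgf_scale} to apply to the normalized gradient.
#' @export
apply_perturbation <- function(params, spec) {
  fgf_scale <- 1
  switch(spec$kind,
         control = NULL,
         bmp_inhibition = { params$k2 <- params$k2 * (1 - spec$magnitude) },
         wnt_inhibition = { params$alpha_W <- params$alpha_W * (1 - spec$magnitude) },
         fgf_inhibition = { fgf_scale <- 1 - spec$magnitude })
  list(params = params, fgf_scale = fgf_scale)
}
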