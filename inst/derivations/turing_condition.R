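# Derivation of the closed-form Turing condition used by
# closed_form_condition(), kept here so the algebra can be re-checked.
#
# System (magnitudes positive, signs explicit, D_S = 0, k1 = k6 = k8 = 0):
#   dS/dt = beta ( k2 B - k3 W)
#   dB/dt = beta (-k4 S - k5 B) + D_B lap B
#   dW/dt = beta (-k7 S - k9 W) + D_W lap W
#
# For a mode exp(sigma t + i k x), sigma are the eigenvalues of
#   M(q) = beta * [ 0    k2        -k3      ]
#                 [-k4  -k5-qDB/b  0        ]
#                 [-k7   0         -k9-qDW/b]   with q = k^2, b = beta.
#
# Write btil = beta k5 + q D_B, wtil = beta k9 + q D_W. Expanding
# det(lambda I - M) = lambda^3 + b2 lambda^2 + b1 lambda + b0 gives
#   b2 = btil + wtil
#   b1 = btil wtil + beta^2 (k2 k4 - k3 k7)
#   b0 = beta^2 [ k2 k4 wtil - k3 k7 btil ]
# (the Sox9-Bmp loop k2 k4 is negative feedback, the Sox9-Wnt loop k3 k7 is
# mutual repression, i.e. positive feedback; note the cross pairing in b0:
# each loop is weighed by the OTHER ligand's decay-plus-diffusion factor).
#
# Well-mixed stability (q = 0), with k5 = k9 = c: the Routh-Hurwitz
# conditions reduce to b0(0) > 0, i.e.
#       k2 k4 > k3 k7.                                   (I)
# (b2 > 0 always; b1(0) > 0 and b2 b1 - b0 > 0 follow from (I) when k5 = k9:
#  b2 b1 - b0 = beta^3 c [ 2 c^2 + k2 k4 - k3 k7 ] > 0.)
#
# A stationary finite-wavenumber instability appears iff b0(q) < 0 for some
# q > 0. b0 is linear in q with slope beta^2 (k2 k4 D_W - k3 k7 D_B), so
# given (I) this happens iff
#       k3 k7 D_B > k2 k4 D_W.                           (II)
# Together: D_W / D_B < (k3 k7)/(k2 k4) < 1. beta cancels throughout (it
# only rescales time).
#
# Numeric spot-check of the coefficient expansion and of (I) + (II) against
# direct eigenvalues:

poly_coef <- function(beta, k2, k3, k4, k5, k7, k9, DB, DW, q) {
  btil <- beta * k5 + q * DB
  wtil <- beta * k9 + q * DW
  c(b0 = beta^2 * (k2 * k4 * wtil - k3 * k7 * btil),
    b1 = btil * wtil + beta^2 * (k2 * k4 - k3 * k7),
    b2 = btil + wtil)
}

check <- function() {
  set.seed(1)
  for (i in 1:200) {
    p <- list(beta = runif(1, 0.5, 8), k2 = runif(1, 0.1, 4),
              k3 = runif(1, 0.1, 4), k4 = runif(1, 0.1, 8),
              k7 = runif(1, 0.1, 4), k5 = runif(1, 0.05, 0.5),
              DB = 160, DW = 25)
    p$k9 <- p$k5
    q <- runif(1, 0, 2)
    M <- p$beta * matrix(c(0, p$k2, -p$k3,
                           -p$k4, -p$k5 - q * p$DB / p$beta, 0,
                           -p$k7, 0, -p$k9 - q * p$DW / p$beta),
                         3, 3, byrow = TRUE)
    cf <- poly_coef(p$beta, p$k2, p$k3, p$k4, p$k5, p$k7, p$k9, p$DB, p$DW, q)
    ev <- eigen(M, only.values = TRUE)$values
    # coefficients from the eigenvalues
    stopifnot(abs(cf["b2"] + Re(sum(ev))) < 1e-8,
              abs(cf["b0"] + Re(prod(ev))) < 1e-6)
    # closed form vs sign of max growth over q
    closed <- (p$k2 * p$k4 > p$k3 * p$k7) &&
      (p$k3 * p$k7 * p$DB > p$k2 * p$k4 * p$DW)
    qs <- c(0, 10^seq(-4, 2, length.out = 300))
    sig <- sapply(qs, function(qq) {
      Mq <- p$beta * matrix(c(0, p$k2, -p$k3,
                              -p$k4, -p$k5 - qq * p$DB / p$beta, 0,
                              -p$k7, 0, -p$k9 - qq * p$DW / p$beta),
                            3, 3, byrow = TRUE)
      max(Re(eigen(Mq, only.values = TRUE)$values))
    })
    numeric <- sig[1] <= 1e-9 && any(sig[-1] > 1e-9)
    stopifnot(closed == numeric)
  }
  cat("derivation checks passed\n")
}

if (sys.nframe() == 0) check()
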