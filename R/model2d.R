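#' Parameters of the two-dimensional benchmark double well
#'
#' The benchmark surface is built from two harmonic wells
#' \deqn{V_{L/R}(x) = \tfrac12 (x - x^{(L/R)})^T H^{(L/R)} (x - x^{(L/R)}),}
#' with \eqn{H^{(L/R)} = R(\pm\theta)\,\mathrm{diag}(\alpha_{1},\alpha_{2})\,
#' R(\pm\theta)^T} and minima at \eqn{x^{(L/R)} = (\mp\beta, 0)}, combined as
#' \deqn{V(x) = \frac{V_L (V_R + d\,\gamma_1)}{\gamma_1 V_L + \gamma_2 V_R}.}
#' The interpolation coefficients are fixed by the harmonic-limit conditions
#' (near the left minimum \eqn{V \approx V_L}, near the right minimum
#' \eqn{V \approx V_R + d}, both with exact Hessians), which gives the linear
#' system \eqn{\gamma_1 = 1 - d\,\gamma_2/V_L(x^{(R)})},
#' \eqn{\gamma_2 = 1 + d\,\gamma_1/V_R(x^{(L)})} (both equal to 1 for
#' `d = 0`).  With this choice the depth `d` and the well curvatures can each
#' be varied without affecting any other printed parameter of either
#' minimum.  Both dimensions carry the same mass
#' `m`, so the harmonic frequencies are \eqn{\omega_i = \sqrt{\alpha_i/m}}.
#'
#' Right-well curvatures (`alpha1_R`, `alpha2_R`) and the depth offset `d` can
#' be varied independently of the left well, which is how the frequency and
#' depth sweeps are generated.
#'
#' @param alpha1_L,alpha2_L Hessian eigenvalues at the left minimum.
#' @param alpha1_R,alpha2_R Hessian eigenvalues at the right minimum.
#' @param beta half-separation of the minima along the first coordinate.
#' @param theta inclination angle (radians) of the soft normal mode to the
#'   first coordinate axis; the right well is inclined by `-theta`.
#' @param d energy offset of the right minimum.
#' @param m mass in both dimensions.
#' @return list of class `vibtun_model2d_params`, including the derived
#'   `gamma1`, `gamma2`, well Hessians and minima.
#' @export
model_2d_params <- function(alpha1_L = 1.6, alpha2_L = 4.0,
                            alpha1_R = alpha1_L, alpha2_R = alpha2_L,
                            beta = 2.0, theta = pi / 12, d = 0, m = 3.5) {
  stopifnot(alpha1_L > 0, alpha2_L > 0, alpha1_R > 0, alpha2_R > 0,
            beta > 0, m > 0, d >= 0)
  rot <- function(t) matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
  HL <- rot(theta)  %*% diag(c(alpha1_L, alpha2_L)) %*% t(rot(theta))
  HR <- rot(-theta) %*% diag(c(alpha1_R, alpha2_R)) %*% t(rot(-theta))
  xL <- c(-beta, 0); xR <- c(beta, 0)
  VR_at_xL <- 0.5 * c((xL - xR) %*% HR %*% (xL - xR))
  VL_at_xR <- 0.5 * c((xR - xL) %*% HL %*% (xR - xL))
  ## harmonic-limit conditions: exact Hessians at both minima and an exact
  ## energy offset d; linear in (gamma1, gamma2)
  g1 <- (1 - d / VL_at_xR) / (1 + d^2 / (VR_at_xL * VL_at_xR))
  g2 <- 1 + d * g1 / VR_at_xL
  if (g1 <= 0) stop("depth offset too large for the interpolation construction")
  p <- list(alpha1_L = alpha1_L, alpha2_L = alpha2_L,
            alpha1_R = alpha1_R, alpha2_R = alpha2_R,
            beta = beta, theta = theta, d = d, m = m,
            gamma1 = g1, gamma2 = g2,
            HL = HL, HR = HR, xL = xL, xR = xR)
  class(p) <- "vibtun_model2d_params"
  p
}

## raw-coordinate well forms, vectorized over row-points
.well_quad <- function(X, x0, H) {
  d1 <- X[, 1] - x0[1]; d2 <- X[, 2] - x0[2]
  0.5 * (H[1, 1] * d1^2 + 2 * H[1, 2] * d1 * d2 + H[2, 2] * d2^2)
}
.well_grad <- function(X, x0, H) {
  d1 <- X[, 1] - x0[1]; d2 <- X[, 2] - x0[2]
  cbind(H[1, 1] * d1 + H[1, 2] * d2, H[2, 1] * d1 + H[2, 2] * d2)
}

model_2d_energy_raw <- function(X, p) {
  vl <- .well_quad(X, p$xL, p$HL); vr <- .well_quad(X, p$xR, p$HR)
  den <- p$gamma1 * vl + p$gamma2 * vr
  out <- vl * (vr + p$d * p$gamma1) / den
  ## removable singularities at the minima
  out[vl == 0] <- 0
  out[vr == 0] <- p$d
  if (any(!is.finite(out))) stop("non-finite model energy: parameter error")
  out
}

model_2d_gradient_raw <- function(X, p) {
  vl <- .well_quad(X, p$xL, p$HL); vr <- .well_quad(X, p$xR, p$HR)
  gl <- .well_grad(X, p$xL, p$HL); gr <- .well_grad(X, p$xR, p$HR)
  den <- p$gamma1 * vl + p$gamma2 * vr
  num <- vl * (vr + p$d * p$gamma1)
  g <- (gl * (vr + p$d * p$gamma1) + vl * gr) / den -
    num * (p$gamma1 * gl + p$gamma2 * gr) / den^2
  g[vl == 0 | vr == 0, ] <- 0
  g
}

#' Two-dimensional benchmark double-well surface
#'
#' Returns the benchmark double well as a [potential_surface()] in mass-scaled
#' coordinates \eqn{\tilde x = \sqrt{m}\,x}.  Energies are relative to the
#' left minimum (`V = 0` there; the right minimum sits at `d`).  Analytic
#' gradients are provided; Hessians use tight central differences of the
#' analytic gradient.  At construction the harmonic limits are self-checked:
#' the Hessian eigenvalues at the left minimum must reproduce
#' (`alpha1_L`, `alpha2_L`) and the right-minimum energy must equal `d`.
#'
#' @param params a [model_2d_params()] object (or arguments forwarded to it).
#' @param ... forwarded to [model_2d_params()] when `params` is missing.
#' @return a `vibtun_pes` with attributes `params`, `min_L`, `min_R`
#'   (mass-scaled minima).
#' @export
model_2d_pes <- function(params = NULL, ...) {
  p <- if (is.null(params)) model_2d_params(...) else params
  stopifnot(inherits(p, "vibtun_model2d_params"))
  sq <- sqrt(p$m)
  e_many <- function(X) model_2d_energy_raw(X / sq, p)
  g_many <- function(X) model_2d_gradient_raw(X / sq, p) / sq
  g_one  <- function(x) as.numeric(g_many(matrix(x, nrow = 1)))
  h_one  <- function(x) {
    h <- 1e-6 * sq
    H <- matrix(0, 2, 2)
    for (i in 1:2) {
      e <- c(0, 0); e[i] <- h
      H[, i] <- (g_one(x + e) - g_one(x - e)) / (2 * h)
    }
    symmetrize(H)
  }
  pes <- potential_surface(
    dimension = 2,
    energy = function(x) e_many(matrix(x, nrow = 1)),
    gradient = g_one, hessian = h_one,
    energy_many = e_many, gradient_many = g_many,
    masses = c(p$m, p$m), label = "model-2d")
  attr(pes, "params") <- p
  attr(pes, "min_L") <- p$xL * sq
  attr(pes, "min_R") <- p$xR * sq
  ## startup self-check of the harmonic-limit construction
  evL <- sort(eigen(h_one(p$xL * sq), symmetric = TRUE, only.values = TRUE)$values)
  want <- sort(c(p$alpha1_L, p$alpha2_L)) / p$m
  if (max(abs(evL - want) / want) > 1e-4)
    stop("harmonic-limit self-check failed at the left minimum")
  eR <- pes$energy(p$xR * sq)
  if (abs(eR - p$d) > 1e-10 * max(1, p$d))
    stop("right-minimum energy self-check failed")
  pes
}

#' Mirror map of the benchmark surface
#'
#' The L/R mirror operation of the model, `(x1, x2) -> (-x1, x2)` (in either
#' raw or mass-scaled coordinates).  With symmetric parameters and `d = 0`
#' the potential is invariant under it.
#'
#' @param X point (length-2 vector) or matrix of row-points.
#' @return mirrored point(s).
#' @export
model_2d_mirror <- function(X) {
  if (is.matrix(X)) { X[, 1] <- -X[, 1]; X } else c(-X[1], X[2])
}
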