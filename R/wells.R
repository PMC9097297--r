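#' Characterize a potential minimum
#'
#' Refines `x_guess` to a stationary point by Newton iterations on the
#' gradient (falling back to quasi-Newton minimization if the local Hessian
#' is not positive definite), then performs normal-mode analysis on the
#' (optionally trans/rot-projected) mass-scaled Hessian.
#'
#' @param pes a [potential_surface()].
#' @param x_guess starting coordinates (mass-scaled), inside the basin of the
#'   target minimum.
#' @param grad_tol convergence threshold on the gradient norm.
#' @param nullspace_tol eigenvalues with `|ev| < nullspace_tol * max(ev)` are
#'   treated as rigid-body nullspace and excluded from frequencies.
#' @return object of class `vibtun_well`: `geometry`, `energy`, `hessian0`,
#'   `normal_modes` (columns, ascending frequency), `frequencies`
#'   (\eqn{\omega_i}, ascending), `A0` (PSD square root of the Hessian),
#'   `n_zero` (nullspace dimension).
#' @export
characterize_minimum <- function(pes, x_guess, grad_tol = 1e-10,
                                 nullspace_tol = 1e-8) {
  x <- as.numeric(x_guess)
  for (it in 1:100) {
    g <- pes$gradient(x)
    if (sqrt(sum(g^2)) < grad_tol) break
    H <- pes$hessian(x)
    ev <- eigen(H, symmetric = TRUE)
    keep <- abs(ev$values) > nullspace_tol * max(abs(ev$values))
    if (any(ev$values[keep] < 0)) {
      ## outside the quadratic basin: damped steepest descent
      x <- x - 0.1 * g / max(1, sqrt(sum(g^2)))
      next
    }
    step <- ev$vectors[, keep, drop = FALSE] %*%
      ((t(ev$vectors[, keep, drop = FALSE]) %*% g) / ev$values[keep])
    x <- x - as.numeric(step)
  }
  g <- pes$gradient(x)
  if (sqrt(sum(g^2)) > grad_tol * 1e3)
    stop("minimum refinement did not converge; |grad| = ", sqrt(sum(g^2)))
  H0 <- pes$hessian(x)
  e <- eigen(H0, symmetric = TRUE)
  scale <- max(abs(e$values))
  zero <- abs(e$values) < nullspace_tol * scale
  if (any(e$values[!zero] < 0))
    stop("negative curvature beyond the rigid-body nullspace: not a minimum")
  ord <- order(e$values)
  ord <- ord[!zero[ord]]
  structure(list(
    geometry = x,
    energy = pes$energy(x),
    hessian0 = H0,
    normal_modes = e$vectors[, ord, drop = FALSE],
    frequencies = sqrt(e$values[ord]),
    A0 = matrix_sqrt_psd(H0, tol = nullspace_tol),
    n_zero = sum(zero)
  ), class = "vibtun_well")
}

#' @export
print.vibtun_well <- function(x, ...) {
  cat("<vibtun_well> energy", format(x$energy, digits = 8),
      "| frequencies:", paste(format(x$frequencies, digits = 6), collapse = ", "),
      "\n")
  invisible(x)
}
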