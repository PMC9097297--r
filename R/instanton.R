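#' Classical momentum profile along one side of the path
#'
#' \eqn{p_0(s) = \sqrt{2(\tilde V(s) - \tilde V_{min})}} with the side's well
#' floor at zero; vanishes at the minimum and is non-negative everywhere on a
#' valid path.
#'
#' @param path a `vibtun_map`.
#' @param side `"L"` or `"R"`.
#' @return function `p0(s)` of the side's arc length.
#' @export
momentum_profile <- function(path, side = c("L", "R")) {
  sd <- map_side(path, side)
  function(s) {
    v <- sd$v(s)
    if (any(v < -1e-8)) stop("negative V - V_min beyond tolerance")
    sqrt(pmax(2 * v, 0))
  }
}

#' Propagate Gaussian width matrices along the path
#'
#' Integrates the matrix Riccati equation
#' \eqn{p_0\, dA/ds = H(s) - A^2} (the imaginary-time transport
#' \eqn{dA/d\tau = H - A^2} reparameterized by arc length) outward from the
#' side's minimum, starting at \eqn{s = \epsilon} with the harmonic value
#' \eqn{A(\epsilon) = A_0 = H_0^{1/2}}.  The amplitude exponent
#' \eqn{W_1} (log-prefactor of the semiclassical wavefunction, with
#' \eqn{dW_1/d\tau = \tfrac12[dp_0/ds + \mathrm{tr}(PAP) - \mathrm{tr} A_0]})
#' and the accumulated action \eqn{W_0} are carried in the same fixed-step
#' fourth-order Runge-Kutta integration; `A` is symmetrized after every step.
#' On a globally harmonic surface `A0` is a fixed point and `A(s) = A0`,
#' `W1 = 0` identically.
#'
#' @param path a `vibtun_map`.
#' @param side `"L"` or `"R"`.
#' @param epsilon initial jump: below this arc length the wavefunction is the
#'   exact harmonic form (0.1 au is the model default, 0.25 au typical for
#'   molecules).
#' @param rk_step RK4 step; default one tenth of the bead spacing.
#' @param s_end propagation end (default: this side's connection point).
#' @return object of class `vibtun_widths` with spline interpolants `A_ij(s)`,
#'   `W1(s)`, `W0(s)`, the momentum profile and bookkeeping fields.
#' @export
propagate_widths <- function(path, side = c("L", "R"), epsilon = 0.1,
                             rk_step = NULL, s_end = NULL) {
  side <- match.arg(side)
  sd <- map_side(path, side)
  if (is.null(s_end)) s_end <- sd$s_cp
  if (is.null(rk_step)) rk_step <- diff(path$S)[1] / 10
  stopifnot(epsilon > 0, s_end > epsilon)
  ndim <- path$ndim
  well <- sd$well
  A0 <- well$A0
  trA0 <- sum(diag(A0))
  p0 <- function(s) sqrt(pmax(2 * sd$v(s), 1e-300))
  ## W0 on (0, epsilon): harmonic region, quadrature on the spline
  W0_eps <- stats::integrate(function(s) sqrt(pmax(2 * sd$v(s), 0)),
                             0, epsilon, rel.tol = 1e-10)$value
  nstep <- max(50L, ceiling((s_end - epsilon) / rk_step))
  h <- (s_end - epsilon) / nstep
  keep_every <- max(1L, nstep %/% 2000L)
  deriv <- function(s, A) {
    p <- p0(s)
    tg <- sd$tangent(s)
    P <- diag(ndim) - tg %*% t(tg)
    dA <- (sd$h(s) - A %*% A) / p
    dW1 <- 0.5 * (sd$dv(s) / p + sum(diag(P %*% A %*% P)) - trA0) / p
    list(dA = dA, dW1 = dW1, dW0 = p)
  }
  A <- A0; W1 <- 0; W0 <- W0_eps; s <- epsilon
  ss <- numeric(0); As <- NULL; W1s <- numeric(0); W0s <- numeric(0)
  push <- function(s, A, W1, W0) {
    ss <<- c(ss, s); W1s <<- c(W1s, W1); W0s <<- c(W0s, W0)
    As <<- cbind(As, c(A))
  }
  push(s, A, W1, W0)
  for (k in seq_len(nstep)) {
    k1 <- deriv(s, A)
    k2 <- deriv(s + h / 2, A + h / 2 * k1$dA)
    k3 <- deriv(s + h / 2, A + h / 2 * k2$dA)
    k4 <- deriv(s + h, A + h * k3$dA)
    A <- A + h / 6 * (k1$dA + 2 * k2$dA + 2 * k3$dA + k4$dA)
    A <- symmetrize(A)
    W1 <- W1 + h / 6 * (k1$dW1 + 2 * k2$dW1 + 2 * k3$dW1 + k4$dW1)
    W0 <- W0 + h / 6 * (k1$dW0 + 2 * k2$dW0 + 2 * k3$dW0 + k4$dW0)
    s <- epsilon + k * h
    tg <- sd$tangent(s)
    Pp <- diag(ndim) - tg %*% t(tg)
    ev <- eigen(Pp %*% A %*% Pp, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-3 * max(abs(ev)))
      stop("width matrix developed a negative transverse eigenvalue at s = ",
           format(s, digits = 6), " (side ", side, ")")
    if (k %% keep_every == 0 || k == nstep) push(s, A, W1, W0)
  }
  A_spl <- lapply(seq_len(ndim * ndim), function(i)
    stats::splinefun(ss, As[i, ], method = "natural"))
  structure(list(
    side = side, epsilon = epsilon, s_end = s_end, rk_step = h,
    ndim = ndim, well = well, sd = sd, p0 = p0,
    A_fun = function(s) matrix(vapply(A_spl, function(f) f(s), numeric(1)),
                               ndim, ndim),
    dA_fun = function(s) matrix(vapply(A_spl, function(f) f(s, deriv = 1),
                                       numeric(1)), ndim, ndim),
    W1_fun = stats::splinefun(ss, W1s, method = "natural"),
    W0_fun = stats::splinefun(ss, W0s, method = "natural"),
    grid = ss
  ), class = "vibtun_widths")
}

#' Transport the excitation amplitude and nodal vector
#'
#' For one quantum ladder in the normal mode `mode_index` (frequency
#' \eqn{\omega_e}), integrates the transport pair
#' \deqn{p_0\, dF/ds = \omega_e F, \qquad
#'       p_0\, dU/ds = (\omega_e - P A P)\,U - 2 \omega_e F\, \kappa(s),}
#' where \eqn{\kappa = d\hat t/ds} is the path curvature and `P` projects out
#' the local tangent.  Initial conditions follow from matching the instanton
#' wavefunction to the harmonic-oscillator excited state at the jump distance:
#' \eqn{F(\epsilon) = U_0^T(x(\epsilon) - x_{min})} and `U` starts as the
#' transverse part of the excited normal mode \eqn{U_0}.  On a separable
#' surface with a transverse excited mode, `F` stays zero and `U` stays
#' \eqn{U_0}; for a longitudinal excitation of a harmonic well, `F(s)` equals
#' the arc-length distance (the WKB transport solution).
#'
#' @param path a `vibtun_map`.
#' @param side `"L"` or `"R"`.
#' @param widths a [propagate_widths()] result for the same side.
#' @param mode_index which normal mode of the side's well is excited.
#' @return object of class `vibtun_excitation` with `F_fun(s)`, `U_fun(s)`
#'   and their derivatives, `omega_e`, and `mode_index`.
#' @export
propagate_excitation <- function(path, side = c("L", "R"), widths, mode_index) {
  side <- match.arg(side)
  sd <- widths$sd
  ndim <- path$ndim
  eps <- widths$epsilon
  omega <- sd$well$frequencies[mode_index]
  U0 <- sd$well$normal_modes[, mode_index]
  x_eps <- sd$x(eps)
  Fv <- sum(U0 * (x_eps - sd$well$geometry))
  tg0 <- sd$tangent(eps)
  U <- U0 - tg0 * sum(tg0 * U0)
  if (sqrt(sum(U^2)) < 1e-10 && abs(Fv) < 1e-12)
    stop("excited mode has neither longitudinal nor transverse content")
  p0 <- widths$p0
  h <- widths$rk_step
  s_end <- widths$s_end
  nstep <- max(50L, ceiling((s_end - eps) / h))
  h <- (s_end - eps) / nstep
  deriv <- function(s, Fv, U) {
    p <- p0(s)
    tg <- sd$tangent(s)
    P <- diag(ndim) - tg %*% t(tg)
    A <- widths$A_fun(s)
    kap <- sd$curvature(s)
    dF <- omega * Fv / p
    dU <- (omega * U - P %*% A %*% P %*% U - 2 * omega * Fv * kap) / p
    list(dF = dF, dU = as.numeric(dU))
  }
  s <- eps
  ss <- s; Fs <- Fv; Us <- matrix(U, ncol = 1)
  for (k in seq_len(nstep)) {
    k1 <- deriv(s, Fv, U)
    k2 <- deriv(s + h / 2, Fv + h / 2 * k1$dF, U + h / 2 * k1$dU)
    k3 <- deriv(s + h / 2, Fv + h / 2 * k2$dF, U + h / 2 * k2$dU)
    k4 <- deriv(s + h, Fv + h * k3$dF, U + h * k3$dU)
    Fv <- Fv + h / 6 * (k1$dF + 2 * k2$dF + 2 * k3$dF + k4$dF)
    U <- U + h / 6 * (k1$dU + 2 * k2$dU + 2 * k3$dU + k4$dU)
    s <- eps + k * h
    tg <- sd$tangent(s)
    U <- U - tg * sum(tg * U)    # keep U transverse
    if (k %% 10 == 0 || k == nstep) {
      ss <- c(ss, s); Fs <- c(Fs, Fv); Us <- cbind(Us, U)
    }
  }
  F_spl <- stats::splinefun(ss, Fs, method = "natural")
  U_spl <- lapply(seq_len(ndim), function(i)
    stats::splinefun(ss, Us[i, ], method = "natural"))
  structure(list(
    side = side, mode_index = mode_index, omega_e = omega,
    F_fun = F_spl,
    dF_fun = function(s) F_spl(s, deriv = 1),
    U_fun = function(s) vapply(U_spl, function(f) f(s), numeric(1)),
    dU_fun = function(s) vapply(U_spl, function(f) f(s, deriv = 1), numeric(1))
  ), class = "vibtun_excitation")
}

#' Semiclassical data for one side and one local state
#'
#' Bundles propagated widths with the excitation transports needed for a
#' local state given as a per-mode quanta vector, e.g. `c(0, 1)` for one
#' quantum in mode 2.
#'
#' @param path a `vibtun_map`.
#' @param side `"L"` or `"R"`.
#' @param quanta integer vector of quanta per normal mode of the side's well.
#' @param epsilon,rk_step,s_end passed to [propagate_widths()].
#' @param widths optionally reuse an existing [propagate_widths()] result.
#' @return object of class `vibtun_field`.
#' @export
instanton_field <- function(path, side = c("L", "R"), quanta = NULL,
                            epsilon = 0.1, rk_step = NULL, s_end = NULL,
                            widths = NULL) {
  side <- match.arg(side)
  if (is.null(widths))
    widths <- propagate_widths(path, side, epsilon = epsilon,
                               rk_step = rk_step, s_end = s_end)
  ndim <- path$ndim
  if (is.null(quanta)) quanta <- rep(0L, length(widths$well$frequencies))
  exc <- list()
  for (m in which(quanta > 0))
    exc[[as.character(m)]] <- propagate_excitation(path, side, widths, m)
  structure(list(side = side, quanta = quanta, widths = widths,
                 excitations = exc, epsilon = widths$epsilon),
            class = "vibtun_field")
}

## ---- local linearization of one side's wavefunction at the dividing plane ----
## Returns everything needed for the Herring surface integral at arc length
## s (per side), with plane normal nhat and in-plane orthonormal basis Q.
.side_snapshot <- function(field, s, nhat, Q) {
  w <- field$widths
  sd <- w$sd
  ndim <- w$ndim
  tau <- sd$tangent(s)
  a <- sum(tau * nhat)
  cs <- as.numeric(t(Q) %*% tau)
  P <- diag(ndim) - tau %*% t(tau)
  A <- w$A_fun(s)
  p <- w$p0(s)
  dp <- sd$dv(s) / p
  W1 <- w$W1_fun(s)
  W0 <- w$W0_fun(s)
  PAP <- P %*% A %*% P
  ## leading-order semiclassical flux: only the classical-action exponent
  ## W0(S) is differentiated / Taylor-expanded on the plane; amplitude
  ## factors (W1, A(S), F, U) enter by value only
  M <- t(Q) %*% PAP %*% Q + dp * (cs %*% t(cs))
  b <- p * cs
  D <- -a * p
  dvec <- -a * dp * cs
  E <- matrix(0, ncol(Q), ncol(Q))
  ## excitation factors
  modes <- list()
  for (nm in names(field$excitations)) {
    ex <- field$excitations[[nm]]
    U <- ex$U_fun(s)
    U <- U - tau * sum(tau * U)
    modes[[nm]] <- list(
      nu = field$quanta[as.integer(nm)],
      omega = ex$omega_e,
      F = ex$F_fun(s),
      u = as.numeric(t(Q) %*% U),
      phi = 0,
      psi = numeric(ncol(Q))
    )
  }
  ## normalization: matched harmonic prefactor x excitation constants
  freqs <- sd$well$frequencies
  n0 <- prod(freqs / pi)^(1 / 4)
  cnu <- 1
  for (mm in modes) cnu <- cnu * (2 * mm$omega)^(mm$nu / 2) / sqrt(factorial(mm$nu))
  list(a = a, cs = cs, M = symmetrize(M), b = b, D = D, dvec = dvec,
       E = symmetrize(E), W0 = W0, W1 = W1, p = p, modes = modes,
       N = n0 * cnu, ndim = ndim)
}

## Gaussian moment of a product of linear forms, x ~ N(mu, Sigma):
## E[prod_i (v_i . x)] by the mean-augmented Isserlis recursion.
.gauss_mom <- function(vs, mu, Sigma) {
  n <- length(vs)
  if (n == 0) return(1)
  v1 <- vs[[1]]
  out <- sum(v1 * mu) * .gauss_mom(vs[-1], mu, Sigma)
  if (n >= 2) {
    for (j in 2:n) {
      out <- out + as.numeric(t(v1) %*% Sigma %*% vs[[j]]) *
        .gauss_mom(vs[-c(1, j)], mu, Sigma)
    }
  }
  out
}

## expectation of a "poly" (list of terms list(coef=, vecs=list())) under
## N(mu, Sigma)
.poly_expect <- function(poly, mu, Sigma) {
  tot <- 0
  for (tm in poly) tot <- tot + tm$coef * .gauss_mom(tm$vecs, mu, Sigma)
  tot
}

.poly_const <- function(c) list(list(coef = c, vecs = list()))
.poly_lin <- function(c0, v) {
  ## c0 + v.x
  out <- list(list(coef = c0, vecs = list()))
  if (sqrt(sum(v^2)) > 0) out <- c(out, list(list(coef = 1, vecs = list(v))))
  out
}
.poly_mul <- function(p1, p2) {
  out <- list()
  for (t1 in p1) for (t2 in p2)
    out[[length(out) + 1]] <- list(coef = t1$coef * t2$coef,
                                   vecs = c(t1$vecs, t2$vecs))
  out
}
.poly_add <- function(...) do.call(c, list(...))
.poly_scale <- function(p, f) lapply(p, function(tm) { tm$coef <- tm$coef * f; tm })
## quadratic form 1/2 x' E x as a poly via eigendecomposition
.poly_quad <- function(E) {
  e <- eigen(symmetrize(E), symmetric = TRUE)
  out <- list()
  for (i in seq_along(e$values)) {
    if (abs(e$values[i]) < 1e-300) next
    v <- e$vectors[, i]
    out[[length(out) + 1]] <- list(coef = 0.5 * e$values[i], vecs = list(v, v))
  }
  if (!length(out)) out <- .poly_const(0)
  out
}

## assemble the Herring bracket polynomial for a pair of side snapshots
.herring_poly <- function(sl, sr) {
  phi_of <- function(sn) {
    p <- .poly_const(1)
    for (mm in sn$modes) for (q in seq_len(mm$nu))
      p <- .poly_mul(p, .poly_lin(mm$F, mm$u))
    p
  }
  dphi_of <- function(sn) {
    ## derivative of the product of linear factors along the plane normal
    mods <- sn$modes
    tot <- .poly_const(0)
    if (!length(mods)) return(tot)
    for (k in seq_along(mods)) {
      term <- .poly_scale(.poly_lin(mods[[k]]$phi, mods[[k]]$psi), mods[[k]]$nu)
      term <- .poly_mul(term, .poly_pow(.poly_lin(mods[[k]]$F, mods[[k]]$u),
                                        mods[[k]]$nu - 1))
      for (j in seq_along(mods)) if (j != k)
        term <- .poly_mul(term, .poly_pow(.poly_lin(mods[[j]]$F, mods[[j]]$u),
                                          mods[[j]]$nu))
      tot <- .poly_add(tot, term)
    }
    tot
  }
  TL <- .poly_add(.poly_lin(sl$D, sl$dvec), .poly_quad(sl$E))
  TR <- .poly_add(.poly_lin(sr$D, sr$dvec), .poly_quad(sr$E))
  PhL <- phi_of(sl); PhR <- phi_of(sr)
  .poly_add(
    .poly_mul(PhR, dphi_of(sl)),
    .poly_mul(.poly_mul(PhR, PhL), TL),
    .poly_scale(.poly_mul(PhL, dphi_of(sr)), -1),
    .poly_scale(.poly_mul(.poly_mul(PhL, PhR), TR), -1)
  )
}

.poly_pow <- function(p, n) {
  if (n <= 0) return(.poly_const(1))
  out <- p
  if (n >= 2) for (k in 2:n) out <- .poly_mul(out, p)
  out
}

## shared setup: plane basis, combined Gaussian, prefactor
.herring_setup <- function(fieldL, fieldR, path, s_cp = NULL) {
  ndim <- path$ndim
  if (is.null(s_cp)) s_cp <- path$S_cp
  sL <- s_cp
  sR <- path$S_tot - s_cp
  ## plane normal: tangent of the full path at s_cp (averaged at the stored
  ## connection point when the path has a kink)
  if (abs(s_cp - path$S_cp) < 1e-12) {
    nhat <- path$tangent_cp
  } else {
    nhat <- vapply(path$x_spline, function(f) f(s_cp, deriv = 1), numeric(1))
    nhat <- nhat / sqrt(sum(nhat^2))
  }
  Q <- qr.Q(qr(cbind(nhat, diag(ndim))))[, -1, drop = FALSE]
  snapL <- .side_snapshot(fieldL, sL, nhat, Q)
  snapR <- .side_snapshot(fieldR, sR, nhat, Q)
  M <- snapL$M + snapR$M
  b <- snapL$b + snapR$b
  em <- eigen(symmetrize(M), symmetric = TRUE)
  keep <- em$values > 1e-8 * max(em$values)
  if (any(em$values < -1e-8 * max(abs(em$values))))
    stop("combined width form is not PSD on the dividing plane")
  lam <- em$values[keep]
  R <- em$vectors[, keep, drop = FALSE]
  Sigma <- R %*% ((1 / lam) * t(R))
  mu <- -as.numeric(Sigma %*% b)
  logZ <- 0.5 * sum(log(2 * pi / lam)) + 0.5 * sum(b * (Sigma %*% b))
  pref <- 0.5 * snapL$N * snapR$N * exp(-(snapL$W0 + snapL$W1 +
                                          snapR$W0 + snapR$W1) + logZ)
  list(snapL = snapL, snapR = snapR, M = M, b = b, mu = mu, Sigma = Sigma,
       lam = lam, R = R, pref = pref, Q = Q, nhat = nhat)
}

#' Tunneling-matrix element from the generalized Herring formula (analytic)
#'
#' Evaluates the surface integral of the Herring flux,
#' \deqn{h_{ij} = \tfrac12 \oint_D \left[\phi_j^{(R)} \partial_n \phi_i^{(L)}
#'  - \phi_i^{(L)} \partial_n \phi_j^{(R)}\right] d\Sigma,}
#' with the semiclassical side wavefunctions linearized at the connection
#' point, by closed-form Gaussian moments (valid for local states with at
#' most one quantum per mode and per side).  The result carries the
#' \eqn{\exp(-W_0)} action factor, the det' ratio of width determinants
#' (zero modes excluded by threshold), and the `F`/`U` excitation prefactors.
#'
#' @param fieldL,fieldR [instanton_field()] objects for the two sides.
#' @param path the `vibtun_map` both fields were propagated on.
#' @param s_cp optional connection-point override (arc length along the full
#'   path; both fields must have been propagated at least that far).
#' @return scalar coupling `h` (same units as the potential).
#' @export
tm_element_fundamental <- function(fieldL, fieldR, path, s_cp = NULL) {
  if (sum(fieldL$quanta) > 1 || sum(fieldR$quanta) > 1)
    stop("analytic element restricted to nu, nu' <= 1; use tm_element_numeric")
  hs <- .herring_setup(fieldL, fieldR, path, s_cp)
  poly <- .herring_poly(hs$snapL, hs$snapR)
  hs$pref * .poly_expect(poly, hs$mu, hs$Sigma)
}

#' Tunneling-matrix element by numerical quadrature on the dividing plane
#'
#' Same Herring flux as [tm_element_fundamental()], but the in-plane integral
#' is evaluated by Gauss-Hermite quadrature in the eigenbasis of the combined
#' width matrix.  Works for arbitrary excitation products (any number of
#' quanta in any number of modes).
#'
#' @inheritParams tm_element_fundamental
#' @param order quadrature order per transverse dimension.
#' @return scalar coupling `h`.
#' @export
tm_element_numeric <- function(fieldL, fieldR, path, s_cp = NULL, order = 20) {
  hs <- .herring_setup(fieldL, fieldR, path, s_cp)
  gh <- pracma::gaussHermite(order)
  k <- length(hs$lam)
  ## tensor nodes xi = mu + R diag(sqrt(2/lam)) z, weight prod w_i e^{z^2} ...
  grids <- rep(list(seq_len(order)), k)
  idx <- as.matrix(expand.grid(grids))
  scale <- sqrt(2 / hs$lam)
  bracket <- function(xi) {
    val_phi <- function(sn) {
      v <- 1
      for (mm in sn$modes) v <- v * (mm$F + sum(mm$u * xi))^mm$nu
      v
    }
    val_dphi <- function(sn) {
      mods <- sn$modes
      if (!length(mods)) return(0)
      tot <- 0
      for (kk in seq_along(mods)) {
        term <- mods[[kk]]$nu * (mods[[kk]]$phi + sum(mods[[kk]]$psi * xi)) *
          (mods[[kk]]$F + sum(mods[[kk]]$u * xi))^(mods[[kk]]$nu - 1)
        for (j in seq_along(mods)) if (j != kk)
          term <- term * (mods[[j]]$F + sum(mods[[j]]$u * xi))^mods[[j]]$nu
        tot <- tot + term
      }
      tot
    }
    Tval <- function(sn) sn$D + sum(sn$dvec * xi) + 0.5 * sum(xi * (sn$E %*% xi))
    val_phi(hs$snapR) * val_dphi(hs$snapL) +
      val_phi(hs$snapR) * val_phi(hs$snapL) * Tval(hs$snapL) -
      val_phi(hs$snapL) * val_dphi(hs$snapR) -
      val_phi(hs$snapL) * val_phi(hs$snapR) * Tval(hs$snapR)
  }
  tot <- 0
  for (r in seq_len(nrow(idx))) {
    z <- gh$x[idx[r, ]]
    wq <- prod(gh$w[idx[r, ]])
    xi <- hs$mu + as.numeric(hs$R %*% (scale * z))
    tot <- tot + wq * bracket(xi)
  }
  ## gaussHermite weights integrate e^{-z^2}; our Gaussian normalization is
  ## absorbed into pref via logZ, so divide by the plain Gaussian integral
  hs$pref * tot * prod(1 / sqrt(pi))^k
}

#' Connection-point sensitivity of a tunneling-matrix element
#'
#' Re-evaluates the coupling on a grid of connection points inside the
#' barrier.  At resonance (equal local energies) the element is invariant;
#' off resonance the spread across the scan estimates the error from the
#' neglected overlap of the local states.
#'
#' @inheritParams tm_element_fundamental
#' @param cp_range fractions of the total path length delimiting the scan
#'   (must lie inside the barrier region, default the central third).
#' @param n_grid number of scan points.
#' @param numeric use the quadrature evaluation instead of the analytic one.
#' @return list with `h_mean`, `h_spread` (max - min), `h_at_cp`, and the
#'   scan table.
#' @export
tm_sensitivity <- function(fieldL, fieldR, path, cp_range = c(1 / 3, 2 / 3),
                           n_grid = 11, numeric = FALSE) {
  stopifnot(cp_range[1] > 0.15, cp_range[2] < 0.85)
  scp <- seq(cp_range[1], cp_range[2], length.out = n_grid) * path$S_tot
  need_L <- max(scp); need_R <- path$S_tot - min(scp)
  if (fieldL$widths$s_end < need_L - 1e-9 ||
      fieldR$widths$s_end < need_R - 1e-9)
    stop("fields not propagated far enough for the requested scan range")
  f <- if (numeric) tm_element_numeric else tm_element_fundamental
  hv <- vapply(scp, function(s) f(fieldL, fieldR, path, s_cp = s), numeric(1))
  list(h_mean = mean(hv), h_spread = max(hv) - min(hv),
       h_at_cp = f(fieldL, fieldR, path),
       scan = data.frame(s_cp = scp, h = hv))
}

#' Effective tunneling barrier for a local state
#'
#' \eqn{V_{eff} = V_{max} + \sum_t (\nu_t + \tfrac12)\lambda_t -
#' E_{loc}} where \eqn{V_{max}} is the potential maximum along the path,
#' \eqn{\lambda_t} are the non-zero eigenvalues of the tangent-projected
#' width matrix \eqn{A_\perp = P A P} at the barrier top (transported from
#' the left minimum), and \eqn{E_{loc} = \sum_i (\nu_i + \tfrac12)\omega_i}
#' is the harmonic local energy.  Longitudinal quanta (mode along the path at
#' the minimum) lower the barrier; transverse quanta raise the zero-point
#' contribution at the barrier by \eqn{\lambda_t} while removing
#' \eqn{\omega_t} at the well.
#'
#' @param path a `vibtun_map`.
#' @param quanta per-mode quanta of the left-well state (default ground
#'   state).
#' @param widths optional precomputed left-side widths reaching the barrier
#'   top.
#' @param epsilon initial jump for the width propagation.
#' @return scalar effective barrier (same units as the potential).
#' @export
effective_barrier <- function(path, quanta = NULL, widths = NULL,
                              epsilon = 0.1) {
  vs <- path$v_spline
  S_tot <- path$S_tot
  op <- stats::optimize(function(s) -vs(s), c(0.15 * S_tot, 0.85 * S_tot))
  S_max <- op$minimum; V_max <- -op$objective
  ## warn about multiple interior maxima
  vb <- path$V
  dmax <- which(diff(sign(diff(vb))) == -2) + 1
  if (length(dmax) > 1)
    warning("multiple maxima of V(S); using the global one")
  if (is.null(widths))
    widths <- propagate_widths(path, "L", epsilon = epsilon,
                               s_end = max(S_max, path$S_cp) + 1e-9)
  wellL <- path$wellL
  nmode <- length(wellL$frequencies)
  if (is.null(quanta)) quanta <- rep(0L, nmode)
  tg <- vapply(path$x_spline, function(f) f(S_max, deriv = 1), numeric(1))
  tg <- tg / sqrt(sum(tg^2))
  P <- diag(path$ndim) - tg %*% t(tg)
  A <- widths$A_fun(S_max)
  evs <- eigen(P %*% A %*% P, symmetric = TRUE, only.values = TRUE)$values
  lam <- sort(evs[evs > 1e-8 * max(evs)], decreasing = TRUE)
  ## classify well modes: longitudinal = largest overlap with the entry tangent
  tg0 <- vapply(path$x_spline, function(f) f(1e-6, deriv = 1), numeric(1))
  tg0 <- tg0 / sqrt(sum(tg0^2))
  ovl <- abs(as.numeric(t(wellL$normal_modes) %*% tg0))
  long_mode <- which.max(ovl)
  trans_modes <- setdiff(seq_len(nmode), long_mode)
  ## transverse well modes matched to barrier eigenvalues by descending order
  ord <- trans_modes[order(wellL$frequencies[trans_modes], decreasing = TRUE)]
  nu_t <- quanta[ord]
  if (length(lam) < length(nu_t))
    stop("fewer transverse width eigenvalues than transverse modes")
  e_loc <- sum((quanta + 0.5) * wellL$frequencies)
  V_max + sum((nu_t + 0.5) * lam[seq_along(nu_t)]) - e_loc
}
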