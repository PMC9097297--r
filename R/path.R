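#' Optimize the minimum action path between two wells
#'
#' Discretizes the path into `n_beads` beads and minimizes the Jacobi action
#' \eqn{W_0 = \int \sqrt{2(\tilde V - \tilde V_{min})}\, dS} by a string
#' method: cycles of limited-memory quasi-Newton minimization over the free
#' interior beads interleaved with equal-arc-length spline reparameterization.
#' Convergence is declared when the largest component of the action gradient
#' perpendicular to the local tangent drops below `tol`.
#'
#' For wells at different energies (`d > 0`) the action is taken on the
#' modified surface \eqn{\tilde V = V - \Theta(S - S_{cp})\,d}: beads beyond
#' the connection point (fixed a priori at fraction `cp` of the bead chain,
#' default the middle) are shifted down by `d` so that both endpoints sit at
#' zero.  The resulting path has a tangent discontinuity at the connection
#' point; the stored connection-point tangent is the renormalized average of
#' its one-sided limits.
#'
#' @param pes a [potential_surface()].
#' @param wellL,wellR [characterize_minimum()] results for the two endpoints
#'   (left = energy reference, right offset by `d`).
#' @param n_beads number of beads (`>= 31`).
#' @param tol convergence threshold on the perpendicular action-gradient
#'   component (au).
#' @param d energy offset of the right minimum (must match the surface).
#' @param cp connection-point position as a fraction of the bead chain.
#' @param max_cycles maximum optimization/reparameterization cycles.
#' @param init optional `n_beads x dim` initial path (default: straight line).
#' @return object of class `vibtun_map`; see Details.
#' @details The returned object carries the beads, arc lengths `S` (equal
#'   spacing, `S[1] = 0`), total length `S_tot`, connection point
#'   (`cp_index`, `S_cp`), natural-cubic-spline interpolants of geometry,
#'   potential and Hessian elements against `S`, per-bead unit tangents, the
#'   convergence residual, and the action history across cycles.
#' @export
optimize_map <- function(pes, wellL, wellR, n_beads = 301, tol = 1e-6,
                         d = 0, cp = 0.5, max_cycles = 80, init = NULL) {
  stopifnot(n_beads >= 31)
  nb <- n_beads
  ndim <- pes$dimension
  e1 <- wellL$geometry; e2 <- wellR$geometry
  if (sqrt(sum((e1 - e2)^2)) < 1e-8) stop("wells coincide")
  cp_index <- max(2, min(nb - 1, round(1 + cp * (nb - 1))))
  edge_shift <- ifelse(seq_len(nb - 1) >= cp_index, d, 0)

  P <- if (is.null(init)) {
    frac <- seq(0, 1, length.out = nb)
    outer(1 - frac, e1) + outer(frac, e2)
  } else as.matrix(init)

  pval <- function(X, sh) sqrt(pmax(2 * (pes$energy_many(X) - sh), 0))
  mkP <- function(z) rbind(e1, matrix(z, ncol = ndim), e2)

  act_full <- function(Pz) {
    pL <- pval(Pz[-nb, , drop = FALSE], edge_shift)
    pR <- pval(Pz[-1, , drop = FALSE], edge_shift)
    dsv <- sqrt(rowSums((Pz[-1, , drop = FALSE] - Pz[-nb, , drop = FALSE])^2))
    sum(0.5 * (pL + pR) * dsv)
  }
  act_gr_full <- function(Pz) {
    dvec <- Pz[-1, , drop = FALSE] - Pz[-nb, , drop = FALSE]
    dn <- sqrt(rowSums(dvec^2))
    u <- dvec / dn
    G <- pes$gradient_many(Pz)
    V <- pes$energy_many(Pz)
    pLv <- pval(Pz[-nb, , drop = FALSE], edge_shift)
    pRv <- pval(Pz[-1, , drop = FALSE], edge_shift)
    pe <- 0.5 * (pLv + pRv)
    g <- matrix(0, nb, ndim)
    for (side in 1:2) {
      idx <- if (side == 1) seq_len(nb - 1) else 2:nb
      vt <- pmax(V[idx] - edge_shift, 0)
      pp <- sqrt(2 * vt)
      dp <- G[idx, , drop = FALSE] / pmax(pp, 1e-12)
      dp[vt <= 0, ] <- 0
      g[idx, ] <- g[idx, ] + 0.5 * dp * dn +
        (if (side == 1) -pe * u else pe * u)
    }
    g
  }

  ## optimize perpendicular offsets relative to a reference chain: removes the
  ## flat tangential directions of the discretized action
  W_hist <- numeric(0)
  resid <- Inf
  nfree <- ndim - 1
  for (cyc in seq_len(max_cycles)) {
    tg <- rbind(P[2, ] - P[1, ],
                P[3:nb, , drop = FALSE] - P[1:(nb - 2), , drop = FALSE],
                P[nb, ] - P[nb - 1, ])
    tg <- tg / sqrt(rowSums(tg^2))
    ## per-bead orthonormal complement of the tangent
    Nbasis <- lapply(seq_len(nb), function(i) {
      qr.Q(qr(cbind(tg[i, ], diag(ndim))))[, -1, drop = FALSE]
    })
    toP <- function(y) {
      Y <- matrix(y, nb - 2, nfree)
      Pz <- P
      for (i in 2:(nb - 1))
        Pz[i, ] <- P[i, ] + Nbasis[[i]] %*% Y[i - 1, ]
      Pz
    }
    fn <- function(y) act_full(toP(y))
    gr <- function(y) {
      g <- act_gr_full(toP(y))
      out <- matrix(0, nb - 2, nfree)
      for (i in 2:(nb - 1))
        out[i - 1, ] <- t(Nbasis[[i]]) %*% g[i, ]
      c(out)
    }
    o <- stats::optim(rep(0, (nb - 2) * nfree), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 3000, factr = 1e2,
                                     pgtol = tol / 10))
    Popt <- toP(o$par)
    W_hist <- c(W_hist, o$value)
    ## residual: perpendicular action-gradient component on the optimized chain
    gfull <- act_gr_full(Popt)[2:(nb - 1), , drop = FALSE]
    tg2 <- Popt[3:nb, , drop = FALSE] - Popt[1:(nb - 2), , drop = FALSE]
    tg2 <- tg2 / sqrt(rowSums(tg2^2))
    gperp <- gfull - tg2 * rowSums(gfull * tg2)
    resid <- max(abs(gperp))
    P <- .reparam_equal(Popt)
    if (resid <= tol) { P_final <- Popt; break }
    if (cyc == max_cycles) {
      warning("string method reached max_cycles; residual = ",
              format(resid, digits = 4))
      P_final <- Popt
    }
  }
  span <- sqrt(sum((e1 - e2)^2))
  mid_min <- min(sqrt(rowSums((P - matrix(e1, nb, ndim, byrow = TRUE))^2)) +
                 sqrt(rowSums((P - matrix(e2, nb, ndim, byrow = TRUE))^2)))
  if (mid_min < 0.5 * span) stop("path collapsed onto one well")
  P <- .reparam_equal(P_final)
  .map_fields(pes, P, cp_index, d, wellL, wellR, resid, W_hist, tol)
}

## equal-arc-length resampling through a natural-spline fit of the bead chain
.reparam_equal <- function(P) {
  nb <- nrow(P)
  ds <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nb, , drop = FALSE])^2))
  s <- c(0, cumsum(ds))
  sp <- lapply(seq_len(ncol(P)), function(k)
    stats::splinefun(s, P[, k], method = "natural"))
  ## refine the arc-length measure on the spline curve
  tfine <- seq(0, s[nb], length.out = 8 * nb)
  Xf <- vapply(sp, function(f) f(tfine), numeric(length(tfine)))
  dsf <- sqrt(rowSums((Xf[-1, , drop = FALSE] - Xf[-nrow(Xf), , drop = FALSE])^2))
  sf <- c(0, cumsum(dsf))
  tk <- stats::approx(sf, tfine, xout = seq(0, sf[length(sf)], length.out = nb))$y
  out <- vapply(sp, function(f) f(tk), numeric(nb))
  out[1, ] <- P[1, ]; out[nb, ] <- P[nb, ]
  out
}

.map_fields <- function(pes, P, cp_index, d, wellL, wellR, resid, W_hist, tol) {
  nb <- nrow(P); ndim <- ncol(P)
  ds <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nb, , drop = FALSE])^2))
  S <- c(0, cumsum(ds))
  S_tot <- S[nb]
  S_cp <- S[cp_index]
  Vraw <- pes$energy_many(P)
  if (min(Vraw) < -1e-9 || min(Vraw[cp_index:nb] - d) < -1e-9)
    stop("path dips below a well floor; aborting")
  Hs <- vapply(seq_len(nb), function(i) c(pes$hessian(P[i, ])),
               numeric(ndim * ndim))
  x_spline <- lapply(seq_len(ndim), function(k)
    stats::splinefun(S, P[, k], method = "natural"))
  h_spline <- lapply(seq_len(ndim * ndim), function(k)
    stats::splinefun(S, Hs[k, ], method = "natural"))
  v_spline <- stats::splinefun(S, Vraw, method = "natural")
  tang <- matrix(NA_real_, nb, ndim)
  for (k in seq_len(ndim)) tang[, k] <- x_spline[[k]](S, deriv = 1)
  tang <- tang / sqrt(rowSums(tang^2))
  ## one-sided tangents at the connection point (kink for d != 0)
  hloc <- min(diff(S))
  tL <- vapply(x_spline, function(f)
    (f(S_cp) - f(S_cp - hloc)) / hloc, numeric(1))
  tR <- vapply(x_spline, function(f)
    (f(S_cp + hloc) - f(S_cp)) / hloc, numeric(1))
  tL <- tL / sqrt(sum(tL^2)); tR <- tR / sqrt(sum(tR^2))
  t_cp <- (tL + tR) / sqrt(sum((tL + tR)^2))
  tang[cp_index, ] <- t_cp
  structure(list(
    beads = P, S = S, S_tot = S_tot, cp_index = cp_index, S_cp = S_cp,
    d = d, V = Vraw, hessians = Hs,
    x_spline = x_spline, h_spline = h_spline, v_spline = v_spline,
    tangents = tang, tangent_cp = t_cp,
    wellL = wellL, wellR = wellR,
    residual = resid, tol = tol, action_history = W_hist,
    ndim = ndim
  ), class = "vibtun_map")
}

#' @export
print.vibtun_map <- function(x, ...) {
  cat("<vibtun_map> ", nrow(x$beads), " beads, S_tot = ",
      format(x$S_tot, digits = 8), ", residual = ",
      format(x$residual, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Per-side view of a minimum action path
#'
#' Reparameterizes the path fields by the arc length `s` measured from the
#' given side's minimum toward the connection point, on the modified surface
#' (right-side energies shifted down by `d` so each side's well floor is 0).
#'
#' @param path a `vibtun_map`.
#' @param side `"L"` or `"R"`.
#' @return list of field closures: `v(s)`, `dv(s)`, `h(s)` (Hessian matrix),
#'   `x(s)`, `tangent(s)` (unit, pointing away from the side's minimum),
#'   `s_cp` (arc length from this side's minimum to the connection point),
#'   `len` (full path length), `well`.
#' @export
map_side <- function(path, side = c("L", "R")) {
  side <- match.arg(side)
  ndim <- path$ndim
  vg <- path$v_spline
  if (side == "L") {
    tosg <- function(s) s
    sgn <- 1
    off <- 0
    s_cp <- path$S_cp
    well <- path$wellL
  } else {
    tosg <- function(s) path$S_tot - s
    sgn <- -1
    off <- path$d
    s_cp <- path$S_tot - path$S_cp
    well <- path$wellR
  }
  list(
    side = side,
    v  = function(s) vg(tosg(s)) - off,
    dv = function(s) sgn * vg(tosg(s), deriv = 1),
    curvature = function(s) {
      sg <- tosg(s)
      k <- vapply(path$x_spline, function(f) f(sg, deriv = 2), numeric(1))
      tg <- vapply(path$x_spline, function(f) f(sg, deriv = 1), numeric(1))
      tg <- tg / sqrt(sum(tg^2))
      k - tg * sum(k * tg)
    },
    h  = function(s) {
      sg <- tosg(s)
      matrix(vapply(path$h_spline, function(f) f(sg), numeric(1)), ndim, ndim)
    },
    x = function(s) {
      sg <- tosg(s)
      vapply(path$x_spline, function(f) f(sg), numeric(1))
    },
    tangent = function(s) {
      sg <- tosg(s)
      tg <- sgn * vapply(path$x_spline, function(f) f(sg, deriv = 1), numeric(1))
      tg / sqrt(sum(tg^2))
    },
    s_cp = s_cp, len = path$S_tot, well = well
  )
}

#' Jacobi action along one side of the path
#'
#' \eqn{W_0 = \int_0^{s} p_0\, ds'} with
#' \eqn{p_0 = \sqrt{2(\tilde V - \tilde V_{min})}} on the side's segment of
#' the (modified) surface.  Adaptive quadrature on the spline representation.
#'
#' @param path a `vibtun_map`.
#' @param side `"L"` or `"R"`.
#' @param s_from,s_to integration limits in the side's own arc length
#'   (defaults: the side minimum to the connection point).
#' @return non-negative scalar action.
#' @export
jacobi_action <- function(path, side = c("L", "R"), s_from = 0, s_to = NULL) {
  sd <- map_side(path, side)
  if (is.null(s_to)) s_to <- sd$s_cp
  if (s_to <= s_from) return(0)
  vmin <- min(sd$v(seq(s_from, s_to, length.out = 400)))
  if (vmin < -1e-8) stop("V below the well floor along the segment")
  f <- function(s) sqrt(pmax(2 * sd$v(s), 0))
  stats::integrate(f, s_from, s_to, rel.tol = 1e-10,
                   subdivisions = 400L)$value
}

#' Heaviside-modified surface for energy-asymmetric wells
#'
#' Returns a copy of `pes` whose energy is lowered by `d` on the right side
#' of the connection point, \eqn{\tilde V = V - \Theta(S - S_{cp})\,d}, with
#' side membership assigned by the nearest bead of the supplied path.
#'
#' @param pes a [potential_surface()].
#' @param d energy offset.
#' @param path a `vibtun_map` providing beads and connection point.
#' @return a `vibtun_pes` evaluating the modified energy.
#' @export
build_modified_pes <- function(pes, d, path) {
  if (d == 0) return(pes)
  B <- path$beads; cpi <- path$cp_index
  sideR <- function(X) {
    apply(X, 1, function(x) {
      i <- which.min(colSums((t(B) - x)^2))
      i >= cpi
    })
  }
  e_many <- function(X) pes$energy_many(X) - d * sideR(X)
  potential_surface(
    dimension = pes$dimension,
    energy = function(x) e_many(matrix(x, nrow = 1)),
    gradient = pes$gradient, hessian = pes$hessian_raw,
    energy_many = e_many, gradient_many = pes$gradient_many,
    masses = pes$masses, label = paste0(pes$label, "-shifted"))
}

#' Write / read a path checkpoint
#'
#' Tabular text checkpoint of a minimum action path: bead index, arc length,
#' coordinates, potential and the flattened Hessian per bead.  Reading
#' rebuilds the full field object (splines, tangents, connection point) from
#' the stored beads, losslessly up to text precision.
#'
#' @param path a `vibtun_map`.
#' @param file destination (CSV).
#' @param pes the surface the path was optimized on (needed to rebuild the
#'   wells on read).
#' @return `write_map_checkpoint` returns `file` invisibly;
#'   `read_map_checkpoint` returns a `vibtun_map`.
#' @export
write_map_checkpoint <- function(path, file) {
  nb <- nrow(path$beads)
  ndim <- path$ndim
  tab <- data.frame(bead = seq_len(nb), S = path$S)
  for (k in seq_len(ndim)) tab[[paste0("x", k)]] <- path$beads[, k]
  tab$V <- path$V
  H <- t(path$hessians)
  colnames(H) <- paste0("h", seq_len(ncol(H)))
  tab <- cbind(tab, H)
  attr1 <- sprintf("# cp_index=%d d=%.17g residual=%.17g tol=%.17g",
                   path$cp_index, path$d, path$residual, path$tol)
  con <- file(file, "w")
  writeLines(attr1, con)
  utils::write.csv(tab, con, row.names = FALSE)
  close(con)
  invisible(file)
}

#' @rdname write_map_checkpoint
#' @export
read_map_checkpoint <- function(file, pes) {
  hdr <- readLines(file, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[-0-9.e+]+", hdr))[[1]]
  meta <- list()
  for (x in kv) {
    p <- strsplit(x, "=")[[1]]
    meta[[p[1]]] <- as.numeric(p[2])
  }
  tab <- utils::read.csv(file, skip = 1)
  ndim <- sum(grepl("^x[0-9]+$", names(tab)))
  P <- as.matrix(tab[, paste0("x", seq_len(ndim))])
  wL <- characterize_minimum(pes, P[1, ])
  wR <- characterize_minimum(pes, P[nrow(P), ])
  .map_fields(pes, P, cp_index = as.integer(meta$cp_index), d = meta$d,
              wellL = wL, wellR = wR, resid = meta$residual,
              W_hist = numeric(0), tol = meta$tol)
}
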