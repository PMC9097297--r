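#' n-mode representation of a single well
#'
#' Samples the potential along each normal mode at Gauss-Hermite DVR points
#' scaled by the mode's harmonic length (`z_k / sqrt(omega_i)`), fits
#' eighth-order polynomials (no constant term; energies relative to the well
#' minimum) by linear regression, and builds pairwise 2-mode corrections on
#' the rectangular grid of the same points: the grid energy minus both
#' sampled 1-mode terms, fitted to tensor monomials `q_i^p q_j^q`
#' (`p, q >= 1`), which vanish on the axes by construction.  Couplings beyond
#' two modes are neglected.
#'
#' @param pes a [potential_surface()] (mass-scaled).
#' @param well a [characterize_minimum()] result.
#' @param n_dvr DVR points per mode (8 for the 2D model, 11 typical for
#'   molecules).
#' @param fit_order polynomial order of the fits.
#' @return object of class `vibtun_nmode` with `poly1` (modes x order
#'   coefficient matrix), `poly2` (list over pairs), sampled points/energies
#'   and fit residuals.
#' @export
build_nmode_surface <- function(pes, well, n_dvr = 8, fit_order = 8) {
  nm <- length(well$frequencies)
  gh <- pracma::gaussHermite(n_dvr)
  x0 <- well$geometry
  v0 <- well$energy
  pts <- lapply(seq_len(nm), function(i) gh$x / sqrt(well$frequencies[i]))
  v1 <- matrix(0, nm, n_dvr)
  poly1 <- matrix(0, nm, fit_order)
  res1 <- numeric(nm)
  for (i in seq_len(nm)) {
    X <- matrix(rep(x0, each = n_dvr), n_dvr) +
      outer(pts[[i]], well$normal_modes[, i])
    v1[i, ] <- pes$energy_many(X) - v0
    B <- outer(pts[[i]], seq_len(fit_order), `^`)
    fit <- stats::lm.fit(B, v1[i, ])
    poly1[i, ] <- fit$coefficients
    res1[i] <- sqrt(mean(fit$residuals^2))
  }
  pairs <- list()
  if (nm >= 2) {
    for (i in seq_len(nm - 1)) for (j in (i + 1):nm) {
      gridij <- expand.grid(k = seq_len(n_dvr), l = seq_len(n_dvr))
      X <- matrix(rep(x0, each = nrow(gridij)), nrow(gridij)) +
        outer(pts[[i]][gridij$k], well$normal_modes[, i]) +
        outer(pts[[j]][gridij$l], well$normal_modes[, j])
      v2 <- pes$energy_many(X) - v0 -
        v1[i, gridij$k] - v1[j, gridij$l]
      B <- matrix(0, nrow(gridij), fit_order^2)
      col <- 0
      for (p in seq_len(fit_order)) for (q in seq_len(fit_order)) {
        col <- col + 1
        B[, col] <- pts[[i]][gridij$k]^p * pts[[j]][gridij$l]^q
      }
      fit <- stats::lm.fit(B, v2)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      pairs[[paste(i, j)]] <- list(
        i = i, j = j,
        coef = matrix(cf, fit_order, fit_order, byrow = TRUE),
        residual = sqrt(mean(fit$residuals^2)))
    }
  }
  structure(list(well = well, n_dvr = n_dvr, fit_order = fit_order,
                 points = pts, v1 = v1, poly1 = poly1, poly2 = pairs,
                 residual1 = res1, v0 = v0, n_modes = nm),
            class = "vibtun_nmode")
}

#' Evaluate the fitted n-mode potential
#'
#' @param nm a [build_nmode_surface()] object.
#' @return function of a normal-coordinate vector `q` returning the fitted
#'   1-mode + 2-mode energy (relative to the well minimum).
#' @export
nmode_potential <- function(nm) {
  function(q) {
    tot <- 0
    for (i in seq_len(nm$n_modes))
      tot <- tot + sum(nm$poly1[i, ] * q[i]^seq_len(nm$fit_order))
    for (pr in nm$poly2) {
      qp <- q[pr$i]^seq_len(nm$fit_order)
      qq <- q[pr$j]^seq_len(nm$fit_order)
      tot <- tot + as.numeric(t(qp) %*% pr$coef %*% qq)
    }
    tot
  }
}

## sine-DVR kinetic matrix on (a, b) with n interior grid points, unit mass
.sine_dvr_kinetic <- function(n, a, b) {
  L <- b - a
  j <- seq_len(n)
  Np1 <- n + 1
  Tm <- matrix(0, n, n)
  for (r in j) for (c in j) {
    if (r == c) {
      Tm[r, c] <- (2 * Np1^2 + 1) / 3 - 1 / sin(pi * r / Np1)^2
    } else {
      Tm[r, c] <- (-1)^(r - c) *
        (1 / sin(pi * (r - c) / (2 * Np1))^2 -
         1 / sin(pi * (r + c) / (2 * Np1))^2)
    }
  }
  Tm * pi^2 / (2 * L^2) / 2
}

#' Basis frequency of a 1-mode potential from a sine-DVR calculation
#'
#' Solves the fitted 1-mode Hamiltonian in a sine-DVR basis (default 100
#' functions) and returns the gap of the lowest two levels, which is then
#' used as the harmonic-oscillator basis frequency for the VSCF step.  The
#' box spans `box_factor` times the sampled DVR range on each side; if the
#' fitted polynomial turns over (runaway even-order tail) the box is shrunk
#' until the potential is monotonically rising at both walls.
#'
#' @param nm a [build_nmode_surface()] object.
#' @param mode mode index.
#' @param n_basis number of sine-DVR functions.
#' @param box_factor initial box extension factor.
#' @return scalar frequency `E1 - E0`.
#' @export
mode_basis_frequency <- function(nm, mode, n_basis = 100, box_factor = 2.0) {
  cf <- nm$poly1[mode, ]
  vf <- function(q) {
    Q <- outer(q, seq_along(cf), `^`)
    as.numeric(Q %*% cf)
  }
  r <- range(nm$points[[mode]])
  fac <- box_factor
  for (tries in 1:8) {
    a <- fac * r[1]; b <- fac * r[2]
    qa <- seq(a, a + 0.1 * (b - a), length.out = 20)
    qb <- seq(b - 0.1 * (b - a), b, length.out = 20)
    ok <- all(diff(vf(qa)) < 0) && all(diff(vf(qb)) > 0)
    if (ok) break
    fac <- fac * 0.8
    if (tries == 8) warning("1-mode potential not confining; box shrunk to ",
                            format(fac, digits = 3), "x the sampled range")
  }
  grid <- a + seq_len(n_basis) * (b - a) / (n_basis + 1)
  H <- .sine_dvr_kinetic(n_basis, a, b) + diag(vf(grid))
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  ev[2] - ev[1]
}

## HO-basis one-mode integral tables at basis frequency w: kinetic matrix and
## q^p moment matrices (p = 0..pmax), n basis functions (quanta 0..n-1)
.ho_tables <- function(n, w, pmax) {
  nq <- 2 * n + 2 * pmax + 8
  gh <- pracma::gaussHermite(nq)
  z <- gh$x
  ## normalized Hermite functions h_k(z) (orthonormal wrt e^{-z^2} weight)
  Hn <- matrix(0, nq, n)
  Hn[, 1] <- pi^(-1 / 4)
  if (n >= 2) Hn[, 2] <- sqrt(2) * z * pi^(-1 / 4)
  if (n >= 3) for (k in 3:n)
    Hn[, k] <- sqrt(2 / (k - 1)) * z * Hn[, k - 1] -
      sqrt((k - 2) / (k - 1)) * Hn[, k - 2]
  Q <- vector("list", pmax + 1)
  for (p in 0:pmax) {
    wz <- gh$w * (z / sqrt(w))^p
    Q[[p + 1]] <- t(Hn) %*% (wz * Hn)
  }
  k <- seq_len(n) - 1
  Tm <- diag((w / 2) * (k + 0.5))
  if (n >= 3) {
    for (m in 3:n) {
      Tm[m, m - 2] <- Tm[m - 2, m] <- -(w / 4) * sqrt((m - 2) * (m - 1))
    }
  }
  list(T = Tm, Q = Q)
}

#' Vibrational self-consistent field on an n-mode surface
#'
#' Harmonic-oscillator basis per mode at the sine-DVR basis frequency of
#' [mode_basis_frequency()]; mean-field iterations until the VSCF energy is
#' stable to `tol`.  All polynomial integrals are evaluated by Gauss-Hermite
#' quadrature of sufficient exact degree.
#'
#' @param nm a [build_nmode_surface()] object.
#' @param basis_size harmonic-oscillator functions per mode (7 for the 2D
#'   model, 16 typical for molecules).
#' @param tol SCF energy convergence threshold.
#' @param max_iter iteration cap (damped restart on oscillation).
#' @return object of class `vibtun_vscf`: modal coefficient matrices (all
#'   virtuals retained), modal energies, the VSCF ground-state energy
#'   (relative to the well minimum), basis frequencies and integral tables.
#' @export
vscf_solve <- function(nm, basis_size = 7, tol = 1e-9, max_iter = 200) {
  nmod <- nm$n_modes
  wb <- vapply(seq_len(nmod), function(i) mode_basis_frequency(nm, i),
               numeric(1))
  tabs <- lapply(wb, function(w) .ho_tables(basis_size, w, nm$fit_order))
  ## bare 1-mode operators
  h1 <- lapply(seq_len(nmod), function(i) {
    V <- matrix(0, basis_size, basis_size)
    for (p in seq_len(nm$fit_order))
      V <- V + nm$poly1[i, p] * tabs[[i]]$Q[[p + 1]]
    tabs[[i]]$T + V
  })
  ## start from bare eigenvectors (columns ascending in energy)
  asc <- function(eg) eg$vectors[, order(eg$values), drop = FALSE]
  C <- lapply(h1, function(h) asc(eigen(symmetrize(h), symmetric = TRUE)))
  occ <- function(Ci) Ci[, 1]
  pair_energy <- function(C) {
    tot <- 0
    for (pr in nm$poly2) {
      mi <- vapply(seq_len(nm$fit_order), function(p)
        as.numeric(t(occ(C[[pr$i]])) %*% tabs[[pr$i]]$Q[[p + 1]] %*%
                     occ(C[[pr$i]])), numeric(1))
      mj <- vapply(seq_len(nm$fit_order), function(q)
        as.numeric(t(occ(C[[pr$j]])) %*% tabs[[pr$j]]$Q[[q + 1]] %*%
                     occ(C[[pr$j]])), numeric(1))
      tot <- tot + as.numeric(t(mi) %*% pr$coef %*% mj)
    }
    tot
  }
  e_total <- function(C) {
    tot <- pair_energy(C)
    for (i in seq_len(nmod))
      tot <- tot + as.numeric(t(occ(C[[i]])) %*% h1[[i]] %*% occ(C[[i]]))
    tot
  }
  E <- e_total(C)
  damp <- 0
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nmod)) {
      mf <- matrix(0, basis_size, basis_size)
      for (pr in nm$poly2) {
        if (pr$i != i && pr$j != i) next
        other <- if (pr$i == i) pr$j else pr$i
        mo <- vapply(seq_len(nm$fit_order), function(q)
          as.numeric(t(occ(C[[other]])) %*% tabs[[other]]$Q[[q + 1]] %*%
                       occ(C[[other]])), numeric(1))
        cc <- if (pr$i == i) as.numeric(pr$coef %*% mo) else
          as.numeric(t(mo) %*% pr$coef)
        for (p in seq_len(nm$fit_order))
          mf <- mf + cc[p] * tabs[[i]]$Q[[p + 1]]
      }
      eg <- eigen(symmetrize(h1[[i]] + mf), symmetric = TRUE)
      newC <- asc(eg)
      ## fix sign for reproducibility
      for (k in seq_len(ncol(newC)))
        if (newC[which.max(abs(newC[, k])), k] < 0) newC[, k] <- -newC[, k]
      C[[i]] <- if (damp > 0) {
        ## damped mixing then re-orthonormalization
        M <- (1 - damp) * newC + damp * C[[i]]
        qr.Q(qr(M))
      } else newC
    }
    Enew <- e_total(C)
    if (abs(Enew - E) < tol) { E <- Enew; break }
    if (it > 50 && damp == 0) damp <- 0.3
    if (it == max_iter) stop("VSCF did not converge")
    E <- Enew
  }
  structure(list(nm = nm, basis_size = basis_size, C = C, tabs = tabs,
                 omega_basis = wb, e_vscf = E, h1 = h1),
            class = "vibtun_vscf")
}

#' Configuration interaction over VSCF modals (singles and doubles)
#'
#' Diagonalizes the full vibrational Hamiltonian (1-mode + 2-mode terms) in
#' the space of VSCF modal products with at most two modes simultaneously
#' excited, each to at most `max_quanta` quanta.  States are labeled by the
#' dominant configuration; near-degenerate leading coefficients (within 10
#' percent) are flagged as ambiguous.
#'
#' @param vscf a [vscf_solve()] result.
#' @param max_quanta excitation cap per mode.
#' @return object of class `vibtun_localstates`: a data frame `table` (label,
#'   quanta, energy relative to the well minimum, ambiguity flag) plus CI
#'   vectors and the configuration list.  Energies are sorted ascending.
#' @export
vcisd_solve <- function(vscf, max_quanta = 6) {
  nm <- vscf$nm
  nmod <- nm$n_modes
  nb <- vscf$basis_size
  cap <- min(max_quanta, nb - 1)
  ## configurations: at most two modes excited
  confs <- list(rep(0L, nmod))
  for (i in seq_len(nmod)) for (n in seq_len(cap)) {
    v <- rep(0L, nmod); v[i] <- n
    confs[[length(confs) + 1]] <- v
  }
  if (nmod >= 2) {
    for (i in seq_len(nmod - 1)) for (j in (i + 1):nmod)
      for (ni in seq_len(cap)) for (nj in seq_len(cap)) {
        v <- rep(0L, nmod); v[i] <- ni; v[j] <- nj
        confs[[length(confs) + 1]] <- v
      }
  }
  ncf <- length(confs)
  cm <- do.call(rbind, confs)
  ## per-mode operator matrices in the modal basis
  h1m <- lapply(seq_len(nmod), function(i)
    t(vscf$C[[i]]) %*% vscf$h1[[i]] %*% vscf$C[[i]])
  Qm <- lapply(seq_len(nmod), function(i)
    lapply(seq_len(nm$fit_order), function(p)
      t(vscf$C[[i]]) %*% vscf$tabs[[i]]$Q[[p + 1]] %*% vscf$C[[i]]))
  H <- matrix(0, ncf, ncf)
  for (r in seq_len(ncf)) for (c in r:ncf) {
    vr <- cm[r, ]; vc <- cm[c, ]
    dif <- which(vr != vc)
    val <- 0
    if (length(dif) == 0) {
      for (i in seq_len(nmod)) val <- val + h1m[[i]][vr[i] + 1, vr[i] + 1]
      for (pr in nm$poly2)
        val <- val + .pair_elem(pr, Qm, vr[pr$i] + 1, vr[pr$i] + 1,
                                vr[pr$j] + 1, vr[pr$j] + 1)
    } else if (length(dif) == 1) {
      i <- dif
      val <- h1m[[i]][vr[i] + 1, vc[i] + 1]
      for (pr in nm$poly2) {
        if (pr$i != i && pr$j != i) next
        val <- val + .pair_elem(pr, Qm, vr[pr$i] + 1, vc[pr$i] + 1,
                                vr[pr$j] + 1, vc[pr$j] + 1)
      }
    } else if (length(dif) == 2) {
      pr <- nm$poly2[[paste(dif[1], dif[2])]]
      if (!is.null(pr))
        val <- .pair_elem(pr, Qm, vr[pr$i] + 1, vc[pr$i] + 1,
                          vr[pr$j] + 1, vc[pr$j] + 1)
    }
    H[r, c] <- H[c, r] <- val
  }
  eg <- eigen(symmetrize(H), symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  lab <- character(ncf); amb <- logical(ncf); domq <- vector("list", ncf)
  for (k in seq_len(ncf)) {
    a <- abs(vecs[, k])
    top <- order(a, decreasing = TRUE)[1:2]
    amb[k] <- a[top[2]] > 0.9 * a[top[1]]
    q <- cm[top[1], ]
    domq[[k]] <- q
    lab[k] <- .quanta_label(q)
    if (vecs[which.max(a), k] < 0) vecs[, k] <- -vecs[, k]
  }
  floor0 <- nm$well$energy
  structure(list(
    table = data.frame(label = lab, energy = vals,
                       energy_abs = vals + floor0, ambiguous = amb,
                       stringsAsFactors = FALSE),
    quanta = domq, vectors = vecs, configs = cm, vscf = vscf,
    e_vscf = vscf$e_vscf
  ), class = "vibtun_localstates")
}

.pair_elem <- function(pr, Qm, ri, ci, rj, cj) {
  fo <- nrow(pr$coef)
  mi <- vapply(seq_len(fo), function(p) Qm[[pr$i]][[p]][ri, ci], numeric(1))
  mj <- vapply(seq_len(fo), function(q) Qm[[pr$j]][[q]][rj, cj], numeric(1))
  as.numeric(t(mi) %*% pr$coef %*% mj)
}

.quanta_label <- function(q) {
  if (all(q == 0)) return("GS")
  parts <- character(0)
  for (i in seq_along(q)) if (q[i] > 0)
    parts <- c(parts, rep(paste0("v", i), q[i]))
  paste(parts, collapse = "+")
}

#' @export
print.vibtun_localstates <- function(x, n = 10, ...) {
  cat("<vibtun_localstates> lowest", min(n, nrow(x$table)), "states:\n")
  print(utils::head(x$table, n))
  invisible(x)
}
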