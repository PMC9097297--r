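#' Grid specification for the 2D reference eigensolver
#'
#' @param xlim,ylim extents per (mass-scaled) coordinate.
#' @param n points per coordinate.
#' @return object of class `vibtun_grid`.
#' @export
grid_spec <- function(xlim, ylim, n = 96) {
  stopifnot(diff(xlim) > 0, diff(ylim) > 0, n >= 16)
  structure(list(xlim = xlim, ylim = ylim, n = n), class = "vibtun_grid")
}

#' Automatic grid from classical turning points
#'
#' Chooses extents so that the box contains the region with
#' \eqn{V \le E_t} (default \eqn{E_t} = 1.5 x the barrier estimated along the
#' straight line between the minima) plus a 20 percent margin.
#'
#' @param pes a [potential_surface()] (2D, mass-scaled).
#' @param minima list of the two minima (mass-scaled coordinates).
#' @param e_target target energy; `NULL` for the default.
#' @param n points per coordinate.
#' @return a [grid_spec()].
#' @export
auto_grid_2d <- function(pes, minima, e_target = NULL, n = 96) {
  m1 <- minima[[1]]; m2 <- minima[[2]]
  if (is.null(e_target)) {
    tt <- seq(0, 1, length.out = 201)
    line <- outer(1 - tt, m1) + outer(tt, m2)
    e_target <- 1.5 * max(pes$energy_many(line))
  }
  span <- sqrt(sum((m1 - m2)^2))
  lo <- pmin(m1, m2) - 1.5 * span
  hi <- pmax(m1, m2) + 1.5 * span
  gx <- seq(lo[1], hi[1], length.out = 161)
  gy <- seq(lo[2], hi[2], length.out = 161)
  G <- as.matrix(expand.grid(gx, gy))
  Vg <- pes$energy_many(G)
  inside <- Vg <= e_target
  if (!any(inside)) stop("no classically allowed region below the target energy")
  xr <- range(G[inside, 1]); yr <- range(G[inside, 2])
  ## pad generously: evanescent tails must be negligible at the box walls
  pad <- function(r) r + c(-1, 1) * max(0.35 * diff(r), 2.5)
  grid_spec(pad(xr), pad(yr), n)
}

## Colbert-Miller sinc-DVR kinetic matrix on a uniform grid, unit mass
.sinc_kinetic <- function(n, dx) {
  i <- seq_len(n)
  D <- outer(i, i, function(a, b) {
    m <- a - b
    out <- ifelse(m == 0, pi^2 / 3, 2 * (-1)^m / m^2)
    out
  })
  D / (2 * dx^2)
}

#' Exact 2D eigensolver on a sinc-DVR grid
#'
#' Colbert-Miller sinc-DVR on a uniform 2D grid (unit mass: pass mass-scaled
#' coordinates), lowest `n_levels` eigenpairs via implicitly restarted
#' Lanczos with a fast separable kinetic matvec.  With `check = TRUE` the
#' grid is refined (1.5x per axis) and levels must agree to `gate`;
#' otherwise the solver enlarges the grid once more and, failing that, stops.
#'
#' @param pes a 2D [potential_surface()].
#' @param grid a [grid_spec()] (or `NULL` with `minima` supplied to
#'   [auto_grid_2d()]).
#' @param n_levels number of lowest eigenpairs to compute.
#' @param minima passed to [auto_grid_2d()] when `grid` is `NULL`.
#' @param check run the grid-refinement convergence gate.
#' @param gate maximum allowed change of any requested level on refinement.
#' @return list with `values` (ascending), `vectors` (`n^2 x n_levels`,
#'   grid-ordered x-fastest), `grid`, `weights` (left-side localization
#'   weight per state, fraction of the mirror plane side containing the
#'   first minimum).
#' @export
solve_2d_dvr <- function(pes, grid = NULL, n_levels = 8, minima = NULL,
                         check = TRUE, gate = 1e-6) {
  stopifnot(pes$dimension == 2)
  if (is.null(grid)) {
    stopifnot(!is.null(minima))
    grid <- auto_grid_2d(pes, minima)
  }
  solve_once <- function(gr) {
    gx <- seq(gr$xlim[1], gr$xlim[2], length.out = gr$n)
    gy <- seq(gr$ylim[1], gr$ylim[2], length.out = gr$n)
    G <- as.matrix(expand.grid(x = gx, y = gy))
    Vg <- pes$energy_many(G)
    Tx <- .sinc_kinetic(gr$n, gx[2] - gx[1])
    Ty <- .sinc_kinetic(gr$n, gy[2] - gy[1])
    nn <- gr$n
    matvec <- function(x, extra = NULL) {
      X <- matrix(x, nn, nn)        # x index fastest
      as.vector(Tx %*% X + X %*% t(Ty) + matrix(Vg * x, nn, nn))
    }
    ar <- igraph::arpack(matvec, sym = TRUE,
                         options = list(n = nn * nn, nev = n_levels,
                                        ncv = max(4 * n_levels, 40),
                                        which = "SA", maxiter = 3000))
    ord <- order(ar$values)
    list(values = ar$values[ord],
         vectors = matrix(ar$vectors, ncol = n_levels)[, ord, drop = FALSE],
         gx = gx, gy = gy, grid = gr)
  }
  res <- solve_once(grid)
  if (check) {
    gr2 <- grid_spec(grid$xlim, grid$ylim, ceiling(grid$n * 1.5))
    res2 <- solve_once(gr2)
    if (max(abs(res2$values - res$values)) > gate) {
      gr3 <- grid_spec(grid$xlim, grid$ylim, ceiling(grid$n * 2.25))
      res3 <- solve_once(gr3)
      if (max(abs(res3$values - res2$values)) > gate)
        stop("DVR levels not converged at the gate after grid enlargement")
      res <- res3
    } else res <- res2
  }
  ## left-side localization weights relative to the midplane between minima
  mid <- if (!is.null(minima)) mean(c(minima[[1]][1], minima[[2]][1])) else
    mean(res$grid$xlim)
  leftcols <- res$gx < mid
  wts <- vapply(seq_len(ncol(res$vectors)), function(k) {
    ps <- matrix(res$vectors[, k]^2, length(res$gx), length(res$gy))
    sum(ps[leftcols, ]) / sum(ps)
  }, numeric(1))
  structure(list(values = res$values, vectors = res$vectors,
                 gx = res$gx, gy = res$gy, grid = res$grid,
                 left_weight = wts), class = "vibtun_dvr")
}

#' Splittings from a reference spectrum
#'
#' Pairs levels and reports gaps.  With `pairing = "adjacent"` consecutive
#' levels `(1,2), (3,4), ...` form the doublets (the symmetric-well case);
#' with `"weights"` each left-localized state is paired with the closest
#' right-localized one, and strongly localized states
#' (`left_weight > 0.95` or `< 0.05`) are reported as such.
#'
#' @param dvr a [solve_2d_dvr()] result.
#' @param pairing `"adjacent"` or `"weights"`.
#' @return data frame of pairs: level indices, energies, gap, localization.
#' @export
qm_splittings <- function(dvr, pairing = c("adjacent", "weights")) {
  pairing <- match.arg(pairing)
  ev <- dvr$values
  if (pairing == "adjacent") {
    k <- seq(1, length(ev) - 1, by = 2)
    out <- data.frame(i = k, j = k + 1, E_i = ev[k], E_j = ev[k + 1],
                      gap = ev[k + 1] - ev[k])
    out$w_i <- dvr$left_weight[k]; out$w_j <- dvr$left_weight[k + 1]
    return(out)
  }
  wl <- dvr$left_weight
  li <- which(wl >= 0.5); ri <- which(wl < 0.5)
  rows <- lapply(li, function(i) {
    if (!length(ri)) return(NULL)
    j <- ri[which.min(abs(ev[ri] - ev[i]))]
    data.frame(i = i, j = j, E_i = ev[i], E_j = ev[j],
               gap = abs(ev[j] - ev[i]), w_i = wl[i], w_j = wl[j],
               localized = wl[i] > 0.95 & wl[j] < 0.05)
  })
  do.call(rbind, rows)
}
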