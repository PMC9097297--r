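#' Potential-energy-surface contract
#'
#' A `vibtun_pes` bundles energy, gradient and Hessian callables in
#' *mass-scaled* Cartesian coordinates (kinetic metric = identity), which is
#' the frame all path and instanton machinery operates in.  Analytic
#' derivatives are optional: missing ones fall back to central finite
#' differences with step `fd_step`.
#'
#' @param dimension integer, number of mass-scaled coordinates.
#' @param energy function of a length-`dimension` numeric vector returning a
#'   scalar potential energy.
#' @param gradient,hessian optional analytic derivative functions taking the
#'   same argument; `hessian` must return a symmetric `dimension x dimension`
#'   matrix.
#' @param energy_many optional vectorized energy taking an `n x dimension`
#'   matrix of row-points (used heavily by the path optimizer); defaults to a
#'   row-wise loop over `energy`.
#' @param gradient_many optional vectorized gradient, `n x dimension` in and out.
#' @param masses per-coordinate masses of the *unscaled* frame (bookkeeping
#'   only; the callables already consume mass-scaled points).
#' @param fd_step finite-difference step (mass-scaled units) for fallback
#'   derivatives.
#' @param projector optional function `(hessian, x) -> hessian` applied to
#'   every Hessian evaluation (used to project out translations/rotations for
#'   molecular surfaces; identity for low-dimensional models).
#' @param label short identifier.
#' @return an object of class `vibtun_pes`.
#' @export
potential_surface <- function(dimension, energy, gradient = NULL, hessian = NULL,
                              energy_many = NULL, gradient_many = NULL,
                              masses = rep(1, dimension), fd_step = 1e-5,
                              projector = NULL, label = "pes") {
  stopifnot(is.function(energy), dimension >= 1)
  if (is.null(gradient)) gradient <- function(x) fd_gradient(energy, x, fd_step)
  if (is.null(hessian))  hessian  <- function(x) fd_hessian(energy, x, fd_step * 10)
  if (is.null(energy_many))
    energy_many <- function(X) apply(X, 1, energy)
  if (is.null(gradient_many))
    gradient_many <- function(X) t(apply(X, 1, gradient))
  hess_proj <- if (is.null(projector)) {
    function(x) symmetrize(hessian(x))
  } else {
    function(x) symmetrize(projector(hessian(x), x))
  }
  structure(list(dimension = dimension, energy = energy, gradient = gradient,
                 hessian = hess_proj, hessian_raw = hessian,
                 energy_many = energy_many, gradient_many = gradient_many,
                 masses = masses, fd_step = fd_step, label = label),
            class = "vibtun_pes")
}

#' @export
print.vibtun_pes <- function(x, ...) {
  cat("<vibtun_pes> ", x$label, ": ", x$dimension,
      " mass-scaled coordinates\n", sep = "")
  invisible(x)
}

symmetrize <- function(m) (m + t(m)) / 2

fd_gradient <- function(f, x, h) {
  n <- length(x)
  g <- numeric(n)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- h
    g[i] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  g
}

fd_hessian <- function(f, x, h) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    ei <- numeric(n); ei[i] <- h
    ej <- numeric(n); ej[j] <- h
    H[i, j] <- H[j, i] <-
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
  }
  H
}

#' Symmetric PSD matrix square root
#'
#' Spectral square root on the non-negative eigenspace.  Tiny negative
#' eigenvalues (numerical noise, trans/rot remainders) are clipped to zero; a
#' significantly negative eigenvalue signals a non-minimum and is an error.
#'
#' @param h symmetric positive-semidefinite matrix.
#' @param tol relative tolerance below which negative eigenvalues are clipped.
#' @return symmetric PSD matrix `A` with `A %*% A == h` on the non-null space.
#' @export
matrix_sqrt_psd <- function(h, tol = 1e-8) {
  e <- eigen(symmetrize(h), symmetric = TRUE)
  scale <- max(abs(e$values), 1e-300)
  if (min(e$values) < -tol * scale)
    stop("matrix has a significantly negative eigenvalue (", min(e$values),
         "); not a PSD matrix")
  v <- sqrt(pmax(e$values, 0))
  symmetrize(e$vectors %*% (v * t(e$vectors)))
}

#' Project translations and rotations out of a molecular Hessian
#'
#' Builds the (mass-scaled) rigid-body nullspace at `geometry` and returns
#' `P H P` with `P` the projector on its orthogonal complement.  For
#' non-molecular (low-dimensional model) surfaces the projector is the
#' identity and the Hessian is returned unchanged.
#'
#' @param hessian symmetric Hessian in mass-scaled Cartesian coordinates
#'   (`3*natom` square for molecules).
#' @param geometry `natom x 3` Cartesian geometry (unscaled lengths), or
#'   `NULL` for model surfaces.
#' @param masses per-atom masses, length `natom`.
#' @param linear_tol singular-value threshold that decides whether the
#'   molecule is linear (5 instead of 6 rigid-body modes).
#' @return projected Hessian with 5 or 6 near-zero eigenvalues.
#' @export
project_trans_rot <- function(hessian, geometry = NULL, masses = NULL,
                              linear_tol = 1e-8) {
  if (is.null(geometry)) return(symmetrize(hessian))
  geometry <- as.matrix(geometry)
  natom <- nrow(geometry)
  stopifnot(ncol(geometry) == 3, length(masses) == natom,
            nrow(hessian) == 3 * natom)
  sm <- sqrt(masses)
  com <- colSums(geometry * masses) / sum(masses)
  gc <- sweep(geometry, 2, com)
  vecs <- matrix(0, 3 * natom, 6)
  for (k in 1:3) vecs[seq(k, 3 * natom, by = 3), k] <- sm   # translations
  for (k in 1:3) {                                           # rotations
    ax <- numeric(3); ax[k] <- 1
    r <- t(apply(gc, 1, function(p) crossprod3(ax, p)))
    vecs[, 3 + k] <- as.vector(t(r * sm))
  }
  qrd <- qr(vecs)
  rank <- sum(abs(diag(qr.R(qrd))) > linear_tol * max(abs(diag(qr.R(qrd)))))
  if (rank < 5 || rank > 6)
    stop("rigid-body nullspace has rank ", rank, "; expected 5 (linear) or 6")
  Q <- qr.Q(qrd)[, seq_len(rank), drop = FALSE]
  P <- diag(3 * natom) - Q %*% t(Q)
  symmetrize(P %*% hessian %*% P)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Read an XYZ geometry file
#'
#' Standard XYZ text: atom count, comment line, then `element x y z` in
#' angstrom.  Coordinates are returned in bohr together with element symbols.
#'
#' @param path file path.
#' @param masses optional named vector mapping element symbols to masses in
#'   electron-mass units; defaults to a small built-in table of common
#'   isotope-averaged masses.
#' @return list with `elements`, `geometry` (`natom x 3`, bohr) and `masses`.
#' @export
read_xyz <- function(path, masses = NULL) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[3:(2 + n)]), "\\s+")
  el <- vapply(rows, `[[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  bohr <- xyz / 0.529177210903
  tab <- c(H = 1837.152646, D = 3671.482934, C = 21874.6618,
           N = 25526.0425, O = 29156.9456, S = 58441.801)
  if (!is.null(masses)) tab[names(masses)] <- masses
  if (any(!el %in% names(tab)))
    stop("no mass for element(s): ", paste(setdiff(el, names(tab)), collapse = ", "))
  list(elements = el, geometry = bohr, masses = unname(tab[el]))
}
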