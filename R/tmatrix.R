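#' Assemble the tunneling matrix
#'
#' Block matrix over well-localized states: diagonal blocks are diagonal
#' (local vibrational energies; intra-well couplings neglected by
#' construction), off-diagonal block is the Herring coupling matrix `h`.
#' The `h` block and its transpose fill the two off-diagonal blocks; when a
#' full (possibly slightly asymmetric) matrix of independently evaluated
#' elements is supplied it is symmetrized by averaging and the asymmetry is
#' recorded as a diagnostic.
#'
#' @param energies_L,energies_R local energies (same units as `h_block`).
#' @param h_block couplings, `length(energies_L) x length(energies_R)`.
#' @param labels_L,labels_R state labels (used for pairing and reports).
#' @param model_size `"all"` for the full matrix, `"pairs"` to keep only the
#'   couplings between correspondingly labeled states (the 2x2-per-doublet
#'   model), or an integer N to truncate to the lowest N states per well.
#' @param symmetry_zero optional logical matrix marking couplings that vanish
#'   by symmetry; they are forced to exact zero.
#' @return object of class `vibtun_tm` with the full symmetric `matrix`,
#'   block bookkeeping and the symmetrization diagnostic.
#' @export
assemble_tm <- function(energies_L, energies_R, h_block,
                        labels_L = NULL, labels_R = NULL,
                        model_size = "all", symmetry_zero = NULL) {
  nl <- length(energies_L); nr <- length(energies_R)
  h_block <- as.matrix(h_block)
  stopifnot(nrow(h_block) == nl, ncol(h_block) == nr)
  if (is.null(labels_L)) labels_L <- paste0("L", seq_len(nl))
  if (is.null(labels_R)) labels_R <- paste0("R", seq_len(nr))
  asym <- 0
  if (!is.null(symmetry_zero)) h_block[symmetry_zero] <- 0
  if (is.numeric(model_size)) {
    n <- as.integer(model_size)
    keepL <- order(energies_L)[seq_len(min(n, nl))]
    keepR <- order(energies_R)[seq_len(min(n, nr))]
    energies_L <- energies_L[keepL]; energies_R <- energies_R[keepR]
    labels_L <- labels_L[keepL]; labels_R <- labels_R[keepR]
    h_block <- h_block[keepL, keepR, drop = FALSE]
    nl <- length(keepL); nr <- length(keepR)
  } else if (identical(model_size, "pairs")) {
    if (nl != nr) stop("pairs model needs equally many states per well")
    if (!all(vapply(seq_len(nl), function(i)
      identical(labels_L[i], labels_R[i]), logical(1))))
      stop("pairs model needs label-aligned states in the two wells")
    h_block <- diag(diag(h_block), nl, nr)
  } else if (!identical(model_size, "all")) stop("unknown model_size")
  M <- matrix(0, nl + nr, nl + nr)
  M[seq_len(nl), seq_len(nl)] <- diag(energies_L, nl)
  M[nl + seq_len(nr), nl + seq_len(nr)] <- diag(energies_R, nr)
  M[seq_len(nl), nl + seq_len(nr)] <- h_block
  M[nl + seq_len(nr), seq_len(nl)] <- t(h_block)
  structure(list(matrix = M, n_L = nl, n_R = nr,
                 energies_L = energies_L, energies_R = energies_R,
                 labels = c(paste0(labels_L, "(L)"), paste0(labels_R, "(R)")),
                 labels_L = labels_L, labels_R = labels_R,
                 h_block = h_block, h_asymmetry = asym),
            class = "vibtun_tm")
}

#' Diagonalize a tunneling matrix
#'
#' @param tm a [assemble_tm()] object.
#' @return object of class `vibtun_spectrum`: `levels` (ascending),
#'   `vectors`, a configuration table with dominant local-state content and
#'   per-well weights, identified doublets with splittings and mixing angles.
#' @export
spectrum <- function(tm) {
  eg <- eigen(symmetrize(tm$matrix), symmetric = TRUE)
  ord <- order(eg$values)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  n <- length(vals)
  nl <- tm$n_L
  dom <- integer(n); wL <- numeric(n)
  for (k in seq_len(n)) {
    if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
    dom[k] <- which.max(abs(vecs[, k]))
    wL[k] <- sum(vecs[seq_len(nl), k]^2)
  }
  cfg <- data.frame(level = seq_len(n), energy = vals,
                    dominant = tm$labels[dom],
                    weight_dominant = vapply(seq_len(n), function(k)
                      vecs[dom[k], k]^2, numeric(1)),
                    weight_L = wL)
  ## doublets: pair each level with the unpaired level sharing the same
  ## base label (ignoring the well tag); ties broken by energy adjacency
  base <- sub("\\((L|R)\\)$", "", tm$labels)
  lvl_base <- base[dom]
  paired <- rep(NA_integer_, n)
  doublets <- NULL
  for (k in seq_len(n)) {
    if (!is.na(paired[k])) next
    cand <- which(lvl_base == lvl_base[k] & is.na(paired) &
                    seq_len(n) != k)
    if (!length(cand)) next
    j <- cand[which.min(abs(vals[cand] - vals[k]))]
    paired[k] <- j; paired[j] <- k
    lo <- min(k, j); hi <- max(k, j)
    wl <- sum(vecs[seq_len(nl), lo]^2)
    wr <- 1 - wl
    phi <- atan(sqrt(min(wl, wr) / max(wl, wr))) * 180 / pi
    doublets <- rbind(doublets, data.frame(
      label = lvl_base[k], lower = lo, upper = hi,
      E_lower = vals[lo], E_upper = vals[hi],
      splitting = vals[hi] - vals[lo], mixing_angle = phi))
  }
  structure(list(levels = vals, vectors = vecs, configurations = cfg,
                 doublets = doublets, tm = tm),
            class = "vibtun_spectrum")
}

#' @export
print.vibtun_spectrum <- function(x, ...) {
  cat("<vibtun_spectrum>", length(x$levels), "levels\n")
  print(x$configurations)
  invisible(x)
}

#' Two-level splitting: exact gap and perturbative expansion
#'
#' Exact two-level gap \eqn{\Delta = \sqrt{(E_L - E_R)^2 + 4h^2}} together
#' with its weak-coupling expansion
#' \eqn{\Delta \approx |E_L - E_R| + 2h^2/|E_L - E_R|} (second-order
#' perturbation theory, valid for \eqn{|h| \ll |E_L - E_R|}; the difference
#' is \eqn{O(h^4/\Delta E^3)}).
#'
#' @param E_L,E_R local energies of the pair.
#' @param h coupling.
#' @return list with `exact`, `perturbative`, and the inputs.
#' @export
pair_splitting <- function(E_L, E_R, h) {
  dE <- abs(E_L - E_R)
  exact <- sqrt(dE^2 + 4 * h^2)
  pert <- if (dE > 0) dE + 2 * h^2 / dE else 2 * abs(h)
  list(exact = exact, perturbative = pert, E_L = E_L, E_R = E_R, h = h)
}

#' Mixing angle of a doublet
#'
#' From the eigenvector content of the lower doublet member: with per-well
#' weights \eqn{w_L, w_R} (summed squared components over each well's
#' states), \eqn{\phi = \arctan\sqrt{w_{minor}/w_{major}}} in degrees,
#' which equals the familiar two-level angle
#' (\eqn{\tan 2\phi = 2|h|/|\Delta E|}) for an isolated pair and is 45
#' degrees for a symmetric degenerate doublet.
#'
#' @param x a `vibtun_spectrum` (uses its doublet table) or a length-2 list
#'   `pair_splitting()`-style specification `list(E_L=, E_R=, h=)`.
#' @param label for a spectrum, which doublet to report (default: first).
#' @return mixing angle in degrees, in `[0, 45]`.
#' @export
mixing_angle <- function(x, label = NULL) {
  if (inherits(x, "vibtun_spectrum")) {
    d <- x$doublets
    if (is.null(d) || !nrow(d)) stop("no identifiable doublet; see configurations")
    if (!is.null(label)) d <- d[d$label == label, , drop = FALSE]
    return(d$mixing_angle[1])
  }
  dE <- x$E_R - x$E_L
  0.5 * atan2(2 * abs(x$h), abs(dE)) * 180 / pi
}

#' Locate an avoided crossing along a parameter sweep
#'
#' Evaluates a gap function on a grid, finds the bracketing cell of its
#' minimum and refines by golden-section search.
#'
#' @param gap_fn function of the swept parameter returning the level gap.
#' @param grid numeric vector of parameter values (monotone).
#' @param tol relative parameter tolerance of the refinement.
#' @return list with `parameter` (argmin), `min_gap`, `grid_table`, and
#'   `bracketed` (FALSE when the minimum sits on the grid edge).
#' @export
locate_avoided_crossing <- function(gap_fn, grid, tol = 1e-4) {
  gv <- vapply(grid, gap_fn, numeric(1))
  k <- which.min(gv)
  tab <- data.frame(parameter = grid, gap = gv)
  if (k == 1 || k == length(grid)) {
    warning("gap minimum not bracketed by the grid; returning the edge value")
    return(list(parameter = grid[k], min_gap = gv[k], grid_table = tab,
                bracketed = FALSE))
  }
  o <- stats::optimize(gap_fn, lower = grid[k - 1], upper = grid[k + 1],
                       tol = tol * max(abs(grid[c(k - 1, k + 1)])))
  list(parameter = o$minimum, min_gap = o$objective, grid_table = tab,
       bracketed = TRUE)
}
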