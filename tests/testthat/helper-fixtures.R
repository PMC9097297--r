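## Shared fixtures, built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

## symmetric benchmark model, fully propagated
fix_sym <- function() fixture("sym", function() {
  pes <- model_2d_pes()
  wL <- characterize_minimum(pes, attr(pes, "min_L"))
  wR <- characterize_minimum(pes, attr(pes, "min_R"))
  path <- optimize_map(pes, wL, wR, n_beads = 301, tol = 1e-6)
  wdL <- propagate_widths(path, "L")
  wdR <- propagate_widths(path, "R")
  field <- function(side, q)
    instanton_field(path, side, q, widths = if (side == "L") wdL else wdR)
  list(pes = pes, wL = wL, wR = wR, path = path, wdL = wdL, wdR = wdR,
       field = field)
})

fix_sym_dvr <- function() fixture("sym_dvr", function() {
  s <- fix_sym()
  solve_2d_dvr(s$pes, minima = list(attr(s$pes, "min_L"),
                                    attr(s$pes, "min_R")),
               n_levels = 8, check = FALSE)
})

## separable double well (quartic in x) x harmonic (in y); unit mass frame
sep_double_well <- function(alpha = 1.6, beta = 3.0, wy = 1.2) {
  emany <- function(X)
    alpha / (8 * beta^2) * (X[, 1]^2 - beta^2)^2 + 0.5 * wy^2 * X[, 2]^2
  potential_surface(
    2, energy = function(x) emany(matrix(x, 1)),
    energy_many = emany, label = "separable-dw")
}

## synthetic one-sided path on an arbitrary 2D PES: straight line from `from`
## to `to`, fields evaluated with the package spline machinery
straight_path <- function(pes, from, to, nb = 201) {
  frac <- seq(0, 1, length.out = nb)
  P <- outer(1 - frac, from) + outer(frac, to)
  wellL <- characterize_minimum(pes, from)
  wellR <- structure(list(geometry = to, energy = pes$energy(to),
                          hessian0 = pes$hessian(to),
                          normal_modes = wellL$normal_modes,
                          frequencies = wellL$frequencies,
                          A0 = wellL$A0, n_zero = 0L),
                     class = "vibtun_well")
  vibtun:::.map_fields(pes, P, cp_index = (nb + 1) %/% 2, d = 0,
                       wellL = wellL, wellR = wellR,
                       resid = 0, W_hist = numeric(0), tol = 1e-6)
}

## globally harmonic 2D PES with distinct frequencies, minimum at origin
harmonic_pes <- function(w1 = 0.7, w2 = 1.3) {
  emany <- function(X) 0.5 * (w1^2 * X[, 1]^2 + w2^2 * X[, 2]^2)
  potential_surface(2, energy = function(x) emany(matrix(x, 1)),
                    energy_many = emany, label = "harmonic")
}
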