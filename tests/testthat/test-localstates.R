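test_that("n-mode surface of a separable potential has no pair coupling", {
  pes <- sep_double_well()
  w <- characterize_minimum(pes, c(-3, 0))
  nm <- build_nmode_surface(pes, w)
  expect_lt(max(abs(nm$poly2[[1]]$coef)), 1e-9)
  ## fitted 1-mode polynomials reproduce the sampled energies
  for (i in 1:2) {
    fit <- outer(nm$points[[i]], seq_len(nm$fit_order), `^`) %*% nm$poly1[i, ]
    expect_equal(as.numeric(fit), nm$v1[i, ],
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("the fitted 1+2-mode surface reproduces the full model on the grid", {
  s <- fix_sym()
  nm <- build_nmode_surface(s$pes, s$wL)
  vf <- nmode_potential(nm)
  for (k in c(1, 4, 8)) for (l in c(2, 5)) {
    q <- c(nm$points[[1]][k], nm$points[[2]][l])
    x <- s$wL$geometry + q[1] * s$wL$normal_modes[, 1] +
      q[2] * s$wL$normal_modes[, 2]
    expect_equal(vf(q), s$pes$energy(x) - s$wL$energy, tolerance = 1e-6)
  }
})

test_that("sine-DVR basis frequency is exact for harmonic and stable", {
  hp <- harmonic_pes(w1 = 0.9, w2 = 1.4)
  w <- characterize_minimum(hp, c(0, 0))
  nm <- build_nmode_surface(hp, w)
  expect_equal(mode_basis_frequency(nm, 1), 0.9, tolerance = 1e-6)
  expect_equal(mode_basis_frequency(nm, 2), 1.4, tolerance = 1e-6)
  ## Morse oscillator: fundamental = omega - 2 omega x_e
  D <- 50; a <- 0.05
  morse <- function(X) D * (1 - exp(-a * (X[, 1])))^2 + 0.5 * 1.2^2 * X[, 2]^2
  mp <- potential_surface(2, function(x) morse(matrix(x, 1)),
                          energy_many = morse)
  wm <- characterize_minimum(mp, c(0, 0))
  nmm <- build_nmode_surface(mp, wm)
  wfun <- a * sqrt(2 * D) - 2 * a^2 / 2
  expect_equal(mode_basis_frequency(nmm, 1), wfun, tolerance = 1e-3)
  ## doubling the sine basis does not move the result
  s <- fix_sym()
  nms <- build_nmode_surface(s$pes, s$wL)
  expect_lt(abs(mode_basis_frequency(nms, 1, n_basis = 200) -
                mode_basis_frequency(nms, 1, n_basis = 100)), 1e-6)
})

test_that("harmonic limit: VSCF and VCI equal exact harmonic sums", {
  hp <- harmonic_pes(w1 = 0.9, w2 = 1.4)
  w <- characterize_minimum(hp, c(0, 0))
  vs <- vscf_solve(build_nmode_surface(hp, w))
  expect_equal(vs$e_vscf, (0.9 + 1.4) / 2, tolerance = 1e-8)
  ls <- vcisd_solve(vs)
  want <- sort(as.vector(outer((0:6 + 0.5) * 0.9, (0:6 + 0.5) * 1.4, `+`)))
  expect_equal(ls$table$energy[1:10], want[1:10], tolerance = 1e-8)
  expect_equal(ls$table$label[1:3], c("GS", "v1", "v2"))
})

test_that("variational chain and basis plateau hold for the model well", {
  s <- fix_sym()
  nm <- build_nmode_surface(s$pes, s$wL)
  vs7 <- vscf_solve(nm, basis_size = 7)
  ls7 <- vcisd_solve(vs7)
  ## VSCF >= VCI ground state
  expect_gte(vs7$e_vscf, ls7$table$energy[1] - 1e-10)
  ## plateau: enlarging the basis changes the ground state by less than the
  ## tunneling-matrix element scale
  vs9 <- vscf_solve(nm, basis_size = 9)
  expect_lt(abs(vs9$e_vscf - vs7$e_vscf), 5e-4)
  ## states come out orthonormal
  G <- t(ls7$vectors) %*% ls7$vectors
  expect_equal(G, diag(nrow(G)), tolerance = 1e-10)
})

test_that("model-well VCI levels agree with a DVR solve of the fitted surface", {
  s <- fix_sym()
  nm <- build_nmode_surface(s$pes, s$wL)
  ls <- vcisd_solve(vscf_solve(nm))
  vf <- nmode_potential(nm)
  ## independent route: exact grid solve of the same fitted 2-mode surface
  ## (complete in two dimensions), box spanning the sampled region
  qpes <- potential_surface(2, function(q) vf(q),
                            energy_many = function(X) apply(X, 1, vf))
  dv <- solve_2d_dvr(qpes, grid_spec(c(-4.5, 5.5), c(-3.2, 3.2), 96),
                     n_levels = 3, check = FALSE)
  expect_equal(ls$table$energy[1], dv$values[1], tolerance = 5e-3)
  expect_equal(ls$table$energy[2], dv$values[2], tolerance = 5e-3)
  ## and the local ground state sits at the mean of the exact doublet
  dvr <- fix_sym_dvr()
  expect_equal(ls$table$energy[1], mean(dvr$values[1:2]), tolerance = 1e-4)
})
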