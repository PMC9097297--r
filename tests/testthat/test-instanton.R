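test_that("momentum profile vanishes at the well and matches closed forms", {
  hp <- harmonic_pes(w1 = 0.8, w2 = 1.7)
  path <- straight_path(hp, c(0, 0), c(4, 0))
  p0 <- momentum_profile(path, "L")
  expect_equal(p0(0), 0, tolerance = 1e-8)
  sg <- seq(0.2, 2.5, length.out = 7)
  expect_equal(p0(sg), 0.8 * sg, tolerance = 1e-6)
  ## integral of p0 equals the Jacobi action (cross-module consistency)
  s <- fix_sym()
  pm <- momentum_profile(s$path, "L")
  W <- stats::integrate(pm, 0, s$path$S_cp, rel.tol = 1e-10)$value
  expect_equal(W, jacobi_action(s$path, "L"), tolerance = 1e-9)
})

test_that("width matrices have the harmonic fixed point", {
  hp <- harmonic_pes(w1 = 0.8, w2 = 1.7)
  path <- straight_path(hp, c(0, 0), c(5, 0))
  wd <- propagate_widths(path, "L", epsilon = 0.1, s_end = 4.5)
  A0 <- diag(c(0.8, 1.7))
  for (sv in c(0.5, 2, 4.4)) {
    expect_lt(max(abs(wd$A_fun(sv) - A0)), 1e-6)
    expect_lt(abs(wd$W1_fun(sv)), 1e-6)
  }
  ## W0 matches the closed form omega s^2 / 2 (natural-spline end effects
  ## limit the agreement to ~1e-5 relative)
  expect_equal(wd$W0_fun(3), 0.8 * 9 / 2, tolerance = 1e-4)
})

test_that("widths are symmetric, mirror-consistent and step-converged", {
  s <- fix_sym()
  Acp_L <- s$wdL$A_fun(s$path$S_cp)
  Acp_R <- s$wdR$A_fun(s$path$S_tot - s$path$S_cp)
  expect_equal(Acp_L, t(Acp_L), tolerance = 1e-8)
  ## mirror image: conjugate by diag(-1, 1)
  Mir <- diag(c(-1, 1))
  expect_lt(max(abs(Acp_L - Mir %*% Acp_R %*% Mir)), 1e-6)
  ## halving the RK step barely changes A at the connection point
  wd_half <- propagate_widths(s$path, "L", rk_step = diff(s$path$S)[1] / 20)
  expect_lt(max(abs(wd_half$A_fun(s$path$S_cp) - Acp_L)), 1e-7)
})

test_that("excitation transport has the expected limits", {
  ## separable transverse mode: F stays 0, U stays the transverse mode
  hp <- harmonic_pes(w1 = 0.8, w2 = 1.7)
  path <- straight_path(hp, c(0, 0), c(5, 0))
  wd <- propagate_widths(path, "L", s_end = 4.5)
  ex2 <- propagate_excitation(path, "L", wd, mode_index = 2)
  for (sv in c(0.5, 2, 4.4)) {
    expect_lt(abs(ex2$F_fun(sv)), 1e-8)
    expect_equal(ex2$U_fun(sv), c(0, 1), tolerance = 1e-6)
  }
  ## longitudinal mode of a harmonic well: |F(s)| = s (1D WKB transport);
  ## the overall sign follows the normal-mode orientation convention
  ex1 <- propagate_excitation(path, "L", wd, mode_index = 1)
  sgn <- sign(ex1$F_fun(0.5))
  for (sv in c(0.5, 2, 4.4))
    expect_equal(ex1$F_fun(sv), sgn * sv, tolerance = 1e-4)
})

test_that("effective barriers match the printed benchmark values", {
  s <- fix_sym()
  expect_equal(effective_barrier(s$path, c(0, 0)), 1.221, tolerance = 0.002)
  expect_equal(effective_barrier(s$path, c(1, 0)), 0.545, tolerance = 0.002)
  expect_equal(effective_barrier(s$path, c(0, 1)), 0.976, tolerance = 0.002)
})

test_that("analytic and quadrature Herring elements agree", {
  s <- fix_sym()
  for (ql in list(c(0, 0), c(1, 0), c(0, 1))) {
    fa <- s$field("L", ql)
    fb <- s$field("R", c(0, 1))
    ha <- tm_element_fundamental(fa, fb, s$path)
    hn <- tm_element_numeric(fa, fb, s$path)
    if (abs(ha) > 1e-12)
      expect_lt(abs(hn - ha) / abs(ha), 1e-3)
  }
  ## quadrature order refinement
  fa <- s$field("L", c(0, 1)); fb <- s$field("R", c(0, 1))
  h20 <- tm_element_numeric(fa, fb, s$path, order = 20)
  h40 <- tm_element_numeric(fa, fb, s$path, order = 40)
  expect_lt(abs(h40 - h20) / abs(h20), 1e-4)
})

test_that("couplings of different-symmetry states vanish for theta = 0", {
  pes <- model_2d_pes(theta = 0)
  wL <- characterize_minimum(pes, attr(pes, "min_L"))
  wR <- characterize_minimum(pes, attr(pes, "min_R"))
  path <- optimize_map(pes, wL, wR, n_beads = 151, tol = 1e-6)
  wdL <- propagate_widths(path, "L"); wdR <- propagate_widths(path, "R")
  f00 <- instanton_field(path, "L", c(0, 0), widths = wdL)
  f02 <- instanton_field(path, "R", c(0, 1), widths = wdR)
  h <- tm_element_fundamental(f00, f02, path)
  h00 <- tm_element_fundamental(f00, instanton_field(path, "R", c(0, 0),
                                                     widths = wdR), path)
  expect_lt(abs(h), 1e-10 * abs(h00))
})

test_that("ground-state doublet splitting matches the exact reference", {
  s <- fix_sym()
  h00 <- tm_element_fundamental(s$field("L", c(0, 0)),
                                s$field("R", c(0, 0)), s$path)
  dvr <- fix_sym_dvr()
  gap <- dvr$values[2] - dvr$values[1]
  expect_lt(abs(2 * abs(h00) - gap) / gap, 0.03)
  ## transverse excitation also accurate; longitudinal overestimates
  h22 <- tm_element_fundamental(s$field("L", c(0, 1)),
                                s$field("R", c(0, 1)), s$path)
  gap22 <- dvr$values[6] - dvr$values[5]
  expect_lt(abs(2 * abs(h22) - gap22) / gap22, 0.08)
  h11 <- tm_element_fundamental(s$field("L", c(1, 0)),
                                s$field("R", c(1, 0)), s$path)
  gap11 <- dvr$values[4] - dvr$values[3]
  expect_gt(2 * abs(h11) / gap11, 1.0)   # known semiclassical overestimate
  expect_lt(2 * abs(h11) / gap11, 1.3)
})

test_that("connection-point invariance holds at resonance only", {
  s <- fix_sym()
  wdL <- propagate_widths(s$path, "L", s_end = 0.72 * s$path$S_tot)
  wdR <- propagate_widths(s$path, "R", s_end = 0.72 * s$path$S_tot)
  fL <- instanton_field(s$path, "L", c(0, 0), widths = wdL)
  fR <- instanton_field(s$path, "R", c(0, 0), widths = wdR)
  sens <- tm_sensitivity(fL, fR, s$path, cp_range = c(0.38, 0.62), n_grid = 7)
  expect_lt(sens$h_spread, 1e-3 * abs(sens$h_mean))
  ## off resonance (depth-asymmetric wells): measurable drift
  d <- 0.3
  pes <- model_2d_pes(d = d)
  wL <- characterize_minimum(pes, attr(pes, "min_L"))
  wR <- characterize_minimum(pes, attr(pes, "min_R"))
  path <- optimize_map(pes, wL, wR, n_beads = 151, tol = 1e-6, d = d)
  wdL2 <- propagate_widths(path, "L", s_end = 0.72 * path$S_tot)
  wdR2 <- propagate_widths(path, "R", s_end = 0.72 * path$S_tot)
  fL2 <- instanton_field(path, "L", c(0, 0), widths = wdL2)
  fR2 <- instanton_field(path, "R", c(0, 0), widths = wdR2)
  sens2 <- tm_sensitivity(fL2, fR2, path, cp_range = c(0.38, 0.62), n_grid = 7)
  expect_gt(sens2$h_spread, 10 * sens$h_spread)
})
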