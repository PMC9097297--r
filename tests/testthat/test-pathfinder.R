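test_that("the MAP of a separable double well is the straight line", {
  pes <- sep_double_well()
  wL <- characterize_minimum(pes, c(-3, 0))
  wR <- characterize_minimum(pes, c(3, 0))
  path <- optimize_map(pes, wL, wR, n_beads = 101, tol = 1e-6)
  expect_lt(max(abs(path$beads[, 2])), 1e-5)
  expect_lte(path$residual, 1e-6)
})

test_that("symmetric model path converges, is mirror symmetric, monotone", {
  s <- fix_sym()
  path <- s$path
  expect_lte(path$residual, 1e-6)
  ## mirror symmetry of the bead chain
  expect_lt(max(abs(path$beads[, 1] + rev(path$beads[, 1]))), 1e-5)
  expect_lt(max(abs(path$beads[, 2] - rev(path$beads[, 2]))), 1e-5)
  ## equally spaced in arc length
  expect_lt(diff(range(diff(path$S))), 1e-6 * path$S_tot)
  ## action history non-increasing overall
  W <- path$action_history
  expect_lte(W[length(W)], W[1] + 1e-12)
  ## central bead coincides with the potential maximum within one spacing
  smax <- stats::optimize(function(s) -path$v_spline(s),
                          c(0.3, 0.7) * path$S_tot)$minimum
  expect_lt(abs(smax - path$S_cp), 1.5 * diff(path$S)[1])
})

test_that("jacobi action reproduces closed forms and quadrature", {
  ## 1D harmonic: W0(0 -> S) = omega S^2 / 2 along the soft-mode line
  hp <- harmonic_pes(w1 = 0.8, w2 = 1.7)
  path <- straight_path(hp, c(0, 0), c(4, 0))
  W <- jacobi_action(path, "L", 0, 2.5)
  expect_equal(W, 0.8 * 2.5^2 / 2, tolerance = 1e-4)
  ## zero-length segment
  expect_identical(jacobi_action(path, "L", 1, 1), 0)
  ## additive over concatenated segments
  expect_equal(jacobi_action(path, "L", 0, 1) + jacobi_action(path, "L", 1, 2.5),
               W, tolerance = 1e-10)
  ## model segment vs an independent trapezoid oracle on a fine grid
  s <- fix_sym()
  Wm <- jacobi_action(s$path, "L")
  sg <- seq(0, s$path$S_cp, length.out = 20001)
  p <- sqrt(pmax(2 * s$path$v_spline(sg), 0))
  Wtrap <- sum((p[-1] + p[-length(p)]) / 2 * diff(sg))
  expect_equal(Wm, Wtrap, tolerance = 1e-7)
})

test_that("spline fields interpolate nodal values with natural ends", {
  s <- fix_sym()
  path <- s$path
  expect_equal(path$v_spline(path$S), path$V, tolerance = 1e-12)
  ## natural boundary: vanishing second derivative at the ends
  h <- 1e-4
  d2 <- (path$v_spline(path$S[1] + 2 * h) - 2 * path$v_spline(path$S[1] + h) +
           path$v_spline(path$S[1])) / h^2
  expect_lt(abs(d2), 5e-3)
  ## geometry spline reproduces beads
  expect_equal(path$x_spline[[1]](path$S), path$beads[, 1], tolerance = 1e-12)
})

test_that("bead-count refinement leaves the action stable", {
  s <- fix_sym()
  path2 <- optimize_map(s$pes, s$wL, s$wR, n_beads = 601, tol = 1e-6)
  W301 <- jacobi_action(s$path, "L") + jacobi_action(s$path, "R")
  W601 <- jacobi_action(path2, "L") + jacobi_action(path2, "R")
  expect_lt(abs(W301 - W601) / W301, 1e-4)
  ## interpolated potential agrees between discretizations mid-path
  sg <- seq(0.2, 0.8, length.out = 50) * s$path$S_tot
  expect_lt(max(abs(s$path$v_spline(sg) - path2$v_spline(sg))), 1e-6)
})

test_that("the Heaviside-modified surface shifts only the far side", {
  s <- fix_sym()
  pes0 <- build_modified_pes(s$pes, 0, s$path)
  expect_identical(pes0, s$pes)
  d <- 0.4
  pes_d <- model_2d_pes(d = d)
  wL <- characterize_minimum(pes_d, attr(pes_d, "min_L"))
  wR <- characterize_minimum(pes_d, attr(pes_d, "min_R"))
  path <- optimize_map(pes_d, wL, wR, n_beads = 101, tol = 1e-6, d = d)
  mod <- build_modified_pes(pes_d, d, path)
  iL <- 10; iR <- 90
  expect_equal(mod$energy(path$beads[iL, ]), pes_d$energy(path$beads[iL, ]))
  expect_equal(mod$energy(path$beads[iR, ]),
               pes_d$energy(path$beads[iR, ]) - d)
  ## both endpoints at equal modified energy
  expect_equal(mod$energy(path$beads[1, ]),
               mod$energy(path$beads[101, ]), tolerance = 1e-8)
  ## kinked path: connection tangent is the mean of one-sided limits
  expect_equal(sum(path$tangent_cp^2), 1, tolerance = 1e-10)
})

test_that("path checkpoints round-trip through tabular text", {
  s <- fix_sym()
  f <- tempfile(fileext = ".csv")
  write_map_checkpoint(s$path, f)
  back <- read_map_checkpoint(f, s$pes)
  expect_equal(back$beads, s$path$beads, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$S_tot, s$path$S_tot, tolerance = 1e-12)
  expect_equal(back$cp_index, s$path$cp_index)
  expect_equal(back$v_spline(1.7), s$path$v_spline(1.7), tolerance = 1e-10)
})
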