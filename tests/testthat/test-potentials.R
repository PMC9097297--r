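test_that("benchmark double well reproduces its printed harmonic limits", {
  pes <- model_2d_pes()
  wL <- characterize_minimum(pes, attr(pes, "min_L"))
  ## Hessian eigenvalues at the left minimum are (alpha1, alpha2)/m
  ev <- sort(eigen(pes$hessian(wL$geometry), symmetric = TRUE)$values)
  expect_equal(ev * 3.5, c(1.6, 4.0), tolerance = 1e-6)
  ## frequencies are sqrt(alpha/m)
  expect_equal(wL$frequencies, c(sqrt(1.6 / 3.5), sqrt(4 / 3.5)),
               tolerance = 1e-8)
  expect_equal(wL$energy, 0, tolerance = 1e-12)
  ## generic local minimizer agrees: optim started at the printed minimum
  o <- stats::optim(attr(pes, "min_L"), pes$energy, pes$gradient,
                    method = "BFGS")
  expect_lt(sqrt(sum((o$par - wL$geometry)^2)), 1e-4)
  expect_lt(abs(o$value), 1e-8)
})

test_that("mirror symmetry holds for symmetric parameters and d = 0", {
  pes <- model_2d_pes()
  set.seed(11)
  X <- matrix(runif(60, -6, 6), ncol = 2)
  expect_equal(pes$energy_many(X), pes$energy_many(model_2d_mirror(X)),
               tolerance = 1e-12)
})

test_that("depth offset d shifts the right minimum exactly, leaving shapes", {
  for (d in c(0.3, 1.1)) {
    pes <- model_2d_pes(d = d)
    wL <- characterize_minimum(pes, attr(pes, "min_L"))
    wR <- characterize_minimum(pes, attr(pes, "min_R"))
    expect_equal(wR$energy - wL$energy, d, tolerance = 1e-9)
    expect_equal(wR$frequencies, wL$frequencies, tolerance = 1e-6)
  }
})

test_that("analytic gradient matches finite differences on random points", {
  pes <- model_2d_pes(alpha1_R = 3.1, d = 0.25)
  set.seed(7)
  X <- matrix(runif(200, -5, 5), ncol = 2)
  for (k in seq_len(nrow(X))) {
    g <- pes$gradient(X[k, ])
    gfd <- vibtun:::fd_gradient(pes$energy, X[k, ], 1e-5)
    expect_lt(max(abs(g - gfd)) / max(1, max(abs(g))), 1e-6)
  }
  ## Hessian symmetric
  H <- pes$hessian(X[1, ])
  expect_equal(H, t(H), tolerance = 1e-12)
})

test_that("matrix_sqrt_psd squares back and rejects indefinite input", {
  expect_equal(matrix_sqrt_psd(diag(2)), diag(2))
  expect_equal(matrix_sqrt_psd(diag(c(4, 9))), diag(c(2, 3)))
  set.seed(3)
  B <- matrix(rnorm(25), 5)
  S <- crossprod(B)
  A <- matrix_sqrt_psd(S)
  expect_equal(A %*% A, S, tolerance = 1e-10)
  expect_equal(A, t(A), tolerance = 1e-12)
  expect_error(matrix_sqrt_psd(diag(c(1, -1))), "negative")
})

test_that("trans/rot projection removes six modes of a bent triatomic", {
  set.seed(5)
  geom <- matrix(c(0, 0, 0, 1.2, 0, 0, -0.3, 1.1, 0), 3, 3, byrow = TRUE)
  masses <- c(16, 1, 1)
  B <- matrix(rnorm(81), 9)
  H <- crossprod(B)
  Hp <- project_trans_rot(H, geom, masses)
  ev <- sort(abs(eigen(Hp, symmetric = TRUE)$values))
  expect_lt(ev[6], 1e-9 * ev[9])
  expect_gt(ev[7], 1e-6 * ev[9])
  ## idempotent
  expect_equal(project_trans_rot(Hp, geom, masses), Hp, tolerance = 1e-9)
  ## identity for model surfaces
  expect_equal(project_trans_rot(H), (H + t(H)) / 2)
})

test_that("XYZ reader converts to bohr and assigns masses", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("2", "test", "O 0 0 0", "H 0.9584 0 0"), f)
  xyz <- read_xyz(f)
  expect_equal(xyz$elements, c("O", "H"))
  expect_equal(xyz$geometry[2, 1], 0.9584 / 0.529177210903, tolerance = 1e-10)
  expect_equal(length(xyz$masses), 2)
  expect_gt(xyz$masses[1], xyz$masses[2])
})
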