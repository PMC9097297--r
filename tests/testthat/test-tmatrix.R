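test_that("degenerate 2x2 block splits into E +/- |h| with 50/50 content", {
  tm <- assemble_tm(1.0, 1.0, matrix(-0.2), labels_L = "GS", labels_R = "GS")
  sp <- spectrum(tm)
  expect_equal(sp$levels, c(0.8, 1.2))
  expect_equal(sp$configurations$weight_L, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sp$doublets$splitting, 0.4)
  expect_equal(sp$doublets$mixing_angle, 45, tolerance = 1e-10)
})

test_that("spectrum matches an independent characteristic-polynomial solve", {
  set.seed(21)
  EL <- sort(runif(3, 0, 2)); ER <- sort(runif(3, 0, 2))
  h <- matrix(rnorm(9, sd = 0.05), 3)
  tm <- assemble_tm(EL, ER, h)
  sp <- spectrum(tm)
  ## oracle: roots of det(M - x I) via polyroot on the expanded characteristic
  ## polynomial (computed from principal minors)
  M <- tm$matrix
  ## Faddeev-LeVerrier recursion for the characteristic coefficients
  fl <- function(M) {
    n <- nrow(M); cfs <- numeric(n + 1); cfs[1] <- 1
    Mk <- diag(n)
    for (k in 1:n) {
      Mk <- M %*% Mk
      cfs[k + 1] <- -sum(diag(Mk)) / k
      Mk <- Mk + cfs[k + 1] * diag(n)
    }
    cfs
  }
  cfs <- fl(M)
  roots <- sort(Re(polyroot(rev(cfs))))
  expect_equal(sp$levels, roots, tolerance = 1e-8)
  ## trace conservation
  expect_equal(sum(sp$levels), sum(EL) + sum(ER), tolerance = 1e-10)
})

test_that("pairs model keeps only corresponding couplings", {
  EL <- c(1, 2); ER <- c(1.1, 2.2)
  h <- matrix(c(-0.1, -0.03, -0.02, -0.2), 2)
  tmp <- assemble_tm(EL, ER, h, labels_L = c("GS", "v1"),
                     labels_R = c("GS", "v1"), model_size = "pairs")
  expect_equal(tmp$matrix[1, 4], 0)
  expect_equal(tmp$matrix[1, 3], -0.1)
  ## symmetric wells: the matrix commutes with the L/R block swap
  tms <- assemble_tm(EL, EL, (h + t(h)) / 2)
  Pswap <- rbind(cbind(matrix(0, 2, 2), diag(2)),
                 cbind(diag(2), matrix(0, 2, 2)))
  expect_equal(tms$matrix %*% Pswap, Pswap %*% tms$matrix, tolerance = 1e-12)
})

test_that("pair splitting: exact gap vs perturbative expansion", {
  expect_equal(pair_splitting(1, 1, -0.2)$exact, 0.4)
  expect_equal(pair_splitting(1, 1.5, 0)$exact, 0.5)
  h <- 0.02; dE <- 10 * h
  ps <- pair_splitting(1, 1 + dE, h)
  resid <- abs(ps$exact - ps$perturbative)
  expect_lt(resid, 4 * h^4 / dE^3)
  expect_gt(resid, 0.5 * h^4 / dE^3)
})

test_that("mixing angle reduces to the two-level formula", {
  ## generalized (eigenvector) route equals the closed-form 2x2 angle
  EL <- 1; ER <- 1.03; h <- -0.012
  sp <- spectrum(assemble_tm(EL, ER, matrix(h),
                             labels_L = "GS", labels_R = "GS"))
  phi_closed <- 0.5 * atan2(2 * abs(h), abs(ER - EL)) * 180 / pi
  expect_equal(sp$doublets$mixing_angle, phi_closed, tolerance = 1e-8)
  expect_equal(mixing_angle(list(E_L = EL, E_R = ER, h = h)), phi_closed,
               tolerance = 1e-10)
})

test_that("avoided-crossing search finds the analytic minimum gap", {
  h <- 0.07
  gap <- function(t) sqrt((2 * t)^2 + 4 * h^2)  # linear diabats, constant h
  loc <- locate_avoided_crossing(gap, seq(-1, 1, by = 0.25))
  expect_equal(loc$parameter, 0, tolerance = 1e-4)
  expect_equal(loc$min_gap, 2 * h, tolerance = 1e-8)
  ## refinement agrees with a dense brute-force scan
  dense <- seq(-1, 1, by = 1e-4)
  expect_equal(loc$parameter, dense[which.min(gap(dense))], tolerance = 2e-4)
  ## edge minimum is flagged
  expect_warning(loc2 <- locate_avoided_crossing(function(t) t, 1:5),
                 "not bracketed")
  expect_false(loc2$bracketed)
})

test_that("spectra are invariant to the normal-mode sign convention", {
  s <- fix_sym()
  EL <- c(1, 1.5, 1.9)
  h <- matrix(c(-0.1, 0.02, -0.03, 0.02, -0.05, 0.01,
                -0.03, 0.01, -0.08), 3)
  sp1 <- spectrum(assemble_tm(EL, EL, h))
  ## flipping the sign of mode 2's wavefunction flips row/column 2 of h
  Fm <- diag(c(1, -1, 1))
  sp2 <- spectrum(assemble_tm(EL, EL, Fm %*% h %*% Fm))
  expect_equal(sp1$levels, sp2$levels, tolerance = 1e-12)
})
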