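# Poisson solver, lateral averaging, and the piecewise profile fit.

test_that("zero density gives zero potential and the solver matches the closed-form single-mode solution", {
  g0 <- charge_density_grid(array(0, c(8, 8, 8)), spacing = 1)
  expect_equal(max(abs(solve_poisson(g0))), 0)

  # rho(z) = rho0 cos(k z), periodic box: psi = rho0/(eps0 k^2) cos(k z)
  nz <- 64; h <- 0.5; Lz <- nz * h
  k <- 2 * pi * 2 / Lz                    # mode 2
  z <- (seq_len(nz) - 1) * h
  rho0 <- 1e-3
  rho_z <- rho0 * cos(k * z)
  rho <- array(rep(rho_z, each = 16), c(4, 4, nz))
  grid <- charge_density_grid(rho, spacing = h, charge_tol = 1e-6)
  psi <- solve_poisson(grid)
  conv <- 4 * pi * mem_constants$coulomb_v * mem_constants$kcal_per_volt
  expected <- rho0 / k^2 * conv * cos(k * z)
  got <- apply(psi, 3, mean)
  expect_lt(max(abs(got - expected)) / max(abs(expected)), 5e-3)
})

test_that("solver matches a direct 1D quadrature oracle for opposite Gaussian slabs", {
  nz <- 320; h <- 0.25
  z <- (seq_len(nz) - 1 - (nz - 1) / 2) * h
  sl <- function(c0) exp(-(z - c0)^2 / 4) / sqrt(4 * pi)
  rho_z <- 1e-3 * (sl(10) - sl(-10))
  rho_z <- rho_z - mean(rho_z)
  rho <- array(rep(rho_z, each = 9), c(3, 3, nz))
  psi <- solve_poisson(charge_density_grid(rho, spacing = h))
  got <- apply(psi, 3, mean)
  got <- got - mean(got)
  oracle <- quadrature_poisson_1d(rho_z, h)
  expect_lt(max(abs(got - oracle)) / diff(range(oracle)), 0.01)
})

test_that("non-neutral grids error without the neutralizing-background flag and zero spacing is rejected", {
  rho <- array(1e-3, c(4, 4, 4))
  expect_error(charge_density_grid(rho, spacing = 1), "net charge")
  expect_silent(charge_density_grid(rho, spacing = 1, neutralize = TRUE))
  expect_error(charge_density_grid(array(0, c(4, 4, 4)), spacing = 0),
               "spacing")
})

test_that("lateral averaging reduces to the z-profile and is insensitive to zero-mean lateral structure", {
  # constant volume -> flat zero profile after referencing
  flat <- lateral_average(array(3.7, c(4, 4, 20)), spacing = 2,
                          reference_depth = 10)
  expect_equal(max(abs(flat$potential)), 0)

  # volume varying only in z equals the z-slice values (re-referenced)
  zv <- seq_len(30)
  vol <- array(rep(zv, each = 16), c(4, 4, 30))
  pr <- lateral_average(vol, spacing = 1, reference_depth = 5)
  iref <- which.min(abs(pr$depths - 5))
  expect_equal(pr$potential, zv - zv[iref])

  # checkerboard (zero lateral mean) superposed on a z-ramp -> the ramp
  chk <- outer(outer((-1)^(seq_len(4)), (-1)^(seq_len(4))), rep(1, 30))
  pr2 <- lateral_average(vol + 5 * chk, spacing = 1, reference_depth = 5)
  expect_equal(pr2$potential, pr$potential)
})

test_that("re-referencing a profile is idempotent", {
  pr <- reference_profile(seq(-45, 45), sin(seq(-45, 45) / 10), 40)
  pr2 <- reference_profile(pr$depths, pr$potential, 40)
  expect_identical(pr$potential, pr2$potential)
})

test_that("profile fit recovers generating parameters, exactly and under 1% noise", {
  true <- synthetic_profile_params()
  zs <- seq(-45, 45, 0.5)
  vals <- eval_profile(true, zs)
  pr <- reference_profile(zs, vals, 40)
  fit <- fit_profile(pr)
  expect_lt(abs(fit$z_c - true$z_c), 0.1)
  expect_lt(abs(fit$A3 - true$A3), 0.2)
  expect_lt(abs(fit$A4 - true$A4), 0.2)
  expect_lt(max(abs(eval_profile(fit, zs) - vals)), 0.05)

  set.seed(42)
  noisy <- vals + stats::rnorm(length(zs), sd = 0.01 * diff(range(vals)))
  fitn <- fit_profile(reference_profile(zs, noisy, 40))
  expect_lt(abs(fitn$z_c - true$z_c), 0.5)
})

test_that("fitted profiles are continuous at the crossover and even in z", {
  true <- synthetic_profile_params()
  zs <- seq(-45, 45, 0.5)
  fit <- fit_profile(reference_profile(zs, eval_profile(true, zs), 40))
  eps <- 1e-6
  expect_lt(abs(eval_profile(fit, fit$z_c - eps) -
                eval_profile(fit, fit$z_c + eps)), 0.02)
  zr <- seq(0.3, 44, length.out = 50)
  expect_identical(eval_profile(fit, zr), eval_profile(fit, -zr))
})

test_that("a flat zero profile yields the documented all-zero-amplitude degenerate fit", {
  pr <- reference_profile(seq(-45, 45), rep(0, 91), 40)
  fit <- fit_profile(pr)
  expect_equal(fit$A1, 0)
  expect_equal(fit$A2, 0)
  expect_equal(eval_profile(fit, c(0, 10, 30)), c(0, 0, 0))
})

test_that("profile evaluation honors the aqueous reference, |z| symmetry, and plain polynomial evaluation", {
  p <- lipid_profile_params("x", A1 = 0.3, A2 = 5, A3 = 15, A4 = 2,
                            C1 = -1e-4, C2 = 0, C3 = 0.05, C4 = 0, C5 = -4,
                            z_c = 10)
  expect_equal(eval_profile(p, 40), 0)
  expect_equal(eval_profile(p, -40), 0)
  expect_equal(eval_profile(p, 7.3), eval_profile(p, -7.3))
  # quartic coefficients zero except C5: value at center is C5 minus offset
  pc <- lipid_profile_params("c", A1 = 0, A2 = 1, A3 = 15, A4 = 2,
                             C1 = 0, C2 = 0, C3 = 0, C4 = 0, C5 = 2.5,
                             z_c = 10)
  raw40 <- memscore:::piecewise_raw(40, 0, 1, 15, 2, 0, 0, 0, 0, 2.5, 10)
  expect_equal(eval_profile(pc, 0), 2.5 - raw40)
})

test_that("profile parameter table and density-grid files round-trip", {
  p <- synthetic_profile_params()
  tf <- tempfile(fileext = ".tsv")
  write_profile_table(list(p), tf)
  back <- read_profile_table(tf, lipid = "synthetic")
  for (f in c("A1", "A2", "A3", "A4", "C1", "C3", "C5", "z_c"))
    expect_equal(back[[f]], p[[f]], tolerance = 1e-9)

  grid <- fixture_density_grid()
  gt <- tempfile(fileext = ".tsv")
  write_density_grid(grid, gt)
  g2 <- read_density_grid(gt)
  expect_equal(g2$dims, grid$dims)
  expect_equal(g2$density_lipid, grid$density_lipid, tolerance = 1e-9)
  gb <- tempfile(fileext = ".bin")
  write_density_grid_bin(grid, gb)
  g3 <- read_density_grid_bin(gb)
  expect_identical(g3$density_lipid, grid$density_lipid)
  expect_identical(g3$density_salt, grid$density_salt)
})
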