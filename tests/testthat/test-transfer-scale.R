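# Hydrophobicity-scale fitting, charged-residue extrapolation, and the
# stoichiometry regression for atom-type transfer energies.

test_that("scale-on-scale regression is exact for collinear synthetic scales and stable under on-line exclusions", {
  ww <- aa_scale(stats::setNames(seq(-2, 2, length.out = 10),
                                 aa_codes()[1:10]), "WW")
  mf <- aa_scale(2 * ww, "MF")
  names(mf) <- names(ww)
  fit <- fit_mf_vs_ww(mf, ww)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  # excluding points already on the line changes nothing
  fit2 <- fit_mf_vs_ww(mf, ww, excluded = names(ww)[c(2, 5)])
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$intercept, fit$intercept, tolerance = 1e-12)
  expect_error(fit_mf_vs_ww(mf, ww, excluded = names(ww)[1:8]),
               "at least 3")
})

test_that("noisy synthetic scales recover the generating slope within 2 standard errors", {
  set.seed(11)
  x <- stats::runif(18, -2, 4)
  y <- 1.8 * x + 0.3 + stats::rnorm(18, sd = 0.1)
  ww <- aa_scale(stats::setNames(x, aa_codes()[1:18]), "WW")
  mf <- aa_scale(stats::setNames(y, aa_codes()[1:18]), "MF")
  fit <- fit_mf_vs_ww(mf, ww)
  se <- summary(stats::lm(y ~ x))$coefficients["x", "Std. Error"]
  expect_lt(abs(fit$slope - 1.8), 2 * se)
  # extrapolation onto a held-out point of the generator line
  held <- extrapolate_charged(fit, 3.0)
  expect_lt(abs(held - (1.8 * 3 + 0.3)), 0.15)
})

test_that("charged-residue extrapolation is plain line evaluation", {
  fit <- structure(list(slope = 2, intercept = 0, r2 = 1),
                   class = "linear_fit")
  expect_equal(extrapolate_charged(fit, 3.0), 6.0)
  fit1 <- structure(list(slope = 1, intercept = 0, r2 = 1),
                    class = "linear_fit")
  expect_equal(extrapolate_charged(fit1, c(-1, 0.5)), c(-1, 0.5))
})

test_that("identity stoichiometry returns the amino-acid values as atom values", {
  codes <- aa_codes()[1:5]
  M <- diag(5); rownames(M) <- codes; colnames(M) <- paste0("t", 1:5)
  A <- stoichiometry_matrix(M)
  g <- aa_scale(stats::setNames(c(1.5, -2, 0.3, 4, -0.7), codes))
  x <- solve_atom_transfer(A, g)
  expect_equal(as.numeric(x), as.numeric(g))
  expect_equal(max(abs(attr(x, "residuals"))), 0)
})

test_that("consistent overdetermined systems recover atom values exactly and appended consistent rows change nothing", {
  set.seed(5)
  types <- paste0("t", 1:4)
  M <- matrix(sample(0:3, 8 * 4, replace = TRUE), 8, 4,
              dimnames = list(aa_codes()[1:8], types))
  M[rowSums(M) == 0, 1] <- 1
  x_true <- c(1.2, -0.4, 2.5, 0.1)
  g <- aa_scale(stats::setNames(as.numeric(M %*% x_true), rownames(M)))
  A <- stoichiometry_matrix(M)
  x <- solve_atom_transfer(A, g)
  expect_equal(as.numeric(x), x_true, tolerance = 1e-10)
  expect_lt(max(abs(attr(x, "residuals"))), 1e-10)

  # append two consistent rows (the deprotonated Asp/Glu analog)
  M2 <- rbind(M, `D-1` = c(1, 2, 0, 1), `E-1` = c(0, 1, 1, 2))
  g2 <- aa_scale(stats::setNames(as.numeric(M2 %*% x_true), rownames(M2)))
  x2 <- solve_atom_transfer(stoichiometry_matrix(M2), g2)
  expect_equal(as.numeric(x2), as.numeric(x), tolerance = 1e-10)
  # residual norm does not increase when exact rows are appended
  expect_lte(sum(attr(x2, "residuals")^2), sum(attr(x, "residuals")^2) + 1e-12)
})

test_that("inconsistent systems match the pseudo-inverse oracle and round-trip composition", {
  set.seed(9)
  M <- matrix(sample(0:2, 12 * 3, replace = TRUE), 12, 3,
              dimnames = list(aa_codes()[1:12], paste0("t", 1:3)))
  M[rowSums(M) == 0, 1] <- 1
  gv <- stats::rnorm(12)
  A <- stoichiometry_matrix(M)
  x <- solve_atom_transfer(A, aa_scale(stats::setNames(gv, rownames(M))))
  oracle <- as.numeric(MASS::ginv(M) %*% gv)
  expect_equal(as.numeric(x), oracle, tolerance = 1e-8)
  # composition is the plain matrix product
  back <- compose_aa_energy(A, x)
  expect_equal(as.numeric(back), as.numeric(M %*% oracle), tolerance = 1e-10)
})

test_that("composition handles hand-arithmetic and degenerate inputs", {
  M <- matrix(c(2, 1), 1, 2, dimnames = list("A", c("t1", "t2")))
  A <- stoichiometry_matrix(M)
  atom <- structure(c(t1 = 1.5, t2 = -0.5), class = "atom_scale")
  expect_equal(as.numeric(compose_aa_energy(A, atom)), 2.5)
  zero <- structure(c(t1 = 0, t2 = 0), class = "atom_scale")
  expect_equal(as.numeric(compose_aa_energy(A, zero)), 0)
  expect_error(compose_aa_energy(A, structure(c(t1 = 1), class = "atom_scale")),
               "t2")
  expect_error(stoichiometry_matrix(matrix(0, 1, 1,
                                           dimnames = list("A", "t"))),
               "at least one atom")
})

test_that("the default extended scale only moves carboxylate atom types relative to the unaugmented fit", {
  # solve with and without the deprotonated Asp/Glu rows; every atom type
  # not borne by a carboxylate residue keeps its value
  A_full <- default_stoichiometry()
  sc <- default_scales()
  fit <- fit_mf_vs_ww(sc$mf, sc$ww, excluded = c("D", "E"))
  g <- stats::setNames(as.numeric(sc$mf), names(sc$mf))
  g[["D-1"]] <- extrapolate_charged(fit, sc$ww[["D-1"]])
  g[["E-1"]] <- extrapolate_charged(fit, sc$ww[["E-1"]])
  rows_base <- setdiff(rownames(A_full), c("D-1", "E-1"))
  A_base <- stoichiometry_matrix(unclass(A_full)[rows_base, ])
  x_base <- suppressWarnings(solve_atom_transfer(A_base, aa_scale(g)))
  x_full <- suppressWarnings(solve_atom_transfer(A_full, aa_scale(g)))
  carbox <- c("COO", "OOC")
  other <- setdiff(colnames(A_full), carbox)
  # D-1/E-1 share the D/E stoichiometry, so only the carboxylate columns
  # receive new information; remaining types move negligibly
  expect_lt(max(abs(x_full[other] - x_base[other])),
            max(abs(x_full[carbox] - x_base[carbox])))
})
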