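# Dielectric mixing, Coulomb terms, lipid-field and transfer energies,
# the combined score and weight fitting.

test_that("sigmoidal dielectric hits its endpoints and is monotone", {
  expect_equal(sigmoidal_dielectric(0, 6, 80), 6)
  expect_equal(sigmoidal_dielectric(0, 3, 10), 3)
  expect_lt(abs(sigmoidal_dielectric(50, 6, 80) - 80), 1e-3)
  expect_lt(abs(sigmoidal_dielectric(50, 3, 10) - 10), 1e-3)
  expect_equal(sigmoidal_dielectric(c(0, 1, 17), 4.2, 4.2), rep(4.2, 3))
  r <- seq(0, 30, 0.05)
  expect_true(all(diff(sigmoidal_dielectric(r, 6, 80)) >= 0))
})

test_that("the mixed dielectric is the linear hydration mixture of the two sigmoids", {
  p <- dielectric_params()
  r <- c(0.5, 2, 5, 12)
  es <- sigmoidal_dielectric(r, p$eps_core_sol, p$eps_surf_sol,
                             p$sigmoid_steepness)
  em <- sigmoidal_dielectric(r, p$eps_core_mem, p$eps_surf_mem,
                             p$sigmoid_steepness)
  expect_equal(mixed_dielectric(r, 1, p), es)
  expect_equal(mixed_dielectric(r, 0, p), em)
  expect_equal(mixed_dielectric(r, 0.5, p), (es + em) / 2)
})

test_that("the truncated Coulomb energy matches hand arithmetic and its sign/truncation contract", {
  p <- dielectric_params()
  expect_equal(coulomb_pair(1, -1, 5.5, 1, p), 0)
  expect_equal(coulomb_pair(1, -1, 7, 1, p), 0)
  expect_equal(coulomb_pair(1, -1, 2.75, 1, p),
               -322 * (1 / 2.75 - 1 / 5.5))
  expect_true(all(coulomb_pair(1, 1, c(1, 2, 4), 6.5, p) > 0))
  expect_error(coulomb_pair(1, 1, 0, 1, p), "clash")
})

test_that("the excess membrane Coulomb energy vanishes in water and follows the substitution at f = 0", {
  p <- dielectric_params()
  r <- seq(0.5, 5.4, 0.1)
  expect_equal(excess_coulomb_pair(0.5, -0.3, r, rep(1, length(r)), p),
               rep(0, length(r)))
  es <- sigmoidal_dielectric(r, p$eps_core_sol, p$eps_surf_sol,
                             p$sigmoid_steepness)
  em <- sigmoidal_dielectric(r, p$eps_core_mem, p$eps_surf_mem,
                             p$sigmoid_steepness)
  expect_equal(excess_coulomb_pair(0.5, -0.3, r, 0, p),
               322 * 0.5 * -0.3 * (1 / r - 1 / 5.5) * (1 / em - 1 / es))
  # membrane strengthens attraction of opposite charges, repulsion of like
  fgrid <- seq(0, 0.99, 0.11)
  for (f in fgrid) {
    expect_true(all(excess_coulomb_pair(1, -1, r, f, p) < 0))
    expect_true(all(excess_coulomb_pair(1, 1, r, f, p) > 0))
  }
})

test_that("lipid-field energy is a plain charge-weighted profile sum", {
  prof <- synthetic_profile_params()
  s <- build_ideal_helix("AAAA", charged_termini = FALSE)
  s$atoms$charge <- 0
  expect_equal(lipid_field_energy(s, prof)$total, 0)
  # single charged atom at depth z0 contributes q * dPsi(z0)
  s2 <- build_ideal_helix("AAAA", charged_termini = FALSE)
  s2$atoms$charge <- 0
  s2$atoms$charge[1] <- 0.7
  z0 <- s2$atoms$z[1]
  expect_equal(lipid_field_energy(s2, prof)$total,
               0.7 * eval_profile(prof, z0))
  # atoms at |z| >= 40 contribute nothing
  s3 <- apply_orientation(s2, 60, 0, 0)
  expect_lt(abs(lipid_field_energy(s3, prof)$total), 1e-10)
})

test_that("transfer energy scales with lipid exposure", {
  s <- build_ideal_helix("AAA", charged_termini = FALSE)
  n <- nrow(s$atoms)
  scale <- structure(stats::setNames(rep(-2, 5),
                                     c("Nbb", "CAbb", "Cbb", "Obb", "CH3")),
                     class = "atom_scale")
  expect_equal(transfer_energy(s, scale, f_hyd = rep(1, n))$total, 0)
  expect_equal(transfer_energy(s, scale, f_hyd = rep(0, n))$total, -2 * n)
  one <- rep(1, n); one[1] <- 0.25
  expect_equal(transfer_energy(s, scale, f_hyd = one)$total, -1.5)
  bad <- structure(c(CH3 = 1), class = "atom_scale")
  expect_error(transfer_energy(s, bad), "missing")
})

test_that("the combined score recovers the transfer-only model at weights (0.5, 0, 0) and is linear in the weights", {
  s <- apply_orientation(build_ideal_helix("KLALALALALW"), 0, 10, 0)
  scale <- default_atom_scale()
  profA <- synthetic_profile_params()
  profB <- lipid_profile_params("other", A1 = 1, A2 = 8, A3 = 20, A4 = 3,
                                C1 = -2e-4, C2 = 0, C3 = 0.08, C4 = 0,
                                C5 = -6, z_c = 14)
  w19 <- weight_set(0.5, 0, 0)
  bA <- total_score(s, w19, profA, scale)
  bB <- total_score(s, w19, profB, scale)
  # lipid-profile independence when the new-term weights are zero
  expect_equal(bA$total[["combined"]], bB$total[["combined"]])
  expect_equal(bA$total[["combined"]], 0.5 * bA$total[["transfer"]])

  w1 <- weight_set(0.4, 0.1, 0.008)
  w2 <- weight_set(0.8, 0.2, 0.016)
  b1 <- total_score(s, w1, profA, scale)
  b2 <- total_score(s, w2, profA, scale)
  expect_equal(b2$total[["combined"]], 2 * b1$total[["combined"]],
               tolerance = 1e-12)
})

test_that("per-residue ledgers sum to the totals and scoring is invariant to atom order within residues", {
  s <- apply_orientation(build_ideal_helix("KLRALAEALW"), 2, 25, 40)
  prof <- synthetic_profile_params()
  b <- total_score(s, weight_set(), prof)
  expect_equal(sum(b$per_residue$transfer), b$total[["transfer"]])
  expect_equal(sum(b$per_residue$lipid_field), b$total[["lipid_field"]])
  expect_equal(sum(b$per_residue$dielec_excess), b$total[["dielec_excess"]])
  # shuffle atoms within each residue; totals unchanged
  at <- s$atoms
  set.seed(2)
  idx <- unlist(lapply(split(seq_len(nrow(at)), at$resno), sample))
  s2 <- s
  s2$atoms <- at[idx, ]
  s2$xyz0 <- s$xyz0[idx, ]
  b2 <- total_score(s2, weight_set(), prof)
  expect_equal(b2$total, b$total, tolerance = 1e-12)
})

test_that("a fully aqueous structure has (numerically) vanishing membrane terms", {
  s <- apply_orientation(build_ideal_helix("KLRALAEALW"), 80, 0, 0)
  prof <- synthetic_profile_params()
  b <- total_score(s, weight_set(), prof)
  expect_lt(abs(b$total[["transfer"]]), 1e-4)
  expect_lt(abs(b$total[["lipid_field"]]), 1e-8)
  expect_lt(abs(b$total[["dielec_excess"]]), 1e-4)
})

test_that("weight fitting recovers a synthetic weighted combination and honors degenerate inputs", {
  df <- fixture_ddg_table(n = 24, seed = 3)
  terms <- as.matrix(df[, 1:3])
  w <- fit_weights(terms, df$ddg_exp, n_starts = 8, seed = 1)
  expect_gte(attr(w, "correlation"), 0.999)
  # collapsed bounds return the single point
  wc <- fit_weights(terms, df$ddg_exp, lower = c(0.3, 0.1, 0.05),
                    upper = c(0.3, 0.1, 0.05))
  expect_equal(unlist(wc[c("w_wl", "w_lipid", "w_dielec")],
                      use.names = FALSE), c(0.3, 0.1, 0.05))
  expect_error(fit_weights(terms, rep(1, 24)), "constant")
  expect_error(fit_weights(terms * 0, df$ddg_exp), "zero")
  expect_error(fit_weights(terms[1:3, ], df$ddg_exp[1:3]), "at least 4")
})
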