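# Independent oracles and small fixture builders shared across tests.

# dense direct solve of the periodic discrete Poisson problem:
# L psi = -rho / eps0 (same units as solve_poisson), gauge = zero mean.
# Independent of the FFT path: builds the Laplacian matrix explicitly and
# uses a pseudo-inverse.
dense_poisson_oracle <- function(rho, spacing) {
  dims <- dim(rho)
  h <- rep_len(spacing, 3)
  n <- prod(dims)
  idx <- function(i, j, k) {
    i <- (i - 1) %% dims[1] + 1
    j <- (j - 1) %% dims[2] + 1
    k <- (k - 1) %% dims[3] + 1
    (k - 1) * dims[1] * dims[2] + (j - 1) * dims[1] + i
  }
  L <- matrix(0, n, n)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (k in seq_len(dims[3])) {
      p <- idx(i, j, k)
      L[p, p] <- -2 / h[1]^2 - 2 / h[2]^2 - 2 / h[3]^2
      L[p, idx(i + 1, j, k)] <- L[p, idx(i + 1, j, k)] + 1 / h[1]^2
      L[p, idx(i - 1, j, k)] <- L[p, idx(i - 1, j, k)] + 1 / h[1]^2
      L[p, idx(i, j + 1, k)] <- L[p, idx(i, j + 1, k)] + 1 / h[2]^2
      L[p, idx(i, j - 1, k)] <- L[p, idx(i, j - 1, k)] + 1 / h[2]^2
      L[p, idx(i, j, k + 1)] <- L[p, idx(i, j, k + 1)] + 1 / h[3]^2
      L[p, idx(i, j, k - 1)] <- L[p, idx(i, j, k - 1)] + 1 / h[3]^2
    }
  rhs <- -as.numeric(rho) * 4 * pi * mem_constants$coulomb_v *
    mem_constants$kcal_per_volt
  psi <- MASS::ginv(L) %*% rhs
  array(psi - mean(psi), dims)
}

# random neutral charge-density grid
random_neutral_grid <- function(dims, spacing = 1, seed = 1) {
  set.seed(seed)
  rho <- array(stats::rnorm(prod(dims)), dims)
  rho <- rho - mean(rho)
  charge_density_grid(rho, spacing = spacing)
}

# 1D double-quadrature oracle for a z-only density on a periodic box:
# integrates E' = -rho/eps0, psi' = -E with periodic-consistent constants
# (zero-mean field offset), zero-mean gauge.
quadrature_poisson_1d <- function(rho_z, h) {
  n <- length(rho_z)
  rho_z <- rho_z - mean(rho_z)
  conv <- 4 * pi * mem_constants$coulomb_v * mem_constants$kcal_per_volt
  # trapezoid cumulative integrals on the periodic cell
  trapz <- function(f) c(0, cumsum((f[-1] + f[-length(f)]) / 2))
  E <- trapz(rho_z) * h * conv           # dE/dz = rho/eps0 (field = -dpsi/dz)
  E <- E - mean(E)
  psi <- -trapz(E) * h
  psi - mean(psi)
}

# synthetic piecewise profile parameters with a genuine quartic core whose
# largest critical point is z_c (continuity satisfied by construction)
synthetic_profile_params <- function() {
  C1 <- -4e-4; C2 <- 0; C3 <- 0.12; C4 <- 0; C5 <- -10
  z_c <- sqrt(-C3 / (2 * C1))            # largest critical point
  qval <- C1 * z_c^4 + C3 * z_c^2 + C5
  A1 <- 0; A3 <- 12; A4 <- 2.5
  # choose A2 so the sigmoid meets the quartic at z_c
  A2 <- A1 - (qval - A1) * (1 + exp((z_c - A3) / A4))
  lipid_profile_params("synthetic", A1 = A1, A2 = A2, A3 = A3, A4 = A4,
                       C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
                       z_c = z_c)
}

# tiny helical structure with uniform custom atom typing for hand-arithmetic
# transfer-energy checks
toy_scorer_depth_well <- function(center = 7) {
  function(structure) {
    (structure$transform[["d"]] - center)^2
  }
}
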