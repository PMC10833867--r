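# Lipid-bilayer electrostatic potential: periodic FFT Poisson solver,
# lateral averaging to a depth profile, and the piecewise analytical fit
# (sigmoid tail / quartic core) used to evaluate Delta-Psi(z) per lipid.

#' Construct a periodic charge-density grid
#'
#' Holds the laterally periodic, gridded charge densities of an empty
#' bilayer-water(-salt) system, split into lipid, water and salt
#' contributions, in elementary charges per cubic Angstrom.
#'
#' @param density_lipid,density_water,density_salt 3D numeric arrays of per-
#'   voxel charge density (e/A^3). All three must share dimensions; water and
#'   salt default to zero arrays.
#' @param spacing numeric length-3 (or scalar) grid spacing in Angstrom.
#' @param neutralize logical; if `TRUE`, a non-neutral total charge is
#'   compensated by a uniform neutralizing background instead of an error.
#' @param charge_tol absolute tolerance (in e) on the total summed charge for
#'   a system to count as neutral.
#' @return An object of class `charge_density_grid` with fields `dims`,
#'   `spacing`, `box`, the three density arrays and the `neutralize` flag.
#' @export
charge_density_grid <- function(density_lipid,
                                density_water = NULL,
                                density_salt = NULL,
                                spacing = 1,
                                neutralize = FALSE,
                                charge_tol = 1e-6) {
  if (!is.array(density_lipid) || length(dim(density_lipid)) != 3L)
    stop("density_lipid must be a 3D array")
  dims <- dim(density_lipid)
  if (is.null(density_water)) density_water <- array(0, dims)
  if (is.null(density_salt))  density_salt  <- array(0, dims)
  if (!identical(dim(density_water), dims) || !identical(dim(density_salt), dims))
    stop("all density arrays must share dimensions")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("grid spacing must be positive")
  dv <- prod(spacing)
  total <- sum(density_lipid + density_water + density_salt) * dv
  if (abs(total) > charge_tol && !neutralize)
    stop(sprintf(
      "grid carries net charge %.3g e; set neutralize = TRUE to add a uniform background",
      total))
  structure(list(
    dims = dims, spacing = spacing, box = dims * spacing,
    density_lipid = density_lipid, density_water = density_water,
    density_salt = density_salt, neutralize = neutralize,
    net_charge = total), class = "charge_density_grid")
}

#' Solve Poisson's equation on a periodic grid by FFT
#'
#' Solves the discrete Poisson equation \eqn{\nabla^2 \Psi = -\rho/\epsilon_0}
#' (vacuum permittivity, explicit charges) on the periodic grid using the
#' eigen-decomposition of the 7-point discrete Laplacian under the 3D FFT.
#' The zero-frequency mode is set to zero (gauge choice); when the system is
#' not neutral this is equivalent to adding a uniform neutralizing
#' background, which is only permitted when the grid was built with
#' `neutralize = TRUE`.
#'
#' Output potential is in kcal mol^-1 e^-1: the solve is carried out in
#' volts (via the Coulomb prefactor e/(4 pi eps0) = 14.399645 V A) and
#' converted once with 1 V = 23.061 kcal mol^-1 e^-1.
#'
#' @param grid a [charge_density_grid()].
#' @return 3D numeric array of electrostatic potential per voxel.
#' @export
solve_poisson <- function(grid) {
  stopifnot(inherits(grid, "charge_density_grid"))
  rho <- grid$density_lipid + grid$density_water + grid$density_salt
  dims <- grid$dims
  h <- grid$spacing
  # eigenvalues of the periodic discrete Laplacian, one factor per axis
  lam1 <- (2 * cos(2 * pi * (seq_len(dims[1]) - 1) / dims[1]) - 2) / h[1]^2
  lam2 <- (2 * cos(2 * pi * (seq_len(dims[2]) - 1) / dims[2]) - 2) / h[2]^2
  lam3 <- (2 * cos(2 * pi * (seq_len(dims[3]) - 1) / dims[3]) - 2) / h[3]^2
  lam <- outer(outer(lam1, lam2, `+`), lam3, `+`)
  rho_hat <- stats::fft(rho)
  psi_hat <- array(0i, dims)
  nz <- lam != 0
  # L psi = -rho/eps0  =>  psi_hat = -rho_hat / (eps0 * lam)
  psi_hat[nz] <- -rho_hat[nz] / lam[nz] * (4 * pi * mem_constants$coulomb_v)
  psi <- Re(stats::fft(psi_hat, inverse = TRUE)) / prod(dims)
  psi * mem_constants$kcal_per_volt
}

#' Laterally average a potential volume to a depth profile
#'
#' Averages \eqn{\Psi(x, y, z)} over the lateral (x, y) directions to obtain
#' the depth profile \eqn{\Psi(z)}, then re-references it to zero at the
#' grid point nearest `reference_depth`. Depths are reported relative to the
#' box center (bilayer midplane at z = 0).
#'
#' @param volume 3D potential array (third index = z).
#' @param spacing grid spacing (scalar or length 3, Angstrom).
#' @param reference_depth depth (Angstrom) pinned to zero potential;
#'   clamped to the covered depth range.
#' @return An object of class `potential_profile` with fields `depths`,
#'   `potential`, `reference_depth`.
#' @export
lateral_average <- function(volume, spacing, reference_depth = 40) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    stop("volume must be a 3D array")
  spacing <- rep_len(as.numeric(spacing), 3L)
  nz <- dim(volume)[3]
  prof <- apply(volume, 3, mean)
  depths <- (seq_len(nz) - 1 - (nz - 1) / 2) * spacing[3]
  reference_profile(depths, prof, reference_depth)
}

#' Build and re-reference a 1D potential profile
#'
#' @param depths strictly increasing z values (Angstrom).
#' @param potential potential values (kcal mol^-1 e^-1).
#' @param reference_depth z pinned to zero (nearest grid point used).
#' @return `potential_profile` object.
#' @export
reference_profile <- function(depths, potential, reference_depth = 40) {
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing")
  if (length(depths) != length(potential)) stop("length mismatch")
  iref <- which.min(abs(depths - reference_depth))
  structure(list(depths = as.numeric(depths),
                 potential = as.numeric(potential - potential[iref]),
                 reference_depth = reference_depth),
            class = "potential_profile")
}

# raw (un-referenced) piecewise profile model: sigmoid tail for |z| >= z_c,
# quartic core for |z| < z_c; a function of |z| only
piecewise_raw <- function(z, A1, A2, A3, A4, C1, C2, C3, C4, C5, z_c) {
  az <- abs(z)
  out <- numeric(length(az))
  tail <- az >= z_c
  out[tail] <- A1 + (A1 - A2) / (1 + exp((az[tail] - A3) / A4))
  core <- !tail
  out[core] <- C1 * az[core]^4 + C2 * az[core]^3 + C3 * az[core]^2 +
    C4 * az[core] + C5
  out
}

#' Construct a lipid profile parameter set
#'
#' The fitted analytical potential profile of one lipid/salt condition:
#' a sigmoid tail `A1 + (A1 - A2)/(1 + exp((|z| - A3)/A4))` for
#' `|z| >= z_c` and a quartic core `C1|z|^4 + ... + C5` for `|z| < z_c`,
#' with `z_c` the largest critical point of the quartic. Evaluation is a
#' function of `|z|` only and is referenced to zero at `reference_depth`.
#'
#' @param lipid_name label, e.g. "DLPC".
#' @param A1,A2 sigmoid amplitudes (kcal mol^-1 e^-1).
#' @param A3,A4 sigmoid midpoint and width (Angstrom); `A4 != 0`.
#' @param C1,C2,C3,C4,C5 quartic core coefficients.
#' @param z_c crossover depth (Angstrom), positive.
#' @param has_salt logical flag recording whether the source system
#'   contained salt.
#' @param reference_depth depth of the aqueous zero reference (default 40).
#' @return object of class `lipid_profile_params`.
#' @export
lipid_profile_params <- function(lipid_name, A1, A2, A3, A4,
                                 C1, C2, C3, C4, C5, z_c,
                                 has_salt = FALSE, reference_depth = 40) {
  if (z_c <= 0) stop("z_c must be positive")
  if (A4 == 0) stop("A4 must be nonzero")
  structure(list(lipid_name = lipid_name,
                 A1 = A1, A2 = A2, A3 = A3, A4 = A4,
                 C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
                 z_c = z_c, has_salt = isTRUE(has_salt),
                 reference_depth = reference_depth),
            class = "lipid_profile_params")
}

#' Evaluate a fitted lipid potential profile
#'
#' Returns \eqn{\Delta\Psi(z)} in kcal mol^-1 e^-1, i.e. the piecewise
#' analytical profile referenced so that the value at
#' `|z| = reference_depth` is exactly zero; beyond the reference depth the
#' potential is bulk water and identically zero. Even in z by
#' construction.
#'
#' @param params a [lipid_profile_params()].
#' @param z depth(s) in Angstrom (vectorized).
#' @return numeric vector of potential differences.
#' @export
eval_profile <- function(params, z) {
  stopifnot(inherits(params, "lipid_profile_params"))
  raw <- function(zz) piecewise_raw(zz, params$A1, params$A2, params$A3,
                                    params$A4, params$C1, params$C2,
                                    params$C3, params$C4, params$C5,
                                    params$z_c)
  out <- raw(z) - raw(params$reference_depth)
  out[abs(z) >= params$reference_depth] <- 0
  out
}

# largest positive critical point of the quartic core, NA if none
quartic_zc <- function(C1, C2, C3, C4, zmax) {
  # roots of d/dz (C1 z^4 + C2 z^3 + C3 z^2 + C4 z + C5)
  co <- c(C4, 2 * C3, 3 * C2, 4 * C1)   # ascending for polyroot
  if (all(abs(co[-1]) < 1e-14)) return(NA_real_)
  r <- polyroot(co)
  re <- Re(r)[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))]
  re <- re[re > 1e-9 & re <= zmax]
  if (!length(re)) NA_real_ else max(re)
}

#' Fit the piecewise analytical profile to a depth profile
#'
#' Fits the two-piece model (sigmoid tail for `|z| >= z_c`, quartic core
#' for `|z| < z_c`) to a laterally averaged potential profile. The
#' crossover `z_c` is located by scanning candidate depths (at each
#' candidate, the quartic is a weighted linear fit on the core and the
#' sigmoid a nonlinear fit on the tail, tied by a soft continuity
#' pseudo-observation at `z_c` weighted `continuity_weight` times the
#' data). Among candidates whose joint residual lies within `rss_band` of
#' the optimum, the most self-consistent one is selected — the one
#' minimizing the gap between `z_c` and the largest critical point of its
#' own fitted quartic — and the fixed-point iteration
#' `z_c <- largest critical point` is then polished to 0.01 A with cycle
#' detection. Profiles with a flat core have degenerate critical points;
#' there the residual optimum is kept as-is.
#'
#' The profile is symmetrized (average of \eqn{\Psi(z)} and \eqn{\Psi(-z)})
#' before fitting, so the result is a function of `|z|` only.
#'
#' @param profile a `potential_profile`.
#' @param initial_guess optional named list with starting values for any of
#'   `A1, A2, A3, A4, z_c` (`z_c` narrows the candidate search to its
#'   neighborhood).
#' @param max_iter maximum self-consistency iterations (default 50).
#' @param zc_tol convergence tolerance on `z_c` in Angstrom (default 0.01).
#' @param continuity_weight weight of the continuity pseudo-observation
#'   relative to the data (default 100).
#' @param rss_band relative residual band within which candidates count as
#'   statistically equivalent (default 1.05).
#' @param lipid_name,has_salt metadata stored on the result.
#' @return a [lipid_profile_params()] with attributes `rss` (final residual
#'   sum of squares) and `iterations`.
#' @export
fit_profile <- function(profile, initial_guess = list(), max_iter = 50,
                        zc_tol = 0.01, continuity_weight = 100,
                        rss_band = 1.05,
                        lipid_name = "fitted", has_salt = FALSE) {
  stopifnot(inherits(profile, "potential_profile"))
  z <- profile$depths
  psi <- profile$potential
  # symmetrize onto |z|
  az <- abs(z)
  ord <- order(az)
  az <- az[ord]; psis <- psi[ord]
  uz <- sort(unique(round(az, 9)))
  pv <- vapply(uz, function(u) mean(psis[abs(az - u) < 1e-9]), numeric(1))
  zmax <- max(uz)
  rng <- diff(range(pv))
  if (rng < 1e-12) {
    # degenerate flat profile: all-zero amplitudes, documented behavior
    out <- lipid_profile_params(lipid_name, A1 = 0, A2 = 0, A3 = zmax / 2,
                                A4 = 1, C1 = 0, C2 = 0, C3 = 0, C4 = 0,
                                C5 = 0, z_c = zmax / 2, has_salt = has_salt,
                                reference_depth = profile$reference_depth)
    attr(out, "rss") <- 0; attr(out, "iterations") <- 0L
    return(out)
  }
  g <- function(nm, default) {
    if (!is.null(initial_guess[[nm]])) initial_guess[[nm]] else default
  }
  # fit both branches at a fixed crossover; returns state with joint rss
  fit_at <- function(zc, sig_start = NULL) {
    core <- uz < zc
    tail <- !core
    if (sum(core) < 6 || sum(tail) < 5) return(NULL)
    # sigmoid on tail first (its value anchors the continuity row)
    a1_0 <- g("A1", pv[which.max(uz)])
    start <- if (!is.null(sig_start)) {
      as.list(stats::setNames(sig_start, c("A1", "A2", "A3", "A4")))
    } else {
      list(A1 = a1_0,
           A2 = g("A2", 2 * a1_0 - pv[max(which(core))]),
           A3 = g("A3", zc), A4 = g("A4", 2))
    }
    zt <- uz[tail]; yt <- pv[tail]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yt ~ A1 + (A1 - A2) / (1 + exp((zt - A3) / A4)),
        start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    sig <- stats::coef(fit)
    sval <- sig[1] + (sig[1] - sig[2]) / (1 + exp((zc - sig[3]) / sig[4]))
    # quartic on core with continuity pseudo-observation at zc
    X <- rbind(cbind(uz[core]^4, uz[core]^3, uz[core]^2, uz[core], 1),
               c(zc^4, zc^3, zc^2, zc, 1))
    y <- c(pv[core], sval)
    w <- c(rep(1, sum(core)), continuity_weight)
    quart <- stats::lm.wfit(X, y, w)$coefficients
    quart[is.na(quart)] <- 0
    pred <- piecewise_raw(uz, sig[[1]], sig[[2]], sig[[3]], sig[[4]],
                          quart[[1]], quart[[2]], quart[[3]], quart[[4]],
                          quart[[5]], zc)
    qc <- sum(quart * c(zc^4, zc^3, zc^2, zc, 1))
    rss <- sum((pred - pv)^2) + continuity_weight * (qc - sval)^2
    qzc <- quartic_zc(quart[1], quart[2], quart[3], quart[4], zmax)
    list(zc = zc, sig = sig, quart = quart, rss = rss, qzc = qzc,
         selfgap = if (is.na(qzc)) Inf else abs(qzc - zc))
  }
  # stage 1: candidate scan; among near-optimal residuals prefer the most
  # self-consistent crossover
  cands <- uz[uz >= uz[7] & uz <= zmax - 5 * mean(diff(uz))]
  if (!is.null(initial_guess$z_c))
    cands <- cands[abs(cands - initial_guess$z_c) <= 5]
  if (!length(cands)) stop("profile too short to place a crossover")
  states <- Filter(Negate(is.null), lapply(cands, fit_at))
  if (!length(states))
    stop("sigmoid fit failed at every candidate crossover")
  rssv <- vapply(states, `[[`, numeric(1), "rss")
  near <- states[rssv <= min(rssv) * rss_band]
  gaps <- vapply(near, `[[`, numeric(1), "selfgap")
  best <- if (all(is.infinite(gaps))) states[[which.min(rssv)]]
          else near[[which.min(gaps)]]
  # stage 2: fixed-point polish z_c <- largest quartic critical point,
  # with cycle detection and the residual band as safeguard
  it <- 0L
  seen <- best$zc
  converged <- is.finite(best$selfgap) && best$selfgap < zc_tol
  while (!converged && it < max_iter) {
    it <- it + 1L
    if (is.na(best$qzc)) break         # degenerate core: keep rss optimum
    if (best$selfgap < zc_tol) { converged <- TRUE; break }
    if (any(abs(best$qzc - seen) < zc_tol)) break   # cycle
    st <- fit_at(best$qzc, sig_start = best$sig)
    if (is.null(st) || st$rss > min(rssv) * rss_band) break
    seen <- c(seen, st$zc)
    best <- st
    converged <- best$selfgap < zc_tol
  }
  out <- lipid_profile_params(lipid_name,
                              A1 = best$sig[[1]], A2 = best$sig[[2]],
                              A3 = best$sig[[3]], A4 = best$sig[[4]],
                              C1 = best$quart[[1]], C2 = best$quart[[2]],
                              C3 = best$quart[[3]], C4 = best$quart[[4]],
                              C5 = best$quart[[5]], z_c = best$zc,
                              has_salt = has_salt,
                              reference_depth = profile$reference_depth)
  attr(out, "rss") <- best$rss
  attr(out, "iterations") <- it
  attr(out, "self_consistent") <- converged
  out
}
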