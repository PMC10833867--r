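# Membrane energy terms: hydration-mixed sigmoidal dielectric Coulomb
# energy, lipid-field energy from the potential profile, water-to-bilayer
# transfer energy, the weighted combined score, and weight fitting against
# experimental ddG data.

#' Dielectric and Coulomb parameters
#'
#' @param eps_core_sol,eps_surf_sol core/surface dielectric constants of the
#'   solution sigmoid (defaults 6 and 80).
#' @param eps_core_mem,eps_surf_mem core/surface dielectric constants of the
#'   membrane sigmoid (defaults 3 and 10).
#' @param sigmoid_steepness sigmoid steepness in 1/Angstrom (default 1.2).
#' @param r_max Coulomb truncation distance in Angstrom (default 5.5).
#' @param C0 Coulomb's constant, 322 Angstrom kcal/mol e^-2.
#' @return object of class `dielectric_params`.
#' @export
dielectric_params <- function(eps_core_sol = 6, eps_surf_sol = 80,
                              eps_core_mem = 3, eps_surf_mem = 10,
                              sigmoid_steepness = 1.2, r_max = 5.5,
                              C0 = mem_constants$coulomb_kcal) {
  if (eps_core_sol <= 0 || eps_core_mem <= 0 ||
      eps_core_sol > eps_surf_sol || eps_core_mem > eps_surf_mem)
    stop("require 0 < eps_core <= eps_surf for both environments")
  if (r_max <= 0) stop("r_max must be positive")
  structure(list(eps_core_sol = eps_core_sol, eps_surf_sol = eps_surf_sol,
                 eps_core_mem = eps_core_mem, eps_surf_mem = eps_surf_mem,
                 sigmoid_steepness = sigmoid_steepness, r_max = r_max,
                 C0 = C0), class = "dielectric_params")
}

#' Weight set for the combined membrane score
#'
#' @param w_wl weight of the water-to-bilayer transfer term.
#' @param w_lipid weight of the lipid-field term.
#' @param w_dielec weight of the membrane-dielectric Coulomb term.
#' @return object of class `weight_set`. Defaults are the fitted values
#'   (1, 0.128, 0.01); `weight_set(0.5, 0, 0)` recovers the predecessor
#'   model without the electrostatic terms.
#' @export
weight_set <- function(w_wl = 1, w_lipid = 0.128, w_dielec = 0.01) {
  w <- c(w_wl = w_wl, w_lipid = w_lipid, w_dielec = w_dielec)
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  structure(as.list(w), class = "weight_set")
}

#' Sigmoidal distance-dependent dielectric
#'
#' Smooth monotone transition from `eps_core` at contact to `eps_surf` at
#' long range (Hingerty-Lavery form):
#' `eps(r) = eps_s - (eps_s - eps_c) * ((sr)^2 + 2sr + 2) * exp(-sr) / 2`.
#'
#' @param r distance(s) in Angstrom, >= 0.
#' @param eps_core,eps_surf endpoint dielectric constants.
#' @param steepness s in 1/Angstrom.
#' @return dielectric constant(s).
#' @export
sigmoidal_dielectric <- function(r, eps_core, eps_surf, steepness = 1.2) {
  if (any(r < 0)) stop("r must be non-negative")
  sr <- steepness * r
  eps_surf - (eps_surf - eps_core) * (sr^2 + 2 * sr + 2) * exp(-sr) / 2
}

#' Hydration-mixed dielectric for an atom pair
#'
#' Linear mixture of the solution and membrane sigmoids weighted by the
#' pair hydration fraction:
#' `eps = f * eps_sol(r) + (1 - f) * eps_memb(r)`.
#'
#' @param r pair distance(s), Angstrom.
#' @param f_pair pair hydration fraction(s) in [0, 1].
#' @param params a [dielectric_params()].
#' @return dielectric constant(s).
#' @export
mixed_dielectric <- function(r, f_pair, params = dielectric_params()) {
  if (any(f_pair < 0 | f_pair > 1)) stop("f_pair must lie in [0, 1]")
  es <- sigmoidal_dielectric(r, params$eps_core_sol, params$eps_surf_sol,
                             params$sigmoid_steepness)
  em <- sigmoidal_dielectric(r, params$eps_core_mem, params$eps_surf_mem,
                             params$sigmoid_steepness)
  f_pair * es + (1 - f_pair) * em
}

#' Truncated Coulomb pair energy
#'
#' `C0 q_i q_j / eps * (1/r - 1/r_max)`, zero at and beyond the truncation
#' distance `r_max`.
#'
#' @param q_i,q_j partial charges (e).
#' @param r pair distance(s), Angstrom, > 0.
#' @param eps dielectric constant(s).
#' @param params a [dielectric_params()] (supplies `C0` and `r_max`).
#' @return energy in kcal/mol.
#' @export
coulomb_pair <- function(q_i, q_j, r, eps, params = dielectric_params()) {
  if (any(r <= 0)) stop("r must be positive (clash)")
  e <- params$C0 * q_i * q_j / eps * (1 / r - 1 / params$r_max)
  e[r >= params$r_max] <- 0
  e
}

#' Excess membrane-dielectric Coulomb pair energy
#'
#' The membrane contribution in excess of the aqueous-phase electrostatics:
#' `C0 q_i q_j (1/r - 1/r_max) * (1/eps(r, f) - 1/eps_sol(r))`. Vanishes
#' identically for fully hydrated pairs (f = 1) and at `r >= r_max`, so the
#' unfolded aqueous reference state is unaffected.
#'
#' @param q_i,q_j partial charges (e).
#' @param r pair distance(s), Angstrom, > 0.
#' @param f_pair pair hydration fraction(s).
#' @param params a [dielectric_params()].
#' @return excess energy in kcal/mol.
#' @export
excess_coulomb_pair <- function(q_i, q_j, r, f_pair,
                                params = dielectric_params()) {
  if (any(r <= 0)) stop("r must be positive (clash)")
  es <- sigmoidal_dielectric(r, params$eps_core_sol, params$eps_surf_sol,
                             params$sigmoid_steepness)
  emix <- mixed_dielectric(r, f_pair, params)
  e <- params$C0 * q_i * q_j * (1 / r - 1 / params$r_max) * (1 / emix - 1 / es)
  e[r >= params$r_max] <- 0
  e
}

# pair list of a structure: all atom pairs within r_max, excluding pairs
# inside the same residue (bonded/1-3 dominated). Distances depend only on
# internal geometry, so the list is computed once per structure and reused
# across rigid-body orientations.
pair_list <- function(structure, r_max) {
  xyz <- structure$xyz0
  n <- nrow(xyz)
  if (n < 2) return(data.frame(i = integer(), j = integer(), r = numeric()))
  d <- as.matrix(stats::dist(xyz))
  resno <- structure$atoms$resno
  same <- outer(resno, resno, `==`)
  sel <- upper.tri(d) & d < r_max & !same
  idx <- which(sel, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2], r = d[sel])
}

#' Lipid-field energy of a structure
#'
#' Sum over atoms of the lipid electrostatic potential at each atom's depth
#' times its partial charge: `sum_r sum_a DeltaPsi(z_ra) q_ra`.
#'
#' @param structure a `mem_structure` with charges, in the membrane frame.
#' @param profile a [lipid_profile_params()].
#' @return list with `total` (kcal/mol) and `per_residue` (named vector).
#' @export
lipid_field_energy <- function(structure, profile) {
  at <- structure$atoms
  if (any(is.na(at$charge)))
    stop("atoms without charges: ",
         paste(unique(at$name[is.na(at$charge)]), collapse = ", "))
  e <- eval_profile(profile, at$z) * at$charge
  per <- tapply(e, at$resno, sum)
  list(total = sum(e), per_residue = per)
}

#' Water-to-bilayer transfer energy of a structure
#'
#' Per-atom transfer energies weighted by lipid exposure:
#' `sum_a dG_atom(type_a) * (1 - f_hyd,a)`; fully hydrated atoms
#' contribute nothing (aqueous reference state).
#'
#' @param structure a `mem_structure`.
#' @param atom_scale an `atom_scale` covering all atom types present.
#' @param f_hyd per-atom hydration fractions (defaults to depth-based values
#'   from `geometry` with `f_pore`).
#' @param geometry a [membrane_geometry()].
#' @param f_pore per-atom pore exposure (recycled).
#' @return list with `total` and `per_residue`.
#' @export
transfer_energy <- function(structure, atom_scale = default_atom_scale(),
                            f_hyd = NULL, geometry = membrane_geometry(),
                            f_pore = 0) {
  at <- structure$atoms
  unknown <- setdiff(unique(at$type), names(atom_scale))
  if (length(unknown))
    stop("atom type(s) missing from scale: ", paste(unknown, collapse = ", "))
  if (is.null(f_hyd))
    f_hyd <- hydration_fraction(at$z, geometry, rep_len(f_pore, nrow(at)))
  g <- as.numeric(atom_scale[at$type])
  e <- g * (1 - f_hyd)
  per <- tapply(e, at$resno, sum)
  list(total = sum(e), per_residue = per)
}

#' Combined membrane score of a structure
#'
#' Linear combination of a baseline (soluble-protein) score with the three
#' membrane terms:
#' `combined = baseline + w_wl * dG_wl + w_lipid * dG_lipid +
#'  w_dielec * sum dE_elec`. Pair energies are split half/half between the
#' partner residues in the per-residue ledger.
#'
#' @param structure a `mem_structure` in the membrane frame.
#' @param weights a [weight_set()].
#' @param profile a [lipid_profile_params()].
#' @param atom_scale an `atom_scale`.
#' @param params a [dielectric_params()].
#' @param geometry a [membrane_geometry()].
#' @param f_pore per-atom pore exposure (recycled).
#' @param baseline_scorer function(structure) -> energy; any external
#'   soluble-protein scorer (default: constant zero).
#' @return object of class `energy_breakdown`: list with `total` (named
#'   vector: transfer, lipid_field, dielec_excess, baseline, combined) and
#'   `per_residue` (data.frame).
#' @export
total_score <- function(structure, weights = weight_set(),
                        profile, atom_scale = default_atom_scale(),
                        params = dielectric_params(),
                        geometry = membrane_geometry(), f_pore = 0,
                        baseline_scorer = function(s) 0) {
  at <- structure$atoms
  fp <- rep_len(f_pore, nrow(at))
  fh <- hydration_fraction(at$z, geometry, fp)
  tr <- transfer_energy(structure, atom_scale, f_hyd = fh)
  lf <- lipid_field_energy(structure, profile)
  pl <- pair_list(structure, params$r_max)
  resn <- sort(unique(at$resno))
  dper <- stats::setNames(numeric(length(resn)), resn)
  dtot <- 0
  if (nrow(pl)) {
    fpair <- pair_hydration(fh[pl$i], fh[pl$j])
    de <- excess_coulomb_pair(at$charge[pl$i], at$charge[pl$j], pl$r, fpair,
                              params)
    dtot <- sum(de)
    half_i <- tapply(de / 2, at$resno[pl$i], sum)
    half_j <- tapply(de / 2, at$resno[pl$j], sum)
    dper[names(half_i)] <- dper[names(half_i)] + half_i
    dper[names(half_j)] <- dper[names(half_j)] + half_j
  }
  base <- baseline_scorer(structure)
  comb <- base + weights$w_wl * tr$total + weights$w_lipid * lf$total +
    weights$w_dielec * dtot
  per <- data.frame(resno = resn,
                    transfer = as.numeric(tr$per_residue[as.character(resn)]),
                    lipid_field = as.numeric(lf$per_residue[as.character(resn)]),
                    dielec_excess = as.numeric(dper[as.character(resn)]))
  per$combined <- weights$w_wl * per$transfer +
    weights$w_lipid * per$lipid_field + weights$w_dielec * per$dielec_excess
  base::structure(list(
    total = c(transfer = tr$total, lipid_field = lf$total,
              dielec_excess = dtot, baseline = base, combined = comb),
    per_residue = per, weights = weights), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy breakdown (kcal/mol):\n")
  print(round(x$total, 4))
  invisible(x)
}

#' Fit combination weights against experimental ddG values
#'
#' Finds weights in [0, 1]^3 maximizing the Pearson correlation between
#' predicted combined scores (`baseline + T w`) and experimental ddG. Since
#' correlation is scale-free, the optimum is a direction, not a point;
#' multiple L-BFGS-B starts (fixed seed) guard against local optima.
#'
#' @param terms numeric matrix with columns `transfer`, `lipid_field`,
#'   `dielec_excess`: per-data-point values of the three membrane terms.
#' @param ddg experimental ddG values (kcal/mol), one per row of `terms`.
#' @param baseline per-point baseline energies (default 0).
#' @param lower,upper weight bounds (default [0, 1]).
#' @param n_starts number of multi-starts (>= 8 recommended).
#' @param seed RNG seed for start points.
#' @return a [weight_set()] with attributes `correlation` and `starts`.
#' @export
fit_weights <- function(terms, ddg, baseline = 0,
                        lower = c(0, 0, 0), upper = c(1, 1, 1),
                        n_starts = 8, seed = 1) {
  terms <- as.matrix(terms)
  if (ncol(terms) != 3) stop("terms must have three columns")
  if (nrow(terms) != length(ddg)) stop("terms rows must match ddg length")
  if (nrow(terms) < 4) stop("need at least 4 data points")
  if (stats::sd(ddg) == 0) stop("experimental ddG is constant; correlation undefined")
  if (all(terms == 0)) stop("all term values are zero; weights unidentifiable")
  baseline <- rep_len(baseline, nrow(terms))
  obj <- function(w) {
    pred <- baseline + as.numeric(terms %*% w)
    if (stats::sd(pred) < 1e-12) return(1)
    -stats::cor(pred, ddg)
  }
  if (all(lower == upper)) {
    w <- lower
    out <- weight_set(w[1], w[2], w[3])
    attr(out, "correlation") <- -obj(w)
    attr(out, "starts") <- 0L
    return(out)
  }
  set.seed(seed)
  starts <- matrix(stats::runif(3 * n_starts, lower, upper), ncol = 3,
                   byrow = TRUE)
  best <- NULL
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      stats::optim(starts[k, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all weight-fit starts failed")
  out <- weight_set(best$par[1], best$par[2], best$par[3])
  attr(out, "correlation") <- -best$value
  attr(out, "starts") <- n_starts
  out
}
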