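# Rigid-body orientation sampling of peptides in the membrane frame:
# exhaustive (depth, tilt, rotation) grid search for the global energy
# minimum, insertion and mutation ddG protocols.

#' Orientation grid specification
#'
#' Default ranges: depth within +/-60 A of the bilayer center, tilt within
#' +/-180 deg of the membrane normal, axial rotation 0-360 deg; default
#' steps 2 A / 5 deg / 15 deg.
#'
#' @param d_range,d_step depth range (A) and step.
#' @param theta_range,theta_step tilt range (deg) and step.
#' @param phi_range,phi_step rotation range (deg) and step; the upper
#'   endpoint is treated as periodic (360 is not duplicated with 0).
#' @return object of class `orientation_grid`.
#' @export
orientation_grid <- function(d_range = c(-60, 60), d_step = 2,
                             theta_range = c(-180, 180), theta_step = 5,
                             phi_range = c(0, 360), phi_step = 15) {
  if (d_step <= 0 || theta_step <= 0 || phi_step <= 0)
    stop("grid steps must be positive")
  d <- seq(d_range[1], d_range[2], by = d_step)
  th <- seq(theta_range[1], theta_range[2], by = theta_step)
  ph <- seq(phi_range[1], phi_range[2], by = phi_step)
  if (length(ph) > 1 && (ph[length(ph)] - ph[1]) %% 360 == 0)
    ph <- ph[-length(ph)]
  if (!length(d) || !length(th) || !length(ph)) stop("empty grid")
  base::structure(list(d = d, theta = th, phi = ph),
                  class = "orientation_grid")
}

fold_tilt <- function(theta) {
  t <- abs(theta) %% 360
  t <- ifelse(t > 180, 360 - t, t)
  ifelse(t > 90, 180 - t, t)
}

# deterministic argmin: minimum energy, ties broken lexicographically on
# (|d|, folded tilt, phi, d, theta)
landscape_argmin <- function(df) {
  emin <- min(df$E)
  cand <- df[df$E <= emin, , drop = FALSE]
  o <- order(abs(cand$d), fold_tilt(cand$theta), cand$phi, cand$d,
             cand$theta)
  cand[o[1], , drop = FALSE]
}

#' Build a membrane scorer
#'
#' Bundles the combined-score inputs into a scorer usable by
#' [scan_orientations()] and the ddG protocols. The scanner exploits
#' rigid-body invariance: internal pair distances never change across
#' orientations, so the pair list is computed once per structure and only
#' atom depths (hence hydration and the lipid field) vary.
#'
#' @param profile a [lipid_profile_params()].
#' @param weights a [weight_set()].
#' @param atom_scale an `atom_scale`.
#' @param params a [dielectric_params()].
#' @param geometry a [membrane_geometry()].
#' @param baseline_scorer external soluble-protein scorer contract,
#'   function(structure) -> energy; default constant zero. Treated as
#'   orientation-independent during scans.
#' @return object of class `membrane_scorer` (also a callable
#'   function(structure) -> energy).
#' @export
membrane_scorer <- function(profile, weights = weight_set(),
                            atom_scale = default_atom_scale(),
                            params = dielectric_params(),
                            geometry = membrane_geometry(),
                            baseline_scorer = function(s) 0) {
  f <- function(structure) {
    unname(total_score(structure, weights, profile, atom_scale, params,
                       geometry, baseline_scorer = baseline_scorer
                       )$total["combined"])
  }
  base::structure(f, class = c("membrane_scorer", "function"),
                  profile = profile, weights = weights,
                  atom_scale = atom_scale, params = params,
                  geometry = geometry, baseline_scorer = baseline_scorer)
}

# static per-structure tables for the vectorized scan path
scan_statics <- function(structure, scorer) {
  atom_scale <- attr(scorer, "atom_scale")
  params <- attr(scorer, "params")
  at <- structure$atoms
  unknown <- setdiff(unique(at$type), names(atom_scale))
  if (length(unknown))
    stop("atom type(s) missing from scale: ", paste(unknown, collapse = ", "))
  pl <- pair_list(structure, params$r_max)
  st <- attr(scorer, "params")$sigmoid_steepness
  list(
    xyz = structure$xyz0 %*% t(structure$align),
    q = at$charge,
    g = as.numeric(atom_scale[at$type]),
    pl = pl,
    es = sigmoidal_dielectric(pl$r, params$eps_core_sol, params$eps_surf_sol, st),
    em = sigmoidal_dielectric(pl$r, params$eps_core_mem, params$eps_surf_mem, st),
    cc = params$C0 * at$charge[pl$i] * at$charge[pl$j] *
      (1 / pl$r - 1 / params$r_max),
    base = attr(scorer, "baseline_scorer")(structure)
  )
}

# energies of one structure at all depths for a fixed rotation:
# z_rot = rotated atom depths at d = 0
scan_depth_block <- function(z_rot, d, s, scorer) {
  geom <- attr(scorer, "geometry")
  w <- attr(scorer, "weights")
  profile <- attr(scorer, "profile")
  nd <- length(d)
  Z <- outer(d, z_rot, `+`)                       # nd x natom
  u <- (abs(Z) / geom$half_thickness)^geom$steepness
  Fh <- u / (1 + u)
  Fh[is.nan(Fh)] <- 1
  e_tr <- as.numeric((1 - Fh) %*% s$g)
  dPsi <- eval_profile(profile, as.numeric(Z))
  e_lip <- as.numeric(matrix(dPsi, nd) %*% s$q)
  e_die <- numeric(nd)
  if (nrow(s$pl)) {
    Fi <- Fh[, s$pl$i, drop = FALSE]
    Fj <- Fh[, s$pl$j, drop = FALSE]
    fp <- sqrt(Fi * Fj)
    np <- nrow(s$pl)
    esM <- matrix(s$es, nd, np, byrow = TRUE)
    emix <- fp * esM + (1 - fp) * matrix(s$em, nd, np, byrow = TRUE)
    e_die <- as.numeric((1 / emix - 1 / esM) %*% s$cc)
  }
  s$base + w$w_wl * e_tr + w$w_lipid * e_lip + w$w_dielec * e_die
}

#' Exhaustive orientation scan
#'
#' Evaluates the scorer over every (depth, tilt, rotation) grid point and
#' records the energy landscape and its global minimum, with a
#' deterministic tie-break (smallest |d|, then smallest folded tilt, then
#' smallest phi). A `membrane_scorer` is evaluated through a vectorized
#' path that reuses the internal pair list across all orientations; any
#' plain function(structure) -> energy is supported as a generic scorer.
#'
#' @param structure a `mem_structure`.
#' @param grid an [orientation_grid()].
#' @param scorer a [membrane_scorer()] or plain scoring function.
#' @return object of class `orientation_landscape`: list with `grid`
#'   (data.frame d, theta, phi, E), `argmin` (one-row data.frame) and
#'   `min_over_phi` (per-(d, theta) minimum for landscape plots).
#' @export
scan_orientations <- function(structure, grid, scorer) {
  stopifnot(inherits(structure, "mem_structure"),
            inherits(grid, "orientation_grid"))
  combos <- expand.grid(theta = grid$theta, phi = grid$phi,
                        KEEP.OUT.ATTRS = FALSE)
  nd <- length(grid$d)
  res <- vector("list", nrow(combos))
  if (inherits(scorer, "membrane_scorer")) {
    s <- scan_statics(structure, scorer)
    for (k in seq_len(nrow(combos))) {
      R <- rot_y(combos$theta[k]) %*% rot_z(combos$phi[k])
      z_rot <- as.numeric(s$xyz %*% R[3, ])
      E <- scan_depth_block(z_rot, grid$d, s, scorer)
      res[[k]] <- data.frame(d = grid$d, theta = combos$theta[k],
                             phi = combos$phi[k], E = E)
    }
  } else if (is.function(scorer)) {
    for (k in seq_len(nrow(combos))) {
      E <- numeric(nd)
      for (m in seq_len(nd)) {
        E[m] <- scorer(apply_orientation(structure, grid$d[m],
                                         combos$theta[k], combos$phi[k]))
      }
      res[[k]] <- data.frame(d = grid$d, theta = combos$theta[k],
                             phi = combos$phi[k], E = E)
    }
  } else stop("scorer must be a membrane_scorer or a function")
  df <- do.call(rbind, res)
  amin <- landscape_argmin(df)
  agg <- stats::aggregate(E ~ d + theta, data = df, FUN = min)
  base::structure(list(grid = df, argmin = amin, min_over_phi = agg),
                  class = "orientation_landscape")
}

#' @export
print.orientation_landscape <- function(x, ...) {
  a <- x$argmin
  cat(sprintf(
    "orientation landscape: %d grid points\n  minimum E = %.4f at d = %g A, theta = %g deg, phi = %g deg (tilt %g deg)\n",
    nrow(x$grid), a$E, a$d, a$theta, a$phi, fold_tilt(a$theta)))
  invisible(x)
}

#' Insertion free-energy difference
#'
#' Energy difference between the lowest-energy membrane-embedded
#' orientation and the lowest-energy aqueous placement:
#' `[G_lipid - G_ref] - [G_water - G_ref]`; the unfolded-state reference
#' `G_ref` cancels and is reported as zero for membrane-only scorers.
#' Membrane placements are grid points with `|d| < aqueous_depth`, aqueous
#' placements those with `|d| >= aqueous_depth`.
#'
#' @param structure a `mem_structure`.
#' @param scorer scorer as in [scan_orientations()].
#' @param grid an [orientation_grid()]; must reach `|d| >= aqueous_depth`.
#' @param aqueous_depth depth beyond which a placement counts as aqueous
#'   (default 40 A, the potential reference depth).
#' @return ddG of insertion (kcal/mol) with attributes `membrane` and
#'   `aqueous` (the two argmin records).
#' @export
ddg_insertion <- function(structure, scorer, grid = orientation_grid(),
                          aqueous_depth = 40) {
  land <- scan_orientations(structure, grid, scorer)
  df <- land$grid
  aq <- df[abs(df$d) >= aqueous_depth, , drop = FALSE]
  mem <- df[abs(df$d) < aqueous_depth, , drop = FALSE]
  if (!nrow(aq))
    stop("grid has no aqueous placements (|d| >= ", aqueous_depth, " A)")
  if (!nrow(mem)) stop("grid has no membrane placements")
  m1 <- landscape_argmin(mem)
  m2 <- landscape_argmin(aq)
  out <- m1$E - m2$E
  attr(out, "membrane") <- m1
  attr(out, "aqueous") <- m2
  attr(out, "G_ref") <- 0
  out
}

# rebuild the side chain of one residue from the internal-coordinate
# template, on the existing backbone, in template (xyz0) coordinates
swap_sidechain <- function(structure, position, code) {
  if (!code %in% unname(AA1)) stop("unknown residue code: ", code)
  at <- structure$atoms
  sel <- at$resno == position
  if (!any(sel)) stop("position ", position, " not in structure")
  res3 <- AA3[[code]]
  xyz <- structure$xyz0 %*% t(structure$align)
  bbnames <- c("N", "CA", "C", "O", "OXT")
  keep <- !sel | at$name %in% bbnames
  pos <- list()
  for (nm in intersect(bbnames, at$name[sel]))
    pos[[nm]] <- xyz[which(sel & at$name == nm)[1], ]
  if (!all(c("N", "CA", "C") %in% names(pos)))
    stop("residue ", position, " lacks backbone atoms for rebuilding")
  zm <- sidechain_zmat()
  zm <- zm[zm$res == res3, , drop = FALSE]
  newrows <- NULL
  if (nrow(zm)) {
    coords <- matrix(NA_real_, nrow(zm), 3)
    for (k in seq_len(nrow(zm))) {
      pos[[zm$name[k]]] <- place_atom(pos[[zm$a[k]]], pos[[zm$b[k]]],
                                      pos[[zm$c[k]]], zm$bond[k],
                                      zm$angle[k], zm$dihedral[k])
      coords[k, ] <- pos[[zm$name[k]]]
    }
    newrows <- data.frame(name = zm$name, elem = substr(zm$name, 1, 1),
                          resno = position, resid = res3,
                          x = coords[, 1], y = coords[, 2], z = coords[, 3],
                          charge = zm$charge, type = zm$type,
                          stringsAsFactors = FALSE)
  }
  kept <- at[keep, , drop = FALSE]
  kept[kept$resno == position, "resid"] <- res3
  kxyz <- xyz[keep, , drop = FALSE]
  kept$x <- kxyz[, 1]; kept$y <- kxyz[, 2]; kept$z <- kxyz[, 3]
  allrows <- rbind(kept, newrows)
  allrows <- allrows[order(allrows$resno), , drop = FALSE]
  seq1 <- strsplit(structure$sequence, "")[[1]]
  seq1[position] <- code
  out <- mem_structure(allrows, paste(seq1, collapse = ""))
  out
}

#' Point-mutation free-energy difference
#'
#' Change in water-to-bilayer folding free energy of a point mutant
#' relative to the native sequence, with fixed backbone and fixed membrane
#' orientation:
#' `[G_bilayer^mut - G_water^mut] - [G_bilayer^nat - G_water^nat]`.
#' Water-state energies are evaluated at a fully aqueous placement (the
#' structure translated so every atom sits beyond `aqueous_depth`). Both
#' native and mutant side chains at the position are rebuilt from the
#' internal-coordinate templates (no repacking), so mutating a residue to
#' itself gives exactly zero.
#'
#' @param structure a `mem_structure`; its current transform defines the
#'   fixed bilayer orientation.
#' @param position residue index to mutate.
#' @param mutant_code one-letter code of the mutant residue.
#' @param scorer scorer as in [scan_orientations()].
#' @param aqueous_depth minimum |z| of every atom in the water state
#'   (default 40 A).
#' @return ddG of mutation (kcal/mol).
#' @export
ddg_mutation <- function(structure, position, mutant_code, scorer,
                         aqueous_depth = 40) {
  tr <- structure$transform
  if (any(is.na(tr))) tr <- c(0, 0, 0)
  seq1 <- strsplit(structure$sequence, "")[[1]]
  if (position < 1 || position > length(seq1))
    stop("position out of range")
  nat <- swap_sidechain(structure, position, seq1[position])
  mut <- swap_sidechain(structure, position, mutant_code)
  score1 <- function(s) {
    if (inherits(scorer, "membrane_scorer") || is.function(scorer)) scorer(s)
    else stop("scorer must be callable")
  }
  place <- function(s, d) apply_orientation(s, d, tr[2], tr[3])
  d_aq <- aqueous_depth + max(abs(range(structure$xyz0))) + 1
  g_bil_nat <- score1(place(nat, tr[1]))
  g_bil_mut <- score1(place(mut, tr[1]))
  g_wat_nat <- score1(place(nat, d_aq))
  g_wat_mut <- score1(place(mut, d_aq))
  (g_bil_mut - g_wat_mut) - (g_bil_nat - g_wat_nat)
}
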