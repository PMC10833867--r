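# Membrane coordinate frame: hydration fraction as a depth proxy, pair
# hydration, and the lipid / interface / aqueous region classification.

#' Membrane geometry parameters
#'
#' The membrane frame is fixed: normal along +z, bilayer center at z = 0.
#'
#' @param half_thickness hydrophobic half-thickness in Angstrom (default 15).
#' @param steepness dimensionless exponent of the hydration transition
#'   (default 10); larger values sharpen the water/lipid boundary.
#' @return object of class `membrane_geometry`.
#' @export
membrane_geometry <- function(half_thickness = 15, steepness = 10) {
  if (half_thickness <= 0) stop("half_thickness must be positive")
  if (steepness <= 0) stop("steepness must be positive")
  structure(list(half_thickness = half_thickness, steepness = steepness),
            class = "membrane_geometry")
}

#' Per-atom hydration fraction
#'
#' Proxy of membrane depth: 0 for a lipid-exposed atom at the bilayer
#' center, 1 for an atom fully exposed to water, intermediate across the
#' head-group region. The depth dependence is a smooth monotone logistic in
#' normalized depth, `f = u^n / (1 + u^n)` with `u = |z|/half_thickness`
#' and `n = steepness`. Pore water raises hydration: the result is the
#' maximum of the depth-based value and `f_pore`.
#'
#' @param z depth(s) in Angstrom (vectorized).
#' @param geometry a [membrane_geometry()].
#' @param f_pore per-atom pore exposure in `[0, 1]` (scalar or vector).
#' @return hydration fraction(s) in `[0, 1]`.
#' @export
hydration_fraction <- function(z, geometry = membrane_geometry(), f_pore = 0) {
  if (any(f_pore < 0 | f_pore > 1)) stop("f_pore must lie in [0, 1]")
  u <- (abs(z) / geometry$half_thickness)^geometry$steepness
  f <- u / (1 + u)
  f[is.nan(f) | is.infinite(u)] <- 1   # overflow at extreme depth
  pmin(pmax(pmax(f, f_pore), 0), 1)
}

#' Pair hydration fraction
#'
#' Geometric mean of the two atoms' hydration fractions, used to mix the
#' solution and membrane dielectric responses for an atom pair.
#'
#' @param f_i,f_j hydration fractions in `[0, 1]` (vectorized).
#' @return `sqrt(f_i * f_j)`.
#' @export
pair_hydration <- function(f_i, f_j) {
  if (any(f_i < 0 | f_i > 1 | f_j < 0 | f_j > 1))
    stop("hydration fractions must lie in [0, 1]")
  sqrt(f_i * f_j)
}

#' Classify a position into membrane regions
#'
#' Region thresholds: lipid when `f_hyd < 0.25` and `f_pore < 0.5`;
#' interface when `0.25 <= f_hyd < 0.75` and `f_pore < 0.5`; everything
#' else aqueous (pore-facing positions are water-exposed). The mapping is
#' total on `[0, 1]^2`.
#'
#' @param f_hyd,f_pore values in `[0, 1]` (vectorized).
#' @return character vector with levels "lipid", "interface", "aqueous".
#' @export
classify_region <- function(f_hyd, f_pore = 0) {
  if (any(f_hyd < 0 | f_hyd > 1 | f_pore < 0 | f_pore > 1))
    stop("f_hyd and f_pore must lie in [0, 1]")
  n <- max(length(f_hyd), length(f_pore))
  f_hyd <- rep_len(f_hyd, n); f_pore <- rep_len(f_pore, n)
  out <- rep("aqueous", n)
  out[f_hyd < 0.25 & f_pore < 0.5] <- "lipid"
  out[f_hyd >= 0.25 & f_hyd < 0.75 & f_pore < 0.5] <- "interface"
  out
}

#' Per-atom hydration report for a structure
#'
#' @param structure a `mem_structure`.
#' @param geometry a [membrane_geometry()].
#' @param f_pore per-atom pore exposure (recycled).
#' @return data.frame with atom index, residue, z, f_hyd, f_pore, region.
#' @export
hydration_report <- function(structure, geometry = membrane_geometry(),
                             f_pore = 0) {
  at <- structure$atoms
  fp <- rep_len(f_pore, nrow(at))
  fh <- hydration_fraction(at$z, geometry, fp)
  data.frame(atom = seq_len(nrow(at)), name = at$name, resno = at$resno,
             resid = at$resid, z = at$z, f_hyd = fh, f_pore = fp,
             region = classify_region(fh, fp))
}
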