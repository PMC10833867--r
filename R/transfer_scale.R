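# Water-to-bilayer transfer energies: amino-acid scales, the MF vs WW
# linear fit used to extrapolate neutral-pH Asp/Glu (D-1, E-1), and the
# stoichiometry regression mapping amino-acid energies to atom-type
# energies.

#' Construct an amino-acid transfer-energy scale
#'
#' @param values named numeric vector, names are amino-acid codes (one
#'   letter; the deprotonated forms use codes "D-1" and "E-1").
#' @param label scale label, e.g. "MF", "WW" or "derived".
#' @return object of class `aa_scale` (a named numeric vector with a
#'   `label` attribute).
#' @export
aa_scale <- function(values, label = "derived") {
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("values must be uniquely named by amino-acid code")
  structure(as.numeric(values), names = names(values), label = label,
            class = "aa_scale")
}

#' Ordinary least-squares fit of one hydrophobicity scale on another
#'
#' Fits `mf = slope * ww + intercept` over the codes shared by both scales
#' and not excluded. Used to relate the bilayer-context (MF) scale to the
#' water-to-octanol (WW) scale, whose higher pH coverage permits
#' extrapolating the deprotonated Asp/Glu transfer energies.
#'
#' @param mf,ww `aa_scale` objects (response and predictor).
#' @param excluded character vector of codes to omit (e.g. the Ala host,
#'   Pro, and the low-pH Asp/Glu points).
#' @return list of class `linear_fit` with `slope`, `intercept`, `r2`,
#'   `codes` (those used) and `n`.
#' @export
fit_mf_vs_ww <- function(mf, ww, excluded = character()) {
  shared <- setdiff(intersect(names(mf), names(ww)), excluded)
  if (length(shared) < 3)
    stop("need at least 3 shared non-excluded codes to fit")
  x <- as.numeric(ww[shared]); y <- as.numeric(mf[shared])
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r2 <- if (stats::var(y) == 0 || stats::var(x) == 0) 1 else
    stats::cor(x, y)^2
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r2 = r2, codes = shared, n = length(shared)),
            class = "linear_fit")
}

#' Extrapolate a transfer energy along a fitted scale relation
#'
#' Maps a WW-scale value onto the MF scale through the fitted line;
#' used for the deprotonated Asp ("D-1") and Glu ("E-1") side chains whose
#' bilayer-context transfer energies cannot be measured at neutral pH.
#'
#' @param fit a `linear_fit` from [fit_mf_vs_ww()].
#' @param ww_value WW-scale value(s) to map.
#' @return extrapolated MF-scale value(s), kcal/mol.
#' @export
extrapolate_charged <- function(fit, ww_value) {
  stopifnot(inherits(fit, "linear_fit"))
  fit$slope * ww_value + fit$intercept
}

#' Construct an atom-type stoichiometry matrix
#'
#' Rows are amino-acid codes, columns atom-type labels, entries the
#' non-negative integer count of each atom type in the residue.
#'
#' @param counts numeric matrix with rownames (codes) and colnames (types).
#' @return object of class `stoichiometry_matrix`.
#' @export
stoichiometry_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry row (amino acid) and column (atom type) names")
  if (any(counts < 0)) stop("stoichiometry entries must be non-negative")
  if (any(rowSums(counts) == 0)) stop("every row needs at least one atom")
  structure(counts, class = c("stoichiometry_matrix", "matrix", "array"))
}

#' Solve for per-atom-type transfer energies
#'
#' Least-squares solution of `A x = g`, where `A` is the atom-type
#' stoichiometry matrix and `g` the amino-acid transfer energies; rows for
#' the deprotonated Asp/Glu can be appended to re-determine the carboxylate
#' atom types. Rank-deficient systems fall back to the minimum-norm
#' solution (Moore-Penrose) with a warning.
#'
#' @param A a [stoichiometry_matrix()] (rows must be named by codes present
#'   in `g_aa`).
#' @param g_aa an [aa_scale()] covering all rows of `A`.
#' @return object of class `atom_scale`: named numeric vector of atom-type
#'   energies with attributes `residuals` (per-row) and `rank_deficient`.
#' @export
solve_atom_transfer <- function(A, g_aa) {
  stopifnot(inherits(A, "stoichiometry_matrix"))
  if (nrow(A) == 0) stop("empty stoichiometry matrix")
  missing <- setdiff(rownames(A), names(g_aa))
  if (length(missing))
    stop("no transfer energy for: ", paste(missing, collapse = ", "))
  g <- as.numeric(g_aa[rownames(A)])
  M <- unclass(A)
  qrA <- qr(M)
  deficient <- qrA$rank < ncol(M)
  x <- if (deficient) {
    warning("stoichiometry matrix is rank deficient; returning the minimum-norm solution")
    as.numeric(MASS::ginv(M) %*% g)
  } else {
    as.numeric(qr.coef(qrA, g))
  }
  names(x) <- colnames(M)
  res <- g - as.numeric(M %*% x)
  names(res) <- rownames(M)
  structure(x, class = "atom_scale", residuals = res,
            rank_deficient = deficient)
}

#' Compose amino-acid energies from an atom scale
#'
#' Matrix-vector product `A x`: the per-residue transfer energy implied by
#' the atom-type energies; round-trips [solve_atom_transfer()] exactly for
#' consistent systems.
#'
#' @param A a [stoichiometry_matrix()].
#' @param atom an `atom_scale` (or named vector) covering all columns of `A`.
#' @return an [aa_scale()] labelled "derived".
#' @export
compose_aa_energy <- function(A, atom) {
  stopifnot(inherits(A, "stoichiometry_matrix"))
  missing <- setdiff(colnames(A), names(atom))
  if (length(missing))
    stop("atom scale missing type(s): ", paste(missing, collapse = ", "))
  g <- as.numeric(unclass(A) %*% as.numeric(atom[colnames(A)]))
  names(g) <- rownames(A)
  aa_scale(g, label = "derived")
}
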