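# Embedded chemical tables: amino-acid codes, side-chain internal-coordinate
# (z-matrix) templates with atom transfer types and partial charges, and the
# shipped hydrophobicity scales.
#
# Charges are a simplified heavy-atom fixed-charge set: hydrogen partial
# charges are aggregated onto their bonded heavy atom so that each residue
# sums to its formal charge. They are synthetic (not transcribed from any
# force field) and user-overridable via the charge-table reader.

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
AA3 <- stats::setNames(names(AA1), AA1)

#' Canonical amino-acid one-letter codes
#' @return character vector of the 20 one-letter codes.
#' @export
aa_codes <- function() unname(AA1)

# side-chain z-matrix rows: residue, atom, three reference atoms (a, b, c),
# bond length c-new (A), angle b-c-new (deg), dihedral a-b-c-new (deg),
# transfer type, partial charge (e). The first side-chain atom CB is placed
# off the backbone with an improper dihedral fixing chirality; chain atoms
# use extended default torsions with +/-120 deg branch offsets.
sidechain_zmat <- function() {
  txt <- "
res name a b c bond angle dihedral type charge
ALA CB N C CA 1.53 110.6 -122.6 CH3 0
SER CB N C CA 1.53 110.6 -122.6 CH2 0.25
SER OG N CA CB 1.417 110.8 180 OH -0.25
CYS CB N C CA 1.53 110.6 -122.6 CH2 0.10
CYS SG N CA CB 1.808 114.4 180 S -0.10
THR CB N C CA 1.53 110.6 -122.6 CH1 0.25
THR OG1 N CA CB 1.43 109.6 180 OH -0.25
THR CG2 N CA CB 1.52 110.5 -60 CH3 0
VAL CB N C CA 1.53 110.6 -122.6 CH1 0
VAL CG1 N CA CB 1.52 110.5 180 CH3 0
VAL CG2 N CA CB 1.52 110.5 60 CH3 0
LEU CB N C CA 1.53 110.6 -122.6 CH2 0
LEU CG N CA CB 1.53 116.3 180 CH1 0
LEU CD1 CA CB CG 1.52 110.7 180 CH3 0
LEU CD2 CA CB CG 1.52 110.7 60 CH3 0
ILE CB N C CA 1.53 110.6 -122.6 CH1 0
ILE CG1 N CA CB 1.53 110.4 180 CH2 0
ILE CG2 N CA CB 1.52 110.5 -60 CH3 0
ILE CD1 CA CB CG1 1.52 113.8 180 CH3 0
MET CB N C CA 1.53 110.6 -122.6 CH2 0
MET CG N CA CB 1.52 114.0 180 CH2 0.06
MET SD CA CB CG 1.803 112.7 180 S -0.12
MET CE CB CG SD 1.791 100.9 180 CH3 0.06
PRO CB N C CA 1.53 103.0 -120.0 CH2 0
PRO CG N CA CB 1.50 104.0 30 CH2 0
PRO CD CA CB CG 1.51 105.0 -35 CH2 0
PHE CB N C CA 1.53 110.6 -122.6 CH2 0
PHE CG N CA CB 1.50 113.8 180 aroC 0
PHE CD1 CA CB CG 1.39 120.8 90 aroC 0
PHE CD2 CA CB CG 1.39 120.8 -90 aroC 0
PHE CE1 CB CG CD1 1.39 120.8 180 aroC 0
PHE CE2 CB CG CD2 1.39 120.8 180 aroC 0
PHE CZ CG CD1 CE1 1.39 120.0 0 aroC 0
TYR CB N C CA 1.53 110.6 -122.6 CH2 0
TYR CG N CA CB 1.50 113.8 180 aroC 0
TYR CD1 CA CB CG 1.39 120.8 90 aroC 0
TYR CD2 CA CB CG 1.39 120.8 -90 aroC 0
TYR CE1 CB CG CD1 1.39 120.8 180 aroC 0
TYR CE2 CB CG CD2 1.39 120.8 180 aroC 0
TYR CZ CG CD1 CE1 1.39 120.0 0 aroC 0.25
TYR OH CD1 CE1 CZ 1.38 120.0 180 OH -0.25
TRP CB N C CA 1.53 110.6 -122.6 CH2 0
TRP CG N CA CB 1.50 113.8 180 aroC 0
TRP CD1 CA CB CG 1.37 126.9 90 aroC 0
TRP CD2 CA CB CG 1.43 126.7 -90 aroC 0
TRP NE1 CB CG CD1 1.38 110.2 180 Ntrp -0.05
TRP CE2 CB CG CD2 1.41 107.2 180 aroC 0.05
TRP CE3 CB CG CD2 1.40 133.9 0 aroC 0
TRP CZ2 CG CD2 CE2 1.40 122.4 180 aroC 0
TRP CZ3 CG CD2 CE3 1.39 118.8 180 aroC 0
TRP CH2 CD2 CE2 CZ2 1.37 117.5 0 aroC 0
ASP CB N C CA 1.53 110.6 -122.6 CH2 0
ASP CG N CA CB 1.52 112.6 180 COO 0.36
ASP OD1 CA CB CG 1.25 118.4 0 OOC -0.68
ASP OD2 CA CB CG 1.25 118.4 180 OOC -0.68
GLU CB N C CA 1.53 110.6 -122.6 CH2 0
GLU CG N CA CB 1.52 114.0 180 CH2 0
GLU CD CA CB CG 1.52 112.6 180 COO 0.36
GLU OE1 CB CG CD 1.25 118.4 0 OOC -0.68
GLU OE2 CB CG CD 1.25 118.4 180 OOC -0.68
ASN CB N C CA 1.53 110.6 -122.6 CH2 0
ASN CG N CA CB 1.52 112.6 180 CNH2 0.55
ASN OD1 CA CB CG 1.23 120.8 0 ONH2 -0.55
ASN ND2 CA CB CG 1.33 116.4 180 NH2O 0
GLN CB N C CA 1.53 110.6 -122.6 CH2 0
GLN CG N CA CB 1.52 114.0 180 CH2 0
GLN CD CA CB CG 1.52 112.6 180 CNH2 0.55
GLN OE1 CB CG CD 1.23 120.8 0 ONH2 -0.55
GLN NE2 CB CG CD 1.33 116.4 180 NH2O 0
LYS CB N C CA 1.53 110.6 -122.6 CH2 0
LYS CG N CA CB 1.52 114.0 180 CH2 0
LYS CD CA CB CG 1.52 111.3 180 CH2 0
LYS CE CB CG CD 1.52 111.3 180 CH2 0.25
LYS NZ CG CD CE 1.49 111.9 180 Nlys 0.75
ARG CB N C CA 1.53 110.6 -122.6 CH2 0
ARG CG N CA CB 1.52 114.0 180 CH2 0
ARG CD CA CB CG 1.52 111.3 180 CH2 0.10
ARG NE CB CG CD 1.46 112.0 180 Narg 0
ARG CZ CG CD NE 1.33 124.2 180 CNH2 0.40
ARG NH1 CD NE CZ 1.33 120.0 0 Narg 0.25
ARG NH2 CD NE CZ 1.33 120.0 180 Narg 0.25
HIS CB N C CA 1.53 110.6 -122.6 CH2 0
HIS CG N CA CB 1.49 113.8 180 aroC 0
HIS ND1 CA CB CG 1.38 122.7 90 Nhis -0.20
HIS CD2 CA CB CG 1.36 131.0 -90 aroC 0.20
HIS CE1 CB CG ND1 1.32 109.0 180 aroC 0
HIS NE2 CB CG CD2 1.37 107.0 180 Nhis 0
"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

# backbone heavy-atom charges and transfer types (neutral residue interior)
backbone_table <- function() {
  data.frame(name = c("N", "CA", "C", "O"),
             type = c("Nbb", "CAbb", "Cbb", "Obb"),
             charge = c(-0.30, 0.30, 0.50, -0.50),
             stringsAsFactors = FALSE)
}

#' Default per-atom charge and transfer-type table
#'
#' One row per (residue, atom) with the partial charge (e) and the atom
#' transfer type used by the water-to-bilayer scale. Covers the 20
#' canonical residues (backbone + side-chain heavy atoms) plus terminal
#' adjustments `NTERM:N`, `CTERM:C/O/OXT`.
#'
#' @return data.frame with columns res, name, type, charge.
#' @export
default_charge_table <- function() {
  bb <- backbone_table()
  rows <- do.call(rbind, lapply(names(AA1), function(res) {
    data.frame(res = res, name = bb$name, type = bb$type, charge = bb$charge,
               stringsAsFactors = FALSE)
  }))
  sc <- sidechain_zmat()
  rows <- rbind(rows, data.frame(res = sc$res, name = sc$name, type = sc$type,
                                 charge = sc$charge, stringsAsFactors = FALSE))
  # charged termini: protonated N (+1 aggregated) and carboxylate C-term
  rows <- rbind(rows,
    data.frame(res = "NTERM", name = "N", type = "Nlys", charge = 0.70,
               stringsAsFactors = FALSE),
    data.frame(res = "CTERM", name = c("C", "O", "OXT"),
               type = c("COO", "OOC", "OOC"),
               charge = c(0.34, -0.67, -0.67), stringsAsFactors = FALSE))
  rows
}

#' Shipped side-chain hydrophobicity scales
#'
#' Returns the water-to-octanol (WW) side-chain transfer energies
#' (kcal/mol) with neutral-form Asp/Glu under codes "D"/"E" and the
#' deprotonated forms under "D-1"/"E-1", plus an approximate bilayer-context
#' (MF-style) scale. The MF column is a placeholder constructed from the WW
#' scale through a linear relation with a higher slope, zeroed at the Ala
#' host; it is intended to be replaced by measured values via
#' [read_aa_scale()] when quantitative absolute energies matter.
#'
#' @return list with `ww` and `mf` ([aa_scale()] objects).
#' @export
default_scales <- function() {
  ww <- c(A = 0.50, R = 1.81, N = 0.85, D = 0.43, C = -0.02, Q = 0.77,
          E = 0.11, G = 1.15, H = 0.11, I = -1.12, L = -1.25, K = 2.80,
          M = -0.67, F = -1.71, P = 0.14, S = 0.46, T = 0.25, W = -2.09,
          Y = -0.71, V = -0.46, `D-1` = 3.64, `E-1` = 3.63)
  mf <- 1.6 * (ww[setdiff(names(ww), c("D-1", "E-1"))] - ww[["A"]])
  list(ww = aa_scale(ww, label = "WW"),
       mf = aa_scale(mf, label = "MF_approx"))
}

#' Default side-chain stoichiometry matrix
#'
#' Counts of each atom transfer type in the side chain of every canonical
#' residue except Gly (whose side chain has no heavy atom), with rows for
#' the deprotonated Asp/Glu ("D-1", "E-1") sharing the Asp/Glu
#' stoichiometry.
#'
#' @return a [stoichiometry_matrix()].
#' @export
default_stoichiometry <- function() {
  sc <- sidechain_zmat()
  types <- sort(unique(sc$type))
  codes <- setdiff(unname(AA1), "G")
  M <- t(vapply(codes, function(code) {
    res <- AA3[[code]]
    tab <- table(factor(sc$type[sc$res == res], levels = types))
    as.numeric(tab)
  }, numeric(length(types))))
  rownames(M) <- codes; colnames(M) <- types
  M <- rbind(M, `D-1` = M["D", ], `E-1` = M["E", ])
  stoichiometry_matrix(M)
}

#' Default derived atom-type transfer scale
#'
#' Builds the package's default per-atom-type water-to-bilayer transfer
#' energies: fits the MF-style scale on the WW scale (excluding the
#' low-pH-contaminated Asp/Glu points), extrapolates the deprotonated
#' Asp/Glu values from their WW counterparts, appends the corresponding
#' stoichiometry rows, and solves the least-squares system for atom types.
#' Backbone types (`Nbb`, `CAbb`, `Cbb`, `Obb`) carry zero since the
#' underlying scales are side-chain scales relative to an Ala host.
#'
#' @param excluded codes excluded from the MF-vs-WW fit (default the low-pH
#'   Asp/Glu measurements).
#' @return an `atom_scale` covering all template atom types.
#' @export
default_atom_scale <- function(excluded = c("D", "E")) {
  sc <- default_scales()
  fit <- fit_mf_vs_ww(sc$mf, sc$ww, excluded = excluded)
  g <- as.numeric(sc$mf)
  names(g) <- names(sc$mf)
  g[["D-1"]] <- extrapolate_charged(fit, sc$ww[["D-1"]])
  g[["E-1"]] <- extrapolate_charged(fit, sc$ww[["E-1"]])
  A <- default_stoichiometry()
  # the side-chain data determine some type pairs only in combination
  # (e.g. the carboxylate C and O always occur 1:2), so the documented
  # minimum-norm solution applies; the warning is expected here
  x <- suppressWarnings(solve_atom_transfer(A, aa_scale(g, label = "MF_extended")))
  full <- c(as.numeric(x), Nbb = 0, CAbb = 0, Cbb = 0, Obb = 0)
  names(full) <- c(names(x), "Nbb", "CAbb", "Cbb", "Obb")
  structure(full, class = "atom_scale",
            residuals = attr(x, "residuals"),
            fit = fit)
}
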