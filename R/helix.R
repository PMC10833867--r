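# Ideal alpha-helix construction from sequence (NeRF internal-coordinate
# chain), the structure container, and rigid-body placement in the
# membrane frame.

# --- small vector helpers -------------------------------------------------
vcross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
vnorm <- function(u) sqrt(sum(u^2))
vunit <- function(u) u / vnorm(u)

# natural extension reference frame: place a new atom bonded to c, with
# bond angle b-c-new and dihedral a-b-c-new (degrees)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  chi <- dihedral * pi / 180
  D <- bond * c(-cos(ang), sin(ang) * cos(chi), -sin(ang) * sin(chi))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  c + D[1] * bc + D[2] * m + D[3] * n
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

rot_z <- function(phi) {
  p <- phi * pi / 180
  matrix(c(cos(p), sin(p), 0, -sin(p), cos(p), 0, 0, 0, 1), 3, 3)
}
rot_y <- function(theta) {
  t <- theta * pi / 180
  matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
}

# rotation taking unit vector v onto unit vector w (Rodrigues)
rotation_between <- function(v, w) {
  v <- vunit(v); w <- vunit(w)
  cr <- vcross(v, w); s <- vnorm(cr); co <- sum(v * w)
  if (s < 1e-12) {
    if (co > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    ax <- if (abs(v[1]) < 0.9) vunit(vcross(v, c(1, 0, 0))) else
      vunit(vcross(v, c(0, 1, 0)))
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, cr[3], -cr[2], -cr[3], 0, cr[1], cr[2], -cr[1], 0), 3, 3)
  diag(3) + K + K %*% K * (1 - co) / s^2
}

#' Construct a structure object
#'
#' Container for an oriented peptide/protein: an atom table with
#' coordinates (Angstrom, membrane frame: +z = membrane normal, bilayer
#' center at z = 0), partial charges (e) and atom transfer types, plus the
#' rigid-body state used by the orientation sampler. `xyz0` holds the
#' centered template coordinates and `align` the rotation taking the
#' helix principal axis onto +z; the current coordinates are always
#' `T(d) R_y(theta) R_z(phi) align xyz0`.
#'
#' @param atoms data.frame with columns name, elem, resno, resid, x, y, z,
#'   charge, type.
#' @param sequence one-letter sequence string.
#' @return object of class `mem_structure`.
#' @export
mem_structure <- function(atoms, sequence) {
  need <- c("name", "elem", "resno", "resid", "x", "y", "z", "charge", "type")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (is.unsorted(atoms$resno)) stop("atoms must be grouped by residue")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xyz0 <- sweep(xyz, 2, ctr)
  ca <- xyz0[atoms$name == "CA", , drop = FALSE]
  axis <- principal_axis(ca)
  s <- structure(list(atoms = atoms, sequence = sequence,
                      xyz0 = xyz0, align = rotation_between(axis, c(0, 0, 1)),
                      transform = c(d = unname(ctr[3]), theta = NA_real_,
                                    phi = NA_real_)),
                 class = "mem_structure")
  s
}

principal_axis <- function(ca) {
  if (nrow(ca) < 2) return(c(0, 0, 1))
  cc <- sweep(ca, 2, colMeans(ca))
  v <- svd(cc, nu = 0, nv = 1)$v[, 1]
  # orient N- to C-terminal
  if (sum((ca[nrow(ca), ] - ca[1, ]) * v) < 0) v <- -v
  vunit(v)
}

#' @export
print.mem_structure <- function(x, ...) {
  cat(sprintf("mem_structure: %d residues, %d atoms\n",
              length(unique(x$atoms$resno)), nrow(x$atoms)))
  cat("  sequence:", x$sequence, "\n")
  tr <- x$transform
  cat(sprintf("  transform: d=%.2f A, theta=%s, phi=%s\n", tr[1],
              ifelse(is.na(tr[2]), "-", sprintf("%.1f deg", tr[2])),
              ifelse(is.na(tr[3]), "-", sprintf("%.1f deg", tr[3]))))
  invisible(x)
}

#' Build an ideal alpha-helical peptide from sequence
#'
#' Constructs backbone coordinates with ideal helical dihedrals
#' (phi = -57 deg, psi = -47 deg, omega = 180 deg) and standard bond
#' lengths/angles, adds carbonyl oxygens and side-chain heavy atoms from
#' internal-coordinate templates at a single default rotamer, assigns
#' partial charges and transfer types from the embedded charge table, and
#' aligns the helix principal axis with +z. Termini are charged by default
#' (protonated N-terminus, carboxylate C-terminus with OXT).
#'
#' @param sequence one-letter amino-acid string, length >= 3.
#' @param phi,psi backbone dihedrals in degrees.
#' @param charged_termini logical; `FALSE` builds neutral (uncapped but
#'   uncharged) ends.
#' @return a [mem_structure()] centered at the origin, axis along +z.
#' @export
build_ideal_helix <- function(sequence, phi = -57, psi = -47,
                              charged_termini = TRUE) {
  seq1 <- strsplit(sequence, "")[[1]]
  if (length(seq1) < 3)
    stop("sequence must have at least 3 residues for a helix")
  bad <- setdiff(seq1, unname(AA1))
  if (length(bad)) stop("unknown residue code(s): ",
                        paste(unique(bad), collapse = ", "))
  n <- length(seq1)
  sc <- sidechain_zmat()
  chg <- default_charge_table()
  # backbone trace
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  a <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  rows <- list()
  for (i in seq_len(n)) {
    res3 <- AA3[[seq1[i]]]
    pos <- list(N = N[i, ], CA = CA[i, ], C = C[i, ])
    pos$O <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.1, psi + 180)
    zm <- sc[sc$res == res3, , drop = FALSE]
    if (nrow(zm)) for (k in seq_len(nrow(zm))) {
      pos[[zm$name[k]]] <- place_atom(pos[[zm$a[k]]], pos[[zm$b[k]]],
                                      pos[[zm$c[k]]], zm$bond[k],
                                      zm$angle[k], zm$dihedral[k])
    }
    if (i == n && charged_termini)
      pos$OXT <- place_atom(N[i, ], CA[i, ], C[i, ], 1.25, 118, psi)
    nm <- names(pos)
    xyz <- do.call(rbind, pos)
    lut <- chg[chg$res == res3, ]
    typ <- lut$type[match(nm, lut$name)]
    q <- lut$charge[match(nm, lut$name)]
    if (charged_termini) {
      if (i == 1) {
        nt <- chg[chg$res == "NTERM", ]
        q[nm == "N"] <- nt$charge[nt$name == "N"]
        typ[nm == "N"] <- nt$type[nt$name == "N"]
      }
      if (i == n) {
        ct <- chg[chg$res == "CTERM", ]
        for (an in c("C", "O", "OXT")) {
          q[nm == an] <- ct$charge[ct$name == an]
          typ[nm == an] <- ct$type[ct$name == an]
        }
      }
    } else if (i == n) {
      # neutral end still needs typing for OXT if present (not built)
    }
    rows[[i]] <- data.frame(name = nm,
                            elem = substr(nm, 1, 1),
                            resno = i, resid = res3,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            charge = q, type = typ,
                            stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  s <- mem_structure(atoms, sequence)
  # canonicalize: template pre-aligned so align becomes identity
  s$xyz0 <- s$xyz0 %*% t(s$align)
  s$align <- diag(3)
  s$atoms[, c("x", "y", "z")] <- s$xyz0
  s$transform <- c(d = 0, theta = 0, phi = 0)
  s
}

#' Apply a rigid-body membrane orientation
#'
#' Places a structure at depth `d`, tilt `theta` and axial rotation `phi`:
#' the template is spun by `phi` about its helical axis, the axis is tilted
#' by `theta` from the membrane normal (+z), and the centroid is translated
#' to depth `d` on the z axis. Orientation parameters are absolute (the
#' template is first normalized to axis = +z), and the motion is exactly
#' rigid: all interatomic distances are preserved.
#'
#' @param structure a `mem_structure`.
#' @param d depth of the centroid in Angstrom.
#' @param theta tilt of the helix axis from the membrane normal, degrees.
#' @param phi rotation about the helix axis, degrees.
#' @return the structure with updated coordinates and transform.
#' @export
apply_orientation <- function(structure, d, theta, phi) {
  stopifnot(inherits(structure, "mem_structure"))
  R <- rot_y(theta) %*% rot_z(phi) %*% structure$align
  xyz <- structure$xyz0 %*% t(R)
  xyz[, 3] <- xyz[, 3] + d
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure$transform <- c(d = d, theta = theta, phi = phi)
  structure
}

#' Tilt angle of a structure's helical axis
#'
#' Angle between the principal helix axis and the membrane normal (+z),
#' folded into [0, 90] degrees (experimental convention; adsorbed,
#' surface-lying peptides report 90 degrees).
#'
#' @param structure a `mem_structure`.
#' @return tilt in degrees.
#' @export
tilt_angle <- function(structure) {
  ca <- as.matrix(structure$atoms[structure$atoms$name == "CA",
                                  c("x", "y", "z")])
  ax <- principal_axis(ca)
  ang <- acos(pmin(1, pmax(-1, abs(ax[3])))) * 180 / pi
  ang
}
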