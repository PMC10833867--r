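# Readers and writers: PDB structures (via bio3d) with sidecar charge
# tables, charge-density grids (voxel-list TSV and compact binary), profile
# parameter tables, amino-acid scales, stoichiometry tables, landscapes,
# and the JSON score report.

#' Write a structure as PDB plus a sidecar charge table
#'
#' PDB carries no full-precision charge column, so charges and transfer
#' types go to `<path>.charges.tsv` by default. Optionally the charge can
#' also be stored in the occupancy column (a lossy dialect, off by
#' default).
#'
#' @param structure a `mem_structure`.
#' @param path output PDB path.
#' @param sidecar logical; write the charge table (default TRUE).
#' @param occupancy_dialect logical; store charge in the occupancy column.
#' @return invisibly, the path(s) written.
#' @export
write_structure <- function(structure, path, sidecar = TRUE,
                            occupancy_dialect = FALSE) {
  at <- structure$atoms
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  occ <- if (occupancy_dialect) round(at$charge, 2) else rep(1, nrow(at))
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                   resid = at$resid, elety = at$name, o = occ,
                   b = rep(0, nrow(at)), chain = rep("A", nrow(at)))
  paths <- path
  if (sidecar) {
    sp <- paste0(path, ".charges.tsv")
    utils::write.table(
      data.frame(atom = seq_len(nrow(at)), resno = at$resno, name = at$name,
                 charge = at$charge, type = at$type),
      sp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, sp)
  }
  invisible(paths)
}

# element-based fallback typing for atoms absent from the template table
fallback_type <- function(elem) {
  c(C = "CH2", O = "OH", N = "NH2O", S = "S")[elem]
}

#' Read a structure from PDB
#'
#' Coordinates are interpreted in the membrane frame (+z = membrane
#' normal, bilayer center at z = 0; the convention of membrane-oriented
#' structure databases). Charges and transfer types come from the sidecar
#' table written by [write_structure()] when present, otherwise from the
#' embedded per-residue charge table; atoms missing from the templates get
#' a warning and element-based best-effort typing with zero charge.
#' Charged-terminus typing is applied when an OXT atom is present.
#'
#' @param path PDB file path.
#' @param charge_table optional data.frame (res, name, type, charge)
#'   overriding the embedded table.
#' @param center logical; re-center the centroid at the origin (default
#'   FALSE: input assumed pre-oriented).
#' @return a [mem_structure()].
#' @export
read_structure <- function(path, charge_table = NULL, center = FALSE) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  a <- a[!grepl("^H", a$elety) & a$elety != "H", , drop = FALSE]
  known <- names(AA3)[1]
  if (!all(a$resid %in% names(AA1)))
    stop("non-standard residues present: ",
         paste(setdiff(unique(a$resid), names(AA1)), collapse = ", "))
  atoms <- data.frame(name = a$elety, elem = substr(a$elety, 1, 1),
                      resno = match(paste(a$chain, a$resno),
                                    unique(paste(a$chain, a$resno))),
                      resid = a$resid, x = a$x, y = a$y, z = a$z,
                      charge = NA_real_, type = NA_character_,
                      stringsAsFactors = FALSE)
  sp <- paste0(path, ".charges.tsv")
  if (is.null(charge_table) && file.exists(sp)) {
    side <- utils::read.table(sp, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    atoms$charge <- side$charge
    atoms$type <- side$type
  } else {
    lut <- if (is.null(charge_table)) default_charge_table() else charge_table
    key <- paste(lut$res, lut$name)
    m <- match(paste(atoms$resid, atoms$name), key)
    atoms$charge <- lut$charge[m]
    atoms$type <- lut$type[m]
    has_oxt <- "OXT" %in% atoms$name
    if (has_oxt) {
      nt <- lut[lut$res == "NTERM", ]
      ct <- lut[lut$res == "CTERM", ]
      first <- atoms$resno == min(atoms$resno) & atoms$name == "N"
      if (nrow(nt)) {
        atoms$charge[first] <- nt$charge[nt$name == "N"]
        atoms$type[first] <- nt$type[nt$name == "N"]
      }
      last <- atoms$resno == max(atoms$resno)
      for (an in intersect(c("C", "O", "OXT"), atoms$name[last])) {
        i <- last & atoms$name == an
        atoms$charge[i] <- ct$charge[ct$name == an]
        atoms$type[i] <- ct$type[ct$name == an]
      }
    }
    miss <- is.na(atoms$type)
    if (any(miss)) {
      warning("no template entry for atom(s): ",
              paste(unique(paste(atoms$resid[miss], atoms$name[miss])),
                    collapse = ", "), "; using element-based typing")
      atoms$type[miss] <- fallback_type(atoms$elem[miss])
      atoms$charge[miss] <- 0
    }
  }
  seq1 <- vapply(split(atoms$resid, atoms$resno), function(r) AA1[[r[1]]], "")
  s <- mem_structure(atoms, paste(seq1[order(as.integer(names(seq1)))],
                                  collapse = ""))
  if (!center) {
    # keep original coordinates as current; template stays centered
    s$atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")]
  }
  s
}

#' Write a charge-density grid as a voxel-list TSV
#'
#' Header lines (prefixed `#`) carry the grid dims and spacing; the body is
#' tab-separated `ix iy iz rho_lipid rho_water rho_salt` with 0-based
#' indices, one voxel per row.
#'
#' @param grid a [charge_density_grid()].
#' @param path output path.
#' @export
write_density_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("# dims", paste(grid$dims, collapse = " ")),
    paste("# spacing", paste(format(grid$spacing, digits = 12), collapse = " ")),
    paste("# neutralize", as.integer(grid$neutralize)),
    "ix\tiy\tiz\trho_lipid\trho_water\trho_salt"), con)
  idx <- expand.grid(ix = seq_len(grid$dims[1]) - 1,
                     iy = seq_len(grid$dims[2]) - 1,
                     iz = seq_len(grid$dims[3]) - 1)
  df <- cbind(idx,
              rho_lipid = as.numeric(grid$density_lipid),
              rho_water = as.numeric(grid$density_water),
              rho_salt = as.numeric(grid$density_salt))
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a charge-density grid from voxel-list TSV
#' @param path file written by [write_density_grid()].
#' @return a [charge_density_grid()].
#' @export
read_density_grid <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key), hdr)][1]
    as.numeric(strsplit(sub(paste0("# ", key, " "), "", ln), " ")[[1]])
  }
  dims <- as.integer(getv("dims"))
  spacing <- getv("spacing")
  neut <- isTRUE(getv("neutralize") == 1)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", skip = length(hdr) + 1)
  names(df) <- c("ix", "iy", "iz", "rho_lipid", "rho_water", "rho_salt")
  o <- order(df$iz, df$iy, df$ix)
  mk <- function(v) array(v[o], dims)
  charge_density_grid(mk(df$rho_lipid), mk(df$rho_water), mk(df$rho_salt),
                      spacing = spacing, neutralize = neut,
                      charge_tol = Inf)
}

#' Write a charge-density grid in the compact binary format
#'
#' Four text header lines (magic, dims, spacing, neutralize flag) followed
#' by the three density arrays as little-endian doubles in column-major
#' (x-fastest) order: lipid, then water, then salt.
#'
#' @param grid a [charge_density_grid()].
#' @param path output path.
#' @export
write_density_grid_bin <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("MEMGRID1",
               paste(grid$dims, collapse = " "),
               paste(format(grid$spacing, digits = 17), collapse = " "),
               as.character(as.integer(grid$neutralize))), con)
  writeBin(as.numeric(grid$density_lipid), con, size = 8, endian = "little")
  writeBin(as.numeric(grid$density_water), con, size = 8, endian = "little")
  writeBin(as.numeric(grid$density_salt), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a compact binary charge-density grid
#' @param path file written by [write_density_grid_bin()].
#' @return a [charge_density_grid()].
#' @export
read_density_grid_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (magic != "MEMGRID1") stop("not a MEMGRID1 file")
  dims <- as.integer(strsplit(readLines(con, n = 1), " ")[[1]])
  spacing <- as.numeric(strsplit(readLines(con, n = 1), " ")[[1]])
  neut <- readLines(con, n = 1) == "1"
  nv <- prod(dims)
  rd <- function() array(readBin(con, "numeric", nv, size = 8,
                                 endian = "little"), dims)
  charge_density_grid(rd(), rd(), rd(), spacing = spacing,
                      neutralize = neut, charge_tol = Inf)
}

#' Write a lipid profile parameter table
#' @param params_list a `lipid_profile_params` or list of them.
#' @param path output TSV path.
#' @export
write_profile_table <- function(params_list, path) {
  if (inherits(params_list, "lipid_profile_params"))
    params_list <- list(params_list)
  df <- do.call(rbind, lapply(params_list, function(p)
    data.frame(lipid_name = p$lipid_name, A1 = p$A1, A2 = p$A2, A3 = p$A3,
               A4 = p$A4, C1 = p$C1, C2 = p$C2, C3 = p$C3, C4 = p$C4,
               C5 = p$C5, z_c = p$z_c, has_salt = as.integer(p$has_salt),
               reference_depth = p$reference_depth)))
  utils::write.table(format(df, digits = 12), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a lipid profile parameter table
#' @param path TSV with columns lipid_name, A1..A4, C1..C5, z_c, has_salt,
#'   reference_depth.
#' @param lipid optional name to select a single entry.
#' @return named list of [lipid_profile_params()] (or one object when
#'   `lipid` is given).
#' @export
read_profile_table <- function(path, lipid = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    lipid_profile_params(df$lipid_name[i], df$A1[i], df$A2[i], df$A3[i],
                         df$A4[i], df$C1[i], df$C2[i], df$C3[i], df$C4[i],
                         df$C5[i], df$z_c[i], as.logical(df$has_salt[i]),
                         df$reference_depth[i]))
  names(out) <- df$lipid_name
  if (!is.null(lipid)) {
    if (!lipid %in% names(out)) stop("no profile for lipid ", lipid)
    return(out[[lipid]])
  }
  out
}

#' Read/write amino-acid scales as TSV
#' @param path TSV with columns code, dg.
#' @param label scale label.
#' @return an [aa_scale()].
#' @export
read_aa_scale <- function(path, label = "file") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  aa_scale(stats::setNames(df$dg, df$code), label = label)
}

#' @rdname read_aa_scale
#' @param scale an [aa_scale()] to write.
#' @param provenance optional header comment lines (e.g. fit parameters).
#' @export
write_aa_scale <- function(scale, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste("#", provenance), con)
  writeLines(paste("# label:", attr(scale, "label")), con)
  writeLines("code\tdg", con)
  utils::write.table(data.frame(names(scale), as.numeric(scale)), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an energy breakdown as a JSON report and TSV ledger
#' @param breakdown an `energy_breakdown` from [total_score()].
#' @param json_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_score_report <- function(breakdown, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(list(total = as.list(breakdown$total),
                              per_residue = breakdown$per_residue,
                              weights = unclass(breakdown$weights)),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path))
    utils::write.table(breakdown$per_residue, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(json_path, tsv_path))
}

#' Write an orientation landscape as TSV (+ JSON argmin summary)
#' @param landscape an `orientation_landscape`.
#' @param tsv_path grid output path.
#' @param json_path optional argmin summary path.
#' @export
write_landscape <- function(landscape, tsv_path, json_path = NULL) {
  utils::write.table(landscape$grid, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(as.list(landscape$argmin), json_path,
                         auto_unbox = TRUE, digits = NA)
  invisible(tsv_path)
}

#' Write sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  writeLines(as.vector(rbind(paste0(">", names(sequences)), sequences)), path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  ln <- readLines(path)
  hd <- grep("^>", ln)
  ends <- c(hd[-1] - 1, length(ln))
  out <- vapply(seq_along(hd), function(i)
    paste(ln[(hd[i] + 1):ends[i]], collapse = ""), "")
  stats::setNames(out, sub("^>", "", ln[hd]))
  }

#' Assemble a configuration with validated keys
#'
#' Defaults equal the model's calibrated values: weights (1, 0.128, 0.01),
#' Coulomb truncation 5.5 A, dielectric pairs 6/80 (solution) and 3/10
#' (membrane), orientation grid +/-60 A, +/-180 deg, 0-360 deg.
#'
#' @param ... overrides for the keys `lipid`, `geometry`, `dielectric`,
#'   `weights`, `grid`, `charge_table`, `log_level`.
#' @param file optional JSON config file; keys are merged (call arguments
#'   win).
#' @return list of class `mem_config`.
#' @export
mem_config <- function(..., file = NULL) {
  defaults <- list(lipid = "DLPC", geometry = membrane_geometry(),
                   dielectric = dielectric_params(), weights = weight_set(),
                   grid = orientation_grid(), charge_table = NULL,
                   log_level = "info")
  overrides <- list(...)
  if (!is.null(file)) {
    fromfile <- jsonlite::read_json(file, simplifyVector = TRUE)
    overrides <- utils::modifyList(fromfile, overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base::structure(utils::modifyList(defaults, overrides),
                  class = "mem_config")
}
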