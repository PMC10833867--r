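# Synthetic fixtures: model peptide sequences, two-slab Gaussian bilayer
# charge densities (with optional anionic head groups and adsorbed
# counter-ion layers), design sequence pairs and ddG tables. Everything is
# deterministic given a seed, so every module is testable without
# downloads.

#' Model peptide sequences
#'
#' Generates the standard fixture sequences: polyalanine `A...A`; WALP
#' peptides `GWW(LA)_nLWWA` (Trp-anchored Leu/Ala core); poly-leucines
#' `G L_x R L_x G`; and the Trp-flanked variant `GW L_6 R L_7 G`.
#'
#' @param kind one of "polyala", "walp", "polyleu", "gwl".
#' @param n residue count for "polyala"; the (LA) repeat count for "walp";
#'   the leucine run length x for "polyleu" (ignored for "gwl").
#' @return sequence string.
#' @export
fixture_sequence <- function(kind = c("polyala", "walp", "polyleu", "gwl"),
                             n = 8) {
  kind <- match.arg(kind)
  if (kind != "gwl" && (n < 1 || n != round(n)))
    stop("n must be a positive integer")
  switch(kind,
    polyala = strrep("A", n),
    walp = paste0("GWW", strrep("LA", n), "LWWA"),
    polyleu = paste0("G", strrep("L", n), "R", strrep("L", n), "G"),
    gwl = paste0("GW", strrep("L", 6), "R", strrep("L", 7), "G"))
}

#' Synthetic bilayer charge-density grid
#'
#' Emulates the laterally averaged charge structure of an empty
#' bilayer-water system as mirrored Gaussian slabs: a zwitterionic
#' head-group dipole (positive layer at `z_plus`, negative at `z_minus` in
#' each leaflet), an optional extra anionic head-group charge (PG-like,
#' compensated by a uniform neutralizing background, as for a bare charged
#' bilayer), and an optional adsorbed counter-ion layer just outside the
#' head groups that partially or fully cancels the anionic charge
#' (screening, as in a salt solution).
#'
#' @param dims grid dimensions (default 4 x 4 x 120).
#' @param spacing grid spacing in Angstrom (default 1).
#' @param dipole_sigma surface charge density of each dipole layer (e/A^2).
#' @param z_plus,z_minus depths (A) of the positive and negative dipole
#'   layers.
#' @param head_charge extra anionic head-group surface density (e/A^2,
#'   >= 0; subtracted at `z_minus`).
#' @param salt logical; add a counter-ion layer of `+salt_fraction *
#'   head_charge` at `z_salt`.
#' @param salt_fraction fraction of the anionic charge cancelled (default 1).
#' @param z_salt counter-ion layer depth (default 20.5 A).
#' @param layer_width Gaussian width of all layers (A).
#' @return a [charge_density_grid()] (neutralizing background enabled when
#'   `head_charge > 0` and salt does not fully compensate).
#' @export
fixture_density_grid <- function(dims = c(4, 4, 120), spacing = 1,
                                 dipole_sigma = 0.001,
                                 z_plus = 15, z_minus = 18,
                                 head_charge = 0, salt = FALSE,
                                 salt_fraction = 1, z_salt = 20.5,
                                 layer_width = 1.5) {
  nz <- dims[3]
  hz <- rep_len(spacing, 3)[3]
  z <- (seq_len(nz) - 1 - (nz - 1) / 2) * hz
  gauss <- function(c0) exp(-(abs(z) - c0)^2 / (2 * layer_width^2)) /
    (sqrt(2 * pi) * layer_width)
  lip <- dipole_sigma * (gauss(z_plus) - gauss(z_minus)) -
    head_charge * gauss(z_minus)
  salt_d <- if (salt) salt_fraction * head_charge * gauss(z_salt) else 0 * z
  expand <- function(v) array(rep(v, each = dims[1] * dims[2]), dims)
  residual <- head_charge * (1 - if (salt) salt_fraction else 0)
  charge_density_grid(expand(lip), density_salt = expand(salt_d),
                      spacing = spacing,
                      neutralize = residual > 0, charge_tol = 1e-7)
}

# per-lipid fixture settings: head-group dipole strength scales with
# head-group charge density (PE > PC), tail length shifts the layer depths,
# PG adds anionic charge screened by counter-ions
lipid_fixture_settings <- function(lipid) {
  tab <- list(
    DLPC = list(dipole_sigma = 0.0010, z_plus = 15.0, z_minus = 18.0,
                head_charge = 0, salt = FALSE),
    DLPE = list(dipole_sigma = 0.0013, z_plus = 14.5, z_minus = 17.0,
                head_charge = 0, salt = FALSE),
    DLPG = list(dipole_sigma = 0.0008, z_plus = 15.0, z_minus = 18.0,
                head_charge = 0.0008, salt = TRUE, salt_fraction = 0.9),
    DPPC = list(dipole_sigma = 0.0010, z_plus = 17.0, z_minus = 20.0,
                head_charge = 0, salt = FALSE),
    DOPC = list(dipole_sigma = 0.0010, z_plus = 18.0, z_minus = 21.0,
                head_charge = 0, salt = FALSE),
    POPC = list(dipole_sigma = 0.0010, z_plus = 17.5, z_minus = 20.5,
                head_charge = 0, salt = FALSE),
    DMPC = list(dipole_sigma = 0.0010, z_plus = 16.0, z_minus = 19.0,
                head_charge = 0, salt = FALSE))
  if (!lipid %in% names(tab)) stop("no fixture settings for lipid ", lipid)
  tab[[lipid]]
}

.profile_cache <- new.env(parent = emptyenv())

#' Default lipid potential profiles (fixture-fit placeholders)
#'
#' Profile parameters for the named lipids, fit from the synthetic
#' two-slab fixture densities via the full solve/average/fit pipeline.
#' These are placeholders standing in for parameters fit from all-atom
#' simulation densities; load measured parameters with
#' [read_profile_table()] when quantitative lipid-specific potentials
#' matter. Results are cached per session.
#'
#' @param lipid lipid name (DLPC, DLPE, DLPG, DPPC, DOPC, POPC, DMPC).
#' @return a [lipid_profile_params()].
#' @export
default_lipid_profile <- function(lipid = "DLPC") {
  if (!is.null(.profile_cache[[lipid]])) return(.profile_cache[[lipid]])
  st <- lipid_fixture_settings(lipid)
  grid <- do.call(fixture_density_grid, st)
  pot <- solve_poisson(grid)
  prof <- lateral_average(pot, grid$spacing, reference_depth = 40)
  params <- fit_profile(prof, lipid_name = lipid,
                        has_salt = isTRUE(st$salt))
  .profile_cache[[lipid]] <- params
  params
}

#' Synthetic design sequence pairs
#'
#' Native sequences drawn uniformly from the 20 canonical amino acids;
#' designed sequences copy the native residue with probability `recovery`
#' and otherwise draw a uniform non-native residue. Optional random region
#' labels exercise region stratification.
#'
#' @param n_pairs number of backbone pairs.
#' @param len residue count per sequence (recycled).
#' @param recovery target per-position recovery probability.
#' @param regions logical; attach random region labels.
#' @param seed RNG seed.
#' @return a [sequence_pair_set()].
#' @export
fixture_design_pairs <- function(n_pairs = 10, len = 50, recovery = 0.3,
                                 regions = TRUE, seed = 1) {
  set.seed(seed)
  len <- rep_len(len, n_pairs)
  codes <- aa_codes()
  nat <- vapply(len, function(l)
    paste(sample(codes, l, replace = TRUE), collapse = ""), "")
  des <- vapply(seq_len(n_pairs), function(i) {
    nt <- strsplit(nat[i], "")[[1]]
    keep <- stats::runif(len[i]) < recovery
    sub <- vapply(nt, function(r) sample(setdiff(codes, r), 1), "")
    paste(ifelse(keep, nt, sub), collapse = "")
  }, "")
  reg <- if (regions) lapply(len, function(l)
    sample(c("lipid", "interface", "aqueous"), l, replace = TRUE))
  sequence_pair_set(nat, des, regions = reg)
}

#' Synthetic ddG table for weight fitting
#'
#' Independent random term vectors (transfer, lipid-field, dielectric) and
#' experimental ddG values generated as their weighted combination plus
#' optional noise.
#'
#' @param n number of data points.
#' @param weights generating [weight_set()] (default the calibrated
#'   weights 1, 0.128, 0.01).
#' @param noise_sd additive Gaussian noise on the ddG (kcal/mol).
#' @param seed RNG seed.
#' @return data.frame with columns transfer, lipid_field, dielec_excess,
#'   ddg_exp.
#' @export
fixture_ddg_table <- function(n = 20, weights = weight_set(),
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  terms <- cbind(transfer = stats::rnorm(n, sd = 2),
                 lipid_field = stats::rnorm(n, sd = 5),
                 dielec_excess = stats::rnorm(n, sd = 20))
  ddg <- as.numeric(terms %*% c(weights$w_wl, weights$w_lipid,
                                weights$w_dielec)) +
    stats::rnorm(n, sd = noise_sd)
  data.frame(terms, ddg_exp = ddg)
}

#' Write fixtures to disk
#'
#' Deterministic for a given seed; dispatches on `kind` and writes the
#' corresponding files under `dir`.
#'
#' @param kind one of "polyala", "walp", "polyleu", "density-grid",
#'   "design-pairs", "ddg-table".
#' @param dir output directory (created if needed).
#' @param seed RNG seed for stochastic fixtures.
#' @param ... parameters forwarded to the underlying generator
#'   ([fixture_sequence()], [fixture_density_grid()],
#'   [fixture_design_pairs()], [fixture_ddg_table()]).
#' @return character vector of paths written.
#' @export
make_fixture <- function(kind, dir = ".", seed = 1, ...) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  args <- list(...)
  switch(kind,
    polyala = , walp = , polyleu = {
      sq <- do.call(fixture_sequence, c(list(kind = kind), args))
      s <- build_ideal_helix(sq)
      p <- file.path(dir, paste0(kind, "_", nchar(sq), ".pdb"))
      write_structure(s, p)
      fp <- file.path(dir, paste0(kind, "_", nchar(sq), ".fasta"))
      write_fasta(stats::setNames(sq, paste0(kind, nchar(sq))), fp)
      c(p, paste0(p, ".charges.tsv"), fp)
    },
    `density-grid` = {
      grid <- do.call(fixture_density_grid, args)
      p <- file.path(dir, "density_grid.tsv")
      write_density_grid(grid, p)
      p
    },
    `design-pairs` = {
      pairs <- do.call(fixture_design_pairs, c(args, list(seed = seed)))
      natp <- file.path(dir, "native.fasta")
      desp <- file.path(dir, "designed.fasta")
      nm <- sprintf("bb%03d", seq_along(pairs$native))
      write_fasta(stats::setNames(vapply(pairs$native, paste, "",
                                         collapse = ""),
                                  paste0(nm, "_nat")), natp)
      write_fasta(stats::setNames(vapply(pairs$designed, paste, "",
                                         collapse = ""),
                                  paste0(nm, "_des")), desp)
      paths <- c(natp, desp)
      if (!is.null(pairs$regions)) {
        rp <- file.path(dir, "regions.tsv")
        df <- data.frame(
          backbone = rep(nm, lengths(pairs$regions)),
          position = unlist(lapply(lengths(pairs$regions), seq_len)),
          region = unlist(pairs$regions))
        utils::write.table(df, rp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, rp)
      }
      paths
    },
    `ddg-table` = {
      df <- do.call(fixture_ddg_table, c(args, list(seed = seed)))
      p <- file.path(dir, "ddg_table.tsv")
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    },
    stop("unknown fixture kind: ", kind))
}
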