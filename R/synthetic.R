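# Synthetic labeled protein-ligand complexes: a pseudo-protein shell of
# single-atom residues enclosing a cavity around a pseudo-ligand, with a
# class-specific atom-type lining planted in a spherical cap so the energy
# channels (not the pocket shape) carry the class signal.

# SYBYL type -> (residue name, atom name, element) used when emitting atoms
.type_atoms <- data.frame(
  sybyl = c("C.3", "C.2", "C.ar", "N.am", "N.pl3", "N.4", "N.ar",
            "O.2", "O.3", "O.co2", "S.3"),
  resid = c("ALA", "ALA", "PHE", "ALA", "ARG", "LYS", "HIS",
            "ALA", "SER", "ASP", "MET"),
  elety = c("CB", "C", "CZ", "N", "NH1", "NZ", "ND1",
            "O", "OG", "OD1", "SD"),
  elesy = c("C", "C", "C", "N", "N", "N", "N", "O", "O", "O", "S"),
  stringsAsFactors = FALSE)

#' Specification of the synthetic-complex generator
#'
#' Defines the study conditions for the synthetic benchmark: three pocket
#' classes whose lining atoms differ only in SYBYL-type composition within a
#' spherical cap (the planted discriminative region), over a shared
#' background mixture, so energy channels are informative while the shape
#' is not.  Each default cap is a single atom type absent from the
#' background (amide nitrogen, aromatic carbon, or thioether sulfur), which
#' keeps the cap the only class-specific evidence in the complex.
#'
#' @param n_per_class Pockets generated per class.
#' @param classes Named list of cap mixtures (named probabilities over SYBYL
#'   types, each summing to 1).
#' @param background Background lining mixture shared by all classes; it
#'   deliberately contains only generic carbon types so that every class cap
#'   introduces atom types absent from the rest of the lining, keeping the
#'   planted region the (only) class-specific evidence.
#' @param cavity_radius Range (min, max) of cavity radii, Angstrom.
#' @param shell_thickness Radial thickness of the atom shell, Angstrom.
#' @param n_shell_atoms Range of shell atom counts.
#' @param n_ligand_atoms Pseudo-ligand heavy-atom count.
#' @param cap_half_angle Half-angle of the planted cap, radians.
#' @param jitter_sd Positional jitter, Angstrom.
#' @param seed Base seed; every complex derives its own stream from
#'   (seed, class, index).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 20,
                           classes = list(
                             polar = c(N.am = 1.0),
                             aromatic = c(C.ar = 1.0),
                             sulfur = c(S.3 = 1.0)),
                           background = c(C.3 = 0.6, C.2 = 0.4),
                           cavity_radius = c(6, 10),
                           shell_thickness = 3,
                           n_shell_atoms = c(200, 300),
                           n_ligand_atoms = 20,
                           cap_half_angle = 1.05,
                           jitter_sd = 0.3,
                           seed = 1) {
  for (m in c(classes, list(background)))
    if (abs(sum(m) - 1) > 1e-9) stopf("class mixtures must sum to 1")
  if (min(cavity_radius) <= 2)
    stopf("cavity radius must exceed the excluded-volume cutoff")
  structure(list(n_per_class = n_per_class, classes = classes,
                 background = background, cavity_radius = cavity_radius,
                 shell_thickness = shell_thickness,
                 n_shell_atoms = n_shell_atoms,
                 n_ligand_atoms = n_ligand_atoms,
                 cap_half_angle = cap_half_angle,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @noRd
complex_seed <- function(spec, class_idx, index) {
  (spec$seed * 97L + class_idx * 7919L + index * 104729L) %% 2147483629L
}

#' Generate one synthetic protein-ligand complex
#'
#' A shell of 200-300 single-atom pseudo-residues (chain A) encloses a
#' cavity of radius 6-10 Angstrom around a 20-atom pseudo-ligand (HETATM
#' residue LIG, chain L) at the origin.  Shell atoms inside the planted cap
#' (+z direction in the generation frame) draw their SYBYL type from the
#' class mixture; the rest draw from the shared background.  Deterministic
#' (byte-identical PDB) for a fixed (seed, class, index).
#'
#' @param spec A [synthetic_spec()].
#' @param class_label Name of one of `spec$classes`.
#' @param index Complex index within the class.
#' @return List with `pdb` (character vector of PDB lines), `label`,
#'   `planted_resno` (residue numbers of cap atoms), `cavity_radius` and
#'   `seed`.
#' @export
make_complex <- function(spec, class_label, index) {
  ci <- match(class_label, names(spec$classes))
  if (is.na(ci)) stopf("unknown class '%s'", class_label)
  if (spec$shell_thickness <= 0)
    stopf("cavity radius must be smaller than the shell radius")
  seed <- complex_seed(spec, ci, index)
  set.seed(seed)

  rcav <- runif(1, spec$cavity_radius[1], spec$cavity_radius[2])
  nsh <- sample(seq(spec$n_shell_atoms[1], spec$n_shell_atoms[2]), 1)

  u <- matrix(rnorm(3 * nsh), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- rcav + runif(nsh, 0, spec$shell_thickness)
  pos <- u * rad + matrix(rnorm(3 * nsh, 0, spec$jitter_sd), ncol = 3)

  in_cap <- u[, 3] > cos(spec$cap_half_angle)
  mix_cap <- spec$classes[[ci]]
  mix_bg <- spec$background
  types <- character(nsh)
  types[in_cap] <- sample(names(mix_cap), sum(in_cap), replace = TRUE,
                          prob = mix_cap)
  types[!in_cap] <- sample(names(mix_bg), sum(!in_cap), replace = TRUE,
                           prob = mix_bg)
  ta <- .type_atoms[match(types, .type_atoms$sybyl), ]
  if (anyNA(ta$resid)) stopf("mixture names must be SYBYL codes from the supported set")

  # ligand fills the cavity (uniform in a ball ~3.5 A short of the lining),
  # so the 5 A binding-residue shell is always populated
  nl <- spec$n_ligand_atoms
  rl <- max(rcav - 3.5, 2)
  ul <- matrix(rnorm(3 * nl), ncol = 3)
  ul <- ul / sqrt(rowSums(ul^2))
  lig <- ul * rl * runif(nl)^(1 / 3)

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  bio3d::write.pdb(pdb = NULL, file = tf,
                   xyz = as.numeric(t(rbind(pos, lig))),
                   type = c(rep("ATOM", nsh), rep("HETATM", nl)),
                   resno = c(seq_len(nsh), rep(900L, nl)),
                   resid = c(ta$resid, rep("LIG", nl)),
                   eleno = seq_len(nsh + nl),
                   elety = c(ta$elety, paste0("C", seq_len(nl))),
                   chain = c(rep("A", nsh), rep("L", nl)),
                   o = rep(1, nsh + nl), b = rep(0, nsh + nl),
                   elesy = c(ta$elesy, rep("C", nl)))
  list(pdb = readLines(tf), label = class_label,
       planted_resno = which(in_cap), cavity_radius = rcav, seed = seed)
}

#' Deterministic toy pairwise potential
#'
#' A 14-probe x 14-protein-type potential over the distance bins 0-4, 4-8
#' and 8-14.5 Angstrom with a distinct nonzero energy for every
#' (probe, protein type, bin) triple, so different lining-type compositions
#' produce separable channel statistics.  Magnitudes decay steeply with the
#' distance bin (1 : 0.2 : 0.05), as interaction potentials do; without the
#' decay the outermost bin - which holds the most atoms - would dominate
#' every channel with the pocket's global composition and no grid point
#' would carry localized information about its own neighborhood.
#'
#' @return A `pair_potential`.
#' @export
toy_potential <- function() {
  types <- sybyl_probe_types()
  n <- length(types)
  edges <- c(0, 4, 8, 14.5)
  decay <- c(1, 0.2, 0.05)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n), b = 1:3)
  e <- round(1.5 * sin(2.1 * idx$i + 1.3 * idx$j + idx$b) +
               0.8 * cos(0.9 * idx$i - 0.7 * idx$j + 0.4 * idx$b), 3)
  e[abs(e) < 0.01] <- 0.01
  e <- e * decay[idx$b]
  pair_potential(types, types, edges, array(e, c(n, n, 3)))
}

#' Run the full pipeline over a generated dataset
#'
#' Generates `n_per_class` complexes per class, runs parse / SYBYL typing /
#' pocket carving / energy channels / canonical orientation / voxelization
#' on each, writes the tensors to `dir` and returns (and writes) a manifest
#' compatible with [crossvalidate()].
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param potential A `pair_potential` (default [toy_potential()]).
#' @param side Voxel side (default 32).
#' @param occupancy Also write 2-channel occupancy tensors.
#' @return The manifest data frame (`id`, `voxel_path`, `occupancy_path`
#'   if requested, `label`, `group`, `planted`), written to
#'   `dir/manifest.csv`.
#' @export
make_dataset <- function(spec, dir, potential = toy_potential(), side = 32,
                         occupancy = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (cl in names(spec$classes)) {
    for (i in seq_len(spec$n_per_class)) {
      id <- sprintf("%s_%03d", cl, i)
      res <- tryCatch({
        cx <- make_complex(spec, cl, i)
        parsed <- parse_structure(cx$pdb)
        prot <- assign_sybyl_types(parsed$structure)
        lig <- select_ligand(parsed, "LIG")
        grid <- carve_pocket(prot, lig)
        br <- binding_residues(prot, lig, cutoff = 5)
        frame <- principal_axes(br, lig$center)
        eg <- canonicalize(energy_channels(grid, prot, potential), frame)
        vt <- to_voxels(eg, side = side)
        vpath <- file.path(dir, paste0(id, ".rds"))
        write_voxels(vt, vpath)
        opath <- NA_character_
        if (occupancy) {
          opath <- file.path(dir, paste0(id, "_occ.rds"))
          write_voxels(to_occupancy(grid, frame, side = side), opath)
        }
        data.frame(id = id, voxel_path = vpath, occupancy_path = opath,
                   label = cl, group = sprintf("G%d", 1 + (i - 1) %% 2),
                   planted = paste(cx$planted_resno, collapse = ";"),
                   stringsAsFactors = FALSE)
      }, error = function(e) stopf("complex %s: %s", id, conditionMessage(e)))
      rows[[length(rows) + 1]] <- res
    }
  }
  manifest <- do.call(rbind, rows)
  if (!occupancy) manifest$occupancy_path <- NULL
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
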