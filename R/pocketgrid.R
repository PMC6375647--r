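#' Build a ligand-centered spherical grid
#'
#' Lattice points `center + spacing * v` for integer vectors `v` with
#' `|spacing * v| <= radius`.  Points are stored in lexicographic
#' (z, y, x) order with x varying fastest, for reproducibility.
#'
#' @param center Numeric 3-vector (Angstrom), usually the ligand geometric
#'   center.
#' @param radius Sphere radius in Angstrom (default 15).
#' @param spacing Lattice spacing in Angstrom (default 1).
#' @return A `pocket_grid`: list with `points` (n x 3 matrix), `center`,
#'   `radius`, `spacing` and a `removal_log` of per-step removed counts.
#' @export
build_sphere_grid <- function(center, radius = 15, spacing = 1) {
  stopifnot(radius > 0, spacing > 0)
  if (radius < spacing) stopf("radius (%g) smaller than spacing (%g)", radius, spacing)
  r <- floor(radius / spacing)
  ax <- seq(-r, r)
  v <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  v <- v[rowSums(v^2) * spacing^2 <= radius^2, , drop = FALSE]
  pts <- sweep(v * spacing, 2, as.numeric(center), "+")
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(list(points = pts, center = as.numeric(center), radius = radius,
                 spacing = spacing,
                 removal_log = c(sphere = nrow(pts))),
            class = "pocket_grid")
}

#' @export
print.pocket_grid <- function(x, ...) {
  cat(sprintf("pocket_grid: %d points (radius %g, spacing %g)\n",
              nrow(x$points), x$radius, x$spacing))
  if (length(x$removal_log) > 1) {
    cat("  refinement:", paste(names(x$removal_log), x$removal_log,
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Remove excluded-volume grid points
#'
#' Drops every grid point within `cutoff` of any protein heavy atom
#' (distance `<= cutoff` removed, strictly greater retained).
#'
#' @param grid A `pocket_grid`.
#' @param protein A `typed_structure`.
#' @param cutoff Exclusion distance in Angstrom (default 2).
#' @return The filtered `pocket_grid` with `removal_log` updated.
#' @export
remove_excluded_volume <- function(grid, protein, cutoff = 2) {
  stopifnot(inherits(grid, "pocket_grid"), nrow(protein$atoms) > 0)
  keep <- min_dist_to_atoms(grid$points, coords_matrix(protein$atoms)) > cutoff
  grid$removal_log <- c(grid$removal_log, excluded_volume = sum(!keep))
  grid$points <- grid$points[keep, , drop = FALSE]
  grid
}

# min distance from each point to any atom, chunked to bound memory
#' @noRd
min_dist_to_atoms <- function(pts, atoms, chunk = 4000L) {
  n <- nrow(pts)
  out <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    out[s:e] <- apply(cross_dist(pts[s:e, , drop = FALSE], atoms), 1, min)
  }
  out
}

#' Clip grid points to the protein envelope
#'
#' Removes grid points sticking out of the protein into bulk solvent.  The
#' default `"hull"` mode keeps points inside the convex hull of the protein
#' heavy-atom centers (boundary counts as inside); `"envelope"` mode keeps
#' points within `r_env` of any protein atom.  A degenerate (coplanar)
#' protein makes hull mode fall back to envelope mode with a warning.
#'
#' @param grid A `pocket_grid`.
#' @param protein A `typed_structure`.
#' @param mode `"hull"` or `"envelope"`.
#' @param r_env Envelope radius in Angstrom (default 4), used in envelope mode.
#' @return The filtered `pocket_grid` with `removal_log` updated.
#' @export
clip_to_envelope <- function(grid, protein, mode = c("hull", "envelope"),
                             r_env = 4) {
  mode <- match.arg(mode)
  atoms <- coords_matrix(protein$atoms)
  if (mode == "hull") {
    hull <- .hull_facets(atoms)
    if (!isTRUE(hull$ok)) {
      warning("protein degenerate for convex hull; falling back to envelope mode",
              call. = FALSE)
      mode <- "envelope"
    } else {
      tol <- 1e-9 * max(1, max(abs(atoms)))
      s <- grid$points %*% t(hull$normals)
      keep <- rowSums(sweep(s, 2, hull$offsets + tol, ">")) == 0
    }
  }
  if (mode == "envelope")
    keep <- min_dist_to_atoms(grid$points, atoms) <= r_env
  grid$removal_log <- c(grid$removal_log, clip = sum(!keep))
  grid$points <- grid$points[keep, , drop = FALSE]
  grid
}

#' @noRd
lattice_codes <- function(grid) {
  v <- round(sweep(grid$points, 2, grid$center) / grid$spacing)
  r <- floor(grid$radius / grid$spacing) + 2L
  b <- 2L * r + 3L
  off <- v + r
  as.integer(off[, 1] + b * off[, 2] + b * b * off[, 3])
}

#' Keep the largest connected component of the grid
#'
#' Lattice adjacency at the grid spacing, with face (6) or face+edge+corner
#' (26) connectivity.  If several components tie for the largest size, the
#' one containing the point closest to the grid center wins, then the
#' first in component order.
#'
#' @param grid A `pocket_grid`.
#' @param connectivity 6 or 26.
#' @return The filtered `pocket_grid` with `removal_log` updated.
#' @export
largest_component <- function(grid, connectivity = 6) {
  stopifnot(connectivity %in% c(6, 26))
  n <- nrow(grid$points)
  if (n == 0) stopf("pocket vanished during refinement")

  codes <- lattice_codes(grid)
  r <- floor(grid$radius / grid$spacing) + 2L
  b <- 2L * r + 3L
  if (connectivity == 6) {
    offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  } else {
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  }
  doffs <- as.integer(offs[, 1] + b * offs[, 2] + b * b * offs[, 3])

  comp <- integer(n)  # 0 = unvisited
  ncomp <- 0L
  for (seed in seq_len(n)) {
    if (comp[seed] > 0) next
    ncomp <- ncomp + 1L
    frontier <- seed
    comp[seed] <- ncomp
    while (length(frontier) > 0) {
      nb <- match(rep(codes[frontier], each = length(doffs)) +
                    rep(doffs, length(frontier)), codes)
      nb <- unique(nb[!is.na(nb)])
      nb <- nb[comp[nb] == 0]
      comp[nb] <- ncomp
      frontier <- nb
    }
  }

  sizes <- tabulate(comp, nbins = ncomp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    d2 <- rowSums(sweep(grid$points, 2, grid$center)^2)
    mind <- vapply(best, function(k) min(d2[comp == k]), numeric(1))
    best <- best[which.min(mind)]
  } else best <- best[1]

  keep <- comp == best
  grid$removal_log <- c(grid$removal_log, disconnected = sum(!keep))
  grid$points <- grid$points[keep, , drop = FALSE]
  grid
}

#' Carve a refined binding-pocket grid from a complex
#'
#' Composition of [build_sphere_grid()], [remove_excluded_volume()],
#' [clip_to_envelope()] and [largest_component()], in that order.
#'
#' @param protein A `typed_structure`.
#' @param ligand A `ligand` from [select_ligand()] (its geometric center
#'   seeds the grid).
#' @param radius,spacing Sphere grid geometry (Angstrom).
#' @param ev_cutoff Excluded-volume cutoff (Angstrom).
#' @param clip_mode `"hull"` or `"envelope"` (see [clip_to_envelope()]).
#' @param r_env Envelope radius for envelope mode.
#' @param connectivity Lattice connectivity for the component step.
#' @return The refined, connected `pocket_grid`.
#' @export
carve_pocket <- function(protein, ligand, radius = 15, spacing = 1,
                         ev_cutoff = 2, clip_mode = "hull", r_env = 4,
                         connectivity = 6) {
  g <- build_sphere_grid(ligand$center, radius = radius, spacing = spacing)
  g <- remove_excluded_volume(g, protein, cutoff = ev_cutoff)
  g <- clip_to_envelope(g, protein, mode = clip_mode, r_env = r_env)
  if (nrow(g$points) == 0) stopf("pocket vanished during refinement")
  largest_component(g, connectivity = connectivity)
}

#' Dump grid points as pseudo-atoms for visualization
#'
#' Writes HETATM records (residue GRD, helium pseudo-atoms) with an optional
#' per-point value in the B-factor column, e.g. CAM values.
#'
#' @param points n x 3 coordinate matrix.
#' @param file Output PDB path.
#' @param values Optional numeric vector written to the B-factor column.
#' @return The file path, invisibly.
#' @export
write_grid_pdb <- function(points, file, values = NULL) {
  n <- nrow(points)
  b <- if (is.null(values)) rep(0, n) else as.numeric(values)
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.numeric(t(points)),
                   type = rep("HETATM", n), resno = seq_len(n),
                   resid = rep("GRD", n), eleno = seq_len(n),
                   elety = rep("HE", n), chain = rep("G", n),
                   o = rep(1, n), b = b, elesy = rep("HE", n))
  invisible(file)
}
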