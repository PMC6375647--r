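#' Canonical frame from binding-residue principal axes
#'
#' The rotation rows are the unit eigenvectors of the covariance of the
#' binding-residue heavy-atom coordinates, ordered by descending eigenvalue,
#' so the longest, middle and shortest principal axes align with x, y and z.
#' The eigenvector sign ambiguity is fixed by requiring the third central
#' moment (skewness) of the binding-atom coordinates along x and along y to
#' be non-negative; z is then chosen as the cross product so the frame is
#' right-handed (determinant +1).
#'
#' @param binding A `residue_set` from [binding_residues()].
#' @param center The pocket grid center (ligand geometric center); mapped to
#'   the origin by the frame.
#' @return A `canonical_frame`: list with `rotation` (3 x 3, rows are the
#'   axes), `center`, and `axis_lengths` (descending eigenvalues).
#' @export
principal_axes <- function(binding, center) {
  a <- coords_matrix(binding$atoms)
  if (nrow(a) < 3) stopf("axes undefined: need at least 3 binding atoms")
  cv <- cov(a)
  eg <- eigen(cv, symmetric = TRUE)
  tol <- 1e-10 * max(1, eg$values[1])
  if (eg$values[2] <= tol)
    stopf("axes undefined: binding atoms are collinear or degenerate")

  ctr <- colMeans(a)
  ac <- sweep(a, 2, ctr)
  v1 <- eg$vectors[, 1]; v2 <- eg$vectors[, 2]
  if (mean((ac %*% v1)^3) < 0) v1 <- -v1
  if (mean((ac %*% v2)^3) < 0) v2 <- -v2
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  rot <- unname(rbind(v1, v2, v3))
  structure(list(rotation = rot, center = as.numeric(center),
                 axis_lengths = eg$values),
            class = "canonical_frame")
}

#' Identity frame centered at a point
#' @param center 3-vector mapped to the origin.
#' @return A `canonical_frame` with identity rotation.
#' @export
identity_frame <- function(center = c(0, 0, 0)) {
  structure(list(rotation = diag(3), center = as.numeric(center),
                 axis_lengths = rep(NA_real_, 3)),
            class = "canonical_frame")
}

#' @noRd
transform_points <- function(pts, frame) {
  sweep(pts, 2, frame$center) %*% t(frame$rotation)
}

#' Rotate an energy grid into its canonical frame
#'
#' Replaces every grid point `p` by `rotation (p - center)`; the energy
#' channels are untouched.  Point norms are preserved, so every transformed
#' point stays within the grid radius.
#'
#' @param egrid An `energy_grid`.
#' @param frame A `canonical_frame`.
#' @return The transformed `energy_grid` with the frame attached.
#' @export
canonicalize <- function(egrid, frame) {
  pts <- transform_points(egrid$grid$points, frame)
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  egrid$grid$points <- pts
  egrid$grid$center <- c(0, 0, 0)
  egrid$frame <- frame
  egrid
}

#' Transform a structure into a canonical frame
#'
#' Applies the same rigid transform as [canonicalize()] to atom coordinates,
#' so structures and grids can be compared in the same frame (as the CAM
#' residue mapping requires).
#'
#' @param structure A `typed_structure`.
#' @param frame A `canonical_frame`.
#' @return The transformed `typed_structure` (frame recorded in `$frame`).
#' @export
transform_structure <- function(structure, frame) {
  pts <- transform_points(coords_matrix(structure$atoms), frame)
  structure$atoms$x <- pts[, 1]
  structure$atoms$y <- pts[, 2]
  structure$atoms$z <- pts[, 3]
  structure$frame <- frame
  structure
}

#' @noRd
voxel_indices <- function(pts, side) {
  if (any(pts < -side / 2) || any(pts >= side / 2))
    stopf("coordinates outside [-%g, %g): increase the voxel side", side / 2, side / 2)
  idx <- floor(pts) + side / 2 + 1  # 1-based per-axis indices
  as.integer(idx[, 1] + side * (idx[, 2] - 1) + side^2 * (idx[, 3] - 1))
}

#' Discretize a canonicalized energy grid into a voxel tensor
#'
#' Each grid point falls into the half-open unit cell
#' `[floor(coord), floor(coord) + 1)` along every axis after shifting by
#' half the side; when several grid points land in the same voxel their
#' channel vectors are averaged.  Voxels with no contributing point are
#' exactly zero.
#'
#' @param egrid A canonicalized `energy_grid` (see [canonicalize()]).
#' @param side Voxels per side (default 32).
#' @return A `voxel_tensor`: list with `values` (side^3 x channels array),
#'   `channel_labels`, `frame`, `side`, `grid_points` (canonical
#'   coordinates), `voxel_index` (per grid point, linear), and `counts`
#'   (contributing points per occupied voxel).
#' @export
to_voxels <- function(egrid, side = 32) {
  pts <- egrid$grid$points
  ch <- egrid$channels
  lin <- voxel_indices(pts, side)
  sums <- rowsum(ch, lin)                 # rows sorted by unique lin
  counts <- as.vector(rowsum(rep(1, length(lin)), lin))
  ulin <- as.integer(rownames(sums))
  nc <- ncol(ch)

  values <- array(0, dim = c(side, side, side, nc))
  for (c_ in seq_len(nc))
    values[ulin + (c_ - 1L) * side^3] <- sums[, c_] / counts

  structure(list(values = values, channel_labels = egrid$channel_labels,
                 frame = egrid$frame %||% identity_frame(),
                 side = side, grid_points = pts, voxel_index = lin,
                 counts = setNames(counts, ulin)),
            class = "voxel_tensor")
}

#' Binary occupancy tensor (shape-only baseline)
#'
#' Two one-hot channels: `occupied` is 1 where at least one grid point maps
#' into the voxel, `empty` is its complement, so the channels sum to one at
#' every voxel.
#'
#' @param grid A `pocket_grid`.
#' @param frame A `canonical_frame` (use [principal_axes()] or
#'   [identity_frame()]).
#' @param side Voxels per side (default 32).
#' @return A 2-channel `voxel_tensor`.
#' @export
to_occupancy <- function(grid, frame, side = 32) {
  pts <- transform_points(grid$points, frame)
  lin <- if (nrow(pts) > 0) voxel_indices(pts, side) else integer(0)
  occ <- array(0, dim = c(side, side, side))
  occ[unique(lin)] <- 1
  values <- array(0, dim = c(side, side, side, 2))
  values[, , , 1] <- occ
  values[, , , 2] <- 1 - occ
  counts <- if (length(lin)) table(lin) else integer(0)
  structure(list(values = values, channel_labels = c("occupied", "empty"),
                 frame = frame, side = side, grid_points = pts,
                 voxel_index = lin,
                 counts = setNames(as.vector(counts), names(counts))),
            class = "voxel_tensor")
}

#' @export
print.voxel_tensor <- function(x, ...) {
  cat(sprintf("voxel_tensor: %d^3 x %d channels, %d occupied voxels\n",
              x$side, dim(x$values)[4], length(x$counts)))
  invisible(x)
}

#' Save / load voxel tensors
#'
#' The default container is RDS (lossless for all fields).  With
#' `format = "h5"` (requires the rhdf5 package) the tensor is written as an
#' HDF5 file with datasets `values`, `channel_labels`, `rotation`, `center`,
#' `grid_points` and `voxel_index`.
#'
#' @param x A `voxel_tensor`.
#' @param path Output path.
#' @param format `"rds"` or `"h5"`.
#' @return `path`, invisibly (`write_voxels`); a `voxel_tensor`
#'   (`read_voxels`).
#' @export
write_voxels <- function(x, path, format = c("rds", "h5")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(x, path)
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stopf("format 'h5' requires the rhdf5 package")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(x$values, path, "values")
    rhdf5::h5write(x$channel_labels, path, "channel_labels")
    rhdf5::h5write(x$frame$rotation, path, "rotation")
    rhdf5::h5write(x$frame$center, path, "center")
    rhdf5::h5write(x$grid_points, path, "grid_points")
    rhdf5::h5write(x$voxel_index, path, "voxel_index")
    rhdf5::h5closeAll()
  }
  invisible(path)
}

#' @rdname write_voxels
#' @export
read_voxels <- function(path, format = c("rds", "h5")) {
  format <- match.arg(format)
  if (format == "rds") return(readRDS(path))
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stopf("format 'h5' requires the rhdf5 package")
  vals <- rhdf5::h5read(path, "values")
  lin <- as.integer(rhdf5::h5read(path, "voxel_index"))
  frame <- structure(list(rotation = rhdf5::h5read(path, "rotation"),
                          center = as.numeric(rhdf5::h5read(path, "center")),
                          axis_lengths = rep(NA_real_, 3)),
                     class = "canonical_frame")
  rhdf5::h5closeAll()
  structure(list(values = vals,
                 channel_labels = as.character(rhdf5::h5read(path, "channel_labels")),
                 frame = frame, side = dim(vals)[1],
                 grid_points = rhdf5::h5read(path, "grid_points"),
                 voxel_index = lin,
                 counts = setNames(as.vector(table(lin)),
                                   names(table(lin)))),
            class = "voxel_tensor")
}
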