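#' Voxel class-activation map
#'
#' Computes the spatial evidence the network holds for one class.  The
#' default, gradient-weighted method weights the second convolution's
#' feature maps by the global average of the class-score gradient over each
#' map, which reduces to the plain global-average-pooling CAM when the model
#' head is GAP + linear (`head = "gap"` in [network_config()]); for that
#' head `method = "cam"` uses the classifier weights directly.  The weighted
#' sum is rectified at zero and trilinearly upsampled from the feature-map
#' side back to the voxel side.
#'
#' @param model A trained `pocket_cnn`.
#' @param x A `voxel_tensor` (or bare array) matching the model input.
#' @param class_index Target class (integer index or class label).
#' @param method `"grad"` (default) or `"cam"` (GAP head only).
#' @return A `cam_volume`: list with `values` (side^3 array), `class_index`,
#'   `class_label`, `method`.
#' @export
activation_map <- function(model, x, class_index, method = c("grad", "cam")) {
  method <- match.arg(method)
  if (is.character(class_index)) {
    ci <- match(class_index, model$class_levels)
    if (is.na(ci)) stopf("unknown class '%s'", class_index)
    class_index <- ci
  }
  if (class_index < 1 || class_index > model$cfg$classes)
    stopf("class index %d out of range 1..%d", class_index, model$cfg$classes)

  v <- tensor_values(x)
  fw <- network_forward(model, v, train = FALSE, cache = TRUE)
  fmaps <- fw$cache$l2                       # (m, m, m, F) feature maps
  nf <- dim(fmaps)[4]

  if (method == "cam") {
    if (model$cfg$head != "gap")
      stopf("plain CAM requires a GAP + linear head; use method = 'grad'")
    w <- model$params$W3[, class_index]
  } else {
    gl <- numeric(model$cfg$classes)
    gl[class_index] <- 1                     # d(logit_class)/d(logits)
    g <- network_backward(model, fw$cache, gl, to_conv2 = TRUE)
    w <- apply(g$conv2_activation, 4, mean)  # global-average pooled gradients
  }

  cam <- array(0, dim(fmaps)[1:3])
  for (k in seq_len(nf)) cam <- cam + w[k] * fmaps[, , , k]
  cam[cam < 0] <- 0
  side <- if (inherits(x, "voxel_tensor")) x$side else dim(v)[1]
  cam <- upsample_trilinear(cam, side)

  structure(list(values = cam, class_index = class_index,
                 class_label = model$class_levels[class_index] %||% class_index,
                 method = method),
            class = "cam_volume")
}

# Trilinear interpolation of a cubic array onto `side` cells per axis,
# sampling at cell centers (the half-pixel convention).
#' @noRd
upsample_trilinear <- function(a, side) {
  m <- dim(a)[1]
  if (m == side) return(a)
  pos <- (seq_len(side) - 0.5) * m / side + 0.5  # position in source index space
  lo <- pmin(pmax(floor(pos), 1), m)
  hi <- pmin(lo + 1, m)
  fr <- pmin(pmax(pos - lo, 0), 1)
  out <- array(0, c(side, side, side))
  for (dz in 0:1) {
    iz <- if (dz == 0) lo else hi
    wz <- if (dz == 0) 1 - fr else fr
    for (dy in 0:1) {
      iy <- if (dy == 0) lo else hi
      wy <- if (dy == 0) 1 - fr else fr
      for (dx in 0:1) {
        ix <- if (dx == 0) lo else hi
        wx <- if (dx == 0) 1 - fr else fr
        w <- outer(outer(wx, wy), wz)
        out <- out + array(a[cbind(rep(ix, side^2),
                                   rep(rep(iy, each = side), side),
                                   rep(iz, each = side^2))],
                           c(side, side, side)) * w
      }
    }
  }
  out
}

#' Select pocket grid points in the top CAM fraction
#'
#' The retention threshold is the CAM value of the `ceiling(fraction * n)`-th
#' largest voxel over all voxels of the volume; grid points whose containing
#' voxel reaches the threshold are retained (ties at the threshold are all
#' kept).  With the default 1 percent on a 32-per-side volume this keeps 328
#' voxels.
#'
#' @param cam A `cam_volume`.
#' @param tensor The `voxel_tensor` the CAM was computed for (provides the
#'   grid-point-to-voxel map).
#' @param fraction Fraction of voxels to retain (default 0.01).
#' @return A data frame with the selected points' canonical coordinates
#'   (`x`, `y`, `z`), their `point` index into the pocket grid, their
#'   `voxel` linear index and the voxel's `cam` value.  Zero rows (with a
#'   warning) when the CAM is identically zero.
#' @export
select_top <- function(cam, tensor, fraction = 0.01) {
  stopifnot(fraction > 0, fraction <= 1)
  v <- as.vector(cam$values)
  if (all(v == 0)) {
    warning("CAM is identically zero; empty selection", call. = FALSE)
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      point = integer(), voxel = integer(), cam = numeric()))
  }
  m <- ceiling(fraction * length(v))
  thr <- sort(v, decreasing = TRUE)[m]
  sel_vox <- which(v >= thr)
  keep <- tensor$voxel_index %in% sel_vox
  pts <- tensor$grid_points[keep, , drop = FALSE]
  out <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    point = which(keep), voxel = tensor$voxel_index[keep],
                    cam = v[tensor$voxel_index[keep]])
  attr(out, "frame") <- tensor$frame
  out
}

#' Aggregate selected CAM points to residue-level scores
#'
#' Each selected grid point is mapped to the residue of its nearest protein
#' heavy atom, provided that distance is within `cutoff`; more distant
#' points are counted as unassigned.  A residue's CAM-score is the sum of
#' the CAM values of its points.  Nearest-atom ties are broken by the
#' lowest residue number, then the chain identifier.
#'
#' @param selected Data frame from [select_top()].
#' @param structure A `typed_structure` transformed into the same canonical
#'   frame as the grid points (see [transform_structure()]).
#' @param cutoff Point-to-atom assignment distance, Angstrom (default 5).
#' @return A `residue_scores` object: data frame `scores` (chain, resno,
#'   insert, resid, cam_score, n_points) sorted by decreasing score, plus
#'   `unassigned` (count) and `unassigned_value` (their CAM sum).
#' @export
residue_scores <- function(selected, structure, cutoff = 5.0) {
  atoms <- structure$atoms
  frame_grid <- attr(selected, "frame")
  if (!is.null(frame_grid) && !is.null(structure$frame) &&
      max(abs(frame_grid$rotation - structure$frame$rotation)) > 1e-9)
    stopf("selected points and structure are in different frames")
  if (nrow(selected) == 0) {
    return(structure(list(scores = data.frame(), unassigned = 0L,
                          unassigned_value = 0), class = "residue_scores"))
  }
  d <- cross_dist(as.matrix(selected[, c("x", "y", "z")]),
                  coords_matrix(atoms))
  # nearest atom, ties by lowest residue number then chain id
  ord <- order(atoms$resno, atoms$chain)
  nearest <- apply(d[, ord, drop = FALSE], 1, which.min)
  nearest <- ord[nearest]
  nd <- d[cbind(seq_len(nrow(d)), nearest)]
  assigned <- nd <= cutoff

  scores <- data.frame()
  if (any(assigned)) {
    key <- residue_key(atoms[nearest[assigned], ])
    agg <- rowsum(cbind(cam = selected$cam[assigned], n = 1), key)
    info <- atoms[nearest[assigned], ][!duplicated(key), ]
    info <- info[match(rownames(agg), residue_key(info)), ]
    scores <- data.frame(chain = info$chain, resno = info$resno,
                         insert = info$insert, resid = info$resid,
                         cam_score = agg[, "cam"], n_points = agg[, "n"],
                         row.names = NULL)
    scores <- scores[order(-scores$cam_score), , drop = FALSE]
    rownames(scores) <- NULL
  }
  structure(list(scores = scores, unassigned = sum(!assigned),
                 unassigned_value = sum(selected$cam[!assigned])),
            class = "residue_scores")
}

#' @export
print.residue_scores <- function(x, ...) {
  cat(sprintf("residue_scores: %d residues scored, %d point(s) unassigned\n",
              nrow(x$scores), x$unassigned))
  if (nrow(x$scores)) print(head(x$scores, 10))
  invisible(x)
}

#' Write residue CAM-scores as CSV
#'
#' @param rs A `residue_scores` object.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_residue_scores <- function(rs, path) {
  write.csv(rs$scores, path, row.names = FALSE)
  invisible(path)
}
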