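# Shared fixtures, built once per test run and cached.

# internal helpers used throughout the tests
coords_matrix <- pocketvox:::coords_matrix
residue_key <- pocketvox:::residue_key
`%||%` <- pocketvox:::`%||%`

.fx <- new.env(parent = emptyenv())

fx_cached <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# one parsed + typed synthetic complex with its carved pocket
fx_complex <- function() {
  fx_cached("complex", function() {
    spec <- synthetic_spec(seed = 5)
    cx <- make_complex(spec, "polar", 1)
    parsed <- parse_structure(cx$pdb)
    prot <- assign_sybyl_types(parsed$structure)
    lig <- select_ligand(parsed, "LIG")
    grid <- carve_pocket(prot, lig)
    br <- binding_residues(prot, lig)
    frame <- principal_axes(br, lig$center)
    list(spec = spec, cx = cx, parsed = parsed, prot = prot, lig = lig,
         grid = grid, br = br, frame = frame)
  })
}

# small, quickly trainable voxel tensors with a planted channel signal:
# class k adds a constant to channel k inside a central blob
fx_small_tensors <- function(n_per_class = 10, side = 12, channels = 3,
                             seed = 99) {
  set.seed(seed)
  classes <- paste0("cl", seq_len(channels))
  tensors <- list(); labels <- character()
  mid <- (side %/% 2 - 1):(side %/% 2 + 2)
  for (k in seq_len(channels)) {
    for (i in seq_len(n_per_class)) {
      a <- array(rnorm(side^3 * channels, 0, 0.1), c(side, side, side, channels))
      a[mid, mid, mid, k] <- a[mid, mid, mid, k] + 1
      tensors[[length(tensors) + 1]] <- a
      labels <- c(labels, classes[k])
    }
  }
  list(tensors = tensors, labels = factor(labels))
}

# network/training configuration used for quick tests on small tensors
fx_small_cfg <- function(side = 12, channels = 3, classes = 3) {
  network_config(input_side = side, input_channels = channels,
                 filters = c(4, 4), kernels = c(5, 3), dense = 16,
                 classes = classes, dropout = c(0.1, 0.2))
}

fx_small_tcfg <- function(epochs = 8, seed = 3) {
  train_config(learning_rate = 2e-3, batch_size = 8, epochs = epochs,
               standardize = TRUE, seed = seed)
}

# the full-scale synthetic study set (60 pockets, energy + occupancy),
# shared by the acceptance tests
fx_study <- function() {
  fx_cached("study", function() {
    dir <- file.path(tempdir(), "pocketvox-study")
    spec <- synthetic_spec(seed = 101)
    man <- make_dataset(spec, dir, occupancy = TRUE)
    list(spec = spec, manifest = man,
         tensors = lapply(man$voxel_path, read_voxels),
         occupancy = lapply(man$occupancy_path, read_voxels))
  })
}

# GAP head: the planted signal is compositional (atom-type mixture of the
# lining), which global average pooling captures irrespective of where the
# cap ends up after canonical orientation; it is also the head under which
# the plain class-activation map is exact (see the methods vignette)
fx_study_cfg <- function(channels) {
  network_config(input_channels = channels, filters = c(8, 8), head = "gap")
}

# trained to convergence at desk scale (~110 Adam steps)
fx_study_tcfg <- function(seed = 101) {
  train_config(learning_rate = 2e-3, batch_size = 8, epochs = 15,
               standardize = "scale", seed = seed)
}

# compare two voxel tensors up to the 8 principal-axis sign combinations:
# rebuilds the candidate tensor under each sign flip of the frame axes
tensors_match_up_to_signs <- function(egrid_b, frame_b, tensor_a, tol = 1e-8) {
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    fb <- frame_b
    fb$rotation <- diag(c(s1, s2, s3)) %*% frame_b$rotation
    vb <- to_voxels(canonicalize(egrid_b, fb), side = tensor_a$side)
    if (max(abs(vb$values - tensor_a$values)) <= tol) return(TRUE)
  }
  FALSE
}

# apply a rigid motion to every coordinate of a parsed complex
rigid_move_parsed <- function(parsed, rot, trans) {
  mv <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    df$x <- xyz[, 1] + trans[1]
    df$y <- xyz[, 2] + trans[2]
    df$z <- xyz[, 3] + trans[3]
    df
  }
  parsed$structure$atoms <- mv(parsed$structure$atoms)
  parsed$hetero <- mv(parsed$hetero)
  parsed
}
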