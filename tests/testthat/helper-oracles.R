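# Independent brute-force oracles; deliberately naive implementations that
# share no code with the package internals they check.

oracle_sphere_count <- function(radius, spacing) {
  r <- floor(radius / spacing)
  n <- 0L
  for (x in -r:r) for (y in -r:r) for (z in -r:r)
    if ((x^2 + y^2 + z^2) * spacing^2 <= radius^2) n <- n + 1L
  n
}

oracle_min_dist <- function(p, atoms) {
  min(sqrt(colSums((t(atoms) - p)^2)))
}

oracle_excluded_keep <- function(points, atoms, cutoff) {
  keep <- logical(nrow(points))
  for (i in seq_len(nrow(points)))
    keep[i] <- oracle_min_dist(points[i, ], atoms) > cutoff
  keep
}

# inside test for an axis-aligned cube given its center and half side
oracle_inside_cube <- function(points, center, half) {
  apply(points, 1, function(p) all(abs(p - center) <= half + 1e-9))
}

# connected components by repeated neighbor expansion on pairwise distances
oracle_components <- function(points, spacing, connectivity = 6) {
  n <- nrow(points)
  lim <- if (connectivity == 6) spacing * 1.01 else spacing * sqrt(3) * 1.01
  d <- as.matrix(dist(points))
  adj <- d > 1e-9 & d <= lim
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    active <- s
    comp[s] <- cur
    while (length(active)) {
      nb <- which(apply(adj[active, , drop = FALSE], 2, any) & comp == 0)
      comp[nb] <- cur
      active <- nb
    }
  }
  comp
}

# energy channels by a naive double loop over (point, atom)
oracle_energy <- function(points, atoms_xyz, atom_types, pot) {
  out <- matrix(0, nrow(points), length(pot$probe_types))
  for (i in seq_len(nrow(points))) {
    for (a in seq_len(nrow(atoms_xyz))) {
      d <- sqrt(sum((points[i, ] - atoms_xyz[a, ])^2))
      for (c_ in seq_along(pot$probe_types))
        out[i, c_] <- out[i, c_] +
          potential_energy(pot, pot$probe_types[c_], atom_types[a], d)
    }
  }
  out
}

# AUC as the Mann-Whitney pair statistic with ties counted 1/2
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_binding_keys <- function(prot_atoms, lig_xyz, cutoff) {
  keys <- paste(prot_atoms$chain, prot_atoms$resno,
                ifelse(is.na(prot_atoms$insert), "", prot_atoms$insert),
                sep = "|")
  hit <- logical(nrow(prot_atoms))
  for (i in seq_len(nrow(prot_atoms)))
    hit[i] <- oracle_min_dist(c(prot_atoms$x[i], prot_atoms$y[i],
                                prot_atoms$z[i]), lig_xyz) <= cutoff
  unique(keys[hit])
}

# random rotation from the octahedral group (signed permutation, det +1)
lattice_rotation <- function() {
  repeat {
    perm <- sample(3)
    signs <- sample(c(-1, 1), 3, replace = TRUE)
    r <- matrix(0, 3, 3)
    r[cbind(1:3, perm)] <- signs
    if (abs(det(r) - 1) < 1e-9) return(r)
  }
}
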