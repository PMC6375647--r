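test_that("sphere grid point counts match exhaustive enumeration", {
  expect_equal(nrow(build_sphere_grid(c(0, 0, 0), 1, 1)$points), 7)
  expect_equal(nrow(build_sphere_grid(c(0, 0, 0), 2, 1)$points), 33)
  g <- build_sphere_grid(c(3.2, -1.5, 0.7), 15, 1)
  expect_equal(nrow(g$points), oracle_sphere_count(15, 1))
  # off-lattice spacing too
  expect_equal(nrow(build_sphere_grid(c(0, 0, 0), 5, 0.7)$points),
               oracle_sphere_count(5, 0.7))
  expect_error(build_sphere_grid(c(0, 0, 0), 0.5, 1), "radius")
})

test_that("grid points are unique, within radius, and centered", {
  g <- build_sphere_grid(c(1, 2, 3), 6, 1)
  expect_equal(anyDuplicated(g$points), 0)
  expect_true(all(sqrt(rowSums(sweep(g$points, 2, g$center)^2)) <= g$radius))
})

mk_protein <- function(xyz) {
  # typed_structure stub with atoms at given coordinates
  at <- data.frame(eleno = seq_len(nrow(xyz)), elety = "CB", elesy = "C",
                   resid = "ALA", chain = "A", resno = seq_len(nrow(xyz)),
                   insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   o = 1, b = 0, sybyl = "C.3")
  structure(list(atoms = at), class = "typed_structure")
}

test_that("excluded volume removes d <= cutoff, keeps strictly beyond", {
  g <- build_sphere_grid(c(0, 0, 0), 4, 1)
  prot <- mk_protein(matrix(c(0, 0, 0), 1))
  g2 <- remove_excluded_volume(g, prot, cutoff = 2)
  d <- sqrt(rowSums(g2$points^2))
  expect_true(all(d > 2))
  expect_true(any(abs(d - sqrt(5)) < 1e-9))  # 2.24 A shell retained
  # far protein leaves the grid unchanged
  far <- mk_protein(matrix(c(30, 0, 0), 1))
  g3 <- remove_excluded_volume(g, far, cutoff = 2)
  expect_equal(nrow(g3$points), nrow(g$points))
})

test_that("excluded volume matches the brute-force all-pairs oracle", {
  set.seed(21)
  for (rep in 1:5) {
    g <- build_sphere_grid(runif(3, -2, 2), 6, 1)
    atoms <- matrix(runif(60, -6, 6), ncol = 3)
    g2 <- remove_excluded_volume(g, mk_protein(atoms), cutoff = 2)
    keep <- oracle_excluded_keep(g$points, atoms, 2)
    expect_equal(g2$points, g$points[keep, , drop = FALSE])
  }
})

test_that("hull clipping matches the half-space oracle on a cube", {
  corners <- as.matrix(expand.grid(c(-5, 5), c(-5, 5), c(-5, 5)))
  g <- build_sphere_grid(c(0, 0, 0), 9, 1)
  g2 <- clip_to_envelope(g, mk_protein(corners), mode = "hull")
  inside <- oracle_inside_cube(g$points, c(0, 0, 0), 5)
  expect_equal(g2$points, g$points[inside, , drop = FALSE])
  # boundary points (on a face) count as inside
  expect_true(any(abs(g2$points[, 1] - 5) < 1e-9))
})

test_that("grid deep inside an enclosing shell is not clipped", {
  set.seed(4)
  u <- matrix(rnorm(900), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * 20
  g <- build_sphere_grid(c(0, 0, 0), 5, 1)
  g2 <- clip_to_envelope(g, mk_protein(u), mode = "hull")
  expect_equal(nrow(g2$points), nrow(g$points))
})

test_that("coplanar protein falls back to envelope mode with a warning", {
  flat <- as.matrix(expand.grid(seq(-6, 6, 2), seq(-6, 6, 2), 0))
  g <- build_sphere_grid(c(0, 0, 0), 5, 1)
  expect_warning(g2 <- clip_to_envelope(g, mk_protein(flat), mode = "hull"),
                 "envelope")
  keep <- !oracle_excluded_keep(g$points, flat, 4)  # within 4 A of an atom
  expect_equal(nrow(g2$points), sum(keep))
})

mk_grid <- function(points, center = c(0, 0, 0), radius = 15, spacing = 1) {
  structure(list(points = points, center = center, radius = radius,
                 spacing = spacing, removal_log = c(sphere = nrow(points))),
            class = "pocket_grid")
}

test_that("largest component survives, matching a BFS oracle", {
  big <- cbind(0:9, 0, 0)
  small <- cbind(20:22, 0, 0)
  g <- mk_grid(rbind(big, small))
  g2 <- largest_component(g, connectivity = 6)
  expect_equal(nrow(g2$points), 10)
  comp <- oracle_components(rbind(big, small), 1, 6)
  expect_equal(sort(g2$points[, 1]), sort(rbind(big, small)[comp == 1, 1]))
  # single point is its own (kept) component
  expect_equal(nrow(largest_component(mk_grid(cbind(1, 1, 1)))$points), 1)
})

test_that("component ties break toward the center-closest cluster", {
  a <- cbind(2:6, 0, 0)    # closest point at distance 2
  b <- cbind(-10:-6, 0, 0) # closest point at distance 6
  g <- mk_grid(rbind(b, a))
  g2 <- largest_component(g)
  expect_equal(sort(g2$points[, 1]), 2:6)
})

test_that("26-connectivity joins diagonal neighbors that 6 does not", {
  pts <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(5, 5, 5))
  expect_equal(nrow(largest_component(mk_grid(pts), 26)$points), 3)
  expect_equal(nrow(largest_component(mk_grid(pts), 6)$points), 1)
})

test_that("random sub-lattices match the component oracle", {
  set.seed(31)
  for (rep in 1:8) {
    pts <- unique(matrix(sample(-4:4, 3 * 40, replace = TRUE), ncol = 3))
    for (conn in c(6, 26)) {
      g2 <- largest_component(mk_grid(pts), conn)
      comp <- oracle_components(pts, 1, conn)
      sizes <- tabulate(comp)
      expect_equal(nrow(g2$points), max(sizes))
    }
  }
})

test_that("carve_pocket equals the composed stages and is deterministic", {
  fx <- fx_complex()
  manual <- build_sphere_grid(fx$lig$center, 15, 1)
  manual <- remove_excluded_volume(manual, fx$prot, 2)
  manual <- clip_to_envelope(manual, fx$prot, mode = "hull")
  manual <- largest_component(manual, 6)
  expect_equal(fx$grid$points, manual$points)
  again <- carve_pocket(fx$prot, fx$lig)
  expect_identical(again$points, fx$grid$points)
})

test_that("refinement only removes points and logs removals consistently", {
  fx <- fx_complex()
  log <- fx$grid$removal_log
  expect_equal(unname(log["sphere"] - sum(log[-1])), nrow(fx$grid$points))
  expect_true(all(log[-1] >= 0))
  # final grid is one connected component (BFS oracle)
  comp <- oracle_components(fx$grid$points, fx$grid$spacing, 6)
  expect_equal(max(comp), 1)
})

test_that("a ligand floating far from a tiny protein makes the pocket vanish", {
  tetra <- mk_protein(rbind(c(40, 0, 0), c(44, 0, 0), c(40, 4, 0), c(40, 0, 4)))
  lig <- structure(list(atoms = NULL, center = c(0, 0, 0)), class = "ligand")
  expect_error(carve_pocket(tetra, lig), "vanished")
})
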