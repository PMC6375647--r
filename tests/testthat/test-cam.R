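# small trained gap-head model on synthetic-signal tensors, for CAM checks
fx_gap_model <- function() {
  fx_cached("gap_model", function() {
    fix <- fx_small_tensors(n_per_class = 6, side = 12)
    cfg <- network_config(input_side = 12, input_channels = 3,
                          filters = c(4, 4), kernels = c(5, 3),
                          classes = 3, head = "gap", dropout = c(0, 0))
    m <- train_network(build_network(cfg), fix$tensors, fix$labels,
                       fx_small_tcfg(epochs = 4, seed = 9))
    list(model = m, fix = fix)
  })
}

test_that("constant feature maps give a spatially constant CAM", {
  cfg <- network_config(input_side = 10, input_channels = 1, filters = c(2, 2),
                        kernels = c(3, 3), classes = 2, head = "gap")
  m <- build_network(cfg, seed = 1)
  m$params$W1[] <- 0; m$params$b1[] <- 1   # conv outputs constant
  m$params$W2[] <- 0; m$params$b2[] <- c(1, 2)
  m$class_levels <- c("a", "b")
  x <- array(rnorm(1000), c(10, 10, 10, 1))
  cam <- activation_map(m, x, 1, method = "cam")
  expect_equal(max(cam$values) - min(cam$values), 0, tolerance = 1e-12)
})

test_that("plain CAM with one unit-weight feature map is the rectified map", {
  cfg <- network_config(input_side = 10, input_channels = 1, filters = c(2, 1),
                        kernels = c(3, 3), classes = 2, head = "gap")
  m <- build_network(cfg, seed = 2)
  m$params$W3 <- matrix(c(1, 0), 1, 2)  # class 1 weight 1 on the single map
  m$class_levels <- c("a", "b")
  x <- array(rnorm(1000), c(10, 10, 10, 1))
  fw <- pocketvox:::network_forward(m, x, cache = TRUE)
  fmap <- fw$cache$l2[, , , 1]
  fmap[fmap < 0] <- 0
  cam <- activation_map(m, x, 1, method = "cam")
  expect_equal(cam$values, pocketvox:::upsample_trilinear(fmap, 10),
               tolerance = 1e-12)
})

test_that("gradient-weighted CAM reduces to plain CAM under a GAP head", {
  gm <- fx_gap_model()
  x <- gm$fix$tensors[[1]]
  c_cam <- activation_map(gm$model, x, 1, method = "cam")
  c_grad <- activation_map(gm$model, x, 1, method = "grad")
  nsp <- prod(dim(x)[1:3] - c(6, 6, 6))  # feature-map voxel count (12-4-2)^3
  expect_equal(c_grad$values * nsp, c_cam$values, tolerance = 1e-9)
  expect_error(activation_map(gm$model, x, 99), "out of range")
})

test_that("trilinear upsampling preserves constants and the mean", {
  a <- array(2.5, c(5, 5, 5))
  up <- pocketvox:::upsample_trilinear(a, 8)
  expect_equal(range(up), c(2.5, 2.5))
  b <- array(rnorm(6^3), c(6, 6, 6))
  upb <- pocketvox:::upsample_trilinear(b, 12)
  expect_equal(dim(upb), c(12, 12, 12))
  expect_equal(mean(upb), mean(b), tolerance = 0.05)
})

mk_cam <- function(values, side = 32) {
  structure(list(values = array(values, c(side, side, side)),
                 class_index = 1, class_label = "a", method = "grad"),
            class = "cam_volume")
}

test_that("top-fraction selection thresholds voxels as specified", {
  fx <- fx_complex()
  eg <- canonicalize(energy_channels(fx$grid, fx$prot, toy_potential()),
                     fx$frame)
  vt <- to_voxels(eg)
  # distinct CAM values: exactly ceiling(1% of 32^3) = 328 voxels retained
  cam <- mk_cam(seq_len(32^3) / 32^3)
  v <- as.vector(cam$values)
  thr <- sort(v, decreasing = TRUE)[ceiling(0.01 * length(v))]
  expect_equal(sum(v >= thr), 328)
  sel <- select_top(cam, vt, fraction = 0.01)
  expect_setequal(sel$point, which(vt$voxel_index %in% which(v >= thr)))
  # fraction 1 selects every grid point; uniform CAM ties select everything
  expect_equal(nrow(select_top(cam, vt, fraction = 1)), nrow(vt$grid_points))
  expect_equal(nrow(select_top(mk_cam(1), vt, fraction = 0.01)),
               nrow(vt$grid_points))
  expect_warning(s0 <- select_top(mk_cam(0), vt), "zero")
  expect_equal(nrow(s0), 0)
})

test_that("selection is monotone in the retained fraction", {
  fx <- fx_complex()
  vt <- to_voxels(canonicalize(energy_channels(fx$grid, fx$prot,
                                               toy_potential()), fx$frame))
  set.seed(23)
  cam <- mk_cam(runif(32^3))
  s1 <- select_top(cam, vt, fraction = 0.01)$point
  s2 <- select_top(cam, vt, fraction = 0.05)$point
  s3 <- select_top(cam, vt, fraction = 0.5)$point
  expect_true(all(s1 %in% s2))
  expect_true(all(s2 %in% s3))
})

test_that("residue mapping honors the 5 A cutoff and conserves CAM mass", {
  atoms <- data.frame(eleno = 1:2, elety = "CB", elesy = "C", resid = "ALA",
                      chain = "A", resno = c(1, 2), insert = "",
                      x = c(4.9, 0), y = c(0, 40), z = 0, o = 1, b = 0,
                      sybyl = "C.3")
  st <- structure(list(atoms = atoms), class = "typed_structure")
  sel <- data.frame(x = c(0, 0), y = c(0, 30), z = 0, point = 1:2,
                    voxel = 1:2, cam = c(2, 7))
  rs <- residue_scores(sel, st, cutoff = 5)
  expect_equal(nrow(rs$scores), 1)
  expect_equal(rs$scores$resno, 1)
  expect_equal(rs$scores$cam_score, 2)   # the 4.9 A point only
  expect_equal(rs$unassigned, 1L)        # the 10 A point
  expect_equal(rs$scores$cam_score + rs$unassigned_value, sum(sel$cam))
})

test_that("residue scores equal a brute-force nearest-atom scan", {
  set.seed(24)
  fx <- fx_complex()
  st <- transform_structure(fx$prot, fx$frame)
  pts <- matrix(runif(60, -10, 10), ncol = 3)
  sel <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    point = 1:20, voxel = 1:20, cam = runif(20))
  rs <- residue_scores(sel, st, cutoff = 5)
  # oracle: all-pairs distances, nearest atom, 5 A gate
  keys <- residue_key(st$atoms)
  expect_scores <- list(); unassigned_val <- 0
  for (i in 1:20) {
    d <- sqrt(colSums((t(coords_matrix(st$atoms)) - pts[i, ])^2))
    j <- which.min(d)
    if (d[j] <= 5) {
      k <- keys[j]
      expect_scores[[k]] <- (expect_scores[[k]] %||% 0) + sel$cam[i]
    } else unassigned_val <- unassigned_val + sel$cam[i]
  }
  got <- setNames(rs$scores$cam_score,
                  paste(rs$scores$chain, rs$scores$resno, rs$scores$insert,
                        sep = "|"))
  expect_equal(sort(names(got)), sort(names(expect_scores)))
  for (k in names(got)) expect_equal(got[[k]], expect_scores[[k]])
  expect_equal(rs$unassigned_value, unassigned_val)
  expect_equal(sum(rs$scores$cam_score) + rs$unassigned_value, sum(sel$cam))
})

test_that("nearest-atom ties break toward the lowest residue number", {
  atoms <- data.frame(eleno = 1:2, elety = "CB", elesy = "C", resid = "ALA",
                      chain = c("B", "A"), resno = c(7, 3), insert = "",
                      x = c(2, -2), y = 0, z = 0, o = 1, b = 0, sybyl = "C.3")
  st <- structure(list(atoms = atoms), class = "typed_structure")
  sel <- data.frame(x = 0, y = 0, z = 0, point = 1, voxel = 1, cam = 1)
  rs <- residue_scores(sel, st, cutoff = 5)
  expect_equal(rs$scores$resno, 3)
})
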