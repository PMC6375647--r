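test_that("default architecture yields 64 feature maps of side 26", {
  m <- build_network(network_config(), seed = 1)
  fw <- pocketvox:::network_forward(m, array(0, c(32, 32, 32, 14)), cache = TRUE)
  expect_equal(dim(fw$cache$l2), c(26, 26, 26, 64))
  expect_equal(sum(fw$probs), 1, tolerance = 1e-9)
  expect_length(fw$probs, 3)
})

test_that("valid-convolution arithmetic holds for other input sides", {
  cfg <- network_config(input_side = 16, input_channels = 2,
                        filters = c(3, 3), dense = 8)
  m <- build_network(cfg, seed = 1)
  fw <- pocketvox:::network_forward(m, array(0, c(16, 16, 16, 2)), cache = TRUE)
  expect_equal(dim(fw$cache$l2)[1:3], rep(10, 3))
  expect_error(network_config(input_side = 5), "too large")
})

test_that("channel count changes only the first conv layer's weights", {
  m14 <- build_network(network_config(input_channels = 14), seed = 1)
  m2 <- build_network(network_config(input_channels = 2), seed = 1)
  d14 <- lapply(m14$params, dim)
  d2 <- lapply(m2$params, dim)
  expect_equal(d14[-1], d2[-1])
  expect_equal(d14$W1[1:3], d2$W1[1:3])
  expect_equal(d14$W1[4], 14)
  expect_equal(d2$W1[4], 2)
})

naive_conv3d <- function(x, w, b) {
  # direct quadruple loop, independent of the compiled kernels
  k <- dim(w)[1]; cin <- dim(w)[4]; cout <- dim(w)[5]
  m <- dim(x)[1] - k + 1
  y <- array(0, c(m, m, m, cout))
  for (co in seq_len(cout)) for (o3 in seq_len(m)) for (o2 in seq_len(m))
    for (o1 in seq_len(m))
      y[o1, o2, o3, co] <- b[co] +
        sum(x[o1:(o1 + k - 1), o2:(o2 + k - 1), o3:(o3 + k - 1), ] *
              w[, , , , co])
  y
}

test_that("convolution agrees with a naive loop on sparse and dense inputs", {
  set.seed(40)
  w <- array(rnorm(3^3 * 2 * 4), c(3, 3, 3, 2, 4))
  b <- rnorm(4)
  for (density in c(0.02, 0.5)) {   # exercises both compute paths
    x <- array(0, c(8, 8, 8, 2))
    nz <- sample(length(x), ceiling(density * length(x)))
    x[nz] <- rnorm(length(nz))
    expect_equal(pocketvox:::.conv3d_forward(x, w, b), naive_conv3d(x, w, b),
                 tolerance = 1e-12)
    # weight gradients against finite differences on the summed output
    gy <- array(rnorm(6^3 * 4), c(6, 6, 6, 4))
    bw <- pocketvox:::.conv3d_backward(x, w, gy, FALSE)
    eps <- 1e-6
    for (i in sample(length(w), 3)) {
      w2 <- w; w2[i] <- w[i] + eps
      f1 <- sum(pocketvox:::.conv3d_forward(x, w2, b) * gy)
      w2[i] <- w[i] - eps
      f0 <- sum(pocketvox:::.conv3d_forward(x, w2, b) * gy)
      expect_equal(bw$gw[i], (f1 - f0) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  cfg <- network_config(input_side = 8, input_channels = 2, filters = c(3, 2),
                        kernels = c(3, 3), dense = 5, classes = 3,
                        dropout = c(0, 0))
  m <- build_network(cfg, seed = 2)
  set.seed(7)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  y <- 2L
  loss <- function(mm) -log(pocketvox:::network_forward(mm, x)$probs[y])
  fw <- pocketvox:::network_forward(m, x, cache = TRUE)
  gl <- fw$probs; gl[y] <- gl[y] - 1
  g <- pocketvox:::network_backward(m, fw$cache, gl)
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (i in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
      m2 <- m; m2$params[[nm]][i] <- m$params[[nm]][i] + eps
      f1 <- loss(m2)
      m2$params[[nm]][i] <- m$params[[nm]][i] - eps
      f0 <- loss(m2)
      expect_equal(g[[nm]][i], (f1 - f0) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("gap-head gradients are also correct", {
  cfg <- network_config(input_side = 8, input_channels = 2, filters = c(2, 2),
                        kernels = c(3, 3), classes = 2, head = "gap",
                        dropout = c(0, 0))
  m <- build_network(cfg, seed = 4)
  set.seed(8)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 2))
  loss <- function(mm) -log(pocketvox:::network_forward(mm, x)$probs[1])
  fw <- pocketvox:::network_forward(m, x, cache = TRUE)
  gl <- fw$probs; gl[1] <- gl[1] - 1
  g <- pocketvox:::network_backward(m, fw$cache, gl)
  eps <- 1e-6
  for (nm in c("W1", "W2", "W3", "b3")) {
    i <- 1L
    m2 <- m; m2$params[[nm]][i] <- m$params[[nm]][i] + eps
    f1 <- loss(m2)
    m2$params[[nm]][i] <- m$params[[nm]][i] - eps
    f0 <- loss(m2)
    expect_equal(g[[nm]][i], (f1 - f0) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("training reduces loss on a separable fixture and is seed-stable", {
  fix <- fx_small_tensors(n_per_class = 6)
  cfg <- fx_small_cfg()
  tcfg <- fx_small_tcfg(epochs = 6, seed = 5)
  m1 <- train_network(build_network(cfg), fix$tensors, fix$labels, tcfg)
  expect_lt(m1$log$loss[nrow(m1$log)], m1$log$loss[1])
  expect_gte(m1$log$accuracy[nrow(m1$log)], 0.9)
  m2 <- train_network(build_network(cfg), fix$tensors, fix$labels, tcfg)
  expect_identical(m1$log$loss, m2$log$loss)
})

test_that("degenerate training inputs are rejected or survive as smoke", {
  fix <- fx_small_tensors(n_per_class = 2)
  expect_error(train_network(NULL, fix$tensors[1:2],
                             factor(c("a", "a")), fx_small_tcfg(1)),
               "2 classes")
  bad <- fix$tensors
  bad[[2]] <- array(0, c(6, 6, 6, 3))
  expect_error(train_network(NULL, bad, fix$labels, fx_small_tcfg(1)),
               "shape")
  # one sample per class, one epoch: runs and emits a model
  idx <- !duplicated(fix$labels)
  m <- train_network(build_network(fx_small_cfg()), fix$tensors[idx],
                     fix$labels[idx], fx_small_tcfg(epochs = 1))
  expect_s3_class(m, "pocket_cnn")
  expect_true(m$trained)
})

test_that("predictions normalize, carry labels, and ignore batch context", {
  fix <- fx_small_tensors(n_per_class = 3)
  m <- train_network(build_network(fx_small_cfg()), fix$tensors, fix$labels,
                     fx_small_tcfg(epochs = 2))
  p_all <- predict_network(m, fix$tensors)
  expect_equal(rowSums(p_all), rep(1, length(fix$tensors)), tolerance = 1e-6)
  expect_equal(attr(p_all, "labels"),
               colnames(p_all)[max.col(p_all, ties.method = "first")])
  p_one <- predict_network(m, fix$tensors[[4]])
  expect_equal(as.numeric(p_one), unname(p_all[4, ]), tolerance = 1e-12)
  expect_error(predict_network(m, array(0, c(5, 5, 5, 3))), "shape")
})

test_that("stratified folds partition the data and respect the seed", {
  labels <- factor(rep(c("a", "b"), each = 5))
  set.seed(1); f1 <- pocketvox:::stratified_folds(labels, 5)
  set.seed(1); f2 <- pocketvox:::stratified_folds(labels, 5)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  expect_true(all(table(f1) == 2))
  for (k in 1:5) expect_equal(sort(as.character(labels[f1 == k])), c("a", "b"))
  expect_error(pocketvox:::stratified_folds(labels, 11), "exceeds")
})

test_that("cross-validation predicts every sample once and separates classes", {
  fix <- fx_small_tensors(n_per_class = 10)
  cv <- crossvalidate(fix$tensors, fix$labels, k = 5, cfg = fx_small_cfg(),
                      tcfg = fx_small_tcfg(epochs = 6, seed = 6))
  expect_equal(nrow(cv$predictions), 30)
  expect_false(anyNA(cv$predictions[, levels(fix$labels)]))
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_true(all(cv$metrics[, "auc"] >= 0.9))
})

test_that("leave-one-group-out runs one round per group", {
  fix <- fx_small_tensors(n_per_class = 5)
  groups <- rep(paste0("G", 1:5), 3)
  cv <- logo_crossvalidate(fix$tensors, fix$labels, groups,
                           cfg = fx_small_cfg(),
                           tcfg = fx_small_tcfg(epochs = 2, seed = 7))
  expect_equal(length(unique(cv$fold_assignment)), 5)
  expect_false(anyNA(cv$predictions[, levels(fix$labels)]))
  # a group of size 1 still validates (other groups keep all classes in training)
  g2 <- c("solo", rep(c("g2", "g3"), length.out = length(fix$tensors) - 1))
  cv2 <- logo_crossvalidate(fix$tensors, fix$labels, g2,
                            cfg = fx_small_cfg(),
                            tcfg = fx_small_tcfg(epochs = 1, seed = 8))
  expect_equal(sum(cv2$fold_assignment == which(levels(factor(g2)) == "solo")), 1)
  expect_error(logo_crossvalidate(fix$tensors, fix$labels,
                                  rep("one", length(fix$tensors)),
                                  cfg = fx_small_cfg(),
                                  tcfg = fx_small_tcfg(1)),
               "2 groups")
})
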