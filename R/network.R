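#' 3D CNN architecture configuration
#'
#' The default architecture takes a 32-per-side voxel tensor through two
#' "valid" (unpadded, stride-1) convolutions with leaky-ReLU activations —
#' 64 filters of kernel 5, then 64 filters of kernel 3, leaving 64 feature
#' maps of spatial side 32 - 4 - 2 = 26 — followed by dropout, 2x2x2 max
#' pooling, dropout, one fully connected hidden layer and a softmax output.
#' With `head = "gap"` the pooling/dense block is replaced by global average
#' pooling straight into the softmax layer, the head under which the plain
#' class-activation map is exact.
#'
#' @param input_side Voxels per side of the input (default 32).
#' @param input_channels Number of channels (14 energy probes, or 2 for the
#'   occupancy baseline).
#' @param filters Two filter counts for the convolutional layers.
#' @param kernels Two cubic kernel sizes (default 5 and 3).
#' @param dropout Dropout rates before and after max pooling.
#' @param dense Width of the fully connected hidden layer.
#' @param classes Number of output classes.
#' @param leaky_slope Negative-side slope of the leaky ReLU.
#' @param head `"fc"` (maxpool + dense, the deployed head) or `"gap"`.
#' @return A `network_config` list.
#' @export
network_config <- function(input_side = 32, input_channels = 14,
                           filters = c(64, 64), kernels = c(5, 3),
                           dropout = c(0.2, 0.4), dense = 128, classes = 3,
                           leaky_slope = 0.1, head = c("fc", "gap")) {
  head <- match.arg(head)
  m1 <- input_side - kernels[1] + 1
  m2 <- m1 - kernels[2] + 1
  if (m1 <= 0 || m2 <= 0)
    stopf("kernels (%d, %d) too large for input side %d", kernels[1],
          kernels[2], input_side)
  structure(list(input_side = input_side, input_channels = input_channels,
                 filters = filters, kernels = kernels, dropout = dropout,
                 dense = dense, classes = classes, leaky_slope = leaky_slope,
                 head = head, conv_sides = c(m1, m2),
                 pooled_side = m2 %/% 2),
            class = "network_config")
}

#' Initialize an untrained network
#'
#' He initialization for convolutional and hidden dense weights, Glorot for
#' the output layer; biases start at zero.
#'
#' @param cfg A [network_config()].
#' @param seed Optional integer seed making the initialization reproducible.
#' @return A `pocket_cnn` model (untrained).
#' @export
build_network <- function(cfg = network_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k1 <- cfg$kernels[1]; k2 <- cfg$kernels[2]
  f1 <- cfg$filters[1]; f2 <- cfg$filters[2]
  he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
  params <- list(
    W1 = he(c(k1, k1, k1, cfg$input_channels, f1), k1^3 * cfg$input_channels),
    b1 = numeric(f1),
    W2 = he(c(k2, k2, k2, f1, f2), k2^3 * f1),
    b2 = numeric(f2))
  if (cfg$head == "fc") {
    nin <- cfg$pooled_side^3 * f2
    params$W3 <- matrix(rnorm(nin * cfg$dense, 0, sqrt(2 / nin)), nin, cfg$dense)
    params$b3 <- numeric(cfg$dense)
    params$W4 <- matrix(rnorm(cfg$dense * cfg$classes, 0,
                              sqrt(2 / (cfg$dense + cfg$classes))),
                        cfg$dense, cfg$classes)
    params$b4 <- numeric(cfg$classes)
  } else {
    params$W3 <- matrix(rnorm(f2 * cfg$classes, 0, sqrt(2 / (f2 + cfg$classes))),
                        f2, cfg$classes)
    params$b3 <- numeric(cfg$classes)
  }
  structure(list(cfg = cfg, params = params, standardize = NULL,
                 class_levels = NULL, trained = FALSE),
            class = "pocket_cnn")
}

#' @export
print.pocket_cnn <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("pocket_cnn (%s): %d^3 x %d -> conv(%d,k%d) -> conv(%d,k%d)",
                     " -> %d^3 x %d -> %s -> %d classes%s\n"),
              if (x$trained) "trained" else "untrained",
              cfg$input_side, cfg$input_channels,
              cfg$filters[1], cfg$kernels[1], cfg$filters[2], cfg$kernels[2],
              cfg$conv_sides[2], cfg$filters[2],
              if (cfg$head == "fc") sprintf("maxpool -> dense(%d)", cfg$dense)
              else "GAP",
              cfg$classes,
              if (is.null(x$standardize)) "" else " [standardized inputs]"))
  invisible(x)
}

#' @noRd
lrelu <- function(x, alpha) x * ((x > 0) + alpha * (x <= 0))

#' @noRd
lrelu_grad <- function(x, alpha) (x > 0) + alpha * (x <= 0)

#' @noRd
softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# 2x2x2 max pooling over a (m, m, m, f) array; returns pooled array and the
# argmax combination (1..8) per output element for backprop.
#' @noRd
maxpool_fwd <- function(x) {
  d <- dim(x)
  mm <- d[1] %/% 2L
  o <- seq_len(mm) * 2L - 1L
  s <- matrix(0, mm^3 * d[4], 8L)
  j <- 0L
  for (d3 in 0:1) for (d2 in 0:1) for (d1 in 0:1) {
    j <- j + 1L
    s[, j] <- x[o + d1, o + d2, o + d3, , drop = FALSE]
  }
  amax <- max.col(s, ties.method = "first")
  y <- array(s[cbind(seq_len(nrow(s)), amax)], c(mm, mm, mm, d[4]))
  list(y = y, amax = amax, in_dim = d)
}

#' @noRd
maxpool_bwd <- function(pool, gy) {
  d <- pool$in_dim
  mm <- d[1] %/% 2L
  o <- seq_len(mm) * 2L - 1L
  # linear index template of output -> input for each of the 8 offsets
  base <- as.matrix(expand.grid(o1 = o, o2 = o, o3 = o, f = seq_len(d[4])))
  gx <- array(0, d)
  gyv <- as.vector(gy)
  j <- 0L
  for (d3 in 0:1) for (d2 in 0:1) for (d1 in 0:1) {
    j <- j + 1L
    sel <- pool$amax == j
    if (!any(sel)) next
    lin <- (base[sel, 1] + d1) +
      d[1] * (base[sel, 2] + d2 - 1L) +
      d[1] * d[2] * (base[sel, 3] + d3 - 1L) +
      d[1] * d[2] * d[3] * (base[sel, 4] - 1L)
    gx[lin] <- gx[lin] + gyv[sel]
  }
  gx
}

#' @noRd
apply_standardize <- function(model, x) {
  st <- model$standardize
  if (is.null(st)) return(x)
  nc <- dim(x)[4]
  for (c_ in seq_len(nc)) x[, , , c_] <- (x[, , , c_] - st$mu[c_]) / st$sd[c_]
  x
}

# Full forward pass.  `train` enables (inverted) dropout with masks drawn
# from the current RNG stream; `cache = TRUE` retains every intermediate
# needed by network_backward().
#' @noRd
network_forward <- function(model, x, train = FALSE, cache = FALSE) {
  cfg <- model$cfg; p <- model$params; al <- cfg$leaky_slope
  x <- apply_standardize(model, x)
  a1 <- .conv3d_forward(x, p$W1, p$b1)
  l1 <- lrelu(a1, al)
  a2 <- .conv3d_forward(l1, p$W2, p$b2)
  l2 <- lrelu(a2, al)

  cc <- if (cache) list(x = x, a1 = a1, l1 = l1, a2 = a2, l2 = l2) else NULL

  if (cfg$head == "fc") {
    d1 <- cfg$dropout[1]; d2 <- cfg$dropout[2]
    if (train && d1 > 0) {
      m1 <- (runif(length(l2)) >= d1) / (1 - d1)
      h <- l2 * m1
    } else { m1 <- NULL; h <- l2 }
    pool <- maxpool_fwd(array(h, dim(l2)))
    if (train && d2 > 0) {
      m2 <- (runif(length(pool$y)) >= d2) / (1 - d2)
      hp <- pool$y * m2
    } else { m2 <- NULL; hp <- pool$y }
    flat <- as.vector(hp)
    a3 <- drop(flat %*% p$W3) + p$b3
    l3 <- lrelu(a3, al)
    logits <- drop(l3 %*% p$W4) + p$b4
    if (cache) cc <- c(cc, list(mask1 = m1, pool = pool, mask2 = m2,
                                flat = flat, a3 = a3, l3 = l3))
  } else {
    gap <- apply(l2, 4, mean)
    logits <- drop(gap %*% p$W3) + p$b3
    if (cache) cc <- c(cc, list(gap = gap))
  }
  probs <- softmax_vec(logits)
  list(probs = probs, logits = logits, cache = cc)
}

# Backpropagation from d(loss)/d(logits).  Returns parameter gradients;
# with `to_conv2 = TRUE` also the gradient at the second conv activation
# (used by the gradient-weighted class-activation map).
#' @noRd
network_backward <- function(model, cc, glogits, to_conv2 = FALSE) {
  cfg <- model$cfg; p <- model$params; al <- cfg$leaky_slope
  g <- list()
  if (cfg$head == "fc") {
    g$W4 <- outer(cc$l3, glogits)
    g$b4 <- glogits
    gl3 <- drop(p$W4 %*% glogits)
    ga3 <- gl3 * lrelu_grad(cc$a3, al)
    g$W3 <- outer(cc$flat, ga3)
    g$b3 <- ga3
    gflat <- drop(p$W3 %*% ga3)
    ghp <- array(gflat, dim(cc$pool$y))
    if (!is.null(cc$mask2)) ghp <- ghp * cc$mask2
    gh <- maxpool_bwd(cc$pool, ghp)
    if (!is.null(cc$mask1)) gh <- gh * cc$mask1
    gl2 <- gh
  } else {
    g$W3 <- outer(cc$gap, glogits)
    g$b3 <- glogits
    ggap <- drop(p$W3 %*% glogits)
    nsp <- prod(dim(cc$l2)[1:3])
    gl2 <- array(rep(ggap / nsp, each = nsp), dim(cc$l2))
  }
  ga2 <- gl2 * lrelu_grad(cc$a2, al)
  bw2 <- .conv3d_backward(cc$l1, p$W2, ga2, TRUE)
  g$W2 <- bw2$gw; g$b2 <- bw2$gb
  gl1 <- bw2$gx * lrelu_grad(cc$a1, al)
  bw1 <- .conv3d_backward(cc$x, p$W1, gl1, FALSE)
  g$W1 <- bw1$gw; g$b1 <- bw1$gb
  if (to_conv2) g$conv2_activation <- gl2  # d(score)/d(feature maps l2)
  g
}
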