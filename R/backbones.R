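#' GoogLeNet (Inception v1) architecture table
#'
#' The stage stack producing the 1024-dimensional global-average-pool
#' embedding (R2): 7x7/2 convolution, 3x3/2 max pools, a 3x3 convolution
#' block, and Inception modules 3a-5b. Per-branch widths follow the canonical
#' Inception v1 design; each row's concatenated output width is listed.
#'
#' @return Data frame of inception modules with branch widths (`b1` 1x1,
#'   `b2r`/`b2` reduced 3x3, `b3r`/`b3` reduced 5x5, `b4` pool projection) and
#'   total output channels.
#' @export
googlenet_spec <- function() {
  m <- rbind(
    `3a` = c(64, 96, 128, 16, 32, 32),
    `3b` = c(128, 128, 192, 32, 96, 64),
    `4a` = c(192, 96, 208, 16, 48, 64),
    `4b` = c(160, 112, 224, 24, 64, 64),
    `4c` = c(128, 128, 256, 24, 64, 64),
    `4d` = c(112, 144, 288, 32, 64, 64),
    `4e` = c(256, 160, 320, 32, 128, 128),
    `5a` = c(256, 160, 320, 32, 128, 128),
    `5b` = c(384, 192, 384, 48, 128, 128)
  )
  colnames(m) <- c("b1", "b2r", "b2", "b3r", "b3", "b4")
  data.frame(module = rownames(m), m, total = rowSums(m[, c(1, 3, 5, 6)]),
             row.names = NULL)
}

conv_init <- function(k, cin, cout) {
  list(w = he_init(c(k, k, cin, cout), k * k * cin), b = numeric(cout))
}

#' Initialise GoogLeNet weights
#'
#' Seeded He-normal initialisation of the full Inception v1 stack. Pretrained
#' weights saved from [googlenet_init()] (an identically shaped list) can be
#' supplied to [googlenet_embed()] instead.
#'
#' @param seed Integer seed.
#' @return Weight list of class `googlenet_weights`.
#' @export
googlenet_init <- function(seed = 1L) {
  spec <- googlenet_spec()
  with_seed(seed, {
    w <- list(conv1 = conv_init(7, 3, 64),
              conv2r = conv_init(1, 64, 64),
              conv2 = conv_init(3, 64, 192))
    cin <- 192
    for (i in seq_len(nrow(spec))) {
      s <- spec[i, ]
      w[[paste0("inc", s$module)]] <- list(
        b1 = conv_init(1, cin, s$b1),
        b2r = conv_init(1, cin, s$b2r), b2 = conv_init(3, s$b2r, s$b2),
        b3r = conv_init(1, cin, s$b3r), b3 = conv_init(5, s$b3r, s$b3),
        b4 = conv_init(1, cin, s$b4)
      )
      cin <- s$total
    }
    structure(w, class = "googlenet_weights", seed = seed)
  })
}

cat_channels <- function(parts) {
  d <- dim(parts[[1]])
  ctot <- sum(vapply(parts, function(p) dim(p)[4], 1))
  out <- array(0, c(d[1], d[2], d[3], ctot))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[4]
    out[, , , at + seq_len(cp)] <- p
    at <- at + cp
  }
  out
}

#' Forward pass of one Inception module
#'
#' Four parallel branches -- 1x1 convolution, dimension-reduced 3x3,
#' dimension-reduced 5x5, and 3x3 max pooling followed by a 1x1 projection --
#' concatenated along the channel axis, rectified-linear activations
#' throughout.
#'
#' @param x Input tensor `(H, W, B, C)`.
#' @param w One module's weight list (see [googlenet_init()]).
#' @return Tensor `(H, W, B, b1 + b2 + b3 + b4)`.
#' @export
inception_forward <- function(x, w) {
  p1 <- relu(conv2d(x, w$b1$w, w$b1$b, pad = "same"))
  p2 <- relu(conv2d(relu(conv2d(x, w$b2r$w, w$b2r$b, pad = "same")),
                    w$b2$w, w$b2$b, pad = "same"))
  p3 <- relu(conv2d(relu(conv2d(x, w$b3r$w, w$b3r$b, pad = "same")),
                    w$b3$w, w$b3$b, pad = "same"))
  p4 <- relu(conv2d(maxpool2d(x, 3L, 1L, "same"), w$b4$w, w$b4$b, pad = "same"))
  cat_channels(list(p1, p2, p3, p4))
}

#' GoogLeNet embeddings (R2, length 1024)
#'
#' Forward pass through the Inception v1 stack; the embedding is taken at the
#' 7x7 global average pool, before dropout and the linear classifier.
#'
#' @param images List of `topo_image`s resized to 224, or a `(224, 224, B, 3)`
#'   tensor.
#' @param weights A `googlenet_weights` list.
#' @param batch_size Images processed per forward chunk (memory control).
#' @return Matrix (B x 1024).
#' @export
googlenet_embed <- function(images, weights = googlenet_init(), batch_size = 8L) {
  x <- if (is.array(images) && length(dim(images)) == 4) images else stack_topomaps(images)
  stopifnot(dim(x)[1] == 224, dim(x)[2] == 224)
  n <- dim(x)[3]
  out <- matrix(0, n, 1024)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- googlenet_forward(x[, , idx, , drop = FALSE], weights)
  }
  colnames(out) <- paste0("R2_", seq_len(1024))
  out
}

googlenet_forward <- function(x, w) {
  h <- relu(conv2d(x, w$conv1$w, w$conv1$b, stride = 2L, pad = "same"))
  h <- maxpool2d(h, 3L, 2L, "same")
  h <- relu(conv2d(h, w$conv2r$w, w$conv2r$b, pad = "same"))
  h <- relu(conv2d(h, w$conv2$w, w$conv2$b, pad = "same"))
  h <- maxpool2d(h, 3L, 2L, "same")
  h <- inception_forward(h, w$inc3a)
  h <- inception_forward(h, w$inc3b)
  h <- maxpool2d(h, 3L, 2L, "same")
  for (m in c("4a", "4b", "4c", "4d", "4e")) {
    h <- inception_forward(h, w[[paste0("inc", m)]])
  }
  h <- maxpool2d(h, 3L, 2L, "same")
  h <- inception_forward(h, w$inc5a)
  h <- inception_forward(h, w$inc5b)
  global_avgpool(h)
}

#' EfficientNet-B0 architecture table
#'
#' The nine-stage stack: a 3x3 stem convolution, seven MBConv stages (mobile
#' inverted bottleneck with squeeze-and-excitation, swish activation) and the
#' 1x1 convolution + pooling head that yields the 1280-dimensional embedding
#' (R3). `resolution` is each stage's input side at a 224 x 224 input.
#'
#' @return Data frame with stage, operator, kernel, input resolution, output
#'   channels, layer count, expansion factor and first-layer stride.
#' @export
efficientnet_b0_spec <- function() {
  data.frame(
    stage = 1:9,
    operator = c("Conv3x3", "MBConv1, k3x3", "MBConv6, k3x3", "MBConv6, k5x5",
                 "MBConv6, k3x3", "MBConv6, k5x5", "MBConv6, k5x5",
                 "MBConv6, k3x3", "Conv1x1&Pooling&FC"),
    kernel = c(3L, 3L, 3L, 5L, 3L, 5L, 5L, 3L, 1L),
    resolution = c(224L, 112L, 112L, 56L, 28L, 14L, 14L, 7L, 7L),
    channels = c(32L, 16L, 24L, 40L, 80L, 112L, 192L, 320L, 1280L),
    layers = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 1L, 1L),
    expansion = c(NA, 1L, 6L, 6L, 6L, 6L, 6L, 6L, NA),
    stride = c(2L, 1L, 2L, 2L, 2L, 1L, 2L, 1L, 1L)
  )
}

mbconv_init <- function(cin, cout, k, expansion) {
  cexp <- cin * expansion
  w <- list(expansion = expansion, k = k, cin = cin, cout = cout)
  if (expansion != 1) w$expand <- conv_init(1, cin, cexp)
  w$dw <- list(w = he_init(c(k, k, cexp), k * k), b = numeric(cexp))
  se_dim <- max(1L, round(cin / 4))
  w$se <- list(w1 = he_init(c(cexp, se_dim), cexp), b1 = numeric(se_dim),
               w2 = he_init(c(se_dim, cexp), se_dim), b2 = numeric(cexp))
  w$project <- conv_init(1, cexp, cout)
  w
}

#' Initialise EfficientNet-B0 weights
#' @param seed Integer seed for the He-normal initialisation.
#' @return Weight list of class `efficientnet_b0_weights`.
#' @export
efficientnet_b0_init <- function(seed = 1L) {
  spec <- efficientnet_b0_spec()
  with_seed(seed, {
    w <- list(stem = conv_init(3, 3, 32))
    cin <- 32L
    for (i in 2:8) {
      s <- spec[i, ]
      blocks <- list()
      for (j in seq_len(s$layers)) {
        blocks[[j]] <- mbconv_init(cin, s$channels, s$kernel, s$expansion)
        cin <- s$channels
      }
      w[[paste0("stage", i)]] <- blocks
    }
    w$head <- conv_init(1, 320, 1280)
    structure(w, class = "efficientnet_b0_weights", seed = seed)
  })
}

#' Forward pass of one MBConv block
#'
#' 1x1 expansion (factor n) + swish, k x k depthwise convolution + swish,
#' squeeze-and-excitation gate (global average pool, two fully connected
#' layers, sigmoid), linear 1x1 projection; identity skip when stride is 1
#' and the channel count is preserved.
#'
#' @param x Input tensor `(H, W, B, Cin)`.
#' @param w Block weights from `mbconv_init`.
#' @param stride Depthwise stride.
#' @return Output tensor.
#' @export
mbconv_forward <- function(x, w, stride = 1L) {
  h <- x
  if (w$expansion != 1) h <- swish(conv2d(h, w$expand$w, w$expand$b))
  h <- swish(depthwise_conv2d(h, w$dw$w, w$dw$b, stride = stride, pad = "same"))
  # squeeze and excitation: per-image channel gate
  d <- dim(h)
  s <- global_avgpool(h) # B x Cexp
  z <- swish(s %*% w$se$w1 + rep(w$se$b1, each = nrow(s)))
  gate <- sigmoid(z %*% w$se$w2 + rep(w$se$b2, each = nrow(z)))
  hm <- matrix(h, d[1] * d[2], d[3] * d[4])
  gm <- matrix(rep(as.vector(gate), each = d[1] * d[2]), d[1] * d[2], d[3] * d[4])
  h <- array(hm * gm, d)
  h <- conv2d(h, w$project$w, w$project$b)
  if (stride == 1L && w$cin == w$cout) h <- h + x
  h
}

#' EfficientNet-B0 embeddings (R3, length 1280)
#'
#' Forward pass through the MBConv stack; the embedding is the stage-9 global
#' average pool of the 1280-channel head convolution.
#'
#' @param images List of `topo_image`s resized to 224, or a `(224, 224, B, 3)`
#'   tensor.
#' @param weights An `efficientnet_b0_weights` list.
#' @param batch_size Images per forward chunk.
#' @return Matrix (B x 1280).
#' @export
efficientnet_b0_embed <- function(images, weights = efficientnet_b0_init(),
                                  batch_size = 8L) {
  x <- if (is.array(images) && length(dim(images)) == 4) images else stack_topomaps(images)
  stopifnot(dim(x)[1] == 224, dim(x)[2] == 224)
  n <- dim(x)[3]
  out <- matrix(0, n, 1280)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- efficientnet_b0_forward(x[, , idx, , drop = FALSE], weights)
  }
  colnames(out) <- paste0("R3_", seq_len(1280))
  out
}

efficientnet_b0_forward <- function(x, w) {
  spec <- efficientnet_b0_spec()
  h <- swish(conv2d(x, w$stem$w, w$stem$b, stride = 2L, pad = "same"))
  for (i in 2:8) {
    blocks <- w[[paste0("stage", i)]]
    for (j in seq_along(blocks)) {
      stride <- if (j == 1L) spec$stride[i] else 1L
      h <- mbconv_forward(h, blocks[[j]], stride)
    }
  }
  h <- swish(conv2d(h, w$head$w, w$head$b))
  global_avgpool(h)
}
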