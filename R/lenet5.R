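#' Initialise LeNet-5 weights
#'
#' Classic LeNet-5 stack: C1 (6 maps, 5 x 5 convolution), S2 (2 x 2 average
#' subsampling with one trainable coefficient and bias per map, sigmoid
#' activation), C3 (16 maps, 5 x 5), S4 (as S2), C5 (120 maps, convolution
#' over the whole remaining spatial extent, so the output is a 120-vector).
#' F6 (84 units, sigmoid) and the softmax output layer form the trainable
#' classification head. With the default 32 x 32 input C5's kernel is the
#' classic 5 x 5; for other input sides (e.g. the 67 x 67 native topography
#' resolution) the C5 kernel spans the S4 output so the embedding stays 120.
#'
#' @param seed Integer seed for the random (He) initialisation.
#' @param input_side Input image side (32 default, 67 supported).
#' @param in_channels Input planes (3 band planes).
#' @param maps Feature-map counts for C1, C3, C5.
#' @param f6 Units of the fully connected F6 layer.
#' @param classes Output classes of the trained head.
#' @return Weight list of class `lenet5_weights`.
#' @export
lenet5_init <- function(seed = 1L, input_side = 32L, in_channels = 3L,
                        maps = c(6L, 16L, 120L), f6 = 84L, classes = 2L) {
  c1 <- input_side - 4L
  s2 <- c1 %/% 2L
  c3 <- s2 - 4L
  s4 <- c3 %/% 2L
  if (c3 < 1L || s4 < 1L) stop("lenet5_init: input side too small for the stack")
  with_seed(seed, {
    w <- list(
      C1_w = he_init(c(5, 5, in_channels, maps[1]), 25 * in_channels),
      C1_b = numeric(maps[1]),
      S2_w = stats::rnorm(maps[1], 1, 0.1), S2_b = numeric(maps[1]),
      C3_w = he_init(c(5, 5, maps[1], maps[2]), 25 * maps[1]),
      C3_b = numeric(maps[2]),
      S4_w = stats::rnorm(maps[2], 1, 0.1), S4_b = numeric(maps[2]),
      C5_w = he_init(c(s4, s4, maps[2], maps[3]), s4 * s4 * maps[2]),
      C5_b = numeric(maps[3]),
      F6_w = he_init(c(maps[3], f6), maps[3]), F6_b = numeric(f6),
      OUT_w = he_init(c(f6, classes), f6), OUT_b = numeric(classes)
    )
    structure(w, class = "lenet5_weights", input_side = input_side,
              in_channels = in_channels, maps = maps, seed = seed)
  })
}

scale_maps <- function(p, w, b) {
  d <- dim(p); nr <- d[1] * d[2] * d[3]
  m <- matrix(p, nr, d[4])
  array(m * rep(w, each = nr) + rep(b, each = nr), d)
}

lenet5_forward <- function(x, w, cache = FALSE) {
  a1 <- conv2d(x, w$C1_w, w$C1_b)
  p2 <- avgpool2d(a1, 2L)
  a2 <- sigmoid(scale_maps(p2, w$S2_w, w$S2_b))
  a3 <- conv2d(a2, w$C3_w, w$C3_b)
  p4 <- avgpool2d(a3, 2L)
  a4 <- sigmoid(scale_maps(p4, w$S4_w, w$S4_b))
  a5 <- conv2d(a4, w$C5_w, w$C5_b)
  emb <- matrix(a5, dim(a5)[3], dim(a5)[4])
  if (cache) list(emb = emb, x = x, a1 = a1, p2 = p2, a2 = a2,
                  a3 = a3, p4 = p4, a4 = a4)
  else emb
}

#' LeNet-5 embeddings (R1, length 120)
#'
#' Forward pass of topography images through the (frozen or trained)
#' convolutional stack; the embedding is the flattened C5 output. F6 and the
#' output layer exist only in the trained head.
#'
#' @param images A list of `topo_image`s, a single `topo_image`, or a batch
#'   tensor from [stack_topomaps()], at the weight's input side.
#' @param weights A `lenet5_weights` object.
#' @return Matrix (B x 120) of embeddings.
#' @export
lenet5_embed <- function(images, weights) {
  x <- if (is.array(images) && length(dim(images)) == 4) images else stack_topomaps(images)
  if (dim(x)[1] != attr(weights, "input_side")) {
    stop(sprintf("lenet5_embed: input side %d does not match weights (%d)",
                 dim(x)[1], attr(weights, "input_side")))
  }
  emb <- lenet5_forward(x, weights)
  colnames(emb) <- paste0("R1_", seq_len(ncol(emb)))
  emb
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Loss and analytic gradients of the full stack + head (cross-entropy).
# Used for end-to-end training and for gradient verification.
lenet5_loss_grad <- function(x, y, w) {
  cc <- lenet5_forward(x, w, cache = TRUE)
  B <- nrow(cc$emb)
  f6_pre <- cc$emb %*% w$F6_w + rep(w$F6_b, each = B)
  f6 <- sigmoid(f6_pre)
  logits <- f6 %*% w$OUT_w + rep(w$OUT_b, each = B)
  p <- softmax_rows(logits)
  onehot <- diag(ncol(p))[y + 1L, , drop = FALSE]
  loss <- -mean(log(pmax(rowSums(p * onehot), 1e-12)))

  dlog <- (p - onehot) / B
  g <- list(OUT_w = t(f6) %*% dlog, OUT_b = colSums(dlog))
  df6 <- (dlog %*% t(w$OUT_w)) * f6 * (1 - f6)
  g$F6_w <- t(cc$emb) %*% df6
  g$F6_b <- colSums(df6)
  demb <- df6 %*% t(w$F6_w)
  da5 <- array(demb, c(1, 1, B, ncol(cc$emb)))

  cb5 <- conv_backward(cc$a4, w$C5_w, da5)
  g$C5_w <- cb5$dw; g$C5_b <- cb5$db
  s4 <- sigmoid_scale_backward(cb5$dx, cc$a4, cc$p4, w$S4_w)
  g$S4_w <- s4$dw; g$S4_b <- s4$db
  da3 <- avgpool_backward(s4$dp, dim(cc$a3))
  cb3 <- conv_backward(cc$a2, w$C3_w, da3)
  g$C3_w <- cb3$dw; g$C3_b <- cb3$db
  s2 <- sigmoid_scale_backward(cb3$dx, cc$a2, cc$p2, w$S2_w)
  g$S2_w <- s2$dw; g$S2_b <- s2$db
  da1 <- avgpool_backward(s2$dp, dim(cc$a1))
  cb1 <- conv_backward(cc$x, w$C1_w, da1)
  g$C1_w <- cb1$dw; g$C1_b <- cb1$db
  list(loss = loss, grads = g, prob = p)
}

conv_backward <- function(x, w, dout) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  ic <- im2col(x, kh, kw, 1L)
  dm <- matrix(dout, length(dout) / cout, cout)
  dw <- array(t(ic$mat) %*% dm, dim(w))
  db <- colSums(dm)
  dcol <- dm %*% t(matrix(w, kh * kw * cin, cout))
  dx <- array(0, dim(x))
  d <- dim(x)
  oh <- ic$oh; ow <- ic$ow; B <- d[3]
  for (dj in 0:(kw - 1L)) {
    for (di in 0:(kh - 1L)) {
      cols <- di + 1L + kh * dj + kh * kw * (0:(cin - 1L))
      dx[(1:oh) + di, (1:ow) + dj, , ] <-
        dx[(1:oh) + di, (1:ow) + dj, , , drop = FALSE] +
        array(dcol[, cols], c(oh, ow, B, cin))
    }
  }
  list(dx = dx, dw = dw, db = db)
}

sigmoid_scale_backward <- function(da, a, p, w) {
  d <- dim(a); nr <- d[1] * d[2] * d[3]
  dz <- da * a * (1 - a)
  dzm <- matrix(dz, nr, d[4])
  pm <- matrix(p, nr, d[4])
  list(dw = colSums(dzm * pm), db = colSums(dzm),
       dp = array(dzm * rep(w, each = nr), d))
}

avgpool_backward <- function(dp, dim_in) {
  dx <- array(0, dim_in)
  d <- dim(dp)
  up <- dp / 4
  for (di in 0:1) {
    for (dj in 0:1) {
      dx[2 * (1:d[1]) - 1 + di, 2 * (1:d[2]) - 1 + dj, , ] <- up
    }
  }
  dx
}

#' Train LeNet-5 end to end
#'
#' Adam optimisation of the full stack and head under cross-entropy. The
#' reference pipeline keeps the convolutional stack frozen at its seeded
#' initialisation and trains only the head ([train_head()]); end-to-end
#' training is provided for completeness.
#'
#' @param images Batch tensor or list of `topo_image`s.
#' @param labels Integer 0/1 labels.
#' @param weights Starting `lenet5_weights` (default fresh init).
#' @param epochs,batch_size,lr Training hyperparameters.
#' @param seed Seed for shuffling.
#' @return Trained `lenet5_weights`.
#' @export
lenet5_train <- function(images, labels, weights = NULL, epochs = 20,
                         batch_size = 16, lr = 1e-3, seed = 1L) {
  x <- if (is.array(images) && length(dim(images)) == 4) images else stack_topomaps(images)
  if (is.null(weights)) weights <- lenet5_init(seed, input_side = dim(x)[1])
  m <- lapply(weights, function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; t <- 0
  with_seed(seed, {
    n <- dim(x)[3]
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n)]
        lg <- lenet5_loss_grad(x[, , idx, , drop = FALSE], labels[idx], weights)
        t <- t + 1
        for (nm in names(lg$grads)) {
          g <- lg$grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g^2
          mhat <- m[[nm]] / (1 - b1^t)
          vhat <- v[[nm]] / (1 - b2^t)
          weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
        }
      }
    }
  })
  weights
}

#' Train the fully connected softmax head
#'
#' Multinomial logistic regression (a fully connected layer + softmax trained
#' by cross-entropy) on fixed embeddings, via [nnet::multinom()].
#'
#' @param embeddings Matrix (B x d) of embeddings or fused vectors.
#' @param labels Integer 0/1 labels, both classes present.
#' @param seed Seed (the optimiser start is randomised).
#' @param maxit Optimiser iteration cap.
#' @return Object of class `fc_head`; predict with [predict.fc_head()].
#' @export
train_head <- function(embeddings, labels, seed = 1L, maxit = 200) {
  if (length(unique(labels)) < 2) {
    stop("degenerate-training error: training labels contain a single class")
  }
  df <- as.data.frame(embeddings)
  colnames(df) <- paste0("e", seq_len(ncol(df)))
  df$.y <- factor(labels, levels = sort(unique(labels)))
  fit <- with_seed(seed, nnet::multinom(.y ~ ., data = df, trace = FALSE,
                                        maxit = maxit, MaxNWts = 100000))
  structure(list(fit = fit, levels = levels(df$.y)), class = "fc_head")
}

#' Predict classes from a trained head
#' @param object An `fc_head`.
#' @param newdata Embedding matrix.
#' @param ... Unused.
#' @return Integer class labels.
#' @export
predict.fc_head <- function(object, newdata, ...) {
  df <- as.data.frame(newdata)
  colnames(df) <- paste0("e", seq_len(ncol(df)))
  as.integer(as.character(stats::predict(object$fit, newdata = df)))
}
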