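# Minimal dense tensor ops for the feature extractors.
#
# Batched image tensors use layout (H, W, B, C): height fastest, then width,
# then batch, then channels. That layout lets a convolution be assembled as
# one im2col matrix ((oH*oW*B) x (kh*kw*Cin)) and a single BLAS matmul, which
# is the only way a from-scratch forward pass is fast enough in R.

sigmoid <- function(x) 1 / (1 + exp(-x))
swish <- function(x) x * sigmoid(x)
relu <- function(x) (x > 0) * x

# "same"-style asymmetric padding for a given stride (TF convention):
# output = ceil(in / stride).
pad_same <- function(n, k, stride) {
  out <- ceiling(n / stride)
  total <- max((out - 1L) * stride + k - n, 0L)
  c(total %/% 2L, total - total %/% 2L)
}

pad_hw <- function(x, pt, pb, pl, pr, value = 0) {
  if (pt + pb + pl + pr == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + pt + pb, d[2] + pl + pr, d[3], d[4]))
  out[pt + seq_len(d[1]), pl + seq_len(d[2]), , ] <- x
  out
}

# im2col: returns list(mat, oh, ow) with mat of dim (oh*ow*B) x (kh*kw*C).
im2col <- function(x, kh, kw, stride) {
  d <- dim(x) # (H, W, B, C)
  oh <- (d[1] - kh) %/% stride + 1L
  ow <- (d[2] - kw) %/% stride + 1L
  B <- d[3]; C <- d[4]
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  mat <- matrix(0, oh * ow * B, kh * kw * C)
  for (dj in 0:(kw - 1L)) {
    for (di in 0:(kh - 1L)) {
      slice <- x[ri + di, ci + dj, , , drop = FALSE]
      cols <- di + 1L + kh * dj + kh * kw * (0:(C - 1L))
      mat[, cols] <- matrix(slice, oh * ow * B, C)
    }
  }
  list(mat = mat, oh = oh, ow = ow)
}

# Convolution, weights (kh, kw, Cin, Cout), bias length Cout.
# pad: NULL (valid), "same", or c(top, bottom, left, right).
conv2d <- function(x, w, b = NULL, stride = 1L, pad = NULL) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  x <- conv_pad(x, kh, kw, stride, pad)
  ic <- im2col(x, kh, kw, stride)
  out <- ic$mat %*% matrix(w, kh * kw * dim(w)[3], cout)
  if (!is.null(b)) out <- out + rep(b, each = nrow(out))
  array(out, c(ic$oh, ic$ow, dim(x)[3], cout))
}

conv_pad <- function(x, kh, kw, stride, pad, value = 0) {
  if (is.null(pad)) return(x)
  if (identical(pad, "same")) {
    ph <- pad_same(dim(x)[1], kh, stride)
    pw <- pad_same(dim(x)[2], kw, stride)
    pad <- c(ph, pw)
  }
  pad_hw(x, pad[1], pad[2], pad[3], pad[4], value)
}

# Depthwise convolution, weights (kh, kw, C): shift-and-accumulate.
depthwise_conv2d <- function(x, w, b = NULL, stride = 1L, pad = "same") {
  kh <- dim(w)[1]; kw <- dim(w)[2]
  x <- conv_pad(x, kh, kw, stride, pad)
  d <- dim(x)
  oh <- (d[1] - kh) %/% stride + 1L
  ow <- (d[2] - kw) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  nr <- oh * ow * d[3]
  acc <- matrix(0, nr, d[4])
  for (dj in 0:(kw - 1L)) {
    for (di in 0:(kh - 1L)) {
      slice <- matrix(x[ri + di, ci + dj, , , drop = FALSE], nr, d[4])
      acc <- acc + slice * rep(w[di + 1L, dj + 1L, ], each = nr)
    }
  }
  if (!is.null(b)) acc <- acc + rep(b, each = nr)
  array(acc, c(oh, ow, d[3], d[4]))
}

maxpool2d <- function(x, k = 3L, stride = 2L, pad = "same") {
  x <- conv_pad(x, k, k, stride, pad, value = -Inf)
  d <- dim(x)
  oh <- (d[1] - k) %/% stride + 1L
  ow <- (d[2] - k) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  nr <- oh * ow * d[3]
  acc <- matrix(-Inf, nr, d[4])
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      acc <- pmax(acc, matrix(x[ri + di, ci + dj, , , drop = FALSE], nr, d[4]))
    }
  }
  array(acc, c(oh, ow, d[3], d[4]))
}

avgpool2d <- function(x, k = 2L, stride = k) {
  d <- dim(x)
  oh <- (d[1] - k) %/% stride + 1L
  ow <- (d[2] - k) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  nr <- oh * ow * d[3]
  acc <- matrix(0, nr, d[4])
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      acc <- acc + matrix(x[ri + di, ci + dj, , , drop = FALSE], nr, d[4])
    }
  }
  array(acc / (k * k), c(oh, ow, d[3], d[4]))
}

# Global average pool -> matrix (B x C).
global_avgpool <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  matrix(m, d[3], d[4])
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Stack topography images into a batch tensor
#'
#' @param images List of `topo_image` objects (dim `c(3, s, s)`), all the same
#'   resolution.
#' @return Array of dim `(s, s, B, 3)` as consumed by the feature extractors.
#' @export
stack_topomaps <- function(images) {
  if (inherits(images, "topo_image")) images <- list(images)
  s <- dim(images[[1]])[2]
  B <- length(images)
  out <- array(0, c(s, s, B, 3))
  for (i in seq_len(B)) {
    out[, , i, ] <- aperm(array(images[[i]], c(3, s, s)), c(2, 3, 1))
  }
  out
}
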