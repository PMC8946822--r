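make_images <- function(n, side = 32L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    structure(array(runif(3 * side * side), c(3, side, side)),
              class = "topo_image")
  })
}

test_that("LeNet-5 embeddings have length 120 and are deterministic", {
  w <- lenet5_init(3L)
  imgs <- make_images(4)
  e1 <- lenet5_embed(imgs, w)
  expect_equal(dim(e1), c(4, 120))
  expect_identical(e1, lenet5_embed(imgs, w))
  # distinct inputs map to distinct embeddings
  expect_false(isTRUE(all.equal(e1[1, ], e1[2, ])))
  # the 67 x 67 configuration keeps the 120-length contract
  w67 <- lenet5_init(3L, input_side = 67L)
  e67 <- lenet5_embed(make_images(2, side = 67L), w67)
  expect_equal(dim(e67), c(2, 120))
})

test_that("analytic gradients match central finite differences", {
  w <- lenet5_init(11L, input_side = 16L, in_channels = 1L,
                   maps = c(1L, 1L, 4L), f6 = 3L)
  set.seed(5)
  x <- array(runif(16 * 16 * 2 * 1), c(16, 16, 2, 1))
  y <- c(0L, 1L)
  lg <- lenet5_loss_grad(x, y, w)
  eps <- 1e-5
  for (nm in c("C1_w", "S2_w", "C3_w", "S4_w", "C5_w", "F6_w", "OUT_w", "S2_b")) {
    idx <- if (length(w[[nm]]) > 3) 2L else 1L
    wp <- w; wp[[nm]][idx] <- wp[[nm]][idx] + eps
    wm <- w; wm[[nm]][idx] <- wm[[nm]][idx] - eps
    fd <- (lenet5_loss_grad(x, y, wp)$loss - lenet5_loss_grad(x, y, wm)$loss) / (2 * eps)
    an <- lg$grads[[nm]][idx]
    expect_equal(an, fd, tolerance = 1e-4, label = paste("grad", nm))
  }
})

test_that("the trained softmax head separates separable embeddings", {
  set.seed(2)
  e <- rbind(matrix(rnorm(40 * 5, mean = 3), 40),
             matrix(rnorm(40 * 5, mean = -3), 40))
  y <- rep(c(1L, 0L), each = 40)
  head <- train_head(e, y, seed = 1L)
  expect_equal(mean(predict(head, e) == y), 1)
  head2 <- train_head(e, y, seed = 1L)
  expect_identical(predict(head2, e), predict(head, e))
  expect_error(train_head(e, rep(1L, 80)), "degenerate-training")
})

test_that("label-shuffled training stays at chance on held-out data", {
  set.seed(4)
  accs <- replicate(20, {
    e <- matrix(rnorm(120 * 10), 120)
    y <- sample(rep(c(0L, 1L), each = 60))
    head <- train_head(e[1:80, ], y[1:80], seed = 1L)
    mean(predict(head, e[81:120, ]) == y[81:120])
  })
  band <- 1.96 * sqrt(0.25 / (20 * 40))
  expect_lt(abs(mean(accs) - 0.5), band + 0.02)
})

test_that("GoogLeNet honours the Inception stack contracts", {
  spec <- googlenet_spec()
  expect_equal(spec$total[spec$module == "3a"], 256)
  expect_equal(spec$total[spec$module == "5b"], 1024)
  w <- googlenet_init(2L)
  # Inception(3a) on a 28 x 28 x 192 input gives 28 x 28 x 256
  x <- array(rnorm(28 * 28 * 192), c(28, 28, 1, 192))
  expect_equal(dim(inception_forward(x, w$inc3a)), c(28, 28, 1, 256))
  # full forward: 224 x 224 image -> 1024-vector at the global average pool
  img <- resize_topomap(make_images(1, side = 67L)[[1]], 224L)
  e <- googlenet_embed(list(img), w)
  expect_equal(dim(e), c(1, 1024))
  expect_true(all(is.finite(e)))
  # zero input with zero biases propagates to a zero embedding
  z <- googlenet_embed(array(0, c(224, 224, 1, 3)), w)
  expect_equal(as.numeric(z), numeric(1024))
})

test_that("EfficientNet-B0 honours the MBConv stack contracts", {
  spec <- efficientnet_b0_spec()
  expect_equal(spec$channels[9], 1280)
  s4 <- spec[spec$stage == 4, ]
  expect_equal(s4$resolution, 56)
  expect_equal(s4$channels, 40)
  expect_equal(s4$kernel, 5)
  expect_equal(s4$layers, 2)
  w <- efficientnet_b0_init(2L)
  img <- resize_topomap(make_images(1, side = 67L, seed = 2)[[1]], 224L)
  e <- efficientnet_b0_embed(list(img), w)
  expect_equal(dim(e), c(1, 1280))
  expect_true(all(is.finite(e)))
})

test_that("a suppressed squeeze-excitation gate silences the MBConv path", {
  set.seed(6)
  blk <- eegworkload:::mbconv_init(8L, 16L, 3L, 6L)
  blk$se$b2[] <- -1e9 # drive the sigmoid gate to zero
  x <- array(rnorm(8 * 8 * 2 * 8), c(8, 8, 2, 8))
  out <- mbconv_forward(x, blk, stride = 2L) # no skip: channels change
  expect_lt(max(abs(out)), 1e-8)
})
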