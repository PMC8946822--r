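test_that("thin-plate interpolation is exact at the electrodes", {
  m <- standard_montage()
  set.seed(3)
  v <- runif(14)
  at_nodes <- eegworkload:::tps_eval(m$xy, v, m$xy)
  expect_equal(as.numeric(at_nodes), v, tolerance = 1e-6)
})

test_that("rendered maps have the contracted shape and fill", {
  fv <- rnorm(42)^2
  img <- render_topomap(fv)
  expect_s3_class(img, "topo_image")
  expect_equal(dim(img), c(3, 67, 67))
  expect_true(all(is.finite(img)))
  expect_true(all(img >= 0 & img <= 1))
  # corners are outside the scalp disk: fill value is the plane minimum -> 0
  expect_equal(img[1, 1, 1], 0)
  expect_equal(img[2, 67, 67], 0)
  sc <- attr(img, "scale")
  expect_equal(dim(sc), c(3, 2))
})

test_that("a constant band plane normalises to all zeros", {
  fv <- c(rep(5, 14), rnorm(14)^2, rnorm(14)^2)
  img <- render_topomap(fv)
  expect_true(all(img[1, , ] == 0))
  raw <- render_topomap(fv, normalize = FALSE)
  g <- seq(-1, 1, length.out = 67)
  disk <- outer(g, g, function(x, y) x^2 + y^2 <= 1)
  expect_equal(matrix(raw[1, , ], 67)[disk], rep(5, sum(disk)), tolerance = 1e-6)
})

test_that("a single hot electrode produces a peak at its pixel", {
  m <- standard_montage()
  for (ch in c("F3", "P8", "O1")) {
    i <- which(m$channels == ch)
    fv <- numeric(42)
    fv[i] <- 1 # theta plane
    img <- render_topomap(fv)
    plane <- matrix(img[1, , ], 67)
    px <- electrode_pixel(m, ch)
    # some maximal pixel lies within 3 px of the electrode (the hot value can
    # tie across the electrode's nearest-neighbour annulus patch)
    peaks <- which(plane == max(plane), arr.ind = TRUE)
    d <- sqrt((peaks[, 1] - px[1])^2 + (peaks[, 2] - px[2])^2)
    expect_lte(min(d), 3)
    # and the electrode's own pixel is near-maximal (grid-snap tolerance)
    expect_gte(plane[px[1], px[2]], 0.9 * max(plane))
  }
})

test_that("rendering is equivariant to channel relabelling", {
  m <- standard_montage()
  set.seed(9)
  fv <- runif(42)
  perm <- sample(14)
  m2 <- m
  m2$channels <- m$channels[perm]
  m2$xyz <- m$xyz[perm, ]
  m2$xy <- m$xy[perm, ]
  fv2 <- c(fv[1:14][perm], fv[15:28][perm], fv[29:42][perm])
  expect_equal(unclass(render_topomap(fv, m)),
               unclass(render_topomap(fv2, m2)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("raising an electrode's value does not lower its own pixel", {
  m <- standard_montage()
  fv <- rep(0.5, 42)
  fv2 <- fv
  i <- which(m$channels == "FC6")
  fv2[i] <- 1.5
  a <- render_topomap(fv, normalize = FALSE)
  b <- render_topomap(fv2, normalize = FALSE)
  px <- electrode_pixel(m, "FC6")
  expect_gte(b[1, px[1], px[2]], a[1, px[1], px[2]])
})

test_that("resizing is shape-correct, bounded and stable", {
  fv <- rnorm(42)^2
  img <- render_topomap(fv)
  small <- resize_topomap(img, 32L)
  expect_equal(dim(small), c(3, 32, 32))
  expect_true(all(small >= 0 & small <= 1))
  big <- resize_topomap(img, 224L)
  expect_equal(dim(big), c(3, 224, 224))
  # constant plane stays constant
  cimg <- structure(array(0.7, c(3, 67, 67)), class = "topo_image")
  expect_equal(as.numeric(resize_topomap(cimg, 32L)), rep(0.7, 3 * 32 * 32))
  # 67 -> 224 -> 67 round trip of a smooth plane
  g <- seq(0, pi, length.out = 67)
  smooth <- structure(array(0, c(3, 67, 67)), class = "topo_image")
  for (b in 1:3) smooth[b, , ] <- outer(sin(g), cos(b * g / 2))^2
  back <- resize_topomap(resize_topomap(smooth, 224L), 67L)
  expect_lt(max(abs(back - smooth)), 0.05)
  expect_error(resize_topomap(img, 100L), "unsupported side")
})

test_that("non-finite features are rejected", {
  fv <- rnorm(42)
  fv[5] <- NA
  expect_error(render_topomap(fv), "finite")
})
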