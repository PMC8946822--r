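#' Render a trial's scalp topography image
#'
#' Turns one 42-dimensional band-power feature vector into a 3 x 67 x 67
#' image: one plane per band feature (theta, alpha, mean of beta and gamma).
#' Each plane interpolates the 14 electrode values over a regular grid on
#' `[-1, 1]^2`: thin-plate-spline scattered interpolation (exact at the
#' electrodes) inside the electrode convex hull, nearest-electrode value
#' between the hull and the unit scalp disk, and the plane minimum outside the
#' disk. Planes are then min-max normalised to `[0, 1]` (a zero-range plane
#' maps to all zeros) with the scale recorded.
#'
#' @param features Numeric vector of 42 features (band-major, see
#'   [feature_names()]) or a single-row `feature_set`.
#' @param montage An `electrode_montage`.
#' @param resolution Grid side in pixels (default 67).
#' @param normalize Apply per-plane min-max normalisation (default `TRUE`).
#' @return A `topo_image`: array of dim `c(3, resolution, resolution)` with
#'   attributes `scale` (per-plane min/max used for normalisation), `label`
#'   and `trial` provenance when available.
#' @export
render_topomap <- function(features, montage = standard_montage(),
                           resolution = 67, normalize = TRUE) {
  label <- NA; trial <- NA
  if (inherits(features, "feature_set") || is.data.frame(features)) {
    stopifnot(nrow(features) == 1)
    label <- features$label[1]; trial <- features$trial[1]
    features <- as.numeric(feature_matrix(features)[1, ])
  }
  if (length(features) != 42 || !all(is.finite(features))) {
    stop("render_topomap: need 42 finite feature values")
  }
  op <- topo_operator(montage, resolution)
  img <- array(0, c(3, resolution, resolution))
  scale <- matrix(NA_real_, 3, 2, dimnames = list(c("theta", "alpha", "bg"),
                                                  c("min", "max")))
  for (b in 1:3) {
    v <- features[(b - 1) * 14 + 1:14]
    plane <- numeric(resolution^2)
    plane[op$in_hull] <- op$tps_map %*% v
    if (length(op$ring)) plane[op$ring] <- v[op$nearest]
    lo <- min(plane[op$on_disk]); hi <- max(plane[op$on_disk])
    plane[!op$on_disk] <- lo
    scale[b, ] <- c(lo, hi)
    if (normalize) {
      rng <- hi - lo
      plane <- if (rng > 1e-9 * max(abs(hi), abs(lo), 1)) {
        (plane - lo) / rng
      } else {
        plane * 0 # constant field: zero-range plane maps to all zeros
      }
    }
    img[b, , ] <- matrix(plane, resolution, resolution) # [x, y] grid order
  }
  structure(img, class = "topo_image", scale = scale, label = label, trial = trial)
}

#' Render topography images for a whole feature set
#'
#' Batch version of [render_topomap()]; the interpolation operator is
#' precomputed once per (montage, resolution).
#'
#' @inheritParams render_topomap
#' @param features A `feature_set` or numeric matrix (trials x 42).
#' @return List of `topo_image`s, one per row.
#' @export
render_topomap_batch <- function(features, montage = standard_montage(),
                                 resolution = 67, normalize = TRUE) {
  labels <- NULL; trials_id <- NULL
  if (inherits(features, "feature_set") || is.data.frame(features)) {
    labels <- features$label; trials_id <- features$trial
    features <- feature_matrix(features)
  }
  lapply(seq_len(nrow(features)), function(i) {
    img <- render_topomap(as.numeric(features[i, ]), montage, resolution, normalize)
    attr(img, "label") <- if (is.null(labels)) NA else labels[i]
    attr(img, "trial") <- if (is.null(trials_id)) NA else trials_id[i]
    img
  })
}

# Cached linear rendering operator: hull pixels get a (n_hull x 14) TPS
# interpolation matrix, annulus pixels a nearest-electrode index.
.topo_cache <- new.env(parent = emptyenv())

topo_operator <- function(montage, resolution) {
  key <- paste0(resolution, ":", paste(round(montage$xy, 6), collapse = ","))
  if (!is.null(.topo_cache[[key]])) return(.topo_cache[[key]])
  xy <- montage$xy
  g <- seq(-1, 1, length.out = resolution)
  grid <- cbind(x = rep(g, times = resolution), y = rep(g, each = resolution))
  on_disk <- grid[, 1]^2 + grid[, 2]^2 <= 1
  hull <- grDevices::chull(xy)
  in_hull <- in_convex_polygon(grid, xy[hull, , drop = FALSE])
  ring <- which(on_disk & !in_hull)
  nearest <- integer(0)
  if (length(ring)) {
    d2 <- outer(grid[ring, 1], xy[, 1], "-")^2 + outer(grid[ring, 2], xy[, 2], "-")^2
    # distance ties (e.g. midline pixels between mirrored electrodes) break
    # by channel name so rendering is invariant to channel order
    rk <- rank(montage$channels)
    nearest <- apply(d2, 1, function(r) {
      cand <- which(r <= min(r) + 1e-12)
      cand[which.min(rk[cand])]
    })
  }
  op <- list(on_disk = on_disk, in_hull = in_hull, ring = ring,
             nearest = nearest,
             tps_map = tps_operator(xy, grid[in_hull, , drop = FALSE]))
  .topo_cache[[key]] <- op
  op
}

# Linear map from node values to interpolated point values: since the TPS
# system is linear in the data, field = T %*% v with T precomputable.
tps_operator <- function(nodes, points) {
  n <- nrow(nodes)
  phi <- function(r2) {
    out <- r2
    pos <- r2 > 0
    out[pos] <- 0.5 * r2[pos] * log(r2[pos]) # r^2 log r
    out
  }
  d2 <- outer(nodes[, 1], nodes[, 1], "-")^2 + outer(nodes[, 2], nodes[, 2], "-")^2
  K <- matrix(phi(d2), n, n)
  P <- cbind(1, nodes)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  Ainv_cols <- solve(A + diag(1e-10, n + 3))[, 1:n] # rhs is c(v, 0, 0, 0)
  d2p <- outer(points[, 1], nodes[, 1], "-")^2 + outer(points[, 2], nodes[, 2], "-")^2
  E <- cbind(matrix(phi(d2p), nrow(points), n), 1, points)
  E %*% Ainv_cols
}

# Thin-plate-spline interpolation through scattered nodes (exact fit).
tps_eval <- function(nodes, values, points) {
  n <- nrow(nodes)
  phi <- function(r2) {
    out <- numeric(length(r2))
    pos <- r2 > 0
    out[pos] <- 0.5 * r2[pos] * log(r2[pos]) # r^2 log r
    out
  }
  d2 <- outer(nodes[, 1], nodes[, 1], "-")^2 + outer(nodes[, 2], nodes[, 2], "-")^2
  K <- matrix(phi(d2), n, n)
  P <- cbind(1, nodes)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(values, 0, 0, 0)
  coef <- solve(A + diag(1e-10, n + 3), rhs)
  w <- coef[1:n]; a <- coef[n + 1:3]
  d2p <- outer(points[, 1], nodes[, 1], "-")^2 + outer(points[, 2], nodes[, 2], "-")^2
  matrix(phi(d2p), nrow(points), n) %*% w + a[1] + points %*% a[2:3]
}

# Vectorised point-in-convex-polygon test (vertices in hull order).
in_convex_polygon <- function(points, poly) {
  m <- nrow(poly)
  inside <- rep(TRUE, nrow(points))
  # orientation of the polygon
  area <- sum(poly[, 1] * poly[c(2:m, 1), 2] - poly[c(2:m, 1), 1] * poly[, 2])
  s <- sign(area)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cross <- (poly[j, 1] - poly[i, 1]) * (points[, 2] - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (points[, 1] - poly[i, 1])
    inside <- inside & (s * cross >= -1e-12)
  }
  inside
}

#' Resize a topography image
#'
#' Bilinear resampling of each band plane to the input side of a feature
#' extractor (32 for LeNet-5, 67 native, 224 for GoogLeNet/EfficientNet-B0).
#' Values stay within `[0, 1]` for a normalised input.
#'
#' @param image A `topo_image` (or bare `c(3, s, s)` array).
#' @param side Target side in pixels; one of 32, 67, 224.
#' @return A `topo_image` of dim `c(3, side, side)`.
#' @export
resize_topomap <- function(image, side) {
  if (!side %in% c(32L, 67L, 224L)) {
    stop("resize_topomap: unsupported side (use 32, 67 or 224)")
  }
  src <- dim(image)[2]
  out <- array(0, c(3, side, side))
  # align-corners mapping keeps constant planes constant
  pos <- if (side == 1) 1 else (seq_len(side) - 1) * (src - 1) / (side - 1) + 1
  i0 <- pmin(floor(pos), src - 1); fr <- pos - i0
  for (b in 1:3) {
    pl <- matrix(image[b, , ], src, src)
    rows <- pl[i0, , drop = FALSE] * (1 - fr) + pl[i0 + 1, , drop = FALSE] * fr
    out[b, , ] <- rows[, i0, drop = FALSE] * rep(1 - fr, each = side) +
      rows[, i0 + 1, drop = FALSE] * rep(fr, each = side)
  }
  attrs <- attributes(image)
  structure(out, class = "topo_image", scale = attrs$scale,
            label = attrs$label, trial = attrs$trial)
}

#' @export
print.topo_image <- function(x, ...) {
  cat(sprintf("<topo_image> %d x %d x %d (band planes: theta, alpha, beta+gamma mean)\n",
              dim(x)[1], dim(x)[2], dim(x)[3]))
  invisible(x)
}

#' Grid pixel nearest to an electrode
#'
#' Utility mapping an electrode's projected coordinate to its (row, col) pixel
#' on the rendering grid.
#' @param montage An `electrode_montage`.
#' @param channel Channel name.
#' @param resolution Grid side.
#' @return Integer `c(ix, iy)` indices into the plane.
#' @export
electrode_pixel <- function(montage, channel, resolution = 67) {
  xy <- montage$xy[channel, ]
  g <- seq(-1, 1, length.out = resolution)
  c(which.min(abs(g - xy[1])), which.min(abs(g - xy[2])))
}
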