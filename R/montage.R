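#' Electrode montage for the 14-channel 10-20 headset
#'
#' Builds the idealized spherical-head montage for the 14 recording sites
#' (AF3, AF4, F3, F4, F7, F8, FC5, FC6, T7, T8, P7, P8, O1, O2) of the
#' consumer headset used in the workload experiment. Positions are constructed
#' geometrically on the unit sphere from the 10-20 system definition: the
#' temporal/occipital ring lies on the equator and intermediate sites are
#' placed by spherical interpolation along the standard coronal arcs. Left and
#' right homologues are exact mirror images in the sagittal plane.
#'
#' @return An object of class `electrode_montage`: a list with
#'   `channels` (character, length 14, in the canonical order above),
#'   `xyz` (14 x 3 matrix of unit-sphere coordinates; x toward the right ear,
#'   y toward the nasion, z toward the vertex) and `xy` (14 x 2 matrix of
#'   projected coordinates, see [project_montage()]).
#' @examples
#' m <- standard_montage()
#' m$channels
#' @export
standard_montage <- function() {
  sph2xyz <- function(incl, azim) {
    i <- incl * pi / 180; a <- azim * pi / 180
    c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  slerp <- function(u, v, t) {
    omega <- acos(max(-1, min(1, sum(u * v))))
    (sin((1 - t) * omega) * u + sin(t * omega) * v) / sin(omega)
  }
  # midline and outer-ring anchors of the 10-20/10-10 construction
  AFz <- sph2xyz(72, 0); Fz <- sph2xyz(54, 0); FCz <- sph2xyz(36, 0)
  AF7 <- sph2xyz(90, -36); F7 <- sph2xyz(90, -54); FT7 <- sph2xyz(90, -72)
  T7 <- sph2xyz(90, -90); P7 <- sph2xyz(90, -126); O1 <- sph2xyz(90, -162)
  AF3 <- slerp(AFz, AF7, 0.5)
  F3 <- slerp(Fz, F7, 0.5)
  FC5 <- slerp(FCz, FT7, 0.75)
  mirror <- function(p) c(-p[1], p[2], p[3])
  left <- list(AF3 = AF3, F3 = F3, F7 = F7, FC5 = FC5, T7 = T7, P7 = P7, O1 = O1)
  xyz <- rbind(
    AF3 = left$AF3, AF4 = mirror(left$AF3),
    F3  = left$F3,  F4  = mirror(left$F3),
    F7  = left$F7,  F8  = mirror(left$F7),
    FC5 = left$FC5, FC6 = mirror(left$FC5),
    T7  = left$T7,  T8  = mirror(left$T7),
    P7  = left$P7,  P8  = mirror(left$P7),
    O1  = left$O1,  O2  = mirror(left$O1)
  )
  xyz <- xyz / sqrt(rowSums(xyz^2))
  m <- structure(
    list(channels = rownames(xyz), xyz = xyz, xy = NULL),
    class = "electrode_montage"
  )
  m$xy <- project_montage(m)
  m
}

#' Project a montage onto the unit disk
#'
#' Azimuthal-equidistant projection from the vertex: each electrode's radius is
#' proportional to its polar angle (angular distance from the vertex), scaled
#' so that the outermost electrode lies at radius 0.9. This is the standard
#' flattening used for scalp topography plots.
#'
#' @param montage An `electrode_montage`.
#' @return A 14 x 2 matrix of (x, y) coordinates inside the unit disk, rows
#'   named by channel.
#' @export
project_montage <- function(montage) {
  xyz <- montage$xyz
  polar <- acos(pmin(1, pmax(-1, xyz[, 3])))
  r <- 0.9 * polar / max(polar)
  horiz <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  horiz[horiz == 0] <- 1 # vertex electrode would sit at the origin anyway
  xy <- cbind(x = r * xyz[, 1] / horiz, y = r * xyz[, 2] / horiz)
  rownames(xy) <- montage$channels
  xy
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat("<electrode_montage> ", length(x$channels), " channels: ",
      paste(x$channels, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Canonical frequency bands (Hz)
#'
#' Half-open intervals `[lo, hi)`; the shared 8 Hz edge belongs to alpha only,
#' so the bands partition the spectrum without double counting.
#' @return Named list of `c(lo, hi)` pairs for theta, alpha, beta, gamma.
#' @export
workload_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(14, 30), gamma = c(31, 40))
}
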