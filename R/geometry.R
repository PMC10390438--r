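# Voxel geometry, in-plane rotation maps, and separable Gaussian filters.
#
# Axis convention throughout the package:
#   axis 1 (x): left-right
#   axis 2 (y): anterior-posterior, anterior surface at low y index
#   axis 3 (z): cranio-caudal, caudal at high z index
# Voxel indices are 1-based in R; voxel centers sit at (i - 0.5) * voxel_mm.

#' Voxel grid specification
#'
#' Defines the shape and voxel size of every volume in the pipeline. Voxel
#' centers are at `(i - 0.5) * voxel_mm` along each axis, so the grid spans
#' `shape * voxel_mm` millimetres.
#'
#' @param shape Integer vector of length 3, voxel counts per axis
#'   (x = left-right, y = anterior-posterior, z = cranio-caudal). Each
#'   component must be at least 8.
#' @param voxel_mm Voxel edge lengths in mm; a scalar is recycled to all
#'   three axes. All must be positive.
#' @return An object of class `grid_spec` with elements `shape`, `voxel_mm`
#'   and `extent_mm`.
#' @examples
#' g <- grid_spec(c(40, 40, 40), 4.92)
#' g$extent_mm
#' @export
grid_spec <- function(shape, voxel_mm) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)))
    stop("`shape` must be three integers")
  if (any(shape < 8L))
    stop("grid too small: every shape component must be >= 8 voxels")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("`voxel_mm` must be three positive numbers")
  structure(
    list(shape = shape, voxel_mm = voxel_mm,
         extent_mm = shape * voxel_mm),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

#' Voxel volume in millilitres
#' @param grid A `grid_spec`.
#' @return Volume of one voxel in ml (cc).
#' @keywords internal
voxel_ml <- function(grid) prod(grid$voxel_mm) / 1000

# Voxel center coordinates (mm) along one axis.
axis_centers <- function(n, vox) (seq_len(n) - 0.5) * vox

# Bilinear rotation map for the (x, y) plane about the grid center.
# Returns four flat source indices and weights per target pixel; pixels whose
# source falls outside the grid receive zero weight (zero padding).
rotation_map <- function(nx, ny, theta_deg) {
  th <- theta_deg * pi / 180
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  ti <- rep(seq_len(nx), times = ny)
  tj <- rep(seq_len(ny), each = nx)
  # source coordinates: rotate target back by -theta about center
  dxv <- ti - cx
  dyv <- tj - cy
  sx <- cos(th) * dxv + sin(th) * dyv + cx
  sy <- -sin(th) * dxv + cos(th) * dyv + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0;  fy <- sy - y0
  w00 <- (1 - fx) * (1 - fy)
  w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy
  w11 <- fx * fy
  idx <- function(xi, yi, w) {
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
    list(i = ifelse(ok, (yi - 1) * nx + xi, 1L), w = w * ok)
  }
  a <- idx(x0,      y0,      w00)
  b <- idx(x0 + 1L, y0,      w10)
  c <- idx(x0,      y0 + 1L, w01)
  d <- idx(x0 + 1L, y0 + 1L, w11)
  list(i1 = a$i, w1 = a$w, i2 = b$i, w2 = b$w,
       i3 = c$i, w3 = c$w, i4 = d$i, w4 = d$w, nx = nx, ny = ny)
}

# Apply a rotation map to a 3-D array [x, y, z]; every z-slice is rotated
# identically, so the 2-D map is applied to the (x*y) x z matricization.
apply_rotation <- function(vol, map) {
  d <- dim(vol)
  m <- matrix(vol, nrow = d[1] * d[2], ncol = d[3])
  out <- map$w1 * m[map$i1, , drop = FALSE] +
         map$w2 * m[map$i2, , drop = FALSE] +
         map$w3 * m[map$i3, , drop = FALSE] +
         map$w4 * m[map$i4, , drop = FALSE]
  array(out, dim = d)
}

# Rotate the (x, y) planes of a volume by theta degrees about the grid center.
rotate_volume_xy <- function(vol, theta_deg) {
  if (theta_deg %% 360 == 0) return(vol)
  apply_rotation(vol, rotation_map(dim(vol)[1], dim(vol)[2], theta_deg))
}

# 1-D Gaussian convolution matrix (n x n), rows renormalized to sum to 1 so
# that smoothing a field of ones returns ones and interior totals are kept.
gaussian_band_matrix <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_px))
  off <- (-r):r
  k <- exp(-off^2 / (2 * sigma_px^2))
  K <- matrix(0, n, n)
  for (o in seq_along(off)) {
    j <- seq_len(n) + off[o]
    ok <- j >= 1 & j <= n
    K[cbind(which(ok), j[ok])] <- K[cbind(which(ok), j[ok])] + k[o]
  }
  # column-normalize: each source voxel's counts are fully redistributed
  K / rep(colSums(K), each = n)
}

# Separable Gaussian blur of a 2-D matrix given FWHM in mm per axis.
blur_matrix <- function(m, fwhm_mm, pixel_mm) {
  if (all(fwhm_mm <= 0)) return(m)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 2L)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / pixel_mm
  K1 <- gaussian_band_matrix(nrow(m), sig[1])
  K2 <- gaussian_band_matrix(ncol(m), sig[2])
  K1 %*% m %*% t(K2)
}

# Separable Gaussian blur of a 3-D array given FWHM in mm per axis.
blur_volume <- function(vol, fwhm_mm, voxel_mm) {
  if (all(fwhm_mm <= 0)) return(vol)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3L)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  d <- dim(vol)
  # axis 1
  if (sig[1] > 0) {
    K <- gaussian_band_matrix(d[1], sig[1])
    vol <- array(K %*% matrix(vol, d[1], d[2] * d[3]), d)
  }
  # axis 2
  if (sig[2] > 0) {
    K <- gaussian_band_matrix(d[2], sig[2])
    v <- aperm(vol, c(2, 1, 3))
    v <- array(K %*% matrix(v, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    vol <- aperm(v, c(2, 1, 3))
  }
  # axis 3
  if (sig[3] > 0) {
    K <- gaussian_band_matrix(d[3], sig[3])
    vol <- array(matrix(vol, d[1] * d[2], d[3]) %*% t(K), d)
  }
  vol
}
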