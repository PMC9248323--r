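#' Scalar volume container
#'
#' A 3D grid of scalar values together with a voxel-to-world affine and a
#' metric label. Voxel indices are 0-based with voxel centers at integer
#' coordinates; the affine maps homogeneous voxel indices to world
#' millimetres (RAS-style, but no anatomical orientation is enforced).
#'
#' @param data numeric 3D array.
#' @param affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @param metric character label for the quantity stored (e.g. "MTR").
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, affine = diag(4), metric = "value") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine must be invertible")
  }
  structure(list(data = data, affine = affine, metric = as.character(metric)),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<scalar_volume '%s'> %d x %d x %d voxels, voxel size %.3g x %.3g x %.3g mm\n",
              x$metric, d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' Four-dimensional diffusion-weighted series
#'
#' @param data numeric 4D array (x, y, z, measurement).
#' @param affine 4x4 voxel-to-world matrix.
#' @param protocol an [acquisition_protocol()] whose number of measurements
#'   matches the 4th dimension of `data`.
#' @return an object of class `dwi_series`.
#' @export
dwi_series <- function(data, affine = diag(4), protocol) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (dim(data)[4] != length(protocol$bvals)) {
    stop("4th dimension of data (", dim(data)[4],
         ") does not match the protocol's ", length(protocol$bvals),
         " measurements")
  }
  structure(list(data = data, affine = as.matrix(affine), protocol = protocol),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_series> %d x %d x %d voxels, %d volumes, shells: %s s/mm^2\n",
              d[1], d[2], d[3], d[4],
              paste(sort(unique(round(x$protocol$bvals))), collapse = "/")))
  invisible(x)
}

# world mm -> continuous 0-based voxel coordinates (n x 3)
world_to_voxel <- function(points, affine) {
  points <- matrix(points, ncol = 3L)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(points) + inv[1:3, 4])
}

# continuous voxel -> world mm
voxel_to_world <- function(voxels, affine) {
  voxels <- matrix(voxels, ncol = 3L)
  t(affine[1:3, 1:3] %*% t(voxels) + affine[1:3, 4])
}

# shared-grid check used by every consumer of multiple volumes
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$affine - b$affine)) > 1e-6) {
    stop(what, " do not share grid shape and affine")
  }
  invisible(TRUE)
}

# Separable Gaussian smoothing of a 3D array; fwhm in mm, voxel sizes in mm.
# Kernel is truncated at 3 sigma and renormalized (zero-padding at edges
# would darken the border otherwise).
smooth_gaussian <- function(x, fwhm, voxel_size) {
  if (fwhm <= 0) return(x)
  voxel_size <- rep(voxel_size, length.out = 3L)
  out <- x
  for (ax in 1:3) {
    sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size[ax]
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r:r)^2) / (2 * sigma^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 26-neighborhood dilation of a set of 1-based linear voxel indices
dilate_voxels <- function(vox, grid_shape) {
  lin0 <- vox - 1L
  x <- lin0 %% grid_shape[1]
  y <- (lin0 %/% grid_shape[1]) %% grid_shape[2]
  z <- lin0 %/% (grid_shape[1] * grid_shape[2])
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    nx <- x + dx; ny <- y + dy; nz <- z + dz
    ok <- nx >= 0 & nx < grid_shape[1] & ny >= 0 & ny < grid_shape[2] &
      nz >= 0 & nz < grid_shape[3]
    out <- c(out, 1L + nx[ok] + grid_shape[1] * (ny[ok] + grid_shape[2] * nz[ok]))
  }
  sort(unique(out))
}

# 1D convolution along one axis with edge renormalization
convolve_axis <- function(x, k, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(1:3, axis))
  xp <- aperm(x, perm)
  n <- d[axis]
  m <- matrix(xp, nrow = n)
  r <- (length(k) - 1L) / 2L
  acc <- matrix(0, nrow = n, ncol = ncol(m))
  wt <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- (1:n) + off
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    wt[ok] <- wt[ok] + k[j]
  }
  acc <- acc / wt
  out <- array(acc, dim = d[perm])
  aperm(out, order(perm))
}
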