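#' Construct a volume
#'
#' A volume is the universal container of this package: a 3D real scalar grid
#' with a physical voxel size in Angstrom.  Particle boxes are cubic; the
#' rotation origin sits at 0-based index `floor(N/2)` on each axis.
#'
#' @param data numeric 3D array, all values finite.
#' @param voxel_size voxel edge length in Angstrom (> 0).
#' @return An object of class `volume`.
#' @export
volume <- function(data, voxel_size) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 8L))
    stop("volume box edge must be at least 8 voxels")
  if (!all(is.finite(data)))
    stop("volume data must be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  structure(list(data = data, voxel_size = voxel_size), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume %d x %d x %d, %.3f A/voxel, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], x$voxel_size, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

is_cubic <- function(vol) {
  d <- dim(vol$data)
  d[1] == d[2] && d[2] == d[3]
}

stopifnot_cubic <- function(vol) {
  if (!is_cubic(vol)) stop("volume must be cubic for this operation")
  invisible(vol)
}

#' Rotation origin of a box (0-based voxel index)
#' @param n box edge in voxels
#' @return `floor(n / 2)` per axis.
#' @export
box_center <- function(n) floor(n / 2)

#' Correlation between two volumes
#'
#' Plain Pearson correlation of voxel values, optionally restricted to a
#' real-space mask (weights in \[0, 1\]).
#'
#' @param a,b volumes of identical dimensions.
#' @param mask optional volume or array of weights.
#' @return correlation in \[-1, 1\].
#' @export
vol_cor <- function(a, b, mask = NULL) {
  va <- as.vector(if (inherits(a, "volume")) a$data else a)
  vb <- as.vector(if (inherits(b, "volume")) b$data else b)
  if (is.null(mask)) return(stats::cor(va, vb))
  w <- as.vector(if (inherits(mask, "volume")) mask$data else mask)
  sw <- sum(w)
  ma <- sum(w * va) / sw; mb <- sum(w * vb) / sw
  num <- sum(w * (va - ma) * (vb - mb))
  den <- sqrt(sum(w * (va - ma)^2) * sum(w * (vb - mb)^2))
  if (den == 0) return(0)
  num / den
}

#' Bin a volume by an integer factor (Fourier cropping)
#'
#' Downsamples by cropping the Fourier transform to the new Nyquist band.
#' Unlike block averaging, this keeps the rotation origin exactly at
#' `floor(N/2)` of the binned grid, so binned and unbinned frames share the
#' same center convention.
#'
#' @param vol a volume.
#' @param factor integer binning factor; box dimensions must be divisible.
#' @return a volume with voxel size scaled by `factor`.
#' @export
bin_volume <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  d <- dim(vol$data)
  if (any(d %% factor != 0L)) stop("dimensions not divisible by binning factor")
  nd <- d %/% factor
  Fs <- fftshift3(fft(vol$data))
  c0 <- floor(d / 2)
  idx <- lapply(1:3, function(ax) (c0[ax] - floor(nd[ax] / 2) + 1):
                  (c0[ax] - floor(nd[ax] / 2) + nd[ax]))
  Fc <- Fs[idx[[1]], idx[[2]], idx[[3]]]
  out <- Re(fft(ifftshift3(Fc), inverse = TRUE)) / prod(d)
  volume(array(out, nd), vol$voxel_size * factor)
}

#' Center-crop a volume to a smaller cubic box
#'
#' @param vol a volume.
#' @param crop_box target cubic edge in voxels (same parity as the box keeps
#'   the rotation origin aligned).
#' @export
crop_volume <- function(vol, crop_box) {
  n <- dim(vol$data)[1]
  if (crop_box > n) stop("crop_box exceeds the volume")
  if (crop_box == n) return(vol)
  lo <- box_center(n) - box_center(crop_box)
  idx <- (lo + 1):(lo + crop_box)
  volume(vol$data[idx, idx, idx], vol$voxel_size)
}

#' Spherical real-space mask
#'
#' @param n cubic box edge in voxels.
#' @param radius radius in voxels (default `n/2 - 1`).
#' @param soft soft cosine edge width in voxels.
#' @return a volume of weights in \[0, 1\] with voxel size 1.
#' @export
spherical_mask <- function(n, radius = n / 2 - 1, soft = 2) {
  c0 <- box_center(n)
  g <- seq_len(n) - 1 - c0
  r <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  m <- array(0, c(n, n, n))
  m[r <= radius - soft] <- 1
  edge <- r > radius - soft & r <= radius
  if (soft > 0) m[edge] <- 0.5 * (1 + cos(pi * (r[edge] - (radius - soft)) / soft))
  volume(m, 1)
}

#' Cylindrical mask aligned with the z axis
#'
#' @param n cubic box edge in voxels.
#' @param radius cylinder radius in voxels.
#' @param z_range 0-based inclusive voxel range `c(lo, hi)` along z;
#'   default spans the whole box.
#' @param soft soft cosine edge in voxels (radial only).
#' @return a volume of weights in \[0, 1\].
#' @export
cylinder_mask <- function(n, radius, z_range = c(0, n - 1), soft = 1) {
  c0 <- box_center(n)
  g <- seq_len(n) - 1 - c0
  r2d <- sqrt(outer(g^2, g^2, "+"))
  disk <- matrix(0, n, n)
  disk[r2d <= radius - soft] <- 1
  edge <- r2d > radius - soft & r2d <= radius
  if (soft > 0) disk[edge] <- 0.5 * (1 + cos(pi * (r2d[edge] - (radius - soft)) / soft))
  m <- array(0, c(n, n, n))
  zi <- seq(z_range[1], z_range[2]) + 1
  m[, , zi] <- rep(disk, length(zi))
  volume(m, 1)
}
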