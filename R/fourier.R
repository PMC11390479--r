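#' Missing-wedge specification
#'
#' Describes the single-axis tilt geometry of a tomogram: data are collected
#' over `+/- theta_max` degrees about the second lattice axis (y), leaving a
#' wedge of Fourier space unsampled around the beam (z) axis.
#'
#' @param theta_max half tilt range in degrees (0 < theta_max <= 90).
#' @param apodization soft cosine edge width in degrees.
#' @return an object of class `wedge_spec`.
#' @export
wedge_spec <- function(theta_max = 60, apodization = 3) {
  if (!is.numeric(theta_max) || theta_max <= 0 || theta_max > 90)
    stop("theta_max must lie in (0, 90] degrees")
  if (apodization < 0) stop("apodization must be >= 0")
  structure(list(theta_max = theta_max, tilt_axis = "y",
                 apodization = apodization), class = "wedge_spec")
}

freq_axis <- function(n) {
  i <- seq_len(n) - 1
  ifelse(i <= n / 2, i, i - n) / n
}

fftshift3 <- function(a) {
  d <- dim(a)
  s <- floor(d / 2)
  idx <- lapply(seq_along(d), function(k) c((s[k] + 1):d[k], seq_len(s[k])))
  a[idx[[1]], idx[[2]], idx[[3]]]
}

ifftshift3 <- function(a) {
  d <- dim(a)
  s <- ceiling(d / 2)
  idx <- lapply(seq_along(d), function(k) c((s[k] + 1):d[k], seq_len(s[k])))
  a[idx[[1]], idx[[2]], idx[[3]]]
}

friedel_symmetrize <- function(m) {
  d <- dim(m)
  idx <- lapply(d, function(n) c(1, n:2))
  pmin(pmax((m + m[idx[[1]], idx[[2]], idx[[3]]]) / 2, 0), 1)
}

#' Build a missing-wedge Fourier mask
#'
#' Passes Fourier voxels whose angle from the plane orthogonal to the beam
#' axis, measured in the plane perpendicular to the tilt axis (y), is within
#' `+/- theta_max`; i.e. `atan2(|kz|, |kx|) <= theta_max`.  The mask is
#' Friedel-symmetric, stored in unshifted FFT layout (DC at index \[1,1,1\]),
#' with a cosine edge of width `apodization` degrees.
#'
#' @param box_edge cubic box edge in voxels (>= 8).
#' @param voxel_size voxel size in Angstrom (recorded, does not affect angles).
#' @param spec a [wedge_spec()].
#' @return an object of class `fourier_mask` (3D array of weights in \[0,1\]).
#' @export
make_wedge_mask <- function(box_edge, voxel_size = 1, spec = wedge_spec()) {
  if (box_edge < 8) stop("box_edge must be >= 8 voxels")
  if (!inherits(spec, "wedge_spec")) stop("spec must be a wedge_spec")
  n <- box_edge
  if (spec$theta_max >= 90) {
    m <- array(1, c(n, n, n))
  } else {
    f <- freq_axis(n)
    kx <- abs(f)
    kz <- abs(f)
    ang <- atan2(rep(kz, each = n), rep(kx, times = n)) * 180 / pi  # n x n (kx, kz)
    am <- matrix(ang, n, n)
    w2 <- matrix(1, n, n)
    a0 <- spec$theta_max - spec$apodization
    w2[am > spec$theta_max] <- 0
    if (spec$apodization > 0) {
      edge <- am > a0 & am <= spec$theta_max
      w2[edge] <- 0.5 * (1 + cos(pi * (am[edge] - a0) / spec$apodization))
    }
    # broadcast over ky (second axis is the tilt axis)
    m <- aperm(array(w2, c(n, n, n)), c(1, 3, 2))
  }
  structure(list(grid = m, voxel_size = voxel_size), class = "fourier_mask")
}

#' All-pass Fourier mask
#' @param box_edge cubic box edge in voxels.
#' @param voxel_size voxel size in Angstrom.
#' @export
full_mask <- function(box_edge, voxel_size = 1) {
  structure(list(grid = array(1, rep(box_edge, 3)), voxel_size = voxel_size),
            class = "fourier_mask")
}

#' Rotate a Fourier mask with a particle orientation
#'
#' The wedge of a particle observed at orientation `e` appears, in the
#' reference frame, rotated by the inverse particle rotation.  The mask grid
#' is resampled in shifted (DC-centred) layout and re-symmetrized to keep
#' Friedel symmetry exact.
#'
#' @param mask a `fourier_mask`.
#' @param euler the particle orientation (one-row Euler data.frame).
#' @param inverse if `TRUE` (default) rotate by the inverse orientation,
#'   mapping the sample-frame wedge into the particle/reference frame.
#' @export
rotate_wedge_mask <- function(mask, euler, inverse = TRUE) {
  R <- euler_to_matrix(euler)
  # particle = wedge-filtered rotation of the map by R; rotating the particle
  # back to the reference frame carries the wedge to W(k') = W0(R k'), which
  # is rotate_array with argument t(R) in this package's convention.
  Q <- if (inverse) t(R) else R
  g <- fftshift3(mask$grid)
  g <- rotate_array(g, Q, fill = 0)
  g <- friedel_symmetrize(ifftshift3(g))
  structure(list(grid = g, voxel_size = mask$voxel_size), class = "fourier_mask")
}

radial_freq_grid <- function(n, voxel_size) {
  f <- freq_axis(n)
  fr <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+")) / voxel_size
  fr
}

#' Band-pass filter a volume
#'
#' Attenuates Fourier amplitudes outside the resolution band with cosine
#' edges.  `low_res` removes low frequencies (including the mean); `high_res`
#' removes high frequencies.  With both `NULL` the volume is returned
#' unchanged.
#'
#' @param vol a volume.
#' @param low_res low-resolution (coarse) cutoff in Angstrom, or `NULL`.
#' @param high_res high-resolution (fine) cutoff in Angstrom, or `NULL`.
#' @param soft_edge_shells cosine edge width in Fourier voxels.
#' @return the filtered volume.
#' @export
bandpass_filter <- function(vol, low_res = NULL, high_res = NULL,
                            soft_edge_shells = 2) {
  if (is.null(low_res) && is.null(high_res)) return(vol)
  if (!is.null(low_res) && low_res <= 0) stop("low_res must be positive")
  if (!is.null(high_res) && high_res <= 0) stop("high_res must be positive")
  if (!is.null(low_res) && !is.null(high_res) && low_res <= high_res)
    stop("low_res must be coarser (larger Angstrom) than high_res")
  n <- dim(vol$data)[1]
  fr <- radial_freq_grid(n, vol$voxel_size)
  df <- soft_edge_shells / (n * vol$voxel_size)
  w <- array(1, dim(vol$data))
  if (!is.null(high_res)) {
    fh <- 1 / high_res
    w[fr > fh] <- 0
    if (df > 0) {
      e <- fr > fh - df & fr <= fh
      w[e] <- 0.5 * (1 + cos(pi * (fr[e] - (fh - df)) / df))
    }
  }
  if (!is.null(low_res)) {
    fl <- 1 / low_res
    wl <- array(1, dim(vol$data))
    wl[fr < fl] <- 0
    if (df > 0) {
      e <- fr >= fl & fr < fl + df
      wl[e] <- 0.5 * (1 - cos(pi * (fr[e] - fl) / df))
    }
    w <- w * wl
  }
  out <- Re(fft(fft(vol$data) * w, inverse = TRUE)) / length(w)
  volume(out, vol$voxel_size)
}

#' Low-pass filter a volume
#' @param vol a volume.
#' @param resolution cutoff in Angstrom.
#' @param soft_edge_shells cosine edge width in Fourier voxels.
#' @export
lowpass_filter <- function(vol, resolution, soft_edge_shells = 2)
  bandpass_filter(vol, NULL, resolution, soft_edge_shells)

#' Apply a Fourier mask to a volume
#' @param vol a volume.
#' @param mask a `fourier_mask` of the same box.
#' @export
apply_fourier_mask <- function(vol, mask) {
  out <- Re(fft(fft(vol$data) * mask$grid, inverse = TRUE)) / length(mask$grid)
  volume(out, vol$voxel_size)
}

#' Symmetrize a volume over a Cn or Dn point group
#'
#' Averages the volume over the group rotations about the beam (z) axis; for
#' Dn groups the in-plane two-fold flip (180 degrees about y) doubles the
#' group.  C1 is the identity.
#'
#' @param vol cubic volume, symmetry axis along z through the box center.
#' @param group symmetry string, e.g. "C7" or "D7".
#' @return the symmetrized volume.
#' @export
symmetrize <- function(vol, group) {
  stopifnot_cubic(vol)
  g <- parse_symmetry(group)
  if (!g$dihedral && g$n == 1L) return(vol)
  acc <- array(0, dim(vol$data))
  count <- 0L
  fill <- mean(vol$data)
  for (k in seq_len(g$n) - 1) {
    for (flip in if (g$dihedral) c(FALSE, TRUE) else FALSE) {
      R <- rot_z(360 * k / g$n)
      if (flip) R <- R %*% rot_y(180)
      if (!flip && k == 0) {
        acc <- acc + vol$data
      } else {
        acc <- acc + rotate_array(vol$data, R, fill = fill)
      }
      count <- count + 1L
    }
  }
  volume(acc / count, vol$voxel_size)
}

#' Missing-wedge constrained cross-correlation
#'
#' Normalized cross-correlation of two volumes computed only over the shared
#' Fourier support (the product of the two wedge masks, DC excluded), after
#' mask-weighted zero-mean normalization of both volumes under `real_mask`.
#' The score is maximized over integer translations within `max_shift` voxels
#' and lies in \[-1, 1\] by Cauchy-Schwarz.
#'
#' @param ref,sub volumes of the same cubic box.
#' @param wedge_ref,wedge_sub `fourier_mask` objects matching the box.
#' @param real_mask real-space weight volume (default: soft spherical mask).
#' @param max_shift maximum translation searched, voxels (0 = no search).
#' @return list with `score` and `shift` (the translation of `sub` relative
#'   to `ref` at the maximum).
#' @export
constrained_cc <- function(ref, sub, wedge_ref = NULL, wedge_sub = NULL,
                           real_mask = NULL, max_shift = 0) {
  d <- dim(ref$data)
  if (!identical(d, dim(sub$data))) stop("ref and sub must share a box")
  n <- d[1]
  if (is.null(wedge_ref)) wedge_ref <- full_mask(n, ref$voxel_size)
  if (is.null(wedge_sub)) wedge_sub <- full_mask(n, sub$voxel_size)
  if (is.null(real_mask)) real_mask <- spherical_mask(n)
  m <- real_mask$data
  sw <- sum(m)
  W <- wedge_ref$grid * wedge_sub$grid
  W[1, 1, 1] <- 0
  prep <- function(v) {
    a <- m * (v$data - sum(m * v$data) / sw)
    fft(a)
  }
  Fr <- prep(ref)
  Fs <- prep(sub)
  nr <- sum(W * (Re(Fr)^2 + Im(Fr)^2))
  ns <- sum(W * (Re(Fs)^2 + Im(Fs)^2))
  if (nr <= 0 || ns <= 0)
    stop("undefined normalization: volume has zero power under the masks")
  den <- sqrt(nr * ns)
  if (max_shift == 0) {
    num <- sum(W * (Re(Fr) * Re(Fs) + Im(Fr) * Im(Fs)))
    return(list(score = num / den, shift = c(0, 0, 0)))
  }
  cc <- Re(fft(W * Conj(Fr) * Fs, inverse = TRUE)) / length(W)
  # signed circular shifts per axis
  s <- freq_axis(n) * n
  ok <- abs(s) <= max_shift
  allow <- outer(outer(ok, ok, "&"), ok, "&")
  cc[!allow] <- -Inf
  i <- which.max(cc)
  ai <- arrayInd(i, d)
  shift <- s[ai]
  list(score = cc[i] * length(W) / den, shift = as.numeric(shift))
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized complex correlation of the Fourier transforms of two
#' maps of identical box and voxel size.  Empty shells are recorded with
#' correlation 0 and `n_voxels` 0.
#'
#' @param half_a,half_b volumes.
#' @param shell_width shell width in Fourier voxels.
#' @return an `fsc_curve` data.frame with columns `shell_freq` (1/Angstrom),
#'   `corr` and `n_voxels`; attribute `nyquist` holds the Nyquist resolution.
#' @export
fsc <- function(half_a, half_b, shell_width = 1) {
  d <- dim(half_a$data)
  if (!identical(d, dim(half_b$data)) ||
      abs(half_a$voxel_size - half_b$voxel_size) > 1e-9)
    stop("half maps must share box and voxel size")
  n <- d[1]
  F1 <- fft(half_a$data)
  F2 <- fft(half_b$data)
  f <- freq_axis(n) * n
  rvox <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+"))
  shell <- as.integer(round(rvox / shell_width))
  maxs <- floor((n / 2) / shell_width)
  keep <- shell <= maxs
  shf <- factor(shell[keep], levels = 0:maxs)
  num <- tapply(Re(F1[keep]) * Re(F2[keep]) + Im(F1[keep]) * Im(F2[keep]), shf,
                sum, default = 0)
  d1 <- tapply(Re(F1[keep])^2 + Im(F1[keep])^2, shf, sum, default = 0)
  d2 <- tapply(Re(F2[keep])^2 + Im(F2[keep])^2, shf, sum, default = 0)
  nv <- tapply(rep(1, sum(keep)), shf, sum, default = 0)
  corr <- ifelse(d1 > 0 & d2 > 0, num / sqrt(d1 * d2), 0)
  out <- data.frame(shell_freq = (0:maxs) * shell_width / (n * half_a$voxel_size),
                    corr = as.numeric(corr), n_voxels = as.integer(nv))
  attr(out, "nyquist") <- 2 * half_a$voxel_size
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' Reciprocal of the spatial frequency at the first downward crossing of the
#' threshold, linearly interpolated between shells.  If the curve never drops
#' below the threshold, the Nyquist resolution is returned with attribute
#' `bound = TRUE` (the estimate is a bound, not a measurement).
#'
#' @param curve an `fsc_curve`.
#' @param threshold FSC threshold (default 0.143).
#' @return resolution in Angstrom; attribute `bound` flags a Nyquist bound.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  if (nrow(curve) == 0) stop("empty FSC curve")
  pop <- curve[curve$n_voxels > 0 & curve$shell_freq > 0, ]
  cr <- pop$corr
  fq <- pop$shell_freq
  for (i in seq_len(length(cr) - 1)) {
    if (cr[i] >= threshold && cr[i + 1] < threshold) {
      f <- fq[i] + (fq[i + 1] - fq[i]) * (cr[i] - threshold) / (cr[i] - cr[i + 1])
      return(structure(1 / f, bound = FALSE))
    }
  }
  if (length(cr) > 0 && cr[1] < threshold) {
    # never rises above threshold: no resolvable signal, report coarsest shell
    return(structure(1 / fq[1], bound = TRUE))
  }
  structure(attr(curve, "nyquist"), bound = TRUE)
}
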