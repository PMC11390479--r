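#' Euler angles (intrinsic ZYZ, degrees)
#'
#' Orientations are parameterized as intrinsic ZYZ Euler angles in degrees:
#' the rotation `Rz(rot) %*% Ry(tilt) %*% Rz(psi)` brings the reference frame
#' into the particle frame.  `tilt` lies in \[0, 180\], `rot` and `psi` in
#' \[-180, 180).
#'
#' @param rot,tilt,psi angles in degrees (vectorized).
#' @return a data.frame with columns rot, tilt, psi.
#' @export
euler <- function(rot = 0, tilt = 0, psi = 0) {
  d <- data.frame(rot = wrap180(rot), tilt = tilt, psi = wrap180(psi))
  if (any(d$tilt < -1e-9 | d$tilt > 180 + 1e-9))
    stop("tilt must lie in [0, 180] degrees")
  d
}

wrap180 <- function(a) ((a + 180) %% 360) - 180

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rot_y <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}

rot_x <- function(deg) {
  t <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3, byrow = TRUE)
}

#' Rotation matrix from ZYZ Euler angles
#'
#' @param e one-row Euler data.frame (or list with rot/tilt/psi in degrees).
#' @return 3x3 rotation matrix mapping reference-frame vectors into the
#'   particle frame.
#' @export
euler_to_matrix <- function(e) {
  rot_z(e$rot) %*% rot_y(e$tilt) %*% rot_z(e$psi)
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]; for gimbal-locked matrices
#' (`tilt` 0 or 180) the convention `psi = 0` is used.
#'
#' @param R 3x3 rotation matrix.
#' @return one-row Euler data.frame.
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct) * 180 / pi
  if (abs(ct) > 1 - 1e-10) {
    # rotation purely about z
    rot <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    if (ct < 0) rot <- -rot
    return(euler(rot, if (ct > 0) 0 else 180, 0))
  }
  rot <- atan2(R[2, 3], R[1, 3]) * 180 / pi
  psi <- atan2(R[3, 2], -R[3, 1]) * 180 / pi
  euler(rot, tilt, psi)
}

#' Compose two orientations
#'
#' Returns the Euler angles of `R(a) %*% R(b)`.
#' @param a,b one-row Euler data.frames.
#' @export
euler_compose <- function(a, b) matrix_to_euler(euler_to_matrix(a) %*% euler_to_matrix(b))

#' Invert an orientation
#' @param e one-row Euler data.frame.
#' @export
euler_inverse <- function(e) matrix_to_euler(t(euler_to_matrix(e)))

#' Geodesic angle between two orientations (degrees)
#' @param a,b one-row Euler data.frames.
#' @export
euler_distance <- function(a, b) {
  R <- euler_to_matrix(a) %*% t(euler_to_matrix(b))
  c_ <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  acos(c_) * 180 / pi
}

#' Geodesic angle between orientations modulo a symmetry group
#'
#' Smallest angular distance between `a` and `g b` over all elements `g`
#' of the point group (rotations about the particle z axis, plus the
#' in-plane flip for Dn).
#'
#' @param a,b one-row Euler data.frames.
#' @param symmetry symmetry string such as "C1", "C7" or "D7".
#' @export
euler_distance_sym <- function(a, b, symmetry = "C1") {
  g <- parse_symmetry(symmetry)
  Rb <- euler_to_matrix(b)
  best <- Inf
  for (k in seq_len(g$n) - 1) {
    for (flip in if (g$dihedral) c(FALSE, TRUE) else FALSE) {
      G <- rot_z(360 * k / g$n)
      if (flip) G <- G %*% rot_y(180)
      R <- euler_to_matrix(a) %*% t(Rb %*% G)
      c_ <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
      best <- min(best, acos(c_) * 180 / pi)
    }
  }
  best
}

parse_symmetry <- function(sym) {
  m <- regmatches(sym, regexec("^([CcDd])([0-9]+)$", sym))[[1]]
  if (length(m) != 3) stop("symmetry must be of the form Cn or Dn")
  n <- as.integer(m[3])
  if (n < 1) stop("symmetry order must be >= 1")
  list(dihedral = toupper(m[2]) == "D", n = n)
}

#' Rotate and shift a volume
#'
#' The volume is resampled so that the reference-frame content appears in the
#' particle frame: `out(x) = in(R^T (x - c - shift) + c)` with `R` the
#' [euler_to_matrix()] rotation, `c` the [box_center()], trilinear
#' interpolation, and out-of-domain voxels filled with the volume mean.
#' Equivalently, `apply_transform(map, e)` is the map as seen in orientation
#' `e`, translated by `shift` voxels.
#'
#' @param vol cubic volume.
#' @param euler one-row Euler data.frame.
#' @param shift length-3 numeric, voxels.
#' @param fill fill value for out-of-domain voxels; default the volume mean.
#' @return volume of the same dimensions.
#' @export
apply_transform <- function(vol, euler = NULL, shift = c(0, 0, 0), fill = NULL) {
  stopifnot_cubic(vol)
  R <- if (is.null(euler)) diag(3) else euler_to_matrix(euler)
  if (is.null(fill)) fill <- mean(vol$data)
  n <- dim(vol$data)[1]
  c0 <- box_center(n)
  # out(x) = in(R^T(x - c - s) + c): pass A = R^T row-major, t = -R^T s
  A <- t(R)
  tvec <- as.numeric(-A %*% shift)
  out <- .affine_resample_cpp(vol$data, dim(vol$data), as.numeric(t(A)), tvec,
                              rep(c0, 3), rep(c0, 3), fill)
  volume(out, vol$voxel_size)
}

rotate_array <- function(arr, R, fill = 0) {
  n <- dim(arr)[1]
  c0 <- box_center(n)
  A <- t(R)  # same convention as apply_transform
  .affine_resample_cpp(arr, dim(arr), as.numeric(t(A)), c(0, 0, 0),
                       rep(c0, 3), rep(c0, 3), fill)
}
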