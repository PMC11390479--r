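# Shared smooth test phantoms, built in code at test time.

# Gaussian blob at an offset from the box center (voxel units).
blob_volume <- function(n, center = c(0, 0, 0), sigma = 3, voxel_size = 2) {
  g <- seq_len(n) - 1 - box_center(n)
  x <- rep(g, times = n * n)
  y <- rep(rep(g, each = n), times = n)
  z <- rep(g, each = n * n)
  a <- exp(-((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2) /
             (2 * sigma^2))
  volume(array(a, c(n, n, n)), voxel_size)
}

# Smooth shell with a 3-fold azimuthal modulation (regularized at the axis),
# tapered to zero near the box edge.  Deliberately asymmetric under Cn, n > 1.
shell_phantom <- function(n = 32, voxel_size = 2, az_order = 3, az_amp = 0.4) {
  g <- seq_len(n) - 1 - box_center(n)
  r <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
  rxy2 <- outer(g^2, g^2, "+")
  phi <- atan2(rep(g, each = n), rep(g, times = n))
  azm <- matrix(cos(az_order * phi), n, n) * (rxy2 / (rxy2 + 36))
  az <- array(rep(azm, n), c(n, n, n))
  taper <- exp(-pmax(r - (n / 2 - 6), 0)^2 / 8)
  volume((exp(-((r - n / 4) / (n / 8))^2) * (1 + az_amp * az)) * taper,
         voxel_size)
}

# Correlation restricted to the inscribed sphere (excludes resampling fill).
cor_in_sphere <- function(a, b, margin = 2) {
  n <- dim(a$data)[1]
  vol_cor(a, b, spherical_mask(n, n / 2 - margin, 2))
}
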