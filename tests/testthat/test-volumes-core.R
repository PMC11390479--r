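test_that("wedge mask passes the full sphere at 90 degrees and rejects bad angles", {
  m <- make_wedge_mask(16, 1, wedge_spec(90, 3))
  expect_true(all(m$grid == 1))
  expect_error(wedge_spec(0), "theta_max")
  expect_error(wedge_spec(95), "theta_max")
  expect_error(make_wedge_mask(4, 1, wedge_spec(60)), "box_edge")
})

test_that("wedge mask sampled fraction matches the per-voxel angle-count oracle", {
  for (n in c(24, 32)) {
    f <- (function(i) ifelse(i <= n / 2, i, i - n) / n)(seq_len(n) - 1)
    kx <- rep(f, times = n)
    kz <- rep(f, each = n)
    disk <- sqrt(kx^2 + kz^2) <= 0.5
    for (th in c(30, 60, 75)) {
      m <- make_wedge_mask(n, 1, wedge_spec(th, 0))
      plane <- m$grid[, 1, ]  # ky = 0 slice; mask is constant along the tilt axis
      # independent oracle: count voxels by angle
      oracle <- mean((atan2(abs(kz), abs(kx)) * 180 / pi <= th)[disk])
      expect_equal(mean(plane[disk]), oracle)
      expect_lt(abs(mean(plane[disk]) - 2 * th / 180), 0.02)
    }
  }
  # default spec carries the +/-60 degree tilt span
  expect_equal(wedge_spec()$theta_max, 60)
})

test_that("wedge masks are Friedel-symmetric, also after rotation", {
  m <- make_wedge_mask(16, 2, wedge_spec(60, 3))
  inv <- function(a) a[c(1, 16:2), c(1, 16:2), c(1, 16:2)]
  expect_equal(m$grid, inv(m$grid))
  mr <- rotate_wedge_mask(m, euler(40, 55, -20))
  expect_equal(mr$grid, inv(mr$grid))
  expect_true(all(mr$grid >= 0 & mr$grid <= 1))
})

test_that("apply_transform honors identity, exact lattice rotations and round trips", {
  ph <- shell_phantom(32)
  expect_equal(apply_transform(ph, euler(0, 0, 0))$data, ph$data)
  # 90-degree rotation about z maps lattice to lattice: +x blob lands on +y
  b <- blob_volume(32, c(5, 0, 0), sigma = 2)
  v <- apply_transform(b, euler(rot = 90), fill = 0)
  peak <- arrayInd(which.max(v$data), dim(v$data)) - 1 - box_center(32)
  expect_equal(as.numeric(peak), c(0, 5, 0))
  expect_equal(max(v$data), max(b$data), tolerance = 1e-12)
  # round trip through an oblique rotation
  e <- euler(25, 40, -60)
  v2 <- apply_transform(apply_transform(ph, e), euler_inverse(e))
  expect_gt(cor_in_sphere(ph, v2), 0.99)
  bad <- list(data = array(0, c(8, 8, 10)), voxel_size = 1)
  class(bad) <- "volume"
  expect_error(apply_transform(bad, euler(0, 0, 0)), "cubic")
})

test_that("rotation by 360/7 leaves a C7-symmetrized map unchanged", {
  s7 <- symmetrize(shell_phantom(32), "C7")
  r7 <- apply_transform(s7, euler(rot = 360 / 7))
  expect_gt(cor_in_sphere(s7, r7), 0.999)
})

test_that("bandpass filter is identity without cutoffs and near-identity at Nyquist", {
  ph <- shell_phantom(24)
  expect_equal(bandpass_filter(ph)$data, ph$data)
  ny <- bandpass_filter(ph, high_res = 2 * ph$voxel_size, soft_edge_shells = 1)
  expect_gt(vol_cor(ph, ny), 0.98)
  expect_error(bandpass_filter(ph, high_res = -3), "positive")
  expect_error(bandpass_filter(ph, low_res = 10, high_res = 20), "coarser")
})

test_that("low-pass at 40 A removes high-frequency power (radial spectrum oracle)", {
  set.seed(42)
  n <- 32
  noise <- volume(array(rnorm(n^3), c(n, n, n)), 7.04)
  lp <- lowpass_filter(noise, 40)
  # oracle: radial power spectrum of the output
  F <- fft(lp$data)
  f <- (function(i) ifelse(i <= n / 2, i, i - n) / n)(seq_len(n) - 1)
  fr <- sqrt(outer(outer(f^2, f^2, "+"), f^2, "+")) / 7.04
  p <- Re(F)^2 + Im(F)^2
  expect_lt(sum(p[fr > 1 / 40]) / sum(p), 0.01)
  # mean preserved when low_res is not set
  expect_equal(mean(lp$data), mean(noise$data), tolerance = 1e-9)
})

test_that("symmetrize is idempotent and invariant under its group", {
  ph <- shell_phantom(32)
  expect_equal(symmetrize(ph, "C1")$data, ph$data)
  s7 <- symmetrize(ph, "C7")
  expect_gt(cor_in_sphere(s7, symmetrize(s7, "C7")), 0.999)
  for (k in 1:6) {
    expect_gt(cor_in_sphere(s7, apply_transform(s7, euler(rot = k * 360 / 7))),
              0.999)
  }
  d7 <- symmetrize(ph, "D7")
  flip <- apply_transform(d7, euler(tilt = 180))
  expect_gt(cor_in_sphere(d7, flip), 0.999)
})

test_that("constrained_cc scores identity and translations correctly", {
  ph <- blob_volume(32, c(1, -2, 0), sigma = 3)
  msk <- spherical_mask(32)
  cc <- constrained_cc(ph, ph, real_mask = msk)
  expect_equal(cc$score, 1, tolerance = 1e-6)
  sh <- volume(ph$data[c(31:32, 1:30), , ], ph$voxel_size)  # content moved +2 in x
  cc2 <- constrained_cc(ph, sh, real_mask = msk, max_shift = 4)
  expect_equal(cc2$shift, c(2, 0, 0))
  expect_gt(cc2$score, 0.99)
  z <- volume(array(0, c(16, 16, 16)), 1)
  expect_error(constrained_cc(z, z), "normalization")
})

test_that("constrained_cc equals the direct-space brute-force oracle", {
  set.seed(7)
  n <- 8
  m <- spherical_mask(n, 3, 1)
  for (rep in 1:4) {
    a <- volume(array(rnorm(n^3), rep(n, 3)), 1)
    b <- volume(array(rnorm(n^3), rep(n, 3)), 1)
    w1 <- make_wedge_mask(n, 1, wedge_spec(40 + 10 * rep, 0))
    w2 <- rotate_wedge_mask(w1, euler(30 * rep, 20 * rep, -15 * rep))
    got <- constrained_cc(a, b, w1, w2, m, max_shift = 2)
    # oracle: sqrt(W)-filter both masked volumes, then brute-force circular
    # real-space correlation over all shifts
    W <- w1$grid * w2$grid
    W[1, 1, 1] <- 0
    prep <- function(v) {
      mm <- m$data
      x <- mm * (v$data - sum(mm * v$data) / sum(mm))
      Re(fft(fft(x) * sqrt(W), inverse = TRUE)) / n^3
    }
    A <- prep(a)
    B <- prep(b)
    best <- -Inf
    bshift <- NULL
    for (sx in -2:2) for (sy in -2:2) for (sz in -2:2) {
      i <- ((seq_len(n) - 1 + sx) %% n) + 1
      j <- ((seq_len(n) - 1 + sy) %% n) + 1
      k <- ((seq_len(n) - 1 + sz) %% n) + 1
      sc <- sum(A * B[i, j, k]) / sqrt(sum(A^2) * sum(B^2))
      if (sc > best) {
        best <- sc
        bshift <- c(sx, sy, sz)
      }
    }
    expect_equal(got$score, best, tolerance = 1e-6)
    expect_equal(got$shift, bshift)
  }
})

test_that("constrained_cc score is invariant under global intensity scaling", {
  ph <- shell_phantom(24)
  other <- blob_volume(24, c(1, 2, -1), 4)
  w <- make_wedge_mask(24, 2, wedge_spec(60, 0))
  s1 <- constrained_cc(ph, other, w, w)$score
  s2 <- constrained_cc(ph, volume(other$data * 37.5, 2), w, w)$score
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("FSC of a map with itself is 1 in every populated shell", {
  ph <- shell_phantom(24)
  curve <- fsc(ph, ph)
  pop <- curve[curve$n_voxels > 0, ]
  expect_true(all(abs(pop$corr - 1) < 1e-9))
  expect_true(all(diff(curve$shell_freq) > 0))
})

test_that("FSC of independent white noise stays within the null bound", {
  set.seed(11)
  n <- 32
  a <- volume(array(rnorm(n^3), rep(n, 3)), 1)
  b <- volume(array(rnorm(n^3), rep(n, 3)), 1)
  curve <- fsc(a, b)
  pop <- curve[curve$n_voxels > 0 & curve$shell_freq > 0, ]
  frac_ok <- mean(abs(pop$corr) <= 3 / sqrt(pop$n_voxels))
  expect_gte(frac_ok, 0.95)
})

test_that("FSC of low-passed half maps decays near the filter resolution", {
  set.seed(12)
  n <- 32
  ph <- shell_phantom(n, voxel_size = 4)
  lp <- lowpass_filter(ph, 20)
  mk <- function() volume(lp$data + 0.05 * sd(lp$data) * array(rnorm(n^3), rep(n, 3)), 4)
  res <- resolution_at_threshold(fsc(mk(), mk()))
  expect_gt(res, 16)
  expect_lt(res, 26)
})

test_that("resolution_at_threshold interpolates and flags Nyquist bounds", {
  curve <- data.frame(shell_freq = c(0.02, 0.025), corr = c(0.5, 0.0),
                      n_voxels = c(100L, 100L))
  attr(curve, "nyquist") <- 10
  class(curve) <- c("fsc_curve", "data.frame")
  got <- resolution_at_threshold(curve, 0.143)
  expect_equal(as.numeric(got), 1 / (0.02 + 0.005 * (0.5 - 0.143) / 0.5))
  expect_false(attr(got, "bound"))
  flat <- data.frame(shell_freq = c(0.01, 0.02, 0.03), corr = c(1, 1, 1),
                     n_voxels = c(10L, 10L, 10L))
  attr(flat, "nyquist") <- 8
  class(flat) <- c("fsc_curve", "data.frame")
  got2 <- resolution_at_threshold(flat)
  expect_equal(as.numeric(got2), 8)
  expect_true(attr(got2, "bound"))
})

test_that("resolution_at_threshold is monotone in the threshold", {
  set.seed(13)
  n <- 24
  ph <- shell_phantom(n, voxel_size = 4)
  lp <- lowpass_filter(ph, 24)
  a <- volume(lp$data + 0.2 * sd(lp$data) * array(rnorm(n^3), rep(n, 3)), 4)
  b <- volume(lp$data + 0.2 * sd(lp$data) * array(rnorm(n^3), rep(n, 3)), 4)
  curve <- fsc(a, b)
  ths <- c(0.1, 0.143, 0.3, 0.5, 0.8)
  res <- vapply(ths, function(t) as.numeric(resolution_at_threshold(curve, t)),
                numeric(1))
  expect_true(all(diff(res) >= -1e-9))
})
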