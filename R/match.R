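#' Quasi-uniform orientation grid
#'
#' Samples particle-axis directions on a golden-spiral (Fibonacci) sphere and
#' in-plane spins in uniform steps, then reduces the in-plane angle modulo
#' the template's symmetry (psi range `360/n` for Cn/Dn) and, for dihedral
#' groups, restricts directions to the upper hemisphere.  The identity
#' orientation is always included.
#'
#' @param step nominal angular step in degrees (5 to 60).
#' @param symmetry template symmetry ("C1", "C7", "D7", ...).
#' @return data.frame of Euler angles with attributes `step` and `symmetry`.
#' @export
make_angular_grid <- function(step, symmetry = "C1") {
  if (step < 5 || step > 60) stop("step must lie in [5, 60] degrees")
  g <- parse_symmetry(symmetry)
  n_dir <- max(2, ceiling(41253 / step^2))  # ~sphere area / step^2 cells
  i <- seq_len(n_dir)
  zdir <- 1 - 2 * (i - 1) / (n_dir - 1)  # includes both poles
  if (g$dihedral) {
    zdir <- zdir[zdir >= -1e-9]
    i <- seq_along(zdir)
  }
  tilt <- acos(pmin(1, pmax(-1, zdir))) * 180 / pi
  rot <- wrap180((180 / pi) * pi * (1 + sqrt(5)) * i)
  rot[tilt < 1e-6 | tilt > 180 - 1e-6] <- 0
  psi_range <- 360 / g$n
  n_psi <- max(1, round(psi_range / step))
  psis <- seq(0, psi_range - psi_range / n_psi, by = psi_range / n_psi)
  out <- do.call(rbind, lapply(psis, function(p) euler(rot, tilt, rep(p, length(tilt)))))
  out <- unique(out)
  # make sure the exact identity is present
  if (!any(out$rot == 0 & out$tilt == 0 & out$psi == 0))
    out <- rbind(euler(0, 0, 0), out)
  attr(out, "step") <- step
  attr(out, "symmetry") <- symmetry
  out
}

#' Match a template against a tomogram
#'
#' FFT-based locally normalized cross-correlation of a low-passed,
#' wedge-filtered template against the tomogram under a spherical mask, for
#' every orientation of the grid; retains the per-voxel maximum score with
#' its argmax orientation.  Matching runs at a configurable binning
#' (default 2), mirroring a coarse-then-fine strategy.
#'
#' @param tomogram a volume.
#' @param template a cubic volume (box not exceeding tomogram dimensions).
#' @param wedge the tomogram's [wedge_spec()].
#' @param grid an orientation grid from [make_angular_grid()].
#' @param template_lowpass template low-pass in Angstrom (default 40).
#' @param binning matching binning factor.
#' @param mask_radius spherical template mask radius in (unbinned) voxels;
#'   default fills the template box.
#' @param template_name recorded in the result.
#' @return an object of class `score_volume` with per-voxel `scores` and
#'   `orientation` index (at the matching binning), the `grid`, `binning`
#'   and `template_name`.
#' @export
match_template <- function(tomogram, template, wedge = wedge_spec(),
                           grid = make_angular_grid(30), template_lowpass = 40,
                           binning = 2, mask_radius = NULL,
                           template_name = "template") {
  if (any(dim(template$data) > dim(tomogram$data)))
    stop("template box exceeds tomogram dimensions")
  tb <- if (binning > 1) bin_tomo(tomogram, binning) else tomogram
  tpl <- if (binning > 1) bin_volume(template, binning) else template
  tpl <- lowpass_filter(tpl, template_lowpass)
  b <- dim(tpl$data)[1]
  W0 <- make_wedge_mask(b, tpl$voxel_size, wedge)
  r_mask <- if (is.null(mask_radius)) b / 2 - 1 else mask_radius / binning
  msk <- spherical_mask(b, r_mask, 2)$data
  M <- sum(msk)
  d <- dim(tb$data)
  Ff <- fft(tb$data)
  Ff2 <- fft(tb$data^2)
  Fm <- fft(embed_box(msk, d, box_center(b)))
  loc_mean <- Re(fft(Conj(Fm) * Ff, inverse = TRUE)) / length(Ff) / M
  loc_e2 <- Re(fft(Conj(Fm) * Ff2, inverse = TRUE)) / length(Ff) / M
  loc_var <- pmax(loc_e2 - loc_mean^2, 0)
  den <- sqrt(M * loc_var)
  den_floor <- 0.05 * stats::quantile(den, 0.9)
  den <- pmax(den, den_floor)
  scores <- array(-Inf, d)
  oidx <- array(1L, d)
  for (k in seq_len(nrow(grid))) {
    tv <- apply_transform(tpl, grid[k, ], fill = mean(tpl$data))
    tv <- apply_fourier_mask(tv, W0)
    a <- msk * (tv$data - sum(msk * tv$data) / M)
    nrm <- sqrt(sum(a^2))
    if (nrm == 0) next
    a <- a / nrm
    Ft <- fft(embed_box(a, d, box_center(b)))
    num <- Re(fft(Conj(Ft) * Ff, inverse = TRUE)) / length(Ff)
    sc <- num / den
    upd <- sc > scores
    scores[upd] <- sc[upd]
    oidx[upd] <- k
  }
  structure(list(scores = scores, orientation = oidx, grid = grid,
                 binning = binning, template_name = template_name,
                 voxel_size = tb$voxel_size),
            class = "score_volume")
}

# bin a (possibly non-cubic) tomogram by block averaging
bin_tomo <- function(vol, factor) {
  d <- dim(vol$data)
  nd <- d %/% factor
  a <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                seq_len(nd[3] * factor)]
  a <- array(a, c(factor, nd[1], factor, nd[2], factor, nd[3]))
  a <- aperm(a, c(2, 4, 6, 1, 3, 5))
  dim(a) <- c(prod(nd), factor^3)
  list(data = array(rowMeans(a), nd), voxel_size = vol$voxel_size * factor)
}

# place a small box into a zero array of dims d with its center voxel at
# index (0,0,0), wrapping circularly
embed_box <- function(box_arr, d, c0) {
  out <- array(0, d)
  b <- dim(box_arr)[1]
  ix <- ((seq_len(b) - 1 - c0) %% d[1]) + 1
  iy <- ((seq_len(b) - 1 - c0) %% d[2]) + 1
  iz <- ((seq_len(b) - 1 - c0) %% d[3]) + 1
  out[ix, iy, iz] <- box_arr
  out
}

#' Extract peaks from a score volume
#'
#' Greedy descending-score non-maximum suppression with an exclusion radius,
#' optionally restricted to a region (cytosol) mask.  With `cutoff = "auto"`
#' the strict threshold is `mean + 5 sd` of the (masked) score volume; the
#' threshold is then relaxed to admit up to `overpick_factor` times the
#' strict-count hits (deliberate overpicking, to be cleaned up by later
#' classification).
#'
#' @param scores a `score_volume` from [match_template()].
#' @param cutoff numeric score cutoff, or "auto".
#' @param min_distance exclusion radius in unbinned voxels.
#' @param region_mask optional volume (unbinned tomogram grid); hits where
#'   the mask is below 0.5 are removed.
#' @param overpick_factor >= 1; only used with `cutoff = "auto"`.
#' @param tomogram_id recorded in the hit table.
#' @return data.frame of hits: `tomogram`, `x`, `y`, `z` (0-based unbinned
#'   voxels), `rot`, `tilt`, `psi`, `score`, `template`.
#' @export
extract_peaks <- function(scores, cutoff = "auto", min_distance,
                          region_mask = NULL, overpick_factor = 2,
                          tomogram_id = "tomo") {
  if (min_distance <= 0) stop("min_distance must be positive")
  bin <- scores$binning
  sc <- scores$scores
  ok <- array(TRUE, dim(sc))
  if (!is.null(region_mask)) {
    rm_b <- if (bin > 1) bin_tomo(region_mask, bin)$data else region_mask$data
    ok <- ok & (rm_b >= 0.5)
  }
  # null location/scale from the left tail of the score distribution: the
  # mean and sd (and even median/MAD) are inflated by the particles and
  # their correlation halos when they fill an appreciable volume fraction
  q <- stats::quantile(sc[ok], c(0.05, 0.25))
  mu <- q[2]
  sdv <- (q[2] - q[1]) / (stats::qnorm(0.25) - stats::qnorm(0.05))
  auto <- identical(cutoff, "auto")
  strict <- if (auto) mu + 5 * sdv else cutoff
  floor_cut <- if (auto) mu + 3 * sdv else cutoff
  cand <- which(ok & sc >= floor_cut)
  if (!length(cand)) return(empty_hits())
  ord <- cand[order(sc[cand], decreasing = TRUE)]
  pos <- arrayInd(ord, dim(sc)) - 1
  excl <- min_distance / bin
  kept <- integer(0)
  kpos <- matrix(0, 0, 3)
  for (i in seq_along(ord)) {
    p <- pos[i, ]
    if (nrow(kpos) == 0 ||
        all(rowSums((kpos - matrix(p, nrow(kpos), 3, byrow = TRUE))^2) >= excl^2)) {
      kept <- c(kept, ord[i])
      kpos <- rbind(kpos, p)
    }
  }
  ksc <- sc[kept]
  n_strict <- sum(ksc >= strict)
  # deliberate overpicking: keep everything above the relaxed threshold, but
  # when confident (strict) peaks exist, cap the list at overpick_factor
  # times their number so later cleanup stays tractable
  n_keep <- if (auto && n_strict > 0)
    min(length(kept), max(n_strict, floor(overpick_factor * n_strict)))
  else length(kept)
  if (n_keep == 0) return(empty_hits())
  sel <- seq_len(n_keep)
  oi <- scores$orientation[kept[sel]]
  data.frame(tomogram = tomogram_id,
             x = kpos[sel, 1] * bin, y = kpos[sel, 2] * bin,
             z = kpos[sel, 3] * bin,
             rot = scores$grid$rot[oi], tilt = scores$grid$tilt[oi],
             psi = scores$grid$psi[oi],
             score = ksc[sel], template = scores$template_name,
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(tomogram = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), rot = numeric(0), tilt = numeric(0),
             psi = numeric(0), score = numeric(0), template = character(0),
             stringsAsFactors = FALSE)
}

#' Merge hit lists and remove duplicates
#'
#' Unions hits from different templates on the same tomogram; any pair of
#' hits closer than `dedupe_distance` collapses to the higher-scoring member.
#' Output is sorted by descending score.
#'
#' @param hits_a,hits_b hit data.frames from [extract_peaks()].
#' @param dedupe_distance collapse radius in voxels (default: half a
#'   particle diameter is a sensible choice).
#' @return merged hit data.frame.
#' @export
merge_remove_duplicates <- function(hits_a, hits_b, dedupe_distance) {
  all_h <- rbind(hits_a, hits_b)
  if (!nrow(all_h)) return(all_h)
  all_h <- all_h[order(all_h$score, decreasing = TRUE), , drop = FALSE]
  keep <- logical(nrow(all_h))
  kpos <- matrix(0, 0, 3)
  for (i in seq_len(nrow(all_h))) {
    p <- as.numeric(all_h[i, c("x", "y", "z")])
    if (nrow(kpos) == 0 ||
        all(rowSums((kpos - matrix(p, nrow(kpos), 3, byrow = TRUE))^2) >=
              dedupe_distance^2)) {
      keep[i] <- TRUE
      kpos <- rbind(kpos, p)
    }
  }
  out <- all_h[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score a particle stack against species templates
#'
#' Stack-level template matching: every subtomogram is scored (constrained
#' cross-correlation under the sample-frame wedge) against each template over
#' an orientation grid; the best template, orientation and score per particle
#' are recorded.  This is the stack counterpart of tomogram template matching
#' used when particles are already boxed.
#'
#' @param set a [particle_set()].
#' @param templates named list of template volumes (full box).
#' @param grids named list of orientation grids, one per template (symmetry
#'   of each species).
#' @param template_lowpass template low-pass in Angstrom.
#' @param binning scoring binning.
#' @return the particle set with `template`, updated orientations and
#'   `score`; attribute `score_matrix` holds per-template best scores.
#' @export
match_stack_templates <- function(set, templates, grids,
                                  template_lowpass = 40, binning = 2) {
  n <- n_particles(set)
  prep <- prep_reference_frame(set, binning = binning, rotate = FALSE)
  best <- matrix(-Inf, n, length(templates),
                 dimnames = list(NULL, names(templates)))
  best_ori <- vector("list", length(templates))
  for (t in seq_along(templates)) {
    tpl <- bin_volume(templates[[t]], binning)
    tpl <- lowpass_filter(tpl, template_lowpass)
    grid <- grids[[names(templates)[t]]]
    sc <- score_orientations(prep, tpl, grid)
    bi <- max.col(sc$score, ties.method = "first")
    best[, t] <- sc$score[cbind(seq_len(n), bi)]
    best_ori[[t]] <- grid[bi, , drop = FALSE]
  }
  ti <- max.col(best, ties.method = "first")
  set$particles$template <- colnames(best)[ti]
  for (i in seq_len(n))
    set$particles[i, c("rot", "tilt", "psi")] <- best_ori[[ti[i]]][i, ]
  set$particles$score <- best[cbind(seq_len(n), ti)]
  attr(set, "score_matrix") <- best
  set
}
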