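#' Extract subtomograms at match hits
#'
#' Crops one cubic box per hit, centered on the hit voxel.  Hits closer than
#' half a box to the tomogram border are dropped (with a message).
#'
#' @param tomogram a volume.
#' @param hits data.frame of match hits (columns `x`, `y`, `z` 0-based
#'   voxels, `rot`, `tilt`, `psi`, `score`, optional `tomogram`, `template`).
#' @param box even box edge in voxels.
#' @param wedge the tomogram's [wedge_spec()].
#' @return a [particle_set()].
#' @export
extract_subtomograms <- function(tomogram, hits, box, wedge = wedge_spec()) {
  if (box %% 2 != 0) stop("box must be even")
  d <- dim(tomogram$data)
  c0 <- box_center(box)
  keep <- logical(nrow(hits))
  stack <- list()
  for (i in seq_len(nrow(hits))) {
    p <- round(as.numeric(hits[i, c("x", "y", "z")]))
    lo <- p - c0
    hi <- lo + box - 1
    if (any(lo < 0) || any(hi > d - 1)) next
    keep[i] <- TRUE
    stack[[length(stack) + 1]] <-
      volume(tomogram$data[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                           (lo[3] + 1):(hi[3] + 1)], tomogram$voxel_size)
  }
  if (sum(keep) == 0) stop("no hits survive border clipping")
  if (any(!keep))
    message(sum(!keep), " hit(s) dropped: closer than box/2 to the border")
  h <- hits[keep, , drop = FALSE]
  p <- data.frame(id = seq_len(nrow(h)),
                  tomogram = h$tomogram %||% "tomo",
                  x = round(h$x), y = round(h$y), z = round(h$z),
                  rot = h$rot %||% 0, tilt = h$tilt %||% 0, psi = h$psi %||% 0,
                  score = h$score %||% NA_real_,
                  dx = 0, dy = 0, dz = 0, stringsAsFactors = FALSE)
  if (!is.null(h$template)) p$template <- h$template
  particle_set(p, stack, wedge)
}

# rotate one subtomogram (with its shift) into the reference frame
particle_to_reference <- function(sub, e, s = c(0, 0, 0)) {
  Rm <- euler_to_matrix(e)
  apply_transform(sub, euler_inverse(e), shift = as.numeric(-t(Rm) %*% s))
}

#' Missing-wedge-compensated average of a particle set
#'
#' Rotates every subtomogram into the reference frame, accumulates Fourier
#' terms weighted by each particle's rotated wedge mask, and divides by the
#' summed wedge (floored at a small fraction of its maximum to avoid
#' blow-up where no orientation sampled a region).
#'
#' @param set a [particle_set()] with orientations in its table.
#' @param binning integer binning applied before averaging.
#' @param floor_frac wedge-sum floor as a fraction of its maximum.
#' @return a volume in the reference frame.
#' @export
wedge_weighted_average <- function(set, binning = 1, floor_frac = 0.01) {
  if (n_particles(set) < 1) stop("cannot average an empty particle set")
  prep <- prep_reference_frame(set, binning = binning)
  average_cached(prep, seq_len(n_particles(set)), floor_frac)
}

#' Alignment parameters
#'
#' @param binning integer binning factors, one pass per entry (coarse to
#'   fine, strictly non-increasing).
#' @param angular_range per pass: half-range of the local orientation search
#'   in degrees (>= 180 requests a global grid search).
#' @param angular_step per pass: orientation step in degrees.
#' @param max_shift per pass: translation search radius in (unbinned) voxels.
#' @param lowpass per pass: reference low-pass in Angstrom (NA = none).
#' @param symmetry symmetry applied to the reference each iteration.
#' @param iterations iterations per pass.
#' @param check_flip if `TRUE`, local passes also test each orientation
#'   composed with the in-plane 180-degree flip, resolving barrel polarity
#'   (lid up vs down) that a narrow local search cannot reach.
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(binning = c(4, 2, 1),
                             angular_range = c(180, 20, 10),
                             angular_step = c(30, 10, 5),
                             max_shift = c(8, 4, 2),
                             lowpass = c(40, 30, 25),
                             symmetry = "C1", iterations = 3,
                             check_flip = FALSE) {
  np <- length(binning)
  if (any(diff(binning) > 0)) stop("binning schedule must be non-increasing")
  pad <- function(x) rep_len(x, np)
  structure(list(binning = binning, angular_range = pad(angular_range),
                 angular_step = pad(angular_step), max_shift = pad(max_shift),
                 lowpass = pad(lowpass), symmetry = symmetry,
                 iterations = iterations, check_flip = check_flip),
            class = "alignment_params")
}

# local orientation perturbations: identity + cone of tilted axes x psi spins
local_orientation_deltas <- function(range, step) {
  if (range <= 0 || step <= 0) return(euler(0, 0, 0))
  tilts <- seq(step, range, by = step)
  rows <- list(euler(0, 0, 0))
  for (t in tilts) {
    naz <- max(4, round(2 * pi * sin(t * pi / 180) / (step * pi / 180)))
    az <- seq(0, 360 - 360 / naz, by = 360 / naz)
    for (a in az) rows[[length(rows) + 1]] <- euler(a, t, -a)
  }
  base <- do.call(rbind, rows)
  psis <- seq(-range, range, by = step)
  out <- do.call(rbind, lapply(psis, function(p) {
    b <- base
    b$psi <- wrap180(b$psi + p)
    b
  }))
  unique(out)
}

# score cached particles against a set of reference orientations;
# returns list(score matrix n x n_orient, shifts if requested)
score_orientations <- function(prep, reference, orients, max_shift = 0) {
  V <- prep$box^3
  K <- nrow(orients)
  TR <- matrix(0, V, K)
  TI <- matrix(0, V, K)
  sw <- sum(prep$mask)
  for (k in seq_len(K)) {
    tv <- apply_transform(reference, orients[k, ], fill = mean(reference$data))
    a <- prep$mask * (tv$data - sum(prep$mask * tv$data) / sw)
    Fv <- fft(a)
    TR[, k] <- Re(Fv)
    TI[, k] <- Im(Fv)
  }
  num <- prep$WFR %*% TR + prep$WFI %*% TI
  den_t <- sqrt(prep$W %*% (TR^2 + TI^2))
  sc <- num / (den_t * prep$norm)
  sc[!is.finite(sc)] <- -1
  list(score = sc, TR = TR, TI = TI)
}

#' Iteratively align particles against a reference
#'
#' Progressive-binning subtomogram alignment: per pass the particles are
#' scored under their rotated wedge masks against rotations of the
#' (symmetrized, low-passed) reference; orientations, shifts and scores are
#' updated and the reference is re-formed by wedge-weighted averaging between
#' iterations.  A pass with `angular_range >= 180` performs a global grid
#' search (particles unrotated, reference rotated over a quasi-uniform grid);
#' narrower passes search a local cone around each particle's current
#' orientation.  If the mean score drops on two consecutive iterations the
#' pass aborts, keeping the best state.
#'
#' @param set a [particle_set()].
#' @param reference starting reference volume (unbinned box).
#' @param params an [alignment_params()].
#' @param update_reference if `FALSE`, keep the reference fixed (used for
#'   half-set refinement starts and template assignment).
#' @param verbose print per-iteration mean scores.
#' @return the particle set with updated `rot`, `tilt`, `psi`, `dx..dz` and
#'   `score`; attribute `reference` holds the final average.
#' @export
align_particles <- function(set, reference, params = alignment_params(),
                            update_reference = TRUE, verbose = FALSE) {
  n <- n_particles(set)
  start_ref <- reference
  for (pass in seq_along(params$binning)) {
    bin <- params$binning[pass]
    if (set$box %% bin != 0) stop("box not divisible by binning")
    lp <- params$lowpass[pass]
    glob <- params$angular_range[pass] >= 180
    step <- params$angular_step[pass]
    orients <- if (glob) {
      make_angular_grid(step, params$symmetry)
    } else {
      d <- local_orientation_deltas(params$angular_range[pass], step)
      if (isTRUE(params$check_flip)) {
        flip <- euler(0, 180, 0)
        d <- rbind(d, do.call(rbind, lapply(seq_len(nrow(d)), function(i)
          euler_compose(d[i, ], flip))))
      }
      d
    }
    ref_pass <- NULL  # working reference at pass binning
    best_state <- set$particles
    best_mean <- -Inf
    drops <- 0L
    prev_mean <- -Inf
    iters <- if (glob) 1L else params$iterations
    prep <- if (glob) prep_reference_frame(set, binning = bin, rotate = FALSE)
            else NULL
    for (it in seq_len(iters)) {
      if (!glob) prep <- prep_reference_frame(set, binning = bin)
      if (is.null(ref_pass)) {
        ref_pass <- bin_volume(start_ref, bin)
      } else if (update_reference) {
        ref_pass <- average_cached(prep, seq_len(n))
      }
      ref <- symmetrize(ref_pass, params$symmetry)
      if (!is.na(lp)) ref <- lowpass_filter(ref, lp)
      sc <- score_orientations(prep, ref, orients)
      bi <- max.col(sc$score, ties.method = "first")
      msc <- sc$score[cbind(seq_len(n), bi)]
      for (i in seq_len(n)) {
        delta <- orients[bi[i], ]
        if (glob) {
          set$particles[i, c("rot", "tilt", "psi")] <- delta
        } else {
          e <- euler_compose(particle_euler(set, i), delta)
          set$particles[i, c("rot", "tilt", "psi")] <- e
        }
      }
      set$particles$score <- msc
      if (params$max_shift[pass] > 0)
        set <- refine_shifts(set, ref, bin, params$max_shift[pass] / bin)
      mean_sc <- mean(msc)
      if (verbose)
        message(sprintf("pass %d (bin %d) iter %d: mean score %.4f",
                        pass, bin, it, mean_sc))
      if (mean_sc > best_mean) {
        best_mean <- mean_sc
        best_state <- set$particles
      }
      if (mean_sc < prev_mean - 1e-9) drops <- drops + 1L else drops <- 0L
      if (drops >= 2L) break
      converged <- mean_sc - prev_mean < 1e-4 && it > 1
      prev_mean <- mean_sc
      if (converged) break
    }
    set$particles <- best_state
    # the refined orientations seed the next (finer) pass's working reference
    start_ref <- if (update_reference) {
      avg <- average_cached(prep_reference_frame(set, binning = bin),
                            seq_len(n))
      upscale_reference(avg, set, start_ref)
    } else start_ref
  }
  ref_full <- if (update_reference) {
    symmetrize(average_cached(prep_reference_frame(set, binning = 1),
                              seq_len(n)), params$symmetry)
  } else start_ref
  attr(set, "reference") <- ref_full
  set
}

# form the next pass's full-resolution starting reference from the refined
# orientations (a fresh unbinned average; cheap relative to the searches)
upscale_reference <- function(avg_binned, set, fallback) {
  if (dim(avg_binned$data)[1] == set$box) return(avg_binned)
  average_cached(prep_reference_frame(set, binning = 1),
                 seq_len(n_particles(set)))
}

# per-particle translation refinement against a fixed reference at one binning
refine_shifts <- function(set, ref_binned, bin, max_shift_binned) {
  n <- n_particles(set)
  b <- dim(ref_binned$data)[1]
  W0 <- make_wedge_mask(b, ref_binned$voxel_size, set$wedge)
  msk <- spherical_mask(b)
  for (i in seq_len(n)) {
    v <- set$stack[[i]]
    if (bin > 1) v <- bin_volume(v, bin)
    e <- particle_euler(set, i)
    # reference in the particle frame; wedge is the sample-frame mask
    refp <- apply_transform(ref_binned, e)
    cc <- constrained_cc(refp, v, W0, W0, msk, max_shift = max_shift_binned)
    set$particles[i, c("dx", "dy", "dz")] <- cc$shift * bin
  }
  set
}

#' Gold-standard half-set refinement
#'
#' Splits the set into two random disjoint halves (sizes differing by at most
#' one), refines each independently from a common 40 Angstrom-filtered start,
#' and reports the FSC between the two half-maps and the resolution at the
#' 0.143 threshold.
#'
#' @param set a [particle_set()] (at least 10 particles).
#' @param reference starting reference.
#' @param params an [alignment_params()].
#' @param seed split / refinement seed.
#' @return list with `half_maps`, `combined`, `fsc`, `resolution`, `halves`
#'   (the particle ids of each half).
#' @export
gold_standard_refine <- function(set, reference, params = alignment_params(),
                                 seed = 1) {
  n <- n_particles(set)
  if (n < 10) stop("gold-standard refinement needs at least 10 particles")
  set.seed(seed)
  perm <- sample(n)
  h1 <- sort(perm[seq_len(floor(n / 2))])
  h2 <- sort(perm[(floor(n / 2) + 1):n])
  start <- lowpass_filter(reference, 40)
  refine_half <- function(idx) {
    sub <- particle_set(set$particles[idx, , drop = FALSE], set$stack[idx],
                        set$wedge)
    align_particles(sub, start, params)
  }
  r1 <- refine_half(h1)
  r2 <- refine_half(h2)
  m1 <- attr(r1, "reference")
  m2 <- attr(r2, "reference")
  curve <- fsc(m1, m2)
  combined <- volume((m1$data + m2$data) / 2, m1$voxel_size)
  list(half_maps = list(m1, m2), combined = combined, fsc = curve,
       resolution = resolution_at_threshold(curve),
       halves = list(set$particles$id[h1], set$particles$id[h2]))
}

#' Pool GroEL-GroES chambers by C2 symmetry expansion
#'
#' Every football contributes two chamber records (the original orientation
#' and the orientation composed with the in-plane 180-degree flip); every
#' bullet contributes its lid-bound cis ring.  Each record is recentred along
#' its particle z axis by half the inter-ring offset so the chamber of
#' interest sits at the box center with GroES toward +z and the equator
#' toward -z.
#'
#' @param bullets,footballs aligned [particle_set()] objects (scores set).
#' @param inter_ring_offset distance between ring centers in Angstrom
#'   (default: the phantom ring height).
#' @param geom a [species_geometry()] supplying the default offset.
#' @return a [particle_set()] of chamber records
#'   (size `2 * n_footballs + n_bullets`).
#' @export
pool_chambers <- function(bullets, footballs,
                          inter_ring_offset = NULL,
                          geom = species_geometry()) {
  if (is.null(inter_ring_offset)) inter_ring_offset <- geom$ring_height
  sets <- list(bullets, footballs)
  for (s in sets) {
    if (n_particles(s) > 0 && any(is.na(s$particles$score)))
      stop("pool_chambers needs aligned inputs (scores set)")
  }
  if (abs(bullets$voxel_size - footballs$voxel_size) > 1e-9)
    stop("voxel sizes differ")
  off <- inter_ring_offset / 2 / bullets$voxel_size  # voxels
  rows <- list()
  stack <- list()
  add <- function(src, i, flip, zoff, parent) {
    p <- src$particles[i, , drop = FALSE]
    e <- particle_euler(src, i)
    if (flip) e <- euler_compose(e, euler(0, 180, 0))
    Rm <- euler_to_matrix(e)
    s <- particle_shift(src, i) + as.numeric(Rm %*% c(0, 0, zoff))
    p[, c("rot", "tilt", "psi")] <- e
    p[, c("dx", "dy", "dz")] <- s
    p$parent_id <- parent
    p$chamber <- if (flip) "flipped" else "direct"
    rows[[length(rows) + 1]] <<- p
    stack[[length(stack) + 1]] <<- src$stack[[i]]
  }
  for (i in seq_len(n_particles(bullets)))
    add(bullets, i, flip = FALSE, zoff = off,
        parent = paste0("b", bullets$particles$id[i]))
  for (i in seq_len(n_particles(footballs))) {
    add(footballs, i, flip = FALSE, zoff = off,
        parent = paste0("f", footballs$particles$id[i]))
    add(footballs, i, flip = TRUE, zoff = off,
        parent = paste0("f", footballs$particles$id[i]))
  }
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  particle_set(out, stack, bullets$wedge)
}

#' Subtract reference signal outside a kept region
#'
#' From each subtomogram, subtracts the particle-oriented, wedge-filtered
#' reference multiplied by `(1 - keep_mask)`; density inside `keep_mask`
#' (defined in the reference frame) is preserved.
#'
#' @param set a [particle_set()] aligned to `reference`.
#' @param reference reference volume in the set's reference frame.
#' @param keep_mask volume of weights in \[0, 1\], reference frame.
#' @return the particle set with modified subtomograms.
#' @export
signal_subtract <- function(set, reference, keep_mask) {
  if (!identical(dim(reference$data), dim(keep_mask$data)))
    stop("mask and reference boxes differ")
  if (!identical(dim(reference$data), dim(set$stack[[1]]$data)))
    stop("reference box does not match the stack")
  b <- set$box
  W0 <- make_wedge_mask(b, set$voxel_size, set$wedge)
  subtract_part <- volume(reference$data * (1 - keep_mask$data),
                          reference$voxel_size)
  for (i in seq_len(n_particles(set))) {
    e <- particle_euler(set, i)
    s <- particle_shift(set, i)
    pred <- apply_transform(subtract_part, e, shift = s, fill = 0)
    pred <- apply_fourier_mask(pred, W0)
    set$stack[[i]] <- volume(set$stack[[i]]$data - pred$data, set$voxel_size)
  }
  set
}
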