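#' Chaperonin and distractor phantom geometry
#'
#' Parametric geometry of the synthetic species, all lengths in Angstrom.
#' The chaperonin barrel is modeled on known GroEL dimensions (about 140 A
#' outer diameter, two stacked 73 A rings); the lid cofactor adds a 30 A
#' dome.  The trans-ring aperture takes one of two diameters: narrow
#' (about 45 A, equal to the cavity) or wide (about 65 A).
#'
#' @param outer_radius barrel outer radius.
#' @param ring_height height of one ring (two rings are stacked).
#' @param cavity_radius radius of the central cavity.
#' @param aperture_diameter_narrow,aperture_diameter_wide apical opening
#'   diameters of the narrow and wide trans-ring conformations.
#' @param lid_height height of the lid dome.
#' @param c7_bump_amplitude relative amplitude of the 7-fold azimuthal wall
#'   modulation.
#' @param ribosome_radius radius of the ribosome-like bumpy sphere.
#' @return an object of class `species_geometry`.
#' @export
species_geometry <- function(outer_radius = 70, ring_height = 73,
                             cavity_radius = 22.5,
                             aperture_diameter_narrow = 45,
                             aperture_diameter_wide = 65,
                             lid_height = 30, c7_bump_amplitude = 0.15,
                             ribosome_radius = 120) {
  if (aperture_diameter_wide <= aperture_diameter_narrow ||
      aperture_diameter_narrow <= 0)
    stop("aperture diameters must satisfy wide > narrow > 0")
  if (any(c(outer_radius, ring_height, cavity_radius, lid_height,
            ribosome_radius) <= 0))
    stop("all lengths must be positive")
  structure(list(outer_radius = outer_radius, ring_height = ring_height,
                 cavity_radius = cavity_radius,
                 aperture_diameter_narrow = aperture_diameter_narrow,
                 aperture_diameter_wide = aperture_diameter_wide,
                 lid_height = lid_height,
                 c7_bump_amplitude = c7_bump_amplitude,
                 ribosome_radius = ribosome_radius),
            class = "species_geometry")
}

#' Species state descriptor
#'
#' Describes one planted particle species: the complex type, the trans-ring
#' conformation, per-chamber substrate occupancy and whether substrate is
#' bound on the open (trans) ring.  Bullets (`ELES1`) have one lid and one
#' chamber; footballs (`ELES2`) two of each; `EL` has none; `CHAMBER` is a
#' single extracted GroEL-GroES chamber (lid up, equator down).  Following
#' the observation that the narrow trans-ring always carries apical substrate
#' density, `trans_sp_bound` is forced to `TRUE` for narrow bullets.
#'
#' @param species one of "EL", "ELES1", "ELES2", "RIBOSOME", "CHAMBER".
#' @param trans_conformation "narrow", "wide" or "na".
#' @param chamber_occupancy character vector, one entry per chamber, each of
#'   "none", "disordered" or "ordered".
#' @param trans_sp_bound logical; substrate bound at the open-ring apex.
#' @return an object of class `species_state`.
#' @export
species_state <- function(species,
                          trans_conformation = c("na", "narrow", "wide"),
                          chamber_occupancy = "none",
                          trans_sp_bound = NULL) {
  species <- match.arg(species, c("EL", "ELES1", "ELES2", "RIBOSOME", "CHAMBER"))
  trans_conformation <- match.arg(trans_conformation)
  n_chambers <- switch(species, ELES1 = 1L, ELES2 = 2L, CHAMBER = 1L, 0L)
  if (length(chamber_occupancy) != n_chambers) {
    if (n_chambers == 0L && identical(chamber_occupancy, "none")) {
      chamber_occupancy <- character(0)
    } else {
      stop(sprintf("%s has %d chamber(s); got %d occupancy label(s)",
                   species, n_chambers, length(chamber_occupancy)))
    }
  }
  if (length(chamber_occupancy))
    chamber_occupancy <- vapply(chamber_occupancy, match.arg,
                                character(1), c("none", "disordered", "ordered"),
                                USE.NAMES = FALSE)
  if (species == "ELES1") {
    if (trans_conformation == "na")
      stop("ELES1 requires a narrow or wide trans conformation")
    if (trans_conformation == "narrow") {
      trans_sp_bound <- TRUE  # narrow trans-rings carry bound substrate
    } else if (is.null(trans_sp_bound)) {
      trans_sp_bound <- FALSE
    } else if (isTRUE(trans_sp_bound)) {
      stop("trans-bound substrate is a feature of the narrow conformation")
    }
  } else {
    if (trans_conformation != "na")
      stop(sprintf("trans conformation applies to ELES1 only, not %s", species))
    trans_sp_bound <- FALSE
  }
  structure(list(species = species, trans_conformation = trans_conformation,
                 chamber_occupancy = chamber_occupancy,
                 trans_sp_bound = trans_sp_bound),
            class = "species_state")
}

state_id <- function(state) {
  paste(c(state$species, state$trans_conformation,
          state$chamber_occupancy,
          if (state$trans_sp_bound) "tsp" else "notsp"), collapse = "/")
}

gaussian_smooth <- function(arr, sigma_vox, voxel_size = 1) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  w <- 1
  for (ax in 1:3) {
    f <- freq_axis(d[ax])
    g <- exp(-2 * pi^2 * sigma_vox^2 * f^2)
    sh <- c(1, 1, 1)
    sh[ax] <- d[ax]
    w <- w * array(rep(g, each = prod(sh[seq_len(ax - 1)])), d)
  }
  Re(fft(fft(arr) * w, inverse = TRUE)) / length(arr)
}

# Gaussian blob added in place, coordinates in Angstrom relative to box center
add_blob <- function(arr, voxel_size, center, sigma, amplitude) {
  n <- dim(arr)[1]
  g <- (seq_len(n) - 1 - box_center(n)) * voxel_size
  x <- rep(g, times = n * n)
  y <- rep(rep(g, each = n), times = n)
  z <- rep(g, each = n * n)
  arr + amplitude * array(exp(-((x - center[1])^2 + (y - center[2])^2 +
                                  (z - center[3])^2) / (2 * sigma^2)), dim(arr))
}

#' Build a density map for one species state
#'
#' Rasterizes the parametric phantom: a double-annulus barrel with 7-fold
#' azimuthal wall bumps, an apical aperture funnel with the state's diameter,
#' lid domes per GroES occupancy, compact (sigma about 10 A) ordered-substrate
#' blobs near the chamber bottom or diffuse (4x wider, per-instance jittered)
#' disordered density, and a bumpy sphere for ribosome-like distractors.
#' The symmetry axis is z through the box center; for full complexes the box
#' center sits on the inter-ring equator, for `CHAMBER` at the chamber middle
#' (lid toward +z).
#'
#' @param geom a [species_geometry()].
#' @param state a [species_state()].
#' @param box cubic box edge in voxels.
#' @param voxel_size voxel size in Angstrom.
#' @param sp_jitter length-3 Angstrom offset applied to disordered substrate
#'   blobs (one draw per instance; defaults to none).
#' @param smooth_sigma edge smoothing in voxels (bandlimits the rasterization).
#' @return a volume.
#' @export
build_species_map <- function(geom, state, box = 48, voxel_size = 7.04,
                              sp_jitter = c(0, 0, 0), smooth_sigma = 0.8) {
  extent <- if (state$species == "RIBOSOME") 2 * geom$ribosome_radius
            else if (state$species == "CHAMBER") geom$ring_height + geom$lid_height
            else 2 * (geom$ring_height + geom$lid_height)
  extent <- max(extent, 2 * geom$outer_radius)
  if (box * voxel_size < 1.1 * extent)
    stop(sprintf("species extent %.0f A does not fit box %d x %.2f A with 10%% margin",
                 extent, box, voxel_size))
  n <- box
  g <- (seq_len(n) - 1 - box_center(n)) * voxel_size
  a <- array(0, c(n, n, n))
  if (state$species == "RIBOSOME") {
    r <- sqrt(outer(outer(g^2, g^2, "+"), g^2, "+"))
    a[r <= geom$ribosome_radius] <- 1
    # deterministic surface bumps on a golden spiral
    kb <- 24
    i <- seq_len(kb)
    zdir <- 1 - 2 * (i - 0.5) / kb
    rad <- sqrt(1 - zdir^2)
    phib <- pi * (1 + sqrt(5)) * i
    dirs <- cbind(rad * cos(phib), rad * sin(phib), zdir) * 0.85 * geom$ribosome_radius
    amp <- 0.6 * (1 + sin(3 * i))
    for (j in i) a <- add_blob(a, voxel_size, dirs[j, ], 0.25 * geom$ribosome_radius,
                               amp[j])
    return(volume(gaussian_smooth(a, smooth_sigma), voxel_size))
  }
  H <- geom$ring_height
  rxy <- sqrt(outer(g^2, g^2, "+"))
  phi <- atan2(rep(g, each = n), rep(g, times = n))
  bump <- geom$c7_bump_amplitude * matrix(cos(7 * phi), n, n) *
    (rxy^2 / (rxy^2 + (0.3 * geom$outer_radius)^2))
  wall2d <- 1 + bump
  # the two rings stack back to back: the lower ring's bump pattern is the
  # dyad (y-axis flip) image of the upper ring's, making full complexes
  # exactly two-fold symmetric in-plane
  wall2d_low <- 1 - bump
  ann <- rxy >= geom$cavity_radius & rxy <= geom$outer_radius
  slab <- H / 3  # aperture funnel spans the apical domains (outer ring third)
  single <- state$species == "CHAMBER"
  z_lo <- if (single) -H / 2 else -H
  z_hi <- if (single) H / 2 else H
  for (k in seq_len(n)) {
    z <- g[k]
    if (z < z_lo || z > z_hi) next
    sl <- matrix(0, n, n)
    w2 <- if (!single && z < 0) wall2d_low else wall2d
    sl[ann] <- w2[ann]
    # apical aperture funnel on open (lid-free) barrel ends
    ap_bottom <- z <= z_lo + slab
    ap_top <- z >= z_hi - slab
    d_ap <- NULL
    if (state$species == "EL" && (ap_bottom || ap_top)) {
      d_ap <- geom$aperture_diameter_narrow
    } else if (state$species == "ELES1" && ap_bottom) {
      d_ap <- switch(state$trans_conformation,
                     narrow = geom$aperture_diameter_narrow,
                     wide = geom$aperture_diameter_wide)
    }
    if (!is.null(d_ap)) sl[rxy < d_ap / 2] <- 0
    a[, , k] <- a[, , k] + sl
  }
  # lids: solid domes capping the GroES-bound ends
  lids <- switch(state$species,
                 ELES1 = "top", ELES2 = c("top", "bottom"),
                 CHAMBER = "top", character(0))
  lid_r <- 0.55 * geom$outer_radius
  for (side in lids) {
    zb <- if (side == "top") z_hi else z_lo
    for (k in seq_len(n)) {
      z <- g[k]
      h <- if (side == "top") z - zb else zb - z
      if (h < 0 || h > geom$lid_height) next
      rmax <- lid_r * sqrt(max(0, 1 - (h / geom$lid_height)^2))
      sl <- a[, , k]
      sl[rxy <= rmax] <- pmax(sl[rxy <= rmax], 1)
      a[, , k] <- sl
    }
  }
  # encapsulated substrate
  chambers <- switch(state$species,
                     ELES1 = "top", ELES2 = c("top", "bottom"),
                     CHAMBER = "center", character(0))
  sp_sigma <- 10
  occ <- state$chamber_occupancy
  for (ci in seq_along(chambers)) {
    if (!length(occ) || occ[ci] == "none") next
    zmid <- switch(chambers[ci], top = H / 2, bottom = -H / 2, center = 0)
    sgn <- if (chambers[ci] == "bottom") 1 else -1  # toward the equator
    cen <- c(0, 0, zmid + sgn * 20)
    if (occ[ci] == "ordered") {
      a <- add_blob(a, voxel_size, cen, sp_sigma, 1)
    } else {
      a <- add_blob(a, voxel_size, cen + sp_jitter, 4 * sp_sigma, 1 / 64)
    }
  }
  # substrate bound at the apical level of the open narrow ring
  if (isTRUE(state$trans_sp_bound))
    a <- add_blob(a, voxel_size, c(0, 0, -(H - 12)), sp_sigma, 1)
  volume(gaussian_smooth(a, smooth_sigma), voxel_size)
}

#' Approximate physical diameter of a species (Angstrom)
#' @param geom a [species_geometry()].
#' @param state a [species_state()].
#' @export
species_diameter <- function(geom, state) {
  if (state$species == "RIBOSOME") return(2 * geom$ribosome_radius)
  if (state$species == "CHAMBER") return(max(2 * geom$outer_radius,
                                             geom$ring_height + geom$lid_height))
  max(2 * geom$outer_radius,
      2 * geom$ring_height + 2 * geom$lid_height)
}

#' Simulation configuration
#'
#' Bundles everything the phantom simulator needs: species mixture, particle
#' count, tomogram shape, voxel size, signal-to-noise ratio (variance of
#' signal inside the particle envelope over noise variance), wedge geometry
#' and the master seed.
#'
#' @param mixture named list: each element a list with `state`
#'   (a [species_state()]) and `prop` (mixing proportion; proportions must sum
#'   to 1).
#' @param n_particles particles per tomogram (or stack size).
#' @param shape tomogram dimensions in voxels (length 3).
#' @param voxel_size Angstrom per voxel.
#' @param snr signal-to-noise variance ratio (> 0).
#' @param wedge a [wedge_spec()].
#' @param box particle box edge in voxels.
#' @param geom a [species_geometry()].
#' @param seed integer master seed.
#' @param min_distance minimum center-to-center particle distance in
#'   Angstrom; default the largest species diameter in the mixture.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(mixture, n_particles = 100,
                       shape = c(160, 160, 64), voxel_size = 7.04,
                       snr = 0.3, wedge = wedge_spec(), box = 48,
                       geom = species_geometry(), seed = 1,
                       min_distance = NULL) {
  props <- vapply(mixture, function(m) m$prop, numeric(1))
  if (abs(sum(props) - 1) > 1e-8) stop("mixture proportions must sum to 1")
  if (snr <= 0) stop("SNR must be positive")
  if (is.null(min_distance))
    min_distance <- max(vapply(mixture, function(m)
      species_diameter(geom, m$state), numeric(1)))
  structure(list(mixture = mixture, n_particles = n_particles, shape = shape,
                 voxel_size = voxel_size, snr = snr, wedge = wedge, box = box,
                 geom = geom, seed = seed, min_distance = min_distance),
            class = "sim_config")
}

#' Exact-quota mixture assignment (largest-remainder rounding)
#'
#' Deterministically converts mixing proportions into integer counts summing
#' to `n`, so planted ground truth is fixed rather than Bernoulli-sampled.
#'
#' @param props numeric proportions summing to 1.
#' @param n total count.
#' @return integer counts, same length as `props`.
#' @export
quota_counts <- function(props, n) {
  raw <- props * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

mixture_states <- function(config) {
  counts <- quota_counts(vapply(config$mixture, function(m) m$prop, numeric(1)),
                         config$n_particles)
  idx <- rep(seq_along(config$mixture), counts)
  idx
}

truth_row <- function(id, state, eul, pos = c(NA, NA, NA)) {
  data.frame(id = id, species = state$species,
             trans_conformation = state$trans_conformation,
             occupancy = paste(state$chamber_occupancy, collapse = "+"),
             trans_sp_bound = state$trans_sp_bound,
             state_label = assign_state_label(state),
             x = pos[1], y = pos[2], z = pos[3],
             rot = eul$rot, tilt = eul$tilt, psi = eul$psi,
             stringsAsFactors = FALSE)
}

random_euler <- function(k = 1) {
  euler(runif(k, -180, 180), acos(1 - 2 * runif(k)) * 180 / pi,
        runif(k, -180, 180))
}

#' Simulate a subtomogram particle stack with ground truth
#'
#' Each particle is a randomly oriented species map, filtered with the
#' sample-frame missing wedge, plus white Gaussian noise scaled so that the
#' variance ratio inside the particle envelope matches the configured SNR.
#' Species are assigned by exact quota.  Identical config and seed give
#' bit-identical output.
#'
#' @param config a [sim_config()].
#' @param n number of particles (defaults to `config$n_particles`).
#' @param seed RNG seed (defaults to `config$seed`).
#' @param aligned if `TRUE`, record the true orientation in the particle
#'   table (emulating a converged upstream alignment); the subtomograms are
#'   identical either way.
#' @return list with `stack` (list of volumes), `truth` (data.frame) and
#'   `wedge` (the sample-frame `fourier_mask`).
#' @export
simulate_particle_stack <- function(config, n = config$n_particles,
                                    seed = config$seed, aligned = TRUE) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  box <- config$box
  W0 <- make_wedge_mask(box, config$voxel_size, config$wedge)
  attr(W0, "spec") <- config$wedge
  idx <- mixture_states(modifyList(config, list(n_particles = n)))
  idx <- sample(idx)  # shuffle quota assignment
  base_maps <- lapply(config$mixture, function(m) {
    st <- m$state
    has_dis <- any(st$chamber_occupancy == "disordered")
    key_state <- st
    if (has_dis)
      key_state$chamber_occupancy[st$chamber_occupancy == "disordered"] <- "none"
    list(state = st, has_dis = has_dis,
         map = build_species_map(config$geom, key_state, box, config$voxel_size))
  })
  stack <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    bm <- base_maps[[idx[i]]]
    st <- bm$state
    map <- bm$map
    if (bm$has_dis) {
      jit <- rnorm(3, 0, 10)
      a <- map$data
      H <- config$geom$ring_height
      chambers <- switch(st$species, ELES1 = "top", ELES2 = c("top", "bottom"),
                         CHAMBER = "center", character(0))
      for (ci in seq_along(chambers)) {
        if (st$chamber_occupancy[ci] != "disordered") next
        zmid <- switch(chambers[ci], top = H / 2, bottom = -H / 2, center = 0)
        sgn <- if (chambers[ci] == "bottom") 1 else -1
        a <- add_blob(a, config$voxel_size, c(0, 0, zmid + sgn * 20) + jit, 40,
                      1 / 64)
      }
      map <- volume(a, map$voxel_size)
    }
    e <- random_euler()
    rot <- apply_transform(map, e, fill = 0)
    sig <- apply_fourier_mask(rot, W0)
    env <- rot$data > 0.1 * max(rot$data)
    vs <- var(sig$data[env])
    noise_sd <- sqrt(vs / config$snr)
    sub <- volume(sig$data + rnorm(box^3, 0, noise_sd), config$voxel_size)
    stack[[i]] <- sub
    truth[[i]] <- truth_row(i, st, e)
  }
  truth <- do.call(rbind, truth)
  if (!aligned) truth$rot <- truth$tilt <- truth$psi <- 0
  list(stack = stack, truth = truth, wedge = W0)
}

#' Simulate a full tomogram with planted particles
#'
#' Particles are placed by rejection sampling under a minimum center-to-center
#' distance, rasterized at random orientations, wedge-filtered as a whole,
#' and covered with white noise at the configured SNR.  A cytosol mask (ones
#' inside the usable volume, zero in a border margin) and the ground-truth
#' particle table are returned.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @param max_tries rejection-sampling retry cap per particle.
#' @return list with `tomogram` (volume), `truth` (data.frame with 0-based
#'   voxel positions), `cytosol_mask` (volume) and `wedge`.
#' @export
simulate_tomogram <- function(config, seed = config$seed, max_tries = 2000) {
  set.seed(seed)
  shape <- config$shape
  vs <- config$voxel_size
  box <- config$box
  idx <- mixture_states(config)
  if (length(idx)) idx <- sample(idx)
  n <- length(idx)
  min_d_vox <- config$min_distance / vs
  margin <- box / 2
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(runif(1, margin, shape[1] - 1 - margin),
             runif(1, margin, shape[2] - 1 - margin),
             runif(1, margin, shape[3] - 1 - margin))
      if (i == 1 || all(sqrt(rowSums((pos[seq_len(i - 1), , drop = FALSE] -
                                        matrix(p, i - 1, 3, byrow = TRUE))^2)) >=
                          min_d_vox)) {
        pos[i, ] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place all particles; reduce the count or the minimum distance")
  }
  maps <- lapply(config$mixture, function(m)
    build_species_map(config$geom, m$state, box, vs))
  tomo <- array(0, shape)
  truth <- vector("list", n)
  env_var <- numeric(n)
  for (i in seq_len(n)) {
    e <- random_euler()
    rot <- apply_transform(maps[[idx[i]]], e, fill = 0)
    off <- round(pos[i, ]) - box_center(box)
    .accumulate_box_cpp(tomo, dim(tomo), rot$data, dim(rot$data), as.integer(off))
    truth[[i]] <- truth_row(i, config$mixture[[idx[i]]]$state, e, round(pos[i, ]))
    env_var[i] <- var(rot$data[rot$data > 0.1 * max(rot$data)])
  }
  W0 <- make_wedge_mask_anisotropic(shape, config$wedge)
  tomo <- Re(fft(fft(tomo) * W0, inverse = TRUE)) / length(tomo)
  sig_var <- if (n > 0) mean(env_var) else 1
  noise_sd <- sqrt(sig_var / config$snr)
  tomo <- tomo + rnorm(length(tomo), 0, noise_sd)
  mask <- array(0, shape)
  m <- ceiling(margin / 2)
  mask[(m + 1):(shape[1] - m), (m + 1):(shape[2] - m), (m + 1):(shape[3] - m)] <- 1
  list(tomogram = volume(array(tomo, shape), vs),
       truth = if (n > 0) do.call(rbind, truth) else NULL,
       cytosol_mask = volume(mask, vs),
       wedge = config$wedge)
}

# wedge mask for a non-cubic grid (same bowtie geometry as make_wedge_mask)
make_wedge_mask_anisotropic <- function(shape, spec) {
  if (spec$theta_max >= 90) return(array(1, shape))
  fx <- freq_axis(shape[1])
  fz <- freq_axis(shape[3])
  ang <- atan2(abs(rep(fz, each = shape[1])), abs(rep(fx, times = shape[3]))) * 180 / pi
  am <- matrix(ang, shape[1], shape[3])
  w2 <- matrix(1, shape[1], shape[3])
  a0 <- spec$theta_max - spec$apodization
  w2[am > spec$theta_max] <- 0
  if (spec$apodization > 0) {
    edge <- am > a0 & am <= spec$theta_max
    w2[edge] <- 0.5 * (1 + cos(pi * (am[edge] - a0) / spec$apodization))
  }
  aperm(array(w2, c(shape[1], shape[3], shape[2])), c(1, 3, 2))
}
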