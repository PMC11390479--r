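#' Bootstrap specification for classification seeding
#'
#' @param n_bootstrap number of bootstrap averages (desk default 500; the
#'   full-scale protocol uses 5,000).
#' @param bootstrap_size particles per bootstrap, sampled with replacement
#'   (desk default 50; full scale 250).
#' @param k number of k-means classes.
#' @param seed RNG seed.
#' @export
bootstrap_spec <- function(n_bootstrap = 500, bootstrap_size = 50, k = 2,
                           seed = 1) {
  if (k < 2) stop("k must be >= 2")
  structure(list(n_bootstrap = n_bootstrap, bootstrap_size = bootstrap_size,
                 k = k, seed = seed), class = "bootstrap_spec")
}

#' Multireference-alignment parameters
#'
#' @param n_classes number of class references.
#' @param n_iterations iterations of multireference alignment (default 40).
#' @param temperature_factor simulated-annealing temperature factor
#'   (default 10); 0 gives pure hill climbing.
#' @param seed_set_size particles drawn to re-seed an emptied class.
#' @param focus_mask optional real-space mask volume restricting scoring.
#' @param angular_search local angular search half-range in degrees
#'   (0 = classify at fixed alignments).
#' @param binning scoring binning.
#' @param crop optional cubic crop (voxels, after binning) applied around the
#'   box center before classification; cuts the cost of every scoring and
#'   averaging step when the region of interest is smaller than the box.
#' @param denoise_lowpass Gaussian-equivalent low-pass in Angstrom applied to
#'   particles before classification (`NA` = none).
#' @param symmetry point group applied to the class references every
#'   iteration ("C1" = none).  Symmetrizing erases azimuthal missing-wedge
#'   memory from the references, preventing classes from separating on wedge
#'   orientation instead of structure.
#' @export
mra_params <- function(n_classes = 2, n_iterations = 40,
                       temperature_factor = 10, seed_set_size = 100,
                       focus_mask = NULL, angular_search = 0, binning = 1,
                       crop = NULL, denoise_lowpass = 25, symmetry = "C1") {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (temperature_factor < 0) stop("temperature_factor must be >= 0")
  structure(list(n_classes = n_classes, n_iterations = n_iterations,
                 temperature_factor = temperature_factor,
                 seed_set_size = seed_set_size, focus_mask = focus_mask,
                 angular_search = angular_search, binning = binning,
                 crop = crop, denoise_lowpass = denoise_lowpass,
                 symmetry = symmetry), class = "mra_params")
}

prep_for_classification <- function(set, params) {
  mask <- params$focus_mask
  if (!is.null(mask) && params$binning > 1)
    mask <- bin_volume(mask, params$binning)
  if (!is.null(mask) && !is.null(params$crop))
    mask <- crop_volume(mask, params$crop)
  lp <- params$denoise_lowpass
  prep_reference_frame(set, binning = params$binning, real_mask = mask,
                       lowpass = if (is.na(lp)) NULL else lp,
                       crop = params$crop)
}

#' Bootstrap-average k-means class seeding
#'
#' Forms `n_bootstrap` wedge-compensated averages of `bootstrap_size`
#' particles sampled with replacement, extracts the voxels under
#' `interior_mask` from each average as features (standardized per voxel),
#' clusters them with k-means (multi-restart, best inertia), and returns the
#' per-cluster mean of bootstrap averages as initial class references.
#'
#' @param set an aligned [particle_set()].
#' @param interior_mask volume of weights (the chamber interior).
#' @param spec a [bootstrap_spec()].
#' @param params an [mra_params()] (controls binning/denoising).
#' @param prep optional precomputed cache from an earlier call.
#' @return list with `references` (list of k volumes), `cluster` (bootstrap
#'   cluster assignment) and `prep` (the reusable Fourier cache).
#' @export
bootstrap_kmeans_seed <- function(set, interior_mask, spec = bootstrap_spec(),
                                  params = mra_params(), prep = NULL) {
  n <- n_particles(set)
  if (n < spec$bootstrap_size) stop("bootstrap_size exceeds the particle count")
  if (is.null(prep)) prep <- prep_for_classification(set, params)
  set.seed(spec$seed)
  imask <- interior_mask
  if (params$binning > 1) imask <- bin_volume(imask, params$binning)
  if (!is.null(params$crop)) imask <- crop_volume(imask, params$crop)
  sel <- which(imask$data > 0.5)
  if (!length(sel)) stop("interior mask is empty")
  draws <- vector("list", spec$n_bootstrap)
  Ind <- matrix(0, spec$n_bootstrap, n)
  for (j in seq_len(spec$n_bootstrap)) {
    idx <- sample(n, spec$bootstrap_size, replace = TRUE)
    draws[[j]] <- idx
    Ind[j, ] <- tabulate(idx, n)
  }
  feats <- average_cached_batch(prep, Ind)[, sel, drop = FALSE]
  sds <- apply(feats, 2, sd)
  sds[sds == 0] <- 1
  fz <- scale(feats, scale = sds)
  km <- kmeans(fz, centers = spec$k, nstart = 10, iter.max = 50)
  if (any(km$size == 0)) stop("degenerate clustering; use larger bootstraps")
  # mean of the cluster's bootstrap averages = multiplicity-weighted particle
  # average; this keeps the k-means contrast instead of washing it out over
  # the near-complete union of drawn particles
  refs <- lapply(seq_len(spec$k), function(cl) {
    w <- Reduce(`+`, lapply(draws[km$cluster == cl], tabulate, nbins = n))
    average_cached_weighted(prep, w / sum(km$cluster == cl))
  })
  # the weighted averages differ only by the bootstrap sampling contrast; one
  # hard assignment pass against them turns the k-means direction into
  # full-contrast class references
  sc <- score_against_refs(prep, refs)
  hard <- max.col(sc, ties.method = "first")
  if (length(unique(hard)) == spec$k) {
    refs <- lapply(seq_len(spec$k), function(cl)
      average_cached(prep, which(hard == cl)))
  }
  if (!identical(params$symmetry, "C1"))
    refs <- lapply(refs, symmetrize, group = params$symmetry)
  list(references = refs, cluster = km$cluster, prep = prep,
       centroids = km$centers)
}

#' Simulated-annealing multireference classification
#'
#' Per iteration every particle is scored (constrained cross-correlation
#' under its rotated wedge, within the focus mask) against each class
#' reference.  Assignment is stochastic hill climbing: the best class is
#' taken, but a worse class is accepted with probability
#' `exp(-delta / T_i)`, where `T_i = temperature_factor * s * (1 - i/n)`
#' decays linearly to zero (pure hill climbing at the final iteration) and
#' `s` is the initial mean inter-class score spread.  References are
#' re-averaged from their members every iteration; an emptied class is
#' re-seeded from `seed_set_size` random particles.
#'
#' @param set an aligned [particle_set()].
#' @param init_refs list of initial class reference volumes.
#' @param params an [mra_params()].
#' @param seed RNG seed.
#' @param prep optional precomputed Fourier cache.
#' @return an object of class `class_model`: `references`, `labels`,
#'   `scores` (n x K), `population_trace`.
#' @export
mra_anneal <- function(set, init_refs, params = mra_params(), seed = 1,
                       prep = NULL) {
  n <- n_particles(set)
  K <- length(init_refs)
  if (is.null(prep)) prep <- prep_for_classification(set, params)
  set.seed(seed)
  refs <- init_refs
  trace <- matrix(0L, params$n_iterations, K)
  sc <- score_against_refs(prep, refs)
  spread0 <- mean(apply(sc, 1, function(x) max(x) - min(x)))
  labels <- max.col(sc, ties.method = "first")
  b <- prep$box
  reaverage <- function(labels, it) {
    Ind <- matrix(0, K, n)
    for (k in seq_len(K)) {
      idx <- which(labels == k)
      if (!length(idx)) {
        idx <- sample(n, min(n, params$seed_set_size))
        message("class ", k, " emptied at iteration ", it,
                "; re-seeded from ", length(idx), " random particles")
      }
      Ind[k, ] <- tabulate(idx, n)
    }
    avgm <- average_cached_batch(prep, Ind)
    lapply(seq_len(K), function(k) {
      r <- volume(array(avgm[k, ], rep(b, 3)), prep$voxel_size)
      if (!identical(params$symmetry, "C1")) r <- symmetrize(r, params$symmetry)
      r
    })
  }
  for (it in seq_len(params$n_iterations)) {
    refs <- reaverage(labels, it)
    sc <- score_against_refs(prep, refs)
    Ti <- params$temperature_factor * spread0 * (1 - it / params$n_iterations)
    if (K > 1) {
      # stochastic hill climbing: propose a random other class, accept if it
      # scores better, otherwise with probability exp(-delta/T)
      prop <- (labels - 1L + sample.int(K - 1, n, replace = TRUE)) %% K + 1L
      delta <- sc[cbind(seq_len(n), labels)] - sc[cbind(seq_len(n), prop)]
      acc <- delta <= 0
      if (Ti > 0) acc <- acc | (runif(n) < exp(-delta / Ti))
      labels[acc] <- prop[acc]
    }
    trace[it, ] <- tabulate(labels, K)
  }
  if (all(tabulate(labels, K) > 0)) refs <- reaverage(labels, params$n_iterations)
  sc <- score_against_refs(prep, refs)
  labels <- max.col(sc, ties.method = "first")
  structure(list(references = refs, labels = labels, scores = sc,
                 population_trace = trace),
            class = "class_model")
}

# deterministic seed derivation (Lehmer step), kept below 2^31
derive_seed <- function(master, i) {
  (as.double(master %% 2147483647L) * 48271 + i * 8191) %% 2147483647
}

#' Repeated-run consensus classification
#'
#' Runs the bootstrap-k-means + annealed-MRA protocol `n_repeats` times with
#' independently derived seeds, matches class labels across runs by
#' maximizing reference-to-reference correlation over label permutations, and
#' retains only particles assigned the same matched label in every run.
#'
#' @param set an aligned [particle_set()].
#' @param interior_mask feature/scoring mask (chamber interior).
#' @param params an [mra_params()].
#' @param spec a [bootstrap_spec()].
#' @param n_repeats independent classification rounds (default 5).
#' @param master_seed seed from which per-run seeds derive.
#' @return an object of class `consensus_result`: `label_matrix` (n x
#'   n_repeats, matched), `labels` (consensus label, NA where runs disagree),
#'   `retained` (particle ids), `retained_idx`, `class_counts`, `references`
#'   (per-class wedge-compensated averages over the retained particles) and
#'   `runs` (the per-run class models).
#' @export
consensus_classify <- function(set, interior_mask, params = mra_params(),
                               spec = bootstrap_spec(), n_repeats = 5,
                               master_seed = 1) {
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  n <- n_particles(set)
  K <- params$n_classes
  if (is.null(params$focus_mask)) params$focus_mask <- interior_mask
  prep <- prep_for_classification(set, params)
  runs <- vector("list", n_repeats)
  lab <- matrix(NA_integer_, n, n_repeats)
  for (r in seq_len(n_repeats)) {
    sp <- spec
    sp$seed <- derive_seed(master_seed, 2 * r)
    seeding <- bootstrap_kmeans_seed(set, interior_mask, sp, params, prep = prep)
    runs[[r]] <- mra_anneal(set, seeding$references, params,
                            seed = derive_seed(master_seed, 2 * r + 1),
                            prep = prep)
    lab[, r] <- runs[[r]]$labels
  }
  # match labels of runs 2..R onto run 1 by reference correlation
  perms <- permutations_of(K)
  for (r in seq(2, n_repeats)) {
    cm <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K))
      cm[i, j] <- vol_cor(runs[[1]]$references[[i]], runs[[r]]$references[[j]])
    tot <- vapply(perms, function(p) sum(cm[cbind(seq_len(K), p)]), numeric(1))
    best <- max(tot)
    cand <- which(tot >= best - 1e-6)
    if (length(cand) > 1)
      message("ambiguous label matching in run ", r,
              "; deterministic tie-break by lowest permutation index")
    p <- perms[[min(cand)]]
    inv <- integer(K)
    inv[p] <- seq_len(K)
    lab[, r] <- inv[lab[, r]]
  }
  agree <- apply(lab, 1, function(x) all(x == x[1]))
  labels <- ifelse(agree, lab[, 1], NA_integer_)
  retained_idx <- which(agree)
  refs <- lapply(seq_len(K), function(k) {
    idx <- retained_idx[labels[retained_idx] == k]
    if (length(idx)) average_cached(prep, idx) else runs[[1]]$references[[k]]
  })
  structure(list(label_matrix = lab, labels = labels,
                 retained = set$particles$id[retained_idx],
                 retained_idx = retained_idx,
                 class_counts = tabulate(labels[retained_idx], K),
                 references = refs, runs = runs),
            class = "consensus_result")
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

#' Focused conformational classification of the trans ring
#'
#' Separates narrow from wide trans-ring conformations: every (aligned)
#' complex is recentred along its particle z axis onto the trans apical
#' region, the box is cropped around it, and two-class consensus
#' classification runs under a disk-shaped mask covering the aperture and
#' the apical substrate position, with C7-symmetrized class references.
#'
#' @param set an aligned [particle_set()] of full complexes (equator at the
#'   box center, lid toward +z).
#' @param params an [mra_params()]; `focus_mask`, `crop` and `symmetry` are
#'   set by this function.
#' @param geom a [species_geometry()] used to place the mask.
#' @param spec a [bootstrap_spec()].
#' @param n_repeats,master_seed as in [consensus_classify()].
#' @param focus optional explicit focus mask volume (full box, reference
#'   frame); when given, no recentering or cropping is applied.
#' @return a `consensus_result`.
#' @export
focused_classify <- function(set, params = mra_params(), geom = species_geometry(),
                             spec = bootstrap_spec(), n_repeats = 5,
                             master_seed = 1, focus = NULL) {
  if (!is.null(focus)) {
    if (sum(focus$data) == 0) stop("focus mask is empty")
    params$focus_mask <- focus
    return(consensus_classify(set, focus, params, spec, n_repeats, master_seed))
  }
  vs <- set$voxel_size
  # recentre each record on the trans apical level (just above the open end)
  z_apical <- -(geom$ring_height - 12)
  zoff <- z_apical / vs
  for (i in seq_len(n_particles(set))) {
    R <- euler_to_matrix(particle_euler(set, i))
    set$particles[i, c("dx", "dy", "dz")] <-
      particle_shift(set, i) + as.numeric(R %*% c(0, 0, zoff))
  }
  crop <- min(set$box, 24)
  rad <- 0.55 * geom$outer_radius / vs
  zw <- round(28 / vs)
  c0 <- box_center(crop)
  imask_c <- cylinder_mask(crop, rad, c(c0 - zw, c0 + zw), 1)$data
  m <- array(0, rep(set$box, 3))
  lo <- box_center(set$box) - box_center(crop)
  idx <- (lo + 1):(lo + crop)
  m[idx, idx, idx] <- imask_c
  params$binning <- 1
  params$crop <- crop
  params$symmetry <- "C7"
  if (is.na(params$denoise_lowpass)) params$denoise_lowpass <- 25
  consensus_classify(set, volume(m, vs), params, spec, n_repeats, master_seed)
}

#' Chamber interior mask
#'
#' Cylinder of the cavity radius spanning the chamber interior of a
#' chamber-centred box (equatorial floor to just below the lid base), the
#' region where encapsulated substrate density lives.  Used as the feature
#' and scoring mask for occupancy classification.
#'
#' @param box box edge in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param geom a [species_geometry()].
#' @export
chamber_interior_mask <- function(box, voxel_size, geom = species_geometry()) {
  H <- geom$ring_height
  c0 <- box_center(box)
  k_lo <- max(0, round(-0.48 * H / voxel_size + c0))
  k_hi <- min(box - 1, round(0.2 * H / voxel_size + c0))
  cylinder_mask(box, geom$cavity_radius / voxel_size, c(k_lo, k_hi), 1)
}

#' Disk mask over the apical third of the open ring
#'
#' A flat disk spanning the apical third of the trans (lower) ring of an
#' equator-centred complex, used for focused conformational classification.
#'
#' @param box box edge in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param geom a [species_geometry()].
#' @export
apical_disk_mask <- function(box, voxel_size, geom = species_geometry()) {
  H <- geom$ring_height
  z_lo <- -H
  z_hi <- -H + H / 3
  c0 <- box_center(box)
  k_lo <- max(0, round(z_lo / voxel_size + c0))
  k_hi <- min(box - 1, round(z_hi / voxel_size + c0))
  cylinder_mask(box, geom$outer_radius / voxel_size, c(k_lo, k_hi), 1)
}

#' Register class maps modulo the 7-fold symmetry
#'
#' For each class map, finds the multiple `m` of `360/n` degrees about the z
#' axis that maximizes correlation with the reference, and returns the
#' rotated map together with `m`.  Exact ties resolve to the smallest `m`.
#'
#' @param class_maps list of volumes.
#' @param reference reference volume.
#' @param n symmetry order (default 7).
#' @return list of lists with `map`, `m` and `correlation`.
#' @export
register_c7_classes <- function(class_maps, reference, n = 7) {
  msk <- spherical_mask(dim(reference$data)[1])
  lapply(class_maps, function(mp) {
    cors <- vapply(0:(n - 1), function(m) {
      vol_cor(apply_transform(mp, euler(rot = m * 360 / n)), reference, msk)
    }, numeric(1))
    m <- which(cors >= max(cors) - 1e-9)[1] - 1
    list(map = if (m == 0) mp else apply_transform(mp, euler(rot = m * 360 / n)),
         m = m, correlation = cors[m + 1])
  })
}
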