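#' Study protocols
#'
#' High-level runners reproducing the study designs end to end on synthetic
#' cohorts: species-split recovery (asymmetric vs symmetric complexes),
#' trans-ring aperture measurement, chamber-occupancy recovery and the
#' ribosome-abundance cross-check.  Each runs the full measurement pipeline
#' (simulation, matching/alignment, classification, measurement) from a
#' single seed.
#'
#' @name protocols
NULL

#' Recover the asymmetric:symmetric complex split from a synthetic cohort
#'
#' Simulates `n` bullet/football particles at the given mixing proportion
#' (exact quota), template-matches every subtomogram against a bullet
#' reference over a C7 orientation grid, refines orientations locally with
#' polarity (flip) checking, then separates the species by two-class
#' bootstrap-seeded annealed consensus classification focused on the trans
#' region, where one species has an open ring and the other a lid.
#'
#' @param n cohort size.
#' @param p_asym planted proportion of asymmetric (bullet) complexes.
#' @param snr simulation signal-to-noise variance ratio.
#' @param seed master seed.
#' @param n_bootstrap,bootstrap_size bootstrap seeding scale.
#' @param n_repeats consensus repeats.
#' @param geom a [species_geometry()].
#' @return list with `pct_asymmetric` (percentage among retained particles),
#'   `retained`, `n`, `accuracy_vs_truth` and the `consensus_result`.
#' @export
protocol_species_split <- function(n = 1000, p_asym = 0.6, snr = 0.3, seed = 1,
                                   n_bootstrap = 500, bootstrap_size = 50,
                                   n_repeats = 5, geom = species_geometry()) {
  mix <- list(
    ELES1 = list(state = species_state("ELES1", "wide", "disordered"),
                 prop = p_asym),
    ELES2 = list(state = species_state("ELES2",
                                       chamber_occupancy = c("none", "none")),
                 prop = 1 - p_asym))
  cfg <- sim_config(mix, box = 48, snr = snr, seed = derive_seed(seed, 1))
  sim <- simulate_particle_stack(cfg, n = n)
  set <- stack_to_particle_set(sim, keep_orientations = FALSE)
  tpl <- build_species_map(geom, species_state("ELES1", "wide", "none"),
                           48, cfg$voxel_size)
  set <- match_stack_templates(set, list(ELES1 = tpl),
                               list(ELES1 = make_angular_grid(15, "C7")),
                               template_lowpass = 40, binning = 2)
  pl <- alignment_params(binning = 2, angular_range = 12, angular_step = 4,
                         max_shift = 0, lowpass = 35, symmetry = "C7",
                         iterations = 2, check_flip = TRUE)
  set <- align_particles(set, tpl, pl, update_reference = FALSE)
  fmask <- trans_region_mask(set$box, cfg$voxel_size, geom)
  params <- mra_params(2, 40, 10, binning = 2, denoise_lowpass = 30)
  spec <- bootstrap_spec(n_bootstrap, min(bootstrap_size, n),
                         seed = derive_seed(seed, 2))
  res <- consensus_classify(set, fmask, params, spec, n_repeats,
                            master_seed = derive_seed(seed, 3))
  ic <- bin_volume(fmask, 2)$data
  dens <- vapply(res$references, function(r) mean(r$data * ic), numeric(1))
  bullet_class <- which.min(dens)  # open trans ring = least density
  ri <- res$retained_idx
  truth_asym <- sim$truth$species == "ELES1"
  list(pct_asymmetric = 100 * mean(res$labels[ri] == bullet_class),
       retained = length(ri), n = n,
       accuracy_vs_truth = mean((res$labels[ri] == bullet_class) ==
                                  truth_asym[ri]),
       bullet_class = bullet_class, consensus = res)
}

#' Cylindrical mask over the trans-ring region of a full complex
#'
#' Covers the open (lower) barrel end plus the zone a second lid would
#' occupy; the region where asymmetric and symmetric complexes differ.
#'
#' @param box box edge in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param geom a [species_geometry()].
#' @export
trans_region_mask <- function(box, voxel_size, geom = species_geometry()) {
  c0 <- box_center(box)
  H <- geom$ring_height
  k_lo <- max(0, round((-(H + geom$lid_height + 5)) / voxel_size + c0))
  k_hi <- round((-0.75 * H) / voxel_size + c0)
  m <- cylinder_mask(box, 0.7 * geom$outer_radius / voxel_size,
                     c(k_lo, k_hi), 1)
  volume(m$data, voxel_size)
}

#' Measure the trans-ring aperture of an aligned synthetic cohort
#'
#' Simulates randomly oriented bullet particles with the requested trans-ring
#' conformation, aligns them from scratch (global C7 grid search, then local
#' refinement) against a 40 Angstrom-filtered template, averages with C7
#' symmetry, and measures the aperture with the azimuthal half-max rule.
#'
#' @param n cohort size.
#' @param conformation "narrow" or "wide".
#' @param snr signal-to-noise ratio.
#' @param seed master seed.
#' @param geom a [species_geometry()].
#' @return list with `aperture` (Angstrom), `average` (the C7 map) and the
#'   aligned set.
#' @export
protocol_aperture <- function(n = 200, conformation = "narrow", snr = 0.3,
                              seed = 3, geom = species_geometry()) {
  st <- species_state("ELES1", conformation, "none")
  mix <- list(s = list(state = st, prop = 1))
  cfg <- sim_config(mix, box = 48, snr = snr, seed = derive_seed(seed, 1))
  sim <- simulate_particle_stack(cfg, n = n)
  set <- stack_to_particle_set(sim, keep_orientations = FALSE)
  tpl <- build_species_map(geom, st, 48, cfg$voxel_size)
  params <- alignment_params(binning = c(2, 2), angular_range = c(180, 12),
                             angular_step = c(16, 4), max_shift = c(0, 0),
                             lowpass = c(40, 30), symmetry = "C7",
                             iterations = 2)
  set <- align_particles(set, lowpass_filter(tpl, 40), params)
  avg <- symmetrize(attr(set, "reference"), "C7")
  list(aperture = aperture_diameter(avg, geom), average = avg, set = set)
}

#' Recover the ordered-substrate chamber fraction
#'
#' Simulates aligned single-chamber subtomograms at the given ordered
#' fraction (exact quota), classifies them with bootstrap-average k-means
#' seeding followed by repeated annealed multireference alignment with
#' consensus retention, and reports the ordered-class percentage among
#' retained chambers.
#'
#' @param n cohort size.
#' @param p_ordered planted ordered fraction.
#' @param snr signal-to-noise ratio.
#' @param seed master seed.
#' @param n_bootstrap,bootstrap_size bootstrap seeding scale.
#' @param n_repeats consensus repeats.
#' @param geom a [species_geometry()].
#' @return list with `pct_ordered`, `retained`, `accuracy_vs_truth` and the
#'   `consensus_result`.
#' @export
protocol_occupancy <- function(n = 1000, p_ordered = 0.4, snr = 0.3, seed = 5,
                               n_bootstrap = 500, bootstrap_size = 50,
                               n_repeats = 5, geom = species_geometry()) {
  mix <- list(
    o = list(state = species_state("CHAMBER", chamber_occupancy = "ordered"),
             prop = p_ordered),
    u = list(state = species_state("CHAMBER", chamber_occupancy = "disordered"),
             prop = 1 - p_ordered))
  cfg <- sim_config(mix, box = 32, snr = snr, seed = derive_seed(seed, 1))
  sim <- simulate_particle_stack(cfg, n = n)
  set <- stack_to_particle_set(sim)
  imask <- chamber_interior_mask(32, cfg$voxel_size, geom)
  params <- mra_params(2, 40, 10, binning = 1, crop = 22, denoise_lowpass = 25)
  spec <- bootstrap_spec(n_bootstrap, min(bootstrap_size, n),
                         seed = derive_seed(seed, 2))
  res <- consensus_classify(set, imask, params, spec, n_repeats,
                            master_seed = derive_seed(seed, 3))
  ic <- crop_volume(imask, 22)$data > 0.5
  dens <- vapply(res$references, function(r) mean(r$data[ic]), numeric(1))
  ordered_class <- which.max(dens)
  ri <- res$retained_idx
  truth_ord <- sim$truth$state_label == "chamber_ordered"
  list(pct_ordered = 100 * mean(res$labels[ri] == ordered_class),
       retained = length(ri),
       accuracy_vs_truth = mean((res$labels[ri] == ordered_class) ==
                                  truth_ord[ri]),
       ordered_class = ordered_class, consensus = res)
}

#' Recover the ribosome-to-chaperonin abundance ratio from tomograms
#'
#' Simulates tomograms planting chaperonin and ribosome phantoms at an exact
#' quota, template-matches both species with automatic cutoffs, removes
#' cross-template duplicates at the physical contact distance, and reports
#' per-tomogram hit ratios and their median.
#'
#' @param n_tomo number of tomograms.
#' @param chap_per_tomo,ribo_per_tomo planted counts per tomogram.
#' @param snr signal-to-noise ratio.
#' @param seed master seed (per-tomogram seeds derive from it).
#' @param shape tomogram dimensions in voxels.
#' @param geom a [species_geometry()].
#' @return list with `median_ratio`, `ratios`, and per-tomogram hit counts.
#' @export
protocol_ribosome_ratio <- function(n_tomo = 5, chap_per_tomo = 2,
                                    ribo_per_tomo = 46, snr = 0.3, seed = 10,
                                    shape = c(288, 288, 96),
                                    geom = species_geometry()) {
  n <- chap_per_tomo + ribo_per_tomo
  mix <- list(
    ELES1 = list(state = species_state("ELES1", "wide", "disordered"),
                 prop = chap_per_tomo / n),
    RIBOSOME = list(state = species_state("RIBOSOME"),
                    prop = ribo_per_tomo / n))
  tpl_b <- build_species_map(geom, species_state("ELES1", "wide", "none"),
                             48, 7.04)
  tpl_r <- build_species_map(geom, species_state("RIBOSOME"), 48, 7.04)
  d_chap <- species_diameter(geom, species_state("ELES1", "wide", "none"))
  d_ribo <- species_diameter(geom, species_state("RIBOSOME"))
  counts <- data.frame(tomogram = integer(0), chap = integer(0),
                       ribo = integer(0))
  for (t in seq_len(n_tomo)) {
    cfg <- sim_config(mix, n_particles = n, shape = shape, snr = snr,
                      box = 48, seed = derive_seed(seed, t),
                      min_distance = 0.95 * (d_chap + d_ribo) / 2)
    sim <- simulate_tomogram(cfg)
    sv_b <- match_template(sim$tomogram, tpl_b, cfg$wedge,
                           make_angular_grid(24, "C7"), 40, 2,
                           template_name = "ELES1")
    sv_r <- match_template(sim$tomogram, tpl_r, cfg$wedge,
                           make_angular_grid(60, "C1"), 40, 2,
                           template_name = "RIBOSOME")
    h_b <- extract_peaks(sv_b, "auto", 0.8 * d_chap / cfg$voxel_size,
                         sim$cytosol_mask, tomogram_id = paste0("tomo_", t))
    h_r <- extract_peaks(sv_r, "auto", 0.8 * d_ribo / cfg$voxel_size,
                         sim$cytosol_mask, tomogram_id = paste0("tomo_", t))
    # collapse radius strictly below the physical contact distance, so true
    # neighbours at minimum separation are never deduped away
    merged <- merge_remove_duplicates(h_b, h_r,
                                      0.85 * 0.5 * (d_chap + d_ribo) /
                                        cfg$voxel_size)
    # settle each surviving hit's species by comparing both templates'
    # local score maxima at that position
    merged$template <- relabel_by_scores(merged, list(ELES1 = sv_b,
                                                      RIBOSOME = sv_r))
    counts <- rbind(counts, data.frame(
      tomogram = t, chap = sum(merged$template == "ELES1"),
      ribo = sum(merged$template == "RIBOSOME")))
  }
  ratios <- counts$ribo / pmax(counts$chap, 1)
  list(median_ratio = median(ratios), ratios = ratios, counts = counts)
}

# assign each hit the template whose score volume peaks higher around it
relabel_by_scores <- function(hits, score_volumes) {
  vapply(seq_len(nrow(hits)), function(i) {
    best <- names(score_volumes)[1]
    best_s <- -Inf
    for (nm in names(score_volumes)) {
      sv <- score_volumes[[nm]]
      d <- dim(sv$scores)
      p <- round(as.numeric(hits[i, c("x", "y", "z")]) / sv$binning) + 1
      lo <- pmax(p - 2, 1)
      hi <- pmin(p + 2, d)
      s <- max(sv$scores[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
      if (s > best_s) {
        best_s <- s
        best <- nm
      }
    }
    best
  }, character(1))
}
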