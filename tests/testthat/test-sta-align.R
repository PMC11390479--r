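geom <- species_geometry()

sim_bullet_stack <- function(n, snr = 0.3, seed = 81, conformation = "narrow") {
  mix <- list(s = list(state = species_state("ELES1", conformation, "none"),
                       prop = 1))
  cfg <- sim_config(mix, box = 48, snr = snr, seed = seed)
  simulate_particle_stack(cfg, n = n)
}

test_that("subtomogram extraction crops at hit centers and drops border hits", {
  set.seed(1)
  tomo <- volume(array(rnorm(64 * 64 * 48), c(64, 64, 48)), 7.04)
  hits <- data.frame(tomogram = "t", x = c(32, 30, 3), y = c(32, 20, 10),
                     z = c(24, 20, 10), rot = 0, tilt = 0, psi = 0,
                     score = c(0.9, 0.8, 0.7))
  expect_message(set <- extract_subtomograms(tomo, hits, 16), "dropped")
  expect_equal(n_particles(set), 2)
  # center voxel of the first box equals the tomogram value at the hit
  expect_equal(set$stack[[1]]$data[9, 9, 9], tomo$data[33, 33, 25])
  far <- data.frame(tomogram = "t", x = 2, y = 2, z = 2, rot = 0, tilt = 0,
                    psi = 0, score = 1)
  expect_error(suppressMessages(extract_subtomograms(tomo, far, 16)),
               "no hits")
})

test_that("the average of one identity particle is that subtomogram", {
  sim <- sim_bullet_stack(1, snr = 1e6, seed = 83)
  set <- stack_to_particle_set(sim)
  set$particles[, c("rot", "tilt", "psi")] <- 0
  avg <- wedge_weighted_average(set)
  expect_gt(vol_cor(avg, set$stack[[1]], spherical_mask(48, 22, 2)), 0.99)
})

test_that("orientation diversity fills the wedge: average matches ground truth", {
  sim <- sim_bullet_stack(100, snr = 1e6, seed = 85)
  set <- stack_to_particle_set(sim)
  avg <- wedge_weighted_average(set)
  tpl <- build_species_map(geom, species_state("ELES1", "narrow", "none"),
                           48, 7.04)
  expect_gt(vol_cor(avg, tpl, spherical_mask(48, 22, 2)), 0.95)
})

test_that("alignment is a fixed point at truth and recovers perturbed orientations", {
  sim <- sim_bullet_stack(60, snr = 0.3, seed = 87)
  set <- stack_to_particle_set(sim)
  tpl <- build_species_map(geom, species_state("ELES1", "narrow", "none"),
                           48, 7.04)
  # zero search range: orientations must not move
  p0 <- alignment_params(binning = 2, angular_range = 0, angular_step = 0,
                         max_shift = 0, lowpass = 35, symmetry = "C7",
                         iterations = 1)
  s0 <- align_particles(set, tpl, p0, update_reference = FALSE)
  expect_equal(s0$particles[, c("rot", "tilt", "psi")],
               set$particles[, c("rot", "tilt", "psi")])
  # perturb orientations by <= 10 degrees and refine locally
  set.seed(88)
  pert <- set
  for (i in seq_len(n_particles(pert))) {
    ax <- euler(runif(1, 0, 360), runif(1, 0, 10), 0)
    pert$particles[i, c("rot", "tilt", "psi")] <-
      euler_compose(particle_euler(set, i), euler(ax$rot, ax$tilt, -ax$rot))
  }
  pl <- alignment_params(binning = 2, angular_range = 12, angular_step = 3,
                         max_shift = 0, lowpass = 30, symmetry = "C7",
                         iterations = 2)
  ref <- align_particles(pert, tpl, pl, update_reference = FALSE)
  errs <- vapply(seq_len(n_particles(ref)), function(i) euler_distance_sym(
    particle_euler(ref, i),
    euler(sim$truth$rot[i], sim$truth$tilt[i], sim$truth$psi[i]), "C7"),
    numeric(1))
  expect_lte(median(errs), 4)
})

test_that("gold-standard refinement is deterministic and improves with n", {
  sim <- sim_bullet_stack(64, snr = 0.3, seed = 89)
  set <- stack_to_particle_set(sim)
  tpl <- build_species_map(geom, species_state("ELES1", "narrow", "none"),
                           48, 7.04)
  params <- alignment_params(binning = 2, angular_range = 8, angular_step = 4,
                             max_shift = 0, lowpass = 30, symmetry = "C7",
                             iterations = 1)
  r1 <- gold_standard_refine(set, tpl, params, seed = 5)
  r2 <- gold_standard_refine(set, tpl, params, seed = 5)
  expect_identical(r1$halves, r2$halves)
  expect_equal(as.numeric(r1$resolution), as.numeric(r2$resolution))
  # a quarter of the data must not beat the full set
  sub <- particle_set(set$particles[1:16, ], set$stack[1:16], set$wedge)
  r_small <- gold_standard_refine(sub, tpl, params, seed = 5)
  expect_gte(as.numeric(r_small$resolution) + 1e-9, as.numeric(r1$resolution))
  tiny <- particle_set(set$particles[1:8, ], set$stack[1:8], set$wedge)
  expect_error(gold_standard_refine(tiny, tpl, params), "at least 10")
})

test_that("noise-free half maps reach the Nyquist bound", {
  sim <- sim_bullet_stack(20, snr = 1e6, seed = 91)
  set <- stack_to_particle_set(sim)
  tpl <- build_species_map(geom, species_state("ELES1", "narrow", "none"),
                           48, 7.04)
  params <- alignment_params(binning = 2, angular_range = 0, angular_step = 0,
                             max_shift = 0, lowpass = NA, symmetry = "C7",
                             iterations = 1)
  r <- gold_standard_refine(set, tpl, params, seed = 7)
  expect_true(attr(r$resolution, "bound"))
  expect_equal(as.numeric(r$resolution), 2 * 7.04)
})

test_that("chamber pooling doubles footballs, keeps ids unique and centers lids at +z", {
  mixb <- list(s = list(state = species_state("ELES1", "wide", "none"), prop = 1))
  mixf <- list(s = list(state = species_state("ELES2",
                                              chamber_occupancy = c("none", "none")),
                        prop = 1))
  cfgb <- sim_config(mixb, box = 48, snr = 1e6, seed = 93)
  cfgf <- sim_config(mixf, box = 48, snr = 1e6, seed = 94)
  sb <- stack_to_particle_set(simulate_particle_stack(cfgb, n = 3))
  sf <- stack_to_particle_set(simulate_particle_stack(cfgf, n = 12))
  sb$particles$score <- sf$particles$score <- 1
  pooled <- pool_chambers(sb, sf, geom = geom)
  expect_equal(n_particles(pooled), 2 * 12 + 3)
  expect_false(anyDuplicated(pooled$particles$id) > 0)
  # average the pooled chambers: lid (GroES) density must sit toward +z
  avg <- wedge_weighted_average(pooled)
  n <- 48
  g <- (seq_len(n) - 1 - box_center(n)) * 7.04
  lid_zone <- which(g > 30 & g < 70)
  bottom_zone <- which(g < -30 & g > -70)
  c0 <- box_center(n) + 1
  axis_lid <- mean(avg$data[c0 + (-2:2), c0 + (-2:2), lid_zone])
  axis_bottom <- mean(avg$data[c0 + (-2:2), c0 + (-2:2), bottom_zone])
  expect_gt(axis_lid, axis_bottom + 0.05)
  # the two expanded chambers of a symmetric football agree
  direct <- pooled$particles$chamber == "direct" &
    grepl("^f", pooled$particles$parent_id)
  flipped <- pooled$particles$chamber == "flipped"
  avg_d <- wedge_weighted_average(particle_set(pooled$particles[direct, ],
                                               pooled$stack[direct], sb$wedge))
  avg_f <- wedge_weighted_average(particle_set(pooled$particles[flipped, ],
                                               pooled$stack[flipped], sb$wedge))
  chamber_zone <- cylinder_mask(48, 12, c(12, 42), 2)
  expect_gt(vol_cor(avg_d, avg_f, chamber_zone), 0.99)
})

test_that("pool_chambers refuses unaligned input", {
  mixb <- list(s = list(state = species_state("ELES1", "wide", "none"), prop = 1))
  cfgb <- sim_config(mixb, box = 48, snr = 1e6, seed = 95)
  sb <- stack_to_particle_set(simulate_particle_stack(cfgb, n = 2))
  expect_error(pool_chambers(sb, sb, geom = geom), "aligned")
})

test_that("signal subtraction preserves only the kept region", {
  mix <- list(s = list(state = species_state("ELES1", "wide", "none"), prop = 1))
  cfg <- sim_config(mix, box = 48, snr = 1e6, seed = 97)
  sim <- simulate_particle_stack(cfg, n = 2)
  set <- stack_to_particle_set(sim)
  ref <- build_species_map(geom, species_state("ELES1", "wide", "none"),
                           48, 7.04)
  ones <- volume(array(1, rep(48, 3)), 7.04)
  s_id <- signal_subtract(set, ref, ones)
  expect_equal(s_id$stack[[1]]$data, set$stack[[1]]$data)
  zeros <- volume(array(0, rep(48, 3)), 7.04)
  s_zero <- signal_subtract(set, ref, zeros)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(s_zero$stack[[1]]$data), 0.1 * rms(set$stack[[1]]$data))
  # keep the cis chamber: residual outside the (particle-frame) kept region
  # is small; measured at full tilt range so the bound reflects the operator
  # rather than missing-wedge smearing of the kept density
  cfg_full <- sim_config(mix, box = 48, snr = 1e6, seed = 97,
                         wedge = wedge_spec(90))
  sim_full <- simulate_particle_stack(cfg_full, n = 1)
  set_full <- stack_to_particle_set(sim_full)
  keep <- volume(cylinder_mask(48, 10, c(24, 40), 2)$data, 7.04)
  s_ch <- signal_subtract(set_full, ref, keep)
  e <- particle_euler(set_full, 1)
  keep_p <- apply_transform(keep, e, fill = 0)
  outside <- keep_p$data < 0.05  # beyond the soft mask edge
  expect_lt(rms(s_ch$stack[[1]]$data[outside]), 0.05 * rms(set_full$stack[[1]]$data))
})
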