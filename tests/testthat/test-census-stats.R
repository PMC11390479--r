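test_that("state assignment maps the taxonomy deterministically", {
  expect_equal(assign_state("ELES1", "wide", "none"), "i")
  expect_equal(assign_state("ELES1", "wide", "disordered"), "i")
  expect_equal(assign_state("ELES1", "wide", "ordered"), "ii")
  expect_equal(assign_state("ELES1", "narrow", "disordered"), "iii")
  expect_equal(assign_state("ELES1", "narrow", "ordered"), "iv")
  expect_equal(assign_state("ELES2", "na", c("none", "disordered")), "v")
  expect_equal(assign_state("ELES2", "na", c("ordered", "none")), "vi")
  expect_equal(assign_state("ELES2", "na", c("ordered", "ordered")), "vii")
  expect_equal(assign_state("EL"), "EL")
  expect_error(assign_state("ELES1", "na", "none"), "invalid")
  expect_error(assign_state("ELES2", "na", "ordered"), "invalid")
  expect_error(assign_state("EL", "na", "ordered"), "invalid")
})

test_that("football chamber labels are an unordered pair", {
  expect_equal(assign_state("ELES2", "na", c("ordered", "none")),
               assign_state("ELES2", "na", c("none", "ordered")))
})

test_that("enumerating the valid label space yields exactly seven bound states", {
  en <- enumerate_states()
  bound <- setdiff(unique(en$label), "EL")
  expect_setequal(bound, c("i", "ii", "iii", "iv", "v", "vi", "vii"))
  expect_equal(length(bound), 7L)
})

make_census_fixture <- function() {
  # 5 tomograms x 2 conditions with fixed per-tomogram compositions
  rows <- list()
  ribs <- list()
  for (cond in c("c37", "hs")) {
    p1 <- if (cond == "c37") 0.6 else 0.7
    for (t in 1:5) {
      n1 <- round(20 * p1) + (t - 3)  # small per-tomogram variation
      n2 <- 20 - n1
      rows[[length(rows) + 1]] <- data.frame(
        tomogram = paste0(cond, "_t", t), condition = cond,
        state_label = rep(c("ELES1", "ELES2"), c(n1, n2)))
      ribs[[length(ribs) + 1]] <- data.frame(
        tomogram = paste0(cond, "_t", t), condition = cond,
        count = 20 * 23)
    }
  }
  list(particles = do.call(rbind, rows),
       ribosomes = do.call(rbind, lapply(ribs, function(r)
         r[rep(1, r$count), c("tomogram", "condition")])))
}

test_that("census conserves counts and proportions sum to one", {
  fx <- make_census_fixture()
  tab <- census(fx$particles, fx$ribosomes)
  per <- tab$per_tomogram
  expect_equal(per$total, rowSums(per[, tab$states]))
  for (cond in unique(tab$pooled$condition)) {
    pr <- tab$pooled$proportion[tab$pooled$condition == cond]
    expect_equal(sum(pr), 1)
  }
})

test_that("census of a planted 60:40 mixture returns the planted proportions", {
  parts <- data.frame(tomogram = "t1", condition = "c37",
                      state_label = rep(c("ELES1", "ELES2"), c(600, 400)))
  tab <- census(parts)
  expect_equal(tab$pooled$proportion[tab$pooled$state == "ELES1"], 0.6)
  expect_equal(tab$pooled$proportion[tab$pooled$state == "ELES2"], 0.4)
})

test_that("ribosome quota of 23:1 over five tomograms gives median ratio 23", {
  parts <- do.call(rbind, lapply(1:5, function(t)
    data.frame(tomogram = paste0("t", t), condition = "c37",
               state_label = rep("ELES1", 4))))
  ribs <- do.call(rbind, lapply(1:5, function(t)
    data.frame(tomogram = paste0("t", t), condition = "c37")[rep(1, 92), ]))
  tab <- census(parts, ribs)
  expect_equal(median(tab$per_tomogram$ratio), 23)
})

test_that("condition comparison reproduces the exact rank-sum p value", {
  per <- rbind(
    data.frame(tomogram = paste0("a", 1:3), condition = "A",
               state_label = "ELES1"),
    data.frame(tomogram = paste0("b", 1:3), condition = "B",
               state_label = "ELES1"))
  # build proportions 0.1,0.2,0.3 vs 0.7,0.8,0.9 out of 10 particles each
  build <- function(tomo, cond, p) data.frame(
    tomogram = tomo, condition = cond,
    state_label = rep(c("ELES1", "ELES2"), c(p * 10, 10 - p * 10)))
  parts <- rbind(build("a1", "A", 0.1), build("a2", "A", 0.2),
                 build("a3", "A", 0.3), build("b1", "B", 0.7),
                 build("b2", "B", 0.8), build("b3", "B", 0.9))
  tab <- census(parts)
  res <- compare_conditions(tab, "ELES1", "A", "B")
  expect_equal(res$p_value, 0.1)  # exact: 2/C(6,3) = 2/20
  # symmetry under swapped group order
  res2 <- compare_conditions(tab, "ELES1", "B", "A")
  expect_equal(res2$p_value, res$p_value)
})

test_that("identical groups give p = 1 with a warning", {
  build <- function(tomo, cond) data.frame(
    tomogram = tomo, condition = cond,
    state_label = rep(c("ELES1", "ELES2"), c(5, 5)))
  parts <- rbind(build("a1", "A"), build("a2", "A"), build("a3", "A"),
                 build("b1", "B"), build("b2", "B"), build("b3", "B"))
  tab <- census(parts)
  expect_warning(res <- compare_conditions(tab, "ELES1", "A", "B"), "tied")
  expect_equal(res$p_value, 1)
})

test_that("exact and normal-approximation p values agree for n >= 8", {
  set.seed(99)
  for (rep in 1:5) {
    a <- round(runif(8, 0.3, 0.7), 3)
    b <- round(runif(8, 0.4, 0.8), 3)
    p_exact <- wilcox.test(a, b, exact = TRUE)$p.value
    p_norm <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("aperture diameter recovers ideal cylinder openings", {
  geom <- species_geometry()
  n <- 48
  vs <- 7.04
  for (d_ap in c(45, 65)) {
    # ideal open ring: annulus from d_ap/2 to outer radius over the slab
    g <- (seq_len(n) - 1 - box_center(n)) * vs
    rxy <- sqrt(outer(g^2, g^2, "+"))
    a <- array(0, c(n, n, n))
    for (k in which(g >= -geom$ring_height & g <= 0)) {
      sl <- matrix(0, n, n)
      inner <- if (g[k] <= -geom$ring_height + 0.15 * geom$ring_height)
        d_ap / 2 else geom$cavity_radius
      sl[rxy >= inner & rxy <= geom$outer_radius] <- 1
      a[, , k] <- sl
    }
    got <- aperture_diameter(volume(a, vs), geom)
    expect_lt(abs(got - d_ap), vs)
  }
})

test_that("aperture measurements match the phantom parameters and are monotone", {
  geom <- species_geometry()
  mn <- build_species_map(geom, species_state("ELES1", "narrow", "none"))
  mw <- build_species_map(geom, species_state("ELES1", "wide", "none"))
  a_n <- aperture_diameter(mn, geom)
  a_w <- aperture_diameter(mw, geom)
  expect_lt(abs(a_n - 45), 7.04)
  expect_lt(abs(a_w - 65), 7.04)
  diams <- vapply(c(35, 45, 55, 65), function(d) {
    gm <- species_geometry(aperture_diameter_narrow = d,
                           aperture_diameter_wide = d + 30)
    aperture_diameter(build_species_map(gm,
      species_state("ELES1", "narrow", "none")), gm)
  }, numeric(1))
  expect_true(all(diff(diams) >= -1e-9))
})

test_that("substrate center of mass locates the planted blob", {
  geom <- species_geometry()
  ch <- build_species_map(geom, species_state("CHAMBER",
                                              chamber_occupancy = "ordered"),
                          box = 32)
  msk <- cylinder_mask(32, geom$cavity_radius / 7.04, c(12, 19), 1)
  com <- sp_center_of_mass(ch, msk)
  expect_lt(sqrt(sum((com - c(0, 0, -20))^2)), 3)
  empty <- build_species_map(geom, species_state("CHAMBER",
                                                 chamber_occupancy = "none"),
                             box = 32)
  r <- sp_center_of_mass(empty, msk)
  expect_equal(attr(r, "flag"), "no SP density")
})
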