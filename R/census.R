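#' Assign the seven-state taxonomy label
#'
#' Deterministically maps a complex's species, trans-ring conformation and
#' per-chamber substrate occupancy onto the state taxonomy: the seven
#' GroES-bound states (i-vii) plus free `EL`.  Bullets in the wide
#' conformation carry no trans-bound substrate and split on cis occupancy
#' into i (no/disordered) and ii (ordered); narrow bullets (which always
#' carry apical trans substrate) split into iii and iv; footballs split on
#' the unordered pair of chamber labels into v (none ordered), vi (one) and
#' vii (both).
#'
#' @param species "EL", "ELES1" or "ELES2" (also accepts "RIBOSOME" and
#'   "CHAMBER" for bookkeeping of distractors and extracted chambers).
#' @param trans_conformation "narrow", "wide" or "na".
#' @param chamber_occupancy character vector of per-chamber labels
#'   ("none"/"disordered"/"ordered"); one for bullets, two for footballs.
#' @return a state label string.
#' @export
assign_state <- function(species, trans_conformation = "na",
                         chamber_occupancy = character(0)) {
  ordered <- chamber_occupancy == "ordered"
  bad <- function(msg) stop("invalid state combination: ", msg)
  switch(species,
    EL = {
      if (length(chamber_occupancy)) bad("EL has no closed chamber")
      "EL"
    },
    ELES1 = {
      if (length(chamber_occupancy) != 1) bad("bullets have exactly one chamber")
      if (trans_conformation == "wide") {
        if (ordered) "ii" else "i"
      } else if (trans_conformation == "narrow") {
        if (ordered) "iv" else "iii"
      } else bad("bullets need a narrow or wide trans conformation")
    },
    ELES2 = {
      if (length(chamber_occupancy) != 2) bad("footballs have exactly two chambers")
      if (trans_conformation != "na") bad("footballs have no trans ring")
      c("v", "vi", "vii")[sum(ordered) + 1]
    },
    RIBOSOME = "ribosome",
    CHAMBER = {
      if (length(chamber_occupancy) != 1) bad("a chamber has one occupancy label")
      paste0("chamber_", if (ordered) "ordered" else "unordered")
    },
    bad(paste("unknown species", species))
  )
}

assign_state_label <- function(state) {
  assign_state(state$species, state$trans_conformation, state$chamber_occupancy)
}

#' All valid GroES-bound state combinations
#'
#' Enumerates the valid (species x conformation x occupancy) label space and
#' returns the data.frame of combinations with their assigned labels.  The
#' distinct GroES-bound labels are exactly i-vii.
#'
#' @return data.frame with columns species, trans_conformation, occupancy
#'   and label.
#' @export
enumerate_states <- function() {
  occ <- c("none", "disordered", "ordered")
  rows <- list(data.frame(species = "EL", trans_conformation = "na",
                          occupancy = "", label = assign_state("EL")))
  for (tc in c("narrow", "wide")) for (o in occ)
    rows[[length(rows) + 1]] <- data.frame(
      species = "ELES1", trans_conformation = tc, occupancy = o,
      label = assign_state("ELES1", tc, o))
  for (o1 in occ) for (o2 in occ) {
    pair <- sort(c(o1, o2))  # chamber labels form an unordered pair
    rows[[length(rows) + 1]] <- data.frame(
      species = "ELES2", trans_conformation = "na",
      occupancy = paste(pair, collapse = "+"),
      label = assign_state("ELES2", "na", pair))
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Per-tomogram state census
#'
#' Counts chaperonin states and ribosome hits per tomogram, and derives
#' per-condition pooled proportions and per-tomogram GroEL:ribosome ratios.
#'
#' @param particles data.frame with columns `tomogram`, `condition` and
#'   `state_label` (one row per chaperonin complex).
#' @param ribosome_hits optional data.frame with columns `tomogram` and
#'   `condition` (one row per ribosome).
#' @return an object of class `census_table`: a list with `per_tomogram`
#'   (counts per state per tomogram, plus `ribosomes` and `ratio`),
#'   `pooled` (per-condition pooled proportions over chaperonin states) and
#'   `per_tomogram_mean` (per-condition means of per-tomogram proportions).
#' @export
census <- function(particles, ribosome_hits = NULL) {
  stopifnot(all(c("tomogram", "condition", "state_label") %in% names(particles)))
  states <- sort(unique(particles$state_label))
  tomos <- unique(particles[, c("condition", "tomogram")])
  tomos <- tomos[order(tomos$condition, tomos$tomogram), , drop = FALSE]
  cnt <- matrix(0L, nrow(tomos), length(states),
                dimnames = list(NULL, states))
  for (i in seq_len(nrow(tomos))) {
    sel <- particles$tomogram == tomos$tomogram[i] &
      particles$condition == tomos$condition[i]
    tab <- table(particles$state_label[sel])
    cnt[i, names(tab)] <- as.integer(tab)
  }
  per <- cbind(tomos, as.data.frame(cnt), row.names = NULL)
  per$total <- rowSums(cnt)
  per$ribosomes <- 0L
  if (!is.null(ribosome_hits) && nrow(ribosome_hits)) {
    for (i in seq_len(nrow(per))) {
      per$ribosomes[i] <- sum(ribosome_hits$tomogram == per$tomogram[i] &
                                ribosome_hits$condition == per$condition[i])
    }
  }
  per$ratio <- ifelse(per$total > 0, per$ribosomes / per$total, NA_real_)
  pooled <- do.call(rbind, lapply(split(per, per$condition), function(d) {
    tot <- colSums(d[, states, drop = FALSE])
    data.frame(condition = d$condition[1], state = states,
               count = as.numeric(tot),
               proportion = as.numeric(tot) / sum(tot),
               row.names = NULL)
  }))
  per_mean <- do.call(rbind, lapply(split(per, per$condition), function(d) {
    pr <- sweep(as.matrix(d[, states, drop = FALSE]), 1, d$total, "/")
    data.frame(condition = d$condition[1], state = states,
               proportion = colMeans(pr, na.rm = TRUE), row.names = NULL)
  }))
  rownames(pooled) <- rownames(per_mean) <- NULL
  structure(list(per_tomogram = per, pooled = pooled,
                 per_tomogram_mean = per_mean, states = states),
            class = "census_table")
}

#' Compare per-tomogram state proportions between two conditions
#'
#' Two-sided Wilcoxon rank-sum test on per-tomogram proportions of a state
#' (or pooled group of states).  Uses exact enumeration when both groups have
#' at most 10 tomograms and no ties, otherwise the normal approximation with
#' tie correction.  P values are reported uncorrected for multiple testing.
#'
#' @param table a `census_table`.
#' @param states state label(s) whose per-tomogram proportion is compared.
#' @param cond_a,cond_b condition names.
#' @return list with `statistic` (rank-sum W), `p_value`, and the per-group
#'   proportions.
#' @export
compare_conditions <- function(table, states, cond_a, cond_b) {
  per <- table$per_tomogram
  states <- intersect(states, table$states)
  grp <- function(cond) {
    d <- per[per$condition == cond, , drop = FALSE]
    if (nrow(d) < 3) stop("need at least 3 tomograms per condition")
    rowSums(d[, states, drop = FALSE]) / d$total
  }
  a <- grp(cond_a)
  b <- grp(cond_b)
  if (all(a == b[1]) && all(b == b[1])) {
    warning("all proportions tied across both groups")
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                group_a = a, group_b = b))
  }
  exact <- length(a) <= 10 && length(b) <= 10 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       group_a = a, group_b = b)
}

#' Measure the apical aperture diameter of a ring average
#'
#' Azimuthally averages the density over the apical slab (top
#' `apical_fraction` of the ring height below the open end), then reports the
#' diameter at which the radial profile first rises to half its wall maximum
#' moving outward from the symmetry axis, with linear interpolation between
#' radial bins.
#'
#' @param ring_average a volume, symmetry axis on z, open ring end toward -z
#'   (the trans ring of an equator-centred complex).
#' @param geom a [species_geometry()] (locates the apical slab).
#' @param apical_fraction fraction of the ring height forming the slab.
#' @param end which barrel end to measure: "bottom" (trans ring of a
#'   full complex, default) or "top".
#' @return diameter in Angstrom, or `NA` with attribute `flag =
#'   "no aperture"` when the profile never reaches half-max.
#' @export
aperture_diameter <- function(ring_average, geom = species_geometry(),
                              apical_fraction = 0.15, end = c("bottom", "top")) {
  end <- match.arg(end)
  n <- dim(ring_average$data)[1]
  vs <- ring_average$voxel_size
  g <- (seq_len(n) - 1 - box_center(n)) * vs
  H <- geom$ring_height
  zr <- if (end == "bottom") c(-H, -H + apical_fraction * H)
        else c(H - apical_fraction * H, H)
  ki <- which(g >= zr[1] & g <= zr[2])
  if (!length(ki)) stop("apical slab lies outside the box")
  slab <- apply(ring_average$data[, , ki, drop = FALSE], c(1, 2), mean)
  rxy <- sqrt(outer(g^2, g^2, "+"))
  rb <- as.integer(round(rxy / vs))
  prof <- tapply(as.vector(slab), as.vector(rb), mean)
  radii <- as.numeric(names(prof)) * vs
  keep <- radii <= geom$outer_radius
  prof <- as.numeric(prof[keep])
  radii <- radii[keep]
  wall_max <- max(prof)
  half <- wall_max / 2
  # scan outward from the profile minimum inside the wall: apical substrate
  # density on the axis (narrow rings) must not masquerade as wall
  i_wall <- which.max(prof)
  i_min <- which.min(prof[seq_len(i_wall)])
  if (prof[i_min] >= half)
    return(structure(NA_real_, flag = "no aperture"))
  rel <- which(prof >= half)
  rel <- rel[rel > i_min]
  i <- rel[1]
  if (is.na(i) || i == 1) return(structure(NA_real_, flag = "no aperture"))
  r_half <- radii[i - 1] + (radii[i] - radii[i - 1]) *
    (half - prof[i - 1]) / (prof[i] - prof[i - 1])
  2 * r_half
}

#' Substrate center of mass inside a chamber average
#'
#' Intensity-weighted centroid of voxels above a density threshold inside the
#' chamber mask, in Angstrom relative to the box center (+z toward the lid).
#'
#' @param chamber_average a volume.
#' @param chamber_mask a volume of weights in \[0, 1\].
#' @param density_threshold fraction of the map maximum (the wall density);
#'   an empty chamber has no masked voxel above it and raises the flag.
#' @return length-3 numeric (Angstrom), or `NA` vector with attribute
#'   `flag = "no SP density"` when nothing exceeds the threshold.
#' @export
sp_center_of_mass <- function(chamber_average, chamber_mask,
                              density_threshold = 0.5) {
  if (sum(chamber_mask$data) == 0) stop("chamber mask is empty")
  n <- dim(chamber_average$data)[1]
  vs <- chamber_average$voxel_size
  a <- chamber_average$data * chamber_mask$data
  thr <- density_threshold * max(chamber_average$data)
  sel <- a > thr & chamber_mask$data > 0.5
  if (!any(sel) || thr <= 0)
    return(structure(c(NA_real_, NA_real_, NA_real_), flag = "no SP density"))
  g <- (seq_len(n) - 1 - box_center(n)) * vs
  x <- rep(g, times = n * n)
  y <- rep(rep(g, each = n), times = n)
  z <- rep(g, each = n * n)
  w <- a[sel]
  c(sum(x[sel] * w), sum(y[sel] * w), sum(z[sel] * w)) / sum(w)
}
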