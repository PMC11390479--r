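#' Write a volume as MRC2014 (mode 2)
#'
#' Little-endian 32-bit float MRC2014 with the voxel size recorded in the
#' cell dimensions; x is the fastest axis.
#'
#' @param vol a volume.
#' @param path output file path.
#' @export
write_mrc <- function(vol, path) {
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NX NY NZ
  wi(2)                      # MODE 2 = float32
  wi(c(0, 0, 0))             # NXSTART..
  wi(d)                      # MX MY MZ
  wf(d * vol$voxel_size)     # CELLA
  wf(c(90, 90, 90))          # CELLB
  wi(c(1, 2, 3))             # MAPC MAPR MAPS
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # DMIN DMAX DMEAN
  wi(c(1, 0))                # ISPG NSYMBT
  writeBin(raw(100), con)    # EXTRA
  wf(c(0, 0, 0))             # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(sd(vol$data))           # RMS
  wi(0)                      # NLABL
  writeBin(raw(800), con)    # labels
  writeBin(as.numeric(vol$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume (mode 2)
#'
#' @param path file path.
#' @return a volume; errors on non-mode-2 or truncated files.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024)
  if (length(hdr) < 1024) stop("truncated MRC file: incomplete header")
  ri <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "integer",
                                     n, size = 4, endian = "little")
  rf <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "numeric",
                                     n, size = 4, endian = "little")
  d <- ri(0, 3)
  mode <- ri(12)
  if (mode != 2)
    stop(sprintf("unsupported MRC mode %d (only mode 2, 32-bit float)", mode))
  mx <- ri(28, 3)
  cella <- rf(40, 3)
  nsymbt <- ri(92)
  if (nsymbt > 0) readBin(con, "raw", nsymbt)
  nvox <- prod(d)
  dat <- readBin(con, "numeric", nvox, size = 4, endian = "little")
  if (length(dat) < nvox) stop("truncated MRC file: incomplete data block")
  voxel <- if (mx[1] > 0) cella[1] / mx[1] else 1
  volume(array(dat, d), voxel)
}

#' Write a particle table as a STAR-dialect file
#'
#' One named data block with a loop header; whitespace-separated rows.
#' Coordinates are 0-based voxels, angles intrinsic ZYZ degrees (a header
#' comment records both conventions).  Numeric values are written with full
#' precision so that a round trip reproduces them exactly; unknown columns
#' are preserved.
#'
#' @param particles data.frame with at least `id`, `tomogram`, `x`, `y`,
#'   `z`, `rot`, `tilt`, `psi`, `score`.
#' @param path output path.
#' @param block data block name.
#' @export
write_particles <- function(particles, path, block = "particles") {
  req <- c("id", "tomogram", "x", "y", "z", "rot", "tilt", "psi", "score")
  miss <- setdiff(req, names(particles))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# chapsta particle table",
               "# coordinates: 0-based voxels; angles: intrinsic ZYZ, degrees",
               "", paste0("data_", block), "", "loop_"), con)
  writeLines(paste0("_", names(particles), sprintf(" #%d", seq_along(particles))),
             con)
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- "NA"
      out
    } else as.character(x)
  }
  cols <- lapply(particles, fmt)
  writeLines(do.call(paste, cols), con)
  invisible(path)
}

#' Read a STAR-dialect particle table
#'
#' @param path file path.
#' @return data.frame with numeric columns restored; errors if a required
#'   column is absent.
#' @export
read_particles <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) stop("no loop_ block found")
  i <- loop_at[1] + 1
  cols <- character(0)
  while (i <= length(lines) && grepl("^_", lines[i])) {
    nm <- sub("^_", "", strsplit(lines[i], "\\s+")[[1]][1])
    cols <- c(cols, nm)
    i <- i + 1
  }
  rows <- lines[i:length(lines)]
  rows <- rows[nzchar(rows)]
  if (!length(rows)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  } else {
    sp <- strsplit(rows, "\\s+")
    if (any(lengths(sp) != length(cols)))
      stop("malformed row: field count does not match the loop header")
    m <- do.call(rbind, sp)
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- cols
    for (j in seq_along(out)) {
      v <- out[[j]]
      suppress <- suppressWarnings(as.numeric(v))
      if (all(!is.na(suppress) | v == "NA")) out[[j]] <- suppress
    }
  }
  req <- c("id", "tomogram", "x", "y", "z", "rot", "tilt", "psi", "score")
  miss <- setdiff(req, names(out))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  out
}

#' Write an FSC curve as a two-column text table
#' @param curve an `fsc_curve`.
#' @param path output path.
#' @export
write_fsc_table <- function(curve, path) {
  utils::write.table(data.frame(freq = curve$shell_freq, fsc = curve$corr),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Every parameter of the desk-scale pipeline with its default; values are
#' overridden by a YAML config file or an override list.  The effective
#' configuration is echoed into the run log.
#'
#' @param path optional YAML file.
#' @param overrides optional named list merged over the file values.
#' @return nested configuration list.
#' @export
default_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    seed = 1,
    out_dir = "chapsta_run",
    condition = "sim",
    simulate = list(n_tomograms = 2, n_particles = 20,
                    shape = c(160, 160, 64), voxel_size = 7.04, snr = 0.3,
                    box = 48, theta_max = 60,
                    mixture = list(ELES1 = 0.6, ELES2 = 0.4, RIBOSOME = 0)),
    match = list(step = 30, template_lowpass = 40, binning = 2,
                 overpick_factor = 2, min_distance_frac = 0.8),
    align = list(binning = c(2, 2), angular_range = c(180, 15),
                 angular_step = c(20, 7.5), max_shift = c(4, 2),
                 lowpass = c(40, 30), iterations = 2),
    classify = list(n_bootstrap = 500, bootstrap_size = 50,
                    n_iterations = 40, temperature_factor = 10,
                    n_repeats = 5, denoise_lowpass = 25))
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  cfg
}

log_line <- function(log_con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the pipeline
#'
#' Executes the desk-scale workflow stage by stage: `simulate` plants ground
#' truth tomograms, `match` template-matches both chaperonin species and
#' ribosomes, `align` refines and averages the matched particles, `classify`
#' separates bullet from football complexes by consensus classification, and
#' `census` tabulates per-tomogram counts.  `all` runs everything.  Reruns
#' with the same config and seed reproduce all tables exactly.
#'
#' @param config configuration list from [default_config()].
#' @param stage one of "simulate", "match", "align", "classify", "census",
#'   "all".
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config = default_config(),
                         stage = c("all", "simulate", "match", "align",
                                   "classify", "census")) {
  stage <- match.arg(stage)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out, "run.log"), "a")
  on.exit(close(log_con))
  log_line(log_con, "stage=", stage, " seed=", config$seed)
  writeLines(yaml::as.yaml(config), file.path(out, "config_effective.yaml"))
  stages <- if (stage == "all")
    c("simulate", "match", "align", "classify", "census") else stage
  for (s in stages) {
    log_line(log_con, "running ", s)
    switch(s,
           simulate = stage_simulate(config, out, log_con),
           match = stage_match(config, out, log_con),
           align = stage_align(config, out, log_con),
           classify = stage_classify(config, out, log_con),
           census = stage_census(config, out, log_con))
  }
  invisible(out)
}

require_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stop(sprintf("missing %s; run the '%s' stage first", path, produced_by))
  path
}

pipeline_mixture <- function(config) {
  p <- config$simulate$mixture
  mix <- list()
  if ((p$ELES1 %||% 0) > 0)
    mix$ELES1 <- list(state = species_state("ELES1", "wide", "disordered"),
                      prop = p$ELES1)
  if ((p$ELES2 %||% 0) > 0)
    mix$ELES2 <- list(state = species_state("ELES2",
                                            chamber_occupancy = c("none", "none")),
                      prop = p$ELES2)
  if ((p$RIBOSOME %||% 0) > 0)
    mix$RIBOSOME <- list(state = species_state("RIBOSOME"), prop = p$RIBOSOME)
  tot <- sum(vapply(mix, function(m) m$prop, numeric(1)))
  for (i in seq_along(mix)) mix[[i]]$prop <- mix[[i]]$prop / tot
  mix
}

stage_simulate <- function(config, out, log_con) {
  sc <- config$simulate
  mix <- pipeline_mixture(config)
  for (t in seq_len(sc$n_tomograms)) {
    cfg <- sim_config(mix, n_particles = sc$n_particles, shape = sc$shape,
                      voxel_size = sc$voxel_size, snr = sc$snr, box = sc$box,
                      wedge = wedge_spec(sc$theta_max),
                      seed = derive_seed(config$seed, t))
    sim <- simulate_tomogram(cfg)
    write_mrc(sim$tomogram, file.path(out, sprintf("tomo_%02d.mrc", t)))
    write_mrc(sim$cytosol_mask, file.path(out, sprintf("mask_%02d.mrc", t)))
    tr <- sim$truth
    tr$tomogram <- sprintf("tomo_%02d", t)
    tr$score <- NA_real_
    write_particles(tr, file.path(out, sprintf("truth_%02d.star", t)))
    log_line(log_con, sprintf("tomo %d: %d particles planted", t, nrow(tr)))
  }
  invisible(NULL)
}

stage_match <- function(config, out, log_con) {
  sc <- config$simulate
  mc <- config$match
  geom <- species_geometry()
  templates <- list(
    ELES1 = build_species_map(geom, species_state("ELES1", "wide", "none"),
                              sc$box, sc$voxel_size),
    ELES2 = build_species_map(geom, species_state("ELES2",
                                                  chamber_occupancy = c("none", "none")),
                              sc$box, sc$voxel_size))
  if ((sc$mixture$RIBOSOME %||% 0) > 0)
    templates$RIBOSOME <- build_species_map(geom, species_state("RIBOSOME"),
                                            sc$box, sc$voxel_size)
  syms <- c(ELES1 = "C7", ELES2 = "D7", RIBOSOME = "C1")
  hits_all <- list()
  for (t in seq_len(sc$n_tomograms)) {
    tomo <- read_mrc(require_artifact(file.path(out, sprintf("tomo_%02d.mrc", t)),
                                      "simulate"))
    mask <- read_mrc(file.path(out, sprintf("mask_%02d.mrc", t)))
    merged <- empty_hits()
    for (nm in names(templates)) {
      grid <- make_angular_grid(mc$step, syms[[nm]])
      sv <- match_template(tomo, templates[[nm]], wedge_spec(sc$theta_max),
                           grid, mc$template_lowpass, mc$binning,
                           template_name = nm)
      diam_vox <- species_diameter(geom, species_state(nm,
        if (nm == "ELES1") "wide" else "na",
        switch(nm, ELES1 = "none", ELES2 = c("none", "none"), character(0)))) /
        sc$voxel_size
      h <- extract_peaks(sv, "auto", mc$min_distance_frac * diam_vox, mask,
                         mc$overpick_factor, sprintf("tomo_%02d", t))
      log_line(log_con, sprintf("tomo %d %s: %d hits", t, nm, nrow(h)))
      merged <- merge_remove_duplicates(merged, h, 0.5 * diam_vox)
    }
    hits_all[[t]] <- merged
  }
  hits <- do.call(rbind, hits_all)
  hits$id <- seq_len(nrow(hits))
  write_particles(hits, file.path(out, "hits.star"))
  invisible(NULL)
}

stage_align <- function(config, out, log_con) {
  sc <- config$simulate
  ac <- config$align
  hits <- read_particles(require_artifact(file.path(out, "hits.star"), "match"))
  geom <- species_geometry()
  sets <- list()
  for (t in seq_len(sc$n_tomograms)) {
    tomo <- read_mrc(file.path(out, sprintf("tomo_%02d.mrc", t)))
    h <- hits[hits$tomogram == sprintf("tomo_%02d", t) &
                hits$template != "RIBOSOME", , drop = FALSE]
    if (!nrow(h)) next
    sets[[length(sets) + 1]] <- extract_subtomograms(tomo, h, sc$box,
                                                     wedge_spec(sc$theta_max))
    sets[[length(sets)]]$particles$tomogram <- sprintf("tomo_%02d", t)
  }
  set <- do.call(merge_particle_sets, sets)
  ref <- build_species_map(geom, species_state("ELES1", "wide", "none"),
                           sc$box, sc$voxel_size)
  params <- alignment_params(binning = ac$binning,
                             angular_range = ac$angular_range,
                             angular_step = ac$angular_step,
                             max_shift = ac$max_shift, lowpass = ac$lowpass,
                             symmetry = "C1", iterations = ac$iterations)
  set <- align_particles(set, lowpass_filter(ref, 40), params)
  log_line(log_con, sprintf("aligned %d particles, mean score %.3f",
                            n_particles(set), mean(set$particles$score)))
  saveRDS_free_particles(set, out)
  write_mrc(attr(set, "reference"), file.path(out, "aligned_average.mrc"))
  invisible(NULL)
}

# persist a particle set as STAR + MRC stack (text-free of R serialization)
saveRDS_free_particles <- function(set, out) {
  write_particles(set$particles, file.path(out, "aligned.star"))
  dir.create(file.path(out, "stack"), showWarnings = FALSE)
  for (i in seq_len(n_particles(set)))
    write_mrc(set$stack[[i]], file.path(out, sprintf("stack/p_%04d.mrc", i)))
  invisible(NULL)
}

load_particles_stack <- function(out, wedge) {
  p <- read_particles(file.path(out, "aligned.star"))
  stack <- lapply(seq_len(nrow(p)), function(i)
    read_mrc(file.path(out, sprintf("stack/p_%04d.mrc", i))))
  particle_set(p, stack, wedge)
}

#' Merge particle sets (shared box and wedge)
#' @param ... particle sets.
#' @export
merge_particle_sets <- function(...) {
  sets <- list(...)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  if (length(sets) == 1) return(sets[[1]])
  p <- do.call(rbind, lapply(sets, function(s) s$particles))
  p$id <- seq_len(nrow(p))
  particle_set(p, do.call(c, lapply(sets, function(s) s$stack)), sets[[1]]$wedge)
}

stage_classify <- function(config, out, log_con) {
  sc <- config$simulate
  cc <- config$classify
  set <- load_particles_stack(out, wedge_spec(sc$theta_max))
  require_artifact(file.path(out, "aligned.star"), "align")
  b <- set$box
  mask <- spherical_mask(b, b / 2 - 2, 2)
  mask <- volume(mask$data, set$voxel_size)
  params <- mra_params(n_classes = 2, n_iterations = cc$n_iterations,
                       temperature_factor = cc$temperature_factor,
                       binning = 2, denoise_lowpass = cc$denoise_lowpass)
  spec <- bootstrap_spec(cc$n_bootstrap,
                         min(cc$bootstrap_size, n_particles(set)),
                         seed = derive_seed(config$seed, 77))
  res <- consensus_classify(set, mask, params, spec,
                            cc$n_repeats, master_seed = config$seed)
  log_line(log_con, sprintf("retained %d/%d particles; class counts %s",
                            length(res$retained), n_particles(set),
                            paste(res$class_counts, collapse = "/")))
  p <- set$particles
  p$class <- res$labels
  write_particles(p, file.path(out, "classified.star"))
  geom <- species_geometry()
  tpl1 <- build_species_map(geom, species_state("ELES1", "wide", "none"),
                            sc$box, sc$voxel_size)
  lab <- label_classes_by_template(res, tpl1, binning = params$binning)
  writeLines(yaml::as.yaml(list(bullet_class = lab$bullet_class,
                                counts = as.list(res$class_counts))),
             file.path(out, "class_assignment.yaml"))
  for (k in seq_along(res$references))
    write_mrc(res$references[[k]], file.path(out, sprintf("class_%d.mrc", k)))
  invisible(NULL)
}

#' Identify which consensus class is the asymmetric (bullet) complex
#'
#' Correlates each consensus class reference with a bullet template
#' (binned to the reference grid) and returns the class index with the
#' higher correlation.
#'
#' @param res a `consensus_result`.
#' @param bullet_template full-box bullet template volume.
#' @param binning binning at which the references were formed.
#' @export
label_classes_by_template <- function(res, bullet_template, binning = 1) {
  tpl <- if (binning > 1) bin_volume(bullet_template, binning) else bullet_template
  cors <- vapply(res$references, function(r) vol_cor(r, tpl), numeric(1))
  list(bullet_class = which.max(cors), correlations = cors)
}

stage_census <- function(config, out, log_con) {
  cl <- read_particles(require_artifact(file.path(out, "classified.star"),
                                        "classify"))
  hits <- read_particles(require_artifact(file.path(out, "hits.star"), "match"))
  asg <- yaml::read_yaml(file.path(out, "class_assignment.yaml"))
  cl$condition <- config$condition
  cl$state_label <- ifelse(is.na(cl$class), "unassigned",
                           ifelse(cl$class == asg$bullet_class, "ELES1", "ELES2"))
  ribo <- hits[hits$template == "RIBOSOME", , drop = FALSE]
  if (nrow(ribo)) ribo$condition <- config$condition
  tab <- census(cl[cl$state_label != "unassigned", , drop = FALSE],
                if (nrow(ribo)) ribo else NULL)
  utils::write.table(tab$per_tomogram, file.path(out, "census_per_tomogram.tsv"),
                     row.names = FALSE, quote = FALSE, sep = "\t")
  utils::write.table(tab$pooled, file.path(out, "census_pooled.tsv"),
                     row.names = FALSE, quote = FALSE, sep = "\t")
  log_line(log_con, "census written")
  invisible(NULL)
}
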