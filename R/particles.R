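#' Particle set
#'
#' Couples a particle table (positions in 0-based voxels, ZYZ Euler angles in
#' degrees, per-particle shifts in voxels, scores and labels) with its
#' subtomogram stack and the tilt geometry the stack was imaged under.
#'
#' @param particles data.frame with at least columns `id`, `tomogram`, `x`,
#'   `y`, `z`, `rot`, `tilt`, `psi`, `score`; optional `dx`, `dy`, `dz`,
#'   `class`, `state`, `condition`.
#' @param stack list of cubic volumes, one per particle row.
#' @param wedge a [wedge_spec()].
#' @return an object of class `particle_set`.
#' @export
particle_set <- function(particles, stack, wedge = wedge_spec()) {
  req <- c("id", "tomogram", "x", "y", "z", "rot", "tilt", "psi", "score")
  miss <- setdiff(req, names(particles))
  if (length(miss)) stop("particle table misses column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(particles$id)) stop("particle ids must be unique")
  if (length(stack) != nrow(particles))
    stop("stack length must equal the number of particle records")
  for (col in c("dx", "dy", "dz"))
    if (is.null(particles[[col]])) particles[[col]] <- 0
  box <- dim(stack[[1]]$data)[1]
  structure(list(particles = particles, stack = stack, wedge = wedge,
                 box = box, voxel_size = stack[[1]]$voxel_size),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set: %d particles, box %d, %.3f A/voxel>\n",
              nrow(x$particles), x$box, x$voxel_size))
  invisible(x)
}

n_particles <- function(set) nrow(set$particles)

particle_euler <- function(set, i) {
  euler(set$particles$rot[i], set$particles$tilt[i], set$particles$psi[i])
}

particle_shift <- function(set, i) {
  as.numeric(set$particles[i, c("dx", "dy", "dz")])
}

#' Build a particle set from a simulated stack
#'
#' Convenience wrapper turning [simulate_particle_stack()] output into a
#' [particle_set()], carrying the ground-truth labels in the `state` column.
#'
#' @param sim output of [simulate_particle_stack()].
#' @param tomogram tomogram identifier recorded for every particle.
#' @param condition condition tag.
#' @param keep_orientations if `FALSE`, zero the recorded orientations
#'   (unaligned set).
#' @export
stack_to_particle_set <- function(sim, tomogram = "sim", condition = "sim",
                                  keep_orientations = TRUE) {
  tr <- sim$truth
  p <- data.frame(id = tr$id, tomogram = tomogram,
                  x = NA_real_, y = NA_real_, z = NA_real_,
                  rot = if (keep_orientations) tr$rot else 0,
                  tilt = if (keep_orientations) tr$tilt else 0,
                  psi = if (keep_orientations) tr$psi else 0,
                  score = NA_real_, dx = 0, dy = 0, dz = 0,
                  state = tr$state_label, condition = condition,
                  stringsAsFactors = FALSE)
  particle_set(p, sim$stack, wedge_spec_of(sim))
}

wedge_spec_of <- function(sim) {
  # the simulator records its tilt geometry on the sample-frame mask
  attr(sim$wedge, "spec") %||% wedge_spec()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- cached Fourier representation -----------------------------------------

# Rotate every subtomogram (and its wedge) into the reference frame and cache
# FFTs as n x V matrices for BLAS-based scoring and averaging.
# Returns list(FR, FI, W, box, voxel_size, norm) where norm[p] = ||sqrt(W_p) F_p||.
prep_reference_frame <- function(set, binning = 1, real_mask = NULL,
                                 lowpass = NULL, rotate = TRUE, crop = NULL) {
  n <- n_particles(set)
  b0 <- set$box
  b <- b0 / binning
  if (b != round(b)) stop("box not divisible by binning")
  if (!is.null(crop) && crop < b) b <- crop else crop <- NULL
  W0 <- make_wedge_mask(b, set$voxel_size * binning, set$wedge)
  if (is.null(real_mask)) real_mask <- spherical_mask(b)
  m <- real_mask$data
  sw <- sum(m)
  V <- b^3
  WFR <- matrix(0, n, V)
  WFI <- matrix(0, n, V)
  W <- matrix(0, n, V)
  for (i in seq_len(n)) {
    v <- set$stack[[i]]
    if (binning > 1) v <- bin_volume(v, binning)
    e <- particle_euler(set, i)
    s <- particle_shift(set, i) / binning
    if (rotate) {
      Rm <- euler_to_matrix(e)
      v <- apply_transform(v, euler_inverse(e), shift = as.numeric(-t(Rm) %*% s))
      Wi <- rotate_wedge_mask(W0, e)$grid
    } else {
      Wi <- W0$grid
    }
    if (!is.null(crop)) v <- crop_volume(v, crop)
    if (!is.null(lowpass)) v <- lowpass_filter(v, lowpass)
    a <- m * (v$data - sum(m * v$data) / sw)
    Fv <- fft(a)
    Wi[1, 1, 1] <- 0
    wv <- as.vector(Wi)
    WFR[i, ] <- wv * Re(Fv)
    WFI[i, ] <- wv * Im(Fv)
    W[i, ] <- wv
  }
  # wedge values lie in [0,1]; ||sqrt(W) F||^2 = sum(W F^2) = sum((WF)^2 / W)
  norm <- sqrt(rowSums(safe_div(WFR^2 + WFI^2, W)))
  list(WFR = WFR, WFI = WFI, W = W, box = b,
       voxel_size = set$voxel_size * binning,
       mask = m, norm = norm, rotated = rotate)
}

# Score every cached particle against reference volumes under the particle
# wedges: score[p, k] = <W_p F_p, T_k> / (||sqrt(W_p) F_p|| ||sqrt(W_p) T_k||)
score_against_refs <- function(prep, refs) {
  V <- prep$box^3
  K <- length(refs)
  TR <- matrix(0, V, K)
  TI <- matrix(0, V, K)
  sw <- sum(prep$mask)
  for (k in seq_len(K)) {
    a <- prep$mask * (refs[[k]]$data - sum(prep$mask * refs[[k]]$data) / sw)
    Fv <- fft(a)
    TR[, k] <- Re(Fv)
    TI[, k] <- Im(Fv)
  }
  num <- prep$WFR %*% TR + prep$WFI %*% TI
  den_t <- sqrt(prep$W %*% (TR^2 + TI^2))
  sc <- num / (den_t * prep$norm)
  sc[!is.finite(sc)] <- -1
  sc
}

safe_div <- function(a, b) {
  out <- a / b
  out[b == 0] <- 0
  out
}

# Wedge-compensated average of a cached subset (row indices), returned as a
# volume in the reference frame.
average_cached <- function(prep, idx, floor_frac = 0.01) {
  if (!length(idx)) stop("cannot average an empty particle subset")
  ind <- tabulate(idx, nrow(prep$W))  # keeps multiplicity of with-replacement draws
  average_cached_weighted(prep, ind, floor_frac)
}

# Batched wedge-compensated averages: Ind is a B x n weight matrix (one row
# per requested average).  Returns real-space averages as a B x V matrix.
# One GEMM per component keeps the cache-friendly path hot.
average_cached_batch <- function(prep, Ind, floor_frac = 0.01) {
  SW <- Ind %*% prep$W
  NR <- Ind %*% prep$WFR
  NI <- Ind %*% prep$WFI
  b <- prep$box
  out <- matrix(0, nrow(Ind), b^3)
  for (j in seq_len(nrow(Ind))) {
    den <- pmax(SW[j, ], floor_frac * max(SW[j, ]))
    Fa <- array(complex(real = NR[j, ] / den, imaginary = NI[j, ] / den),
                rep(b, 3))
    out[j, ] <- Re(fft(Fa, inverse = TRUE)) / b^3
  }
  out
}

# weighted wedge-compensated average (w = per-particle weights)
average_cached_weighted <- function(prep, ind, floor_frac = 0.01) {
  if (sum(ind) <= 0) stop("cannot average an empty particle subset")
  sw <- as.numeric(crossprod(ind, prep$W))
  nr <- as.numeric(crossprod(ind, prep$WFR))
  ni <- as.numeric(crossprod(ind, prep$WFI))
  den <- pmax(sw, floor_frac * max(sw))
  b <- prep$box
  Fa <- array(complex(real = nr / den, imaginary = ni / den), rep(b, 3))
  volume(Re(fft(Fa, inverse = TRUE)) / b^3, prep$voxel_size)
}
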