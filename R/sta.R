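# Desk-scale analog of the subtomogram-averaging workflow: synthetic bell
# densities, noisy particle stacks with a missing wedge, in-plane alignment
# and averaging, rotational symmetry detection and FSC resolution.

#' Synthesize a bell-shaped density volume
#'
#' Builds a smooth truncated-cone shell running from the base diameter at
#' the bilayer to the narrowed top diameter, sitting atop a planar bilayer
#' patch, with `n_fold`-periodic azimuthal bumps representing the subunits.
#' The result is symmetric under rotation by `360 / n_fold` degrees to
#' within interpolation error. For `n_fold = 1` the volume is azimuthally
#' uniform.
#'
#' @param geometry A [bell_geometry()] (defaults give the 190.2 / 84.0 /
#'   89.0 A envelope).
#' @param n_fold Rotational symmetry order of the azimuthal modulation.
#' @param n Grid side in voxels, `>= 16`.
#' @param voxel_size Voxel size in Angstrom; the envelope must fit in the
#'   box with at least a 10% margin.
#' @param shell_sigma Gaussian width of the cone shell, Angstrom.
#' @param bump_amplitude Relative amplitude of the azimuthal modulation
#'   (ignored for `n_fold = 1`).
#' @return A [density_volume()]; density is nonzero only inside the
#'   envelope plus a `3 * shell_sigma` margin.
#' @export
synth_bell_volume <- function(geometry = bell_geometry(), n_fold = 11,
                              n = 64, voxel_size = 4, shell_sigma = 6,
                              bump_amplitude = 0.5) {
  stopifnot(inherits(geometry, "bell_geometry"))
  check_scalar(n_fold, "n_fold", 1, integer = TRUE)
  check_scalar(n, "n", 16, integer = TRUE)
  check_scalar(voxel_size, "voxel_size", 0, strict_lower = TRUE)
  box <- n * voxel_size
  margin <- 3 * shell_sigma
  extent_xy <- geometry$base_diameter + 2 * margin
  extent_z <- geometry$height + geometry$membrane_thickness + 2 * margin
  if (extent_xy > 0.9 * box || extent_z > 0.9 * box)
    stop_invalid("envelope does not fit in the grid with a 10% margin")

  c0 <- (n + 1) / 2
  coord <- (seq_len(n) - c0) * voxel_size
  r_base <- geometry$base_diameter / 2
  r_top <- geometry$top_diameter / 2
  h <- geometry$height
  th <- geometry$membrane_thickness
  amp <- if (n_fold == 1L) 0 else bump_amplitude

  xg <- matrix(rep(coord, times = n), n, n)
  yg <- matrix(rep(coord, each = n), n, n)
  r2d <- sqrt(xg^2 + yg^2)
  az <- atan2(yg, xg)
  modulation <- 1 + amp * cos(n_fold * az)

  grid <- array(0, dim = c(n, n, n))
  # center the structure (z spans [-th, h]) in the box
  z_off <- (h - th) / 2
  # radially tapered bilayer patch: a hard disc edge would dominate the
  # interpolation error of rotational resampling
  slab_taper <- exp(-pmax(r2d - r_base, 0)^2 / (2 * (margin / 3)^2))
  slab_taper[r2d > r_base + margin] <- 0
  for (k in seq_len(n)) {
    z <- coord[k] + z_off
    if (z >= -th && z < 0) {
      grid[, , k] <- slab_taper * exp(-((z + th / 2) / (th / 3))^2)
    } else if (z >= 0 && z <= h) {
      rc <- r_base + (r_top - r_base) * z / h
      shell <- exp(-((r2d - rc) / shell_sigma)^2)
      shell[abs(r2d - rc) > margin] <- 0
      grid[, , k] <- shell * modulation
    }
  }
  density_volume(grid, voxel_size)
}

#' Simulate a particle stack from a template
#'
#' Each particle is the template rotated in-plane by a uniform random angle
#' and shifted by uniform random x/y offsets of at most `max_shift` voxels
#' (one combined bilinear resampling), then degraded by a hard Fourier-space
#' missing wedge and white Gaussian noise. True poses are recorded and half
#' sets assigned alternately. Reproducible for a fixed seed.
#'
#' @param template A [density_volume()].
#' @param n_particles Number of particles, `>= 2`.
#' @param noise_sd Gaussian noise standard deviation, `>= 0` (template
#'   shell density has unit scale).
#' @param max_shift Maximum |shift| per axis, voxels.
#' @param wedge_halfangle Missing-wedge half-angle in degrees (0 disables;
#'   30 corresponds to a +/-60 degree tilt range).
#' @param seed Integer seed.
#' @param angles Optional fixed per-particle angles (degrees), overriding
#'   the random draw.
#' @return Object of class `particle_stack`: list with `particles` (list of
#'   arrays), `voxel_size`, `true_poses` (data.frame `angle`, `sx`, `sy`),
#'   `half_set`, `wedge_halfangle`.
#' @export
simulate_stack <- function(template, n_particles, noise_sd = 1,
                           max_shift = 2, wedge_halfangle = 30, seed = 1,
                           angles = NULL) {
  stopifnot(inherits(template, "density_volume"))
  check_scalar(n_particles, "n_particles", 2, integer = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(max_shift, "max_shift", 0)
  n <- dim(template$grid)[1]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ang <- if (is.null(angles)) stats::runif(n_particles, 0, 360)
         else rep_len(angles, n_particles)
  sx <- stats::runif(n_particles, -max_shift, max_shift)
  sy <- stats::runif(n_particles, -max_shift, max_shift)

  particles <- vector("list", n_particles)
  for (i in seq_len(n_particles)) {
    g <- apply_inplane_map(template$grid,
                           inplane_map(n, ang[i], c(sx[i], sy[i])))
    g <- apply_wedge(g, wedge_halfangle)
    if (noise_sd > 0)
      g <- g + array(stats::rnorm(n^3, 0, noise_sd), dim = dim(g))
    particles[[i]] <- g
  }
  structure(list(
    particles = particles, voxel_size = template$voxel_size,
    true_poses = data.frame(angle = ang, sx = sx, sy = sy),
    half_set = rep_len(c(1L, 2L), n_particles),
    wedge_halfangle = wedge_halfangle), class = "particle_stack")
}

#' @export
print.particle_stack <- function(x, ...) {
  n <- dim(x$particles[[1]])[1]
  cat(sprintf("particle_stack: %d particles, %d^3 voxels, %.3g A/voxel\n",
              length(x$particles), n, x$voxel_size))
  invisible(x)
}

# integer x/y shift with zero fill
shift_grid <- function(grid, sx, sy) {
  n <- dim(grid)[1]
  out <- array(0, dim = dim(grid))
  xs <- seq_len(n) - sx; ys <- seq_len(n) - sy
  okx <- xs >= 1 & xs <= n; oky <- ys >= 1 & ys <= n
  out[which(okx), which(oky), ] <- grid[xs[okx], ys[oky], , drop = FALSE]
  out
}

#' Align a particle stack and compute its average and half maps
#'
#' Exhaustive in-plane search: for every particle, every angle on a grid of
#' step `angle_step` degrees combined with every integer x/y shift up to
#' `max_shift` voxels is scored by real-space cross-correlation against the
#' reference (initialized as the unaligned mean), and the best pose kept.
#' One refinement pass against the first-pass average follows. Half maps
#' average the aligned particles of each half set under the final poses.
#'
#' @param stack A [simulate_stack()] particle stack.
#' @param angle_step Angular search step in degrees, `> 0`.
#' @param max_shift Maximum integer shift searched per axis, voxels.
#' @return List with `average`, `half_map_1`, `half_map_2` (all
#'   [density_volume()]) and `poses` (data.frame `angle`, `sx`, `sy`,
#'   `score` per particle).
#' @export
align_and_average <- function(stack, angle_step = 15, max_shift = 2) {
  stopifnot(inherits(stack, "particle_stack"))
  check_scalar(angle_step, "angle_step", 0, strict_lower = TRUE)
  check_scalar(max_shift, "max_shift", 0, integer = TRUE)
  n <- dim(stack$particles[[1]])[1]
  np <- length(stack$particles)
  nvox <- n^3

  p_mat <- vapply(stack$particles, as.numeric, numeric(nvox))
  angles <- seq(0, 360 - angle_step, by = angle_step)
  shifts <- expand.grid(sx = -max_shift:max_shift, sy = -max_shift:max_shift)
  ns <- nrow(shifts)

  search_pass <- function(ref_grid) {
    best_score <- rep(-Inf, np)
    best <- data.frame(angle = numeric(np), sx = integer(np),
                       sy = integer(np), score = numeric(np))
    for (a in angles) {
      rot <- apply_inplane_map(ref_grid, inplane_map(n, a))
      # the missing wedge is fixed in the lab frame: filter the rotated
      # reference with it, otherwise the wedge imprint biases the search
      rot <- apply_wedge(rot, stack$wedge_halfangle)
      s_mat <- vapply(seq_len(ns), function(s)
        as.numeric(shift_grid(rot, shifts$sx[s], shifts$sy[s])),
        numeric(nvox))
      scores <- crossprod(s_mat, p_mat)      # ns x np
      for (i in seq_len(np)) {
        s <- which.max(scores[, i])
        if (scores[s, i] > best_score[i]) {
          best_score[i] <- scores[s, i]
          best$angle[i] <- a
          best$sx[i] <- shifts$sx[s]; best$sy[i] <- shifts$sy[s]
          best$score[i] <- scores[s, i]
        }
      }
    }
    best
  }
  align_particles <- function(poses) {
    aligned <- vector("list", np)
    for (i in seq_len(np)) {
      a <- poses$angle[i]
      t_rot <- rot_z(-a * pi / 180)[1:2, 1:2] %*%
        c(poses$sx[i], poses$sy[i])
      aligned[[i]] <- apply_inplane_map(
        stack$particles[[i]], inplane_map(n, -a, -as.numeric(t_rot)))
    }
    aligned
  }

  ref <- array(rowMeans(p_mat), dim = c(n, n, n))
  poses <- search_pass(ref)
  aligned <- align_particles(poses)
  ref2 <- Reduce(`+`, aligned) / np
  poses <- search_pass(ref2)
  aligned <- align_particles(poses)

  h1 <- which(stack$half_set == 1L); h2 <- which(stack$half_set == 2L)
  avg <- Reduce(`+`, aligned) / np
  # degenerate stacks may leave a half set empty; fall back to the average
  m1 <- if (length(h1)) Reduce(`+`, aligned[h1]) / length(h1) else avg
  m2 <- if (length(h2)) Reduce(`+`, aligned[h2]) / length(h2) else avg
  list(average = density_volume(avg, stack$voxel_size),
       half_map_1 = density_volume(m1, stack$voxel_size),
       half_map_2 = density_volume(m2, stack$voxel_size),
       poses = poses)
}

#' Azimuthal rotational power spectrum of a volume
#'
#' Samples the density on rings (cylindrical coordinates) across radii and
#' heights, computes the azimuthal Fourier power at each requested order
#' summed over all rings, and normalizes by the total sampled energy (so a
#' value is the fraction of ring energy carried by that order; an
#' azimuthally uniform volume gives near-zero for every order). The argmax
#' over orders `>= 2` is the detected rotational symmetry order.
#'
#' @param volume A [density_volume()].
#' @param orders Integer vector of candidate orders within `[1, 24]`.
#' @param n_azimuth Number of azimuthal samples per ring.
#' @return Named numeric vector of normalized power per order, with
#'   attribute `detected` = order of maximal power among orders `>= 2`.
#' @export
rotational_power_spectrum <- function(volume, orders = 2:15,
                                      n_azimuth = 180) {
  stopifnot(inherits(volume, "density_volume"))
  orders <- as.integer(orders)
  if (any(orders < 1L) || any(orders > 24L))
    stop_invalid("orders must lie within [1, 24]")
  n <- dim(volume$grid)[1]
  c0 <- (n + 1) / 2
  r_max <- (n / 2 - 2)
  radii <- seq(0.15, 0.95, by = 0.04) * r_max
  if (!length(radii)) stop_input("empty sampling annulus")
  phi <- 2 * pi * (seq_len(n_azimuth) - 1) / n_azimuth

  # bilinear sample every ring in every slice
  pts_x <- outer(radii, cos(phi)) + c0      # n_r x n_az
  pts_y <- outer(radii, sin(phi)) + c0
  i0 <- floor(pts_x); j0 <- floor(pts_y)
  fx <- pts_x - i0; fy <- pts_y - j0
  idx <- function(ii, jj) {
    ii <- pmin(pmax(ii, 1L), n); jj <- pmin(pmax(jj, 1L), n)
    (jj - 1L) * n + ii
  }
  i00 <- idx(i0, j0); i10 <- idx(i0 + 1, j0)
  i01 <- idx(i0, j0 + 1); i11 <- idx(i0 + 1, j0 + 1)
  w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
  w01 <- (1 - fx) * fy; w11 <- fx * fy

  power <- stats::setNames(numeric(length(orders)), orders)
  energy <- 0
  e_basis <- exp(-1i * outer(orders, phi))  # n_orders x n_az
  for (k in seq_len(n)) {
    sl <- volume$grid[, , k]
    ring <- sl[i00] * w00 + sl[i10] * w10 + sl[i01] * w01 + sl[i11] * w11
    ring <- matrix(ring, nrow = length(radii))
    energy <- energy + sum(ring^2) * n_azimuth
    ring <- ring - rowMeans(ring)            # remove order-0 component
    coef <- ring %*% t(Conj(e_basis))        # n_r x n_orders
    power <- power + colSums(Mod(coef)^2)
  }
  if (energy > 0) power <- power / energy
  det_orders <- orders[orders >= 2L]
  attr(power, "detected") <-
    det_orders[which.max(power[as.character(det_orders)])]
  power
}

#' Detected rotational symmetry order
#'
#' @param volume A [density_volume()].
#' @param orders Candidate orders (default 2 to 15).
#' @return Integer order with maximal azimuthal power.
#' @export
detect_symmetry_order <- function(volume, orders = 2:15) {
  attr(rotational_power_spectrum(volume, orders), "detected")
}

#' Fourier shell correlation between two half maps
#'
#' Correlates the Fourier coefficients of two volumes shell by shell
#' (shell width one frequency voxel):
#' `FSC(s) = Re(sum F1 conj(F2)) / sqrt(sum |F1|^2 sum |F2|^2)`.
#'
#' @param half_1,half_2 [density_volume()] objects on matching grids.
#' @param threshold Threshold for [fsc_resolution()] (default 0.143).
#' @return Object of class `fsc_curve`: data.frame with
#'   `shell_frequency` (1/Angstrom, ascending) and `correlation`, plus
#'   attributes `threshold` and `voxel_size`.
#' @export
fsc <- function(half_1, half_2, threshold = 0.143) {
  stopifnot(inherits(half_1, "density_volume"),
            inherits(half_2, "density_volume"))
  if (!identical(dim(half_1$grid), dim(half_2$grid)) ||
      half_1$voxel_size != half_2$voxel_size)
    stop_input("half maps must share grid and voxel size")
  n <- dim(half_1$grid)[1]
  f1 <- stats::fft(half_1$grid)
  f2 <- stats::fft(half_2$grid)
  k <- fft_freq_index(n)
  kx <- array(rep(k, times = n * n), dim = c(n, n, n))
  ky <- array(rep(rep(k, each = n), times = n), dim = c(n, n, n))
  kz <- array(rep(k, each = n * n), dim = c(n, n, n))
  shell <- round(sqrt(kx^2 + ky^2 + kz^2))
  keep <- shell >= 1 & shell <= n / 2
  sh <- factor(shell[keep], levels = seq_len(n %/% 2))
  num <- tapply(Re(f1[keep] * Conj(f2[keep])), sh, sum)
  d1 <- tapply(Mod(f1[keep])^2, sh, sum)
  d2 <- tapply(Mod(f2[keep])^2, sh, sum)
  corr <- as.numeric(num) / sqrt(as.numeric(d1) * as.numeric(d2))
  freq <- seq_len(n %/% 2) / (n * half_1$voxel_size)
  out <- data.frame(shell_frequency = freq, correlation = corr)
  attr(out, "threshold") <- threshold
  attr(out, "voxel_size") <- half_1$voxel_size
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Resolution at an FSC threshold
#'
#' Reads the resolution at the first downward crossing of the threshold,
#' linearly interpolating the frequency between the bracketing shells.
#'
#' @param curve An [fsc()] curve.
#' @param threshold Correlation threshold (defaults to the curve's own,
#'   normally 0.143).
#' @return Resolution in Angstrom (`1 / frequency`). If the curve never
#'   drops below the threshold, the Nyquist resolution `2 * voxel_size` is
#'   returned; if it starts below, the resolution of the first shell.
#' @export
fsc_resolution <- function(curve, threshold = NULL) {
  stopifnot(inherits(curve, "fsc_curve"))
  threshold <- threshold %||% attr(curve, "threshold")
  corr <- curve$correlation
  freq <- curve$shell_frequency
  if (corr[1] < threshold) return(1 / freq[1])
  below <- which(corr < threshold)
  if (!length(below)) return(2 * attr(curve, "voxel_size"))
  j <- below[1]
  f_cross <- freq[j - 1] + (freq[j] - freq[j - 1]) *
    (corr[j - 1] - threshold) / (corr[j - 1] - corr[j])
  1 / f_cross
}

#' Write an FSC curve as TSV
#'
#' @param curve An [fsc()] curve.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fsc <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Particle density and group comparison
#'
#' @param count Particle count, `>= 0`.
#' @param volume_um3 Sampled volume in cubic micrometres, `> 0`.
#' @return Particle density, particles per cubic micrometre.
#' @export
particle_density <- function(count, volume_um3) {
  check_scalar(count, "count", 0)
  check_scalar(volume_um3, "volume_um3", 0, strict_lower = TRUE)
  count / volume_um3
}

#' @rdname particle_density
#' @param densities_1,densities_2 Per-tomogram particle densities of two
#'   groups (e.g. wild-type vs knockdown).
#' @return `compare_particle_densities` returns the two-sided two-sample
#'   Student's t-test (`stats::t.test`, pooled variance) of the group
#'   densities.
#' @export
compare_particle_densities <- function(densities_1, densities_2) {
  stats::t.test(densities_1, densities_2, var.equal = TRUE)
}
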