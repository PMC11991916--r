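# Cubic density volumes: container, MRC (mode 2) I/O, in-plane resampling
# and rotational symmetrization.

#' Cubic density volume
#'
#' Container for a cubic voxel grid with isotropic voxel size. The volume
#' center sits at the grid center, voxel `(N + 1) / 2` in 1-based
#' continuous coordinates; rotations are about the +z axis through that
#' center.
#'
#' @param grid Numeric 3D array with equal dimensions `N >= 16`.
#' @param voxel_size Voxel edge length in Angstrom, `> 0`.
#' @return Object of class `density_volume`.
#' @export
density_volume <- function(grid, voxel_size) {
  d <- dim(grid)
  if (is.null(d) || length(d) != 3L || length(unique(d)) != 1L)
    stop_input("grid must be a cubic 3D array")
  if (d[1] < 16L) stop_invalid("grid side must be >= 16 voxels")
  check_scalar(voxel_size, "voxel_size", 0, strict_lower = TRUE)
  if (!all(is.finite(grid))) stop_input("grid values must be finite")
  structure(list(grid = grid, voxel_size = voxel_size),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  n <- dim(x$grid)[1]
  cat(sprintf("density_volume: %d^3 voxels, %.3g A/voxel (%.1f A box)\n",
              n, x$voxel_size, n * x$voxel_size))
  invisible(x)
}

# ---- MRC I/O ----------------------------------------------------------------
# Minimal MRC2014 mode-2 (float32) reader/writer. R arrays are column-major
# with the first index fastest, matching the MRC x-fastest data layout.

#' Write a density volume as an MRC file
#'
#' Writes MRC2014 mode 2 (32-bit float, little-endian) with the voxel size
#' in the cell header. 32-bit float volumes round-trip bit-exactly.
#'
#' @param volume A [density_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(volume, path) {
  stopifnot(inherits(volume, "density_volume"))
  n <- dim(volume$grid)[1]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  g <- volume$grid
  wi(c(n, n, n))                      # nx ny nz
  wi(2L)                              # mode 2 = float32
  wi(c(0L, 0L, 0L))                   # nxstart nystart nzstart
  wi(c(n, n, n))                      # mx my mz
  wf(rep(n * volume$voxel_size, 3))   # cella
  wf(c(90, 90, 90))                   # cellb
  wi(c(1L, 2L, 3L))                   # mapc mapr maps
  wf(c(min(g), max(g), mean(g)))      # dmin dmax dmean
  wi(c(1L, 0L))                       # ispg nsymbt
  wi(rep(0L, 25))                     # extra
  wf(c(0, 0, 0))                      # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(g)))        # rms
  wi(0L)                              # nlabl
  writeBin(raw(800L), con)            # labels
  writeBin(as.numeric(g), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC volume
#'
#' Reads cubic MRC2014 mode-2 volumes written by [write_mrc()] (or any
#' little-endian float32 MRC with a cubic grid).
#'
#' @param path MRC file path.
#' @return A [density_volume()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4L, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4L, endian = "little")
  nxyz <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop_input("only MRC mode 2 (float32) is supported")
  if (length(unique(nxyz)) != 1L) stop_input("only cubic volumes supported")
  ri(3)                               # nxstart..
  mxyz <- ri(3)
  cella <- rf(3)
  seek(con, 1024L)
  n <- nxyz[1]
  g <- readBin(con, "numeric", n^3, size = 4L, endian = "little")
  density_volume(array(g, dim = c(n, n, n)), cella[1] / mxyz[1])
}

# ---- in-plane resampling ----------------------------------------------------

# Sparse bilinear resampling matrix for an in-plane (about +z) rotation by
# `theta` degrees followed by a shift of `shift` voxels in (x, y):
# out(x) = in(R_{-theta} (x - t)). Acting on a vectorized N x N slice;
# shared by every z-slice. Source samples outside the grid contribute zero.
inplane_map <- function(n, theta, shift = c(0, 0)) {
  c0 <- (n + 1) / 2
  th <- theta * pi / 180
  idx <- seq_len(n) - c0
  px <- rep(idx, times = n) - shift[1]
  py <- rep(idx, each = n) - shift[2]
  sx <- cos(th) * px + sin(th) * py + c0
  sy <- -sin(th) * px + cos(th) * py + c0
  i0 <- floor(sx); j0 <- floor(sy)
  fx <- sx - i0; fy <- sy - j0
  out <- seq_len(n * n)
  entries <- function(ii, jj, w) {
    ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n & w > 0
    list(o = out[ok], s = (jj[ok] - 1L) * n + ii[ok], w = w[ok])
  }
  e <- list(entries(i0, j0, (1 - fx) * (1 - fy)),
            entries(i0 + 1, j0, fx * (1 - fy)),
            entries(i0, j0 + 1, (1 - fx) * fy),
            entries(i0 + 1, j0 + 1, fx * fy))
  Matrix::sparseMatrix(
    i = unlist(lapply(e, `[[`, "o")),
    j = unlist(lapply(e, `[[`, "s")),
    x = unlist(lapply(e, `[[`, "w")),
    dims = c(n * n, n * n))
}

apply_inplane_map <- function(grid, map) {
  n <- dim(grid)[1]
  array(as.matrix(map %*% matrix(grid, n * n, n)), dim = dim(grid))
}

#' Rotate (and shift) a volume in-plane
#'
#' Applies a rotation about +z through the volume center, followed by a
#' translation in x/y, using bilinear interpolation within each z-slice.
#' Regions resampled from outside the grid become zero.
#'
#' @param volume A [density_volume()].
#' @param theta Rotation angle in degrees (counter-clockwise viewed
#'   from +z).
#' @param shift Length-2 shift in voxels (x, y), applied after rotation.
#' @return A [density_volume()].
#' @export
rotate_volume <- function(volume, theta, shift = c(0, 0)) {
  stopifnot(inherits(volume, "density_volume"))
  n <- dim(volume$grid)[1]
  density_volume(apply_inplane_map(volume$grid, inplane_map(n, theta, shift)),
                 volume$voxel_size)
}

#' Impose n-fold rotational symmetry about +z
#'
#' Averages the volume over the `n` rotations by multiples of `360/n`
#' degrees (trilinear in-plane interpolation). The operator is idempotent
#' up to interpolation smoothing: applying it twice correlates with
#' applying it once to better than `1 - 1e-3` for smooth volumes.
#'
#' @param volume A [density_volume()].
#' @param n Symmetry order, integer `>= 1`; `n = 1` returns the input.
#' @return A [density_volume()].
#' @export
apply_cn_symmetry <- function(volume, n) {
  stopifnot(inherits(volume, "density_volume"))
  check_scalar(n, "n", 1, integer = TRUE)
  if (n == 1L) return(volume)
  nn <- dim(volume$grid)[1]
  acc <- volume$grid
  for (k in seq_len(n - 1L))
    acc <- acc + apply_inplane_map(volume$grid,
                                   inplane_map(nn, 360 * k / n))
  density_volume(acc / n, volume$voxel_size)
}

#' Pearson correlation between two volumes
#'
#' @param a,b [density_volume()] objects on matching grids.
#' @return Correlation of the voxel values.
#' @export
volume_correlation <- function(a, b) {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop_input("volumes must share grid dimensions")
  stats::cor(as.numeric(a$grid), as.numeric(b$grid))
}

# signed FFT frequencies in cycles per box edge, length n
fft_freq_index <- function(n) {
  k <- seq_len(n) - 1L
  ifelse(k <= n / 2, k, k - n)
}

# hard missing-wedge mask in Fourier space: excludes directions within
# `halfangle` degrees of the kz axis in the kx-kz plane (tilt axis = y),
# keeping the DC term
wedge_mask <- function(n, halfangle) {
  if (halfangle <= 0) return(array(1, dim = c(n, n, n)))
  k <- fft_freq_index(n)
  kx <- array(rep(abs(k), times = n * n), dim = c(n, n, n))
  kz <- array(rep(abs(k), each = n * n), dim = c(n, n, n))
  ang <- atan2(kx, kz) * 180 / pi
  mask <- ang >= halfangle
  mask[1, , ] <- mask[1, , ] | (kz[1, , ] == 0)  # keep kz = 0 plane's DC row
  mask[1, 1, 1] <- TRUE
  array(as.numeric(mask), dim = c(n, n, n))
}

apply_wedge <- function(grid, halfangle) {
  if (halfangle <= 0) return(grid)
  n <- dim(grid)[1]
  Re(stats::fft(stats::fft(grid) * wedge_mask(n, halfangle),
                inverse = TRUE)) / n^3
}
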