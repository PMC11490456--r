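#' Intensity volume container
#'
#' A 3D scalar grid with voxel spacing and origin in millimetres, the input
#' to segmentation. Voxel `[i, j, k]` has world coordinate
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric length-3, mm per voxel along each axis (or a
#'   scalar, recycled). Must be strictly positive.
#' @param origin Numeric length-3, world coordinate (mm) of voxel `[1,1,1]`.
#' @return An object of class `fstd_volume` with elements `data`, `spacing`,
#'   `origin`.
#' @export
fstd_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (length(data) == 0L) stop("volume grid is empty")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be strictly positive")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "fstd_volume")
}

#' @export
print.fstd_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fstd_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' World coordinates of all voxel centres
#' @param volume An [fstd_volume()].
#' @return List of three vectors `x`, `y`, `z` of per-axis coordinates (mm).
#' @keywords internal
voxel_axes <- function(volume) {
  d <- dim(volume$data)
  lapply(1:3, function(a) volume$origin[a] + (seq_len(d[a]) - 1) * volume$spacing[a])
}

# Separable Gaussian smoothing, kernel truncated at 3 sigma, replicate
# padding at the borders. sigma is in voxels, per axis.
smooth_volume <- function(volume, sigma = 1) {
  sigma <- rep_len(sigma, 3L)
  arr <- volume$data
  for (axis in 1:3) {
    s <- sigma[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, axis)
  }
  fstd_volume(arr, volume$spacing, volume$origin)
}

convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  r <- (length(kernel) - 1L) / 2L
  # replicate-pad rows, then filter columnwise
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m,
              m[rep(nrow(m), r), , drop = FALSE])
  out <- stats::filter(mp, kernel, sides = 2)
  out <- out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  a[] <- as.numeric(out)
  aperm(a, order(perm))
}
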