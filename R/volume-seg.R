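#' Histogram-based multi-class thresholds
#'
#' Computes `n_classes - 1` intensity thresholds by maximising the
#' between-class variance of the intensity histogram (multi-level Otsu),
#' the standard formalisation of valley-seeking "histogram" segmentation.
#' When several threshold placements are equally good (empty histogram
#' valleys), the midmost placement is returned.
#'
#' @param volume An [fstd_volume()].
#' @param n_classes Number of intensity classes (default 3: air, soft
#'   tissue, bone).
#' @param n_bins Histogram bin count.
#' @return Ascending numeric vector of `n_classes - 1` thresholds.
#' @export
histogram_thresholds <- function(volume, n_classes = 3L, n_bins = 128L) {
  x <- as.numeric(volume$data)
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate histogram: volume is constant")
  if (length(unique(round((x - rng[1]) / diff(rng) * (n_bins - 1)))) < n_classes)
    stop("volume has fewer than ", n_classes, " distinct intensity modes")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  cn <- cumsum(counts)
  cs <- cumsum(counts * mids)
  n_tot <- cn[n_bins]

  class_stat <- function(lo, hi) { # bins lo..hi inclusive
    w <- cn[hi] - if (lo > 1L) cn[lo - 1L] else 0
    s <- cs[hi] - if (lo > 1L) cs[lo - 1L] else 0
    if (w == 0) 0 else s^2 / w
  }
  k <- n_classes - 1L
  combos <- utils::combn(n_bins - 1L, k)
  score <- apply(combos, 2, function(th) {
    bounds <- c(0L, th, n_bins)
    tot <- 0
    for (c in seq_len(k + 1L))
      tot <- tot + class_stat(bounds[c] + 1L, bounds[c + 1L])
    tot
  })
  best <- which(score >= max(score) - 1e-9 * abs(max(score)))
  th_bins <- round(rowMeans(combos[, best, drop = FALSE]))
  breaks[th_bins + 1L] # upper edge of last bin in each class
}

#' Extract a surface mesh from an intensity volume
#'
#' Meshes the boundary of the region `{intensity >= low}` (optionally
#' `<= high`) with marching-tetrahedra isosurfacing at the threshold value,
#' restricted to the largest connected component. A light Gaussian
#' pre-smoothing of the intensity field (default 1 voxel SD) places the
#' iso-crossing at the half-maximum point of the partial-volume ramp, which
#' localises the tissue boundary sub-voxel; set `presmooth_sigma = 0` for
#' raw-field extraction. No mesh-level smoothing is ever applied.
#'
#' @param volume An [fstd_volume()].
#' @param low Lower intensity threshold (the iso-level).
#' @param high Optional upper threshold for band segmentation.
#' @param largest_component Keep only the largest connected surface/mask
#'   component (removes noise blobs). Default `TRUE`.
#' @param presmooth_sigma Gaussian pre-smoothing SD in voxels (0 disables).
#' @param closing Apply a radius-1 binary closing to the mask before
#'   reporting it (the surface itself is threshold-based). Default `FALSE`.
#' @param on_open What to do when the mask touches the grid border so the
#'   surface cannot be closed: `"warn"` (flag `closed = FALSE`) or
#'   `"error"`.
#' @param target Label recorded in the result (`"head"`, `"skull"`, ...).
#' @return An `fstd_segmentation` list: `mask`, `threshold_low`,
#'   `threshold_high`, `surface` ([fstd_mesh()] in mm), `closed`, `target`.
#' @export
extract_surface <- function(volume, low, high = NULL, largest_component = TRUE,
                            presmooth_sigma = 1, closing = FALSE,
                            on_open = c("warn", "error"), target = "head") {
  on_open <- match.arg(on_open)
  rng <- range(volume$data)
  if (low < rng[1] || low > rng[2])
    stop("threshold `low` is outside the volume intensity range")
  mask <- volume$data >= low
  if (!is.null(high)) mask <- mask & volume$data <= high
  if (!any(mask)) stop("empty mask: no voxels within the threshold band")
  d <- dim(volume$data)
  if (largest_component)
    mask <- array(.largest_component_mask(as.logical(mask), d), dim = d)
  touches <- any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])
  if (touches && on_open == "error")
    stop("mask touches the grid border; surface would be open")
  if (closing) mask <- binary_close(mask)

  field_vol <- if (presmooth_sigma > 0)
    smooth_volume(volume, presmooth_sigma) else volume
  if (is.null(high)) {
    field <- field_vol$data
    level <- low
  } else {
    field <- pmin(field_vol$data - low, high - field_vol$data)
    dim(field) <- d
    level <- 0
  }
  iso <- .mt_isosurface(as.numeric(field), d, volume$spacing, volume$origin, level)
  surface <- fstd_mesh(iso$vertices, iso$faces)
  if (largest_component) surface <- mesh_largest_component(surface)
  closed <- !touches && mesh_is_closed(surface)
  if (touches)
    warning("mask touches the grid border; surface flagged open")
  structure(list(mask = mask, threshold_low = low, threshold_high = high,
                 surface = surface, closed = closed, target = target),
            class = "fstd_segmentation")
}

#' @export
print.fstd_segmentation <- function(x, ...) {
  cat(sprintf("<fstd_segmentation> target %s, low %.4g%s, %s surface\n",
              x$target, x$threshold_low,
              if (!is.null(x$threshold_high))
                sprintf(", high %.4g", x$threshold_high) else "",
              if (x$closed) "closed" else "open"))
  print(x$surface)
  invisible(x)
}

#' Segment a head or skull surface from a CT-like volume
#'
#' Convenience pipeline step: derives the air/soft-tissue/bone thresholds
#' with [histogram_thresholds()] and extracts the skin surface (everything
#' above the air threshold) or the skull surface (everything above the
#' bone threshold). Either threshold can be overridden manually, mirroring
#' interactive edge correction.
#'
#' @param volume An [fstd_volume()].
#' @param target `"head"` (skin surface) or `"skull"`.
#' @param low Optional manual threshold override.
#' @param ... Passed to [extract_surface()].
#' @return An `fstd_segmentation`.
#' @export
segment_volume <- function(volume, target = c("head", "skull"), low = NULL, ...) {
  target <- match.arg(target)
  if (is.null(low)) {
    th <- histogram_thresholds(volume, 3L)
    low <- if (target == "head") th[1] else th[2]
  }
  extract_surface(volume, low = low, target = target, ...)
}

#' Enclosed volume of a closed mesh (mm^3)
#' @param mesh A closed [fstd_mesh()] with outward orientation.
#' @return Numeric scalar.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
        a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
        a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# radius-1 binary closing (6-connectivity dilate then erode)
binary_close <- function(mask) binary_erode(binary_dilate(mask))

shift_or <- function(mask, combine) {
  d <- dim(mask)
  out <- mask
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in shifts) {
    shifted <- array(FALSE, d)
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a]) - s[a]
      pmin(pmax(i, 1L), d[a])
    })
    shifted[] <- mask[src[[1]], src[[2]], src[[3]]]
    out <- combine(out, shifted)
  }
  out
}

binary_dilate <- function(mask) shift_or(mask, `|`)
binary_erode <- function(mask) shift_or(mask, `&`)
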