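#' Specify a voxel phantom with analytically known tissue depths
#'
#' The phantom is a star-shaped "skull" (by default an ellipsoid) wrapped in
#' a soft-tissue shell whose radial thickness is a known function of
#' direction, embedded in air. Because both surfaces are star-shaped around
#' the skull centroid, the tissue depth at any landmark direction is known
#' in closed form and the full segmentation/measurement pipeline can be
#' validated without CT data.
#'
#' @param semi_axes Skull ellipsoid semi-axes `c(a, b, c)` in mm.
#' @param thickness Radial soft-tissue thickness: a positive number
#'   (constant shell) or a function mapping an n x 3 matrix of unit
#'   directions to n non-negative thicknesses (mm).
#' @param intensities Named numeric `c(air=, soft_tissue=, bone=)`;
#'   must be strictly increasing in that order.
#' @param spacing Voxel spacing, mm (scalar or length 3).
#' @param noise_sd SD of additive Gaussian intensity noise (0 = noiseless).
#' @param margin_voxels Air margin around the skin surface, in voxels.
#' @param seed Integer seed used when noise is drawn.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(semi_axes = c(60, 50, 45), thickness = 5,
                         intensities = c(air = 0, soft_tissue = 100, bone = 200),
                         spacing = 1, noise_sd = 0, margin_voxels = 2,
                         seed = 1L) {
  if (length(semi_axes) != 3L || any(semi_axes <= 0))
    stop("`semi_axes` must be three positive numbers")
  if (is.numeric(thickness)) {
    th0 <- thickness
    if (th0 < 0) stop("tissue thickness must be non-negative")
    thickness <- function(dirs) rep(th0, nrow(dirs))
  }
  if (!is.function(thickness)) stop("`thickness` must be a number or function")
  if (length(intensities) != 3L || is.unsorted(intensities, strictly = TRUE))
    stop("`intensities` must be three increasing values (air < soft tissue < bone)")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("`spacing` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(semi_axes = as.numeric(semi_axes), thickness = thickness,
                 intensities = intensities, spacing = spacing,
                 noise_sd = noise_sd, margin_voxels = margin_voxels,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# radial distance to the ellipsoid surface along unit directions
ellipsoid_radius <- function(dirs, semi_axes) {
  1 / sqrt((dirs[, 1] / semi_axes[1])^2 + (dirs[, 2] / semi_axes[2])^2 +
             (dirs[, 3] / semi_axes[3])^2)
}

phantom_skin_radius <- function(spec, dirs) {
  th <- spec$thickness(dirs)
  if (any(!is.finite(th)) || any(th < 0))
    stop("tissue thickness must be non-negative everywhere")
  ellipsoid_radius(dirs, spec$semi_axes) + th
}

#' Build a voxel phantom volume with analytic ground truth
#'
#' Voxels are labelled by radial containment (inside the skull surface ->
#' bone intensity, between skull and skin -> soft tissue, outside -> air)
#' and optional Gaussian intensity noise is added. Ground-truth surfaces
#' are analytic star-shaped meshes, and `true_depth(dirs)` returns the
#' radial tissue thickness in any direction.
#'
#' @param spec A [phantom_spec()].
#' @param grid_dim Optional integer length-3 grid size; when given the grid
#'   must contain the skin surface plus the margin, otherwise an error names
#'   the offending axis. Default: smallest grid that does.
#' @param mesh_subdivisions Icosphere subdivision level of the ground-truth
#'   meshes.
#' @return List with `volume` ([fstd_volume()]), `skull` and `skin`
#'   ground-truth meshes ([fstd_mesh()]), `true_depth` (function of unit
#'   direction matrix), `centre` (mm) and `labels` (the noiseless class
#'   array: 0 air, 1 soft tissue, 2 bone).
#' @export
make_phantom_volume <- function(spec, grid_dim = NULL, mesh_subdivisions = 4) {
  stopifnot(inherits(spec, "phantom_spec"))
  probe <- icosphere(3)$vertices
  r_skin <- phantom_skin_radius(spec, probe)
  half_extent <- vapply(1:3, function(a) max(abs(probe[, a] * r_skin)), 0)
  need <- half_extent + spec$margin_voxels * spec$spacing
  if (is.null(grid_dim)) {
    grid_dim <- 2L * ceiling(need / spec$spacing) + 1L
  } else {
    grid_dim <- as.integer(rep_len(grid_dim, 3L))
    have <- (grid_dim - 1L) / 2 * spec$spacing
    short <- which(have < need - 1e-9)
    if (length(short) > 0L)
      stop("skin surface exits the grid along axis ",
           paste(c("x", "y", "z")[short], collapse = ", "))
  }
  centre <- c(0, 0, 0)
  origin <- centre - (grid_dim - 1L) / 2 * spec$spacing
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(grid_dim[a]) - 1) * spec$spacing[a])

  # radial containment per voxel
  px <- rep(ax[[1]], times = grid_dim[2] * grid_dim[3])
  py <- rep(rep(ax[[2]], each = grid_dim[1]), times = grid_dim[3])
  pz <- rep(ax[[3]], each = grid_dim[1] * grid_dim[2])
  r <- sqrt(px^2 + py^2 + pz^2)
  dirs <- cbind(px, py, pz) / pmax(r, 1e-12)
  dirs[r < 1e-12, ] <- matrix(c(1, 0, 0), sum(r < 1e-12), 3, byrow = TRUE)
  rk <- ellipsoid_radius(dirs, spec$semi_axes)
  rs <- rk + spec$thickness(dirs)
  labels <- ifelse(r <= rk, 2L, ifelse(r <= rs, 1L, 0L))
  data <- spec$intensities[labels + 1L]
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    data <- data + stats::rnorm(length(data), sd = spec$noise_sd)
  }
  volume <- fstd_volume(array(data, dim = grid_dim), spec$spacing, origin)

  skull <- make_star_mesh(function(d) ellipsoid_radius(d, spec$semi_axes),
                          centre, mesh_subdivisions)
  skin <- make_star_mesh(function(d) phantom_skin_radius(spec, d),
                         centre, mesh_subdivisions)
  true_depth <- function(dirs) {
    dirs <- matrix(dirs, ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    spec$thickness(dirs)
  }
  list(volume = volume, skull = skull, skin = skin, true_depth = true_depth,
       centre = centre, labels = array(labels, dim = grid_dim), spec = spec)
}

#' Specify a synthetic measurement cohort
#'
#' Emulates the statistical structure of an FSTD study: per-landmark
#' normal depth distributions with per-sex means, balanced sex-by-age-group
#' cells, an optional left-minus-right asymmetry shift at bilateral
#' landmarks, an optional linear age trend, and paired remeasurement
#' sessions with independent Gaussian session noise. Depths are truncated
#' at zero by redrawing (not clipping), preserving approximate normality.
#'
#' @param n_per_cell Subjects per sex-by-age-group cell (10 cells).
#' @param landmark_means Tibble with columns `code`, `sex`, `mean_mm`
#'   (and optionally `sd_mm`); default [greek_cohort_defaults()], the pooled
#'   per-sex values of the packaged Greek descriptive tables.
#' @param landmark_sds Optional tibble `code`, `sex`, `sd_mm` overriding the
#'   SDs in `landmark_means`.
#' @param asymmetry_shift Named numeric, per bilateral code: mean
#'   left-minus-right offset (mm). Default none.
#' @param age_effect Named numeric, per code: slope in mm per year, applied
#'   about the cohort mid-age. Default none.
#' @param session_noise_sd Remeasurement SD (mm) between the two sessions.
#' @param sessions Number of measurement sessions (default 2).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_cell = 5, landmark_means = greek_cohort_defaults(),
                        landmark_sds = NULL, asymmetry_shift = NULL,
                        age_effect = NULL, session_noise_sd = 0.3,
                        sessions = 2L, seed = 1L) {
  lm <- tibble::as_tibble(landmark_means)
  if (nrow(lm) == 0L) stop("landmark list is empty")
  if (!all(c("code", "sex", "mean_mm") %in% names(lm)))
    stop("`landmark_means` needs columns code, sex, mean_mm")
  if (!"sd_mm" %in% names(lm)) lm$sd_mm <- 1
  if (!is.null(landmark_sds)) {
    lm$sd_mm <- NULL
    lm <- dplyr::left_join(lm, tibble::as_tibble(landmark_sds),
                           by = c("code", "sex"))
  }
  if (any(lm$mean_mm <= 0)) stop("landmark means must be positive")
  if (any(lm$sd_mm < 0)) stop("landmark SDs must be non-negative")
  if (n_per_cell < 1) stop("`n_per_cell` must be at least 1")
  if (session_noise_sd < 0) stop("`session_noise_sd` must be non-negative")
  structure(list(n_per_cell = as.integer(n_per_cell), landmark_means = lm,
                 asymmetry_shift = asymmetry_shift, age_effect = age_effect,
                 session_noise_sd = session_noise_sd,
                 sessions = as.integer(sessions), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort depth table
#'
#' @param spec A [cohort_spec()].
#' @return A depth table tibble: `subject_id`, `sex` (`M`/`F`),
#'   `age_years`, `landmark_code`, `side` (`L`/`R`/`mid`), `session`,
#'   `depth_mm`; one row per subject x landmark position x session.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- age_group_table()
  reg <- landmark_registry()

  subjects <- expand.grid(sex = c("M", "F"), group = groups$label,
                          rep = seq_len(spec$n_per_cell),
                          stringsAsFactors = FALSE)
  lo <- groups$lower[match(subjects$group, groups$label)]
  hi <- pmin(groups$upper[match(subjects$group, groups$label)], 99L)
  subjects$age_years <- lo + floor(stats::runif(nrow(subjects)) * (hi - lo + 1))
  subjects$subject_id <- sprintf("S%03d", seq_len(nrow(subjects)))
  mid_age <- mean(subjects$age_years)

  lmtab <- spec$landmark_means
  lmtab$laterality <- reg$laterality[match(lmtab$code, reg$code)]
  if (any(is.na(lmtab$laterality)))
    stop("unknown landmark code(s): ",
         paste(unique(lmtab$code[is.na(lmtab$laterality)]), collapse = ", "))

  rows <- list()
  for (s in seq_len(nrow(subjects))) {
    sub <- subjects[s, ]
    lms <- lmtab[lmtab$sex == sub$sex, ]
    sides <- ifelse(lms$laterality == "midline", "mid", NA)
    pos <- dplyr::bind_rows(
      tibble::tibble(code = lms$code[lms$laterality == "midline"],
                     mean = lms$mean_mm[lms$laterality == "midline"],
                     sd = lms$sd_mm[lms$laterality == "midline"],
                     side = "mid"),
      tibble::tibble(code = rep(lms$code[lms$laterality == "bilateral"], each = 2),
                     mean = rep(lms$mean_mm[lms$laterality == "bilateral"], each = 2),
                     sd = rep(lms$sd_mm[lms$laterality == "bilateral"], each = 2),
                     side = rep(c("L", "R"), sum(lms$laterality == "bilateral"))))
    shift <- numeric(nrow(pos))
    if (!is.null(spec$asymmetry_shift)) {
      sh <- spec$asymmetry_shift[pos$code]
      sh[is.na(sh)] <- 0
      shift <- ifelse(pos$side == "L", sh / 2, ifelse(pos$side == "R", -sh / 2, 0))
    }
    slope <- numeric(nrow(pos))
    if (!is.null(spec$age_effect)) {
      sl <- spec$age_effect[pos$code]
      sl[is.na(sl)] <- 0
      slope <- sl * (sub$age_years - mid_age)
    }
    mu <- pos$mean + shift + slope
    true_depth <- rnorm_truncated(mu, pos$sd)
    for (sess in seq_len(spec$sessions)) {
      meas <- if (spec$session_noise_sd > 0)
        rnorm_truncated(true_depth, spec$session_noise_sd) else true_depth
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sub$subject_id, sex = sub$sex,
        age_years = sub$age_years, landmark_code = pos$code,
        side = pos$side, session = sess, depth_mm = meas)
    }
  }
  dplyr::bind_rows(rows)
}

# normal draws truncated at zero by redraw
rnorm_truncated <- function(mean, sd, max_tries = 100L) {
  x <- stats::rnorm(length(mean), mean, sd)
  for (i in seq_len(max_tries)) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[if (length(sd) == 1L) 1L else bad])
  }
  stop("could not draw positive depths; check means and SDs")
}

#' Default synthetic-cohort parameters: Greek pooled per-sex values
#'
#' Pools the packaged Greek age-group descriptive tables into one mean and
#' SD per landmark and sex (n-weighted mean of group means; SD as the
#' n-weighted root mean square of group SDs), so that default synthetic
#' cohorts resemble the scale of a real FSTD study.
#'
#' @return Tibble with columns `code`, `sex`, `mean_mm`, `sd_mm`.
#' @export
greek_cohort_defaults <- function() {
  d <- greek_descriptives_fixture()
  d$code <- sub("[LR]$", "", d$printed_code)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$code, .data$sex),
    mean_mm = stats::weighted.mean(.data$mean_mm, .data$n),
    sd_mm = sqrt(stats::weighted.mean(.data$sd_mm^2, .data$n)),
    .groups = "drop")
  out
}

# packaged transcription of the Greek age-group descriptive tables
greek_descriptives_fixture <- function() {
  path <- system.file("extdata", "greek_fstd_descriptives.csv",
                      package = "fstdkit", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Landmark placements on a phantom skull
#'
#' Places every measured registry position on the analytic skull surface of
#' a phantom, on the equator (z = 0) so that every measurement direction is
#' horizontal: mid-sagittal landmarks at the anterior pole (azimuth 0),
#' coronal-plane landmarks near the lateral pole (azimuth 81-99 degrees,
#' mirrored for the right side) and sagitto-coronal landmarks spread over
#' intermediate azimuths where the radial direction itself is horizontal.
#'
#' @param phantom Result of [make_phantom_volume()].
#' @return Landmark tibble (`code`, `side`, `x`, `y`, `z`) in mm.
#' @export
phantom_landmarks <- function(phantom) {
  pos <- measured_positions()
  azi <- numeric(nrow(pos))
  cor_codes <- unique(pos$code[pos$plane == "coronal"])
  sc_codes <- unique(pos$code[pos$plane == "sagitto_coronal"])
  azi[pos$plane == "coronal"] <-
    (81 + 3 * (match(pos$code, cor_codes) - 1))[pos$plane == "coronal"]
  azi[pos$plane == "sagitto_coronal"] <-
    (20 + 5 * (match(pos$code, sc_codes) - 1))[pos$plane == "sagitto_coronal"]
  azi[pos$side == "R"] <- -azi[pos$side == "R"]
  th <- azi * pi / 180
  dirs <- cbind(cos(th), sin(th), 0)
  r <- ellipsoid_radius(dirs, phantom$spec$semi_axes)
  tibble::tibble(code = pos$code, side = pos$side,
                 x = phantom$centre[1] + dirs[, 1] * r,
                 y = phantom$centre[2] + dirs[, 2] * r,
                 z = phantom$centre[3] + dirs[, 3] * r)
}

#' Frankfurt-plane anchor points of a phantom
#'
#' Equatorial stand-ins for the two porions (posterior-lateral) and two
#' orbitales (anterior-lateral) on the analytic skull surface, exactly
#' coplanar in z = 0.
#'
#' @param phantom Result of [make_phantom_volume()].
#' @return List `porion_L`, `porion_R`, `orbitale_L`, `orbitale_R`.
#' @export
phantom_fhp_points <- function(phantom) {
  az <- c(porion_L = 100, porion_R = -100, orbitale_L = 30, orbitale_R = -30)
  th <- az * pi / 180
  dirs <- cbind(cos(th), sin(th), 0)
  r <- ellipsoid_radius(dirs, phantom$spec$semi_axes)
  pts <- sweep(dirs * r, 2, phantom$centre, `+`)
  stats::setNames(lapply(seq_len(4), function(i) pts[i, ]), names(az))
}
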