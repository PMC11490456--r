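#' The cranial landmark registry
#'
#' The 23 cranial landmarks used for facial soft tissue depth work on the
#' upper skull: 5 mid-sagittal and 17 bilateral landmarks are measured; the
#' nasomaxillofrontale (Nmf) is located only to help place the
#' mid-nasomaxillare and carries no depth (the eyelids obstruct the skin
#' point), so it is flagged `measured = FALSE`.
#'
#' Each landmark carries the plane in which its depth is taken once the
#' skull sits in the Frankfurt Horizontal Plane: `sagittal` (anterior, +x),
#' `coronal` (lateral, toward the landmark's side) or `sagitto_coronal`
#' (the horizontal projection of the outward surface normal). The
#' assignment is a documented convention of this package and can be
#' overridden per call in [measure_subject()].
#'
#' @return A tibble with columns `code`, `name`, `laterality`
#'   (`"midline"`/`"bilateral"`), `plane`, `measured`, `definition`.
#' @export
landmark_registry <- function() {
  tibble::tribble(
    ~code, ~name, ~laterality, ~plane, ~measured, ~definition,
    "Sg", "Supraglabella", "midline", "sagittal", TRUE,
    "On the frontal bone, 10 mm superior to the glabella",
    "G", "Glabella", "midline", "sagittal", TRUE,
    "Most anterior point between the supraorbital ridges",
    "N", "Nasion", "midline", "sagittal", TRUE,
    "Midpoint of the suture between the frontal and the two nasal bones",
    "Mn", "Mid-nasal", "midline", "sagittal", TRUE,
    "On the internasal suture, midway between nasion and rhinion",
    "Rhi", "Rhinion", "midline", "sagittal", TRUE,
    "Anterior tip of the nasal bone",
    "Fe", "Frontal eminence", "bilateral", "sagitto_coronal", TRUE,
    "On the projections at both sides of the forehead",
    "So", "Supraorbital", "bilateral", "sagitto_coronal", TRUE,
    "Most anterior point of the supraciliary arch in the axis of the orbit centre",
    "Sk", "Supraconchion", "bilateral", "sagitto_coronal", TRUE,
    "Most superior point of the orbital rim",
    "Or", "Orbitale", "bilateral", "sagitto_coronal", TRUE,
    "Most inferior point of the orbital margin",
    "Smc", "Sub-maxillar curvature", "bilateral", "sagitto_coronal", TRUE,
    "Most supero-medial point on the maxillary inflexion between zygomaxillare and ectomolare",
    "Ft", "Frontotemporale", "bilateral", "coronal", TRUE,
    "Most antero-medial point of the linea temporalis superior",
    "Fmt", "Frontomalare temporale", "bilateral", "coronal", TRUE,
    "Most posterior point of the zygo-frontal suture",
    "Ec", "Ectoconchion", "bilateral", "coronal", TRUE,
    "Most lateral point at the lateral margin of the orbit",
    "Mz", "Mid-zygomatic", "bilateral", "coronal", TRUE,
    "On the centre of the zygomatic process, lined up with the lateral orbit border",
    "Zm", "Zygomaxillare", "bilateral", "sagitto_coronal", TRUE,
    "Most inferior point on the zygo-maxillary suture",
    "Ju", "Jugale", "bilateral", "coronal", TRUE,
    "Most antero-inferior point on the posterior border of the zygomatic bone",
    "Zy", "Zygion", "bilateral", "coronal", TRUE,
    "Most lateral extent of the lateral surface of the zygomatic arch",
    "Co", "Condylion", "bilateral", "coronal", TRUE,
    "Most lateral point of the glenoid process of the mandible",
    "Al", "Alare", "bilateral", "sagitto_coronal", TRUE,
    "Most lateral point on the margin of the anterior nasal aperture",
    "Mnm", "Mid-nasomaxillare", "bilateral", "sagitto_coronal", TRUE,
    "Midpoint of the naso-maxillary suture between nasomaxillare and nasomaxillofrontale",
    "Nm", "Nasomaxillare", "bilateral", "sagitto_coronal", TRUE,
    "Most inferior point of the naso-maxillary suture on the nasal aperture",
    "Fmo", "Frontomalare orbitale", "bilateral", "sagitto_coronal", TRUE,
    "Point where the frontozygomatic suture crosses the inner orbital rim",
    "Nmf", "Nasomaxillofrontale", "bilateral", "sagitto_coronal", FALSE,
    "Junction of the frontal, maxillary and lacrimal bones on the medial orbit wall"
  )
}

#' Measurement positions implied by the registry
#'
#' Expands the measured registry into one row per expected depth record:
#' midline landmarks with side `"mid"`, bilateral ones with `"L"` and
#' `"R"` (5 + 17 x 2 = 39 positions).
#'
#' @return Tibble with columns `code`, `side`, `plane`.
#' @export
measured_positions <- function() {
  reg <- landmark_registry()
  reg <- reg[reg$measured, ]
  mid <- reg[reg$laterality == "midline", ]
  bil <- reg[reg$laterality == "bilateral", ]
  dplyr::bind_rows(
    tibble::tibble(code = mid$code, side = "mid", plane = mid$plane),
    tibble::tibble(code = rep(bil$code, each = 2),
                   side = rep(c("L", "R"), nrow(bil)),
                   plane = rep(bil$plane, each = 2)))
}

#' Fit the Frankfurt Horizontal Plane frame
#'
#' Fits a plane through the two porions and two orbitales and returns the
#' rigid transform into the measurement frame: the fitted plane becomes
#' horizontal (constant z), +z points superior, +x anterior (from the mean
#' porion towards the mean orbitale) and +y from the right porion towards
#' the left porion. Four points over-determine a plane, so a total
#' least-squares plane is used and the RMS point-to-plane distance is
#' reported as `fit_residual`. A three-point variant (both porions plus the
#' left orbitale, the classical craniometric convention) is available via
#' `method = "three_point"`.
#'
#' @param porion_L,porion_R,orbitale_L,orbitale_R Length-3 points (mm).
#' @param method `"least_squares"` (default) or `"three_point"`.
#' @param superior_hint Optional point known to lie superior to the plane
#'   (e.g. bregma); if supplied and it maps below the plane, a warning about
#'   possibly swapped porion labels is raised.
#' @return An object of class `fhp_frame`: list with `rotation` (3 x 3,
#'   orthonormal), `translation` (mm), `fit_residual` (mm). Points map as
#'   `rotation %*% p + translation`.
#' @export
fit_fhp <- function(porion_L, porion_R, orbitale_L, orbitale_R,
                    method = c("least_squares", "three_point"),
                    superior_hint = NULL) {
  method <- match.arg(method)
  pts <- rbind(porion_L, porion_R, orbitale_L, orbitale_R)
  if (nrow(pts) != 4L || ncol(pts) != 3L || any(!is.finite(pts)))
    stop("four finite 3D points are required")
  fit_pts <- if (method == "three_point") pts[1:3, ] else pts
  ctr <- colMeans(fit_pts)
  sv <- svd(sweep(fit_pts, 2, ctr))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("porion/orbitale points are collinear; no plane is defined")
  normal <- sv$v[, 3]
  # in-plane axes from anatomy: anterior = porions -> orbitales, left = R -> L
  ant <- colMeans(pts[3:4, ]) - colMeans(pts[1:2, ])
  ant <- ant - sum(ant * normal) * normal
  if (sqrt(sum(ant^2)) < 1e-9)
    stop("orbitales coincide with porions; anterior axis undefined")
  xax <- ant / sqrt(sum(ant^2))
  left <- pts[1, ] - pts[2, ]
  left <- left - sum(left * normal) * normal - sum(left * xax) * xax
  if (sqrt(sum(left^2)) < 1e-9)
    stop("porions coincide; lateral axis undefined")
  yax <- left / sqrt(sum(left^2))
  zax <- c(xax[2] * yax[3] - xax[3] * yax[2],
           xax[3] * yax[1] - xax[1] * yax[3],
           xax[1] * yax[2] - xax[2] * yax[1])
  rotation <- rbind(xax, yax, zax)
  dimnames(rotation) <- NULL
  translation <- -as.numeric(rotation %*% colMeans(pts))
  # RMS distance of all four points to the fitted plane (through `ctr`)
  resid <- sqrt(mean((sweep(pts, 2, ctr) %*% zax)^2))
  frame <- structure(list(rotation = rotation, translation = translation,
                          fit_residual = resid, method = method),
                     class = "fhp_frame")
  if (!is.null(superior_hint)) {
    hz <- (rotation %*% as.numeric(superior_hint) + translation)[3]
    if (hz < 0)
      warning("superior hint maps below the plane: porion L/R labels may be swapped")
  }
  frame
}

#' @export
print.fhp_frame <- function(x, ...) {
  cat(sprintf("<fhp_frame> %s fit, residual %.4g mm\n", x$method, x$fit_residual))
  invisible(x)
}

#' Map meshes or landmarks into the Frankfurt frame
#'
#' Applies the rigid transform of an [fit_fhp()] frame; pairwise distances
#' are preserved.
#'
#' @param x An [fstd_mesh()], a landmark tibble (see [read_landmarks()]) or
#'   an n x 3 matrix.
#' @param frame An `fhp_frame`.
#' @return `x` transformed, same type.
#' @export
to_fhp <- function(x, frame) {
  stopifnot(inherits(frame, "fhp_frame"))
  if (inherits(x, "fstd_mesh"))
    return(transform_points(x, frame$rotation, frame$translation))
  if (is.data.frame(x)) {
    xyz <- transform_points(as.matrix(x[, c("x", "y", "z")]),
                            frame$rotation, frame$translation)
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    return(x)
  }
  transform_points(x, frame$rotation, frame$translation)
}
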