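#' Horizontal measurement direction at a cranial landmark
#'
#' With the skull in the Frankfurt frame, the depth at each landmark is
#' taken along a horizontal direction determined by its measurement plane:
#' `sagittal` landmarks are measured anteriorly (+x), `coronal` landmarks
#' laterally (toward the landmark's own side, +y on the left and -y on the
#' right), and `sagitto_coronal` landmarks along the outward skull-surface
#' normal projected onto the horizontal plane. The returned vector always
#' has unit length and zero z-component.
#'
#' @param plane One of `"sagittal"`, `"coronal"`, `"sagitto_coronal"`.
#' @param side `"L"`, `"R"` or `"mid"`.
#' @param skull Skull [fstd_mesh()] in the Frankfurt frame (needed for
#'   `sagitto_coronal` only).
#' @param point Length-3 cranial landmark position (mm), on the skull
#'   surface.
#' @param normals Optional precomputed [vertex_normals()] matrix for
#'   `skull` (avoids recomputation across landmarks).
#' @return Unit length-3 vector with attribute `degenerate = TRUE` when the
#'   projected normal was near-vertical and the quadrant-bisector fallback
#'   was used.
#' @export
measurement_direction <- function(plane, side, skull = NULL, point = NULL,
                                  normals = NULL) {
  plane <- match.arg(plane, c("sagittal", "coronal", "sagitto_coronal"))
  if (plane == "sagittal") return(c(1, 0, 0))
  if (plane == "coronal") {
    if (!side %in% c("L", "R"))
      stop("coronal landmarks must carry side L or R")
    return(c(0, if (side == "L") 1 else -1, 0))
  }
  if (is.null(skull) || is.null(point))
    stop("sagitto_coronal directions need the skull mesh and the point")
  n <- surface_normal_at(skull, point, normals)
  h <- c(n[1], n[2], 0)
  len <- sqrt(sum(h^2))
  if (len < 1e-6) {
    # near-vertical normal: fall back to the bisector of the +-x/+-y
    # quadrant the raw normal leans into (anterior/lateral by sign)
    sx <- if (n[1] >= 0) 1 else -1
    sy <- if (side == "L") 1 else if (side == "R") -1 else sign(n[2] + 1e-12)
    out <- c(sx, sy, 0) / sqrt(2)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  h / len
}

# outward surface normal at the mesh vertex nearest to `point`
# (area-weighted average of incident triangle normals)
surface_normal_at <- function(mesh, point, normals = NULL) {
  d2 <- colSums((t(mesh$vertices) - as.numeric(point))^2)
  vi <- which.min(d2)
  if (is.null(normals)) normals <- vertex_normals(mesh)
  normals[vi, ]
}

#' Measure a single bone-to-skin depth by ray casting
#'
#' Casts a ray from the cranial landmark along the horizontal measurement
#' direction and takes the first intersection with the skin surface as the
#' traced cephalometric landmark; the depth is the distance between the two
#' points.
#'
#' @param cranial Length-3 cranial point (mm), inside or on the skin mesh.
#' @param direction Unit, horizontal direction (see
#'   [measurement_direction()]).
#' @param skin Skin [fstd_mesh()] in the same frame.
#' @param landmark_code Optional label used in error messages.
#' @param side Side label carried into the record (`"L"`, `"R"`, `"mid"`).
#' @param assume_closed Whether `skin` is watertight, enabling the
#'   point-outside check; precompute for repeated calls on large meshes.
#' @return A one-row tibble: `landmark_code`, `side`, `depth_mm`,
#'   `cranial_x/y/z`, `skin_x/y/z`, `dir_x/y/z`, `degenerate_direction`.
#' @export
measure_depth <- function(cranial, direction, skin, landmark_code = NA_character_,
                          side = NA_character_, assume_closed = mesh_is_closed(skin)) {
  cranial <- as.numeric(cranial)
  dir_attr <- attr(direction, "degenerate")
  direction <- as.numeric(direction)
  if (assume_closed && point_outside_mesh(cranial, skin, tol = 1e-3))
    stop("landmark outside skin", if (!is.na(landmark_code))
      paste0(" (", landmark_code, ")") else "")
  hits <- .ray_mesh_hits(cranial, direction, skin$vertices, skin$faces)
  t_hit <- hits[hits > 1e-9]
  if (length(t_hit) == 0L)
    stop("measurement ray does not intersect the skin surface",
         if (!is.na(landmark_code)) paste0(" at ", landmark_code) else "")
  t1 <- t_hit[1]
  skin_pt <- cranial + t1 * direction
  tibble::tibble(
    landmark_code = landmark_code, side = side, depth_mm = t1,
    cranial_x = cranial[1], cranial_y = cranial[2], cranial_z = cranial[3],
    skin_x = skin_pt[1], skin_y = skin_pt[2], skin_z = skin_pt[3],
    dir_x = direction[1], dir_y = direction[2], dir_z = direction[3],
    degenerate_direction = isTRUE(dir_attr))
}

# ray-parity inside test; points within `tol` of the surface count as on
# the mesh, not outside. The probe ray is oblique to the voxel lattice so
# it cannot run along mesh edges, and coincident hits on shared edges are
# collapsed before the parity count.
point_outside_mesh <- function(point, mesh, tol = 0) {
  probe <- c(0.5387647, 0.6154235, 0.5754823)
  hits <- .ray_mesh_hits(as.numeric(point), probe, mesh$vertices, mesh$faces)
  ahead <- sort(hits[hits > 1e-9])
  if (length(ahead) > 1L)
    ahead <- ahead[c(TRUE, diff(ahead) > 1e-8)]
  outside <- length(ahead) %% 2L == 0L
  if (outside && tol > 0) {
    d <- .points_mesh_dist(matrix(as.numeric(point), 1, 3),
                           mesh$vertices, mesh$faces)
    outside <- d > tol
  }
  outside
}

#' Measure all landmark depths for one subject
#'
#' Transforms the skull, skin and landmarks into the Frankfurt frame,
#' derives each landmark's horizontal measurement direction and ray-casts
#' the depth to the skin. Landmarks that cannot be measured (unmeasured
#' registry entries such as Nmf, rays that miss an open mesh, points
#' outside the skin) are reported in the `missing` table with a reason,
#' never imputed.
#'
#' @param skull,skin [fstd_mesh()] surfaces in a common native frame (mm).
#' @param landmarks Landmark tibble (`code`, `side`, `x`, `y`, `z`) in the
#'   same native frame; see [read_landmarks()].
#' @param frame An [fit_fhp()] frame; use `NULL` if inputs are already in
#'   the Frankfurt frame.
#' @param planes Optional override of the per-landmark measurement-plane
#'   assignment: tibble with columns `code`, `plane`.
#' @return List with `depths` (tibble of depth records, see
#'   [measure_depth()]) and `missing` (tibble `code`, `side`, `reason`).
#' @export
measure_subject <- function(skull, skin, landmarks, frame = NULL, planes = NULL) {
  landmarks <- validate_landmark_table(landmarks)
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "fhp_frame"))
    skull <- to_fhp(skull, frame)
    skin <- to_fhp(skin, frame)
    landmarks <- to_fhp(landmarks, frame)
  }
  reg <- landmark_registry()
  if (!is.null(planes))
    reg$plane[match(planes$code, reg$code)] <- planes$plane

  skin_closed <- mesh_is_closed(skin)
  skull_normals <- if (any(reg$plane == "sagitto_coronal")) vertex_normals(skull)
  depths <- list()
  missing <- list()
  note_missing <- function(code, side, reason)
    missing[[length(missing) + 1L]] <<- tibble::tibble(
      code = code, side = side, reason = reason)

  for (i in seq_len(nrow(landmarks))) {
    code <- landmarks$code[i]
    side <- landmarks$side[i]
    ri <- match(code, reg$code)
    if (is.na(ri)) { note_missing(code, side, "unknown landmark code"); next }
    if (!reg$measured[ri]) { note_missing(code, side, "unmeasured landmark"); next }
    pt <- c(landmarks$x[i], landmarks$y[i], landmarks$z[i])
    rec <- tryCatch({
      dir <- measurement_direction(reg$plane[ri], side, skull, pt,
                                   normals = skull_normals)
      measure_depth(pt, dir, skin, landmark_code = code, side = side,
                    assume_closed = skin_closed)
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) note_missing(code, side, rec)
    else depths[[length(depths) + 1L]] <- rec
  }
  list(depths = dplyr::bind_rows(depths), missing = dplyr::bind_rows(missing))
}

#' Convert per-subject depth records to a cohort depth-table row block
#'
#' @param depths The `depths` tibble from [measure_subject()].
#' @param subject_id,sex,age_years Subject metadata.
#' @return Depth-table tibble (see [simulate_cohort()]) with `session = 1`.
#' @export
as_depth_table <- function(depths, subject_id, sex = NA_character_,
                           age_years = NA_integer_) {
  tibble::tibble(subject_id = subject_id, sex = sex, age_years = age_years,
                 landmark_code = depths$landmark_code, side = depths$side,
                 session = 1L, depth_mm = depths$depth_mm)
}
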