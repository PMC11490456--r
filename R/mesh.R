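#' Triangle surface mesh container
#'
#' Vertices in millimetres, faces as 1-based vertex index triplets oriented
#' with outward normals.
#'
#' @param vertices Numeric matrix, n x 3 (mm).
#' @param faces Integer matrix, m x 3, 1-based indices into `vertices`.
#' @return An object of class `fstd_mesh`.
#' @export
fstd_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  structure(list(vertices = vertices, faces = faces), class = "fstd_mesh")
}

#' @export
print.fstd_mesh <- function(x, ...) {
  cat(sprintf("<fstd_mesh> %d vertices, %d faces, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area of a mesh (mm^2)
#' @param mesh An [fstd_mesh()].
#' @return Numeric scalar.
#' @export
mesh_area <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0)
  cr <- face_cross(mesh)
  sum(sqrt(rowSums(cr^2))) / 2
}

face_areas <- function(mesh) sqrt(rowSums(face_cross(mesh)^2)) / 2

#' Area-weighted centroid of a mesh surface
#' @param mesh An [fstd_mesh()].
#' @return Numeric length-3 (mm).
#' @export
mesh_centroid <- function(mesh) {
  f <- mesh$faces
  v <- mesh$vertices
  ctr <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  w <- face_areas(mesh)
  colSums(ctr * w) / sum(w)
}

#' Per-vertex outward normals
#'
#' Area-weighted average of incident triangle normals (the triangle cross
#' product already carries the area weight), normalised to unit length.
#'
#' @param mesh An [fstd_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  cr <- face_cross(mesh) # length = 2 * area, outward by face orientation
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (c in 1:3) {
      acc <- rowsum(cr[, c], idx)
      n[as.integer(rownames(acc)), c] <- n[as.integer(rownames(acc)), c] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Is a mesh closed (watertight)?
#'
#' A mesh is closed when every undirected edge is shared by exactly two
#' faces.
#'
#' @param mesh An [fstd_mesh()].
#' @return Logical scalar.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  key <- sort(pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2]))
  all(rle(key)$lengths == 2L)
}

#' Keep the largest connected component of a mesh
#' @param mesh An [fstd_mesh()].
#' @return An [fstd_mesh()] restricted to the largest vertex-connected set
#'   of faces.
#' @export
mesh_largest_component <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(mesh)
  g <- igraph::graph_from_edgelist(
    rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  keep_v <- comp$membership == big
  keep_f <- keep_v[f[, 1]] & keep_v[f[, 2]] & keep_v[f[, 3]]
  remap <- cumsum(keep_v)
  fstd_mesh(mesh$vertices[keep_v, , drop = FALSE],
            matrix(remap[f[keep_f, ]], ncol = 3))
}

#' Sample points uniformly (by area) on a mesh surface
#'
#' Face selection is area-weighted and barycentric coordinates are uniform
#' within each face; draws come from the current R random stream.
#'
#' @param mesh An [fstd_mesh()].
#' @param n Number of points.
#' @return n x 3 matrix of points on the surface.
#' @export
sample_mesh_points <- function(mesh, n) {
  w <- face_areas(mesh)
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = w)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  u <- 1 - r1
  v <- r1 * (1 - r2)
  w3 <- r1 * r2
  f <- mesh$faces[fi, , drop = FALSE]
  vtx <- mesh$vertices
  u * vtx[f[, 1], , drop = FALSE] + v * vtx[f[, 2], , drop = FALSE] +
    w3 * vtx[f[, 3], , drop = FALSE]
}

#' Apply a rigid transform to a mesh or point matrix
#' @param x An [fstd_mesh()] or an n x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 offset applied after rotation.
#' @return Same type as `x`.
#' @export
transform_points <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  if (inherits(x, "fstd_mesh")) {
    x$vertices <- transform_points(x$vertices, rotation, translation)
    return(x)
  }
  sweep(as.matrix(x) %*% t(rotation), 2, -as.numeric(translation))
}

#' Star-shaped analytic mesh from a radial profile
#'
#' Builds a triangulated surface by evaluating a radius function over unit
#' directions of a subdivided icosahedron. Any star-shaped surface (sphere,
#' ellipsoid, skull+tissue shell) can be produced this way, with vertices
#' lying exactly on the analytic surface.
#'
#' @param radius_fn Function taking an n x 3 matrix of unit directions and
#'   returning n radii (mm); or a single number for a sphere.
#' @param centre Length-3 centre (mm).
#' @param subdivisions Icosahedron subdivision level; vertex count is
#'   `10 * 4^subdivisions + 2`.
#' @return An [fstd_mesh()].
#' @export
make_star_mesh <- function(radius_fn, centre = c(0, 0, 0), subdivisions = 4) {
  if (is.numeric(radius_fn)) {
    r0 <- radius_fn
    radius_fn <- function(d) rep(r0, nrow(d))
  }
  ico <- icosphere(subdivisions)
  r <- radius_fn(ico$vertices)
  if (any(!is.finite(r)) || any(r <= 0)) stop("radius function must be positive")
  v <- sweep(ico$vertices * r, 2, as.numeric(centre), `+`)
  m <- fstd_mesh(v, ico$faces)
  # enforce outward orientation (valid for star-shaped surfaces)
  cr <- face_cross(m)
  ctr <- (v[m$faces[, 1], ] + v[m$faces[, 2], ] + v[m$faces[, 3], ]) / 3
  out_dir <- sweep(ctr, 2, as.numeric(centre))
  flip <- rowSums(cr * out_dir) < 0
  m$faces[flip, ] <- m$faces[flip, c(1, 3, 2)]
  m
}

# Unit icosphere: icosahedron subdivided `n` times, vertices renormalised.
icosphere <- function(n = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (i in seq_len(n)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    verts <- vector("list", 0)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      verts[[length(verts) + 1L]] <<- m
      mid_cache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- newf
  }
  list(vertices = v, faces = f)
}
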