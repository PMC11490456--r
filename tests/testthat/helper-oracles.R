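# Independent oracles used across tests. These deliberately avoid the
# package's compiled kernels: distances and intersections are recomputed
# in plain R so the fast paths are checked against a second route.

# exact point-to-triangle distance via projection onto the plane and
# clamping to edges (brute force over all candidate closest points)
oracle_point_tri_dist <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w * w)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * w))^2))
  }
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  n <- cross3(b - a, c - a)
  n <- n / sqrt(sum(n^2))
  q <- p - sum((p - a) * n) * n
  # barycentric test for the projected point
  v0 <- b - a; v1 <- c - a; v2 <- q - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  if (v >= 0 && w >= 0 && v + w <= 1) return(abs(sum((p - a) * n)))
  min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, c, a))
}

# directed Hausdorff by brute force: dense sampled points of A against all
# triangles of B
oracle_directed_hd <- function(points_a, mesh_b) {
  max(apply(points_a, 1, function(p) {
    min(apply(mesh_b$faces, 1, function(f) {
      oracle_point_tri_dist(p, mesh_b$vertices[f[1], ],
                            mesh_b$vertices[f[2], ], mesh_b$vertices[f[3], ])
    }))
  }))
}

# dense deterministic point sample of a mesh (barycentric grid per face)
oracle_mesh_points <- function(mesh, per_edge = 4) {
  bary <- expand.grid(i = 0:per_edge, j = 0:per_edge)
  bary <- bary[bary$i + bary$j <= per_edge, ]
  u <- bary$i / per_edge
  v <- bary$j / per_edge
  w <- 1 - u - v
  out <- lapply(seq_len(nrow(mesh$faces)), function(fi) {
    f <- mesh$faces[fi, ]
    cbind(u, v, w) %*% mesh$vertices[f, ]
  })
  unique(do.call(rbind, out))
}

# first intersection of a ray with a star-shaped analytic surface
# r(direction), found by root bracketing on g(t) = |p + t d| - r(dir(t))
oracle_ray_star_surface <- function(origin, dir, radius_fn) {
  g <- function(t) {
    p <- origin + t * dir
    sqrt(sum(p^2)) - radius_fn(matrix(p / sqrt(sum(p^2)), 1, 3))
  }
  lo <- 0
  hi <- 1
  while (g(hi) < 0 && hi < 1e4) hi <- hi * 2
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

# RMS point-to-plane distance of the best plane found by brute-force search
# over normal directions (coarse global grid, then local refinement around
# the best normal; the plane offset is optimal at the centred mean)
oracle_plane_rms <- function(pts, n_dir = 60) {
  rms_for <- function(n) {
    n <- n / sqrt(sum(n^2))
    d <- pts %*% n
    sqrt(mean((d - mean(d))^2))
  }
  best <- Inf
  best_n <- c(0, 0, 1)
  for (a in seq(0, pi, length.out = n_dir))
    for (b in seq(0, 2 * pi, length.out = 2 * n_dir)) {
      n <- c(sin(a) * cos(b), sin(a) * sin(b), cos(a))
      r <- rms_for(n)
      if (r < best) { best <- r; best_n <- n }
    }
  # refine in the tangent plane of the best normal (pole-free)
  step <- pi / n_dir
  for (round in 1:8) {
    t1 <- if (abs(best_n[3]) < 0.9) c(-best_n[2], best_n[1], 0) else c(1, 0, 0)
    t1 <- t1 - sum(t1 * best_n) * best_n
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(best_n[2] * t1[3] - best_n[3] * t1[2],
            best_n[3] * t1[1] - best_n[1] * t1[3],
            best_n[1] * t1[2] - best_n[2] * t1[1])
    grid <- expand.grid(u = seq(-step, step, length.out = 9),
                        v = seq(-step, step, length.out = 9))
    for (i in seq_len(nrow(grid))) {
      n <- best_n + grid$u[i] * t1 + grid$v[i] * t2
      r <- rms_for(n)
      if (r < best) { best <- r; best_n <- n / sqrt(sum(n^2)) }
    }
    step <- step / 3
  }
  best
}

# small two-surface sphere phantom shared by several tests
small_sphere_phantom <- function(r_skull = 12, thick = 3, spacing = 1,
                                 noise_sd = 0, seed = 1) {
  make_phantom_volume(phantom_spec(
    semi_axes = rep(r_skull, 3), thickness = thick, spacing = spacing,
    noise_sd = noise_sd, seed = seed))
}
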