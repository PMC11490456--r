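# analytic concentric-sphere meshes sharing vertex directions, so radial
# rays from skull vertices pass exactly through skin vertices
concentric_spheres <- function(r_in = 50, r_out = 55, subdivisions = 4) {
  list(skull = make_star_mesh(r_in, subdivisions = subdivisions),
       skin = make_star_mesh(r_out, subdivisions = subdivisions))
}

equatorial_vertex_dirs <- function(mesh, n = 8) {
  v <- mesh$vertices
  eq <- which(abs(v[, 3]) < 1e-9)
  d <- v[eq, ] / sqrt(rowSums(v[eq, , drop = FALSE]^2))
  d[seq_len(min(n, nrow(d))), , drop = FALSE]
}

test_that("measurement directions follow the per-plane conventions", {
  expect_equal(measurement_direction("sagittal", "mid"), c(1, 0, 0))
  expect_equal(measurement_direction("coronal", "L"), c(0, 1, 0))
  expect_equal(measurement_direction("coronal", "R"), c(0, -1, 0))
  expect_error(measurement_direction("coronal", "mid"), "side")

  # sphere: sagitto-coronal direction is the horizontal projection of the
  # radial direction
  sph <- make_star_mesh(20, subdivisions = 4)
  v <- sph$vertices[which.max(sph$vertices[, 1] + 0.5 * sph$vertices[, 3]), ]
  d <- measurement_direction("sagitto_coronal", "L", sph, v)
  expected <- c(v[1], v[2], 0) / sqrt(v[1]^2 + v[2]^2)
  expect_equal(as.numeric(d), expected, tolerance = 5e-3)
  expect_equal(d[3], 0)

  # near-vertical normal falls back to the flagged quadrant bisector
  top <- sph$vertices[which.max(sph$vertices[, 3]), ]
  db <- measurement_direction("sagitto_coronal", "L", sph, top)
  expect_true(isTRUE(attr(db, "degenerate")))
  expect_equal(sqrt(sum(db^2)), 1)
  expect_equal(db[3], 0)
})

test_that("radial depths on vertex-aligned analytic meshes are exact", {
  cs <- concentric_spheres(50, 55)
  dirs <- equatorial_vertex_dirs(cs$skull)
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ]
    rec <- measure_depth(50 * d, d, cs$skin, assume_closed = TRUE)
    expect_equal(rec$depth_mm, 5, tolerance = 1e-6)
    # closed-form oracle: ray from r_in along the radial hits the sphere
    # at r_out - r_in exactly
    expect_equal(rec$depth_mm, 55 - 50, tolerance = 1e-4)
    # the traced skin point lies on the skin surface
    expect_equal(sqrt(sum(c(rec$skin_x, rec$skin_y, rec$skin_z)^2)), 55,
                 tolerance = 1e-6)
  }
})

test_that("ellipsoid depths match the root-found analytic oracle", {
  semi <- c(24, 20, 17)
  f <- function(d) 3 + 2 * abs(d[, 3])
  r_sk <- function(d) 1 / sqrt((d[, 1] / semi[1])^2 + (d[, 2] / semi[2])^2 +
                                 (d[, 3] / semi[3])^2)
  r_skin <- function(d) r_sk(d) + f(d)
  skull <- make_star_mesh(r_sk, subdivisions = 5)
  skin <- make_star_mesh(r_skin, subdivisions = 5)

  # vertex-aligned radial rays: exact agreement with the thickness function
  eq <- equatorial_vertex_dirs(skull, n = 4)
  for (i in seq_len(nrow(eq))) {
    d <- eq[i, ]
    rec <- measure_depth(r_sk(matrix(d, 1)) * d, d, skin, assume_closed = TRUE)
    expect_equal(rec$depth_mm, f(matrix(d, 1)), tolerance = 1e-6)
  }

  # generic horizontal directions: ray-cast against uniroot on the analytic
  # star surface, within a tenth of a millimetre on subdivided meshes
  set.seed(31)
  az <- runif(10, 0, 2 * pi)
  pol <- runif(10, -0.5, 0.5)
  n_checked <- 0
  for (i in seq_len(10)) {
    d0 <- c(cos(az[i]) * cos(pol[i]), sin(az[i]) * cos(pol[i]), sin(pol[i]))
    start <- r_sk(matrix(d0, 1)) * d0
    dir <- measurement_direction("sagitto_coronal", "L", skull, start)
    rec <- measure_depth(start, as.numeric(dir), skin, assume_closed = TRUE)
    oracle <- oracle_ray_star_surface(start, as.numeric(dir), r_skin)
    expect_equal(rec$depth_mm, oracle, tolerance = 0.1)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 10)
})

test_that("the zero-depth limit and error contracts hold", {
  cs <- concentric_spheres(50, 55, subdivisions = 3)
  d <- equatorial_vertex_dirs(cs$skin, 1)[1, ]
  near <- (55 - 0.01) * d
  rec <- measure_depth(near, d, cs$skin, assume_closed = TRUE)
  expect_lt(rec$depth_mm, 0.02)

  # cranial point outside the skin is rejected by name
  expect_error(measure_depth(60 * d, d, cs$skin, landmark_code = "G",
                             assume_closed = TRUE),
               "landmark outside skin")
  # open mesh: ray through the hole errors
  top_half <- cs$skin
  keep <- apply(top_half$faces, 1, function(f)
    mean(top_half$vertices[f, 3]) < 40)
  top_half$faces <- top_half$faces[keep, ]
  expect_error(measure_depth(c(0, 0, 0), c(0, 0, 1), top_half,
                             landmark_code = "Sg", assume_closed = FALSE),
               "Sg")
})

test_that("a full subject yields 39 records with principled degradation", {
  ph <- small_sphere_phantom(r_skull = 12, thick = 3)
  lm <- phantom_landmarks(ph)
  fp <- phantom_fhp_points(ph)
  fr <- fit_fhp(fp$porion_L, fp$porion_R, fp$orbitale_L, fp$orbitale_R)
  res <- measure_subject(ph$skull, ph$skin, lm, frame = fr)
  expect_equal(nrow(res$depths), 39)
  expect_equal(nrow(res$missing), 0)
  expect_true(all(abs(res$depths$depth_mm - 3) < 0.3))
  # horizontality of every reported direction
  expect_true(all(abs(res$depths$dir_z) <= 1e-9))

  # Nmf is excluded with a reason, not measured
  lm_nmf <- rbind(lm, tibble::tibble(code = "Nmf", side = "L",
                                     x = 12, y = 0, z = 0))
  res2 <- measure_subject(ph$skull, ph$skin, lm_nmf, frame = fr)
  expect_equal(nrow(res2$depths), 39)
  expect_match(res2$missing$reason[res2$missing$code == "Nmf"], "unmeasured")

  # a hole in the skin over one landmark degrades to 38 records + 1 missing
  holey <- ph$skin
  target <- c(cos(20 * pi / 180), sin(20 * pi / 180), 0) # FeL azimuth
  ctr <- (holey$vertices[holey$faces[, 1], ] +
            holey$vertices[holey$faces[, 2], ] +
            holey$vertices[holey$faces[, 3], ]) / 3
  ctr <- ctr / sqrt(rowSums(ctr^2))
  holey$faces <- holey$faces[ctr %*% target < cos(3 * pi / 180), ]
  res3 <- measure_subject(ph$skull, holey, lm, frame = fr)
  expect_equal(nrow(res3$depths), 38)
  expect_equal(res3$missing$code, "Fe")
  expect_equal(res3$missing$side, "L")
})

test_that("depths are invariant under a rigid motion of the whole scene", {
  ph <- small_sphere_phantom(r_skull = 12, thick = 3)
  lm <- phantom_landmarks(ph)
  fp <- phantom_fhp_points(ph)
  fr0 <- fit_fhp(fp$porion_L, fp$porion_R, fp$orbitale_L, fp$orbitale_R)
  base <- measure_subject(ph$skull, ph$skin, lm, frame = fr0)$depths

  ang <- 0.6
  Q <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  shift <- c(5, -8, 13)
  skull_r <- transform_points(ph$skull, Q, shift)
  skin_r <- transform_points(ph$skin, Q, shift)
  lm_r <- lm
  xyz <- transform_points(as.matrix(lm[, c("x", "y", "z")]), Q, shift)
  lm_r$x <- xyz[, 1]; lm_r$y <- xyz[, 2]; lm_r$z <- xyz[, 3]
  fp_r <- lapply(fp, function(p) as.numeric(Q %*% p + shift))
  fr1 <- fit_fhp(fp_r$porion_L, fp_r$porion_R, fp_r$orbitale_L, fp_r$orbitale_R)
  moved <- measure_subject(skull_r, skin_r, lm_r, frame = fr1)$depths
  expect_equal(moved$depth_mm[order(paste(moved$landmark_code, moved$side))],
               base$depth_mm[order(paste(base$landmark_code, base$side))],
               tolerance = 1e-6)
})
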