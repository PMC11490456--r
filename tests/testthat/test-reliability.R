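unit_square_pair <- function(gap = 0.3) {
  sq <- function(z) fstd_mesh(
    rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z), c(0, 1, z)),
    rbind(c(1, 2, 3), c(1, 3, 4)))
  list(a = sq(0), b = sq(gap))
}

test_that("Hausdorff distance matches geometry and the brute-force oracle", {
  ph <- small_sphere_phantom(r_skull = 8, thick = 2)
  hd0 <- hausdorff(ph$skull, ph$skull, n_samples = 2000, seed = 1)
  expect_equal(hd0$symmetric, 0)
  expect_equal(hd0$classification, "good")

  # two parallel unit squares 0.3 mm apart
  sq <- unit_square_pair(0.3)
  hd <- hausdorff(sq$a, sq$b, n_samples = 2000, seed = 1)
  expect_equal(hd$directed_ab, 0.3, tolerance = 1e-9)
  expect_equal(hd$directed_ba, 0.3, tolerance = 1e-9)
  expect_equal(hd$symmetric, max(hd$directed_ab, hd$directed_ba))

  # sampled HD vs all-pairs point-triangle brute force on small meshes
  a <- make_star_mesh(10, subdivisions = 1)
  b <- transform_points(make_star_mesh(10.8, subdivisions = 1),
                        translation = c(0.4, 0.2, -0.3))
  hd2 <- hausdorff(a, b, n_samples = 20000, seed = 5)
  o_ab <- oracle_directed_hd(oracle_mesh_points(a, 4), b)
  o_ba <- oracle_directed_hd(oracle_mesh_points(b, 4), a)
  expect_equal(hd2$symmetric, max(o_ab, o_ba), tolerance = 0.01)
})

test_that("the 0.5 mm classification boundary behaves as specified", {
  expect_equal(hd_classification(0.63), "poor")
  expect_equal(hd_classification(0.15), "good")
  expect_equal(hd_classification(0.5), "good")   # poor strictly above 0.5
  expect_equal(hd_classification(0.5001), "poor")
  expect_error(hd_classification(-1), "negative")
  sq <- unit_square_pair(0.63)
  expect_equal(hausdorff(sq$a, sq$b, n_samples = 500, seed = 2)$classification,
               "poor")
})

test_that("Hausdorff is metric-like and stable under resampling", {
  set.seed(17)
  meshes <- lapply(1:3, function(i)
    transform_points(make_star_mesh(6 + i, subdivisions = 2),
                     translation = rnorm(3)))
  h <- function(a, b) hausdorff(a, b, n_samples = 4000, seed = 11)$symmetric
  hab <- h(meshes[[1]], meshes[[2]])
  hba <- h(meshes[[2]], meshes[[1]])
  hbc <- h(meshes[[2]], meshes[[3]])
  hac <- h(meshes[[1]], meshes[[3]])
  expect_equal(hab, hba, tolerance = 0.05)
  expect_lte(hac, hab + hbc + 0.05)
  # doubling the sample size moves the estimate by < 5 percent
  h2 <- hausdorff(meshes[[1]], meshes[[2]], n_samples = 8000, seed = 11)$symmetric
  expect_lt(abs(h2 - hab) / hab, 0.05)
  # determinism under a fixed seed
  expect_identical(h(meshes[[1]], meshes[[2]]), hab)
  expect_error(hausdorff(fstd_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                         meshes[[1]]), "empty")
})

test_that("TEM, rTEM and R follow their defining formulas", {
  expect_equal(tem(cbind(c(5, 6, 7), c(5, 6, 7))), 0)
  expect_equal(tem(cbind(rep(1, 4), rep(0, 4))), sqrt(4 / 8)) # 0.70711
  expect_equal(tem(cbind(2, 0)), sqrt(4 / 2))                  # 1.41421
  expect_error(tem(matrix(0, 0, 2)), "no measurement pairs")

  r5 <- rtem(0.5, c(10, 10))
  expect_equal(as.numeric(r5), 5.0)
  expect_true(attr(r5, "reliable")) # 5.0 percent still counts repeatable
  r10 <- rtem(1.0, c(9, 11))
  expect_equal(as.numeric(r10), 10.0)
  expect_false(attr(r10, "reliable"))
  expect_equal(as.numeric(rtem(0, c(4, 6))), 0)
  expect_error(rtem(0.5, c(-10, 2)), "positive")

  expect_equal(as.numeric(reliability_coefficient(0, 2)), 1)
  expect_equal(as.numeric(reliability_coefficient(0.3, 1)), 0.91)
  rneg <- reliability_coefficient(1, 0.25) # S = 0.5
  expect_equal(as.numeric(rneg), -3)
  expect_true(attr(rneg, "unreliable"))
  expect_false(attr(rneg, "accurate"))
  expect_error(reliability_coefficient(0.3, 0), "dispersion")
})

test_that("TEM is scale-equivariant and estimates the session noise", {
  set.seed(8)
  pairs <- cbind(rnorm(50, 10), rnorm(50, 10))
  k <- 3.7
  expect_equal(tem(pairs * k), k * tem(pairs))
  expect_equal(as.numeric(rtem(tem(pairs * k), colMeans(pairs * k))),
               as.numeric(rtem(tem(pairs), colMeans(pairs))))

  # session2 = session1 + eps, eps ~ N(0, sigma^2): since only one session
  # carries the perturbation, E[TEM^2] = sigma^2 / 2
  set.seed(9)
  m1 <- rnorm(1e4, 12, 1)
  eps <- rnorm(1e4, 0, 0.4)
  expect_equal(tem(cbind(m1, m1 + eps)), 0.4 / sqrt(2), tolerance = 0.01)
  # independent noise in both sessions: TEM estimates sigma itself
  m0 <- rnorm(1e4, 12, 1)
  expect_equal(tem(cbind(m0 + rnorm(1e4, 0, 0.4), m0 + rnorm(1e4, 0, 0.4))),
               0.4, tolerance = 0.01)
})

test_that("observer-error reports aggregate two-session tables correctly", {
  lm <- tibble::tibble(code = c("G", "Zy", "Zy"), sex = c("M", "M", "F"),
                       mean_mm = c(6, 9, 10), sd_mm = 1.5)
  lm <- rbind(lm, tibble::tibble(code = "G", sex = "F", mean_mm = 6, sd_mm = 1.5))
  noiseless <- simulate_cohort(cohort_spec(n_per_cell = 3, landmark_means = lm,
                                           session_noise_sd = 0, seed = 2))
  rep0 <- observer_error_report(noiseless)
  expect_true(all(rep0$tem_mm == 0))
  expect_true(all(rep0$rtem_pct == 0))
  expect_true(all(rep0$r_coefficient == 1))
  expect_true(all(rep0$rtem_reliable))

  noisy <- simulate_cohort(cohort_spec(n_per_cell = 20, landmark_means = lm,
                                       session_noise_sd = 0.3, seed = 12))
  repn <- observer_error_report(noisy)
  expect_equal(unique(repn$n), 200)
  in_band <- repn$tem_mm >= 0.25 & repn$tem_mm <= 0.35
  expect_gte(mean(in_band), 0.9)

  # per-landmark n tracks completeness: drop session 2 of one subject/landmark
  drop <- noisy[!(noisy$subject_id == "S001" & noisy$landmark_code == "G" &
                    noisy$session == 2), ]
  repd <- observer_error_report(drop)
  expect_equal(repd$n[repd$landmark_code == "G" & repd$side == "mid"], 199)

  # the literal mean-difference dispersion mode is exposed
  repm <- observer_error_report(noisy, s2_mode = "mean_difference")
  expect_true(all(is.finite(repm$s2_mm2)))
})
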