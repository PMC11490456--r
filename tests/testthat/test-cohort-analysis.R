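mk_table <- function(depths, sex = "M", age = 30, code = "G", side = "mid") {
  n <- length(depths)
  tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), sex = sex,
                 age_years = age, landmark_code = code, side = side,
                 session = 1L, depth_mm = depths)
}

test_that("age binning follows the five cohort groups", {
  expect_equal(as.character(assign_age_group(c(18, 34, 35, 44, 45, 54, 55, 64, 65, 99))),
               c("18-34", "18-34", "35-44", "35-44", "45-54", "45-54",
                 "55-64", "55-64", ">=65", ">=65"))
  expect_error(assign_age_group(17), "18 or older")
  g <- age_group_table()
  expect_equal(g$lower[-1], g$upper[-5] + 1L) # bins partition with no gaps
})

test_that("descriptive tables summarise by landmark, sex and age group", {
  one <- mk_table(7.25)
  d1 <- descriptive_table(one)
  expect_equal(d1$n, 1)
  expect_equal(d1$mean_mm, 7.25)
  expect_equal(d1$min_mm, d1$max_mm)
  expect_true(is.na(d1$sd_mm))

  # 16 subjects split 8/8 by sex in one age bin report n = 8 per sex
  both <- dplyr::bind_rows(mk_table(rnorm(8, 7), sex = "M"),
                           mk_table(rnorm(8, 6), sex = "F"))
  both$subject_id <- sprintf("S%03d", 1:16)
  d2 <- descriptive_table(both)
  expect_equal(sort(d2$n), c(8, 8))
  expect_equal(unique(as.character(d2$age_group)), "18-34")

  expect_error(descriptive_table(both[0, ]), "empty")

  # generating means recovered within CLT bounds on a simulated cohort
  lm <- tibble::tibble(code = "G", sex = c("M", "F"), mean_mm = c(8, 7), sd_mm = 1)
  tab <- simulate_cohort(cohort_spec(n_per_cell = 40, landmark_means = lm,
                                     session_noise_sd = 0, sessions = 1, seed = 3))
  d3 <- descriptive_table(tab)
  expect_true(all(abs(d3$mean_mm[d3$sex == "M"] - 8) < 3 * 1 / sqrt(40)))
  expect_equal(sum(d3$n), 400)
})

test_that("the normality screen is calibrated and powered", {
  set.seed(41)
  norm_p <- replicate(100, normality(mk_table(rnorm(500)))$p_value)
  expect_gte(mean(norm_p >= 0.05), 0.90)
  exp_p <- replicate(100, normality(mk_table(rexp(500)))$p_value)
  expect_gte(mean(exp_p < 0.05), 0.99)

  const <- normality(mk_table(rep(4, 10)))
  expect_match(const$note, "degenerate")
  small <- normality(mk_table(c(1, 2)))
  expect_match(small$note, "n < 3")
})

test_that("age/sex effects detect overwhelming shifts and reject bad designs", {
  lm <- tibble::tibble(code = "G", sex = c("M", "F"), mean_mm = c(10, 10), sd_mm = 1)
  tab <- simulate_cohort(cohort_spec(n_per_cell = 8, landmark_means = lm,
                                     session_noise_sd = 0, sessions = 1, seed = 6))
  tab$depth_mm[tab$sex == "M"] <- tab$depth_mm[tab$sex == "M"] + 3 # 3 sigma
  eff <- age_sex_effects(tab)
  expect_equal(nrow(eff), 3)
  expect_lt(eff$p_value[eff$test_name == "manova_sex"], 0.001)

  solo <- tab[tab$sex == "M", ]
  expect_error(age_sex_effects(solo), "two levels")

  # multivariate mode returns one Pillai row per factor
  lm2 <- tibble::tibble(code = rep(c("G", "N"), each = 2),
                        sex = rep(c("M", "F"), 2), mean_mm = 8, sd_mm = 1)
  tab2 <- simulate_cohort(cohort_spec(n_per_cell = 6, landmark_means = lm2,
                                      session_noise_sd = 0, sessions = 1, seed = 7))
  mv <- age_sex_effects(tab2, mode = "multivariate")
  expect_equal(mv$test_name,
               c("manova_age", "manova_sex", "manova_interaction"))
  expect_true(all(mv$p_value >= 0 & mv$p_value <= 1))
})

test_that("the packaged age/sex p-value table flags exactly OrL, MzL, CoR for age", {
  p9 <- greek_age_sex_pvalues()
  expect_equal(nrow(p9), 39)
  expect_setequal(p9$code[p9$p_age < 0.05], c("OrL", "MzL", "CoR"))
  expect_true(all(p9$p_age >= 0 & p9$p_age <= 1))
})

test_that("bilateral asymmetry recovers injected effects and respects symmetry", {
  lm <- tibble::tibble(code = rep("Zm", 2), sex = c("M", "F"),
                       mean_mm = 15, sd_mm = 1)
  # perfect symmetry: L copied onto R
  tab <- simulate_cohort(cohort_spec(n_per_cell = 5, landmark_means = lm,
                                     session_noise_sd = 0, sessions = 1, seed = 4))
  sym <- tab
  sym$depth_mm[sym$side == "R"] <-
    sym$depth_mm[sym$side == "L"][match(sym$subject_id[sym$side == "R"],
                                        sym$subject_id[sym$side == "L"])]
  asym0 <- bilateral_asymmetry(sym, n_boot = 200, seed = 2)
  expect_true(all(asym0$abs_diff_mm == 0))
  expect_true(all(!asym0$significant))

  # injected 1.89 mm shift at n = 50 per sex, sigma = 1: detected with power
  tab2 <- simulate_cohort(cohort_spec(
    n_per_cell = 10, landmark_means = lm, session_noise_sd = 0, sessions = 1,
    asymmetry_shift = c(Zm = 1.89), seed = 9))
  asym <- bilateral_asymmetry(tab2, n_boot = 500, seed = 3)
  expect_equal(unique(asym$n), 50)
  expect_true(all(asym$p_value < 0.01))
  expect_true(all(abs(asym$abs_diff_mm - 1.89) < 0.4))
  expect_true(all(asym$bootstrap_p < 0.05))
})

test_that("the paired t branch equals the hand-computed statistic", {
  d <- c(0.4, -0.1, 0.3, 0.5, 0.2, 0.6, -0.2, 0.1, 0.35, 0.05)
  l <- 10 + d
  r <- rep(10, length(d))
  tab <- dplyr::bind_rows(
    mk_table(l, code = "Zy", side = "L"),
    mk_table(r, code = "Zy", side = "R"))
  res <- bilateral_asymmetry(tab, n_boot = 100, seed = 1)
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$test_name, "paired_t")
  expect_equal(res$statistic, t_hand, tolerance = 1e-9)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), length(d) - 1),
               tolerance = 1e-9)
})

test_that("bootstrap p-values are seeded, calibrated and flag degeneracy", {
  x <- rnorm(20, 1)
  expect_identical(bootstrap_p(x, 0, 500, seed = 7),
                   bootstrap_p(x, 0, 500, seed = 7))
  expect_warning(bootstrap_p(x, 0, n_boot = 50, seed = 1), "100")
  dg <- bootstrap_p(rep(2, 10), 0, 200, seed = 1)
  expect_true(isTRUE(attr(dg, "degenerate")))

  # null p-values approximately uniform (KS over 500 replicates)
  set.seed(55)
  ps <- vapply(1:500, function(i)
    as.numeric(bootstrap_p(rnorm(15), 0, n_boot = 500, seed = i)), 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
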