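#' Age group definitions
#'
#' The five adult age bins used throughout the cohort analysis. Bins
#' partition ages 18 and above with inclusive integer bounds.
#'
#' @return Tibble with columns `label`, `lower`, `upper` (years; last upper
#'   is `Inf`).
#' @export
age_group_table <- function() {
  tibble::tibble(
    label = c("18-34", "35-44", "45-54", "55-64", ">=65"),
    lower = c(18L, 35L, 45L, 55L, 65L),
    upper = c(34L, 44L, 54L, 64L, Inf))
}

#' Assign ages to age groups
#' @param age_years Integer ages (>= 18).
#' @return Factor of group labels with the levels of [age_group_table()].
#' @export
assign_age_group <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years < 18))
    stop("ages must be 18 or older")
  g <- age_group_table()
  idx <- findInterval(age_years, g$lower)
  factor(g$label[idx], levels = g$label)
}

#' Descriptive depth summaries by landmark, sex and age group
#'
#' One row per landmark position x sex x age group with data: sample size,
#' mean, SD, minimum and maximum depth. Missing landmarks simply reduce
#' `n`; nothing is imputed. Only the requested measurement session is
#' summarised (a real study has one; synthetic tables may carry two).
#'
#' @param table Depth table (see [simulate_cohort()]).
#' @param session Measurement session to summarise (default 1).
#' @return Tibble: `landmark_code`, `side`, `sex`, `age_group`, `n`,
#'   `mean_mm`, `sd_mm`, `min_mm`, `max_mm` (SD is `NA` for `n = 1`).
#' @export
descriptive_table <- function(table, session = 1L) {
  if (nrow(table) == 0L) stop("empty depth table")
  if (!all(table$sex %in% c("M", "F"))) stop("sex must be M or F")
  t1 <- table[table$session == session, ]
  t1$age_group <- assign_age_group(t1$age_years)
  dplyr::summarise(
    dplyr::group_by(t1, .data$landmark_code, .data$side, .data$sex,
                    .data$age_group),
    n = dplyr::n(),
    mean_mm = mean(.data$depth_mm),
    sd_mm = if (dplyr::n() >= 2L) stats::sd(.data$depth_mm) else NA_real_,
    min_mm = min(.data$depth_mm),
    max_mm = max(.data$depth_mm),
    .groups = "drop")
}

#' Shapiro-Wilk normality screen per landmark and sex
#'
#' Tests each landmark position x sex group and records whether the
#' downstream test should be parametric (p >= 0.05). Groups with fewer
#' than 3 values are skipped with a note; constant groups are flagged
#' degenerate.
#'
#' @param table Depth table; session 1 is used.
#' @return Tibble: `landmark_code`, `side`, `sex`, `n`, `test_name`,
#'   `statistic`, `p_value`, `significant`, `parametric`, `note`.
#' @export
normality <- function(table) {
  t1 <- table[table$session == 1L, ]
  out <- lapply(split(t1, paste(t1$landmark_code, t1$side, t1$sex)), function(g) {
    base <- tibble::tibble(
      landmark_code = g$landmark_code[1], side = g$side[1], sex = g$sex[1],
      n = nrow(g), test_name = "shapiro_wilk", statistic = NA_real_,
      p_value = NA_real_, significant = NA, parametric = NA, note = NA_character_)
    if (nrow(g) < 3L) { base$note <- "skipped: n < 3"; return(base) }
    if (stats::sd(g$depth_mm) == 0) { base$note <- "degenerate: constant values"; return(base) }
    sw <- stats::shapiro.test(g$depth_mm)
    base$statistic <- unname(sw$statistic)
    base$p_value <- sw$p.value
    base$significant <- sw$p.value < 0.05
    base$parametric <- sw$p.value >= 0.05
    base
  })
  dplyr::bind_rows(out)
}

#' Age and sex effects on depth, per landmark
#'
#' Two-factor between-subjects analysis of each landmark position's depth
#' on age group, sex and their interaction (type-III sums of squares with
#' sum-to-zero contrasts, matching conventional social-science ANOVA
#' output), laid out one row per landmark and factor. A genuinely
#' multivariate test across landmarks (Pillai trace on subjects with
#' complete landmark profiles) is available with
#' `mode = "multivariate"`.
#'
#' @param table Depth table; session 1 is used.
#' @param mode `"per_landmark"` (default) or `"multivariate"`.
#' @return Tibble: `landmark_code`, `side`, `test_name` (`manova_age`,
#'   `manova_sex`, `manova_interaction`), `statistic` (F or Pillai),
#'   `p_value`, `significant`, `n`. In multivariate mode `landmark_code`
#'   is `"(all)"`.
#' @export
age_sex_effects <- function(table, mode = c("per_landmark", "multivariate")) {
  mode <- match.arg(mode)
  t1 <- table[table$session == 1L, ]
  t1$age_group <- assign_age_group(t1$age_years)
  if (length(unique(t1$sex)) < 2L || length(unique(t1$age_group)) < 2L)
    stop("both age group and sex need at least two levels")
  if (mode == "multivariate") return(age_sex_effects_mv(t1))
  out <- lapply(split(t1, paste(t1$landmark_code, t1$side)), function(g) {
    g$age_group <- droplevels(g$age_group)
    g$sex <- factor(g$sex)
    fit <- stats::lm(depth_mm ~ age_group * sex, data = g,
                     contrasts = list(age_group = "contr.sum", sex = "contr.sum"))
    an <- car::Anova(fit, type = 3)
    rows <- c(age = "age_group", sex = "sex", interaction = "age_group:sex")
    tibble::tibble(
      landmark_code = g$landmark_code[1], side = g$side[1],
      test_name = paste0("manova_", names(rows)),
      statistic = an[rows, "F value"],
      p_value = an[rows, "Pr(>F)"],
      significant = an[rows, "Pr(>F)"] < 0.05,
      n = nrow(g))
  })
  dplyr::bind_rows(out)
}

age_sex_effects_mv <- function(t1) {
  t1$pos <- paste0(t1$landmark_code, ifelse(t1$side == "mid", "", t1$side))
  wide <- stats::reshape(
    as.data.frame(t1[, c("subject_id", "sex", "age_group", "pos", "depth_mm")]),
    idvar = c("subject_id", "sex", "age_group"), timevar = "pos",
    direction = "wide")
  wide <- wide[stats::complete.cases(wide), ]
  y <- as.matrix(wide[, -(1:3)])
  fit <- stats::manova(y ~ age_group * sex, data = wide)
  sm <- summary(fit, test = "Pillai")$stats
  rows <- c(age = "age_group", sex = "sex", interaction = "age_group:sex")
  tibble::tibble(
    landmark_code = "(all)", side = NA_character_,
    test_name = paste0("manova_", names(rows)),
    statistic = sm[rows, "Pillai"],
    p_value = sm[rows, "Pr(>F)"],
    significant = sm[rows, "Pr(>F)"] < 0.05,
    n = nrow(wide))
}

#' Bilateral asymmetry tests per landmark pair
#'
#' For every bilateral landmark and sex, computes per-subject left-minus-
#' right differences, gates the test on Shapiro-Wilk normality of those
#' differences (paired t-test when p >= 0.05, Wilcoxon signed-rank
#' otherwise), and reports the absolute mean difference, the asymptotic p
#' and a seeded subject-resampling bootstrap p.
#'
#' @param table Depth table; session 1 is used.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return Tibble: `landmark_code`, `sex`, `n`, `mean_diff_mm` (signed
#'   left-minus-right), `abs_diff_mm`, `test_name`, `statistic`, `p_value`,
#'   `bootstrap_p`, `significant`.
#' @export
bilateral_asymmetry <- function(table, n_boot = 1000L, seed = 1L) {
  t1 <- table[table$session == 1L & table$side %in% c("L", "R"), ]
  out <- list()
  for (g in split(t1, paste(t1$landmark_code, t1$sex))) {
    l <- g[g$side == "L", c("subject_id", "depth_mm")]
    r <- g[g$side == "R", c("subject_id", "depth_mm")]
    m <- merge(l, r, by = "subject_id", suffixes = c("_L", "_R"))
    if (nrow(m) < 3L) next
    d <- m$depth_mm_L - m$depth_mm_R
    res <- paired_location_test(d)
    bp <- if (n_boot >= 1L)
      bootstrap_p(d, null_value = 0, n_boot = n_boot,
                  seed = seed + match(g$landmark_code[1],
                                      landmark_registry()$code))
    else NA_real_
    out[[length(out) + 1L]] <- tibble::tibble(
      landmark_code = g$landmark_code[1], sex = g$sex[1], n = nrow(m),
      mean_diff_mm = mean(d), abs_diff_mm = abs(mean(d)),
      test_name = res$test_name, statistic = res$statistic,
      p_value = res$p_value, bootstrap_p = as.numeric(bp),
      significant = res$p_value < 0.05)
  }
  dplyr::bind_rows(out)
}

# normality-gated one-sample location test on differences/values
paired_location_test <- function(d, mu = 0) {
  if (stats::sd(d) == 0) {
    # no dispersion: either exactly at the null (no evidence) or a constant
    # offset (degenerate certainty); flag rather than fabricate a statistic
    return(list(test_name = "degenerate_constant", statistic = NA_real_,
                p_value = if (isTRUE(all.equal(mean(d), mu))) 1 else 0))
  }
  parametric <- stats::shapiro.test(d)$p.value >= 0.05
  if (parametric) {
    tt <- stats::t.test(d, mu = mu)
    list(test_name = "paired_t", statistic = unname(tt$statistic),
         p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, mu = mu, exact = FALSE))
    list(test_name = "wilcoxon_signed_rank", statistic = unname(wt$statistic),
         p_value = wt$p.value)
  }
}

#' Bootstrap p-value for a one-sample (or paired-difference) mean
#'
#' Nonparametric case resampling at the subject level: the data are
#' shifted to satisfy the null (`mean = null_value`), resampled `n_boot`
#' times, and the two-sided p is the proportion of resampled t statistics
#' at least as extreme as the observed one (with a +1 continuity
#' correction). Deterministic under `seed`.
#'
#' @param values Numeric vector (differences for a paired design).
#' @param null_value Null mean (default 0).
#' @param n_boot Number of resamples; values below 100 warn.
#' @param seed Integer seed.
#' @return p-value in `[0, 1]`; attribute `degenerate = TRUE` (and p `NA`)
#'   when the data have no dispersion.
#' @export
bootstrap_p <- function(values, null_value = 0, n_boot = 1000L, seed = 1L) {
  if (n_boot < 100L) warning("fewer than 100 bootstrap resamples")
  n <- length(values)
  if (n < 2L || stats::sd(values) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  t_obs <- (mean(values) - null_value) / (stats::sd(values) / sqrt(n))
  shifted <- values - mean(values) + null_value
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  xs <- matrix(shifted[idx], nrow = n)
  ms <- colMeans(xs)
  ss <- sqrt((colSums(xs^2) - n * ms^2) / (n - 1))
  tb <- (ms - null_value) / (ss / sqrt(n))
  tb <- tb[is.finite(tb)]
  (1 + sum(abs(tb) >= abs(t_obs))) / (length(tb) + 1)
}

#' Packaged age/sex effect p-values of the Greek cohort
#'
#' Transcription of the published per-landmark two-factor p-values for the
#' Greek FSTD cohort (age, sex and their interaction). The raw per-subject
#' depths behind them are unpublished, so these are a reference surface for
#' integrity checks, not something the package recomputes.
#'
#' @return Tibble: `code`, `p_age`, `p_sex`, `p_interaction`.
#' @export
greek_age_sex_pvalues <- function() {
  path <- system.file("extdata", "greek_age_sex_pvalues.csv",
                      package = "fstdkit", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
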