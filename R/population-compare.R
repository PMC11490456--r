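#' Load a packaged reference population mean-depth table
#'
#' The package ships transcriptions of published mean facial soft tissue
#' depths for six populations (Greek, Cretan, Turkish, Korean, Czech,
#' French), exactly as printed in the comparison tables of the Greek FSTD
#' study they were compared in. Each comparison table keeps its own
#' landmark granularity (most pool left/right into one value; the Czech
#' table keeps sides separate), so the Greek means are loaded *per
#' comparison*: `load_reference("greek", "M", versus = "cretan")` returns
#' the Greek male means at the granularity of the Cretan comparison.
#' The French dataset is pooled across sexes only.
#'
#' @param population_id One of `"greek"`, `"cretan"`, `"turkish"`,
#'   `"korean"`, `"czech"`, `"french"`.
#' @param sex `"M"`, `"F"` or `"pooled"` (French only).
#' @param versus Required when `population_id = "greek"`: the comparison
#'   table whose Greek column to return.
#' @return Tibble of class `reference_dataset`: `population`, `sex`,
#'   `code` (landmark, side-suffixed where the table separates sides),
#'   `n`, `mean_mm`, `source`.
#' @export
load_reference <- function(population_id, sex = c("M", "F", "pooled"),
                           versus = NULL) {
  pops <- c("greek", "cretan", "turkish", "korean", "czech", "french")
  if (!population_id %in% pops)
    stop("unknown population id: ", population_id)
  sex <- match.arg(sex)
  tab <- reference_fixture()
  if (population_id == "french" && sex != "pooled")
    stop("the French reference is pooled only; use sex = \"pooled\"")
  if (population_id == "greek") {
    if (is.null(versus))
      stop("Greek means are printed per comparison table; give `versus`")
    if (!versus %in% setdiff(pops, "greek")) stop("unknown `versus` population")
    sub <- tab[tab$population == versus &
                 tab$sex == (if (versus == "french") "pooled" else sex), ]
    out <- tibble::tibble(population = "greek", sex = sex, code = sub$code,
                          n = sub$n_greek, mean_mm = sub$greek_mm,
                          source = paste0("greek column of the ", versus,
                                          " comparison table"))
  } else {
    if (population_id == "french") sex <- "pooled"
    sub <- tab[tab$population == population_id & tab$sex == sex, ]
    if (nrow(sub) == 0L) stop("no rows for ", population_id, "/", sex)
    out <- tibble::tibble(population = population_id, sex = sex,
                          code = sub$code, n = sub$n_ref, mean_mm = sub$ref_mm,
                          source = paste0("packaged ", population_id,
                                          " comparison table"))
  }
  if (any(out$mean_mm <= 0)) stop("reference means must be positive")
  class(out) <- c("reference_dataset", class(out))
  out
}

reference_fixture <- function() {
  path <- system.file("extdata", "reference_populations.csv",
                      package = "fstdkit", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    colClasses = c(sig = "character")))
}

# round half away from zero at `digits` decimals (printed-precision rule)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-landmark mean differences between a cohort and a reference
#'
#' Joins the two datasets on shared landmark codes and reports signed and
#' absolute cohort-minus-reference differences, computed at printed
#' precision (2 decimals, half-up) so summaries reproduce published
#' comparisons exactly. When a raw depth table is supplied as the cohort,
#' per-landmark means are computed first at the reference's granularity
#' (sides pooled where the reference pools them).
#'
#' @param cohort A `reference_dataset` (see [load_reference()]) or a raw
#'   depth table (see [simulate_cohort()]).
#' @param reference A `reference_dataset`.
#' @return List with `rows` (tibble: `code`, `cohort_mean_mm`,
#'   `reference_mean_mm`, `signed_diff_mm`, `abs_diff_mm`) and `summary`
#'   (one-row tibble: `max_abs`, `argmax`, `min_abs`, `argmin`).
#' @export
mean_differences <- function(cohort, reference) {
  stopifnot(inherits(reference, "reference_dataset"))
  if (!inherits(cohort, "reference_dataset"))
    cohort <- depth_table_means(cohort, granularity_of(reference))
  rows <- dplyr::inner_join(
    tibble::tibble(code = cohort$code,
                   cohort_mean_mm = round_half_up(cohort$mean_mm)),
    tibble::tibble(code = reference$code,
                   reference_mean_mm = round_half_up(reference$mean_mm)),
    by = "code")
  if (nrow(rows) == 0L) stop("no shared landmarks between the datasets")
  rows$signed_diff_mm <- round_half_up(rows$cohort_mean_mm - rows$reference_mean_mm)
  rows$abs_diff_mm <- abs(rows$signed_diff_mm)
  summary <- tibble::tibble(
    max_abs = max(rows$abs_diff_mm),
    argmax = rows$code[which.max(rows$abs_diff_mm)],
    min_abs = min(rows$abs_diff_mm),
    argmin = rows$code[which.min(rows$abs_diff_mm)])
  list(rows = rows, summary = summary)
}

granularity_of <- function(reference) {
  if (any(grepl("[LR]$", reference$code) &
            sub("[LR]$", "", reference$code) %in% landmark_registry()$code))
    "sided" else "pooled"
}

# per-landmark means of a raw depth table at the requested granularity
depth_table_means <- function(table, granularity = c("pooled", "sided")) {
  granularity <- match.arg(granularity)
  t1 <- table[table$session == 1L, ]
  code <- if (granularity == "sided")
    paste0(t1$landmark_code, ifelse(t1$side == "mid", "", t1$side))
  else t1$landmark_code
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(code = code, depth_mm = t1$depth_mm), .data$code),
    n = dplyr::n(), mean_mm = mean(.data$depth_mm), .groups = "drop")
  agg
}

#' One-sample tests of a raw cohort against reference means
#'
#' For every shared landmark with at least 3 cohort values, tests the
#' cohort depths against the reference mean: one-sample t-test when the
#' cohort values pass the Shapiro-Wilk normality screen (p >= 0.05),
#' Wilcoxon one-sample signed-rank otherwise, plus a seeded bootstrap p
#' (1000 resamples by default).
#'
#' @param cohort_raw Raw depth table (see [simulate_cohort()]).
#' @param reference A `reference_dataset`.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return Tibble: `code`, `n`, `cohort_mean_mm`, `reference_mean_mm`,
#'   `signed_diff_mm`, `abs_diff_mm`, `test_name`, `statistic`, `p_value`,
#'   `bootstrap_p`, `significant`.
#' @export
one_sample_tests <- function(cohort_raw, reference, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(reference, "reference_dataset"))
  gran <- granularity_of(reference)
  t1 <- cohort_raw[cohort_raw$session == 1L, ]
  t1$code <- if (gran == "sided")
    paste0(t1$landmark_code, ifelse(t1$side == "mid", "", t1$side))
  else t1$landmark_code
  out <- list()
  for (i in seq_len(nrow(reference))) {
    code <- reference$code[i]
    x <- t1$depth_mm[t1$code == code]
    if (length(x) < 3L) next
    mu <- reference$mean_mm[i]
    res <- paired_location_test(x, mu = mu)
    res$test_name <- switch(res$test_name, paired_t = "one_sample_t",
                            wilcoxon_signed_rank = "wilcoxon_one_sample",
                            res$test_name)
    bp <- if (n_boot >= 1L) bootstrap_p(x, null_value = mu, n_boot = n_boot,
                                        seed = seed + i) else NA_real_
    out[[length(out) + 1L]] <- tibble::tibble(
      code = code, n = length(x), cohort_mean_mm = mean(x),
      reference_mean_mm = mu,
      signed_diff_mm = mean(x) - mu, abs_diff_mm = abs(mean(x) - mu),
      test_name = res$test_name, statistic = res$statistic,
      p_value = res$p_value, bootstrap_p = as.numeric(bp),
      significant = res$p_value < 0.05)
  }
  dplyr::bind_rows(out)
}

#' The published extreme inter-population differences
#'
#' Recomputes, from the packaged fixtures alone, the extreme per-landmark
#' mean differences reported for each comparison of the Greek cohort with
#' the five reference populations (plus the Turkish-female nasion offset,
#' the one landmark where that population exceeds the Greek mean).
#'
#' @return Tibble: `comparison`, `quantity`, `landmark`, `value_mm`.
#' @export
interpopulation_extremes <- function() {
  cmp <- function(pop, sex) {
    mean_differences(load_reference("greek", sex, versus = pop),
                     load_reference(pop, sex))
  }
  rows <- list()
  add <- function(comparison, quantity, landmark, value)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      comparison = comparison, quantity = quantity, landmark = landmark,
      value_mm = value)
  cm <- cmp("cretan", "M")$summary
  add("greek_vs_cretan_male", "max_abs", cm$argmax, cm$max_abs)
  add("greek_vs_cretan_male", "min_abs", cm$argmin, cm$min_abs)
  cf <- cmp("cretan", "F")$summary
  add("greek_vs_cretan_female", "max_abs", cf$argmax, cf$max_abs)
  add("greek_vs_cretan_female", "min_abs", cf$argmin, cf$min_abs)
  tm <- cmp("turkish", "M")$summary
  add("greek_vs_turkish_male", "max_abs", tm$argmax, tm$max_abs)
  add("greek_vs_turkish_male", "min_abs", tm$argmin, tm$min_abs)
  tfr <- cmp("turkish", "F")$rows
  add("greek_vs_turkish_female", "nasion_excess_in_reference", "N",
      -tfr$signed_diff_mm[tfr$code == "N"])
  kf <- cmp("korean", "F")$summary
  add("greek_vs_korean_female", "max_abs", kf$argmax, kf$max_abs)
  zm <- cmp("czech", "M")$summary
  add("greek_vs_czech_male", "max_abs", zm$argmax, zm$max_abs)
  zf <- cmp("czech", "F")$summary
  add("greek_vs_czech_female", "max_abs", zf$argmax, zf$max_abs)
  fr <- mean_differences(load_reference("greek", "pooled", versus = "french"),
                         load_reference("french", "pooled"))$summary
  add("greek_vs_french_pooled", "max_abs", fr$argmax, fr$max_abs)
  dplyr::bind_rows(rows)
}
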