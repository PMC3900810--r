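# Published summary tables from a Japanese 16-day diet-record survey of
# trans fatty acid intake (225 adults aged 30-69 in 4 areas), used as
# reference fixtures: the per-step provenance counts of its 1995-food
# composition database, the food-group contribution table, and the
# stratified intake distribution. Only the printed aggregates are encoded;
# no subject-level data exist.

#' Published per-group, per-step provenance counts
#'
#' The number of foods in each TFA-containing food group resolved at each
#' step of the four-step assignment hierarchy in the published 1995-food
#' Japanese TFA database (526 foods with TFA; the remaining 1469 are covered
#' by the zero rule).
#'
#' @return Tibble with `group` and one column per step.
#' @export
reference_step_counts <- function() {
  tibble::tribble(
    ~group, ~S1, ~S2_1A, ~S2_1B, ~S2_2A, ~S2_2B, ~S2_2C, ~S2_2D, ~S2_2E, ~S3, ~S4,
    "Confectionaries (I)",          25, 49, 34,  0,  0,  0, 0,  0,  2, 12,
    "Bakery (I)",                    6, 12,  9,  0,  0,  0, 0,  0,  1,  0,
    "Fats and oils (N)",            11,  2,  6,  0,  0,  0, 0,  0,  0,  0,
    "Fats and oils (I)",             5,  0,  0,  0,  0,  0, 0,  0,  0,  0,
    "Instant and retort foods (I)", 17, 26,  0,  0,  0,  0, 0,  0,  0,  0,
    "Milk and dairy products (N)",  23, 13,  8,  0,  0,  0, 0,  0,  0,  0,
    "Milk and dairy products (I)",   7,  0,  0,  0,  0,  0, 0,  0,  0,  0,
    "Meat and meat products (N)",   41,  0, 21, 22, 17, 38, 7, 88,  0,  2,
    "Margarine (I)",                 3,  0,  0,  0,  0,  0, 0,  0,  0,  0,
    "Fast foods (I)",                1,  0,  0,  0,  0,  0, 0,  0, 10,  0,
    "Miscellaneous (I)",             4,  1,  0,  0,  0,  0, 0,  0,  1,  2)
}

#' Published food-group contribution to total TFA intake
#'
#' Mean and SD over subjects of the percentage of total TFA mass intake
#' contributed by each food group, per sex, from the published survey.
#'
#' @param sex `"women"` or `"men"`.
#' @return Contribution rows (`group`, `origin`, `mean_pct`, `sd_pct`).
#' @export
reference_group_contributions <- function(sex = c("women", "men")) {
  sex <- match.arg(sex)
  d <- tibble::tribble(
    ~group, ~mean_women, ~sd_women, ~mean_men, ~sd_men,
    "Confectionaries (I)",          21.7, 19.7, 15.3, 25.0,
    "Bakery (I)",                   19.1, 13.3, 18.0, 13.7,
    "Fats and oils (N)",             2.0,  2.0,  2.1,  2.4,
    "Fats and oils (I)",            14.1,  6.0, 20.0,  7.4,
    "Instant and retort foods (I)",  7.5,  6.4, 10.0,  8.3,
    "Milk and dairy products (N)",  12.3,  8.2,  9.7,  7.9,
    "Milk and dairy products (I)",   3.3,  4.1,  3.1,  5.1,
    "Meat and meat products (N)",   10.7,  6.6, 15.5,  8.9,
    "Margarine (I)",                 4.8,  6.7,  5.8,  8.9,
    "Fast foods (I)",                3.5,  7.0,  3.7,  8.8,
    "Miscellaneous (I)",             1.1,  1.0,  1.0,  0.9)
  tibble(group = d$group,
         origin = group_origin(d$group),
         mean_pct = if (sex == "women") d$mean_women else d$mean_men,
         sd_pct = if (sex == "women") d$sd_women else d$sd_men)
}

#' Published stratified distribution of TFA intake
#'
#' Subject counts per intake bin, stratified by living area (urban/rural)
#' and by 10-year age group, for both the g/day and the %-of-energy scale,
#' as printed in the published survey (119 women, 106 men after outlier
#' exclusion).
#'
#' @return Long tibble: `sex`, `measure` (`"g_day"` or `"pct_energy"`),
#'   `bin_lo`, `bin_hi` (printed bin label bounds), `stratum_type`
#'   (`"area"`, `"age"`), `stratum`, `n`.
#' @export
reference_intake_distribution <- function() {
  row <- function(sex, measure, lo, hi, urban, rural, a30, a40, a50, a60) {
    tibble(sex = sex, measure = measure, bin_lo = lo, bin_hi = hi,
           stratum_type = c("area", "area", "age", "age", "age", "age"),
           stratum = c("urban", "rural", "30-39", "40-49", "50-59", "60-69"),
           n = c(urban, rural, a30, a40, a50, a60))
  }
  bind_rows(
    row("women", "g_day", 0.47, 0.99,  4, 11,  0,  1,  2, 12),
    row("women", "g_day", 1.00, 1.49, 16, 24,  6, 10, 10, 14),
    row("women", "g_day", 1.50, 1.99, 18, 16, 11,  6, 13,  4),
    row("women", "g_day", 2.00, 2.49,  7,  5,  2,  4,  6,  0),
    row("women", "g_day", 2.50, 2.99,  4,  5,  4,  4,  0,  1),
    row("women", "g_day", 3.00, 4.08,  7,  2,  4,  4,  1,  0),
    row("women", "pct_energy", 0.31, 0.49,  3, 11,  0,  0,  3, 11),
    row("women", "pct_energy", 0.50, 0.74, 16, 27,  6, 12, 10, 15),
    row("women", "pct_energy", 0.75, 0.99, 18, 15, 12,  6, 11,  4),
    row("women", "pct_energy", 1.00, 1.24, 11,  4,  5,  4,  6,  0),
    row("women", "pct_energy", 1.25, 1.49,  6,  4,  2,  5,  2,  1),
    row("women", "pct_energy", 1.50, 1.95,  3,  1,  2,  2,  0,  0),
    row("men", "g_day", 0.68, 0.99,  6,  5,  0,  0,  5,  6),
    row("men", "g_day", 1.00, 1.49, 13, 21,  4, 11,  7, 12),
    row("men", "g_day", 1.50, 1.99, 12, 19,  7,  9,  9,  6),
    row("men", "g_day", 2.00, 2.49,  9,  6,  6,  4,  3,  2),
    row("men", "g_day", 2.50, 2.99,  7,  2,  2,  1,  3,  3),
    row("men", "g_day", 3.00, 3.49,  4,  2,  1,  4,  1,  0),
    row("men", "pct_energy", 0.20, 0.49, 10, 17,  0,  8,  7, 12),
    row("men", "pct_energy", 0.50, 0.74, 20, 27,  9,  9, 16, 13),
    row("men", "pct_energy", 0.75, 0.99, 15, 11,  9,  9,  5,  3),
    row("men", "pct_energy", 1.00, 1.23,  6,  0,  2,  3,  0,  1))
}

#' Expand published distribution counts into a subject-level fixture
#'
#' Reconstructs a subject-level cohort consistent with the published
#' stratified bin counts: each subject receives the midpoint of their bin as
#' intake value, an area label, and an age-group label. Within each bin the
#' area and age marginals are both honoured (any pairing of the two labels
#' within a bin is consistent, since the published strata are marginals of
#' the same bin total).
#'
#' @param measure `"pct_energy"` (default) or `"g_day"`.
#'
#' @return Tibble: `subject_id`, `sex`, `area_type`, `age_group`, and the
#'   intake column (`tfa_pct_energy` or `tfa_g_day`).
#' @export
reference_distribution_cohort <- function(measure = c("pct_energy", "g_day")) {
  measure <- match.arg(measure)
  dist <- reference_intake_distribution()
  dist <- dist[dist$measure == measure, , drop = FALSE]
  value_col <- if (measure == "pct_energy") "tfa_pct_energy" else "tfa_g_day"
  out <- list()
  for (sx in unique(dist$sex)) {
    dsx <- dist[dist$sex == sx, , drop = FALSE]
    for (lo in unique(dsx$bin_lo)) {
      bin <- dsx[dsx$bin_lo == lo, , drop = FALSE]
      area_n <- bin$n[bin$stratum_type == "area"]
      age_n <- bin$n[bin$stratum_type == "age"]
      stopifnot(sum(area_n) == sum(age_n))
      total <- sum(area_n)
      if (total == 0) next
      mid <- (lo + bin$bin_hi[[1]]) / 2
      out[[length(out) + 1L]] <- tibble(
        sex = sx,
        area_type = rep(c("urban", "rural"), times = area_n),
        age_group = rep(c("30-39", "40-49", "50-59", "60-69"), times = age_n),
        value = mid)
    }
  }
  res <- bind_rows(out)
  res$subject_id <- sprintf("ref%03d", seq_len(nrow(res)))
  res[[value_col]] <- res$value
  res[, c("subject_id", "sex", "area_type", "age_group", value_col)]
}
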