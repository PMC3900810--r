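#' Per-subject mean daily TFA intake by food group
#'
#' Attributes each resolved component's TFA to the component's food group
#' (so a restaurant dish decomposed into raw materials credits the
#' materials' groups) and averages over the subject's recorded days.
#'
#' @inheritParams subject_mean_intake
#'
#' @return Tibble `subject_id`, `group`, `tfa_g_day` (all consumed groups,
#'   including zero rows for groups the subject never touched).
#' @export
intake_by_group <- function(records, foods, assignments, recipes = NULL,
                            config = intake_config()) {
  comp <- resolve_entries(records, recipes, foods)
  idx <- match(comp$food_id, foods$food_id)
  aidx <- match(comp$food_id, assignments$food_id)
  tfa100 <- assignments$tfa_g_100g[aidx]
  if (anyNA(tfa100)) {
    if (config$missing_tfa == "zero") tfa100[is.na(tfa100)] <- 0
    else stop("no TFA assignment for consumed food(s): ",
              paste(sort(unique(comp$food_id[is.na(tfa100)])), collapse = ", "),
              call. = FALSE)
  }
  comp$group <- foods$group[idx]
  comp$tfa <- comp$grams * tfa100 / 100
  days <- comp |>
    group_by(.data$subject_id) |>
    summarise(n_days = dplyr::n_distinct(.data$day_index), .groups = "drop")
  comp |>
    group_by(.data$subject_id, .data$group) |>
    summarise(tfa_total = sum(.data$tfa), .groups = "drop") |>
    inner_join(days, by = "subject_id") |>
    mutate(tfa_g_day = .data$tfa_total / .data$n_days) |>
    select("subject_id", "group", "tfa_g_day") |>
    tidyr::complete(.data$subject_id, .data$group,
                    fill = list(tfa_g_day = 0)) |>
    arrange(.data$subject_id, .data$group)
}

#' Food-group contribution to total TFA intake
#'
#' Per subject, the share (%) of total TFA mass intake contributed by each
#' food group; rows report the mean and SD of the shares over subjects.
#' Subjects with zero total TFA carry no shares and are dropped with a
#' warning.
#'
#' @param group_intakes Per-subject group intakes from [intake_by_group()].
#' @param groups Group set to report; defaults to the groups present.
#'
#' @return Tibble with `group`, `origin` (parsed from the "(I)"/"(N)" label
#'   suffix), `mean_pct`, `sd_pct`, `n_subjects`.
#' @export
contribution_by_group <- function(group_intakes, groups = NULL) {
  totals <- group_intakes |>
    group_by(.data$subject_id) |>
    summarise(total = sum(.data$tfa_g_day), .groups = "drop")
  zero <- totals$subject_id[totals$total <= 0]
  if (length(zero)) {
    warning(length(zero), " subject(s) with zero total TFA excluded from ",
            "the contribution decomposition", call. = FALSE)
  }
  shares <- group_intakes |>
    inner_join(totals, by = "subject_id") |>
    filter(.data$total > 0) |>
    mutate(share = 100 * .data$tfa_g_day / .data$total)
  if (!is.null(groups)) {
    shares <- shares |>
      filter(.data$group %in% groups) |>
      mutate(group = factor(.data$group, levels = groups)) |>
      tidyr::complete(.data$subject_id, .data$group, fill = list(share = 0))
  }
  shares |>
    group_by(.data$group) |>
    summarise(mean_pct = mean(.data$share),
              sd_pct = sd(.data$share),
              n_subjects = dplyr::n(), .groups = "drop") |>
    mutate(group = as.character(.data$group),
           origin = group_origin(.data$group)) |>
    select("group", "origin", "mean_pct", "sd_pct", "n_subjects")
}

#' Share of TFA intake from industrial sources
#'
#' Sums the mean group contributions over the rows whose origin is
#' industrial (partially hydrogenated oils), as opposed to natural
#' (ruminant) sources.
#'
#' @param rows Contribution rows from [contribution_by_group()] (or any
#'   tibble with `origin` and `mean_pct`).
#'
#' @return The industrial share in percent.
#' @export
industrial_share <- function(rows) {
  if (anyNA(rows$origin)) {
    stop("every contribution row must be labelled industrial or natural",
         call. = FALSE)
  }
  sum(rows$mean_pct[rows$origin == "industrial"])
}

#' Classify an area as urban or rural by population density
#'
#' @param density Population density in persons/km^2 (vectorised).
#' @param urban_density_threshold Density at or above which the area is
#'   urban; see [summary_config()].
#'
#' @return Character vector, `"urban"` or `"rural"`.
#' @export
#' @examples
#' classify_area(c(11743, 285))
classify_area <- function(density, urban_density_threshold = 1000) {
  if (any(density <= 0)) stop("density must be positive", call. = FALSE)
  ifelse(density >= urban_density_threshold, "urban", "rural")
}

#' Frequency of intake above a threshold, per stratum
#'
#' Counts subjects whose intake exceeds (strictly) a threshold, overall or
#' within strata.
#'
#' @param intakes Intake tibble.
#' @param threshold Threshold on `value`; default 1 (the conventional
#'   %-of-energy ceiling).
#' @param value Column to compare; default `"tfa_pct_energy"`.
#' @param by Character vector of stratum columns (e.g. `c("sex", "area_type")`),
#'   or `NULL` for the whole table.
#'
#' @return Tibble with the stratum columns, `n`, `n_above`, and `pct_above`
#'   (unrounded; round to the desired display precision at report time).
#' @export
frequency_above <- function(intakes, threshold = 1, value = "tfa_pct_energy",
                            by = NULL) {
  grouped <- if (is.null(by)) intakes else
    group_by(intakes, across(all_of(by)), .drop = FALSE)
  grouped |>
    summarise(n = dplyr::n(),
              n_above = sum(.data[[value]] > threshold),
              .groups = "drop") |>
    mutate(pct_above = ifelse(.data$n > 0, 100 * .data$n_above / .data$n, 0))
}

#' Intake distribution table
#'
#' Counts subjects per half-open intake bin `[lo, hi)` per stratum. Interior
#' bin edges are given; the extreme bins are open-ended, with display labels
#' truncated at the observed minimum and maximum.
#'
#' @param intakes Intake tibble.
#' @param edges Strictly increasing interior bin edges.
#' @param value Column to bin.
#' @param by Stratum columns, or `NULL`.
#'
#' @return Tibble with `bin` (label), `bin_lo`, `bin_hi`, the stratum
#'   columns, and `n`.
#' @export
distribution_table <- function(intakes, edges, value = "tfa_g_day",
                               by = NULL) {
  if (any(diff(edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  x <- intakes[[value]]
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  labels <- sprintf("%.2f-%.2f",
                    ifelse(is.finite(lo), lo, min(x)),
                    ifelse(is.finite(hi), hi, max(x)))
  bin <- cut(x, breaks = c(lo, Inf)[seq_len(length(lo) + 1)], right = FALSE,
             labels = labels)
  df <- intakes
  df$bin <- bin
  grouped <- if (is.null(by)) group_by(df, .data$bin, .drop = FALSE) else
    group_by(df, .data$bin, across(all_of(by)), .drop = FALSE)
  counts <- grouped |> summarise(n = dplyr::n(), .groups = "drop")
  key <- tibble(bin = factor(labels, levels = labels), bin_lo = lo, bin_hi = hi)
  counts |>
    inner_join(key, by = "bin") |>
    mutate(bin = as.character(.data$bin)) |>
    select("bin", "bin_lo", "bin_hi", dplyr::everything())
}

#' Urban/rural and age-group comparisons of intake
#'
#' Per sex and variable: a two-sided unpaired t-test of urban vs rural
#' means, and a one-way ANOVA over the four 10-year age groups followed by
#' Tukey-Kramer pairwise comparisons (family-wise 0.05, valid for unequal
#' group sizes). Degenerate strata (fewer than two groups with data, or zero
#' variance everywhere) yield `NA` p-values.
#'
#' @param intakes Intake tibble with `sex`, `area_type`, `age_group`
#'   columns.
#' @param vars Variables to compare.
#'
#' @return List of tibbles: `t_tests` (sex, variable, urban/rural means and
#'   SDs, p_value), `anova` (sex, variable, p_value), `tukey` (sex,
#'   variable, contrast, diff, p_adj).
#' @export
compare_strata <- function(intakes,
                           vars = c("energy_kcal_day", "fat_g_day",
                                    "fat_pct_energy", "tfa_g_day",
                                    "tfa_pct_energy", "tfa_pct_fat")) {
  sexes <- sort(unique(intakes$sex))
  tt <- list(); av <- list(); tk <- list()
  for (sx in sexes) {
    d <- intakes[intakes$sex == sx, , drop = FALSE]
    for (v in vars) {
      u <- d[[v]][d$area_type == "urban"]
      r <- d[[v]][d$area_type == "rural"]
      p <- if (length(u) >= 2 && length(r) >= 2 &&
               (sd(u) > 0 || sd(r) > 0)) {
        t.test(u, r, var.equal = TRUE)$p.value
      } else NA_real_
      tt[[length(tt) + 1L]] <- tibble(
        sex = sx, variable = v,
        mean_urban = mean(u), sd_urban = sd(u), n_urban = length(u),
        mean_rural = mean(r), sd_rural = sd(r), n_rural = length(r),
        p_value = p)

      grp <- droplevels(factor(d$age_group))
      ok <- nlevels(grp) >= 2 && all(table(grp) >= 2) && sd(d[[v]]) > 0
      if (ok) {
        fit <- aov(d[[v]] ~ grp)
        pa <- summary(fit)[[1]][["Pr(>F)"]][[1]]
        th <- TukeyHSD(fit)$grp
        tk[[length(tk) + 1L]] <- tibble(
          sex = sx, variable = v, contrast = rownames(th),
          diff = th[, "diff"], p_adj = th[, "p adj"])
      } else {
        pa <- NA_real_
      }
      av[[length(av) + 1L]] <- tibble(sex = sx, variable = v, p_value = pa)
    }
  }
  list(t_tests = bind_rows(tt), anova = bind_rows(av), tukey = bind_rows(tk))
}

#' Mean and SD of intake variables per stratum
#'
#' Descriptive stratum summaries (overall, by area type, or by age group).
#'
#' @inheritParams compare_strata
#' @param by Stratum columns in addition to `sex`.
#'
#' @return Long tibble: stratum columns, `variable`, `n`, `mean`, `sd`.
#' @export
stratum_summary <- function(intakes, by = NULL,
                            vars = c("energy_kcal_day", "fat_g_day",
                                     "fat_pct_energy", "tfa_g_day",
                                     "tfa_pct_energy", "tfa_pct_fat")) {
  intakes |>
    tidyr::pivot_longer(all_of(vars), names_to = "variable") |>
    group_by(across(all_of(c("sex", by, "variable")))) |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = sd(.data$value), .groups = "drop")
}

#' Compare intake under the full and a reduced composition database
#'
#' Re-estimates TFA intake with a database restricted to a base food list
#' (consumed foods missing from it contribute zero TFA) and reports per-sex
#' means under both databases; the difference is the impact of the added
#' foods.
#'
#' @param records,subjects,foods,recipes As in [estimate_intakes()].
#' @param assignments_full Assignments covering all foods.
#' @param assignments_reduced Assignments restricted to the base food list.
#' @param config An [intake_config()].
#'
#' @return Tibble: `sex`, `variable` (`tfa_g_day`, `tfa_pct_energy`),
#'   `mean_full`, `mean_reduced`, `difference`.
#' @export
compare_databases <- function(records, subjects, foods, assignments_full,
                              assignments_reduced, recipes = NULL,
                              config = intake_config()) {
  cfg_red <- intake_config(energy_per_gram_fat = config$energy_per_gram_fat,
                           outlier_k = config$outlier_k,
                           missing_tfa = "zero")
  full <- estimate_intakes(records, subjects, foods, assignments_full,
                           recipes, config)
  red <- estimate_intakes(records, subjects, foods, assignments_reduced,
                          recipes, cfg_red)
  joined <- inner_join(full, red, by = c("subject_id", "sex"),
                       suffix = c("_full", "_reduced"))
  joined |>
    group_by(.data$sex) |>
    summarise(
      tfa_g_day_full = mean(.data$tfa_g_day_full),
      tfa_g_day_reduced = mean(.data$tfa_g_day_reduced),
      tfa_pct_energy_full = mean(.data$tfa_pct_energy_full),
      tfa_pct_energy_reduced = mean(.data$tfa_pct_energy_reduced),
      .groups = "drop") |>
    tidyr::pivot_longer(-"sex",
                        names_to = c("variable", "database"),
                        names_pattern = "(tfa_g_day|tfa_pct_energy)_(full|reduced)") |>
    tidyr::pivot_wider(names_from = "database", values_from = "value",
                       names_prefix = "mean_") |>
    mutate(difference = .data$mean_full - .data$mean_reduced)
}
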