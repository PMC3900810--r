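#' Flatten nested recipes to elementary components
#'
#' Repeatedly substitutes composed ingredients by their own recipes until
#' only elementary foods remain, multiplying gram fractions along the way
#' and summing duplicated components.
#'
#' @param recipes Long-format recipes (`food_id`, `ingredient_id`,
#'   `grams_per_100g`).
#'
#' @return A tibble of the same shape whose `ingredient_id`s are all
#'   elementary.
#' @export
flatten_recipes <- function(recipes) {
  empty <- tibble(food_id = character(), ingredient_id = character(),
                  grams_per_100g = numeric())
  if (is.null(recipes) || !nrow(recipes)) return(empty)
  composed <- unique(recipes$food_id)
  flat <- as_tibble(recipes[, c("food_id", "ingredient_id", "grams_per_100g")])
  for (iter in seq_len(length(composed) + 1L)) {
    nested <- flat$ingredient_id %in% composed
    if (!any(nested)) break
    if (iter > length(composed)) {
      stop("cyclic recipes detected while flattening", call. = FALSE)
    }
    keep <- flat[!nested, , drop = FALSE]
    expand <- flat[nested, , drop = FALSE] |>
      inner_join(recipes, by = c("ingredient_id" = "food_id"),
                 suffix = c("", ".inner"), relationship = "many-to-many") |>
      mutate(grams_per_100g = .data$grams_per_100g *
               .data$grams_per_100g.inner / 100,
             ingredient_id = .data$ingredient_id.inner) |>
      select("food_id", "ingredient_id", "grams_per_100g")
    flat <- bind_rows(keep, expand)
  }
  flat |>
    group_by(.data$food_id, .data$ingredient_id) |>
    summarise(grams_per_100g = sum(.data$grams_per_100g), .groups = "drop") |>
    arrange(.data$food_id, .data$ingredient_id)
}

# Is each food "composed"? An explicit is_composed column wins; otherwise
# membership in the recipe table defines it.
composed_ids <- function(foods, recipes) {
  if (!is.null(foods) && "is_composed" %in% names(foods)) {
    foods$food_id[!is.na(foods$is_composed) & foods$is_composed]
  } else if (!is.null(recipes) && nrow(recipes)) {
    unique(recipes$food_id)
  } else {
    character()
  }
}

#' Resolve one diet-record entry to elementary consumption
#'
#' Commercial and home entries pass through unchanged: commercial products
#' (e.g. fast-food fries) are valued as the products themselves, not as
#' their raw materials. A composed dish eaten at a restaurant, for which no
#' product declaration exists, is decomposed into its raw materials via its
#' recipe, scaled to the consumed mass.
#'
#' @param entry One diet-record row (`food_id`, `grams`, `venue`).
#' @param recipes Long-format recipes (possibly nested).
#' @param foods Food table; an optional `is_composed` column marks dishes
#'   that require a recipe when eaten at a restaurant.
#'
#' @return A tibble of `(food_id, grams)` component rows.
#' @export
resolve_entry <- function(entry, recipes = NULL, foods = NULL) {
  comp <- composed_ids(foods, recipes)
  if (identical(entry$venue, "restaurant") && entry$food_id %in% comp) {
    flat <- flatten_recipes(recipes)
    flat <- flat[flat$food_id == entry$food_id, , drop = FALSE]
    if (!nrow(flat)) {
      stop("restaurant entry for composed food ", entry$food_id,
           " has no recipe to decompose", call. = FALSE)
    }
    tibble(food_id = flat$ingredient_id,
           grams = entry$grams * flat$grams_per_100g / 100)
  } else {
    tibble(food_id = entry$food_id, grams = entry$grams)
  }
}

# Vectorised resolution of a whole record table; keeps subject/day columns.
resolve_entries <- function(records, recipes = NULL, foods = NULL) {
  comp <- composed_ids(foods, recipes)
  is_rest <- records$venue == "restaurant" & records$food_id %in% comp
  simple <- records[!is_rest, , drop = FALSE]
  simple <- simple[, setdiff(names(simple), "venue"), drop = FALSE]
  if (!any(is_rest)) return(as_tibble(simple))
  flat <- flatten_recipes(recipes)
  missing <- setdiff(unique(records$food_id[is_rest]), unique(flat$food_id))
  if (length(missing)) {
    stop("restaurant entries for composed food(s) without a recipe: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  expanded <- records[is_rest, , drop = FALSE] |>
    inner_join(flat, by = "food_id", relationship = "many-to-many") |>
    mutate(grams = .data$grams * .data$grams_per_100g / 100,
           food_id = .data$ingredient_id) |>
    select(all_of(setdiff(names(records), "venue")))
  bind_rows(as_tibble(simple), expanded)
}

#' Per-subject mean daily intake from diet records
#'
#' For every recorded day, energy, total fat and TFA are accumulated over
#' the resolved components (`grams x content per 100 g / 100`); daily totals
#' are then averaged over the subject's recorded days. Percent-of-energy
#' expressions use the fat energy factor (kcal/g) from `config` and are
#' computed as the ratio of the multi-day means.
#'
#' @param records Diet-record rows (`subject_id`, `day_index`, `food_id`,
#'   `grams`, `venue`).
#' @param foods Food table (energy and fat per 100 g).
#' @param assignments TFA assignments from [build_database()].
#' @param recipes Recipes for restaurant decomposition, or `NULL`.
#' @param config An [intake_config()].
#'
#' @return A tibble with one row per subject: `subject_id`, `n_days`,
#'   `energy_kcal_day`, `fat_g_day`, `tfa_g_day`, `fat_pct_energy`,
#'   `tfa_pct_energy`, `tfa_pct_fat`.
#' @export
subject_mean_intake <- function(records, foods, assignments, recipes = NULL,
                                config = intake_config()) {
  comp <- resolve_entries(records, recipes, foods)
  unknown <- setdiff(unique(comp$food_id), foods$food_id)
  if (length(unknown)) {
    stop("diet records reference unknown food(s): ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  idx <- match(comp$food_id, foods$food_id)
  aidx <- match(comp$food_id, assignments$food_id)
  tfa100 <- assignments$tfa_g_100g[aidx]
  if (anyNA(tfa100)) {
    if (config$missing_tfa == "zero") {
      tfa100[is.na(tfa100)] <- 0
    } else {
      stop("no TFA assignment for consumed food(s): ",
           paste(sort(unique(comp$food_id[is.na(tfa100)])), collapse = ", "),
           call. = FALSE)
    }
  }
  comp$energy <- comp$grams * foods$energy_kcal_100g[idx] / 100
  comp$fat <- comp$grams * foods$fat_g_100g[idx] / 100
  comp$tfa <- comp$grams * tfa100 / 100

  daily <- comp |>
    group_by(.data$subject_id, .data$day_index) |>
    summarise(energy = sum(.data$energy), fat = sum(.data$fat),
              tfa = sum(.data$tfa), .groups = "drop")
  subj <- daily |>
    group_by(.data$subject_id) |>
    summarise(n_days = dplyr::n(),
              energy_kcal_day = mean(.data$energy),
              fat_g_day = mean(.data$fat),
              tfa_g_day = mean(.data$tfa), .groups = "drop")
  if (any(subj$energy_kcal_day <= 0)) {
    stop("subject(s) with zero total energy intake: ",
         paste(subj$subject_id[subj$energy_kcal_day <= 0], collapse = ", "),
         call. = FALSE)
  }
  short <- sum(subj$n_days < 16)
  if (short > 0) {
    warning(short, " subject(s) have fewer than 16 recorded days; ",
            "averaging over available days", call. = FALSE)
  }
  kf <- config$energy_per_gram_fat
  subj |>
    mutate(fat_pct_energy = 100 * .data$fat_g_day * kf / .data$energy_kcal_day,
           tfa_pct_energy = 100 * .data$tfa_g_day * kf / .data$energy_kcal_day,
           tfa_pct_fat = ifelse(.data$fat_g_day > 0,
                                100 * .data$tfa_g_day / .data$fat_g_day, 0))
}

#' Cohort intake estimation
#'
#' Runs [subject_mean_intake()] for all subjects and joins subject
#' descriptors (sex, age, area, BMI).
#'
#' @param records Diet records for the whole cohort.
#' @param subjects Subject table (`subject_id`, `sex`, `age_years`, `area`,
#'   `height_cm`, `weight_kg`).
#' @inheritParams subject_mean_intake
#'
#' @return Intake tibble with one row per subject, including `sex`,
#'   `age_years`, `age_group`, `area`, and `bmi_kg_m2`.
#' @export
estimate_intakes <- function(records, subjects, foods, assignments,
                             recipes = NULL, config = intake_config()) {
  intakes <- subject_mean_intake(records, foods, assignments, recipes, config)
  subj <- subjects |>
    mutate(age_group = age_decade(.data$age_years),
           bmi_kg_m2 = bmi(.data$weight_kg, .data$height_cm)) |>
    select(dplyr::any_of(c("subject_id", "sex", "age_years", "age_group",
                           "area", "area_type", "bmi_kg_m2")))
  inner_join(intakes, subj, by = "subject_id")
}

# 10-year age strata used throughout the stratified summaries.
age_decade <- function(age_years) {
  cut(age_years, breaks = c(30, 40, 50, 60, 70), right = FALSE,
      labels = c("30-39", "40-49", "50-59", "60-69"))
}

#' Body mass index
#'
#' @param weight_kg Body weight in kilograms.
#' @param height_cm Body height in centimetres.
#'
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(53.4, 154.6)
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' Exclude intake outliers within sex
#'
#' A subject is excluded when either the g/day or the %-of-energy TFA intake
#' falls outside the sex-group mean plus/minus `k` standard deviations. A
#' single pass: mean and SD come from the full group. Groups with zero or
#' undefined SD keep all subjects.
#'
#' @param intakes Intake table from [estimate_intakes()] (needs `sex`,
#'   `tfa_g_day`, `tfa_pct_energy`).
#' @param k SD multiplier; default 3.
#'
#' @return List with `kept` and `excluded` intake tibbles.
#' @export
exclude_outliers <- function(intakes, k = 3) {
  flagged <- intakes |>
    group_by(.data$sex) |>
    mutate(.out = flag_outside(.data$tfa_g_day, k) |
             flag_outside(.data$tfa_pct_energy, k)) |>
    ungroup()
  list(kept = flagged |> filter(!.data$.out) |> select(-".out"),
       excluded = flagged |> filter(.data$.out) |> select(-".out"))
}

flag_outside <- function(x, k) {
  if (length(x) < 2) return(rep(FALSE, length(x)))
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  m <- mean(x)
  x < m - k * s | x > m + k * s
}
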