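# CSV schemas, input validation, and the one-call pipeline. All tables are
# plain UTF-8 comma-separated files with a header row and "." decimals.

table_schemas <- function() {
  list(
    foods = c("food_id", "name", "group", "origin", "category", "species",
              "part", "energy_kcal_100g", "fat_g_100g", "protein_g_100g",
              "carb_g_100g", "contains_hydrogenated_oil",
              "contains_ruminant"),
    references = c("article_id", "food_id", "n_samples", "mean_value",
                   "min_value", "max_value", "basis", "ref_fat_g_100g"),
    foreign = c("food_id", "foreign_tfa_g_100g", "foreign_energy_kcal_100g",
                "foreign_fat_g_100g", "foreign_protein_g_100g",
                "foreign_carb_g_100g", "same_manufacturer"),
    recipes = c("food_id", "ingredient_id", "grams_per_100g"),
    records = c("subject_id", "day_index", "season", "food_id", "grams",
                "venue"),
    subjects = c("subject_id", "sex", "age_years", "area", "height_cm",
                 "weight_kg"))
}

#' Read / write the pipeline's CSV tables
#'
#' Thin readr wrappers pinned to the documented schemas.
#'
#' @param path File path.
#' @param table Table to write.
#' @name tfa_io
NULL

read_pinned <- function(path, classes) {
  as_tibble(utils::read.csv(path, colClasses = classes,
                            stringsAsFactors = FALSE))
}

#' @rdname tfa_io
#' @export
read_foods <- function(path) {
  read_pinned(path, c(food_id = "character", name = "character",
                      group = "character", origin = "character",
                      category = "character", species = "character",
                      part = "character", energy_kcal_100g = "numeric",
                      fat_g_100g = "numeric", protein_g_100g = "numeric",
                      carb_g_100g = "numeric",
                      contains_hydrogenated_oil = "logical",
                      contains_ruminant = "logical"))
}

#' @rdname tfa_io
#' @export
read_references <- function(path) {
  read_pinned(path, c(article_id = "character", food_id = "character",
                      n_samples = "integer", mean_value = "numeric",
                      min_value = "numeric", max_value = "numeric",
                      basis = "character", ref_fat_g_100g = "numeric"))
}

#' @rdname tfa_io
#' @export
read_diet_records <- function(path) {
  read_pinned(path, c(subject_id = "character", day_index = "integer",
                      season = "character", food_id = "character",
                      grams = "numeric", venue = "character"))
}

#' @rdname tfa_io
#' @export
write_table_csv <- function(table, path) {
  # 17 significant digits reproduce IEEE doubles exactly, so
  # write -> read -> write is byte-identical
  fmt <- function(x) {
    if (is.double(x)) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    else x
  }
  out <- as.data.frame(lapply(table, fmt), check.names = FALSE,
                       stringsAsFactors = FALSE)
  readr::write_csv(out, path)
  invisible(path)
}

violation <- function(table, row, column, problem) {
  tibble(table = table, row = as.integer(row), column = column,
         problem = problem)
}

#' Validate pipeline input tables
#'
#' Schema check (required columns), enum checks, numeric-range checks, and
#' foreign-key resolution (references/foreign/recipes/records against the
#' food table). Every violation is reported with its table, row number and
#' column; an empty result means the inputs are clean.
#'
#' @param foods Food table (required).
#' @param references,foreign,recipes,records,subjects Optional tables.
#'
#' @return Tibble of violations (zero rows when valid).
#' @export
validate_inputs <- function(foods, references = NULL, foreign = NULL,
                            recipes = NULL, records = NULL, subjects = NULL) {
  v <- list()
  add <- function(x) if (!is.null(x) && nrow(x)) v[[length(v) + 1L]] <<- x
  need_cols <- function(tab, name) {
    missing <- setdiff(table_schemas()[[name]], names(tab))
    if (length(missing)) {
      add(violation(name, NA, missing, "required column missing"))
      return(FALSE)
    }
    TRUE
  }
  check_fk <- function(tab, name, col, universe) {
    bad <- which(!tab[[col]] %in% universe)
    if (length(bad)) {
      add(violation(name, bad, col, paste0("unresolved id: ", tab[[col]][bad])))
    }
  }
  check_range <- function(tab, name, col, lo, hi, allow_na = FALSE) {
    x <- tab[[col]]
    bad <- which((!allow_na & is.na(x)) |
                   (!is.na(x) & (x < lo | x > hi)))
    if (length(bad)) {
      add(violation(name, bad, col,
                    sprintf("value outside [%g, %g]", lo, hi)))
    }
  }
  check_enum <- function(tab, name, col, levels) {
    bad <- which(!tab[[col]] %in% levels)
    if (length(bad)) {
      add(violation(name, bad, col,
                    paste0("invalid value: ", tab[[col]][bad])))
    }
  }

  if (need_cols(foods, "foods")) {
    check_range(foods, "foods", "energy_kcal_100g", 0, Inf)
    for (col in c("fat_g_100g", "protein_g_100g", "carb_g_100g")) {
      check_range(foods, "foods", col, 0, 100)
    }
    dup <- which(duplicated(foods$food_id))
    if (length(dup)) add(violation("foods", dup, "food_id", "duplicated id"))
    blank <- which(is.na(foods$group) | !nzchar(foods$group))
    if (length(blank)) add(violation("foods", blank, "group", "empty group"))
  }
  ids <- foods$food_id

  if (!is.null(references) && need_cols(references, "references")) {
    check_fk(references, "references", "food_id", ids)
    check_enum(references, "references", "basis",
               c("percent_of_fat", "g_per_100g_food"))
    bad <- which(!is.na(references$n_samples) & references$n_samples < 1)
    if (length(bad)) {
      add(violation("references", bad, "n_samples", "must be >= 1 when known"))
    }
    bad <- which(!is.na(references$min_value) & !is.na(references$max_value) &
                   (references$min_value > references$mean_value |
                      references$mean_value > references$max_value))
    if (length(bad)) {
      add(violation("references", bad, "mean_value",
                    "mean outside [min, max]"))
    }
  }
  if (!is.null(foreign) && need_cols(foreign, "foreign")) {
    check_fk(foreign, "foreign", "food_id", ids)
    for (col in grep("^foreign_", table_schemas()$foreign, value = TRUE)) {
      check_range(foreign, "foreign", col, 0, Inf)
    }
  }
  if (!is.null(recipes) && need_cols(recipes, "recipes")) {
    check_fk(recipes, "recipes", "food_id", ids)
    check_fk(recipes, "recipes", "ingredient_id", ids)
    check_range(recipes, "recipes", "grams_per_100g", 1e-9, Inf)
  }
  if (!is.null(records) && need_cols(records, "records")) {
    check_fk(records, "records", "food_id", ids)
    check_enum(records, "records", "venue",
               c("home", "commercial", "restaurant"))
    check_enum(records, "records", "season",
               c("autumn", "winter", "spring", "summer"))
    check_range(records, "records", "grams", 1e-9, Inf)
    check_range(records, "records", "day_index", 1, 16)
    if (!is.null(subjects)) {
      check_fk(records, "records", "subject_id", subjects$subject_id)
    }
  }
  if (!is.null(subjects) && need_cols(subjects, "subjects")) {
    check_enum(subjects, "subjects", "sex",
               c("women", "men", "female", "male"))
    check_range(subjects, "subjects", "age_years", 30, 69)
    check_range(subjects, "subjects", "height_cm", 1e-9, Inf)
    check_range(subjects, "subjects", "weight_kg", 1e-9, Inf)
  }
  if (!length(v)) {
    return(tibble(table = character(), row = integer(), column = character(),
                  problem = character()))
  }
  bind_rows(v)
}

#' Run the full pipeline on a simulated study
#'
#' simulate -> validate -> build the composition database -> estimate
#' intakes -> exclude outliers -> stratified summaries, writing every input
#' and report as CSV under `out_dir`. Deterministic given `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the simulation.
#' @param sim A [sim_config()].
#' @param db A [db_config()].
#' @param intake An [intake_config()].
#' @param summaries A [summary_config()].
#' @param quiet Suppress per-stage messages.
#'
#' @return (Invisibly) a list with all intermediate tables and reports.
#' @export
run_pipeline <- function(out_dir, seed = 1, sim = sim_config(),
                         db = db_config(), intake = intake_config(),
                         summaries = summary_config(), quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  study <- simulate_study(sim, seed = seed)
  say("simulated ", nrow(study$foods), " foods, ", nrow(study$subjects),
      " subjects, ", nrow(study$records), " record rows")
  viol <- validate_inputs(study$foods, study$references, study$foreign,
                          study$recipes, study$records, study$subjects)
  if (nrow(viol)) {
    stop("input validation failed with ", nrow(viol), " violation(s)",
         call. = FALSE)
  }

  built <- build_database(study$foods, study$references, study$foreign,
                          study$recipes, db)
  say("assigned TFA values to ", nrow(built$assignments), " foods")

  intakes <- estimate_intakes(study$records, study$subjects, study$foods,
                              built$assignments, study$recipes, intake)
  split_int <- exclude_outliers(intakes, intake$outlier_k)
  kept <- split_int$kept
  say("intakes for ", nrow(intakes), " subjects; excluded ",
      nrow(split_int$excluded), " outlier(s)")

  gi <- intake_by_group(study$records, study$foods, built$assignments,
                        study$recipes, intake)
  gi <- gi[gi$subject_id %in% kept$subject_id & gi$group != "no-TFA", ,
           drop = FALSE]
  contrib <- lapply(split(kept$subject_id, kept$sex), function(idset) {
    contribution_by_group(gi[gi$subject_id %in% idset, , drop = FALSE],
                          groups = tfa_food_groups())
  })

  reports <- list(
    characteristics = stratum_summary(kept),
    by_area = stratum_summary(kept, by = "area_type"),
    by_age = stratum_summary(kept, by = "age_group"),
    tests = compare_strata(kept),
    contribution = bind_rows(contrib, .id = "sex"),
    frequency = frequency_above(kept,
                                threshold = summaries$who_threshold_pct_energy,
                                by = c("sex", "area_type", "age_group")),
    distribution_gday = distribution_table(kept, summaries$gday_bin_edges,
                                           value = "tfa_g_day",
                                           by = c("sex", "area_type")),
    distribution_pcte = distribution_table(kept,
                                           summaries$pct_energy_bin_edges,
                                           value = "tfa_pct_energy",
                                           by = c("sex", "area_type")))

  out <- c(study["foods"], study["references"], study["recipes"],
           study["subjects"], study["records"],
           list(assignments = built$assignments,
                provenance = built$provenance,
                intakes = intakes, excluded = split_int$excluded,
                kept = kept),
           reports["characteristics"], reports["by_area"],
           reports["by_age"], reports["contribution"],
           reports["frequency"], reports["distribution_gday"],
           reports["distribution_pcte"],
           list(t_tests = reports$tests$t_tests,
                anova = reports$tests$anova,
                tukey = reports$tests$tukey))
  for (nm in names(out)) {
    write_table_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  say("wrote ", length(out), " CSV files to ", out_dir)
  invisible(c(out, list(truth_intake = study$truth_intake)))
}
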