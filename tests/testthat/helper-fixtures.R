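# Fixture builders shared across the test files. Everything is constructed
# in code; no data files.

make_foods <- function(food_id, group = "Confectionaries (I)",
                       category = NA_character_, species = NA_character_,
                       part = NA_character_, energy = 400, fat = 20,
                       protein = 6, carb = 50, hydro = TRUE, rumin = FALSE) {
  n <- length(food_id)
  tibble::tibble(
    food_id = food_id, name = paste0("food ", food_id),
    group = rep_len(group, n),
    origin = tfaintake:::group_origin(rep_len(group, n)),
    category = rep_len(category, n), species = rep_len(species, n),
    part = rep_len(part, n),
    energy_kcal_100g = rep_len(energy, n), fat_g_100g = rep_len(fat, n),
    protein_g_100g = rep_len(protein, n), carb_g_100g = rep_len(carb, n),
    contains_hydrogenated_oil = rep_len(hydro, n),
    contains_ruminant = rep_len(rumin, n))
}

make_ref <- function(food_id, mean_value, n_samples = 1L,
                     basis = "percent_of_fat", ref_fat = NA_real_,
                     article_id = NULL) {
  k <- max(length(food_id), length(mean_value), length(n_samples))
  tibble::tibble(
    article_id = article_id %||% sprintf("a%02d", seq_len(k)),
    food_id = rep_len(food_id, k),
    n_samples = as.integer(rep_len(n_samples, k)),
    mean_value = rep_len(mean_value, k),
    min_value = NA_real_, max_value = NA_real_,
    basis = rep_len(basis, k), ref_fat_g_100g = rep_len(ref_fat, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A meat fixture with one Step-1 donor and recipients engineered to land at
# every level of the meat cascade (plus one that falls through entirely).
# Hand enumeration of the rule order:
#   A: same species + part as the donor            -> S2_2A
#   B: same species, adjacent part, similar comp   -> S2_2B
#   C: adjacent species, similar composition       -> S2_2C
#   D: unrelated species, similar composition      -> S2_2D
#   E: same species, unrelated part, similar comp  -> S2_2E
#   F: same species, unrelated part, far comp      -> unresolved
meat_cascade_fixture <- function() {
  grp <- "Meat and meat products (N)"
  foods <- dplyr::bind_rows(
    make_foods("D1", grp, species = "cattle", part = "loin",
               energy = 250, fat = 15, protein = 20, carb = 1, hydro = FALSE,
               rumin = TRUE),
    make_foods("A", grp, species = "cattle", part = "loin",
               energy = 400, fat = 30, protein = 15, carb = 1, hydro = FALSE,
               rumin = TRUE),
    make_foods("B", grp, species = "cattle", part = "rib",
               energy = 260, fat = 16, protein = 20, carb = 1, hydro = FALSE,
               rumin = TRUE),
    make_foods("C", grp, species = "buffalo", part = "loin",
               energy = 255, fat = 15, protein = 21, carb = 1, hydro = FALSE,
               rumin = TRUE),
    make_foods("D", grp, species = "horse", part = "fillet",
               energy = 245, fat = 14, protein = 20, carb = 1, hydro = FALSE,
               rumin = TRUE),
    make_foods("E", grp, species = "cattle", part = "shank",
               energy = 265, fat = 16, protein = 19, carb = 1, hydro = FALSE,
               rumin = TRUE))
  config <- db_config(part_adjacency = list(c("rib", "loin")),
                      species_adjacency = list(c("buffalo", "cattle")))
  refs <- make_ref("D1", mean_value = 4, n_samples = 3L)
  list(foods = foods, refs = refs, config = config,
       expected = c(A = "S2_2A", B = "S2_2B", C = "S2_2C", D = "S2_2D",
                    E = "S2_2E"))
}

# Noise-free simulation config kept small for fast exact-closure checks.
closure_sim_config <- function(...) {
  des <- default_cohort_design()
  des <- des[des$area %in% c("Osaka", "Matsumoto"), , drop = FALSE]
  sim_config(n_foods_per_group = 4, n_zero_foods = 30,
             literature_noise_sd = 0, unknown_n_fraction = 0,
             design = des, ...)
}
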