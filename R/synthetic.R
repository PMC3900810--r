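# Stochastic generator for a full synthetic study: food table with known
# true TFA contents, a literature corpus, recipes for composed dishes, and a
# stratified 16-day diet-record cohort calibrated to prescribed stratum
# means. Everything downstream of the generated tables is testable against
# the generator's ground truth.

#' Default cohort design
#'
#' Cell sizes per sex x area x 10-year age group for the synthetic cohort,
#' mirroring a four-area Japanese study population (119 women, 106 men;
#' urban 57/51, rural 62/55).
#'
#' @return Tibble: `sex`, `area`, `age_group`, `n`.
#' @export
default_cohort_design <- function() {
  decades <- c("30-39", "40-49", "50-59", "60-69")
  bind_rows(
    tibble(sex = "women", area = "Osaka", age_group = decades,
           n = c(7, 7, 8, 7)),
    tibble(sex = "women", area = "Ginowan", age_group = decades,
           n = c(6, 7, 8, 7)),
    tibble(sex = "women", area = "Matsumoto", age_group = decades,
           n = c(7, 8, 8, 9)),
    tibble(sex = "women", area = "Kurayoshi", age_group = decades,
           n = c(7, 7, 8, 8)),
    tibble(sex = "men", area = "Osaka", age_group = decades,
           n = c(5, 7, 7, 7)),
    tibble(sex = "men", area = "Ginowan", age_group = decades,
           n = c(5, 7, 6, 7)),
    tibble(sex = "men", area = "Matsumoto", age_group = decades,
           n = c(5, 8, 8, 8)),
    tibble(sex = "men", area = "Kurayoshi", age_group = decades,
           n = c(5, 7, 7, 7)))
}

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the published study conditions: a 119-woman / 106-man
#' cohort in four areas (two urban, two rural), 16 recording days (four per
#' season), stratum targets of 1847 kcal/day and 1.7 g/day TFA for women
#' (2372 kcal/day, 1.7 g/day for men), and mild urban-over-rural and
#' younger-over-older TFA gradients.
#'
#' @param n_foods_per_group TFA-containing foods generated per food group.
#' @param n_zero_foods Zero-rule (TFA-free) foods.
#' @param tfa_sdlog Log-scale SD of the per-group lognormal true TFA
#'   content (% of fat).
#' @param articles_lambda,samples_lambda Poisson means: extra articles per
#'   covered food (articles = 1 + Poisson) and extra samples per article
#'   (samples = 1 + Poisson).
#' @param literature_noise_sd Additive SD (percentage points of fat) of the
#'   article-level measurement noise around the true content.
#' @param unknown_n_fraction Fraction of articles that omit their sample
#'   count.
#' @param g_basis_fraction Fraction of articles reporting g/100 g of food
#'   (with their own fat content) instead of % of fat.
#' @param design Cohort design tibble; see [default_cohort_design()].
#' @param area_density Named persons/km^2 vector for the design's areas.
#' @param targets Per-sex list: `energy_mean`, `energy_sd` (kcal/day,
#'   between subjects), `tfa_mean`, `tfa_sd` (g/day, between subjects).
#' @param energy_day_sd,tfa_day_sd Within-subject day-to-day SDs.
#' @param urban_multiplier,age_multipliers Multiplicative TFA gradients over
#'   area type and 10-year age group; they are renormalised so the
#'   design-weighted mean multiplier is 1 per sex (the stratum targets stay
#'   the cohort targets).
#' @param foods_per_day_lambda,fillers_per_day_lambda Poisson means for the
#'   number of TFA-containing foods (1 + Poisson) and TFA-free fillers
#'   (2 + Poisson) per subject-day.
#' @param amount_sdlog Log-scale SD of raw consumed amounts before scaling.
#' @param venue_probs Probabilities of home/commercial/restaurant venues for
#'   TFA-food entries.
#' @param composed_fraction Fraction of TFA foods that are composed dishes
#'   with a recipe.
#'
#' @return List of class `tfa_sim_config`.
#' @export
sim_config <- function(n_foods_per_group = 8,
                       n_zero_foods = 80,
                       tfa_sdlog = 0.35,
                       articles_lambda = 0.8,
                       samples_lambda = 3,
                       literature_noise_sd = 0.2,
                       unknown_n_fraction = 0.05,
                       g_basis_fraction = 0.2,
                       design = default_cohort_design(),
                       area_density = c(Osaka = 11743, Ginowan = 4446,
                                        Matsumoto = 786, Kurayoshi = 285),
                       targets = list(
                         women = list(energy_mean = 1847, energy_sd = 280,
                                      tfa_mean = 1.7, tfa_sd = 0.6),
                         men = list(energy_mean = 2372, energy_sd = 375,
                                    tfa_mean = 1.7, tfa_sd = 0.55)),
                       energy_day_sd = 250,
                       tfa_day_sd = 0.6,
                       urban_multiplier = c(urban = 1.12, rural = 0.89),
                       age_multipliers = c("30-39" = 1.25, "40-49" = 1.1,
                                           "50-59" = 0.95, "60-69" = 0.72),
                       foods_per_day_lambda = 3,
                       fillers_per_day_lambda = 4,
                       amount_sdlog = 0.4,
                       venue_probs = c(home = 0.80, commercial = 0.15,
                                       restaurant = 0.05),
                       composed_fraction = 0.1) {
  structure(as.list(environment()), class = "tfa_sim_config")
}

# Macro templates per group: fat, protein, carb ranges (g/100 g) and the
# lognormal meanlog of the true TFA content as % of fat.
group_templates <- function() {
  tibble::tribble(
    ~group, ~fat_lo, ~fat_hi, ~prot_lo, ~prot_hi, ~carb_lo, ~carb_hi, ~tfa_meanlog,
    "Confectionaries (I)",          12, 28, 4,  8,  45, 65, log(4.2),
    "Bakery (I)",                    8, 18, 7, 10,  45, 60, log(4.2),
    "Fats and oils (N)",            75, 83, 0.5, 1, 0.1, 1, log(2.5),
    "Fats and oils (I)",            75, 95, 0.1, 1, 0.1, 1, log(5.9),
    "Instant and retort foods (I)", 15, 25, 8, 12,  50, 62, log(2.1),
    "Milk and dairy products (N)",   3, 30, 3, 25,   3,  8, log(2.5),
    "Milk and dairy products (I)",  10, 30, 3, 10,   5, 15, log(3.4),
    "Meat and meat products (N)",    5, 35, 14, 22,  0,  1, log(2.1),
    "Margarine (I)",                78, 84, 0.1, 1, 0.1, 1, log(8.4),
    "Fast foods (I)",               10, 25, 8, 16,  25, 40, log(3.8),
    "Miscellaneous (I)",             8, 25, 4, 10,  30, 55, log(2.9))
}

#' Generate a synthetic food table with known true TFA contents
#'
#' Emits foods in the eleven TFA-carrying groups plus a block of zero-rule
#' foods (`"no-TFA"` group). Macronutrients are internally consistent
#' (energy within 5% of 9*fat + 4*protein + 4*carbohydrate); true TFA
#' content (% of fat) is lognormal per group.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (the caller may also set the RNG state).
#'
#' @return List: `foods` (with `is_composed` and `is_added` flags all
#'   `FALSE`/partially `TRUE`; see Details) and `truth`
#'   (`food_id`, `tfa_pct_fat_true`, `tfa_g_100g_true`).
#' @export
generate_food_table <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tpl <- group_templates()
  out <- list()
  for (gi in seq_len(nrow(tpl))) {
    g <- tpl[gi, ]
    n <- config$n_foods_per_group
    fat <- runif(n, g$fat_lo, g$fat_hi)
    prot <- runif(n, g$prot_lo, g$prot_hi)
    carb <- runif(n, g$carb_lo, g$carb_hi)
    energy <- (9 * fat + 4 * prot + 4 * carb) * runif(n, 0.97, 1.03)
    pct <- rlnorm(n, g$tfa_meanlog, config$tfa_sdlog)
    is_meat <- grepl("^Meat", g$group)
    out[[gi]] <- tibble(
      food_id = sprintf("T%02d%03d", gi, seq_len(n)),
      name = sprintf("%s item %d", g$group, seq_len(n)),
      group = g$group, origin = group_origin(g$group),
      category = sprintf("g%02d_cat%d", gi, (seq_len(n) - 1) %% 3 + 1),
      species = if (is_meat) sample(c("cattle", "swine", "chicken"), n,
                                    replace = TRUE) else NA_character_,
      part = if (is_meat) sprintf("part%02d", sample(6, n, replace = TRUE))
             else NA_character_,
      energy_kcal_100g = energy, fat_g_100g = fat, protein_g_100g = prot,
      carb_g_100g = carb,
      contains_hydrogenated_oil = group_origin(g$group) == "industrial",
      contains_ruminant = group_origin(g$group) == "natural",
      tfa_pct_fat_true = pct)
  }
  tfa_foods <- bind_rows(out)

  nz <- config$n_zero_foods
  staple <- runif(nz) < 0.6
  zfat <- ifelse(staple, runif(nz, 0, 1), runif(nz, 1, 5))
  zprot <- runif(nz, 2, 8)
  zcarb <- ifelse(staple, runif(nz, 20, 35), runif(nz, 5, 20))
  zero <- tibble(
    food_id = sprintf("Z%03d", seq_len(nz)),
    name = sprintf("staple item %d", seq_len(nz)),
    group = "no-TFA", origin = "none", category = NA_character_,
    species = NA_character_, part = NA_character_,
    energy_kcal_100g = (9 * zfat + 4 * zprot + 4 * zcarb) *
      runif(nz, 0.97, 1.03),
    fat_g_100g = zfat, protein_g_100g = zprot, carb_g_100g = zcarb,
    contains_hydrogenated_oil = FALSE, contains_ruminant = FALSE,
    tfa_pct_fat_true = 0)

  foods <- bind_rows(tfa_foods, zero)
  foods$is_composed <- FALSE
  foods$is_added <- FALSE
  # A handful of market additions (fast foods, baked goods, confectionaries)
  # absent from the base national table.
  for (spec in list(c("Fast foods (I)", 3), c("Bakery (I)", 2),
                    c("Confectionaries (I)", 2))) {
    ids <- head(foods$food_id[foods$group == spec[[1]]], as.integer(spec[[2]]))
    foods$is_added[foods$food_id %in% ids] <- TRUE
  }
  truth <- tibble(food_id = foods$food_id,
                  tfa_pct_fat_true = foods$tfa_pct_fat_true,
                  tfa_g_100g_true = foods$tfa_pct_fat_true *
                    foods$fat_g_100g / 100)
  foods$tfa_pct_fat_true <- NULL
  list(foods = foods, truth = truth)
}

#' Generate recipes for composed dishes
#'
#' Marks a fraction of TFA foods as composed restaurant-style dishes and
#' gives each a two-ingredient recipe (a TFA-free staple plus a plain TFA
#' food of the same group). The composed dish's macronutrients and true TFA
#' content are redefined as the gram-weighted sums of its ingredients, so
#' recipe decomposition and direct valuation agree exactly.
#'
#' @param foods,truth From [generate_food_table()].
#' @param config A [sim_config()].
#' @param seed Optional seed.
#'
#' @return List: updated `foods` and `truth`, plus `recipes`.
#' @export
generate_recipes <- function(foods, truth, config = sim_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tfa_ids <- foods$food_id[foods$group != "no-TFA"]
  n_comp <- floor(length(tfa_ids) * config$composed_fraction)
  if (n_comp == 0) {
    return(list(foods = foods, truth = truth,
                recipes = tibble(food_id = character(),
                                 ingredient_id = character(),
                                 grams_per_100g = numeric())))
  }
  comp_ids <- sample(tfa_ids, n_comp)
  zero_ids <- foods$food_id[foods$group == "no-TFA"]
  rec <- list()
  for (id in comp_ids) {
    grp <- foods$group[foods$food_id == id]
    pool <- setdiff(foods$food_id[foods$group == grp], comp_ids)
    if (!length(pool)) pool <- setdiff(tfa_ids, comp_ids)
    ing_tfa <- sample(pool, 1)
    ing_zero <- sample(zero_ids, 1)
    rec[[length(rec) + 1L]] <- tibble(
      food_id = id, ingredient_id = c(ing_zero, ing_tfa),
      grams_per_100g = c(60, 40))
    # redefine the dish as the mixture of its ingredients
    zi <- match(ing_zero, foods$food_id); ti <- match(ing_tfa, foods$food_id)
    ci <- match(id, foods$food_id)
    for (col in nutrient_cols()) {
      foods[[col]][ci] <- 0.6 * foods[[col]][zi] + 0.4 * foods[[col]][ti]
    }
    foods$is_composed[ci] <- TRUE
    tt <- match(ing_tfa, truth$food_id)
    truth$tfa_g_100g_true[match(id, truth$food_id)] <-
      0.4 * truth$tfa_g_100g_true[tt]
  }
  truth$tfa_pct_fat_true <- ifelse(
    foods$fat_g_100g[match(truth$food_id, foods$food_id)] > 0,
    100 * truth$tfa_g_100g_true /
      foods$fat_g_100g[match(truth$food_id, foods$food_id)], 0)
  list(foods = foods, truth = truth, recipes = bind_rows(rec))
}

#' Generate a literature corpus around the true TFA contents
#'
#' Every TFA-containing food receives one or more articles whose mean is the
#' true content (% of fat) plus additive measurement noise; multi-sample
#' articles also report bracketing minima and maxima; a configurable
#' fraction of articles omit their sample count (never all articles of a
#' multi-article food).
#'
#' @param foods,truth From the generators above.
#' @param config A [sim_config()].
#' @param seed Optional seed.
#'
#' @return Reference-record tibble.
#' @export
generate_literature <- function(foods, truth, config = sim_config(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  covered <- truth$food_id[truth$tfa_g_100g_true > 0]
  refs <- list()
  for (id in covered) {
    pct_true <- truth$tfa_pct_fat_true[truth$food_id == id]
    fat <- foods$fat_g_100g[foods$food_id == id]
    k <- 1 + rpois(1, config$articles_lambda)
    n <- 1 + rpois(k, config$samples_lambda)
    unknown <- runif(k) < config$unknown_n_fraction
    if (k > 1 && all(unknown)) unknown[1] <- FALSE
    pct_obs <- pmax(0, pct_true + rnorm(k, 0, config$literature_noise_sd))
    spread <- abs(rnorm(k, 0, config$literature_noise_sd))
    g_basis <- runif(k) < config$g_basis_fraction
    ref_fat <- fat * runif(k, 0.9, 1.1)
    refs[[length(refs) + 1L]] <- tibble(
      article_id = sprintf("art_%s_%d", id, seq_len(k)),
      food_id = id,
      n_samples = ifelse(unknown, NA_integer_, n),
      mean_value = ifelse(g_basis, pct_obs / 100 * ref_fat, pct_obs),
      min_value = ifelse(n > 1, pmax(0, ifelse(g_basis,
                                               (pct_obs - spread) / 100 * ref_fat,
                                               pct_obs - spread)), NA_real_),
      max_value = ifelse(n > 1, ifelse(g_basis,
                                       (pct_obs + spread) / 100 * ref_fat,
                                       pct_obs + spread), NA_real_),
      basis = ifelse(g_basis, "g_per_100g_food", "percent_of_fat"),
      ref_fat_g_100g = ifelse(g_basis, ref_fat, NA_real_))
  }
  bind_rows(refs)
}

#' Generate a stratified 16-day diet-record cohort
#'
#' Each subject records 4 days in each of 4 seasons. Per day, the generator
#' draws a handful of TFA-containing foods (subject-specific Dirichlet
#' weights over food groups) whose amounts are scaled to hit the day's
#' target TFA intake, then TFA-free fillers scaled to top energy up to the
#' day's target. Stratum TFA targets carry multiplicative urban/rural and
#' age-gradient factors, renormalised so each sex's cohort mean target
#' equals the configured target. Per-subject ground-truth intakes are
#' recomputed exactly from the emitted records.
#'
#' @param foods,truth,recipes From the generators above.
#' @param config A [sim_config()].
#' @param seed Optional seed.
#'
#' @return List: `subjects`, `records`, `truth_intake` (per-subject true
#'   mean daily energy, fat, TFA).
#' @export
generate_cohort <- function(foods, truth, recipes = NULL,
                            config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design <- config$design[config$design$n > 0, , drop = FALSE]
  area_type <- classify_area(config$area_density)
  seasons <- c("autumn", "winter", "spring", "summer")

  subj <- design[rep(seq_len(nrow(design)), design$n), , drop = FALSE]
  subj$subject_id <- sprintf("%s%03d", ifelse(subj$sex == "women", "W", "M"),
                             stats::ave(seq_len(nrow(subj)), subj$sex,
                                        FUN = seq_along))
  lo_age <- as.integer(substr(subj$age_group, 1, 2))
  subj$age_years <- lo_age + sample(0:9, nrow(subj), replace = TRUE)
  subj$height_cm <- ifelse(subj$sex == "women",
                           rnorm(nrow(subj), 154.6, 6.2),
                           rnorm(nrow(subj), 168.0, 6.4))
  subj$weight_kg <- ifelse(subj$sex == "women",
                           rnorm(nrow(subj), 53.4, 7.1),
                           rnorm(nrow(subj), 67.1, 10.2))
  subj$area_type <- area_type[subj$area]

  # design-weighted renormalisation of the TFA gradient per sex
  mult_raw <- config$urban_multiplier[subj$area_type] *
    config$age_multipliers[subj$age_group]
  subj$tfa_mult <- mult_raw
  for (sx in unique(subj$sex)) {
    sel <- subj$sex == sx
    subj$tfa_mult[sel] <- mult_raw[sel] / mean(mult_raw[sel])
  }

  tfa_pool <- which(foods$group != "no-TFA" &
                      truth$tfa_g_100g_true[match(foods$food_id,
                                                  truth$food_id)] > 0.3)
  zero_pool <- which(foods$group == "no-TFA")
  tdens <- truth$tfa_g_100g_true[match(foods$food_id, truth$food_id)] / 100
  edens <- foods$energy_kcal_100g / 100
  fdens <- foods$fat_g_100g / 100
  groups <- unique(foods$group[tfa_pool])

  recs <- vector("list", nrow(subj))
  for (i in seq_len(nrow(subj))) {
    s <- subj[i, ]
    tg <- config$targets[[s$sex]]
    E_s <- min(max(rnorm(1, tg$energy_mean, tg$energy_sd), 1200), 3400)
    tau_s <- min(max(rnorm(1, tg$tfa_mean * s$tfa_mult, tg$tfa_sd), 0.3), 4.5)
    w_g <- setNames(stats::rgamma(length(groups), shape = 2), groups)
    p_food <- w_g[foods$group[tfa_pool]]
    p_food <- p_food / sum(p_food)

    day_list <- vector("list", 16)
    for (d in 1:16) {
      tau_d <- max(tau_s + rnorm(1, 0, config$tfa_day_sd), 0.05)
      E_d <- max(E_s + rnorm(1, 0, config$energy_day_sd), 900)
      k <- 1 + rpois(1, config$foods_per_day_lambda)
      idx <- sample(tfa_pool, k, replace = TRUE, prob = p_food)
      a <- rlnorm(k, log(60), config$amount_sdlog)
      grams <- a * tau_d / sum(a * tdens[idx])
      venue <- sample(names(config$venue_probs), k, replace = TRUE,
                      prob = config$venue_probs)
      filler_E <- E_d - sum(grams * edens[idx])
      if (filler_E > 1) {
        m <- 2 + rpois(1, config$fillers_per_day_lambda)
        fidx <- sample(zero_pool, m, replace = TRUE)
        b <- rlnorm(m, log(80), config$amount_sdlog)
        fgrams <- b * filler_E / sum(b * edens[fidx])
        idx <- c(idx, fidx)
        grams <- c(grams, fgrams)
        venue <- c(venue, rep("home", m))
      }
      day_list[[d]] <- tibble(
        subject_id = s$subject_id, day_index = d,
        season = seasons[ceiling(d / 4)],
        food_id = foods$food_id[idx], grams = grams, venue = venue)
    }
    recs[[i]] <- bind_rows(day_list)
  }
  records <- bind_rows(recs)

  truth_intake <- ground_truth_intake(records, foods, truth, recipes)
  subjects <- subj[, c("subject_id", "sex", "age_years", "area", "area_type",
                       "height_cm", "weight_kg")]
  list(subjects = as_tibble(subjects), records = records,
       truth_intake = truth_intake)
}

#' Ground-truth intake implied by generated records
#'
#' Aggregates the emitted records against the generator's true per-food
#' contents (decomposing restaurant composed dishes through their recipes),
#' independently of the estimation pipeline.
#'
#' @param records,foods,recipes As emitted by [generate_cohort()].
#' @param truth True content table.
#'
#' @return Tibble: `subject_id`, `energy_kcal_day`, `fat_g_day`,
#'   `tfa_g_day` (true mean daily values).
#' @export
ground_truth_intake <- function(records, foods, truth, recipes = NULL) {
  r <- as_tibble(records)
  if (!is.null(recipes) && nrow(recipes)) {
    is_rest <- r$venue == "restaurant" & r$food_id %in% recipes$food_id
    plain <- r[!is_rest, , drop = FALSE]
    exp <- merge(r[is_rest, , drop = FALSE], recipes, by = "food_id")
    exp$grams <- exp$grams * exp$grams_per_100g / 100
    exp$food_id <- exp$ingredient_id
    r <- bind_rows(plain, exp[, names(plain)])
  }
  fi <- match(r$food_id, foods$food_id)
  ti <- match(r$food_id, truth$food_id)
  r$energy <- r$grams * foods$energy_kcal_100g[fi] / 100
  r$fat <- r$grams * foods$fat_g_100g[fi] / 100
  r$tfa <- r$grams * truth$tfa_g_100g_true[ti] / 100
  days <- tapply(r$day_index, r$subject_id,
                 function(d) length(unique(d)))
  agg <- rowsum(r[, c("energy", "fat", "tfa")], r$subject_id)
  ids <- rownames(agg)
  tibble(subject_id = ids,
         energy_kcal_day = agg$energy / as.numeric(days[ids]),
         fat_g_day = agg$fat / as.numeric(days[ids]),
         tfa_g_day = agg$tfa / as.numeric(days[ids]))
}

#' Simulate a complete synthetic study
#'
#' Runs all generators under one seed: food table, recipes, literature, and
#' the diet-record cohort. The foreign-product table is empty by default
#' (the literature covers every TFA food, so Steps 2-4 are exercised by
#' [generate_provenance_corpus()] instead).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed fixing the entire stream.
#'
#' @return List: `foods`, `truth`, `recipes`, `references`, `foreign`,
#'   `subjects`, `records`, `truth_intake`, `config`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  ft <- generate_food_table(config)
  rc <- generate_recipes(ft$foods, ft$truth, config)
  references <- generate_literature(rc$foods, rc$truth, config)
  cohort <- generate_cohort(rc$foods, rc$truth, rc$recipes, config)
  list(foods = rc$foods, truth = rc$truth, recipes = rc$recipes,
       references = references,
       foreign = tibble(food_id = character(),
                        foreign_tfa_g_100g = numeric(),
                        foreign_energy_kcal_100g = numeric(),
                        foreign_fat_g_100g = numeric(),
                        foreign_protein_g_100g = numeric(),
                        foreign_carb_g_100g = numeric(),
                        same_manufacturer = logical()),
       subjects = cohort$subjects, records = cohort$records,
       truth_intake = cohort$truth_intake, config = config)
}
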