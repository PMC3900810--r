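# Deterministic corpus generator that routes a prescribed number of foods in
# each group through each step of the assignment hierarchy. Nutrient vectors
# are placed geometrically: every group (and, for meats, every species) lives
# in its own composition region; donors sit in a tight band, recipients that
# must match sit within the similarity threshold of a donor, and recipients
# that must fall through to Steps 3/4 sit far outside it.

#' Generate a corpus with prescribed per-step provenance counts
#'
#' Constructs a food table, literature corpus, foreign-product records, and
#' recipes such that [build_database()] resolves exactly the prescribed
#' number of foods per group at each step, plus a block of zero-rule foods.
#' The default counts are the published per-step counts of the 1995-food
#' Japanese TFA database ([reference_step_counts()]; 526 TFA foods + 1469
#' zero-rule foods). The construction is fully deterministic.
#'
#' @param step_counts Tibble like [reference_step_counts()]: `group` plus
#'   step-count columns `S1`, `S2_1A`, ..., `S4`.
#' @param n_zero Number of zero-rule foods to add (group `"no-TFA"`).
#' @param s1_split Integer vector of length 3: how many Step-1 foods (in
#'   corpus order) receive a single-sample article, a multi-sample article,
#'   and multiple articles pooled by sample weighting. Must sum to the total
#'   `S1` count; default the published split (13, 71, 59).
#'
#' @return List: `foods`, `references`, `foreign`, `recipes`, and the
#'   matching `config` (a [db_config()] carrying the part/species adjacency
#'   lists the corpus was built against).
#' @export
generate_provenance_corpus <- function(step_counts = reference_step_counts(),
                                       n_zero = 1469,
                                       s1_split = c(13, 71, 59)) {
  if (sum(s1_split) != sum(step_counts$S1)) {
    stop("s1_split must sum to the total Step-1 count", call. = FALSE)
  }
  thr <- 0.25
  species_pool <- c("cattle", "swine", "chicken")
  species_scale <- c(cattle = 1, swine = 1.6, chicken = 2.56)
  adjacent_species <- c(cattle = "buffalo", swine = "wildboar",
                        chicken = "duck")

  foods <- list(); refs <- list(); foreign <- list(); recipes <- list()
  part_adj <- list()
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("F%04d", counter)
  }
  base_vec <- function(gi) c(300 + 40 * gi, 18 + gi, 8 + gi, 40 + gi)
  add_food <- function(id, group, origin, category, species, part, vec) {
    foods[[length(foods) + 1L]] <<- tibble(
      food_id = id, name = paste0("food ", id), group = group,
      origin = origin, category = category, species = species, part = part,
      energy_kcal_100g = vec[[1]], fat_g_100g = vec[[2]],
      protein_g_100g = vec[[3]], carb_g_100g = vec[[4]],
      contains_hydrogenated_oil = origin == "industrial",
      contains_ruminant = origin == "natural")
  }

  s1_ids <- character()       # global order, for the s1_split reference design
  s1_by_group <- list()       # per group: tibble id/category/species/part/m

  for (gi in seq_len(nrow(step_counts))) {
    g <- step_counts$group[[gi]]
    origin <- group_origin(g)
    B <- base_vec(gi)
    is_meat_group <- grepl("^Meat", g)
    donors <- list()

    n1 <- step_counts$S1[[gi]]
    for (j in seq_len(n1)) {
      id <- new_id()
      m <- 1 + 0.002 * (j - 1)
      if (is_meat_group) {
        sp <- species_pool[[(j - 1) %% 3 + 1]]
        pt <- sprintf("%s_part%02d", sp, (j - 1) %/% 3 + 1)
        vec <- B * species_scale[[sp]] * m
      } else {
        sp <- NA_character_; pt <- NA_character_
        vec <- B * m
      }
      cat_j <- sprintf("g%02d_cat%03d", gi, j)
      add_food(id, g, origin, cat_j, sp, pt, vec)
      donors[[j]] <- tibble(food_id = id, category = cat_j, species = sp,
                            part = pt, m = m)
      s1_ids <- c(s1_ids, id)
    }
    donors <- bind_rows(donors)
    s1_by_group[[g]] <- donors

    pick_donor <- function(k) donors[(k - 1) %% nrow(donors) + 1, , drop = FALSE]

    # Step 2-1A: share a donor's category, composition inside the threshold.
    for (k in seq_len(step_counts$S2_1A[[gi]])) {
      dn <- pick_donor(k)
      add_food(new_id(), g, origin, dn$category, NA_character_, NA_character_,
               B * dn$m * 1.05)
    }
    # Step 2-1B: own category, inside the threshold of the donor band.
    for (k in seq_len(step_counts$S2_1B[[gi]])) {
      id <- new_id()
      if (is_meat_group) {
        # meat-group products without a species label use the non-meat path
        dn <- pick_donor(k)
        vec <- B * species_scale[[dn$species]] * dn$m * 1.05
      } else {
        vec <- B * 1.06
      }
      add_food(id, g, origin, paste0("own_", id), NA_character_, NA_character_,
               vec)
    }

    if (is_meat_group) {
      # 2-2A: same species and part as a donor; composition free.
      for (k in seq_len(step_counts$S2_2A[[gi]])) {
        dn <- pick_donor(k)
        add_food(new_id(), g, origin, NA_character_, dn$species, dn$part,
                 B * species_scale[[dn$species]] * 1.18)
      }
      # 2-2B: same species, adjacent part, similar composition.
      for (k in seq_len(step_counts$S2_2B[[gi]])) {
        id <- new_id()
        dn <- pick_donor(k)
        pt <- sprintf("nearcut%03d_%s", k, dn$species)
        part_adj[[length(part_adj) + 1L]] <- c(pt, dn$part)
        add_food(id, g, origin, NA_character_, dn$species, pt,
                 B * species_scale[[dn$species]] * dn$m * 1.04)
      }
      # 2-2C: similar animal type of the same species (adjacent species,
      # no donors of its own), similar composition.
      for (k in seq_len(step_counts$S2_2C[[gi]])) {
        dn <- pick_donor(k)
        sp <- adjacent_species[[dn$species]]
        add_food(new_id(), g, origin, NA_character_, sp,
                 sprintf("xcut%03d", k),
                 B * species_scale[[dn$species]] * dn$m * 1.05)
      }
      # 2-2D: a species with no donors and no adjacent donors, composition
      # similar to a donor of a different species.
      for (k in seq_len(step_counts$S2_2D[[gi]])) {
        dn <- pick_donor(k)
        add_food(new_id(), g, origin, NA_character_, "horse",
                 sprintf("hcut%03d", k),
                 B * species_scale[[dn$species]] * dn$m * 1.07)
      }
      # 2-2E: same species, unrelated part, similar composition.
      for (k in seq_len(step_counts$S2_2E[[gi]])) {
        dn <- pick_donor(k)
        add_food(new_id(), g, origin, NA_character_, dn$species,
                 sprintf("farcut%03d", k),
                 B * species_scale[[dn$species]] * dn$m * 1.09)
      }
    }

    # Step 3: far from every donor; matched foreign product.
    for (k in seq_len(step_counts$S3[[gi]])) {
      id <- new_id()
      vec <- B * 6
      add_food(id, g, origin, paste0("imp_", id), NA_character_, NA_character_,
               vec)
      foreign[[length(foreign) + 1L]] <- tibble(
        food_id = id, foreign_tfa_g_100g = 0.8 + 0.01 * k,
        foreign_energy_kcal_100g = vec[[1]], foreign_fat_g_100g = vec[[2]],
        foreign_protein_g_100g = vec[[3]], foreign_carb_g_100g = vec[[4]],
        same_manufacturer = TRUE)
    }
    # Step 4: far from every donor, no foreign match, has a recipe.
    for (k in seq_len(step_counts$S4[[gi]])) {
      id <- new_id()
      add_food(id, g, origin, paste0("rcp_", id), NA_character_, NA_character_,
               B * 9)
      recipes[[length(recipes) + 1L]] <- tibble(
        food_id = id,
        ingredient_id = c("ZING1", "ZING2"),
        grams_per_100g = c(60, 40))
    }
  }

  # Some recipe-imputed foods do contain TFA: give the meat-group and
  # miscellaneous-group recipes a Step-1 ingredient.
  rec <- bind_rows(recipes)
  if (nrow(rec)) {
    food_tab <- bind_rows(foods)
    tfa_rec_ids <- food_tab$food_id[grepl("^rcp_", food_tab$category) &
                                      food_tab$group %in%
                                      c("Meat and meat products (N)",
                                        "Miscellaneous (I)")]
    for (id in tfa_rec_ids) {
      grp <- food_tab$group[food_tab$food_id == id]
      donor1 <- s1_by_group[[grp]]$food_id[[1]]
      rec$ingredient_id[rec$food_id == id & rec$ingredient_id == "ZING2"] <-
        donor1
    }
  }

  # Zero-rule foods: trace fat, no hydrogenated oil, no ruminant fat. The
  # first two double as all-zero recipe ingredients.
  stopifnot(n_zero >= 2)
  zero <- tibble(
    food_id = c("ZING1", "ZING2", sprintf("Z%04d", seq_len(n_zero - 2L))),
    name = "zero-rule food", group = "no-TFA", origin = "none",
    category = NA_character_, species = NA_character_, part = NA_character_,
    energy_kcal_100g = 120, fat_g_100g = 0.05, protein_g_100g = 3,
    carb_g_100g = 26,
    contains_hydrogenated_oil = FALSE, contains_ruminant = FALSE)

  foods <- bind_rows(bind_rows(foods), zero)

  # Literature: single-sample, multi-sample, and weighted-pool articles in
  # corpus order.
  kind <- rep(c("single", "mean", "weighted"), times = s1_split)
  for (i in seq_along(s1_ids)) {
    id <- s1_ids[[i]]
    pct <- 4 + 0.01 * i
    refs[[length(refs) + 1L]] <- switch(
      kind[[i]],
      single = tibble(article_id = sprintf("A%04d_1", i), food_id = id,
                      n_samples = 1L, mean_value = pct, min_value = NA_real_,
                      max_value = NA_real_, basis = "percent_of_fat",
                      ref_fat_g_100g = NA_real_),
      mean = tibble(article_id = sprintf("A%04d_1", i), food_id = id,
                    n_samples = 5L, mean_value = pct, min_value = pct - 0.5,
                    max_value = pct + 0.5, basis = "percent_of_fat",
                    ref_fat_g_100g = NA_real_),
      weighted = tibble(article_id = sprintf("A%04d_%d", i, 1:2),
                        food_id = id, n_samples = c(4L, 2L),
                        mean_value = c(pct - 0.3, pct + 0.6),
                        min_value = NA_real_, max_value = NA_real_,
                        basis = "percent_of_fat", ref_fat_g_100g = NA_real_))
  }

  config <- db_config(
    part_adjacency = part_adj,
    species_adjacency = list(c("buffalo", "cattle"), c("wildboar", "swine"),
                             c("duck", "chicken")))

  list(foods = foods,
       references = bind_rows(refs),
       foreign = bind_rows(foreign),
       recipes = rec,
       config = config)
}
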