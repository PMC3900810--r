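#' Zero rule: foods that cannot contain trans fatty acids
#'
#' A food is assigned a TFA content of exactly zero when it contains no or
#' only a trace amount of fat, or when it contains neither industrially
#' hydrogenated oils nor ruminant-derived ingredients (the only two sources
#' of dietary TFA).
#'
#' @param foods A food table (see [validate_inputs()] for the schema); may be
#'   a single row.
#' @param fat_threshold Trace-fat cutoff in g/100 g; see [db_config()].
#'
#' @return Logical vector, `TRUE` for foods resolved by the zero rule.
#' @export
#' @examples
#' f <- tibble::tibble(food_id = "f1", fat_g_100g = 0,
#'                     contains_hydrogenated_oil = FALSE, contains_ruminant = FALSE)
#' zero_rule(f)
zero_rule <- function(foods, fat_threshold = 0.1) {
  if (anyNA(foods$fat_g_100g)) {
    bad <- foods$food_id[is.na(foods$fat_g_100g)]
    stop("missing fat content for food(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  foods$fat_g_100g <= fat_threshold |
    (!foods$contains_hydrogenated_oil & !foods$contains_ruminant)
}

#' Convert a literature TFA value to g per 100 g of food
#'
#' Analytic values are reported either as a percentage of total fat or as
#' grams per 100 g of the analysed food. Both are rescaled to the fat content
#' of the food as tabulated in the national composition table:
#' `tfa_g_100g = (tfa / fat in reference) * (fat per 100 g in the table)`.
#' When a g/100 g record does not report the fat content of the analysed
#' sample, the table's own fat content is used for both terms, so the
#' reported value passes through unchanged.
#'
#' @param ref One reference record (one-row data frame or list) with fields
#'   `mean_value`, `basis` (`"percent_of_fat"` or `"g_per_100g_food"`), and
#'   optionally `ref_fat_g_100g`.
#' @param food The food the record refers to (needs `fat_g_100g`).
#'
#' @return TFA in g per 100 g of food.
#' @export
convert_reference <- function(ref, food) {
  mean_v <- ref$mean_value
  fat <- food$fat_g_100g
  if (is.null(mean_v) || is.na(mean_v)) {
    stop("reference record for food ", food$food_id, " has no mean value",
         call. = FALSE)
  }
  if (!ref$basis %in% c("percent_of_fat", "g_per_100g_food")) {
    stop("unknown basis '", ref$basis, "' in reference record", call. = FALSE)
  }
  if (fat == 0 && mean_v > 0) {
    stop("food ", food$food_id,
         " has zero fat in the composition table but a nonzero reference ",
         "TFA value; inconsistent inputs", call. = FALSE)
  }
  if (ref$basis == "percent_of_fat") {
    return(mean_v / 100 * fat)
  }
  ref_fat <- if ("ref_fat_g_100g" %in% names(ref)) ref$ref_fat_g_100g else NA_real_
  if (!is.na(ref_fat)) {
    if (ref_fat <= 0) stop("reference fat content must be positive", call. = FALSE)
    mean_v / ref_fat * fat
  } else {
    # (mean / table fat) * table fat: the table's fat stands in for the
    # unreported analysed-sample fat.
    mean_v
  }
}

#' Pool literature records for one food (Step 1)
#'
#' One article that analysed a single sample contributes its value directly;
#' one article with several samples contributes its mean; several articles
#' are pooled by a mean weighted by the number of samples each analysed.
#' An article that does not state its sample count is usable on its own but
#' is dropped from weighted pooling, since weighting requires the count.
#'
#' @param records Reference records for a single food (>= 1 row).
#' @param food The food they refer to.
#'
#' @return List with `tfa_pct_fat` (TFA as % of total fat) and `step`
#'   (`"S1_SINGLE"`, `"S1_MEAN"` or `"S1_WEIGHTED"`).
#' @export
pool_step1 <- function(records, food) {
  if (nrow(records) < 1) stop("no records to pool", call. = FALSE)
  if (length(unique(records$food_id)) > 1) {
    stop("pool_step1() expects records for a single food", call. = FALSE)
  }
  # Fixed article order makes the floating-point sum independent of input
  # row order.
  records <- records[order(records$article_id), , drop = FALSE]
  g <- vapply(seq_len(nrow(records)),
              function(i) convert_reference(records[i, ], food),
              numeric(1))
  pct <- if (food$fat_g_100g > 0) 100 * g / food$fat_g_100g else rep(0, length(g))
  n <- records$n_samples
  if (nrow(records) == 1L) {
    step <- if (!is.na(n) && n > 1) "S1_MEAN" else "S1_SINGLE"
    return(list(tfa_pct_fat = pct[[1]], step = step))
  }
  known <- !is.na(n)
  if (!any(known)) {
    stop("food ", food$food_id, ": multiple articles, none reporting sample ",
         "counts; weighted pooling impossible, resolve manually", call. = FALSE)
  }
  list(tfa_pct_fat = sum(pct[known] * n[known]) / sum(n[known]),
       step = "S1_WEIGHTED")
}

#' Nutrient distance between two foods
#'
#' Scale-free dissimilarity over the four-component nutrient vector
#' (energy kcal/100 g, fat, protein, carbohydrate g/100 g): the maximum over
#' components of `|a - b| / max(b, floor)`. Zero iff the vectors are
#' identical; the floor keeps near-zero components from dominating.
#'
#' @param a Candidate nutrient vector(s): a length-4 numeric vector or an
#'   n x 4 matrix (one candidate per row).
#' @param b Reference nutrient vector (length 4); the denominator is taken
#'   from this side.
#' @param floor Denominator floor; see [db_config()].
#'
#' @return Nonnegative distance(s), one per row of `a`.
#' @export
#' @examples
#' nutrient_distance(c(200, 10, 5, 20), c(100, 10, 5, 20))
nutrient_distance <- function(a, b, floor = 1) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  a <- as.matrix(a)
  b <- as.numeric(b)
  if (ncol(a) != length(b)) {
    stop("nutrient vectors must have the same length", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) {
    stop("nutrient vectors must be complete (no missing values)", call. = FALSE)
  }
  denom <- pmax(b, floor)
  rel <- abs(sweep(a, 2, b, "-")) / matrix(denom, nrow = nrow(a),
                                           ncol = length(b), byrow = TRUE)
  out <- apply(rel, 1, max)
  unname(out)
}

# ---- internal helpers for Step 2 ------------------------------------------

assignment_row <- function(food_id, tfa_g_100g, tfa_pct_fat, step,
                           donor_food_id = NA_character_) {
  tibble(food_id = food_id, tfa_g_100g = tfa_g_100g,
         tfa_pct_fat = tfa_pct_fat, step = step,
         donor_food_id = donor_food_id)
}

# Symmetric lookup into an adjacency list of character pairs.
label_adjacent <- function(x, y, adjacency) {
  if (!length(adjacency)) return(rep(FALSE, length(y)))
  vapply(y, function(yy) {
    any(vapply(adjacency, function(p) {
      (p[[1]] == x && p[[2]] == yy) || (p[[2]] == x && p[[1]] == yy)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

# Transfer a donor's % of fat onto a recipient, rescaling by the recipient's
# fat content. A recipient with zero fat (flagged but fat-free) gets 0.
transfer_assignment <- function(food, donor, step) {
  pct <- donor$tfa_pct_fat
  if (food$fat_g_100g > 0) {
    assignment_row(food$food_id, pct * food$fat_g_100g / 100, pct, step,
                   donor$food_id)
  } else {
    assignment_row(food$food_id, 0, 0, step, donor$food_id)
  }
}

# Nearest candidate donor by nutrient distance; ties broken by lowest
# food_id for determinism. Returns NULL when no candidate qualifies.
nearest_donor <- function(food, candidates, config, thresholded = TRUE) {
  if (!nrow(candidates)) return(NULL)
  d <- nutrient_distance(as.matrix(candidates[, nutrient_cols()]),
                         as.numeric(food[, nutrient_cols()]),
                         config$similarity_floor)
  if (thresholded) {
    keep <- d <= config$similarity_threshold
    candidates <- candidates[keep, , drop = FALSE]
    d <- d[keep]
  }
  if (!nrow(candidates)) return(NULL)
  ord <- order(d, candidates$food_id)
  candidates[ord[[1]], , drop = FALSE]
}

#' Assign a TFA value by similarity to a Step-1-resolved food (Step 2)
#'
#' Foods without analytic values borrow the TFA content (% of total fat) of
#' the most nutritionally similar food that was resolved from the literature.
#' Ordinary foods are matched first within the same category of the same
#' food group (2-1A), then within the same group (2-1B). Meat cuts — foods
#' carrying a species label — run a dedicated cascade instead: same species
#' and same part regardless of composition (2-2A); same species and a similar
#' part with similar composition (2-2B); a similar animal type of the same
#' species with similar composition (2-2C); a different species with similar
#' composition (2-2D); finally any similar food of the same meat group,
#' i.e. the same species (2-2E). "Similar part"/"similar type" relations are
#' supplied as adjacency lists in `config`.
#'
#' @param food One food row not resolved by the zero rule or Step 1.
#' @param resolved Assignments produced by Step 1 (their `tfa_pct_fat` is the
#'   donor pool).
#' @param foods The full food table.
#' @param config A [db_config()].
#'
#' @return A one-row assignment tibble, or `NULL` when no donor exists
#'   anywhere in the cascade (the food then falls through to Steps 3/4).
#' @export
assign_step2 <- function(food, resolved, foods, config = db_config()) {
  donors <- inner_join(foods, resolved[, c("food_id", "tfa_pct_fat")],
                       by = "food_id")
  donors <- donors[donors$food_id != food$food_id, , drop = FALSE]
  donors <- donors[donors$group == food$group, , drop = FALSE]
  if (!nrow(donors)) return(NULL)

  has_species <- "species" %in% names(food) && !is.na(food$species) &&
    nzchar(food$species)

  if (!has_species) {
    thr <- config$step2_thresholded
    if (!is.na(food$category) && nzchar(food$category)) {
      cand <- donors[!is.na(donors$category) &
                       donors$category == food$category, , drop = FALSE]
      best <- nearest_donor(food, cand, config, thresholded = thr)
      if (!is.null(best)) return(transfer_assignment(food, best, "S2_1A"))
    }
    best <- nearest_donor(food, donors, config, thresholded = thr)
    if (!is.null(best)) return(transfer_assignment(food, best, "S2_1B"))
    return(NULL)
  }

  meat <- donors[!is.na(donors$species) & nzchar(donors$species), , drop = FALSE]
  if (!nrow(meat)) return(NULL)
  same_sp <- meat[meat$species == food$species, , drop = FALSE]

  # 2-2A: same part of the same animal, composition free to differ.
  cand <- same_sp[!is.na(same_sp$part) & same_sp$part == food$part, , drop = FALSE]
  best <- nearest_donor(food, cand, config, thresholded = FALSE)
  if (!is.null(best)) return(transfer_assignment(food, best, "S2_2A"))

  # 2-2B: similar part of the same animal with similar composition.
  if (nrow(same_sp) && !is.na(food$part)) {
    adj <- label_adjacent(food$part, same_sp$part, config$part_adjacency)
    best <- nearest_donor(food, same_sp[adj, , drop = FALSE], config)
    if (!is.null(best)) return(transfer_assignment(food, best, "S2_2B"))
  }

  # 2-2C: similar animal type of the same species, similar composition.
  adj_sp <- label_adjacent(food$species, meat$species, config$species_adjacency)
  best <- nearest_donor(food, meat[adj_sp, , drop = FALSE], config)
  if (!is.null(best)) return(transfer_assignment(food, best, "S2_2C"))

  # 2-2D: a different species with similar composition.
  diff_sp <- meat[meat$species != food$species & !adj_sp, , drop = FALSE]
  best <- nearest_donor(food, diff_sp, config)
  if (!is.null(best)) return(transfer_assignment(food, best, "S2_2D"))

  # 2-2E: any similar member of the same meat group (same species).
  best <- nearest_donor(food, same_sp, config)
  if (!is.null(best)) return(transfer_assignment(food, best, "S2_2E"))

  NULL
}

#' Assign a TFA value from a matched foreign product (Step 3)
#'
#' Products marketed by the same manufacturer in both countries are matched
#' by comparing the domestic nutrient declaration with the foreign
#' database's; when the compositions are similar the foreign TFA value is
#' adopted as is.
#'
#' @param food One food row unresolved after Step 2.
#' @param foreign Foreign product records (may cover many foods; only rows
#'   matching `food$food_id` are considered). Schema: `food_id`,
#'   `foreign_tfa_g_100g`, the four foreign nutrient columns
#'   (`foreign_energy_kcal_100g`, `foreign_fat_g_100g`,
#'   `foreign_protein_g_100g`, `foreign_carb_g_100g`), `same_manufacturer`.
#' @param config A [db_config()].
#'
#' @return A one-row assignment tibble (step `"S3"`), or `NULL`.
#' @export
assign_step3 <- function(food, foreign, config = db_config()) {
  if (is.null(foreign) || !nrow(foreign)) return(NULL)
  cand <- foreign[foreign$food_id == food$food_id &
                    foreign$same_manufacturer, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  fcols <- paste0("foreign_", nutrient_cols())
  d <- nutrient_distance(as.matrix(cand[, fcols]),
                         as.numeric(food[, nutrient_cols()]),
                         config$similarity_floor)
  cand <- cand[d <= config$similarity_threshold, , drop = FALSE]
  d <- d[d <= config$similarity_threshold]
  if (!nrow(cand)) return(NULL)
  best <- cand[order(d)[[1]], , drop = FALSE]
  g <- best$foreign_tfa_g_100g
  pct <- if (food$fat_g_100g > 0) 100 * g / food$fat_g_100g else 0
  assignment_row(food$food_id, g, pct, "S3")
}

#' Impute a TFA value from a recipe (Step 4)
#'
#' A composed food's TFA content is the gram-weighted sum of its
#' ingredients' contents: `sum(grams_i / 100 * tfa_i)` per 100 g of the
#' composed food.
#'
#' @param food One food row.
#' @param recipe Long-format recipe rows for this food (`food_id`,
#'   `ingredient_id`, `grams_per_100g`).
#' @param assignments Assignments covering every ingredient.
#'
#' @return A one-row assignment tibble (step `"S4"`).
#' @export
assign_step4 <- function(food, recipe, assignments) {
  recipe <- recipe[recipe$food_id == food$food_id, , drop = FALSE]
  if (!nrow(recipe)) stop("no recipe for food ", food$food_id, call. = FALSE)
  if (any(recipe$grams_per_100g <= 0)) {
    stop("recipe for food ", food$food_id, " has nonpositive ingredient grams",
         call. = FALSE)
  }
  missing <- setdiff(recipe$ingredient_id, assignments$food_id)
  if (length(missing)) {
    stop("recipe for food ", food$food_id, " has unresolved ingredient(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  recipe <- recipe[order(recipe$ingredient_id), , drop = FALSE]
  tfa <- assignments$tfa_g_100g[match(recipe$ingredient_id, assignments$food_id)]
  g <- sum(recipe$grams_per_100g / 100 * tfa)
  pct <- if (food$fat_g_100g > 0) 100 * g / food$fat_g_100g else 0
  assignment_row(food$food_id, g, pct, "S4")
}

#' Build the complete TFA composition database
#'
#' Assigns exactly one TFA value with provenance to every food, with strict
#' precedence: the zero rule first, then analytic literature values
#' (Step 1), similarity transfer (Step 2, sub-steps in order), foreign
#' product matching (Step 3), and recipe imputation (Step 4, in topological
#' order so recipes may nest). Any food left unresolved after Step 4 is an
#' error.
#'
#' @param foods Food table.
#' @param references Literature records, or `NULL`.
#' @param foreign Foreign product records, or `NULL`.
#' @param recipes Long-format recipes, or `NULL`.
#' @param config A [db_config()].
#'
#' @return List with `assignments` (one row per food, ordered by `food_id`)
#'   and `provenance` (foods counted per group x step; Step 1 sub-steps
#'   collapsed into one column; grand total equals the number of foods).
#' @export
build_database <- function(foods, references = NULL, foreign = NULL,
                           recipes = NULL, config = db_config()) {
  if (anyDuplicated(foods$food_id)) {
    stop("duplicated food_id in food table", call. = FALSE)
  }
  foods <- foods[order(foods$food_id), , drop = FALSE]

  z <- zero_rule(foods, config$fat_threshold)
  out <- list()
  if (any(z)) {
    out$zero <- assignment_row(foods$food_id[z], 0, 0, "ZERO")
  }
  todo <- foods[!z, , drop = FALSE]

  # Step 1: pooled analytic values.
  s1 <- NULL
  if (!is.null(references) && nrow(references)) {
    refs <- references[references$food_id %in% todo$food_id, , drop = FALSE]
    if (nrow(refs)) {
      s1 <- bind_rows(lapply(split(refs, refs$food_id), function(r) {
        fd <- todo[todo$food_id == r$food_id[[1]], , drop = FALSE]
        pooled <- pool_step1(r, fd)
        assignment_row(fd$food_id, pooled$tfa_pct_fat * fd$fat_g_100g / 100,
                       pooled$tfa_pct_fat, pooled$step)
      }))
      out$s1 <- s1
      todo <- todo[!todo$food_id %in% s1$food_id, , drop = FALSE]
    }
  }

  # Step 2: similarity transfer from Step-1-resolved foods.
  if (!is.null(s1) && nrow(todo)) {
    s2 <- bind_rows(lapply(seq_len(nrow(todo)), function(i) {
      assign_step2(todo[i, , drop = FALSE], s1, foods, config)
    }))
    if (nrow(s2)) {
      out$s2 <- s2
      todo <- todo[!todo$food_id %in% s2$food_id, , drop = FALSE]
    }
  }

  # Step 3: foreign product matching.
  if (!is.null(foreign) && nrow(foreign) && nrow(todo)) {
    s3 <- bind_rows(lapply(seq_len(nrow(todo)), function(i) {
      assign_step3(todo[i, , drop = FALSE], foreign, config)
    }))
    if (nrow(s3)) {
      out$s3 <- s3
      todo <- todo[!todo$food_id %in% s3$food_id, , drop = FALSE]
    }
  }

  # Step 4: recipe imputation in topological order (recipes may nest).
  if (!is.null(recipes) && nrow(recipes) && nrow(todo)) {
    pending <- intersect(unique(recipes$food_id), todo$food_id)
    assigned <- bind_rows(out)
    while (length(pending)) {
      ready <- vapply(pending, function(fid) {
        ing <- recipes$ingredient_id[recipes$food_id == fid]
        all(ing %in% assigned$food_id)
      }, logical(1))
      if (!any(ready)) {
        # Distinguish a genuine cycle from an unresolved plain ingredient.
        ing_all <- recipes$ingredient_id[recipes$food_id %in% pending]
        outside <- setdiff(ing_all, c(assigned$food_id, pending))
        if (length(outside)) {
          stop("recipe ingredient(s) without any TFA assignment: ",
               paste(sort(outside), collapse = ", "), call. = FALSE)
        }
        stop("cyclic recipes among foods: ",
             paste(sort(pending), collapse = ", "), call. = FALSE)
      }
      for (fid in sort(pending[ready])) {
        fd <- todo[todo$food_id == fid, , drop = FALSE]
        a <- assign_step4(fd, recipes, assigned)
        assigned <- bind_rows(assigned, a)
        out$s4 <- bind_rows(out$s4, a)
      }
      pending <- pending[!ready]
    }
    todo <- todo[!todo$food_id %in% assigned$food_id, , drop = FALSE]
  }

  if (nrow(todo)) {
    stop("foods unresolved after Step 4: ",
         paste(sort(todo$food_id), collapse = ", "), call. = FALSE)
  }

  assignments <- bind_rows(out)
  assignments <- assignments[order(assignments$food_id), , drop = FALSE]
  list(assignments = as_tibble(assignments),
       provenance = provenance_table(assignments, foods))
}

#' Provenance table: foods per group and assignment step
#'
#' Counts how many foods in each food group were resolved at each step of
#' the hierarchy, with the three Step-1 variants collapsed into one column.
#' The grand total equals the number of foods; the non-zero total is the
#' number of foods found to contain TFA.
#'
#' @param assignments Assignment table from [build_database()].
#' @param foods The food table (for group labels).
#'
#' @return A tibble with one row per group (sorted), one column per step
#'   plus `Total`, and a final `Total` row.
#' @export
provenance_table <- function(assignments, foods) {
  step_levels <- c("ZERO", "S1", "S2_1A", "S2_1B", "S2_2A", "S2_2B", "S2_2C",
                   "S2_2D", "S2_2E", "S3", "S4")
  df <- tibble(
    group = foods$group[match(assignments$food_id, foods$food_id)],
    step = sub("^S1_.*$", "S1", assignments$step))
  groups <- sort(unique(df$group), method = "radix")
  tab <- table(factor(df$group, levels = groups),
               factor(df$step, levels = step_levels))
  mat <- matrix(as.integer(tab), nrow = length(groups),
                dimnames = list(groups, step_levels))
  res <- as_tibble(mat)
  res <- tibble(group = groups, res)
  res$Total <- unname(rowSums(mat))
  total_row <- res[1, ]
  total_row$group <- "Total"
  for (cl in c(step_levels, "Total")) total_row[[cl]] <- sum(res[[cl]])
  bind_rows(res, total_row)
}
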