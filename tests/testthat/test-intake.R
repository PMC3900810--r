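entry <- function(food_id, grams, venue = "home", subject = "s1", day = 1L) {
  tibble::tibble(subject_id = subject, day_index = day, season = "autumn",
                 food_id = food_id, grams = grams, venue = venue)
}

test_that("venue rule: commercial products pass through, restaurant dishes decompose", {
  rec <- tibble::tibble(food_id = "cutlet", ingredient_id = c("pork", "lard"),
                        grams_per_100g = c(60, 10))
  out <- resolve_entry(entry("fries", 100, "commercial"), rec)
  expect_equal(out, tibble::tibble(food_id = "fries", grams = 100))

  out <- resolve_entry(entry("cutlet", 150, "restaurant"), rec)
  expect_setequal(out$food_id, c("pork", "lard"))
  expect_equal(out$grams[out$food_id == "pork"], 90)
  expect_equal(out$grams[out$food_id == "lard"], 15)

  out <- resolve_entry(entry("rice", 200, "home"), rec)
  expect_equal(out$grams, 200)

  # a dish flagged composed but lacking a recipe cannot be valued
  foods <- make_foods("mystery")
  foods$is_composed <- TRUE
  expect_error(resolve_entry(entry("mystery", 100, "restaurant"), rec, foods),
               "no recipe")
})

test_that("daily totals scale by mass and multi-day intakes average", {
  foods <- make_foods("f1", energy = 200, fat = 10)
  asg <- tibble::tibble(food_id = "f1", tfa_g_100g = 0.5, tfa_pct_fat = 5,
                        step = "S1_MEAN", donor_food_id = NA_character_)
  one <- suppressWarnings(subject_mean_intake(entry("f1", 100), foods, asg))
  expect_equal(one$energy_kcal_day, 200)
  expect_equal(one$fat_g_day, 10)
  expect_equal(one$tfa_g_day, 0.5)

  two <- suppressWarnings(subject_mean_intake(
    dplyr::bind_rows(entry("f1", 200, day = 1L), entry("f1", 400, day = 2L)),
    foods, asg))
  expect_equal(two$tfa_g_day, mean(c(1.0, 2.0)))

  # percent of energy uses the fat energy factor on the 16-day means
  expect_equal(one$tfa_pct_energy, 100 * 0.5 * 9 / 200)
  expect_equal(one$fat_pct_energy, 100 * 10 * 9 / 200)
  expect_equal(one$tfa_pct_fat, 100 * 0.5 / 10)
})

test_that("a 1.7 g/day intake at 1847 kcal/day is about 0.83% of energy", {
  foods <- make_foods("f1", energy = 1847, fat = 56.9)
  asg <- tibble::tibble(food_id = "f1", tfa_g_100g = 1.7, tfa_pct_fat = NA,
                        step = "S1_MEAN", donor_food_id = NA_character_)
  out <- suppressWarnings(subject_mean_intake(entry("f1", 100), foods, asg))
  expect_equal(out$tfa_pct_energy, 1.7 * 9 / 1847 * 100)
  expect_equal(round(out$tfa_pct_energy, 2), 0.83)
})

test_that("intake is additive over groups, monotone in entries, and venue-neutral for simple foods", {
  set.seed(21)
  st <- simulate_study(closure_sim_config(), seed = 21)
  built <- build_database(st$foods, st$references, st$foreign, st$recipes)
  ints <- subject_mean_intake(st$records, st$foods, built$assignments,
                              st$recipes)
  gi <- intake_by_group(st$records, st$foods, built$assignments, st$recipes)
  tot <- tapply(gi$tfa_g_day, gi$subject_id, sum)
  expect_equal(as.numeric(tot[ints$subject_id]), ints$tfa_g_day,
               tolerance = 1e-12)

  # adding an entry with positive TFA strictly increases intake
  sid <- ints$subject_id[1]
  tfa_food <- built$assignments$food_id[built$assignments$tfa_g_100g > 0][1]
  extra <- entry(tfa_food, 50, subject = sid)
  ints2 <- subject_mean_intake(dplyr::bind_rows(st$records, extra),
                               st$foods, built$assignments, st$recipes)
  expect_gt(ints2$tfa_g_day[ints2$subject_id == sid],
            ints$tfa_g_day[ints$subject_id == sid])

  # venue has no effect on a non-composed food
  simple <- st$foods$food_id[!st$foods$is_composed & st$foods$group != "no-TFA"][1]
  for (v in c("home", "commercial", "restaurant")) {
    out <- suppressWarnings(subject_mean_intake(entry(simple, 80, v), st$foods,
                                                built$assignments, st$recipes))
    if (v == "home") base <- out
    expect_equal(out$tfa_g_day, base$tfa_g_day)
    expect_equal(out$energy_kcal_day, base$energy_kcal_day)
  }
})

test_that("outlier exclusion implements a single mean +/- kSD pass within sex", {
  mk <- function(tfa, sex = "women") {
    tibble::tibble(subject_id = sprintf("%s%03d", sex, seq_along(tfa)),
                   sex = sex, tfa_g_day = tfa,
                   tfa_pct_energy = tfa * 9 / 2000 * 100)
  }
  same <- mk(rep(1.5, 10))
  out <- exclude_outliers(same)
  expect_identical(nrow(out$excluded), 0L)

  set.seed(5)
  vals <- rnorm(50, 1.7, 0.3)
  vals[17] <- 1.7 + 10      # plant one extreme subject
  cohort <- mk(vals)
  out <- exclude_outliers(cohort, k = 3)
  # brute-force re-check of the criterion for every subject
  m <- mean(vals); s <- sd(vals)
  brute <- which(vals < m - 3 * s | vals > m + 3 * s)
  expect_identical(sort(out$excluded$subject_id),
                   sort(cohort$subject_id[brute]))
  expect_identical(out$excluded$subject_id, cohort$subject_id[17])

  # exclusion is symmetric under reflection about the mean
  flipped <- mk(2 * m - vals)
  expect_identical(nrow(exclude_outliers(flipped)$excluded),
                   nrow(out$excluded))

  # exclusion is computed within sex, not pooled
  both <- dplyr::bind_rows(mk(rnorm(30, 1.7, 0.2)),
                           mk(rnorm(30, 10, 0.2), sex = "men"))
  expect_identical(nrow(exclude_outliers(both)$excluded), 0L)
})

test_that("BMI is weight over squared height", {
  expect_equal(round(bmi(53.4, 154.6), 1), 22.3)
  expect_equal(bmi(100, 200), 25)
  expect_equal(round(bmi(67.1, 168.0), 1), 23.8)
  expect_error(bmi(-1, 160), "positive")
})
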