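test_that("zero rule covers trace-fat and source-free foods and rejects missing fat", {
  foods <- dplyr::bind_rows(
    make_foods("nofat", fat = 0),
    make_foods("trace", fat = 0.1),
    make_foods("oilrich", fat = 80, hydro = TRUE),
    make_foods("fatty_unflagged", fat = 30, hydro = FALSE, rumin = FALSE),
    make_foods("ruminant", fat = 25, hydro = FALSE, rumin = TRUE))
  expect_identical(zero_rule(foods),
                   c(TRUE, TRUE, FALSE, TRUE, FALSE))
  bad <- make_foods("x"); bad$fat_g_100g <- NA_real_
  expect_error(zero_rule(bad), "x")
})

test_that("reference conversion rescales all three reporting bases", {
  food <- make_foods("f", fat = 80)
  expect_equal(convert_reference(make_ref("f", 10), food), 8.0)
  food20 <- make_foods("f", fat = 20)
  expect_equal(convert_reference(
    make_ref("f", 2, basis = "g_per_100g_food", ref_fat = 40), food20), 1.0)
  # no reference fat reported: the table's own fat is used on both sides
  expect_equal(convert_reference(
    make_ref("f", 1.5, basis = "g_per_100g_food"), food20), 1.5)
  expect_equal(convert_reference(make_ref("f", 0), food), 0)
  nofat <- make_foods("f", fat = 0)
  expect_error(convert_reference(make_ref("f", 2), nofat), "zero fat")
})

test_that("literature pooling follows the single/mean/weighted guidelines", {
  food <- make_foods("f", fat = 10)
  one_single <- make_ref("f", 3.0, n_samples = 1L)
  expect_identical(pool_step1(one_single, food)$step, "S1_SINGLE")
  one_multi <- make_ref("f", 3.0, n_samples = 6L)
  expect_identical(pool_step1(one_multi, food)$step, "S1_MEAN")

  weighted <- make_ref("f", c(2, 5), n_samples = c(4L, 1L))
  out <- pool_step1(weighted, food)
  expect_equal(out$tfa_pct_fat, 2.6)
  expect_identical(out$step, "S1_WEIGHTED")

  sole_unknown <- make_ref("f", 3.0, n_samples = 1L)
  sole_unknown$n_samples <- NA_integer_
  out <- pool_step1(sole_unknown, food)
  expect_equal(out$tfa_pct_fat, 3.0)
  expect_identical(out$step, "S1_SINGLE")

  mixed <- make_ref("f", c(2, 3), n_samples = c(4L, 2L))
  mixed$n_samples[2] <- NA_integer_
  expect_equal(pool_step1(mixed, food)$tfa_pct_fat, 2.0)

  all_unknown <- make_ref("f", c(2, 3), n_samples = c(1L, 1L))
  all_unknown$n_samples <- NA_integer_
  expect_error(pool_step1(all_unknown, food), "resolve manually")
})

test_that("sample-size weighting equals flat pooling over listed samples and stays within article bounds", {
  food <- make_foods("f", fat = 10)
  for (s in 1:20) {
    set.seed(s)
    k <- sample(2:5, 1)
    samples <- lapply(seq_len(k), function(i) runif(sample(1:8, 1), 1, 9))
    refs <- make_ref("f", vapply(samples, mean, numeric(1)),
                     n_samples = lengths(samples))
    out <- pool_step1(refs, food)
    # weighting by sample count reproduces the flat mean over all samples
    expect_equal(out$tfa_pct_fat, mean(unlist(samples)), tolerance = 1e-12)
    expect_gte(out$tfa_pct_fat, min(refs$mean_value))
    expect_lte(out$tfa_pct_fat, max(refs$mean_value))
  }
})

test_that("nutrient distance is zero at identity and ranks donors like exhaustive search", {
  expect_equal(nutrient_distance(c(200, 10, 5, 20), c(200, 10, 5, 20)), 0)
  expect_equal(nutrient_distance(c(200, 10, 5, 20), c(100, 10, 5, 20)), 1.0)
  expect_error(nutrient_distance(c(1, NA, 3, 4), c(1, 2, 3, 4)), "complete")

  set.seed(11)
  target <- c(300, 15, 8, 40)
  cand <- matrix(runif(20, 1, 500), ncol = 4)
  d <- nutrient_distance(cand, target)
  brute <- apply(cand, 1, function(a)
    max(abs(a - target) / pmax(target, 1)))
  expect_equal(d, brute)
  expect_identical(which.min(d), which.min(brute))
})

test_that("similarity transfer moves the donor's share of fat, cascading category before group", {
  foods <- dplyr::bind_rows(
    make_foods("donor", category = "catC", fat = 12),
    make_foods("recipC", category = "catC", fat = 10, energy = 390),
    make_foods("recipG", category = "other", fat = 11, energy = 395))
  s1 <- tibble::tibble(food_id = "donor", tfa_g_100g = 0.36,
                       tfa_pct_fat = 3, step = "S1_MEAN",
                       donor_food_id = NA_character_)
  a <- assign_step2(foods[2, ], s1, foods, db_config())
  expect_identical(a$step, "S2_1A")
  expect_equal(a$tfa_g_100g, 0.3)      # 3% of 10 g fat
  expect_equal(a$tfa_pct_fat, 3)
  expect_identical(a$donor_food_id, "donor")

  b <- assign_step2(foods[3, ], s1, foods, db_config())
  expect_identical(b$step, "S2_1B")
  expect_equal(b$tfa_pct_fat, 3)
  expect_equal(b$tfa_g_100g, 3 * 11 / 100)
})

test_that("meat cascade labels match the hand-enumerated rule order", {
  fx <- meat_cascade_fixture()
  built <- build_database(fx$foods, fx$refs, config = fx$config)
  got <- setNames(built$assignments$step, built$assignments$food_id)
  for (id in names(fx$expected)) {
    expect_identical(got[[id]], fx$expected[[id]])
  }
  # a cut far from every donor at every level falls through the cascade
  far_cut <- make_foods("FAR", fx$foods$group[1], species = "cattle",
                        part = "tail", energy = 901, fat = 71, protein = 5,
                        carb = 1, hydro = FALSE, rumin = TRUE)
  s1 <- built$assignments[built$assignments$step == "S1_MEAN", ]
  expect_null(assign_step2(far_cut, s1, dplyr::bind_rows(fx$foods, far_cut),
                           fx$config))
  expect_error(build_database(dplyr::bind_rows(fx$foods, far_cut), fx$refs,
                              config = fx$config),
               "unresolved")
})

test_that("step 2 transfers are internally consistent with their donors", {
  fx <- meat_cascade_fixture()
  built <- build_database(fx$foods, fx$refs, config = fx$config)
  a <- built$assignments
  s2 <- a[grepl("^S2", a$step), ]
  for (i in seq_len(nrow(s2))) {
    donor <- a[a$food_id == s2$donor_food_id[i], ]
    fat <- fx$foods$fat_g_100g[fx$foods$food_id == s2$food_id[i]]
    expect_equal(s2$tfa_pct_fat[i], donor$tfa_pct_fat)
    expect_equal(s2$tfa_g_100g[i], donor$tfa_pct_fat * fat / 100)
  }
})

test_that("foreign matching requires the same manufacturer and similar composition", {
  food <- make_foods("f", fat = 20)
  match_row <- tibble::tibble(
    food_id = "f", foreign_tfa_g_100g = 1.2,
    foreign_energy_kcal_100g = 400, foreign_fat_g_100g = 20,
    foreign_protein_g_100g = 6, foreign_carb_g_100g = 50,
    same_manufacturer = TRUE)
  a <- assign_step3(food, match_row, db_config())
  expect_equal(a$tfa_g_100g, 1.2)
  expect_identical(a$step, "S3")

  far <- match_row; far$foreign_energy_kcal_100g <- 900
  expect_null(assign_step3(food, far, db_config()))
  other <- match_row; other$same_manufacturer <- FALSE
  expect_null(assign_step3(food, other, db_config()))
})

test_that("recipe imputation mixes linearly and nested recipes flatten exactly", {
  asg <- tibble::tibble(food_id = c("i1", "i2"),
                        tfa_g_100g = c(2, 0), tfa_pct_fat = c(10, 0),
                        step = "S1_MEAN", donor_food_id = NA_character_)
  food <- make_foods("dish", fat = 10)
  rec <- tibble::tibble(food_id = "dish", ingredient_id = c("i1", "i2"),
                        grams_per_100g = c(50, 50))
  a <- assign_step4(food, rec, asg)
  expect_equal(a$tfa_g_100g, 1.0)
  expect_identical(a$step, "S4")

  zero <- assign_step4(food, rec,
                       dplyr::mutate(asg, tfa_g_100g = 0))
  expect_equal(zero$tfa_g_100g, 0)

  # doubling every ingredient's TFA doubles the output
  twice <- assign_step4(food, rec, dplyr::mutate(asg, tfa_g_100g = 2 * tfa_g_100g))
  expect_equal(twice$tfa_g_100g, 2 * a$tfa_g_100g)

  expect_error(assign_step4(food, rec, asg[1, ]), "i2")

  # three-level nesting equals the brute-force flattened computation
  nested <- tibble::tibble(
    food_id = c("top", "top", "mid", "mid", "base", "base"),
    ingredient_id = c("mid", "i2", "base", "i1", "i1", "i2"),
    grams_per_100g = c(80, 20, 50, 30, 40, 60))
  flat <- flatten_recipes(nested)
  flat_top <- flat[flat$food_id == "top", ]
  brute <- sum(flat_top$grams_per_100g / 100 *
                 asg$tfa_g_100g[match(flat_top$ingredient_id, asg$food_id)])
  # the composed foods sit far from the Step-1 donors so similarity
  # transfer cannot pre-empt recipe imputation
  foods <- dplyr::bind_rows(make_foods(c("top", "mid", "base"), fat = 10,
                                       energy = 900),
                            make_foods(c("i1", "i2"), fat = 10))
  refs <- make_ref(c("i1", "i2"), c(20, 0), n_samples = 2L)
  built <- build_database(foods, refs, recipes = nested)
  expect_equal(built$assignments$tfa_g_100g[built$assignments$food_id == "top"],
               brute, tolerance = 1e-12)

  cyc <- tibble::tibble(food_id = c("a", "b"), ingredient_id = c("b", "a"),
                        grams_per_100g = 50)
  expect_error(flatten_recipes(cyc), "cyclic")
})

test_that("database construction is complete, precedence-ordered, and order-invariant", {
  fx <- meat_cascade_fixture()
  foods <- dplyr::bind_rows(fx$foods, make_foods("zf", fat = 0.05))
  built <- build_database(foods, fx$refs, config = fx$config)
  expect_identical(nrow(built$assignments), nrow(foods))
  expect_identical(anyDuplicated(built$assignments$food_id), 0L)
  prov <- built$provenance
  expect_equal(prov$Total[prov$group == "Total"], nrow(foods))

  # analytic data for every food wins over every later step
  refs_all <- make_ref(fx$foods$food_id, 4, n_samples = 2L,
                       article_id = paste0("art", seq_len(nrow(fx$foods))))
  all_s1 <- build_database(fx$foods, refs_all, config = fx$config)
  expect_true(all(grepl("^S1", all_s1$assignments$step)))

  # shuffling input rows changes nothing
  set.seed(3)
  shuffled <- build_database(foods[sample(nrow(foods)), ],
                             fx$refs[sample(nrow(fx$refs)), ],
                             config = fx$config)
  expect_identical(built$assignments, shuffled$assignments)
  expect_identical(built$provenance, shuffled$provenance)
})
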