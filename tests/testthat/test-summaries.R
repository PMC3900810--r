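test_that("group contributions decompose each subject's intake to 100%", {
  one <- tibble::tibble(subject_id = "s1",
                        group = c("Confectionaries (I)", "Bakery (I)"),
                        tfa_g_day = c(1.2, 0))
  rows <- contribution_by_group(one)
  expect_equal(rows$mean_pct[rows$group == "Confectionaries (I)"], 100)
  expect_equal(rows$mean_pct[rows$group == "Bakery (I)"], 0)

  two <- tibble::tibble(subject_id = rep(c("s1", "s2"), each = 2),
                        group = rep(c("Confectionaries (I)", "Bakery (I)"), 2),
                        tfa_g_day = c(2, 0, 0, 0.5))
  rows <- contribution_by_group(two)
  expect_equal(rows$mean_pct, c(50, 50), ignore_attr = TRUE)

  zero <- tibble::tibble(subject_id = "s3", group = "Bakery (I)",
                         tfa_g_day = 0)
  expect_warning(contribution_by_group(dplyr::bind_rows(two, zero)),
                 "zero total")
})

test_that("contribution means equal brute-force re-aggregation from raw records", {
  st <- simulate_study(closure_sim_config(), seed = 8)
  built <- build_database(st$foods, st$references, st$foreign, st$recipes)
  gi <- intake_by_group(st$records, st$foods, built$assignments, st$recipes)
  gi <- gi[gi$group != "no-TFA", ]
  rows <- contribution_by_group(gi, groups = tfa_food_groups())

  # per-subject decomposition conserves mass exactly
  shares <- merge(gi, aggregate(tfa_g_day ~ subject_id, gi, sum),
                  by = "subject_id", suffixes = c("", "_tot"))
  per_subject <- tapply(100 * shares$tfa_g_day / shares$tfa_g_day_tot,
                        shares$subject_id, sum)
  expect_true(all(abs(per_subject - 100) < 1e-9))

  # row means equal an independent aggregation
  shares$pct <- 100 * shares$tfa_g_day / shares$tfa_g_day_tot
  brute <- tapply(shares$pct, shares$group, mean)
  for (g in names(brute)) {
    expect_equal(rows$mean_pct[rows$group == g], unname(brute[[g]]),
                 tolerance = 1e-12)
  }
})

test_that("industrial share sums the industrial rows and complements the natural share", {
  ref <- reference_group_contributions("women")
  expect_equal(industrial_share(ref), 75.1, tolerance = 1e-9)

  natural_only <- ref[ref$origin == "natural", ]
  expect_equal(industrial_share(natural_only), 0)

  st <- simulate_study(closure_sim_config(), seed = 8)
  built <- build_database(st$foods, st$references, st$foreign, st$recipes)
  gi <- intake_by_group(st$records, st$foods, built$assignments, st$recipes)
  rows <- contribution_by_group(gi[gi$group != "no-TFA", ],
                                groups = tfa_food_groups())
  nat <- sum(rows$mean_pct[rows$origin == "natural"])
  expect_equal(industrial_share(rows) + nat, 100, tolerance = 1e-9)
})

test_that("population density classifies areas with an inclusive urban boundary", {
  expect_identical(classify_area(11743), "urban")
  expect_identical(classify_area(4446), "urban")
  expect_identical(classify_area(786), "rural")
  expect_identical(classify_area(285), "rural")
  expect_identical(classify_area(1000), "urban")
  expect_error(classify_area(0), "positive")
})

test_that("threshold frequencies and distribution tables agree with brute-force binning", {
  cohort <- reference_distribution_cohort("pct_energy")
  women <- cohort[cohort$sex == "women", ]

  freq <- frequency_above(women, threshold = 1)
  expect_equal(freq$n_above, sum(women$tfa_pct_energy > 1))
  by_area <- frequency_above(women, threshold = 1, by = "area_type")
  expect_equal(sum(by_area$n_above), freq$n_above)
  expect_equal(sum(by_area$n), 119)

  edges <- c(0.5, 0.75, 1, 1.25, 1.5)
  tab <- distribution_table(women, edges, value = "tfa_pct_energy",
                            by = "area_type")
  expect_equal(sum(tab$n), 119)
  # row sums match each stratum's size
  for (at in c("urban", "rural")) {
    expect_equal(sum(tab$n[tab$area_type == at]),
                 sum(women$area_type == at))
  }
  # brute-force binning
  for (i in seq_len(nrow(tab))) {
    sel <- women$area_type == tab$area_type[i] &
      women$tfa_pct_energy >= tab$bin_lo[i] &
      women$tfa_pct_energy < tab$bin_hi[i]
    expect_equal(tab$n[i], sum(sel))
  }
  # frequency at a bin edge equals the sum of fully-above bins
  above_bins <- sum(tab$n[tab$bin_lo >= 1])
  expect_equal(above_bins, freq$n_above)

  single <- women[1, ]
  stab <- distribution_table(single, edges, value = "tfa_pct_energy")
  expect_equal(sum(stab$n > 0), 1L)
  expect_error(distribution_table(women, c(1, 1)), "strictly increasing")
})

test_that("urban/rural and age-group comparisons behave at the degenerate and forced extremes", {
  # perfectly balanced groups: every stratum sees the same value multiset
  set.seed(9)
  base <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:40), sex = "women",
    area_type = rep(c("urban", "rural"), 20),
    age_group = rep(rep(c("30-39", "40-49", "50-59", "60-69"), each = 2), 5),
    tfa_g_day = rep(rnorm(5, 1.7, 0.3), each = 8))
  out <- compare_strata(base, vars = "tfa_g_day")
  expect_equal(out$t_tests$p_value, 1)
  expect_equal(out$anova$p_value, 1)

  area_shift <- base
  area_shift$tfa_g_day <- area_shift$tfa_g_day +
    ifelse(area_shift$area_type == "urban", 10, 0)
  out <- compare_strata(area_shift, vars = "tfa_g_day")
  expect_lt(out$t_tests$p_value, 0.001)

  age_shift <- base
  age_shift$tfa_g_day <- age_shift$tfa_g_day +
    ifelse(age_shift$age_group == "30-39", 5, 0)
  out <- compare_strata(age_shift, vars = "tfa_g_day")
  expect_lt(out$anova$p_value, 0.001)
  expect_true(all(c("40-49-30-39", "50-59-30-39", "60-69-30-39") %in%
                    out$tukey$contrast))
  expect_true(all(out$tukey$p_adj[grepl("-30-39$", out$tukey$contrast)] < 0.05))

  # degenerate variance is reported as not computable
  flat <- base; flat$tfa_g_day <- 1
  out <- compare_strata(flat, vars = "tfa_g_day")
  expect_true(is.na(out$t_tests$p_value))
  expect_true(is.na(out$anova$p_value))
})

test_that("reduced-database intake is dominated by the full database and their gap is the added foods' intake", {
  st <- simulate_study(closure_sim_config(composed_fraction = 0), seed = 12)
  built <- build_database(st$foods, st$references, st$foreign, st$recipes)
  base_ids <- st$foods$food_id[!st$foods$is_added]
  reduced <- built$assignments[built$assignments$food_id %in% base_ids, ]

  full_int <- estimate_intakes(st$records, st$subjects, st$foods,
                               built$assignments, st$recipes)
  red_int <- estimate_intakes(st$records, st$subjects, st$foods, reduced,
                              st$recipes,
                              intake_config(missing_tfa = "zero"))
  j <- merge(full_int, red_int, by = "subject_id",
             suffixes = c("_f", "_r"))
  expect_true(all(j$tfa_g_day_r <= j$tfa_g_day_f + 1e-12))

  cmp <- compare_databases(st$records, st$subjects, st$foods,
                           built$assignments, reduced, st$recipes)
  expect_true(all(cmp$difference >= -1e-12))

  # the gap equals the direct intake sum over added foods
  added <- st$foods$food_id[st$foods$is_added]
  gi <- intake_by_group(st$records, st$foods, built$assignments, st$recipes)
  # recompute per-subject added-food intake directly from the records
  r <- st$records
  ai <- match(r$food_id, built$assignments$food_id)
  r$tfa <- r$grams * built$assignments$tfa_g_100g[ai] / 100
  r$tfa[!r$food_id %in% added] <- 0
  gap <- tapply(r$tfa, r$subject_id, sum) / 16
  jj <- j$tfa_g_day_f - j$tfa_g_day_r
  expect_equal(jj, as.numeric(gap[j$subject_id]), tolerance = 1e-9)

  # if nobody eats an added food the two databases agree exactly
  r0 <- st$records[!st$records$food_id %in% added, ]
  f0 <- estimate_intakes(r0, st$subjects, st$foods, built$assignments,
                         st$recipes)
  r0i <- estimate_intakes(r0, st$subjects, st$foods, reduced, st$recipes,
                          intake_config(missing_tfa = "zero"))
  expect_equal(f0$tfa_g_day, r0i$tfa_g_day)
})
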