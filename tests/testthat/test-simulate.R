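test_that("ingredient sampling stays inside the reference ranges", {
  ing <- sample_ingredients(10, seed = 4)
  comp <- ing$composition
  expect_equal(nrow(comp), 10)
  expect_true(all(comp$cp >= 9.29 & comp$cp <= 14.26))
  expect_true(all(comp$adf >= 3.65 & comp$adf <= 6.07))
  expect_equal(comp$tdf, comp$idf + comp$sdf, tolerance = 1e-12)
  expect_true(all(comp$ndf >= comp$adf))
  e <- ing$energy
  expect_true(all(e$ne >= 7.85 & e$ne <= 11.85))
  expect_true(all(e$de >= e$me & e$me >= e$ne))
  # conversion efficiencies bracket the reference ratios
  expect_true(all(e$ne / e$me >= 0.62 & e$ne / e$me <= 0.81))
  expect_true(all(e$me / e$de >= 0.87 & e$me / e$de <= 0.99))

  empty <- sample_ingredients(0)
  expect_equal(nrow(empty$composition), 0)
  expect_equal(nrow(empty$energy), 0)
})

test_that("generation is reproducible from the seed", {
  a <- sample_ingredients(5, seed = 12)
  b <- sample_ingredients(5, seed = 12)
  expect_identical(a, b)

  t1 <- trial_ground_truth(seed = 9, n_ingredients = 2, sows_per_diet = 2)
  t2 <- trial_ground_truth(seed = 9, n_ingredients = 2, sows_per_diet = 2)
  expect_identical(t1, t2)
  s1 <- simulate_trial(t1, resolution_min = 30)
  s2 <- simulate_trial(t2, resolution_min = 30)
  expect_identical(s1$gas, s2$gas)
  expect_identical(s1$collections, s2$collections)

  # ingredient draws do not depend on how many sows are simulated
  t3 <- trial_ground_truth(seed = 9, n_ingredients = 2, sows_per_diet = 5)
  expect_identical(t1$ingredients, t3$ingredients)
})

test_that("study-condition defaults land in the reference ranges", {
  truth <- trial_ground_truth(seed = 2, n_ingredients = 1, sows_per_diet = 3)
  expect_true(all(truth$sows$fed_rq >= 0.93 & truth$sows$fed_rq <= 1.00))
  expect_true(all(truth$sows$fasted_rq >= 0.76 & truth$sows$fasted_rq <= 0.83))
  expect_true(all(truth$sows$fhp_kj_kg075 >= 348 &
                    truth$sows$fhp_kj_kg075 <= 380))
  expect_equal(truth$substitution_rate, 0.289)
  expect_equal(truth$basal$ne, 12.23)
})

test_that("gas traces invert the Brouwer equation and target RQ exactly", {
  truth <- trial_ground_truth(seed = 6, n_ingredients = 1, sows_per_diet = 1,
                              noise = noiseless_cv)
  one <- simulate_sow_period(truth$sows[1, ], truth$diets[2, ],
                             noise = noiseless_cv)
  day0 <- utc(paste(one$sow_period$fed_start, "00:00:00"))
  fed <- one$gas[one$gas$state == "fed", ]
  v <- integrate_gas_day(fed, day0, day0 + 86400)
  urine_fed <- one$collections[one$collections$kind == "urine" &
                                 one$collections$state == "fed", ]
  thp <- brouwer_thp(v$vo2_l, v$vco2_l, v$vch4_l, urine_fed$n_g_d)
  expect_equal(thp, one$truth$thp_kj_d, tolerance = 1e-6)
  expect_equal(respiratory_quotient(v$vo2_l, v$vco2_l),
               truth$sows$fed_rq[1], tolerance = 1e-9)
})

test_that("feed allowance meets the target ME intake", {
  truth <- trial_ground_truth(seed = 8, n_ingredients = 1, sows_per_diet = 1,
                              noise = noiseless_cv)
  one <- simulate_sow_period(truth$sows[1, ], truth$diets[1, ],
                             noise = noiseless_cv)
  me_intake <- truth$diets$me[1] * 1000 * one$truth$dmi /
    truth$sows$bw_kg[1]^0.75
  expect_equal(me_intake, 544, tolerance = 1e-9)
})

test_that("infeasible generator targets fail loudly, naming the culprit", {
  truth <- trial_ground_truth(seed = 3, n_ingredients = 1, sows_per_diet = 1,
                              noise = noiseless_cv)
  bad_diet <- truth$diets[1, ]
  bad_diet$ne <- 40 # NE above ME implies negative heat production
  expect_error(simulate_sow_period(truth$sows[1, ], bad_diet,
                                   noise = noiseless_cv),
               "infeasible.*THP")
  bad_diet2 <- truth$diets[1, ]
  expect_error(simulate_sow_period(truth$sows[1, ], bad_diet2,
                                   noise = noiseless_cv, ch4_pct_de = 50),
               "infeasible.*ch4_pct_de")
})

test_that("trial bundles written to disk reload into the same report", {
  truth <- trial_ground_truth(seed = 14, n_ingredients = 1,
                              sows_per_diet = 2, noise = noiseless_cv)
  dir <- withr::local_tempdir()
  trial <- simulate_trial(truth, dir = dir, resolution_min = 20)
  expect_true(all(file.exists(file.path(
    dir, c("gas.csv", "collections.csv", "sow_periods.csv",
           "diet_truth.csv", "composition.csv", "ingredient_truth.csv",
           "sow_truth.csv")))))
  rep_mem <- run_pipeline(trial, run_stats = FALSE)
  rep_disk <- run_pipeline(dir, run_stats = FALSE)
  expect_equal(rep_disk$ingredient_values$ne, rep_mem$ingredient_values$ne,
               tolerance = 1e-6)
  expect_equal(rep_disk$sow_results$de_mj_kg_dm,
               rep_mem$sow_results$de_mj_kg_dm, tolerance = 1e-6)
})
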