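test_that("reference diet specs parse and conserve calories exactly", {
  specs <- reference_diets()
  expect_named(specs, c("baseline", "eat_lancet", "vegetarian", "vegan"))
  for (s in specs) expect_equal(sum(s$group_fractions), 1, tolerance = 1e-12)
  w <- small_world()
  roster <- w$roster
  baseline <- w$tables$food_per_capita[1, ] / 365
  names(baseline) <- roster$commodity
  total0 <- sum(baseline * roster$energy_kcal_per_kg)
  for (s in specs) {
    use <- if (s$name == "baseline")
      diet_spec("baseline", baseline_group_fractions(baseline, roster)) else s
    intake <- build_diet(use, baseline, roster)
    expect_equal(sum(intake * roster$energy_kcal_per_kg), total0,
                 tolerance = 1e-9)
  }
})

test_that("the baseline's own fractions reproduce the baseline intakes", {
  w <- small_world()
  roster <- w$roster
  baseline <- w$tables$food_per_capita[1, ] / 365
  names(baseline) <- roster$commodity
  spec <- diet_spec("identity", baseline_group_fractions(baseline, roster))
  rebuilt <- build_diet(spec, baseline, roster)
  expect_equal(rebuilt, baseline, tolerance = 1e-9)
})

test_that("the plant-based spec zeroes all animal-product intakes", {
  w <- small_world()
  roster <- w$roster
  baseline <- w$tables$food_per_capita[1, ] / 365
  names(baseline) <- roster$commodity
  vegan <- build_diet(reference_diets()$vegan, baseline, roster)
  expect_true(all(vegan[roster$commodity[roster$is_animal]] == 0))
  # held-constant stimulants are copied from the baseline in every diet
  held <- roster$commodity[roster$is_stimulant]
  for (s in reference_diets())
    expect_identical(build_diet(s, baseline, roster)[held], baseline[held])
})

test_that("within-group allocation follows baseline calorie ratios", {
  w <- small_world()
  roster <- w$roster
  baseline <- w$tables$food_per_capita[1, ] / 365
  names(baseline) <- roster$commodity
  intake <- build_diet(reference_diets()$eat_lancet, baseline, roster)
  # grains_roots members keep their baseline kcal proportions
  g <- roster$commodity[roster$group == "grains_roots"]
  kc0 <- baseline[g] * roster[g, "energy_kcal_per_kg"]
  kc1 <- intake[g] * roster[g, "energy_kcal_per_kg"]
  expect_equal(kc1 / sum(kc1), kc0 / sum(kc0), tolerance = 1e-12)
  # constructed 2:1 case
  b2 <- c(a = 2 / 1000, b = 1 / 1000)
  r2 <- data.frame(commodity = c("a", "b"), group = "grains_roots",
                   energy_kcal_per_kg = 1000, is_stimulant = FALSE,
                   row.names = c("a", "b"))
  s2 <- diet_spec("x", c(grains_roots = 1))
  out <- build_diet(s2, b2, r2)
  expect_equal(unname(out[["a"]] / out[["b"]]), 2)
})

test_that("sugar receives calories but contributes no impact", {
  w <- small_world()
  roster <- w$roster
  baseline <- w$tables$food_per_capita[1, ] / 365
  names(baseline) <- roster$commodity
  intake <- build_diet(reference_diets()$eat_lancet, baseline, roster)
  sugar <- roster$commodity[roster$is_sugar]
  expect_true(all(intake[sugar] > 0))
  wimp <- setNames(rep(1e-11, nrow(roster)), roster$commodity)
  f1 <- diet_footprint(intake, wimp, roster)$total
  wimp2 <- wimp; wimp2[sugar] <- 1  # enormous sugar impact changes nothing
  f2 <- diet_footprint(intake, wimp2, roster)$total
  expect_identical(f1, f2)
})

test_that("diet ordering holds when ruminant impact per kcal dominates", {
  # engineer a world whose ruminant per-kcal impact is maximal by a wide
  # margin (beef-like grazing demand, light dairy/poultry pathways)
  w <- small_world()
  w$feed$grazing[, "ruminant_1"] <- 5e-4
  w$feed$grazing[, "dairyegg_1"] <- 2e-6
  imp <- compute_impacts(w)
  perkcal <- imp$consumption[, 1] / w$roster$energy_kcal_per_kg
  expect_identical(names(which.max(perkcal)), "ruminant_1")
  cd <- compare_diets(reference_diets(), w, imp, "C01")
  de <- setNames(cd$de_per_day, cd$diet)
  expect_gt(de[["baseline"]], de[["eat_lancet"]])
  expect_gt(de[["eat_lancet"]], de[["vegetarian"]])
  expect_gte(de[["vegetarian"]], de[["vegan"]])
  expect_equal(cd$ratio_to_baseline[cd$diet == "baseline"], 1, tolerance = 1e-9)
})

test_that("moving energy from the worst to the best group lowers the footprint", {
  w <- small_world()
  imp <- compute_impacts(w)
  roster <- w$roster
  baseline <- w$tables$food_per_capita[1, ] / 365
  names(baseline) <- roster$commodity
  wimp <- imp$consumption[, 1]
  names(wimp) <- roster$commodity
  gf <- baseline_group_fractions(baseline, roster)
  # per-kcal impact of each allocatable group under the baseline mix
  kcal0 <- baseline * roster$energy_kcal_per_kg
  counted <- !roster$is_stimulant & !roster$is_sugar
  per_kcal_g <- vapply(food_groups(), function(g) {
    in_g <- roster$group == g & counted & kcal0 > 0
    if (!any(in_g)) return(NA_real_)
    sum(baseline[in_g] * wimp[roster$commodity[in_g]]) / sum(kcal0[in_g])
  }, numeric(1))
  hi <- names(which.max(per_kcal_g)); lo <- names(which.min(per_kcal_g))
  gf2 <- gf; gf2[hi] <- gf[hi] - 0.01; gf2[lo] <- gf[lo] + 0.01
  f1 <- diet_footprint(build_diet(diet_spec("a", gf), baseline, roster),
                       wimp, roster)$total
  f2 <- diet_footprint(build_diet(diet_spec("b", gf2), baseline, roster),
                       wimp, roster)$total
  expect_lt(f2, f1)
})

test_that("diet ratios are invariant to rescaling the restore layer", {
  w1 <- uniform_world(d = 1e-3, n_countries = 2)
  w2 <- uniform_world(d = 1e-3, n_countries = 2, life_scale = 4)
  cd1 <- compare_diets(reference_diets(), w1, compute_impacts(w1), 1)
  cd2 <- compare_diets(reference_diets(), w2, compute_impacts(w2), 1)
  expect_equal(cd2$ratio_to_baseline, cd1$ratio_to_baseline, tolerance = 1e-12)
  expect_identical(cd2$de_per_day, cd1$de_per_day * 4)
})

test_that("invalid diet specs are rejected", {
  expect_error(diet_spec("x", c(fruit_veg = 0.5)), "sum to 1")
  expect_error(diet_spec("x", c(fruit_veg = 1.2, legumes_nuts = -0.2)), ">= 0")
  expect_error(diet_spec("x", c(bad_group = 1)), "unknown food groups")
  w <- small_world()
  roster <- w$roster
  baseline <- w$tables$food_per_capita[1, ] / 365
  names(baseline) <- roster$commodity
  b0 <- baseline
  b0[roster$commodity[roster$group == "ruminant_meat"]] <- 0
  expect_error(build_diet(reference_diets()$baseline, b0, roster),
               "no baseline calories")
})
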