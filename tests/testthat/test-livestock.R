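test_that("grazing density aggregates pasture cells by livestock weight", {
  cid <- matrix(1, 1, 2)
  pa <- matrix(c(10, 10), 1, 2)
  # two cells {d, 10d}, head weights 1000:1 -> the heavy cell's value
  d <- matrix(c(4e-10, 4e-9), 1, 2)
  ld <- matrix(c(100, 0.1), 1, 2)
  expect_equal(grazing_life_density(d, pa, ld, cid, 1), 4e-10)
  # uniform density -> that density, either statistic
  du <- matrix(7e-10, 1, 2)
  expect_equal(grazing_life_density(du, pa, ld, cid, 1), 7e-10)
  expect_equal(grazing_life_density(du, pa, ld, cid, 1, stat = "mean"), 7e-10)
  # zero restore density -> 0; no pasture -> defined-absent
  expect_identical(grazing_life_density(d * 0, pa, ld, cid, 1), 0)
  expect_identical(grazing_life_density(d, pa * 0, ld, cid, 1), NA_real_)
})

test_that("grazing component is the density-requirement product", {
  expect_equal(grazing_component(4e-10, 0.005), 2e-12)
  expect_identical(grazing_component(4e-10, 0), 0)           # monogastrics
  expect_equal(grazing_component(4e-10, 0.01), 2 * grazing_component(4e-10, 0.005))
  expect_error(grazing_component(4e-10, NA, label = "C01:ruminant_1"),
               "C01:ruminant_1")
  expect_identical(grazing_component(NA_real_, 0), 0)  # no pasture, no need
})

test_that("feed component sums requirement x consumption impact over feed crops", {
  expect_identical(feed_component(c(grain_1 = 0, legume_1 = 0),
                                  c(grain_1 = 1e-10, legume_1 = 2e-10)), 0)
  expect_equal(feed_component(c(grain_1 = 3), c(grain_1 = 2e-11)), 6e-11)
  expect_error(feed_component(c(grain_1 = 3), c(legume_1 = 1e-11)), "grain_1")
  expect_error(feed_component(c(grain_1 = -1), c(grain_1 = 1e-11)), ">= 0")
})

test_that("animal impacts add components and keep the decomposition", {
  v <- animal_production_impact(2e-12, 6e-11)
  expect_equal(v$value, 6.2e-11)
  expect_identical(v$crop, 0)
  expect_equal(v$grazing + v$feed, v$value)
  expect_identical(animal_production_impact(0, 0)$value, 0)
})

test_that("autarkic feed valuation equals domestic production impacts", {
  w <- uniform_world(d = 1e-3)
  imp <- compute_impacts(w)
  feeds <- w$roster$commodity[w$roster$is_feed_crop]
  # no trade: consumption = production for the feed crops, so the feed
  # component is exactly sum_f req x domestic production impact
  expect_identical(imp$consumption[feeds, ], imp$production[feeds, ])
  for (a in w$roster$commodity[w$roster$is_animal]) {
    req <- w$feed$requirement[1, a, ]
    expect_equal(unname(imp$feed[a, 1]),
                 sum(req * imp$production[feeds, 1]), tolerance = 1e-15)
  }
})

test_that("an engineered ruminant:grain impact ratio is recovered", {
  d <- 1e-3
  w <- uniform_world(d = d)
  v_g <- uniform_expected_vegetal(w, "grain_1", d)
  v_l <- uniform_expected_vegetal(w, "legume_1", d)
  R <- 340
  req <- list(ruminant_1 = c(grain_1 = 2, legume_1 = 0.5))
  G <- (R * v_g - 2 * v_g - 0.5 * v_l) / d
  w2 <- uniform_world(d = d, G_override = list(ruminant_1 = G),
                      req_override = req)
  imp <- compute_impacts(w2)
  ratio <- imp$production["ruminant_1", 1] / imp$production["grain_1", 1]
  expect_equal(unname(ratio), R, tolerance = 1e-6)
})

test_that("animal impacts are linear in grazing and feed requirements", {
  w <- uniform_world(d = 1e-3)
  base <- compute_impacts(w)
  w2 <- w
  w2$feed$grazing <- w$feed$grazing * 2
  w2$feed$requirement <- w$feed$requirement * 2
  doubled <- compute_impacts(w2)
  animals <- w$roster$commodity[w$roster$is_animal]
  expect_equal(doubled$grazing[animals, ], base$grazing[animals, ] * 2)
  expect_equal(doubled$feed[animals, ], base$feed[animals, ] * 2)
})

test_that("sourcing feed from a lower-impact origin shrinks the feed component", {
  # consumption impacts for the feed crop under two provenance portfolios
  v_origin <- c(5e-10, 1e-11)  # high-impact vs low-impact origin
  S_high <- matrix(c(1, 0), 1, 2)
  S_low <- matrix(c(0, 1), 1, 2)
  w_high <- consumption_perkg_impact(S_high, v_origin)$value
  w_low <- consumption_perkg_impact(S_low, v_origin)$value
  f_high <- feed_component(c(soy = 3), c(soy = w_high))
  f_low <- feed_component(c(soy = 3), c(soy = w_low))
  expect_lt(f_low, f_high)
})
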