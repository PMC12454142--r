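test_that("identical config and seed give byte-identical worlds", {
  cfg <- small_config(seed = 11)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  w3 <- generate_world(small_config(seed = 12))
  expect_false(identical(serialize(w1, NULL), serialize(w3, NULL)))
})

test_that("gridded production sums match the national tables", {
  w <- small_world()
  cid <- raster_values(w$country_id)
  for (cm in names(w$production)) {
    v <- raster_values(w$production[[cm]])
    sums <- vapply(seq_along(w$countries), function(i) sum(v[cid == i]), 0)
    expect_equal(sums, unname(w$tables$production[, cm]), tolerance = 1e-9)
  }
})

test_that("supply accounts balance exactly with no stock residual", {
  for (seed in c(1, 5)) {
    w <- small_world(seed)
    tb <- w$tables
    comms <- colnames(tb$production)
    imports <- sapply(comms, function(cm) colSums(tb$trade[[cm]]))
    exports <- sapply(comms, function(cm) rowSums(tb$trade[[cm]]))
    bal <- tb$production + imports - exports - tb$feed_use - tb$food
    expect_lt(max(abs(bal)), 1e-9 * max(tb$production))
    expect_true(all(tb$production >= 0) && all(tb$food >= 0) &&
                  all(tb$feed_use >= 0))
    # exports never exceed supply
    expect_true(all(exports <= tb$production + imports + 1e-9))
  }
})

test_that("autarky mode has no trade and food = production - feed exactly", {
  w <- generate_world(small_config(trade_mode = "autarky"))
  for (cm in colnames(w$tables$production))
    expect_true(all(w$tables$trade[[cm]] == 0))
  expect_equal(w$tables$food, w$tables$production - w$tables$feed_use)
})

test_that("reexport mode yields a country with zero production but exports", {
  w <- generate_world(small_config(trade_mode = "reexport"))
  a1 <- w$roster$commodity[w$roster$is_animal][1]
  expect_identical(w$tables$production[2, a1], 0)
  expect_gt(rowSums(w$tables$trade[[a1]])[2], 0)
})

test_that("baseline food supply delivers the configured daily energy", {
  w <- small_world()
  kcal_day <- as.numeric(w$tables$food_per_capita %*%
                           w$roster$energy_kcal_per_kg) / 365
  expect_equal(kcal_day, rep(3911, length(w$countries)), tolerance = 1e-9)
})

test_that("tropics gradient raises restore density in low-latitude rows", {
  w <- generate_world(world_config(grid_rows = 30, grid_cols = 30,
                                   n_countries = 4, n_species = 150, seed = 3,
                                   tropics_gradient = TRUE))
  d <- raster_values(w$life_density)
  lo <- mean(d[21:30, ])   # low-latitude third (bottom rows)
  hi <- mean(d[1:10, ])    # high-latitude third
  expect_gt(lo, hi)
})

test_that("species sets satisfy their habitat invariants", {
  cfg <- small_config(seed = 9)
  sp <- generate_species_set(cfg)
  expect_length(sp, cfg$n_species)
  for (s in sp) {
    expect_true(s$A > 0)
    expect_true(s$A <= s$A0 + 1e-9)
    expect_true(s$A0 <= length(s$cells) * cfg$cell_area + 1e-9)
  }
  # all-endemic config: every range is small
  sp_e <- generate_species_set(small_config(seed = 9, endemic_fraction = 1))
  expect_true(all(vapply(sp_e, function(s) length(s$cells), 0L) <= 20))
  # seeded reproducibility
  expect_identical(generate_species_set(cfg), sp)
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(n_commodities = 3, n_animal_commodities = 3),
               "n_animal_commodities")
  expect_error(world_config(z = 0), "z must be")
  expect_error(world_config(n_species = 0), "counts")
  expect_error(world_config(n_countries = 2, trade_mode = "reexport"),
               "reexport")
})

test_that("standalone table generation matches the world's tables", {
  cfg <- small_config(seed = 4)
  w <- generate_world(cfg)
  tb <- generate_supply_and_trade(cfg)
  expect_identical(tb$production, w$tables$production)
  expect_identical(tb$trade, w$tables$trade)
  expect_identical(tb$feed, w$feed)
})

test_that("random trade networks keep exports within supply", {
  for (seed in 1:20) {
    net <- random_trade_network(sample(2:20, 1), seed)
    supply <- net$production + colSums(net$trade)
    expect_true(all(rowSums(net$trade) <= supply + 1e-9))
    expect_true(all(net$use >= -1e-9))
  }
})
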