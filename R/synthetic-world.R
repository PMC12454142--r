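#' Configuration for a synthetic world
#'
#' Defines the dimensions and statistical structure of a seeded synthetic
#' world: a species-derived extinction-risk ("restore") raster, gridded
#' agricultural layers, and balanced FAO-style supply/trade tables. The
#' generator emulates the *structure* of the real data (overlapping species
#' ranges scored with a power-law extinction model, per-commodity production
#' and yield grids, pasture and livestock density, balanced country accounts),
#' not real biogeography.
#'
#' @param grid_rows,grid_cols grid dimensions; row 1 is the highest-latitude
#'   band, the last row the lowest ("tropics").
#' @param cell_area area of every cell in km2 (abstract equal-area grid).
#' @param n_countries,n_commodities,n_animal_commodities,n_species counts
#'   (all >= 1 except `n_animal_commodities` which may be 0;
#'   `n_animal_commodities < n_commodities`).
#' @param z exponent of the extinction power law p(A) = 1 - (A/A0)^z; > 0.
#' @param seed integer seed; identical (config, seed) gives a byte-identical
#'   world.
#' @param tropics_gradient if `TRUE`, species richness and endemism increase
#'   toward low-latitude rows, producing the tropical gradient in restore
#'   densities seen in real data.
#' @param endemic_fraction fraction of species given narrow ranges.
#' @param tolerant_fraction probability that a species tolerates cropland
#'   (and, independently, pasture) as habitat.
#' @param trade_mode `"random"` (re-export chains possible but not forced),
#'   `"autarky"` (no trade) or `"reexport"` (forces a production-less
#'   re-exporting intermediary on the first animal commodity; requires
#'   `n_countries >= 3` and at least one animal commodity).
#' @param export_fraction upper bound on the share of a country's exportable
#'   supply traded away per commodity.
#' @param baseline_kcal_day baseline mean daily per-capita energy intake the
#'   tables are calibrated to (kcal/person/day); default 3911.
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(grid_rows = 40, grid_cols = 40, cell_area = 100,
                         n_countries = 6, n_commodities = 10,
                         n_animal_commodities = 3, n_species = 80,
                         z = 0.25, seed = 1L, tropics_gradient = TRUE,
                         endemic_fraction = 0.35, tolerant_fraction = 0.25,
                         trade_mode = c("random", "autarky", "reexport"),
                         export_fraction = 0.2,
                         baseline_kcal_day = 3911) {
  trade_mode <- match.arg(trade_mode)
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              cell_area = cell_area, n_countries = as.integer(n_countries),
              n_commodities = as.integer(n_commodities),
              n_animal_commodities = as.integer(n_animal_commodities),
              n_species = as.integer(n_species), z = z, seed = as.integer(seed),
              tropics_gradient = isTRUE(tropics_gradient),
              endemic_fraction = endemic_fraction,
              tolerant_fraction = tolerant_fraction,
              trade_mode = trade_mode, export_fraction = export_fraction,
              baseline_kcal_day = baseline_kcal_day)
  with(cfg, {
    if (grid_rows < 1L || grid_cols < 1L) stop("grid dimensions must be >= 1", call. = FALSE)
    if (cell_area <= 0) stop("cell_area must be > 0", call. = FALSE)
    if (n_countries < 1L || n_commodities < 1L || n_species < 1L)
      stop("counts must be >= 1", call. = FALSE)
    if (n_animal_commodities < 0L || n_animal_commodities >= n_commodities)
      stop("need n_animal_commodities < n_commodities (at least one vegetal commodity)",
           call. = FALSE)
    if (z <= 0) stop("power-law exponent z must be > 0", call. = FALSE)
    if (endemic_fraction < 0 || endemic_fraction > 1 ||
        tolerant_fraction < 0 || tolerant_fraction > 1)
      stop("fractions must lie in [0, 1]", call. = FALSE)
    if (trade_mode == "reexport" && (n_countries < 3L || n_animal_commodities < 1L))
      stop("reexport mode needs >= 3 countries and >= 1 animal commodity", call. = FALSE)
  })
  structure(cfg, class = "world_config")
}

# deterministic per-stage sub-seed so adding a generator stage never perturbs
# the draws of the others
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

food_groups <- function() {
  c("fruit_veg", "legumes_nuts", "grains_roots", "dairy_eggs",
    "ruminant_meat", "poultry_pig", "sugar_other")
}

#' Commodity roster for a synthetic world
#'
#' Builds the commodity table: names, food-group membership (the seven groups
#' used in the diet analyses), energy density, protein fraction, base yield,
#' and flags (animal / ruminant / sugar / stimulant-or-spice / feed crop).
#' The first grain and first legume act as feed crops; stimulants are held
#' constant in diet scenarios; sugar is excluded from consumption impacts by
#' default.
#'
#' @param n_commodities,n_animal_commodities total and animal commodity counts.
#' @return data.frame, one row per commodity.
#' @export
commodity_roster <- function(n_commodities, n_animal_commodities) {
  n_veg <- n_commodities - n_animal_commodities
  veg_types <- c("grain", "fruitveg", "legume", "sugar", "stimulant")
  veg_cycle <- c(veg_types, rep(c("grain", "fruitveg", "legume"), length.out =
                                  max(0, n_veg - length(veg_types))))
  veg_slots <- veg_cycle[seq_len(n_veg)]
  ani_slots <- rep(c("ruminant", "porkpoultry", "dairyegg"),
                   length.out = n_animal_commodities)
  slots <- c(veg_slots, ani_slots)
  counts <- stats::ave(seq_along(slots), slots, FUN = seq_along)
  name <- paste0(slots, "_", counts)
  spec <- list(
    grain       = list(group = "grains_roots",  e = 3400, p = 0.12, yield = 300),
    fruitveg    = list(group = "fruit_veg",     e = 500,  p = 0.02, yield = 1500),
    legume      = list(group = "legumes_nuts",  e = 3300, p = 0.24, yield = 150),
    sugar       = list(group = "sugar_other",   e = 3800, p = 0.00, yield = 5000),
    stimulant   = list(group = "sugar_other",   e = 900,  p = 0.10, yield = 80),
    ruminant    = list(group = "ruminant_meat", e = 2500, p = 0.26, yield = NA),
    porkpoultry = list(group = "poultry_pig",   e = 2100, p = 0.25, yield = NA),
    dairyegg    = list(group = "dairy_eggs",    e = 1400, p = 0.20, yield = NA))
  df <- data.frame(
    commodity = name,
    type = slots,
    group = vapply(slots, function(s) spec[[s]]$group, ""),
    energy_kcal_per_kg = vapply(slots, function(s) spec[[s]]$e, 0),
    protein_fraction = vapply(slots, function(s) spec[[s]]$p, 0),
    base_yield_t_per_km2 = vapply(slots, function(s) spec[[s]]$yield, 0),
    is_animal = slots %in% c("ruminant", "porkpoultry", "dairyegg"),
    is_ruminant = slots == "ruminant",
    is_sugar = slots == "sugar",
    is_stimulant = slots == "stimulant",
    stringsAsFactors = FALSE)
  df$is_feed_crop <- df$commodity %in% c(name[slots == "grain"][1],
                                         name[slots == "legume"][1])
  df$is_feed_crop[is.na(df$is_feed_crop)] <- FALSE
  rownames(df) <- df$commodity
  df
}

country_names <- function(n) sprintf("C%02d", seq_len(n))

# sample() that never falls back to sample.int() on a length-1 candidate set
resample <- function(x, size) x[sample.int(length(x), size)]

# nearest-centre (Voronoi) partition of the grid into contiguous-ish countries
generate_country_map <- function(config) {
  set.seed(substream_seed(config$seed, "country_map"))
  nr <- config$grid_rows; nc <- config$grid_cols; n <- config$n_countries
  idx <- sample.int(nr * nc, n, replace = nr * nc < n)
  cr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  d <- array(0, c(nr, nc, n))
  for (k in seq_len(n)) d[, , k] <- (rows - cr[k])^2 + (cols - cc[k])^2
  id <- apply(d, c(1, 2), which.min)
  raster_grid(matrix(as.numeric(id), nr, nc), layer = "country_id", units = "country-id")
}

# per-cell area fractions: natural + pasture + crop_total = 1; the split of
# cropland between commodities is demand-driven and happens later
generate_landcover <- function(config) {
  set.seed(substream_seed(config$seed, "landcover"))
  nr <- config$grid_rows; nc <- config$grid_cols
  n <- nr * nc
  natural <- matrix(stats::runif(n, 0.25, 0.75), nr, nc)
  ag <- 1 - natural
  pasture_share <- matrix(stats::runif(n, 0.25, 0.45), nr, nc)
  pasture <- ag * pasture_share
  crop_total <- ag - pasture
  list(natural = natural, pasture = pasture, crop_total = crop_total,
       cell_area = config$cell_area)
}

#' Generate a synthetic species set
#'
#' Draws `n_species` species with circular ranges — a configurable fraction
#' narrow-ranged ("endemic") — and per-land-cover habitat suitability:
#' natural cover is always suitable, cropland and pasture each tolerated with
#' probability `tolerant_fraction`. The pristine area of habitat `A0` is the
#' range area; current habitat `A` counts natural plus tolerated agricultural
#' area within the range. With `tropics_gradient`, range centres concentrate
#' toward low-latitude rows and endemics more strongly so.
#'
#' @param config a [world_config()].
#' @param landcover land-cover fraction layers (generated from `config` when
#'   `NULL`).
#' @return list of species records: `id`, `cells` (cell indices of the range),
#'   `A0`, `A` (km2), `suit_natural`, `suit_cropland`, `suit_pasture`.
#' @export
generate_species_set <- function(config, landcover = NULL) {
  stopifnot(inherits(config, "world_config"))
  if (is.null(landcover)) landcover <- generate_landcover(config)
  set.seed(substream_seed(config$seed, "species"))
  nr <- config$grid_rows; nc <- config$grid_cols
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  t_ramp <- if (nr > 1) (seq_len(nr) - 1) / (nr - 1) else rep(0, nr)
  w_rich <- if (config$tropics_gradient) 1 + 3 * t_ramp else rep(1, nr)
  w_end  <- if (config$tropics_gradient) (1 + 3 * t_ramp)^2 else rep(1, nr)
  species <- vector("list", config$n_species)
  for (s in seq_len(config$n_species)) {
    endemic <- stats::runif(1) < config$endemic_fraction
    r0 <- sample.int(nr, 1, prob = if (endemic) w_end else w_rich)
    c0 <- sample.int(nc, 1)
    radius <- if (endemic) stats::runif(1, 0.8, 2.2)
              else stats::runif(1, 0.15, 0.35) * max(3, min(nr, nc))
    cells <- which((rows - r0)^2 + (cols - c0)^2 <= radius^2)
    if (length(cells) == 0L) cells <- (c0 - 1L) * nr + r0
    suit_crop <- stats::runif(1) < config$tolerant_fraction
    suit_past <- stats::runif(1) < config$tolerant_fraction
    A0 <- length(cells) * config$cell_area
    A <- sum(landcover$natural[cells] +
               (if (suit_crop) landcover$crop_total[cells] else 0) +
               (if (suit_past) landcover$pasture[cells] else 0)) * config$cell_area
    species[[s]] <- list(id = s, cells = cells, A0 = A0, A = A,
                         suit_natural = TRUE, suit_cropland = suit_crop,
                         suit_pasture = suit_past, endemic = endemic)
  }
  species
}

generate_livestock <- function(config) {
  set.seed(substream_seed(config$seed, "livestock"))
  nr <- config$grid_rows; nc <- config$grid_cols
  raster_grid(matrix(50 * exp(stats::rnorm(nr * nc, 0, 0.5)), nr, nc),
              layer = "livestock_density", units = "head_per_km2")
}

# feed requirements (kg feed crop per kg product) and grazing requirements
# (km2-yr per kg product) by country x animal commodity; magnitudes follow
# typical feed-conversion ratios and land footprints: beef-like products
# ~200 m2-yr/kg of pasture, dairy/eggs ~2 m2-yr/kg, monogastrics none
generate_feed_tables <- function(config, roster) {
  set.seed(substream_seed(config$seed, "feed_tables"))
  countries <- country_names(config$n_countries)
  animals <- roster$commodity[roster$is_animal]
  feeds <- roster$commodity[roster$is_feed_crop]
  req <- array(0, dim = c(length(countries), length(animals), length(feeds)),
               dimnames = list(countries, animals, feeds))
  base_req <- list(ruminant = c(grain = 2.0, legume = 0.5),
                   porkpoultry = c(grain = 2.5, legume = 0.8),
                   dairyegg = c(grain = 0.8, legume = 0.2))
  base_G <- c(ruminant = 2e-4, porkpoultry = 0, dairyegg = 2e-6)
  G <- matrix(0, length(countries), length(animals),
              dimnames = list(countries, animals))
  for (a in animals) {
    ty <- roster[a, "type"]
    for (f in feeds) {
      fty <- roster[f, "type"]
      b <- base_req[[ty]][[fty]]
      if (!is.null(b) && !is.na(b))
        req[, a, f] <- b * exp(stats::rnorm(length(countries), 0, 0.1))
    }
    G[, a] <- base_G[[ty]] * exp(stats::rnorm(length(countries), 0, 0.2))
  }
  list(requirement = req, grazing = G)
}

# country x commodity accounts: food targets follow an FAO-style baseline
# calorie-share profile (grains-dominated, a few percent of energy from
# ruminant meat); production is food target + feed demand so the balance
# P + imports - exports - feed - food = 0 is exact, with no stock residual.
# National food energy is sized so crop-area demand at base yields fills the
# country's cropland, keeping effective yields at realistic magnitudes.
generate_accounts <- function(config, roster, crop_area_by_country) {
  countries <- country_names(config$n_countries)
  comms <- roster$commodity
  nC <- length(countries); nM <- length(comms)

  set.seed(substream_seed(config$seed, "food_targets"))
  group_share <- c(fruit_veg = 0.06, legumes_nuts = 0.12, grains_roots = 0.35,
                   dairy_eggs = 0.13, ruminant_meat = 0.04, poultry_pig = 0.10,
                   sugar_other = 0.20)
  present <- intersect(names(group_share), unique(roster$group))
  gs <- group_share[present] / sum(group_share[present])
  tshare <- matrix(0, nC, nM, dimnames = list(countries, comms))
  for (i in seq_len(nC)) for (g in present) {
    in_g <- which(roster$group == g)
    wgt <- stats::runif(length(in_g), 0.5, 1.5)
    tshare[i, in_g] <- gs[[g]] * wgt / sum(wgt)
  }
  E <- roster$energy_kcal_per_kg
  animals <- comms[roster$is_animal]
  feeds <- comms[roster$is_feed_crop]
  veg <- comms[!roster$is_animal]
  feed <- generate_feed_tables(config, roster)

  # per unit of national food energy (K = 1 kcal/yr): food masses, animal
  # production, feed demand, vegetal production, cropland area demand
  food1 <- tshare / rep(E * 1000, each = nC)  # tonnes per kcal/yr
  P1 <- matrix(0, nC, nM, dimnames = list(countries, comms))
  P1[, animals] <- food1[, animals]
  feed1 <- matrix(0, nC, nM, dimnames = list(countries, comms))
  for (f in feeds) {
    reqf <- matrix(feed$requirement[, , f], nC, length(animals))
    feed1[, f] <- rowSums(reqf * P1[, animals, drop = FALSE])
  }
  P1[, veg] <- food1[, veg] + feed1[, veg]
  area1 <- as.numeric(P1[, veg, drop = FALSE] %*%
                        (1 / roster[veg, "base_yield_t_per_km2"]))
  K <- crop_area_by_country / pmax(area1, .Machine$double.xmin)  # kcal/yr

  food_target <- food1 * K
  P <- P1 * K
  feed_use <- feed1 * K
  if (config$trade_mode == "reexport") {
    # production-less re-exporting intermediary on the first animal commodity
    food_target[2, animals[1]] <- 0
    P[2, animals[1]] <- 0
    for (f in feeds) {
      reqf <- matrix(feed$requirement[2, , f], 1, length(animals))
      feed_use[2, f] <- sum(reqf * P[2, animals])
    }
    P[2, veg] <- food_target[2, veg] + feed_use[2, veg]
  }

  set.seed(substream_seed(config$seed, "trade"))
  trade <- list()
  for (cm in comms) {
    T <- matrix(0, nC, nC, dimnames = list(countries, countries))
    if (config$trade_mode != "autarky" && nC > 1) {
      exportable <- pmax(P[, cm] - feed_use[, cm], 0)
      for (o in seq_len(nC)) {
        k <- sample.int(min(3L, nC - 1L), 1)
        partners <- resample(setdiff(seq_len(nC), o), k)
        frac <- config$export_fraction * stats::runif(1)
        split <- stats::rgamma(k, 1); split <- split / sum(split)
        T[o, partners] <- exportable[o] * frac * split
      }
    }
    trade[[cm]] <- T
  }
  if (config$trade_mode == "reexport") {
    a1 <- animals[1]
    x <- 0.5 * P[1, a1]
    trade[[a1]][1, 2] <- trade[[a1]][1, 2] + x
    trade[[a1]][2, 3] <- trade[[a1]][2, 3] + 0.4 * x
  }

  imports <- sapply(comms, function(cm) colSums(trade[[cm]]))
  exports <- sapply(comms, function(cm) rowSums(trade[[cm]]))
  if (nC == 1) { imports <- matrix(imports, 1); exports <- matrix(exports, 1) }
  dimnames(imports) <- dimnames(exports) <- dimnames(P)
  food <- P + imports - exports - feed_use
  if (any(food < -1e-9 * max(P)))
    stop("internal error: generated tables do not balance to nonnegative food",
         call. = FALSE)
  food[food < 0] <- 0

  pop <- as.numeric((food * 1000) %*% E) / (config$baseline_kcal_day * 365)
  pop <- pmax(pop, 1e-9)
  names(pop) <- countries
  food_pc <- sweep(food * 1000, 1, pop, "/")  # kg/person/yr

  list(production = P, trade = trade, feed_use = feed_use, food = food,
       food_per_capita = food_pc, population = pop,
       conversion = data.frame(commodity = comms, primary = comms, factor = 1,
                               stringsAsFactors = FALSE),
       feed = feed)
}

#' Generate balanced FAO-style supply and trade tables
#'
#' Produces country x commodity production, bilateral trade, feed use, food
#' supply and population tables that balance exactly:
#' `production + imports - exports - feed - food = 0` for every country and
#' commodity (no stock residual). Food-supply calorie shares follow an
#' FAO-style baseline group profile; vegetal production covers food plus feed
#' demand; population is derived so baseline food supply delivers exactly
#' `baseline_kcal_day` kcal/person/day in every country.
#'
#' @param config a [world_config()].
#' @return list with elements `production`, `trade` (list of origin x
#'   destination matrices per commodity), `feed_use`, `food`,
#'   `food_per_capita`, `population`, `conversion`, and the `feed`
#'   requirement tables used.
#' @export
generate_supply_and_trade <- function(config) {
  stopifnot(inherits(config, "world_config"))
  roster <- commodity_roster(config$n_commodities, config$n_animal_commodities)
  cid <- raster_values(generate_country_map(config))
  landcover <- generate_landcover(config)
  generate_accounts(config, roster,
                    country_crop_area(landcover, cid, config$n_countries))
}

country_crop_area <- function(landcover, cid, n_countries) {
  ca <- landcover$crop_total * landcover$cell_area
  vapply(seq_len(n_countries), function(i) sum(ca[cid == i]), 0)
}

# demand-driven cropland allocation and gridded production: within each
# country, each vegetal commodity's share of cropland is proportional to its
# required area at base yield, so relative yields across commodities keep
# their characteristic ratios; cell-level yield noise is rescaled so national
# production sums match the accounts exactly
generate_production_layers <- function(config, roster, landcover, country_id, P) {
  set.seed(substream_seed(config$seed, "yields"))
  nr <- config$grid_rows; nc <- config$grid_cols
  veg <- roster$commodity[!roster$is_animal]
  cid <- raster_values(country_id)
  nC <- config$n_countries
  area_demand <- sweep(P[, veg, drop = FALSE], 2,
                       roster[veg, "base_yield_t_per_km2"], "/")
  share <- area_demand / rowSums(area_demand)
  production <- list(); harvested <- list()
  crop_area <- landcover$crop_total * config$cell_area
  for (cm in veg) {
    area <- crop_area * matrix(share[, cm][cid], nr, nc)
    noise <- matrix(exp(stats::rnorm(nr * nc, 0, 0.15)), nr, nc)
    raw <- area * noise
    raw_nat <- vapply(seq_len(nC), function(i) sum(raw[cid == i]), 0)
    sc <- ifelse(raw_nat > 0, P[, cm] / raw_nat, 0)
    production[[cm]] <- raster_grid(raw * matrix(sc[cid], nr, nc),
                                    layer = paste0("production_", cm),
                                    units = "tonnes")
    harvested[[cm]] <- raster_grid(area, layer = paste0("harvested_area_", cm),
                                   units = "km2")
  }
  list(production = production, harvested_area = harvested)
}

#' Generate a complete synthetic world
#'
#' Assembles all layers and tables into one mutually consistent object: the
#' country map, land-cover fractions, species set, LIFE-style restore-density
#' raster, per-commodity production and harvested-area rasters, livestock
#' density, pasture area, balanced supply/trade tables, feed/grazing
#' requirement tables and the commodity roster. National sums of the gridded
#' production equal the tables' production entries; everything is
#' deterministic under `config$seed`.
#'
#' @param config a [world_config()].
#' @return list of class `synthetic_world`.
#' @examples
#' w <- generate_world(world_config(grid_rows = 8, grid_cols = 8,
#'                                  n_countries = 2, n_species = 10, seed = 1))
#' names(w)
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  roster <- commodity_roster(config$n_commodities, config$n_animal_commodities)
  country_id <- generate_country_map(config)
  landcover <- generate_landcover(config)
  species <- generate_species_set(config, landcover)
  life <- life_restore_density(species, landcover, config$z)
  cid <- raster_values(country_id)
  accounts <- generate_accounts(
    config, roster, country_crop_area(landcover, cid, config$n_countries))
  prod_layers <- generate_production_layers(config, roster, landcover,
                                            country_id, accounts$production)
  livestock <- generate_livestock(config)
  pasture_area <- raster_grid(landcover$pasture * config$cell_area,
                              layer = "pasture_area", units = "km2")
  structure(list(
    config = config, countries = country_names(config$n_countries),
    roster = roster, country_id = country_id, landcover = landcover,
    species = species, life_density = life,
    production = prod_layers$production,
    harvested_area = prod_layers$harvested_area,
    livestock_density = livestock, pasture_area = pasture_area,
    tables = accounts[setdiff(names(accounts), "feed")],
    feed = accounts$feed
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_world> %dx%d cells (%g km2 each), %d countries, %d commodities (%d animal), %d species, seed %d\n",
    cfg$grid_rows, cfg$grid_cols, cfg$cell_area, cfg$n_countries,
    cfg$n_commodities, cfg$n_animal_commodities, cfg$n_species, cfg$seed))
  invisible(x)
}

#' Random balanced trade network
#'
#' Generates a single-commodity trade network (production vector plus
#' bilateral flow matrix, cycles and production-less re-exporters allowed)
#' in which every country's exports stay below its supply, for exercising
#' the provenance solver on arbitrary topologies.
#'
#' @param n_countries number of countries (>= 2).
#' @param seed integer seed.
#' @param n_flows number of flow draws (default `3 * n_countries`).
#' @return list with `production`, `trade` (origin x destination matrix) and
#'   `use` (domestic use = supply - exports).
#' @export
random_trade_network <- function(n_countries, seed, n_flows = 3L * n_countries) {
  stopifnot(n_countries >= 2)
  set.seed(as.integer(seed))
  P <- stats::runif(n_countries, 0, 100)
  nz <- sample.int(n_countries, max(0L, min(n_countries - 1L,
                                            stats::rbinom(1, n_countries, 0.2))))
  P[nz] <- 0
  if (all(P == 0)) P[1] <- 50
  T <- matrix(0, n_countries, n_countries,
              dimnames = list(country_names(n_countries), country_names(n_countries)))
  for (k in seq_len(n_flows)) {
    o <- sample.int(n_countries, 1)
    d <- resample(setdiff(seq_len(n_countries), o), 1)
    supply_o <- P[o] + sum(T[, o])
    headroom <- 0.9 * supply_o - sum(T[o, ])
    if (headroom > 0) T[o, d] <- T[o, d] + stats::runif(1, 0, headroom / 2)
  }
  supply <- P + colSums(T)
  list(production = P, trade = T, use = supply - rowSums(T))
}
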