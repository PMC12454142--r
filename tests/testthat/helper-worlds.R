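# Shared fixtures, built in code.

small_config <- function(seed = 1, ...) {
  defaults <- list(grid_rows = 12, grid_cols = 12, n_countries = 3,
                   n_commodities = 10, n_animal_commodities = 3,
                   n_species = 30, seed = seed)
  do.call(world_config, utils::modifyList(defaults, list(...)))
}

# cached default small world (generation is cheap but used by many tests)
small_world_cache <- new.env(parent = emptyenv())
small_world <- function(seed = 1, ...) {
  key <- paste(seed, paste(c(...), collapse = "_"), sep = "_")
  if (is.null(small_world_cache[[key]]))
    small_world_cache[[key]] <- generate_world(small_config(seed, ...))
  small_world_cache[[key]]
}

# Overwrite a generated world with spatially uniform layers: constant restore
# density d, constant per-commodity yields, optional grazing/feed-requirement
# overrides, no trade. True per-kg impacts are then known in closed form:
#   vegetal:  d / (yield * 1000)
#   animal :  G * d + sum_f req_f * d / (yield_f * 1000)
uniform_world <- function(d = 1e-3, seed = 1, n_countries = 1,
                          G_override = NULL, req_override = NULL,
                          life_scale = 1, yield_scale = 1) {
  cfg <- world_config(grid_rows = 6, grid_cols = 6, n_countries = n_countries,
                      n_commodities = 10, n_animal_commodities = 3,
                      n_species = 10, seed = seed, trade_mode = "autarky")
  w <- generate_world(cfg)
  w$life_density$values[] <- d * life_scale
  w$livestock_density$values[] <- 10
  w$pasture_area$values[] <- 20
  veg <- w$roster$commodity[!w$roster$is_animal]
  for (cm in veg) {
    y <- w$roster[cm, "base_yield_t_per_km2"] * yield_scale
    a <- 5  # km2 harvested per cell
    w$harvested_area[[cm]]$values[] <- a
    w$production[[cm]]$values[] <- y * a
    cid <- raster_values(w$country_id)
    w$tables$production[, cm] <- vapply(
      seq_len(n_countries), function(i) sum((y * a) * (cid == i)), 0)
  }
  for (a in w$roster$commodity[w$roster$is_animal]) {
    if (!is.null(G_override) && a %in% names(G_override))
      w$feed$grazing[, a] <- G_override[[a]]
    if (!is.null(req_override) && a %in% names(req_override)) {
      w$feed$requirement[, a, ] <- 0
      for (f in names(req_override[[a]]))
        w$feed$requirement[, a, f] <- req_override[[a]][[f]]
    }
  }
  w
}

uniform_expected_vegetal <- function(w, cm, d = 1e-3) {
  d / (w$roster[cm, "base_yield_t_per_km2"] * 1000)
}

generate_landcover_fixture <- function(seed = 3) {
  lifecost:::generate_landcover(small_config(seed))
}

# plain-quantile oracle: expand each value `weight` times, take the type-1
# sample quantile (index ceiling(q * N), at least 1)
expand_quantile_oracle <- function(values, weights, q) {
  x <- sort(rep(values, times = weights))
  vapply(q, function(qi) x[max(1L, ceiling(qi * length(x)))], numeric(1))
}
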