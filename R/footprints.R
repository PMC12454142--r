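#' Per-capita consumption footprint of a country
#'
#' Total extinction impact of a person's yearly food consumption:
#' `sum_c q[i,c] x w[i,c]` over consumed commodities, with `q` the food
#' supply (kg/person/yr, waste embedded as in FAO food-balance accounting)
#' and `w` the consumption-basis per-kg impact. Sugar is excluded by default
#' (its supply chains cannot be traced reliably); the flag leaves
#' production-side sugar analyses untouched. Breakdowns by food group and by
#' ultimate origin (domestic vs imported, feed resolved to its true origins)
#' are returned alongside the implied land area.
#'
#' @param world a `synthetic_world`.
#' @param impacts matching `impact_set`.
#' @param country country name (e.g. `"C01"`) or index.
#' @param include_sugar include sugar-flagged commodities (default `FALSE`).
#' @return list of class `footprint_record`: `country`, `total`
#'   (dE/person/yr), `by_group`, `by_origin` (`domestic`, `imported`),
#'   `domestic_share`, `imported_share`, `implied_land_km2`,
#'   `by_commodity`.
#' @export
per_capita_footprint <- function(world, impacts, country,
                                 include_sugar = FALSE) {
  i <- if (is.character(country)) match(country, world$countries) else country
  if (is.na(i) || i < 1 || i > length(world$countries))
    stop("unknown country: ", country, call. = FALSE)
  roster <- world$roster
  q <- world$tables$food_per_capita[i, ]  # kg/person/yr
  keep <- q > 0 & (include_sugar | !roster$is_sugar)
  cms <- roster$commodity[keep]
  w <- impacts$consumption[cms, i]
  if (any(is.na(w)))
    stop("missing consumption impacts for consumed commodities: ",
         paste(cms[is.na(w)], collapse = ", "), call. = FALSE)
  contrib <- q[cms] * w
  total <- sum(contrib)
  by_group <- tapply(contrib, roster$group[keep], sum)
  by_group <- by_group[!is.na(by_group)]
  dom <- sum(vapply(cms, function(cm)
    q[cm] * impacts$cons_origin[[cm]][i, i], numeric(1)))
  land <- consumption_land_per_kg(world, impacts)
  implied <- sum(q[cms] * land[cms, i], na.rm = TRUE)
  structure(list(
    country = world$countries[i], total = total,
    by_group = as.list(by_group),
    by_origin = list(domestic = dom, imported = total - dom),
    domestic_share = if (total > 0) dom / total else NA_real_,
    imported_share = if (total > 0) 1 - dom / total else NA_real_,
    implied_land_km2 = implied,
    by_commodity = contrib
  ), class = "footprint_record")
}

#' @export
print.footprint_record <- function(x, ...) {
  cat(sprintf("<footprint_record> %s: %.3e dE/person/yr (%.0f%% imported), %.4f km2/person\n",
              x$country, x$total,
              100 * ifelse(is.na(x$imported_share), 0, x$imported_share),
              x$implied_land_km2))
  invisible(x)
}

#' Domestic vs imported shares of a consumption footprint
#'
#' Shares of the total consumption impact accruing from domestic primary
#' production versus production in other countries (traced to ultimate
#' origins through the provenance portfolios, including feed embedded in
#' animal products).
#'
#' @inheritParams per_capita_footprint
#' @return named numeric `c(domestic, imported)`, summing to 1, or both
#'   `NA` when the total footprint is zero (undefined).
#' @export
import_domestic_split <- function(world, impacts, country,
                                  include_sugar = FALSE) {
  fp <- per_capita_footprint(world, impacts, country, include_sugar)
  c(domestic = fp$domestic_share, imported = fp$imported_share)
}

#' Consumption-basis land intensity (km2 per kg)
#'
#' Land area occupied per kg of each commodity as consumed in each country:
#' crops use national harvested-area/production (provenance-weighted over
#' origins); animal products add grazing land and the land behind their feed.
#'
#' @param world a `synthetic_world`.
#' @param impacts matching `impact_set` (for the provenance shares).
#' @return matrix (commodity x country), km2-yr per kg.
#' @export
consumption_land_per_kg <- function(world, impacts) {
  roster <- world$roster
  countries <- world$countries
  nC <- length(countries)
  comms <- roster$commodity
  veg <- comms[!roster$is_animal]
  L_prod <- matrix(NA_real_, length(comms), nC, dimnames = list(comms, countries))
  cid <- raster_values(world$country_id)
  for (cm in veg) {
    a <- raster_values(world$harvested_area[[cm]])
    p <- raster_values(world$production[[cm]])
    for (i in seq_len(nC)) {
      sel <- cid == i
      pk <- sum(p[sel]) * 1000
      L_prod[cm, i] <- if (pk > 0) sum(a[sel]) / pk else NA_real_
    }
  }
  L_cons <- L_prod
  for (cm in veg) {
    S <- impacts$shares[[cm]]; Sz <- S; Sz[is.na(Sz)] <- 0
    L_cons[cm, ] <- as.numeric(Sz %*% ifelse(is.na(L_prod[cm, ]), 0, L_prod[cm, ]))
    L_cons[cm, is.na(S[, 1])] <- NA_real_
  }
  for (a in comms[roster$is_animal]) {
    lp <- numeric(nC)
    for (i in seq_len(nC)) {
      req <- world$feed$requirement[i, a, ]
      lp[i] <- world$feed$grazing[i, a] +
        sum(req * ifelse(is.na(L_cons[names(req), i]), 0, L_cons[names(req), i]))
    }
    L_prod[a, ] <- lp
    S <- impacts$shares[[a]]; Sz <- S; Sz[is.na(Sz)] <- 0
    L_cons[a, ] <- as.numeric(Sz %*% lp)
    L_cons[a, is.na(S[, 1])] <- NA_real_
  }
  L_cons
}

#' Implied land area of a consumption basket, with marginality check
#'
#' The restore layer is a *marginal* metric: aggregating it is only reliable
#' for land-cover changes up to about 1,000 km2, beyond which deviation from
#' a full recomputation grows past roughly 10%. This helper sums the land
#' implied by a basket of commodity masses and flags aggregates beyond the
#' threshold.
#'
#' @param masses named vector of commodity masses (kg).
#' @param land_per_kg named vector of land intensities (km2-yr per kg), e.g.
#'   a column of [consumption_land_per_kg()]; commodities with `NA`
#'   intensity are skipped with a warning.
#' @param threshold_km2 warning threshold (default 1000 km2).
#' @return implied land in km2, with attribute `marginality_warning`
#'   (logical). A warning condition is also raised when the threshold is
#'   exceeded.
#' @export
implied_land_and_marginality <- function(masses, land_per_kg,
                                         threshold_km2 = 1000) {
  cms <- names(masses)
  li <- land_per_kg[cms]
  if (any(is.na(li))) {
    warning("land intensity missing for: ",
            paste(cms[is.na(li)], collapse = ", "), "; skipped")
  }
  land <- sum(masses * li, na.rm = TRUE)
  flag <- land > threshold_km2
  if (flag)
    warning(sprintf(
      "implied land-cover change %.0f km2 exceeds %.0f km2; marginal LIFE values degrade beyond this scale",
      land, threshold_km2))
  structure(land, marginality_warning = flag)
}

#' Footprint summary for all countries
#'
#' @param world a `synthetic_world`.
#' @param impacts matching `impact_set`.
#' @param include_sugar include sugar-flagged commodities.
#' @return data.frame `country, de_per_capita_yr, domestic_share,
#'   imported_share, implied_land_km2`.
#' @export
footprint_summary <- function(world, impacts, include_sugar = FALSE) {
  recs <- lapply(world$countries, function(ct)
    per_capita_footprint(world, impacts, ct, include_sugar))
  data.frame(
    country = vapply(recs, `[[`, "", "country"),
    de_per_capita_yr = vapply(recs, `[[`, 0, "total"),
    domestic_share = vapply(recs, `[[`, 0, "domestic_share"),
    imported_share = vapply(recs, `[[`, 0, "imported_share"),
    implied_land_km2 = vapply(recs, `[[`, 0, "implied_land_km2"),
    stringsAsFactors = FALSE)
}
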