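#' Per-cell extinction opportunity cost of production
#'
#' Intersects the restore-density layer with a commodity's production and
#' harvested-area layers: each producing cell's value is
#' `density x harvested_area / production`, the expected extinctions forgone
#' per kg produced there (production supplied in tonnes and converted to kg).
#' Cells without production are `NA` (no per-kg value is defined there);
#' cells with nodata restore density stay `NA` and are excluded from any
#' later aggregation rather than treated as zero.
#'
#' @param life_density restore-density layer (dE/km2), `raster_grid` or matrix.
#' @param production production layer (tonnes per cell).
#' @param harvested_area harvested-area layer (km2 per cell).
#' @return `raster_grid` of dE per kg.
#' @export
cell_perkg_impacts <- function(life_density, production, harvested_area) {
  d <- raster_values(life_density)
  p <- raster_values(production)
  a <- raster_values(harvested_area)
  if (!all(dim(d) == dim(p)) || !all(dim(d) == dim(a)))
    stop("layers are not aligned", call. = FALSE)
  if (any(p < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE))
    stop("production and harvested area must be nonnegative", call. = FALSE)
  bad <- !is.na(p) & !is.na(a) & p > 0 & a == 0
  if (any(bad))
    stop(sprintf("%d cells have production > 0 but zero harvested area", sum(bad)),
         call. = FALSE)
  out <- matrix(NA_real_, nrow(d), ncol(d))
  ok <- !is.na(p) & !is.na(a) & !is.na(d) & p > 0
  out[ok] <- d[ok] * a[ok] / (p[ok] * 1000)
  raster_grid(out, layer = "perkg_impact", units = "dE_per_kg")
}

#' National per-kg production impact of a commodity
#'
#' The production-mass-weighted median of per-cell per-kg impacts over a
#' country's producing cells — the national per-kg extinction opportunity
#' cost of the commodity. Cells with `NA` per-kg values (nodata density or no
#' production) are excluded from the median.
#'
#' @param cell_impacts per-cell dE/kg layer from [cell_perkg_impacts()].
#' @param production production layer (tonnes per cell) — the weights.
#' @param country_id country-id layer.
#' @param country country id (numeric) or name position in the id raster.
#' @param cell_weighting `"production"` (default: weights are cell production
#'   mass) or `"area"` (weights are harvested area; requires
#'   `harvested_area`).
#' @param harvested_area harvested-area layer, needed for `"area"` weighting.
#' @return dE per kg, or `NA_real_` when the country has no production of the
#'   commodity (defined-absent; callers must handle, a zero would understate).
#' @export
national_production_impact <- function(cell_impacts, production, country_id,
                                       country,
                                       cell_weighting = c("production", "area"),
                                       harvested_area = NULL) {
  cell_weighting <- match.arg(cell_weighting)
  v <- raster_values(cell_impacts)
  p <- raster_values(production)
  cid <- raster_values(country_id)
  sel <- !is.na(cid) & cid == country & !is.na(p) & p > 0 & !is.na(v)
  if (!any(sel)) return(NA_real_)
  w <- if (cell_weighting == "production") p[sel]
       else raster_values(harvested_area)[sel]
  weighted_quantile(v[sel], w, 0.5)
}

#' Global weighted distribution of per-kg impacts
#'
#' Production-mass-weighted 10th/50th/90th percentiles of national per-kg
#' impact values; for a commodity the values are its national medians, for a
#' group the pooled commodity x country values, each weighted by the
#' production mass it represents.
#'
#' @param values national per-kg impacts (dE/kg); `NA`s dropped with their
#'   weights.
#' @param weights production masses.
#' @return named numeric `c(q10, q50, q90)`.
#' @export
global_commodity_distribution <- function(values, weights) {
  keep <- !is.na(values)
  if (!any(keep)) stop("no impact values supplied", call. = FALSE)
  q <- weighted_quantile(values[keep], weights[keep], c(0.1, 0.5, 0.9))
  names(q) <- c("q10", "q50", "q90")
  q
}

#' Express a per-kg impact per kg of protein
#'
#' Functional-unit conversion: dividing a per-mass impact by the commodity's
#' protein fraction gives dE per kg protein, the basis on which
#' protein-dense animal products close part of their gap to plant proteins.
#'
#' @param value dE per kg (scalar or vector).
#' @param protein_fraction g protein per g commodity, in (0, 1].
#' @return dE per kg protein.
#' @export
protein_adjusted_impact <- function(value, protein_fraction) {
  if (any(protein_fraction <= 0))
    stop("protein_fraction must be > 0 (commodity not expressible per-protein)",
         call. = FALSE)
  value / protein_fraction
}

#' National production impacts for all vegetal commodities of a world
#'
#' Convenience wrapper looping [cell_perkg_impacts()] and
#' [national_production_impact()] over every vegetal commodity and country.
#'
#' @param world a `synthetic_world`.
#' @param cell_weighting passed to [national_production_impact()].
#' @return matrix (commodity x country) of dE/kg; `NA` where a country does
#'   not produce a commodity.
#' @export
vegetal_production_impacts <- function(world,
                                       cell_weighting = c("production", "area")) {
  cell_weighting <- match.arg(cell_weighting)
  veg <- world$roster$commodity[!world$roster$is_animal]
  out <- matrix(NA_real_, length(veg), length(world$countries),
                dimnames = list(veg, world$countries))
  for (cm in veg) {
    ci <- cell_perkg_impacts(world$life_density, world$production[[cm]],
                             world$harvested_area[[cm]])
    for (i in seq_along(world$countries))
      out[cm, i] <- national_production_impact(
        ci, world$production[[cm]], world$country_id, i,
        cell_weighting = cell_weighting,
        harvested_area = world$harvested_area[[cm]])
  }
  out
}
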