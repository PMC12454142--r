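#' Grazing-land restore density for a country
#'
#' Aggregates per-cell restore densities over a country's pasture cells,
#' weighting each cell by its livestock numbers (density x pasture area) so
#' cells that carry more animals count for more. The default aggregate is
#' the weighted median, consistent with the cropland aggregation; a weighted
#' mean is available.
#'
#' @param life_density restore-density layer (dE/km2).
#' @param pasture_area pasture-area layer (km2 per cell).
#' @param livestock_density livestock-density layer (head/km2).
#' @param country_id country-id layer.
#' @param country country id.
#' @param stat `"median"` (default) or `"mean"`.
#' @return dE per km2, or `NA_real_` when the country has no stocked pasture
#'   (defined-absent).
#' @export
grazing_life_density <- function(life_density, pasture_area, livestock_density,
                                 country_id, country,
                                 stat = c("median", "mean")) {
  stat <- match.arg(stat)
  d <- raster_values(life_density)
  pa <- raster_values(pasture_area)
  ld <- raster_values(livestock_density)
  cid <- raster_values(country_id)
  sel <- !is.na(cid) & cid == country & !is.na(pa) & pa > 0 &
    !is.na(ld) & ld > 0 & !is.na(d)
  if (!any(sel)) return(NA_real_)
  w <- ld[sel] * pa[sel]  # head counts
  if (stat == "median") weighted_quantile(d[sel], w, 0.5)
  else sum(d[sel] * w) / sum(w)
}

#' Grazing component of an animal product's per-kg impact
#'
#' `grazing density (dE/km2) x grazing requirement (km2-yr per kg product)`.
#' Zero requirement (monogastrics) gives zero.
#'
#' @param grazing_density country grazing restore density (dE/km2).
#' @param grazing_requirement km2-yr of pasture per kg of product.
#' @param label optional `country:commodity` label for error messages.
#' @return dE per kg.
#' @export
grazing_component <- function(grazing_density, grazing_requirement,
                              label = NULL) {
  if (is.null(grazing_requirement) || length(grazing_requirement) != 1 ||
      is.na(grazing_requirement))
    stop("missing grazing requirement",
         if (!is.null(label)) paste0(" for ", label), call. = FALSE)
  if (grazing_requirement < 0) stop("grazing requirement must be >= 0", call. = FALSE)
  if (grazing_requirement == 0) return(0)
  if (is.na(grazing_density))
    stop("grazing density undefined but grazing requirement > 0",
         if (!is.null(label)) paste0(" for ", label), call. = FALSE)
  grazing_density * grazing_requirement
}

#' Feed component of an animal product's per-kg impact
#'
#' Sums over feed crops: requirement (kg feed per kg product) times the
#' *consumption-basis* per-kg impact of the feed crop in the producing
#' country, so imported feed carries the impacts of its true origins (e.g.
#' soy grown abroad feeding domestic livestock).
#'
#' @param feed_requirement named vector, kg of each feed crop per kg product.
#' @param feed_impacts named vector of consumption-basis dE/kg for the feed
#'   crops in the producing country.
#' @return dE per kg.
#' @export
feed_component <- function(feed_requirement, feed_impacts) {
  if (any(feed_requirement < 0)) stop("feed requirements must be >= 0", call. = FALSE)
  used <- names(feed_requirement)[feed_requirement > 0]
  missing_i <- used[!(used %in% names(feed_impacts)) |
                      is.na(feed_impacts[used])]
  if (length(missing_i))
    stop("missing feed-crop consumption impacts: ",
         paste(missing_i, collapse = ", "), call. = FALSE)
  if (!length(used)) return(0)
  sum(feed_requirement[used] * feed_impacts[used])
}

#' Per-kg production impact of an animal product
#'
#' Grazing plus feed components, with the decomposition retained. Crop-only
#' commodities have zero grazing and feed components by construction; for
#' animal products the crop component is zero and the two livestock pathways
#' sum to the total.
#'
#' @param grazing grazing component (dE/kg).
#' @param feed feed component (dE/kg).
#' @return list `value`, `crop` (0), `grazing`, `feed`.
#' @export
animal_production_impact <- function(grazing, feed) {
  if (is.na(grazing) || is.na(feed))
    stop("animal impact components must be available", call. = FALSE)
  list(value = grazing + feed, crop = 0, grazing = grazing, feed = feed)
}
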