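#' LIFE-style restore density from a species set
#'
#' Scores each cell with the marginal reduction in expected extinctions per
#' km2 of agricultural land restored to natural habitat. For each species the
#' probability of extinction is related to its proportional area of habitat
#' by a power law,
#' \deqn{p(A) = 1 - (A / A_0)^z,}
#' where `A` is the current area of habitat and `A0` the area in a
#' human-absent baseline. Restoring a cell's agricultural area changes the
#' species' habitat by `dA`:
#'
#' * `+` the restored area, when natural cover is suitable and the
#'   agricultural cover is not (habitat is gained);
#' * `0`, when the species tolerates both the agricultural and natural cover
#'   (no change in area of habitat — no contribution);
#' * negative, when the agricultural cover is suitable but natural cover is
#'   not (restoration removes habitat — a negative contribution).
#'
#' The cell value is the unweighted sum over all species present of
#' `p(A) - p(A + dA)`, divided by the restored (agricultural) area of the
#' cell, in expected extinctions per km2. Species are treated equally
#' regardless of any threat status, so the layer scales with richness,
#' endemism and habitat loss to date: a narrow-ranged species loses a larger
#' fraction of its habitat to a one-cell change and contributes more.
#'
#' @param species list of species records as from [generate_species_set()].
#' @param landcover land-cover fraction layers (`natural`, `pasture`,
#'   `crop_total`, `cell_area`).
#' @param z power-law exponent (> 0), default 0.25.
#' @return A `raster_grid` in `dE_per_km2`; cells with no agricultural land
#'   score 0.
#' @examples
#' cfg <- world_config(grid_rows = 6, grid_cols = 6, n_species = 12, seed = 2)
#' sp <- generate_species_set(cfg)
#' # landcover regenerated internally by generate_world in normal use
#' @export
life_restore_density <- function(species, landcover, z = 0.25) {
  if (z <= 0) stop("z must be > 0", call. = FALSE)
  crop_total <- landcover$crop_total
  nr <- nrow(crop_total); nc <- ncol(crop_total)
  cell_area <- landcover$cell_area
  crop_area <- crop_total * cell_area
  past_area <- landcover$pasture * cell_area
  ag_area <- crop_area + past_area
  dE <- matrix(0, nr, nc)
  for (sp in species) {
    if (sp$A <= 0) stop(sprintf("species %s has A <= 0", sp$id), call. = FALSE)
    if (sp$A > sp$A0 * (1 + 1e-12))
      stop(sprintf("species %s violates A <= A0", sp$id), call. = FALSE)
    cells <- sp$cells
    nat <- as.numeric(isTRUE(sp$suit_natural))
    dA <- crop_area[cells] * (nat - as.numeric(isTRUE(sp$suit_cropland))) +
          past_area[cells] * (nat - as.numeric(isTRUE(sp$suit_pasture)))
    Anew <- pmin(pmax(sp$A + dA, 0), sp$A0)
    # p(A) - p(A + dA) = ((A+dA)/A0)^z - (A/A0)^z
    dE[cells] <- dE[cells] + (Anew / sp$A0)^z - (sp$A / sp$A0)^z
  }
  dens <- ifelse(ag_area > 0, dE / ifelse(ag_area > 0, ag_area, 1), 0)
  raster_grid(dens, layer = "life_restore_density", units = "dE_per_km2")
}
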