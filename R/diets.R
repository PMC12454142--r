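#' Diet specification from food-group energy fractions
#'
#' A diet is specified by the fraction of (allocatable) energy coming from
#' each of the seven food groups, plus a total daily energy. Stimulants and
#' spices contribute almost no energy and are held constant across diets, so
#' their calories are subtracted from the allocatable budget before the
#' group fractions are applied; every built diet then matches the baseline's
#' total energy exactly.
#'
#' @param name diet name.
#' @param group_fractions named numeric over the food groups (see
#'   [commodity_roster()]): `fruit_veg`, `legumes_nuts`, `grains_roots`,
#'   `dairy_eggs`, `ruminant_meat`, `poultry_pig`, `sugar_other`. Must be
#'   nonnegative and sum to 1 (within 1e-9). Missing groups count as 0.
#' @param total_energy total intake in kcal/person/day; `NULL` (default)
#'   means "match the baseline intake it is built against".
#' @return list of class `diet_spec`.
#' @export
diet_spec <- function(name, group_fractions, total_energy = NULL) {
  gf <- setNames(numeric(length(food_groups())), food_groups())
  unknown <- setdiff(names(group_fractions), food_groups())
  if (length(unknown))
    stop("unknown food groups: ", paste(unknown, collapse = ", "), call. = FALSE)
  gf[names(group_fractions)] <- as.numeric(group_fractions)
  if (any(gf < 0)) stop("group fractions must be >= 0", call. = FALSE)
  if (abs(sum(gf) - 1) > 1e-9)
    stop(sprintf("group fractions must sum to 1 (got %.12f)", sum(gf)),
         call. = FALSE)
  structure(list(name = name, group_fractions = gf, total_energy = total_energy),
            class = "diet_spec")
}

#' Reference diet specifications
#'
#' The four modelled diets, as shares of total calories by food group:
#' the observed baseline; a planetary-health-style reference allowing a
#' little ruminant meat; and vegetarian and plant-based ("Eatwell"-style)
#' diets with no meat (the plant-based one also without dairy and eggs).
#'
#' @return named list of [diet_spec()] objects: `baseline`, `eat_lancet`,
#'   `vegetarian`, `vegan`.
#' @export
reference_diets <- function() {
  list(
    baseline = diet_spec("baseline", c(
      fruit_veg = 0.06, legumes_nuts = 0.12, grains_roots = 0.35,
      dairy_eggs = 0.13, ruminant_meat = 0.04, poultry_pig = 0.10,
      sugar_other = 0.20)),
    eat_lancet = diet_spec("eat_lancet", c(
      fruit_veg = 0.12, legumes_nuts = 0.23, grains_roots = 0.43,
      dairy_eggs = 0.08, ruminant_meat = 0.01, poultry_pig = 0.05,
      sugar_other = 0.08)),
    vegetarian = diet_spec("vegetarian", c(
      fruit_veg = 0.40, legumes_nuts = 0.10, grains_roots = 0.35,
      dairy_eggs = 0.15, ruminant_meat = 0, poultry_pig = 0,
      sugar_other = 0)),
    vegan = diet_spec("vegan", c(
      fruit_veg = 0.40, legumes_nuts = 0.25, grains_roots = 0.35,
      dairy_eggs = 0, ruminant_meat = 0, poultry_pig = 0,
      sugar_other = 0)))
}

#' Group energy fractions of a baseline intake
#'
#' Computes the food-group fractions of allocatable energy (held-constant
#' stimulant calories excluded) implied by a baseline intake, such that
#' [build_diet()] with these fractions reproduces the baseline exactly.
#'
#' @param baseline_intake named vector, kg/person/day per commodity.
#' @param roster commodity roster (see [commodity_roster()]).
#' @return named fractions over [food_groups()], summing to 1.
#' @export
baseline_group_fractions <- function(baseline_intake, roster) {
  cms <- names(baseline_intake)
  kcal <- baseline_intake * roster[cms, "energy_kcal_per_kg"]
  held <- roster[cms, "is_stimulant"]
  g <- tapply(kcal[!held], roster[cms, "group"][!held], sum)
  gf <- setNames(numeric(length(food_groups())), food_groups())
  gf[names(g)] <- g / sum(g)
  gf
}

#' Build commodity-level intakes for a diet
#'
#' Allocates the diet's energy budget to food groups by the spec fractions
#' and, within each group, to commodities in proportion to their baseline
#' energy shares ("consumed in the same ratios that they currently are").
#' Held-constant commodities (stimulants/spices) are copied from the
#' baseline; their calories are netted off the allocatable budget, so the
#' built diet's total energy (held-constant included) equals the target
#' exactly.
#'
#' @param spec a [diet_spec()].
#' @param baseline_intake named vector, kg/person/day.
#' @param roster commodity roster with energy densities and flags.
#' @return named vector, kg/person/day per commodity.
#' @export
build_diet <- function(spec, baseline_intake, roster) {
  stopifnot(inherits(spec, "diet_spec"))
  cms <- names(baseline_intake)
  E <- roster[cms, "energy_kcal_per_kg"]
  names(E) <- cms
  if (any(E <= 0 & baseline_intake > 0))
    stop("zero energy density for consumed commodity: ",
         paste(cms[E <= 0 & baseline_intake > 0], collapse = ", "), call. = FALSE)
  kcal0 <- baseline_intake * E
  held <- roster[cms, "is_stimulant"]
  H <- sum(kcal0[held])
  total <- if (is.null(spec$total_energy)) sum(kcal0) else spec$total_energy
  budget <- total - H
  if (budget < 0) stop("held-constant calories exceed the diet's total energy",
                       call. = FALSE)
  out <- setNames(numeric(length(cms)), cms)
  out[held] <- baseline_intake[held]
  grp <- roster[cms, "group"]
  for (g in food_groups()) {
    frac <- spec$group_fractions[[g]]
    in_g <- grp == g & !held
    if (frac == 0 || !any(in_g)) {
      if (frac > 0 && !any(in_g))
        stop("group with positive fraction has no commodities: ", g, call. = FALSE)
      next
    }
    base_g <- kcal0[in_g]
    if (sum(base_g) <= 0)
      stop("group with positive fraction has no baseline calories: ", g,
           call. = FALSE)
    alloc <- frac * budget * base_g / sum(base_g)
    out[in_g] <- alloc / E[in_g]
  }
  out
}

#' Extinction footprint of a diet
#'
#' `sum_c kg_c x w_c` per day over non-sugar commodities: sugar is allocated
#' calories like any other group but contributes zero impact (its supply
#' chains cannot be attributed reliably). Stimulants carry their impact.
#'
#' @param intake named vector, kg/person/day.
#' @param impacts named vector of consumption-basis dE/kg for the consuming
#'   country.
#' @param roster commodity roster (for the sugar flag and groups).
#' @return list `total` (dE/person/day) and `by_group`.
#' @export
diet_footprint <- function(intake, impacts, roster) {
  cms <- names(intake)
  w <- impacts[cms]
  counted <- !roster[cms, "is_sugar"]
  active <- counted & intake > 0
  if (any(is.na(w[active])))
    stop("missing impacts for commodities: ",
         paste(cms[active][is.na(w[active])], collapse = ", "), call. = FALSE)
  contrib <- ifelse(counted & intake > 0, intake * w, 0)
  list(total = sum(contrib),
       by_group = tapply(contrib, roster[cms, "group"], sum))
}

#' Compare diet scenarios for a country
#'
#' Builds each diet from the country's baseline consumption (same total
#' calories, same within-group commodity ratios, same sourcing as current
#' provenance) and computes its footprint and ratio to baseline. The first
#' row is always the observed baseline.
#'
#' @param specs list of [diet_spec()] objects (e.g. [reference_diets()]);
#'   a spec named `baseline` is replaced by the country's observed intake.
#' @param world a `synthetic_world`.
#' @param impacts matching `impact_set`.
#' @param country country name or index.
#' @return data.frame `diet, kcal_day, de_per_day, ratio_to_baseline`, with
#'   attribute `"detail"`: long data.frame `diet, group, kcal, kg,
#'   de_per_day`.
#' @export
compare_diets <- function(specs, world, impacts, country) {
  i <- if (is.character(country)) match(country, world$countries) else country
  roster <- world$roster
  baseline <- world$tables$food_per_capita[i, ] / 365  # kg/day
  names(baseline) <- roster$commodity
  w <- impacts$consumption[, i]
  names(w) <- roster$commodity
  base_spec <- diet_spec("baseline", baseline_group_fractions(baseline, roster))
  base_total <- diet_footprint(baseline, w, roster)$total
  rows <- list(); detail <- list()
  for (spec in specs) {
    use_spec <- if (spec$name == "baseline") base_spec else spec
    intake <- build_diet(use_spec, baseline, roster)
    fp <- diet_footprint(intake, w, roster)
    kcal <- intake * roster[names(intake), "energy_kcal_per_kg"]
    rows[[length(rows) + 1L]] <- data.frame(
      diet = spec$name, kcal_day = sum(kcal), de_per_day = fp$total,
      ratio_to_baseline = if (base_total > 0) fp$total / base_total else NA_real_,
      stringsAsFactors = FALSE)
    kg_g <- tapply(intake, roster[names(intake), "group"], sum)
    kcal_g <- tapply(kcal, roster[names(intake), "group"], sum)
    detail[[length(detail) + 1L]] <- data.frame(
      diet = spec$name, group = names(kcal_g),
      kcal = as.numeric(kcal_g), kg = as.numeric(kg_g),
      de_per_day = as.numeric(fp$by_group[names(kcal_g)]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "detail") <- do.call(rbind, detail)
  out
}
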