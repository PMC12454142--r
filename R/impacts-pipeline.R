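#' Compute the full production/consumption impact set of a world
#'
#' Runs the whole attribution chain on a synthetic (or assembled) world:
#'
#' 1. national per-kg production impacts of vegetal commodities
#'    (production-mass-weighted medians of cell values);
#' 2. provenance portfolios per commodity via the re-export correction;
#' 3. consumption-basis per-kg impacts of vegetal commodities;
#' 4. animal-product production impacts = grazing component (livestock-
#'    weighted grazing restore density x grazing requirement) + feed
#'    component (feed requirements x consumption-basis feed-crop impacts in
#'    the producing country, so imported feed carries origin impacts);
#' 5. provenance and consumption impacts for animal products, with the
#'    per-kg impact decomposed down to the *ultimate* origin country
#'    (grazing accrues to the producer, feed to the feed crops' origins).
#'
#' @param world a `synthetic_world` (or structurally identical list).
#' @param cell_weighting per-cell weights for national medians:
#'   `"production"` mass (default) or harvested `"area"`.
#' @param grazing_stat grazing aggregation, `"median"` (default) or `"mean"`.
#' @return list of class `impact_set`: `production` and `consumption`
#'   matrices (commodity x country, dE/kg), `crop`/`grazing`/`feed`
#'   decomposition matrices, `shares` (per-commodity provenance matrices),
#'   `prod_origin` and `cons_origin` (per-commodity origin-decomposition
#'   matrices whose rows sum to the per-kg values), `grazing_density`
#'   (per-country dE/km2).
#' @export
compute_impacts <- function(world, cell_weighting = c("production", "area"),
                            grazing_stat = c("median", "mean")) {
  cell_weighting <- match.arg(cell_weighting)
  grazing_stat <- match.arg(grazing_stat)
  roster <- world$roster
  countries <- world$countries
  nC <- length(countries)
  comms <- roster$commodity
  veg <- comms[!roster$is_animal]
  animals <- comms[roster$is_animal]
  feeds <- comms[roster$is_feed_crop]
  tb <- world$tables
  use <- tb$food + tb$feed_use  # domestic use = supply - exports

  empty <- matrix(0, length(comms), nC, dimnames = list(comms, countries))
  v_prod <- empty; v_prod[] <- NA_real_
  crop <- empty; grazing <- empty; feedc <- empty
  shares <- list(); prod_origin <- list(); cons_origin <- list()
  v_cons <- empty; v_cons[] <- NA_real_

  vp <- vegetal_production_impacts(world, cell_weighting)
  v_prod[veg, ] <- vp
  crop[veg, ] <- vp

  for (cm in veg) {
    S <- provenance_shares(tb$production[, cm], tb$trade[[cm]], use = use[, cm])
    V <- matrix(0, nC, nC, dimnames = list(countries, countries))
    diag(V) <- ifelse(is.na(v_prod[cm, ]), 0, v_prod[cm, ])
    ci <- consumption_perkg_impact(S, v_prod[cm, ])
    shares[[cm]] <- S
    prod_origin[[cm]] <- V
    cons_origin[[cm]] <- ci$by_origin
    v_cons[cm, ] <- ci$value
  }

  gld <- vapply(seq_len(nC), function(i)
    grazing_life_density(world$life_density, world$pasture_area,
                         world$livestock_density, world$country_id, i,
                         stat = grazing_stat), numeric(1))
  names(gld) <- countries

  for (a in animals) {
    V <- matrix(0, nC, nC, dimnames = list(countries, countries))
    for (i in seq_len(nC)) {
      g <- grazing_component(gld[i], world$feed$grazing[i, a],
                             label = paste0(countries[i], ":", a))
      req <- world$feed$requirement[i, a, ]
      feed_component(req, v_cons[feeds, i])  # validates availability
      # feed impact accumulated through the feed crops' own origin
      # decompositions, so the component and its origin split agree exactly
      forigin <- numeric(nC)
      for (fc in names(req)[req > 0])
        forigin <- forigin + req[fc] * cons_origin[[fc]][i, ]
      f <- sum(forigin)
      v_prod[a, i] <- g + f
      grazing[a, i] <- g
      feedc[a, i] <- f
      V[i, ] <- forigin
      V[i, i] <- V[i, i] + g
    }
    S <- provenance_shares(tb$production[, a], tb$trade[[a]], use = use[, a])
    ci <- consumption_perkg_impact(S, v_prod[a, ])
    shares[[a]] <- S
    prod_origin[[a]] <- V
    Sz <- S; Sz[is.na(Sz)] <- 0
    W <- Sz %*% V
    W[is.na(S[, 1]), ] <- NA_real_
    cons_origin[[a]] <- W
    v_cons[a, ] <- ci$value
  }

  structure(list(
    commodities = comms, countries = countries, roster = roster,
    production = v_prod, consumption = v_cons,
    crop = crop, grazing = grazing, feed = feedc,
    shares = shares, prod_origin = prod_origin, cons_origin = cons_origin,
    grazing_density = gld,
    cell_weighting = cell_weighting, grazing_stat = grazing_stat
  ), class = "impact_set")
}

#' @export
print.impact_set <- function(x, ...) {
  cat(sprintf("<impact_set> %d commodities x %d countries (cell weights: %s, grazing: %s)\n",
              length(x$commodities), length(x$countries),
              x$cell_weighting, x$grazing_stat))
  invisible(x)
}

#' Tidy table of per-kg impacts
#'
#' @param impacts an `impact_set`.
#' @param world the world the impacts were computed from (for production
#'   weights).
#' @return data.frame `commodity, country, impact_de_per_kg, crop, grazing,
#'   feed, q10, q50, q90, basis` with the commodity's global
#'   production-mass-weighted quantiles repeated per row, for both bases.
#' @export
impacts_table <- function(impacts, world) {
  P <- world$tables$production
  rows <- list()
  for (basis in c("production", "consumption")) {
    M <- impacts[[basis]]
    for (cm in impacts$commodities) {
      q <- global_commodity_distribution(impacts$production[cm, ], P[, cm])
      rows[[length(rows) + 1L]] <- data.frame(
        commodity = cm, country = impacts$countries,
        impact_de_per_kg = M[cm, ],
        crop = if (basis == "production") impacts$crop[cm, ] else NA_real_,
        grazing = if (basis == "production") impacts$grazing[cm, ] else NA_real_,
        feed = if (basis == "production") impacts$feed[cm, ] else NA_real_,
        q10 = q[["q10"]], q50 = q[["q50"]], q90 = q[["q90"]],
        basis = basis, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Global distributions per commodity group
#'
#' Pools commodity x country national medians within each food group,
#' weighting by production mass, and returns the weighted 10/50/90
#' percentiles per group.
#'
#' @param impacts an `impact_set`.
#' @param world the corresponding world.
#' @return data.frame `group, q10, q50, q90`.
#' @export
group_distributions <- function(impacts, world) {
  P <- world$tables$production
  groups <- unique(impacts$roster$group)
  out <- lapply(groups, function(g) {
    cms <- impacts$roster$commodity[impacts$roster$group == g]
    vals <- as.numeric(impacts$production[cms, , drop = FALSE])
    wts <- as.numeric(t(P[, cms, drop = FALSE]))
    q <- global_commodity_distribution(vals, wts)
    data.frame(group = g, q10 = q[["q10"]], q50 = q[["q50"]], q90 = q[["q90"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
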