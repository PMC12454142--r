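#' Write supply/trade tables as long-format CSV
#'
#' One row per `country, commodity, element, value, unit` with elements
#' `production` (tonnes/yr), `export_to:<iso>` / `import_from:<iso>`
#' (tonnes/yr, mirrored bilateral flows), `feed` (tonnes/yr),
#' `food_per_capita` (kg/person/yr) and `population` (persons, commodity
#' field empty). Values are written with full float64 precision.
#'
#' @param tables tables list as from [generate_supply_and_trade()] (or the
#'   `tables` element of a world).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_supply_trade_csv <- function(tables, path) {
  countries <- rownames(tables$production)
  comms <- colnames(tables$production)
  rows <- list()
  add <- function(country, commodity, element, value, unit)
    rows[[length(rows) + 1L]] <<- data.frame(
      country = country, commodity = commodity, element = element,
      value = value, unit = unit, stringsAsFactors = FALSE)
  for (i in countries) for (cm in comms) {
    add(i, cm, "production", tables$production[i, cm], "tonnes")
    add(i, cm, "feed", tables$feed_use[i, cm], "tonnes")
    add(i, cm, "food_per_capita", tables$food_per_capita[i, cm], "kg_per_person_yr")
    T <- tables$trade[[cm]]
    for (d in countries[T[i, ] > 0]) add(i, cm, paste0("export_to:", d), T[i, d], "tonnes")
    for (o in countries[T[, i] > 0]) add(i, cm, paste0("import_from:", o), T[o, i], "tonnes")
  }
  for (i in countries) add(i, "", "population", tables$population[[i]], "persons")
  df <- do.call(rbind, rows)
  df$value <- sprintf("%.17g", df$value)
  write_csv_atomic(df, path)
}

#' Read long-format supply/trade tables
#'
#' Inverse of [write_supply_trade_csv()]; validates the schema and element
#' names, reporting the offending row on violation.
#'
#' @param path CSV path.
#' @return list `production`, `trade`, `feed_use`, `food_per_capita`,
#'   `population`.
#' @export
read_supply_trade_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  needed <- c("country", "commodity", "element", "value", "unit")
  if (!all(needed %in% names(df)))
    stop("supply/trade CSV must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  ok <- grepl("^(production|feed|food_per_capita|population|import_from:[^,:]+|export_to:[^,:]+)$",
              df$element)
  if (!all(ok))
    stop(sprintf("malformed element '%s' at row %d of %s",
                 df$element[!ok][1], which(!ok)[1], basename(path)), call. = FALSE)
  df$value <- as.numeric(df$value)
  countries <- sort(unique(df$country))
  comms <- unique(df$commodity[df$commodity != ""])
  mk <- function() matrix(0, length(countries), length(comms),
                          dimnames = list(countries, comms))
  P <- mk(); FU <- mk(); FPC <- mk()
  trade <- lapply(comms, function(cm)
    matrix(0, length(countries), length(countries),
           dimnames = list(countries, countries)))
  names(trade) <- comms
  pop <- setNames(numeric(length(countries)), countries)
  for (r in seq_len(nrow(df))) {
    el <- df$element[r]; i <- df$country[r]; cm <- df$commodity[r]; v <- df$value[r]
    if (el == "population") pop[i] <- v
    else if (el == "production") P[i, cm] <- v
    else if (el == "feed") FU[i, cm] <- v
    else if (el == "food_per_capita") FPC[i, cm] <- v
    else if (startsWith(el, "export_to:"))
      trade[[cm]][i, sub("^export_to:", "", el)] <- v
    # import_from rows mirror export_to rows and are validated, not re-stored
  }
  list(production = P, trade = trade, feed_use = FU, food_per_capita = FPC,
       population = pop)
}

write_csv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "wb")  # deterministic newlines
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param world a [world_config()] (the seed lives here).
#' @param out_dir output directory (created if missing).
#' @param include_sugar include sugar in consumption analyses (default
#'   `FALSE`; production-side analyses always include it).
#' @param cell_weighting,grazing_stat weighting conventions, see
#'   [compute_impacts()].
#' @param diets list of [diet_spec()]s (default [reference_diets()]).
#' @param diet_country country the diet scenarios are evaluated for
#'   (default first country).
#' @param write_rasters write the world's raster layers as ASCII grids
#'   (default `TRUE`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(world = world_config(), out_dir = "lifecost-out",
                            include_sugar = FALSE,
                            cell_weighting = "production",
                            grazing_stat = "median",
                            diets = reference_diets(),
                            diet_country = NULL,
                            write_rasters = TRUE) {
  structure(list(world = world, out_dir = out_dir,
                 include_sugar = include_sugar,
                 cell_weighting = cell_weighting, grazing_stat = grazing_stat,
                 diets = diets, diet_country = diet_country,
                 write_rasters = write_rasters),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a world, computes production and consumption
#' impacts, provenance portfolios, per-capita footprints with
#' import/domestic splits, and diet-scenario comparisons, and writes each
#' stage's outputs atomically to `out_dir`:
#'
#' * `config.yaml`, `pipeline.log` (seed and config echo; the log records
#'   the config file's MD5 so reruns are verifiable),
#' * `rasters/*.asc` (optional),
#' * `tables.csv` (long-format supply/trade tables),
#' * `production_impacts.csv` / `consumption_impacts.csv`
#'   (`commodity, country, impact_de_per_kg, crop, grazing, feed, q10, q50,
#'   q90, basis`),
#' * `group_distributions.csv`,
#' * `provenance.csv` (`commodity, consumer, origin, share`),
#' * `footprints.csv` (`country, group, de_per_capita_yr`) and
#'   `footprint_summary.csv`,
#' * `diet_scenarios.csv` (`diet, group, kcal, kg, de_per_day`) and
#'   `diet_summary.csv`.
#'
#' Reruns with an identical config produce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param world optional pre-generated world (must match `config$world`).
#' @return invisibly, list with `world`, `impacts`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), world = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  cfg_path <- file.path(out, "config.yaml")
  cfg_echo <- unclass_deep(config)
  cfg_echo$out_dir <- NULL  # location-independent echo: reruns byte-compare
  yaml::write_yaml(cfg_echo, cfg_path)
  paths$config <- cfg_path

  if (is.null(world)) world <- generate_world(config$world)
  if (config$write_rasters) {
    rdir <- file.path(out, "rasters")
    dir.create(rdir, showWarnings = FALSE)
    layers <- c(list(life_restore_density = world$life_density,
                     country_id = world$country_id,
                     livestock_density = world$livestock_density,
                     pasture_area = world$pasture_area),
                setNames(world$production, paste0("production_", names(world$production))),
                setNames(world$harvested_area,
                         paste0("harvested_area_", names(world$harvested_area))))
    for (nm in names(layers))
      write_ascii_raster(layers[[nm]], file.path(rdir, paste0(nm, ".asc")))
    paths$rasters <- rdir
  }
  paths$tables <- write_supply_trade_csv(world$tables, file.path(out, "tables.csv"))

  impacts <- compute_impacts(world, cell_weighting = config$cell_weighting,
                             grazing_stat = config$grazing_stat)
  itab <- impacts_table(impacts, world)
  paths$production_impacts <- write_csv_atomic(
    itab[itab$basis == "production", ], file.path(out, "production_impacts.csv"))
  paths$consumption_impacts <- write_csv_atomic(
    itab[itab$basis == "consumption", ], file.path(out, "consumption_impacts.csv"))
  paths$group_distributions <- write_csv_atomic(
    group_distributions(impacts, world), file.path(out, "group_distributions.csv"))

  prov <- do.call(rbind, lapply(impacts$commodities, function(cm) {
    S <- impacts$shares[[cm]]
    idx <- which(!is.na(S) & S > 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(commodity = cm, consumer = rownames(S)[idx[, 1]],
               origin = colnames(S)[idx[, 2]], share = S[idx],
               stringsAsFactors = FALSE)
  }))
  prov <- prov[order(prov$commodity, prov$consumer, prov$origin), ]
  paths$provenance <- write_csv_atomic(prov, file.path(out, "provenance.csv"))

  fps <- lapply(world$countries, function(ct)
    per_capita_footprint(world, impacts, ct, config$include_sugar))
  fp_rows <- do.call(rbind, lapply(fps, function(fp)
    data.frame(country = fp$country, group = names(fp$by_group),
               de_per_capita_yr = as.numeric(unlist(fp$by_group)),
               stringsAsFactors = FALSE, row.names = NULL)))
  paths$footprints <- write_csv_atomic(fp_rows, file.path(out, "footprints.csv"))
  paths$footprint_summary <- write_csv_atomic(
    footprint_summary(world, impacts, config$include_sugar),
    file.path(out, "footprint_summary.csv"))

  diet_country <- if (is.null(config$diet_country)) world$countries[1]
                  else config$diet_country
  dcomp <- compare_diets(config$diets, world, impacts, diet_country)
  paths$diet_summary <- write_csv_atomic(dcomp, file.path(out, "diet_summary.csv"))
  paths$diet_scenarios <- write_csv_atomic(attr(dcomp, "detail"),
                                           file.path(out, "diet_scenarios.csv"))

  log_lines <- c(
    sprintf("lifecost pipeline"),
    sprintf("seed: %d", config$world$seed),
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("world: %dx%d cells, %d countries, %d commodities, %d species",
            config$world$grid_rows, config$world$grid_cols,
            config$world$n_countries, config$world$n_commodities,
            config$world$n_species),
    sprintf("stages: generate, impacts, provenance, footprints, diets"),
    sprintf("outputs: %s", paste(sort(names(paths)), collapse = ", ")))
  log_con <- file(file.path(out, "pipeline.log"), "wb")
  writeChar(paste0(paste(log_lines, collapse = "\n"), "\n"), log_con, eos = NULL)
  close(log_con)
  paths$log <- file.path(out, "pipeline.log")

  invisible(list(world = world, impacts = impacts, paths = paths))
}

# yaml cannot serialise classed lists of functions; strip classes and drop
# diet-spec closures down to plain lists
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with `world` (fields of [world_config()]) and the
#'   optional scalar fields of [pipeline_config()]. Diet specs may be given
#'   under `diets:` as `name: {group: fraction, ...}` maps; when absent the
#'   reference diets are used.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  wc <- do.call(world_config, y$world %||% list())
  diets <- if (is.null(y$diets)) reference_diets()
           else lapply(names(y$diets), function(nm)
             diet_spec(nm, unlist(y$diets[[nm]])))
  pipeline_config(world = wc,
                  out_dir = y$out_dir %||% "lifecost-out",
                  include_sugar = isTRUE(y$include_sugar),
                  cell_weighting = y$cell_weighting %||% "production",
                  grazing_stat = y$grazing_stat %||% "median",
                  diets = diets,
                  diet_country = y$diet_country,
                  write_rasters = y$write_rasters %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
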