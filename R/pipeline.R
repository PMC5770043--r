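# End-to-end orchestration: geodata (read or generated) -> network ->
# route catalog -> catchments -> zones -> zone summary -> call analytics,
# with every artifact written to an output directory and a manifest making
# the run reproducible. Identical inputs and config give identical outputs.

#' Pipeline run configuration
#'
#' @param breaks Two ascending travel-time break values in minutes
#'   (default 30 and 50: the green/yellow and yellow/red boundaries).
#' @param coverage_threshold Village area share a zone band must cover to
#'   claim the village (default 0.5).
#' @param max_connector_km Village-to-network walking connector distance
#'   above which an isolation warning is raised.
#' @param exclusion_list Village ids excluded from assignment and zoning
#'   (out-of-study catchments).
#' @param manual_overrides Optional tibble (village_id, route_id) applied
#'   after automatic catchment assignment.
#' @param speed_overrides Optional named vector of speed-table overrides
#'   (see [speed_table()]).
#' @param seed Integer recorded in the manifest and used by any stage that
#'   draws random numbers.
#' @return A `run_config` list.
#' @export
run_config <- function(breaks = c(30, 50), coverage_threshold = 0.5,
                       max_connector_km = 5, exclusion_list = character(),
                       manual_overrides = NULL, speed_overrides = NULL,
                       seed = 1L) {
  stopifnot(length(breaks) == 2, all(breaks > 0), diff(breaks) > 0,
            coverage_threshold > 0, coverage_threshold <= 1)
  structure(list(breaks = breaks, coverage_threshold = coverage_threshold,
                 max_connector_km = max_connector_km,
                 exclusion_list = exclusion_list,
                 manual_overrides = manual_overrides,
                 speed_overrides = speed_overrides, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full referral-transport pipeline
#'
#' Builds the multimodal network, the hub-to-facility route catalog and the
#' village catchments, delineates the travel-time zones and their summary
#' table, and (when a call log is supplied) computes the referral
#' statistics. All artifacts are written under `out_dir`: `routes.csv`,
#' `catchments.csv`, `zones.csv`, `zone_summary.csv`, `stats.json` and
#' `manifest.json`.
#'
#' @param geodata Either a scenario bundle from [generate_scenario()] or a
#'   directory containing `villages.geojson`, `roads.geojson`,
#'   `hubs.geojson`, `facilities.geojson` and optionally
#'   `constraints.geojson`.
#' @param calls Optional call-record tibble or CSV path ([read_call_log()]
#'   layout). Records are joined to zones via their village.
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return Invisible list with `network`, `routes`, `assignments`, `zones`,
#'   `zone_summary`, `stats` (or NULL) and `manifest`.
#' @export
run_pipeline <- function(geodata, calls = NULL, config = run_config(),
                         out_dir = NULL) {
  if (is.character(geodata)) {
    geodata <- stage("read_geodata", {
      cpath <- file.path(geodata, "constraints.geojson")
      list(
        villages = read_geodata(file.path(geodata, "villages.geojson"), "villages"),
        roads = read_geodata(file.path(geodata, "roads.geojson"), "roads"),
        hubs = read_geodata(file.path(geodata, "hubs.geojson"), "hubs"),
        facilities = read_geodata(file.path(geodata, "facilities.geojson"),
                                  "facilities"),
        constraints = if (file.exists(cpath)) read_geodata(cpath, "constraints")
      )
    })
  }
  speeds <- speed_table(config$speed_overrides)
  network <- stage("build_network",
    build_network(geodata$villages, geodata$roads, geodata$constraints,
                  speeds, config$max_connector_km))
  catalog <- stage("build_route_catalog",
    build_route_catalog(network, geodata$hubs, geodata$facilities))
  asg <- stage("assign_catchments",
    assign_catchments(catalog, geodata$villages, network,
                      config$manual_overrides, config$exclusion_list))
  sa <- stage("service_polygons",
    service_polygons(network, geodata$facilities, config$breaks))
  zones <- stage("assign_zones",
    assign_zones(geodata$villages, sa, config$exclusion_list,
                 config$coverage_threshold))
  zsum <- stage("zone_summary", zone_summary(geodata$villages, zones))
  stats <- NULL
  if (!is.null(calls)) {
    stats <- stage("analytics", {
      if (is.character(calls)) calls <- read_call_log(calls)
      if (!"zone" %in% names(calls)) {
        calls$zone <- zones$zone[match(calls$village_id, zones$village_id)]
      }
      if (!"semester" %in% names(calls)) {
        calls$semester <- call_semester(calls$date)
      }
      referral_statistics(tabulate_calls(calls[calls$referred == 1L, ]))
    })
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("refnet")),
    seed = config$seed, breaks = config$breaks,
    coverage_threshold = config$coverage_threshold,
    max_connector_km = config$max_connector_km,
    n_villages = nrow(geodata$villages), n_routes = nrow(catalog),
    n_active_routes = sum(catalog$active),
    excluded_villages = length(config$exclusion_list))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_route_catalog(asg$routes, file.path(out_dir, "routes.csv"))
    readr::write_csv(asg$assignments, file.path(out_dir, "catchments.csv"),
                     progress = FALSE)
    readr::write_csv(zones, file.path(out_dir, "zones.csv"), progress = FALSE)
    readr::write_csv(zsum, file.path(out_dir, "zone_summary.csv"),
                     progress = FALSE)
    if (!is.null(stats)) {
      jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(network = network, routes = asg$routes,
                 assignments = asg$assignments, zones = zones,
                 zone_summary = zsum, stats = stats, manifest = manifest))
}
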