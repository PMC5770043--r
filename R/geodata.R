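# Domain collections and file I/O. Every layer is a tibble with one row per
# feature; geometries live in list-columns of (x, y) km matrices on a planar
# projected plane. Files are GeoJSON FeatureCollections carrying a
# `metadata.coordinate_system = "planar_km"` member; geographic (lon/lat)
# inputs are rejected rather than silently projected, because all distances
# in the model are ground distances.

LAYER_KINDS <- c("villages", "roads", "hubs", "facilities", "constraints")
PLANAR_TAG <- "planar_km"

new_layer <- function(tbl, kind) {
  structure(tbl, class = c(paste0("rn_", kind), class(tbl)))
}

layer_kind <- function(x) {
  for (k in LAYER_KINDS) if (inherits(x, paste0("rn_", k))) return(k)
  stop("object is not a refnet geodata layer", call. = FALSE)
}

#' Construct a villages layer
#'
#' @param village_id,name Character vectors.
#' @param boundary List of (x, y) km matrices, one open polygon ring each.
#' @param population,households Non-negative integer vectors.
#' @param union_id,upazila_id Administrative unit identifiers.
#' @return A `rn_villages` tibble; centroid columns (`cx`, `cy`) and
#'   `area_km2` are derived from the boundary.
#' @export
villages <- function(village_id, name, boundary, population,
                     households = NA_integer_, union_id = NA_character_,
                     upazila_id = NA_character_) {
  cen <- t(vapply(boundary, polygon_centroid, numeric(2)))
  tbl <- tibble::tibble(
    village_id = as.character(village_id), name = as.character(name),
    boundary = boundary,
    population = as.integer(population),
    households = as.integer(households),
    union_id = as.character(union_id), upazila_id = as.character(upazila_id),
    cx = cen[, 1], cy = cen[, 2],
    area_km2 = vapply(boundary, polygon_area, numeric(1))
  )
  validate_villages(tbl)
  new_layer(tbl, "villages")
}

validate_villages <- function(tbl) {
  stopifnot(!anyDuplicated(tbl$village_id))
  if (any(tbl$population < 0, na.rm = TRUE)) {
    stop("village population must be non-negative", call. = FALSE)
  }
  bad <- tbl$area_km2 <= 0
  if (any(bad)) {
    stop("degenerate village boundary (non-positive area): ",
         paste(tbl$village_id[bad], collapse = ", "), call. = FALSE)
  }
  inside <- mapply(function(r, x, y) point_in_polygon(x, y, r),
                   tbl$boundary, tbl$cx, tbl$cy)
  if (!all(inside)) {
    stop("village centroid outside boundary: ",
         paste(tbl$village_id[!inside], collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

#' Construct a roads layer (roads and waterways)
#'
#' @param segment_id Character vector.
#' @param geometry List of (x, y) km polyline matrices.
#' @param road_type One of paved, herringbone, unpaved, waterway per segment.
#' @param width_ft Road width in feet; `NA` for waterways.
#' @param fixed_route_modes List of character vectors (subset of tempo, cng,
#'   nasiman); only meaningful on paved segments.
#' @return A `rn_roads` tibble with derived `length_km`.
#' @export
roads <- function(segment_id, geometry, road_type, width_ft = NA_real_,
                  fixed_route_modes = NULL) {
  n <- length(segment_id)
  if (is.null(fixed_route_modes)) fixed_route_modes <- rep(list(character()), n)
  tbl <- tibble::tibble(
    segment_id = as.character(segment_id), geometry = geometry,
    road_type = as.character(road_type),
    width_ft = as.numeric(rep_len(width_ft, n)),
    fixed_route_modes = fixed_route_modes,
    length_km = vapply(geometry, polyline_length, numeric(1))
  )
  validate_roads(tbl)
  new_layer(tbl, "roads")
}

validate_roads <- function(tbl) {
  bad <- !tbl$road_type %in% ROAD_TYPES
  if (any(bad)) {
    stop("unknown road_type for segment(s): ",
         paste(tbl$segment_id[bad], collapse = ", "), call. = FALSE)
  }
  ww <- tbl$road_type == "waterway"
  if (any(ww & !is.na(tbl$width_ft))) {
    stop("waterway segments must not carry width_ft: ",
         paste(tbl$segment_id[ww & !is.na(tbl$width_ft)], collapse = ", "),
         call. = FALSE)
  }
  frm_n <- lengths(tbl$fixed_route_modes)
  if (any(ww & frm_n > 0)) {
    stop("waterway segments cannot carry fixed-route modes", call. = FALSE)
  }
  if (any(frm_n > 0 & tbl$road_type != "paved")) {
    stop("fixed-route services run on paved segments only: ",
         paste(tbl$segment_id[frm_n > 0 & tbl$road_type != "paved"],
               collapse = ", "), call. = FALSE)
  }
  badm <- vapply(tbl$fixed_route_modes,
                 function(m) any(!m %in% FIXED_ROUTE_MODES), logical(1))
  if (any(badm)) stop("unknown fixed-route mode", call. = FALSE)
  invisible(tbl)
}

#' Construct a hubs layer (vehicle pick-up points)
#'
#' @param hub_id,name Character vectors.
#' @param x,y Planar km coordinates.
#' @param kind `"hub"` (route-anchoring market stand) or `"sub_hub"`
#'   (intermediate stop).
#' @return A `rn_hubs` tibble.
#' @export
hubs <- function(hub_id, x, y, kind = "hub", name = hub_id) {
  stopifnot(all(kind %in% c("hub", "sub_hub")))
  new_layer(tibble::tibble(
    hub_id = as.character(hub_id), x = as.numeric(x), y = as.numeric(y),
    kind = as.character(rep_len(kind, length(hub_id))),
    name = as.character(name)
  ), "hubs")
}

#' Construct a health-facilities layer
#'
#' @param facility_id,name Character vectors.
#' @param x,y Planar km coordinates.
#' @param level `"UHC"` (subdistrict hospital), `"district"` or
#'   `"union_clinic"`.
#' @return A `rn_facilities` tibble.
#' @export
facilities <- function(facility_id, x, y, level = "UHC", name = facility_id) {
  stopifnot(all(level %in% c("UHC", "district", "union_clinic")))
  new_layer(tibble::tibble(
    facility_id = as.character(facility_id), x = as.numeric(x),
    y = as.numeric(y), level = as.character(rep_len(level, length(facility_id))),
    name = as.character(name)
  ), "facilities")
}

#' Construct a constraints layer
#'
#' Constraints attach to road segments: a single-pole bamboo bridge forces
#' everyone to walk; a natural barrier (river, canal, wetland) blocks passage
#' entirely.
#'
#' @param constraint_id Character vector.
#' @param segment_id Segment each constraint applies to.
#' @param kind `"bamboo_bridge"` or `"natural_barrier"`.
#' @param effect `"forces_walk"` or `"blocks_passage"`.
#' @return A `rn_constraints` tibble.
#' @export
constraints <- function(constraint_id, segment_id, kind, effect) {
  stopifnot(all(kind %in% c("bamboo_bridge", "natural_barrier")),
            all(effect %in% c("forces_walk", "blocks_passage")))
  if (any(effect == "forces_walk" & kind != "bamboo_bridge")) {
    stop("forces_walk is valid only for bamboo_bridge constraints",
         call. = FALSE)
  }
  new_layer(tibble::tibble(
    constraint_id = as.character(constraint_id),
    segment_id = as.character(segment_id),
    kind = as.character(kind), effect = as.character(effect)
  ), "constraints")
}

coords_to_list <- function(m) lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))

feature <- function(geom_type, coords, props) {
  list(type = "Feature", geometry = list(type = geom_type, coordinates = coords),
       properties = props)
}

#' Write a geodata layer to GeoJSON
#'
#' The file is a FeatureCollection with a `metadata.coordinate_system =
#' "planar_km"` foreign member declaring the planar km coordinate convention;
#' [read_geodata()] of the result reproduces the layer field-for-field.
#'
#' @param collection A layer built by [villages()], [roads()], [hubs()],
#'   [facilities()] or [constraints()], or read by [read_geodata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geodata <- function(collection, path) {
  kind <- layer_kind(collection)
  if (nrow(collection) == 0) stop("refusing to write an empty collection",
                                  call. = FALSE)
  feats <- switch(kind,
    villages = lapply(seq_len(nrow(collection)), function(i) {
      r <- collection[i, ]
      ring <- r$boundary[[1]]
      ring_closed <- rbind(ring, ring[1, ])
      feature("Polygon", list(coords_to_list(ring_closed)), list(
        village_id = r$village_id, name = r$name, population = r$population,
        households = r$households, union_id = r$union_id,
        upazila_id = r$upazila_id))
    }),
    roads = lapply(seq_len(nrow(collection)), function(i) {
      r <- collection[i, ]
      feature("LineString", coords_to_list(r$geometry[[1]]), list(
        segment_id = r$segment_id, road_type = r$road_type,
        width_ft = r$width_ft, fixed_route_modes = I(r$fixed_route_modes[[1]])))
    }),
    hubs = lapply(seq_len(nrow(collection)), function(i) {
      r <- collection[i, ]
      feature("Point", c(r$x, r$y), list(
        hub_id = r$hub_id, kind = r$kind, name = r$name))
    }),
    facilities = lapply(seq_len(nrow(collection)), function(i) {
      r <- collection[i, ]
      feature("Point", c(r$x, r$y), list(
        facility_id = r$facility_id, level = r$level, name = r$name))
    }),
    constraints = lapply(seq_len(nrow(collection)), function(i) {
      r <- collection[i, ]
      feature("Point", c(0, 0), list(
        constraint_id = r$constraint_id, segment_id = r$segment_id,
        kind = r$kind, effect = r$effect))
    })
  )
  obj <- list(type = "FeatureCollection",
              metadata = list(coordinate_system = PLANAR_TAG, layer = kind),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

prop <- function(f, name, id, required = TRUE) {
  v <- f$properties[[name]]
  if (is.null(v) || (length(v) == 1 && is.na(v))) {
    if (required) {
      stop("feature '", id, "' is missing required property '", name, "'",
           call. = FALSE)
    }
    return(NA)
  }
  v
}

coords_matrix <- function(cc) {
  do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
}

#' Read a geodata layer from GeoJSON
#'
#' Expects a FeatureCollection written in planar km coordinates with the
#' `metadata.coordinate_system` member set to `"planar_km"`. Files without it
#' (typically geographic lon/lat data) are rejected: this package never
#' projects coordinates implicitly.
#'
#' @param path File path.
#' @param layer_kind One of `"villages"`, `"roads"`, `"hubs"`,
#'   `"facilities"`, `"constraints"`.
#' @return The matching layer tibble.
#' @export
read_geodata <- function(path, layer_kind) {
  layer_kind <- match.arg(layer_kind, LAYER_KINDS)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cs <- obj$metadata$coordinate_system
  if (is.null(cs) || !identical(cs, PLANAR_TAG)) {
    stop("coordinate-system error: file does not declare planar km ",
         "coordinates (metadata.coordinate_system = 'planar_km'); ",
         "geographic lon/lat input must be projected upstream", call. = FALSE)
  }
  fs <- obj$features
  get_id <- function(f, key) {
    v <- f$properties[[key]]
    if (is.null(v)) "<missing id>" else as.character(v)
  }
  switch(layer_kind,
    villages = {
      ids <- vapply(fs, get_id, "", key = "village_id")
      villages(
        village_id = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "village_id", ids[i])), ""),
        name = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "name", ids[i])), ""),
        boundary = lapply(fs, function(f) {
          ring <- coords_matrix(f$geometry$coordinates[[1]])
          # drop the closing vertex GeoJSON repeats
          if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
          ring
        }),
        population = vapply(seq_along(fs), function(i)
          as.integer(prop(fs[[i]], "population", ids[i])), 1L),
        households = vapply(seq_along(fs), function(i)
          as.integer(prop(fs[[i]], "households", ids[i], required = FALSE)), 1L),
        union_id = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "union_id", ids[i], required = FALSE)), ""),
        upazila_id = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "upazila_id", ids[i], required = FALSE)), "")
      )
    },
    roads = {
      ids <- vapply(fs, get_id, "", key = "segment_id")
      roads(
        segment_id = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "segment_id", ids[i])), ""),
        geometry = lapply(fs, function(f) coords_matrix(f$geometry$coordinates)),
        road_type = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "road_type", ids[i])), ""),
        width_ft = vapply(seq_along(fs), function(i)
          as.numeric(prop(fs[[i]], "width_ft", ids[i], required = FALSE)), 1),
        fixed_route_modes = lapply(fs, function(f) {
          v <- f$properties$fixed_route_modes
          if (is.null(v)) character() else as.character(unlist(v))
        })
      )
    },
    hubs = {
      ids <- vapply(fs, get_id, "", key = "hub_id")
      hubs(
        hub_id = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "hub_id", ids[i])), ""),
        x = vapply(fs, function(f) as.numeric(f$geometry$coordinates[[1]]), 1),
        y = vapply(fs, function(f) as.numeric(f$geometry$coordinates[[2]]), 1),
        kind = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "kind", ids[i])), ""),
        name = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "name", ids[i], required = FALSE)), "")
      )
    },
    facilities = {
      ids <- vapply(fs, get_id, "", key = "facility_id")
      facilities(
        facility_id = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "facility_id", ids[i])), ""),
        x = vapply(fs, function(f) as.numeric(f$geometry$coordinates[[1]]), 1),
        y = vapply(fs, function(f) as.numeric(f$geometry$coordinates[[2]]), 1),
        level = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "level", ids[i])), ""),
        name = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "name", ids[i], required = FALSE)), "")
      )
    },
    constraints = {
      ids <- vapply(fs, get_id, "", key = "constraint_id")
      constraints(
        constraint_id = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "constraint_id", ids[i])), ""),
        segment_id = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "segment_id", ids[i])), ""),
        kind = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "kind", ids[i])), ""),
        effect = vapply(seq_along(fs), function(i)
          as.character(prop(fs[[i]], "effect", ids[i])), "")
      )
    }
  )
}

CALL_WINDOW <- c(as.Date("2013-10-01"), as.Date("2015-09-30"))

#' Semester index (1-4) of a call date
#'
#' Semesters are the four six-month bins of the two-year call-centre window:
#' S1 Oct 2013 - Mar 2014, S2 Apr - Sep 2014, S3 Oct 2014 - Mar 2015,
#' S4 Apr - Sep 2015.
#'
#' @param date A `Date` vector within the window.
#' @return Integer vector in 1:4.
#' @export
call_semester <- function(date) {
  m <- as.integer(format(date, "%m"))
  y <- as.integer(format(date, "%Y"))
  # months since Oct 2013, integer-divided into 6-month bins
  1L + ((y - 2013L) * 12L + (m - 10L)) %/% 6L
}

#' Read and validate a referral call log
#'
#' The CSV must have columns `call_id`, `date` (ISO-8601, within the Oct 2013
#' - Sep 2015 service window), `village_id`, `referred` (0/1), `complied`
#' (0/1, empty when not referred) and `used_transport` (0/1, empty unless
#' complied): a patient can only use the project's dispatched transport after
#' complying with a referral. Records whose village could not be ascertained
#' (`village_id` `"unknown"` or empty) are dropped with a message; the count
#' is kept in the `dropped_unknown_village` attribute.
#'
#' @param path CSV file path.
#' @return Tibble of call records with a derived `semester` column.
#' @export
read_call_log <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    call_id = readr::col_character(), date = readr::col_date(),
    village_id = readr::col_character(), referred = readr::col_integer(),
    complied = readr::col_integer(), used_transport = readr::col_integer()
  ), progress = FALSE)
  if (any(is.na(tbl$date))) stop("unparseable date in call log", call. = FALSE)
  out <- tbl$date < CALL_WINDOW[1] | tbl$date > CALL_WINDOW[2]
  if (any(out)) {
    stop("range error: call date outside the Oct 2013-Sep 2015 window: ",
         paste(utils::head(tbl$call_id[out], 5), collapse = ", "), call. = FALSE)
  }
  tbl$referred <- ifelse(is.na(tbl$referred), 0L, tbl$referred)
  tbl$complied <- ifelse(is.na(tbl$complied), 0L, tbl$complied)
  tbl$used_transport <- ifelse(is.na(tbl$used_transport), 0L, tbl$used_transport)
  bad <- tbl$used_transport > tbl$complied | tbl$complied > tbl$referred
  if (any(bad)) {
    stop("consistency error: used_transport <= complied <= referred violated ",
         "for call(s): ", paste(utils::head(tbl$call_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  unknown <- is.na(tbl$village_id) | tbl$village_id %in% c("", "unknown")
  if (any(unknown)) {
    message("dropping ", sum(unknown),
            " call(s) whose village could not be ascertained")
  }
  tbl <- tbl[!unknown, , drop = FALSE]
  tbl$semester <- call_semester(tbl$date)
  attr(tbl, "dropped_unknown_village") <- sum(unknown)
  tbl
}

#' Write a call log CSV
#'
#' @param calls Call-record tibble (as from [read_call_log()] or
#'   [generate_call_log()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_log <- function(calls, path) {
  cols <- c("call_id", "date", "village_id", "referred", "complied",
            "used_transport")
  readr::write_csv(calls[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write a route catalog CSV
#'
#' One row per route in the published catalog layout: identifier, name, mode,
#' distance (km), travel time (minutes) and catchment population.
#'
#' @param routes Route catalog (see [build_route_catalog()] or
#'   [table_fixtures()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_route_catalog <- function(routes, path) {
  out <- tibble::tibble(
    route_id = routes$route_id, route_name = routes$name, mode = routes$mode,
    distance_km = routes$distance_km,
    time_min = round_half_up(routes$time_min, 2),
    catchment_population = routes$catchment_population,
    active = routes$active
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
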