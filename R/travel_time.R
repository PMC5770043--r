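# The travel-time cost model: field-measured speeds per (mode, road type),
# the 5-ft road-width accessibility rule, and segment/path time computation.
# Times are minutes: t = 60 * length_km / speed_kmh.

ROAD_TYPES <- c("paved", "herringbone", "unpaved", "waterway")
MODES <- c("rickshaw", "tempo", "cng", "walk", "boat", "nasiman")
FIXED_ROUTE_MODES <- c("tempo", "cng", "nasiman")

#' Default mode-by-road-type speed table
#'
#' Field-measured speeds (km/h) for the transport modes of the study area:
#' rickshaw/rickshaw-van on paved 8.05, herringbone 8.55, unpaved 7.10; tempo
#' (diesel auto-rickshaw) 12.64 on paved; CNG (gas auto-rickshaw) 20.40 on
#' paved; walking 4.00 on every road type; engine boat 8.00 on waterways.
#' A nasiman entry (12.63 km/h on paved, back-derived from its route's
#' published distance and time) is included so nasiman-served corridors can be
#' timed, but flagged non-dispatchable: the vehicle is deemed unsafe for
#' patient transport and never enters the referral fleet.
#'
#' @param overrides Optional named numeric vector of replacement speeds, names
#'   `"mode.road_type"` (e.g. `c("cng.paved" = 22)`). New pairs may be added.
#' @return Tibble with columns `mode`, `road_type`, `speed_kmh`,
#'   `dispatchable`.
#' @export
speed_table <- function(overrides = NULL) {
  tb <- tibble::tribble(
    ~mode,      ~road_type,    ~speed_kmh, ~dispatchable,
    "rickshaw", "paved",        8.05, TRUE,
    "rickshaw", "herringbone",  8.55, TRUE,
    "rickshaw", "unpaved",      7.10, TRUE,
    "tempo",    "paved",       12.64, TRUE,
    "cng",      "paved",       20.40, TRUE,
    "walk",     "paved",        4.00, TRUE,
    "walk",     "herringbone",  4.00, TRUE,
    "walk",     "unpaved",      4.00, TRUE,
    "boat",     "waterway",     8.00, TRUE,
    "nasiman",  "paved",       12.63, FALSE
  )
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)), all(overrides > 0))
    for (key in names(overrides)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !parts[1] %in% MODES || !parts[2] %in% ROAD_TYPES) {
        stop("speed override key must be 'mode.road_type', got: ", key)
      }
      hit <- tb$mode == parts[1] & tb$road_type == parts[2]
      if (any(hit)) {
        tb$speed_kmh[hit] <- overrides[[key]]
      } else {
        tb <- dplyr::bind_rows(tb, tibble::tibble(
          mode = parts[1], road_type = parts[2],
          speed_kmh = overrides[[key]], dispatchable = parts[1] != "nasiman"
        ))
      }
    }
  }
  tb
}

#' Look up a mode's speed on a road type
#'
#' @param mode One of `r toString(MODES)`.
#' @param road_type One of paved, herringbone, unpaved, waterway.
#' @param table Speed table, see [speed_table()].
#' @return Speed in km/h.
#' @export
lookup_speed <- function(mode, road_type, table = speed_table()) {
  hit <- table$mode == mode & table$road_type == road_type
  if (!any(hit)) {
    stop("undefined speed for mode '", mode, "' on road type '", road_type,
         "'", call. = FALSE)
  }
  table$speed_kmh[hit][1]
}

#' Transport modes able to traverse a road or waterway segment
#'
#' Encodes the accessibility rule of the cost model: waterways carry boats
#' only; roads under 5 ft wide are walk-only (no vehicle fits); roads of 5 ft
#' or wider carry rickshaws and pedestrians, plus any fixed-route service
#' (tempo/CNG/nasiman) operating on the segment. A forces_walk constraint
#' (single-pole bamboo bridge) reduces the set to walking; a blocks_passage
#' constraint (natural barrier) empties it.
#'
#' @param road_type Segment road type.
#' @param width_ft Road width in feet (ignored for waterways).
#' @param fixed_route_modes Character vector of fixed-route services on the
#'   segment (subset of tempo, cng, nasiman).
#' @param constraint `NA`/`NULL`, `"forces_walk"` or `"blocks_passage"`.
#' @return Ordered character vector of modes (fixed services first, then
#'   rickshaw, then walk).
#' @export
applicable_modes <- function(road_type, width_ft = NA_real_,
                             fixed_route_modes = character(),
                             constraint = NULL) {
  if (!is.null(constraint) && !is.na(constraint)) {
    if (constraint == "blocks_passage") return(character())
    if (constraint == "forces_walk") return("walk")
    stop("unknown constraint effect: ", constraint)
  }
  if (road_type == "waterway") return("boat")
  if (!is.na(width_ft) && width_ft < 5) return("walk")
  fixed <- FIXED_ROUTE_MODES[FIXED_ROUTE_MODES %in% fixed_route_modes]
  c(fixed, "rickshaw", "walk")
}

#' Travel time over one segment
#'
#' @param length_km Segment length, km (>= 0).
#' @param mode Transport mode.
#' @param road_type Road type.
#' @param table Speed table.
#' @return Minutes.
#' @export
segment_time <- function(length_km, mode, road_type, table = speed_table()) {
  stopifnot(length_km >= 0)
  60 * length_km / lookup_speed(mode, road_type, table)
}

#' Travel time over a multi-leg path
#'
#' Sums per-leg times; additive over concatenation, so a journey decomposed as
#' walk-to-hub then vehicle-to-facility is the sum of its legs.
#'
#' @param legs Data frame with columns `length_km`, `mode`, `road_type` (one
#'   row per leg, in order), or a list of such length-3 vectors/lists.
#' @param table Speed table.
#' @return Minutes (0 for an empty path).
#' @export
path_time <- function(legs, table = speed_table()) {
  if (is.list(legs) && !is.data.frame(legs)) {
    legs <- do.call(rbind, lapply(legs, function(l) {
      data.frame(length_km = as.numeric(l[[1]]), mode = as.character(l[[2]]),
                 road_type = as.character(l[[3]]))
    }))
  }
  if (is.null(legs) || nrow(legs) == 0) return(0)
  sum(vapply(seq_len(nrow(legs)), function(i) {
    segment_time(legs$length_km[i], legs$mode[i], legs$road_type[i], table)
  }, numeric(1)))
}
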