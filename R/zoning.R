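# Travel-time zoning of facility catchments. Zones are delineated under a
# rickshaw-only policy (rickshaw being the ubiquitous mode): green <= 30
# minutes, yellow 30-50, red > 50. The service area is realised as buffered
# network reach: travel time is known at network vertices and along edges,
# and any off-network point adds straight-line walking (4 km/h) to its
# nearest reached network point. Village labels follow the 50%-coverage
# rule on the village polygon.

#' Rickshaw-policy travel time from each village to its nearest facility
#'
#' Minimum over facilities of the shortest-path time under the
#' `rickshaw_only` policy (rickshaw on vehicle-passable roads, walking on
#' sub-5-ft roads, boat on waterways).
#'
#' @param network A `transport_network` with villages attached.
#' @param facility_tbl Facilities layer.
#' @param village_ids Villages to report (default: all attached).
#' @return Tibble (village_id, minutes); `Inf` marks disconnected villages.
#' @export
village_facility_time <- function(network, facility_tbl,
                                  village_ids = NULL) {
  if (is.null(village_ids)) village_ids <- network$village_vertices$village_id
  w <- policy_weights(network, "rickshaw_only")
  adjl <- adjacency(network, w)
  fv <- vapply(seq_len(nrow(facility_tbl)), function(i)
    snap_to_vertex(network, facility_tbl$x[i], facility_tbl$y[i],
                   what = paste0("facility ", facility_tbl$facility_id[i])),
    character(1))
  dists <- vapply(fv, function(v) dijkstra_dist(adjl, adjl$idx[[v]]),
                  numeric(length(adjl$adj)))
  best <- apply(dists, 1, min)
  tibble::tibble(village_id = village_ids,
                 minutes = best[adjl$idx[village_ids]])
}

#' Facility service area at travel-time breaks
#'
#' Computes rickshaw-policy travel times at every network vertex and at
#' interpolated points along every passable edge, from the given facility
#' (or facilities: the pooled multi-facility service area is the pointwise
#' minimum). The reachable region within break b is the union of walking
#' buffers around network points with time t <= b (buffer radius =
#' remaining time x 4 km/h); regions are nested in b by construction.
#'
#' @param network A `transport_network`.
#' @param facility_tbl One or more facilities (rows of a facilities layer).
#' @param breaks Ascending minutes, default `c(30, 50)`.
#' @param sample_km Spacing of interpolated points along edges (km); the
#'   band boundary's positional error is bounded by about half this
#'   spacing times the walking pace.
#' @return A `service_area` object: sample points with minutes, the breaks
#'   and the walking speed.
#' @export
service_polygons <- function(network, facility_tbl, breaks = c(30, 50),
                             sample_km = 0.1) {
  stopifnot(all(diff(breaks) > 0), all(breaks > 0))
  w <- policy_weights(network, "rickshaw_only")
  adjl <- adjacency(network, w)
  fv <- vapply(seq_len(nrow(facility_tbl)), function(i)
    snap_to_vertex(network, facility_tbl$x[i], facility_tbl$y[i],
                   what = paste0("facility ", facility_tbl$facility_id[i])),
    character(1))
  dists <- vapply(fv, function(v) dijkstra_dist(adjl, adjl$idx[[v]]),
                  numeric(length(adjl$adj)))
  tv <- apply(dists, 1, min)
  if (all(!is.finite(tv))) {
    stop("degenerate service area: nothing reachable", call. = FALSE)
  }
  vv <- network$vertices
  pts <- cbind(vv$x, vv$y, tv)
  ed <- network$edges
  keep <- is.finite(w) & !startsWith(ed$segment_id, "connector_")
  for (i in which(keep)) {
    iu <- adjl$idx[[ed$from[i]]]; iv <- adjl$idx[[ed$to[i]]]
    if (!is.finite(tv[iu]) && !is.finite(tv[iv])) next
    L <- ed$length_km[i]
    n_int <- floor(L / sample_km)
    if (n_int < 1) next
    fr <- seq_len(n_int) * sample_km / L
    x <- vv$x[iu] + fr * (vv$x[iv] - vv$x[iu])
    y <- vv$y[iu] + fr * (vv$y[iv] - vv$y[iu])
    tt <- pmin(tv[iu] + fr * w[i], tv[iv] + (1 - fr) * w[i])
    pts <- rbind(pts, cbind(x, y, tt))
  }
  pts <- pts[is.finite(pts[, 3]), , drop = FALSE]
  structure(list(points = pts, breaks = breaks, walk_kmh = WALK_KMH),
            class = "service_area")
}

#' @export
print.service_area <- function(x, ...) {
  cat("<service_area> breaks ", paste(x$breaks, collapse = "/"),
      " min; ", nrow(x$points), " network sample points\n", sep = "")
  invisible(x)
}

#' Travel time of arbitrary plane points under a service area
#'
#' t(p) = min over network sample points q of t(q) + walking time over the
#' straight-line distance p-q. Points beyond every buffer return `Inf`
#' (they exceed the largest break).
#'
#' @param sa A `service_area`.
#' @param pts Matrix (x, y) of query points.
#' @return Minutes per point.
#' @export
service_time <- function(sa, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2)
  q <- sa$points
  per_km <- 60 / sa$walk_kmh
  out <- numeric(nrow(pts))
  chunk <- 256L
  for (s in seq(1, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    dx <- outer(pts[s:e, 1], q[, 1], "-")
    dy <- outer(pts[s:e, 2], q[, 2], "-")
    tt <- sqrt(dx * dx + dy * dy) * per_km +
      matrix(q[, 3], nrow = e - s + 1L, ncol = nrow(q), byrow = TRUE)
    out[s:e] <- tt[cbind(seq_len(nrow(tt)), max.col(-tt, "first"))]
  }
  out
}

zone_of_time <- function(t, breaks) {
  ifelse(t <= breaks[1], "green", ifelse(t <= breaks[2], "yellow", "red"))
}

#' Zone label of one village under the 50%-coverage rule
#'
#' Computes the share of the village polygon lying in each travel-time band
#' (on a deterministic interior grid) and assigns the band covering at
#' least the coverage threshold of the village; when no band reaches it,
#' the largest share wins; all ties resolve toward the faster (greener)
#' band. A fast path labels the village directly when its boundary
#' vertices, centroid and grid all fall in one band.
#'
#' @param boundary Village polygon ring (x, y km matrix).
#' @param sa A `service_area` with two breaks.
#' @param coverage Coverage threshold in (0, 1], default 0.5.
#' @param n_grid Grid resolution per axis for area shares.
#' @return Character zone label with a `shares` attribute (named green /
#'   yellow / red area shares).
#' @export
assign_zone <- function(boundary, sa, coverage = 0.5, n_grid = 12) {
  stopifnot(coverage > 0, coverage <= 1)
  if (polygon_area(boundary) <= 0) {
    stop("degenerate village geometry: zero area", call. = FALSE)
  }
  corners <- service_time(sa, boundary)
  zc <- zone_of_time(corners, sa$breaks)
  if (length(unique(zc)) == 1) {
    # entire convex hull of the boundary could still straddle, but the
    # travel-time field is 1-Lipschitz in walking time, so check margins
    margin <- min(abs(c(corners - sa$breaks[1], corners - sa$breaks[2])))
    diam <- max(stats::dist(boundary))
    if (margin > diam * 60 / sa$walk_kmh) {
      shares <- stats::setNames(as.numeric(zc[1] == c("green", "yellow", "red")),
                                c("green", "yellow", "red"))
      return(structure(zc[1], shares = shares))
    }
  }
  g <- grid_points_in_polygon(boundary, n_grid)
  tz <- zone_of_time(service_time(sa, g), sa$breaks)
  shares <- vapply(c("green", "yellow", "red"),
                   function(z) mean(tz == z), numeric(1))
  qual <- which(shares >= coverage - 1e-9)
  z <- if (length(qual) > 0) qual[1] else {
    m <- max(shares)
    which(shares >= m - 1e-9)[1]
  }
  structure(c("green", "yellow", "red")[z], shares = shares)
}

#' Zone labels for all villages
#'
#' @param villages Villages layer.
#' @param sa A `service_area`.
#' @param exclusion_list Village ids labelled `"excluded"` (out-of-study
#'   catchments).
#' @param coverage,n_grid See [assign_zone()].
#' @return Tibble (village_id, minutes at centroid, zone).
#' @export
assign_zones <- function(villages, sa, exclusion_list = character(),
                         coverage = 0.5, n_grid = 12) {
  zone <- character(nrow(villages))
  for (i in seq_len(nrow(villages))) {
    zone[i] <- if (villages$village_id[i] %in% exclusion_list) "excluded"
      else assign_zone(villages$boundary[[i]], sa, coverage, n_grid)
  }
  tibble::tibble(
    village_id = villages$village_id,
    minutes = service_time(sa, cbind(villages$cx, villages$cy)),
    zone = zone)
}

#' Zone summary table
#'
#' Per-zone village counts, settlement area, population and integer percent
#' of the grand-total population (rounded half-up; the column sums to
#' 100 +- 1 by construction of integer rounding), plus a Total row.
#'
#' @param villages Villages layer.
#' @param zones Tibble (village_id, zone) from [assign_zones()].
#' @return Tibble with rows green, yellow, red, excluded (present zones
#'   only) and Total.
#' @export
zone_summary <- function(villages, zones) {
  stopifnot(!anyDuplicated(zones$village_id))
  m <- match(villages$village_id, zones$village_id)
  if (anyNA(m)) stop("village without a zone label", call. = FALSE)
  zl <- zones$zone[m]
  rows <- dplyr::bind_rows(lapply(
    intersect(ZONE_LEVELS, unique(zl)), function(z) {
      s <- zl == z
      tibble::tibble(zone = z, n_villages = sum(s),
                     settlement_area_km2 = sum(villages$area_km2[s]),
                     population = sum(villages$population[s]))
    }))
  zone_table(rows)
}

#' Finish a zone table: percents and Total row
#'
#' Adds the integer percent-of-total-population column and the Total row to
#' per-zone summary rows; also the entry point for summarising published
#' zone rows directly.
#'
#' @param rows Tibble with columns `zone`, `n_villages`,
#'   `settlement_area_km2`, `population`.
#' @return The rows plus `population_pct` and a `total` row.
#' @export
zone_table <- function(rows) {
  tot <- sum(rows$population)
  rows$population_pct <- as.integer(round_half_up(100 * rows$population / tot))
  dplyr::bind_rows(rows, tibble::tibble(
    zone = "total", n_villages = sum(rows$n_villages),
    settlement_area_km2 = sum(rows$settlement_area_km2),
    population = tot, population_pct = sum(rows$population_pct)))
}
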