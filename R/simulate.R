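# Seeded generators for study-shaped synthetic data: two subdistricts, each
# with one subdistrict hospital, a mixed paved/herringbone/unpaved radial
# road network with fixed tempo/CNG corridors anchored at edge markets, a
# ring road crossing the corridors, a river severing an island strip
# reachable only by boat via ghats, narrow walk-only spur roads, and a
# referral call log with zone-conditional compliance and transport-use
# probabilities. Everything is deterministic for a fixed seed.

#' Scenario generator configuration
#'
#' Defaults emulate the study geography at quarter scale: two 11 x 9 km
#' subdistricts (one flat, one with a river isolating about a third of its
#' villages on islands), roughly 88 villages in jittered-grid partitions
#' (requested counts round up to a full nx x ny grid), 17 route-anchoring
#' hubs, an 80% fixed-route share on paved corridors, and one
#' nasiman-served corridor. `paper_scale = TRUE` quadruples the village
#' counts to about 340.
#'
#' @param seed Integer seed for the geography stream.
#' @param villages_per_subdistrict Length-2 integer; each is rounded to a
#'   full nx x ny grid.
#' @param river Whether subdistrict 1 has a river and islands.
#' @param island_fraction Fraction of subdistrict 1's width cut off by the
#'   river.
#' @param road_type_mix Named proportions over paved/herringbone/unpaved
#'   for the corridors (must sum to 1).
#' @param narrow_road_fraction Share of villages gaining a sub-5-ft
#'   (walk-only) spur road.
#' @param hubs_per_subdistrict Length-2 integer count of route anchors
#'   (subdistrict 1 reserves two for island boat routes when `river`).
#' @param fixed_route_fraction Probability a paved corridor carries a
#'   tempo/CNG service.
#' @param nasiman_route Whether one corridor is served by nasiman only.
#' @param paper_scale Quadruple village counts.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            villages_per_subdistrict = c(36L, 48L),
                            river = TRUE, island_fraction = 1 / 3,
                            road_type_mix = c(paved = 0.45,
                                              herringbone = 0.25,
                                              unpaved = 0.30),
                            narrow_road_fraction = 0.15,
                            hubs_per_subdistrict = c(9L, 8L),
                            fixed_route_fraction = 0.8,
                            nasiman_route = TRUE,
                            paper_scale = FALSE) {
  stopifnot(abs(sum(road_type_mix) - 1) < 1e-9,
            all(villages_per_subdistrict > 0),
            all(hubs_per_subdistrict > 0),
            island_fraction > 0, island_fraction < 1)
  if (paper_scale) villages_per_subdistrict <- villages_per_subdistrict * 4L
  structure(list(
    seed = as.integer(seed),
    villages_per_subdistrict = as.integer(villages_per_subdistrict),
    river = river, island_fraction = island_fraction,
    road_type_mix = road_type_mix,
    narrow_road_fraction = narrow_road_fraction,
    hubs_per_subdistrict = as.integer(hubs_per_subdistrict),
    fixed_route_fraction = fixed_route_fraction,
    nasiman_route = nasiman_route,
    width_km = 11, height_km = 9, densify_km = 0.4
  ), class = "scenario_config")
}

densify <- function(coords, step) {
  out <- coords[1, , drop = FALSE]
  for (i in seq_len(nrow(coords) - 1)) {
    a <- coords[i, ]; b <- coords[i + 1, ]
    L <- sqrt(sum((b - a)^2))
    n <- max(1, ceiling(L / step))
    fr <- seq_len(n) / n
    out <- rbind(out, cbind(a[1] + fr * (b[1] - a[1]),
                            a[2] + fr * (b[2] - a[2])))
  }
  out
}

# point where the ray from centre at angle theta leaves the box, pulled
# inwards by `inset`
ray_box_point <- function(cx, cy, theta, xlim, ylim, inset = 0.4) {
  dx <- cos(theta); dy <- sin(theta)
  ts <- c(
    if (dx > 1e-12) (xlim[2] - cx) / dx else Inf,
    if (dx < -1e-12) (xlim[1] - cx) / dx else Inf,
    if (dy > 1e-12) (ylim[2] - cy) / dy else Inf,
    if (dy < -1e-12) (ylim[1] - cy) / dy else Inf)
  t <- min(ts[ts > 0]) - inset
  c(cx + t * dx, cy + t * dy)
}

jittered_breaks <- function(lo, hi, n, jitter_frac = 0.25) {
  b <- seq(lo, hi, length.out = n + 1)
  step <- (hi - lo) / n
  if (n > 1) {
    b[2:n] <- b[2:n] + stats::runif(n - 1, -jitter_frac, jitter_frac) * step
  }
  b
}

#' Generate a synthetic study scenario
#'
#' See [scenario_config()] for the shape of the world generated. The
#' output bundle feeds directly into [build_network()],
#' [build_route_catalog()], [service_polygons()] and [assign_zones()].
#'
#' @param config A `scenario_config`.
#' @return Named list: `villages`, `roads` (roads + waterways), `hubs`,
#'   `facilities`, `constraints`, `config`, plus `island_villages`
#'   (ids generated on the far side of the river).
#' @export
generate_scenario <- function(config = scenario_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  W <- config$width_km; H <- config$height_km
  step <- config$densify_km
  vil_rows <- list(); road_rows <- list(); hub_rows <- list()
  fac_rows <- list(); island_ids <- character()
  seg_n <- 0L
  new_seg_id <- function() {
    seg_n <<- seg_n + 1L
    sprintf("s%03d", seg_n)
  }
  for (s in seq_len(2)) {
    off <- (s - 1) * W
    has_river <- config$river && s == 1L
    x_r <- off + if (has_river) config$island_fraction * W else 0
    main_xlim <- c(if (has_river) x_r + 0.15 else off + 0.15, off + W - 0.15)
    ylim <- c(0.15, H - 0.15)
    fx <- main_xlim[1] + 0.35 * diff(main_xlim)
    fy <- 0.5 * H + stats::runif(1, -0.5, 0.5)
    fac_rows[[s]] <- tibble::tibble(
      facility_id = sprintf("uhc%d", s), x = fx, y = fy, level = "UHC",
      name = sprintf("Subdistrict %d UHC", s))

    # villages: jittered-grid partition of the subdistrict
    n_v <- config$villages_per_subdistrict[s]
    ny <- max(1L, floor(sqrt(n_v * H / W)))
    nx <- as.integer(ceiling(n_v / ny))
    bx <- jittered_breaks(off, off + W, nx)
    by <- jittered_breaks(0, H, ny)
    k <- 0L
    for (ix in seq_len(nx)) {
      for (iy in seq_len(ny)) {
        k <- k + 1L
        vid <- sprintf("sd%d_v%03d", s, k)
        ring <- rbind(c(bx[ix], by[iy]), c(bx[ix + 1], by[iy]),
                      c(bx[ix + 1], by[iy + 1]), c(bx[ix], by[iy + 1]))
        cen <- polygon_centroid(ring)
        if (has_river && cen[1] < x_r) island_ids <- c(island_ids, vid)
        vil_rows[[length(vil_rows) + 1L]] <- list(
          village_id = vid, name = paste0("Village ", vid), ring = ring,
          population = max(50L, as.integer(round(stats::rlnorm(1, log(1150), 0.55)))),
          union_id = sprintf("sd%d_u%d", s, 1L + (ix - 1L) %/% 2L),
          upazila_id = sprintf("sd%d", s))
      }
    }

    # radial corridors from edge markets (hubs) to the facility
    n_hub <- config$hubs_per_subdistrict[s]
    n_island <- if (has_river) 2L else 0L
    n_corr <- n_hub - n_island
    theta <- seq(0, 2 * pi, length.out = n_corr + 1)[-(n_corr + 1)] +
      stats::runif(n_corr, -0.1, 0.1)
    types <- sample(rep(names(config$road_type_mix),
                        times = round(config$road_type_mix * n_corr * 2)),
                    n_corr)
    widths <- c(paved = 12, herringbone = 8, unpaved = 6)
    nasiman_done <- FALSE
    corridor_hub_xy <- matrix(numeric(0), ncol = 2)
    for (j in seq_len(n_corr)) {
      hxy <- ray_box_point(fx, fy, theta[j], main_xlim, ylim)
      vias <- lapply(c(0.35, 0.7), function(fr) {
        p <- c(fx, fy) + fr * (hxy - c(fx, fy))
        perp <- c(-(hxy - c(fx, fy))[2], (hxy - c(fx, fy))[1])
        perp <- perp / sqrt(sum(perp^2))
        p + perp * stats::runif(1, -0.4, 0.4)
      })
      line <- rbind(c(fx, fy), vias[[1]], vias[[2]], hxy)
      ty <- types[j]
      serv <- character()
      if (ty == "paved" && stats::runif(1) < config$fixed_route_fraction) {
        serv <- if (stats::runif(1) < 0.5) "tempo" else "cng"
      }
      if (config$nasiman_route && !nasiman_done && s == 2L &&
          ty == "paved" && length(serv) > 0) {
        serv <- "nasiman"
        nasiman_done <- TRUE
      }
      road_rows[[length(road_rows) + 1L]] <- list(
        segment_id = new_seg_id(), geometry = densify(line, step),
        road_type = ty, width_ft = widths[[ty]], fixed = serv)
      hid <- sprintf("sd%d_h%02d", s, j)
      hub_rows[[length(hub_rows) + 1L]] <- tibble::tibble(
        hub_id = hid, x = hxy[1], y = hxy[2], kind = "hub",
        name = sprintf("Market %d-%d", s, j))
      for (q in 1:2) {
        hub_rows[[length(hub_rows) + 1L]] <- tibble::tibble(
          hub_id = sprintf("%s_s%d", hid, q), x = vias[[q]][1],
          y = vias[[q]][2], kind = "sub_hub",
          name = sprintf("Stop %d-%d-%d", s, j, q))
      }
      corridor_hub_xy <- rbind(corridor_hub_xy, hxy)
    }

    # ring road crossing the corridors (exercises noding at crossings)
    r_ring <- 0.45 * min(diff(main_xlim) / 2, H / 2)
    ang <- seq(0, 2 * pi, length.out = 25)
    ring_line <- cbind(fx + r_ring * cos(ang), fy + r_ring * sin(ang))
    road_rows[[length(road_rows) + 1L]] <- list(
      segment_id = new_seg_id(), geometry = ring_line,
      road_type = "herringbone", width_ft = 8, fixed = character())

    if (has_river) {
      # island spine + bank roads + boat crossings to a mainland ghat road
      spine_x <- off + 0.55 * (x_r - off)
      spine <- rbind(c(spine_x, 0.12 * H), c(spine_x, 0.88 * H))
      road_rows[[length(road_rows) + 1L]] <- list(
        segment_id = new_seg_id(), geometry = densify(spine, step),
        road_type = "unpaved", width_ft = 6, fixed = character())
      ghat_y <- c(0.3, 0.7) * H
      # mainland ghat: reuse the corridor hub nearest the river bank
      for (g in 1:2) {
        bank <- c(x_r, ghat_y[g])
        road_rows[[length(road_rows) + 1L]] <- list(
          segment_id = new_seg_id(),
          geometry = densify(rbind(c(spine_x, ghat_y[g]), bank), step),
          road_type = "unpaved", width_ft = 6, fixed = character())
        d <- sqrt((corridor_hub_xy[, 1] - bank[1])^2 +
                    (corridor_hub_xy[, 2] - bank[2])^2)
        mg <- corridor_hub_xy[which.min(d), ]
        road_rows[[length(road_rows) + 1L]] <- list(
          segment_id = new_seg_id(),
          geometry = rbind(bank, mg),
          road_type = "waterway", width_ft = NA_real_, fixed = character())
        hid <- sprintf("sd%d_isl%d", s, g)
        hub_rows[[length(hub_rows) + 1L]] <- tibble::tibble(
          hub_id = hid, x = spine_x, y = ghat_y[g], kind = "hub",
          name = sprintf("Island ghat %d-%d", s, g))
      }
    }
  }

  vil <- villages(
    village_id = vapply(vil_rows, `[[`, "", "village_id"),
    name = vapply(vil_rows, `[[`, "", "name"),
    boundary = lapply(vil_rows, `[[`, "ring"),
    population = vapply(vil_rows, `[[`, 1L, "population"),
    households = as.integer(round(vapply(vil_rows, `[[`, 1L, "population") / 4.5)),
    union_id = vapply(vil_rows, `[[`, "", "union_id"),
    upazila_id = vapply(vil_rows, `[[`, "", "upazila_id"))

  # narrow walk-only spurs from a sample of village centroids to the network
  n_spur <- round(config$narrow_road_fraction * nrow(vil))
  spur_vids <- if (n_spur > 0) sort(sample(vil$village_id, n_spur)) else character()
  all_pts <- do.call(rbind, lapply(road_rows, `[[`, "geometry"))
  for (vid in spur_vids) {
    i <- match(vid, vil$village_id)
    cen <- c(vil$cx[i], vil$cy[i])
    d <- sqrt((all_pts[, 1] - cen[1])^2 + (all_pts[, 2] - cen[2])^2)
    tgt <- all_pts[which.min(d), ]
    if (sqrt(sum((tgt - cen)^2)) < 1e-6) next
    # a spur must not bridge the river: skip when the target is across
    if (config$river && (cen[1] < config$island_fraction * W) !=
        (tgt[1] < config$island_fraction * W)) next
    road_rows[[length(road_rows) + 1L]] <- list(
      segment_id = new_seg_id(), geometry = rbind(cen, tgt),
      road_type = "unpaved", width_ft = 4, fixed = character())
  }

  rd <- roads(
    segment_id = vapply(road_rows, `[[`, "", "segment_id"),
    geometry = lapply(road_rows, `[[`, "geometry"),
    road_type = vapply(road_rows, `[[`, "", "road_type"),
    width_ft = vapply(road_rows, `[[`, 1, "width_ft"),
    fixed_route_modes = lapply(road_rows, `[[`, "fixed"))
  hb <- dplyr::bind_rows(hub_rows)
  hb <- new_layer(hb, "hubs")
  fc <- dplyr::bind_rows(fac_rows)
  fc <- new_layer(fc, "facilities")
  narrow <- rd$segment_id[!is.na(rd$width_ft) & rd$width_ft < 5]
  cons <- if (length(narrow) > 0) {
    constraints("bb1", narrow[1], "bamboo_bridge", "forces_walk")
  } else {
    new_layer(tibble::tibble(constraint_id = character(),
                             segment_id = character(), kind = character(),
                             effect = character()), "constraints")
  }
  list(villages = vil, roads = rd, hubs = hb, facilities = fc,
       constraints = cons, config = config, island_villages = island_ids)
}

#' Call-log generator configuration
#'
#' Default probabilities are the zone-conditional rates implied by the
#' published referral tabulation: compliance among referred calls 0.77
#' (green), 0.72 (yellow), 0.70 (red); project-transport use among
#' compliers 0.30 (red), 0.06 (yellow) and structurally 0 in the green
#' zone, where the project transport did not operate. Semester weights
#' follow the published referred-call totals.
#'
#' @param seed Integer seed (independent of the geography stream).
#' @param n_calls Number of calls to draw.
#' @param referral_probability Probability a call is an emergency referral.
#' @param compliance_probability_by_zone Named (green/yellow/red/excluded)
#'   probabilities in \[0, 1\].
#' @param transport_probability_by_zone Named (yellow/red) probabilities;
#'   green and excluded are fixed at 0.
#' @param semester_weights Four proportions.
#' @return A `call_log_config` list.
#' @export
call_log_config <- function(seed = 2L, n_calls = 1200L,
                            referral_probability = 0.565,
                            compliance_probability_by_zone =
                              c(green = 0.77, yellow = 0.72, red = 0.70,
                                excluded = 0.5),
                            transport_probability_by_zone =
                              c(yellow = 0.06, red = 0.30),
                            semester_weights = c(0.39, 0.28, 0.25, 0.08)) {
  stopifnot(all(compliance_probability_by_zone >= 0),
            all(compliance_probability_by_zone <= 1),
            all(transport_probability_by_zone >= 0),
            all(transport_probability_by_zone <= 1),
            referral_probability >= 0, referral_probability <= 1,
            length(semester_weights) == 4, all(semester_weights >= 0))
  structure(list(
    seed = as.integer(seed), n_calls = as.integer(n_calls),
    referral_probability = referral_probability,
    compliance_probability_by_zone = compliance_probability_by_zone,
    transport_probability_by_zone = transport_probability_by_zone,
    semester_weights = semester_weights / sum(semester_weights)
  ), class = "call_log_config")
}

SEMESTER_STARTS <- as.Date(c("2013-10-01", "2014-04-01", "2014-10-01",
                             "2015-04-01"))
SEMESTER_ENDS <- as.Date(c("2014-03-31", "2014-09-30", "2015-03-31",
                           "2015-09-30"))

#' Generate a synthetic referral call log
#'
#' Calls draw a village (population-weighted when populations are given), a
#' semester and a date; referral, zone-conditional compliance and
#' zone-conditional transport use are independent Bernoulli draws, so
#' `used_transport <= complied <= referred` holds by construction and the
#' green zone never records transport use.
#'
#' @param config A `call_log_config`.
#' @param zone_assignments Tibble (village_id, zone) covering every village.
#' @param villages Optional villages layer for population-weighted draws.
#' @return Call-record tibble (call_id, date, village_id, referred,
#'   complied, used_transport, zone, semester).
#' @export
generate_call_log <- function(config, zone_assignments, villages = NULL) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_calls
  wts <- if (!is.null(villages)) {
    villages$population[match(zone_assignments$village_id,
                              villages$village_id)]
  } else rep(1, nrow(zone_assignments))
  pick <- sample.int(nrow(zone_assignments), n, replace = TRUE, prob = wts)
  vid <- zone_assignments$village_id[pick]
  zone <- zone_assignments$zone[pick]
  if (anyNA(zone)) stop("consistency error: drawn village without a zone",
                        call. = FALSE)
  sem <- sample.int(4L, n, replace = TRUE, prob = config$semester_weights)
  span <- as.integer(SEMESTER_ENDS - SEMESTER_STARTS)
  date <- SEMESTER_STARTS[sem] +
    floor(stats::runif(n) * (span[sem] + 1L))
  referred <- as.integer(stats::runif(n) < config$referral_probability)
  pc <- config$compliance_probability_by_zone[zone]
  complied <- as.integer(referred == 1L & stats::runif(n) < pc)
  pt <- rep(0, n)
  yr <- zone %in% names(config$transport_probability_by_zone)
  pt[yr] <- config$transport_probability_by_zone[zone[yr]]
  used <- as.integer(complied == 1L & stats::runif(n) < pt)
  tibble::tibble(
    call_id = sprintf("c%05d", seq_len(n)), date = date, village_id = vid,
    referred = referred, complied = complied, used_transport = used,
    zone = zone, semester = sem)
}
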