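# A single straight paved road east from the facility gives closed-form
# travel times: t(x) = 60 x / 8.05 under the rickshaw policy, so the
# 30-minute boundary sits at 4.025 km and the 50-minute one at 6.708 km.
straight_road_world <- function(road_km = 12, centres = c(2, 5, 9)) {
  micro_scenario(road_km = road_km, service = character(),
                 village_centres_km = centres)
}

test_that("village facility times follow rickshaw speeds plus walking", {
  s <- straight_road_world(centres = c(4.025))
  nw <- build_network(s$villages, s$roads)
  vt <- village_facility_time(nw, s$facilities)
  # centroid (4.025, 0.6) attaches to the road vertex at x = 4.0 (the
  # polyline is densified every 0.5 km): walk the connector, then
  # rickshaw 4 km to the facility
  d_conn <- sqrt(0.025^2 + 0.6^2)
  expect_equal(vt$minutes, 60 * d_conn / 4 + 60 * 4 / 8.05,
               tolerance = 1e-6)
  # a village centred at the facility is instantaneous up to its connector
  s0 <- straight_road_world(centres = c(0.0001))
  nw0 <- build_network(s0$villages, s0$roads)
  vt0 <- village_facility_time(nw0, s0$facilities)
  expect_equal(vt0$minutes, 9, tolerance = 1e-3)
})

test_that("rickshaw-policy times agree with exhaustive enumeration", {
  set.seed(202)
  for (rep in 1:10) {
    g <- random_test_graph(6)
    nw <- network_from_edges(g)
    ids <- nw$vertices$id
    want <- enumerate_best_path(g, ids[1], ids[4])
    got <- shortest_time_path(nw, ids[1], ids[4], "rickshaw_only")
    expect_equal(got$minutes, want$cost, tolerance = 1e-9)
  }
})

test_that("service areas reach the closed-form distance along a road", {
  s <- straight_road_world()
  nw <- build_network(s$villages, s$roads)
  sa <- service_polygons(nw, s$facilities, breaks = c(30, 50))
  # on-road points at the break distances
  t_at <- service_time(sa, rbind(c(4.025, 0), c(6.708, 0), c(2, 0)))
  expect_equal(t_at[1], 30, tolerance = 0.5)
  expect_equal(t_at[2], 50, tolerance = 0.5)
  expect_equal(t_at[3], 60 * 2 / 8.05, tolerance = 0.5)
  # 1 km off-road adds 15 minutes of walking
  expect_equal(service_time(sa, c(2, 1)),
               60 * 2 / 8.05 + 15, tolerance = 0.5)
  # an island facility's service area stays on the island
  rd_i <- roads(c("m", "i"),
                list(cbind(c(0, 3), c(0, 0)), cbind(c(0, 3), c(5, 5))),
                "paved", 12)
  fc_i <- facilities("f_i", 0, 5)
  nw_i <- build_network(NULL, rd_i)
  sa_i <- service_polygons(nw_i, fc_i, breaks = c(30, 50))
  expect_true(all(sa_i$points[, 2] == 5))
})

test_that("zone labels follow the 50 percent coverage rule", {
  s <- straight_road_world()
  nw <- build_network(s$villages, s$roads)
  sa <- service_polygons(nw, s$facilities, breaks = c(30, 50))
  # squares far inside one band
  expect_equal(as.character(assign_zone(
    rbind(c(1, 0.1), c(2, 0.1), c(2, 0.9), c(1, 0.9)), sa)), "green")
  expect_equal(as.character(assign_zone(
    rbind(c(9, 0.1), c(10, 0.1), c(10, 0.9), c(9, 0.9)), sa)), "red")
  # 60% yellow / 40% red split across the 50-minute boundary at 6.708 km:
  # a thin box hugging the road from 5.508 to 7.508 km (a tall box would
  # shift the boundary inward through the off-road walking penalty)
  z <- assign_zone(rbind(c(5.508, -0.01), c(7.508, -0.01), c(7.508, 0.01),
                         c(5.508, 0.01)), sa, n_grid = 40)
  expect_equal(as.character(z), "yellow")
  sh <- attr(z, "shares")
  expect_lt(abs(sh[["yellow"]] - 0.6), 0.05)
  expect_lt(abs(sh[["red"]] - 0.4), 0.05)
  # an exact 50/50 split lands in the faster band
  z2 <- assign_zone(rbind(c(3.025, -0.01), c(5.025, -0.01), c(5.025, 0.01),
                          c(3.025, 0.01)), sa, n_grid = 40)
  expect_equal(as.character(z2), "green")
  sh2 <- attr(z2, "shares")
  expect_equal(unname(sh2["green"]), 0.5, tolerance = 0.05)
  expect_error(assign_zone(rbind(c(0, 0), c(1, 0), c(2, 0)), sa),
               "degenerate")
})

test_that("exclusion lists label villages excluded", {
  s <- straight_road_world(centres = c(2, 9))
  nw <- build_network(s$villages, s$roads)
  sa <- service_polygons(nw, s$facilities)
  z <- assign_zones(s$villages, sa, exclusion_list = "vil2")
  expect_equal(z$zone, c("green", "excluded"))
})

test_that("zone summaries aggregate and percentages sum to about 100", {
  s <- straight_road_world(centres = c(1, 2, 5, 9))
  nw <- build_network(s$villages, s$roads)
  sa <- service_polygons(nw, s$facilities)
  z <- assign_zones(s$villages, sa)
  zs <- zone_summary(s$villages, z)
  tot <- zs[zs$zone == "total", ]
  expect_equal(tot$population, sum(s$villages$population))
  expect_equal(tot$n_villages, 4)
  expect_lte(abs(tot$population_pct - 100), 1)
  expect_equal(tot$settlement_area_km2, sum(s$villages$area_km2),
               tolerance = 1e-9)
  # all-green world collapses to a single 100% row
  sg <- straight_road_world(centres = c(1, 2))
  nwg <- build_network(sg$villages, sg$roads)
  sag <- service_polygons(nwg, sg$facilities)
  zg <- assign_zones(sg$villages, sag)
  zsg <- zone_summary(sg$villages, zg)
  expect_equal(zsg$zone, c("green", "total"))
  expect_equal(zsg$population_pct, c(100L, 100L))
})

test_that("zoning is correct and monotone across synthetic scenarios", {
  # villages wholly inside the 30-minute reach are green, wholly outside
  # the 50-minute reach are red; labels partition; growing the break
  # values never moves a village to a slower band
  rank <- c(green = 1, yellow = 2, red = 3)
  for (seed in 1:6) {
    sc <- generate_scenario(scenario_config(seed = seed))
    nw <- build_network(sc$villages, sc$roads, sc$constraints)
    sa <- service_polygons(nw, sc$facilities, breaks = c(30, 50))
    z <- assign_zones(sc$villages, sa)
    expect_setequal(z$village_id, sc$villages$village_id)
    expect_true(all(z$zone %in% c("green", "yellow", "red")))
    for (i in seq_len(nrow(sc$villages))) {
      b <- sc$villages$boundary[[i]]
      tt <- service_time(sa, rbind(b, refnet:::grid_points_in_polygon(b, 8)))
      if (all(tt <= 30)) expect_equal(z$zone[i], "green")
      if (all(tt > 50)) expect_equal(z$zone[i], "red")
    }
    sa2 <- service_polygons(nw, sc$facilities, breaks = c(40, 65))
    z2 <- assign_zones(sc$villages, sa2)
    expect_true(all(rank[z2$zone] <= rank[z$zone]))
  }
})

test_that("the published zone table recomputes to 24/28/44/4 percent", {
  fx <- table_fixtures()$zones
  zt <- zone_table(fx)
  expect_equal(zt$population_pct[match(c("green", "yellow", "red", "excluded"),
                                       zt$zone)], c(24L, 28L, 44L, 4L))
  tot <- zt[zt$zone == "total", ]
  expect_equal(tot$population, sum(fx$population))
  expect_equal(tot$n_villages, 338L)
  expect_equal(tot$settlement_area_km2, 84.99, tolerance = 1e-9)
  expect_equal(tot$population_pct, 100L)
})
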