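test_that("polylines are noded at shared endpoints and crossings", {
  # two roads sharing an endpoint: 3 vertices, 2 edges
  rd <- roads(c("a", "b"),
              list(cbind(c(0, 1), c(0, 0)), cbind(c(1, 2), c(0, 0))),
              "paved", 12)
  nw <- build_network(NULL, rd)
  expect_equal(nrow(nw$vertices), 3)
  expect_equal(nrow(nw$edges), 2)
  # an X crossing gains a vertex at the intersection and splits both roads
  rd2 <- roads(c("a", "b"),
               list(rbind(c(0, 0), c(2, 2)), rbind(c(0, 2), c(2, 0))),
               "paved", 12)
  nw2 <- build_network(NULL, rd2)
  expect_equal(nrow(nw2$vertices), 5)
  expect_equal(nrow(nw2$edges), 4)
  expect_true(any(nw2$vertices$x == 1 & nw2$vertices$y == 1))
})

test_that("edge times cover every applicable mode and constraints apply", {
  rd <- roads(c("r", "w", "n"),
              list(cbind(c(0, 1), c(0, 0)), cbind(c(1, 2), c(0, 0)),
                   cbind(c(2, 3), c(0, 0))),
              c("paved", "waterway", "unpaved"),
              c(12, NA, 4), list("tempo", character(), character()))
  cs <- constraints("c1", "n", "bamboo_bridge", "forces_walk")
  nw <- build_network(NULL, rd, cs)
  by_seg <- split(seq_len(nrow(nw$edges)), nw$edges$segment_id)
  m_r <- nw$edges$minutes[[by_seg$r[1]]]
  expect_equal(sort(names(m_r)), c("rickshaw", "tempo", "walk"))
  expect_equal(unname(m_r["tempo"]), 60 / 12.64, tolerance = 1e-9)
  expect_equal(names(nw$edges$minutes[[by_seg$w[1]]]), "boat")
  # narrow road already walk-only; bamboo bridge keeps it that way
  expect_equal(names(nw$edges$minutes[[by_seg$n[1]]]), "walk")
  # a natural barrier empties the mode set
  cs2 <- constraints("c2", "r", "natural_barrier", "blocks_passage")
  nw2 <- build_network(NULL, rd, cs2)
  by2 <- split(seq_len(nrow(nw2$edges)), nw2$edges$segment_id)
  expect_length(nw2$edges$minutes[[by2$r[1]]], 0)
})

test_that("village connectors walk to the nearest vertex at 4 km/h", {
  rd <- roads("a", list(cbind(c(0, 2), c(0, 0))), "paved", 12)
  sq <- rbind(c(-0.5, 0.5), c(0.5, 0.5), c(0.5, 1.5), c(-0.5, 1.5))
  vl <- villages("v1", "One", list(sq), 100L)  # centroid (0, 1), 1 km north
  nw <- build_network(vl, rd)
  cv <- nw$village_vertices
  expect_equal(cv$connector_km, 1, tolerance = 1e-9)
  ce <- nw$edges[nw$edges$from == "v1", ]
  expect_equal(unname(ce$minutes[[1]]["walk"]), 15, tolerance = 1e-9)
  # distant villages raise an isolation warning but stay connected
  far <- villages("v2", "Far", list(sq + 20), 50L)
  expect_warning(nw2 <- build_network(far, rd, max_connector_km = 5),
                 "isolation.*v2")
  expect_true("v2" %in% nw2$vertices$id)
})

test_that("shortest paths agree with exhaustive enumeration on random graphs", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:9, 1)
    g <- random_test_graph(n)
    nw <- network_from_edges(g)
    ids <- nw$vertices$id
    od <- sample(ids, 2)
    want <- enumerate_best_path(g, od[1], od[2])
    got <- shortest_time_path(nw, od[1], od[2])
    expect_equal(got$minutes, want$cost, tolerance = 1e-9)
    expect_identical(got$path, want$path)
  }
})

test_that("igraph agrees on shortest-path cost for a larger network", {
  skip_if_not_installed("igraph")
  sc <- generate_scenario(scenario_config(seed = 3))
  nw <- build_network(sc$villages, sc$roads, sc$constraints)
  w <- refnet:::policy_weights(nw, "fastest_available")
  keep <- is.finite(w)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nw$edges$from[keep], to = nw$edges$to[keep]),
    directed = FALSE,
    vertices = data.frame(name = nw$vertices$id))
  set.seed(11)
  verts <- sample(nw$vertices$id[!startsWith(nw$vertices$id, "sd")], 12)
  for (i in seq(1, 11, by = 2)) {
    d_ig <- igraph::distances(g, verts[i], verts[i + 1],
                              weights = w[keep])[1, 1]
    got <- tryCatch(shortest_time_path(nw, verts[i], verts[i + 1])$minutes,
                    error = function(e) Inf)
    expect_equal(got, d_ig, tolerance = 1e-9)
  }
})

test_that("trivial path endpoints behave", {
  rd <- roads("a", list(cbind(c(0, 5.64), c(0, 0))), "paved", 12,
              list("tempo"))
  nw <- build_network(NULL, rd)
  ids <- nw$vertices$id
  sp <- shortest_time_path(nw, ids[1], ids[length(ids)])
  expect_equal(round(sp$minutes, 2), 26.77)
  expect_equal(sp$distance_km, 5.64, tolerance = 1e-9)
  same <- shortest_time_path(nw, ids[1], ids[1])
  expect_equal(same$minutes, 0)
  expect_equal(same$distance_km, 0)
  # disconnected destination errors
  rd2 <- roads(c("a", "b"),
               list(cbind(c(0, 1), c(0, 0)), cbind(c(10, 11), c(10, 10))),
               "paved", 12)
  nw2 <- build_network(NULL, rd2)
  v_far <- nw2$vertices$id[which(nw2$vertices$x == 10)]
  expect_error(shortest_time_path(nw2, nw2$vertices$id[1], v_far),
               "unreachable")
})

test_that("removing an edge never shortens any shortest path", {
  set.seed(77)
  for (rep in 1:15) {
    g <- random_test_graph(7)
    nw <- network_from_edges(g)
    ids <- nw$vertices$id
    base <- vapply(ids[-1], function(v)
      shortest_time_path(nw, ids[1], v)$minutes, numeric(1))
    drop <- sample(nrow(g), 1)
    nw2 <- network_from_edges(g[-drop, ])
    for (v in ids[-1]) {
      after <- tryCatch(shortest_time_path(nw2, ids[1], v)$minutes,
                        error = function(e) Inf)
      expect_gte(after + 1e-12, base[[v]])
    }
  }
})

test_that("closest hub prefers time, then hub kind, then id", {
  s <- micro_scenario(road_km = 8, village_centres_km = c(4.2))
  nw <- build_network(s$villages, s$roads)
  # village at 4.2 km: mid sub-hub at 4 km is nearer than the far hub
  got <- closest_hub(nw, "vil1", s$hubs)
  expect_equal(got$hub$hub_id, "h1_s1")
  # equidistant hub and sub-hub: the hub wins
  hb <- hubs(c("hub_a", "sub_b"), x = c(3.5, 5.0), y = 0,
             kind = c("hub", "sub_hub"))
  # centroid walk connector reaches the road at x = 4.2 (nearest vertex is
  # at 4.0 or 4.5 on the densified line); use symmetric positions instead
  hb2 <- hubs(c("hub_a", "sub_b"), x = c(3, 5), y = 0,
              kind = c("hub", "sub_hub"))
  s2 <- micro_scenario(road_km = 8, village_centres_km = c(4))
  nw2 <- build_network(s2$villages, s2$roads)
  got2 <- closest_hub(nw2, "vil1", hb2)
  expect_equal(got2$hub$hub_id, "hub_a")
})

test_that("route catalog builds hub-to-facility corridors with sub-hubs", {
  s <- micro_scenario(road_km = 8, service = "tempo")
  nw <- build_network(s$villages, s$roads)
  cat <- build_route_catalog(nw, s$hubs, s$facilities)
  expect_equal(nrow(cat), 1)
  expect_equal(cat$distance_km, 8, tolerance = 1e-9)
  expect_equal(cat$time_min, 60 * 8 / 12.64, tolerance = 1e-9)
  expect_equal(cat$mode, "tempo")
  expect_true(cat$active)
  p <- cat$pickups[[1]]
  expect_equal(p$pickup_id, c("h1", "h1_s1", "f1"))
  expect_equal(p$kind, c("hub", "sub_hub", "facility"))
  expect_equal(p$remaining_min,
               c(60 * 8 / 12.64, 60 * 4 / 12.64, 0), tolerance = 1e-9)
  # nasiman-served corridor yields an inactive route
  s_n <- micro_scenario(service = "nasiman")
  nw_n <- build_network(s_n$villages, s_n$roads)
  cat_n <- build_route_catalog(nw_n, s_n$hubs, s_n$facilities)
  expect_false(cat_n$active)
  expect_equal(cat_n$mode, "nasiman")
})

test_that("catchment assignment partitions population over active routes", {
  sc <- generate_scenario(scenario_config(seed = 2))
  nw <- build_network(sc$villages, sc$roads, sc$constraints)
  cat <- build_route_catalog(nw, sc$hubs, sc$facilities)
  asg <- assign_catchments(cat, sc$villages, nw)
  a <- asg$assignments
  expect_setequal(a$village_id, sc$villages$village_id)
  expect_true(all(a$route_id %in% cat$route_id[cat$active]))
  # disjoint cover: each village exactly once; population conserved
  expect_equal(anyDuplicated(a$village_id), 0)
  expect_equal(sum(asg$routes$catchment_population),
               sum(sc$villages$population))
  # per-route populations are the sums of their villages
  pops <- stats::setNames(sc$villages$population, sc$villages$village_id)
  for (i in seq_len(nrow(asg$routes))) {
    expect_equal(asg$routes$catchment_population[i],
                 as.integer(sum(pops[asg$routes$catchment_village_ids[[i]]])))
  }
})

test_that("excluding a route reassigns its villages and conserves population", {
  sc <- generate_scenario(scenario_config(seed = 2))
  nw <- build_network(sc$villages, sc$roads, sc$constraints)
  cat <- build_route_catalog(nw, sc$hubs, sc$facilities)
  asg0 <- assign_catchments(cat, sc$villages, nw)
  # pick the active route with the largest catchment and exclude it
  act <- asg0$routes[asg0$routes$active, ]
  victim <- act$route_id[which.max(act$catchment_population)]
  asg1 <- exclude_route(asg0$routes, victim, sc$villages, nw)
  expect_false(asg1$routes$active[asg1$routes$route_id == victim])
  expect_equal(sum(asg1$routes$catchment_population[asg1$routes$active]),
               sum(sc$villages$population))
  expect_false(victim %in% asg1$assignments$route_id)
  # re-include and reassign: the original assignment returns
  cat2 <- asg1$routes
  cat2$active[cat2$route_id == victim] <- TRUE
  asg2 <- assign_catchments(cat2, sc$villages, nw)
  expect_equal(asg2$assignments, asg0$assignments)
})

test_that("manual overrides and exclusion lists are honoured", {
  sc <- generate_scenario(scenario_config(seed = 2))
  nw <- build_network(sc$villages, sc$roads, sc$constraints)
  cat <- build_route_catalog(nw, sc$hubs, sc$facilities)
  asg0 <- assign_catchments(cat, sc$villages, nw)
  v <- asg0$assignments$village_id[1]
  other <- setdiff(cat$route_id[cat$active], asg0$assignments$route_id[1])[1]
  asg1 <- assign_catchments(cat, sc$villages, nw,
                            manual_overrides = tibble::tibble(
                              village_id = v, route_id = other))
  expect_equal(asg1$assignments$route_id[asg1$assignments$village_id == v],
               other)
  drop2 <- sc$villages$village_id[1:3]
  asg2 <- assign_catchments(cat, sc$villages, nw, exclusion_list = drop2)
  expect_false(any(drop2 %in% asg2$assignments$village_id))
  expect_equal(sum(asg2$routes$catchment_population),
               sum(sc$villages$population) -
                 sum(sc$villages$population[1:3]))
})

test_that("arrival estimates add access time to the remaining route time", {
  s <- micro_scenario(road_km = 8, village_centres_km = c(4, 7.9))
  nw <- build_network(s$villages, s$roads)
  cat <- build_route_catalog(nw, s$hubs, s$facilities)
  asg <- assign_catchments(cat, s$villages, nw)
  # village 1 centroid sits 0.6 km north of the mid sub-hub (x = 4)
  a1 <- asg$assignments[asg$assignments$village_id == "vil1", ]
  expect_equal(a1$pickup_id, "h1_s1")
  est1 <- estimate_arrival(nw, "vil1", asg$assignments, asg$routes)
  expect_equal(est1, 60 * 0.6 / 4 + 60 * 4 / 12.64, tolerance = 1e-9)
  # a village at the facility end estimates its own walk only
  s3 <- micro_scenario(road_km = 8, village_centres_km = c(0.0001))
  nw3 <- build_network(s3$villages, s3$roads)
  cat3 <- build_route_catalog(nw3, s3$hubs, s3$facilities)
  asg3 <- assign_catchments(cat3, s3$villages, nw3)
  est3 <- estimate_arrival(nw3, "vil1", asg3$assignments, asg3$routes)
  walk_to_road <- 60 * 0.6 / 4  # centroid is 0.6 km north of the road
  expect_equal(est3, walk_to_road, tolerance = 1e-6)
  expect_error(estimate_arrival(nw, "nope", asg$assignments, asg$routes),
               "unassigned")
})

test_that("the published route catalog totals are internally consistent", {
  fx <- table_fixtures()$routes
  expect_equal(nrow(fx), 17)
  expect_equal(sum(fx$catchment_population), 306426)
  expect_equal(sum(!fx$active), 1)
  expect_equal(fx$route_id[!fx$active], "09")
})
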