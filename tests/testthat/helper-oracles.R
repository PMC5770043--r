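# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive shortest-path oracle: enumerate every simple path in a small
# undirected weighted graph and return the optimum under the package's
# tie-break order (total weight, then hop count, then lexicographically
# smallest vertex-id sequence). Implemented by depth-first enumeration,
# entirely independent of the Dijkstra implementation under test.
enumerate_best_path <- function(edges, origin, destination) {
  # edges: data.frame(from, to, w)
  verts <- sort(unique(c(edges$from, edges$to)))
  nbrs <- lapply(stats::setNames(verts, verts), function(v) {
    rbind(
      data.frame(to = edges$to[edges$from == v], w = edges$w[edges$from == v]),
      data.frame(to = edges$from[edges$to == v], w = edges$w[edges$to == v]))
  })
  best <- NULL
  better <- function(cost_a, path_a, cost_b, path_b) {
    if (cost_a < cost_b - 1e-9) return(TRUE)
    if (cost_a > cost_b + 1e-9) return(FALSE)
    if (length(path_a) != length(path_b)) return(length(path_a) < length(path_b))
    for (i in seq_along(path_a)) {
      if (path_a[i] < path_b[i]) return(TRUE)
      if (path_a[i] > path_b[i]) return(FALSE)
    }
    FALSE
  }
  recurse <- function(v, path, cost) {
    if (v == destination) {
      if (is.null(best) || better(cost, path, best$cost, best$path)) {
        best <<- list(cost = cost, path = path)
      }
      return()
    }
    nb <- nbrs[[v]]
    for (i in seq_len(nrow(nb))) {
      if (nb$to[i] %in% path) next
      recurse(nb$to[i], c(path, nb$to[i]), cost + nb$w[i])
    }
  }
  recurse(origin, origin, 0)
  best
}

# random connected graph on n vertices with weights that deliberately
# produce ties (weights drawn from a small integer set)
random_test_graph <- function(n, p_extra = 0.4) {
  ids <- sprintf("v%02d", seq_len(n))
  # spanning path guarantees connectivity, then random extra edges
  edges <- data.frame(from = ids[-n], to = ids[-1])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j > i + 1 && stats::runif(1) < p_extra) {
        edges <- rbind(edges, data.frame(from = ids[i], to = ids[j]))
      }
    }
  }
  edges$w <- sample(c(1, 2, 3, 5), nrow(edges), replace = TRUE)
  edges
}

# wrap a bare weighted edge list as a transport_network whose
# fastest_available minutes equal the given weights (each edge one paved
# rickshaw segment of length w * 8.05 / 60 km => w minutes)
network_from_edges <- function(edges) {
  n <- nrow(edges)
  verts <- sort(unique(c(edges$from, edges$to)))
  # place vertices on a line; geometry is irrelevant to routing
  xy <- stats::setNames(seq_along(verts), verts)
  structure(list(
    vertices = tibble::tibble(id = verts, x = as.numeric(xy[verts]), y = 0),
    edges = tibble::tibble(
      from = edges$from, to = edges$to,
      segment_id = sprintf("e%03d", seq_len(n)),
      length_km = edges$w * 8.05 / 60, road_type = "paved",
      width_ft = 12, fixed_route_modes = rep(list(character()), n),
      modes = rep(list(c("rickshaw", "walk")), n),
      minutes = lapply(edges$w, function(w)
        c(rickshaw = w, walk = w * 8.05 / 4))),
    village_vertices = tibble::tibble(village_id = character(),
                                      attach = character(),
                                      connector_km = numeric()),
    speeds = refnet::speed_table()), class = "transport_network")
}

# one-subdistrict micro-scenario used by routing/zoning unit tests: a
# single straight paved road east from the facility with a hub at the far
# end and a sub-hub in the middle, plus square villages along it
micro_scenario <- function(road_km = 8, width_ft = 12, service = "tempo",
                           village_centres_km = c(1, 4, 7)) {
  rd <- refnet::roads(
    segment_id = "r1",
    geometry = list(cbind(seq(0, road_km, by = 0.5), 0)),
    road_type = "paved", width_ft = width_ft,
    fixed_route_modes = list(service))
  vb <- lapply(village_centres_km, function(cx) {
    rbind(c(cx - 0.4, 0.2), c(cx + 0.4, 0.2), c(cx + 0.4, 1.0),
          c(cx - 0.4, 1.0))
  })
  vl <- refnet::villages(
    village_id = sprintf("vil%d", seq_along(village_centres_km)),
    name = sprintf("Village %d", seq_along(village_centres_km)),
    boundary = vb,
    population = rep(1000L, length(village_centres_km)))
  hb <- refnet::hubs(
    hub_id = c("h1", "h1_s1"), x = c(road_km, road_km / 2), y = c(0, 0),
    kind = c("hub", "sub_hub"), name = c("Far market", "Mid stop"))
  fc <- refnet::facilities("f1", 0, 0, "UHC", "Test UHC")
  list(villages = vl, roads = rd, hubs = hb, facilities = fc)
}

expect_tbl_equal_num <- function(x, y, tol = 1e-9) {
  expect_equal(as.numeric(x), as.numeric(y), tolerance = tol)
}
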