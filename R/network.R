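# Multimodal transport network: polylines noded at shared endpoints and
# crossings, per-mode edge times, walking connectors from village centroids,
# and the closest-facility analysis (routes, catchments, arrival estimates).
#
# Deterministic tie-breaking everywhere: shortest paths by minutes, then
# hop count, then lexicographically smallest vertex-id sequence; pick-up
# ties by kind (hub < sub_hub < facility end), then id. Runs are therefore
# bit-reproducible.

WALK_KMH <- 4

vertex_key <- function(x, y) paste(round(x, 6), round(y, 6), sep = "|")

# split every polyline into straight sub-segments, then split those at
# pairwise crossings so the graph is properly noded
node_segments <- function(road_tbl) {
  pieces <- list()
  for (i in seq_len(nrow(road_tbl))) {
    g <- road_tbl$geometry[[i]]
    for (j in seq_len(nrow(g) - 1)) {
      pieces[[length(pieces) + 1L]] <- list(
        a = g[j, ], b = g[j + 1, ], row = i)
    }
  }
  np <- length(pieces)
  splits <- vector("list", np)
  if (np > 1) {
    A <- t(vapply(pieces, `[[`, numeric(2), "a"))
    B <- t(vapply(pieces, `[[`, numeric(2), "b"))
    lo_x <- pmin(A[, 1], B[, 1]); hi_x <- pmax(A[, 1], B[, 1])
    lo_y <- pmin(A[, 2], B[, 2]); hi_y <- pmax(A[, 2], B[, 2])
    for (i in seq_len(np - 1)) {
      for (j in (i + 1):np) {
        if (lo_x[i] > hi_x[j] || lo_x[j] > hi_x[i] ||
            lo_y[i] > hi_y[j] || lo_y[j] > hi_y[i]) next
        p <- segment_intersection(pieces[[i]]$a, pieces[[i]]$b,
                                  pieces[[j]]$a, pieces[[j]]$b)
        if (is.null(p)) next
        for (k in c(i, j)) {
          v <- pieces[[k]]$b - pieces[[k]]$a
          t <- sum((p - pieces[[k]]$a) * v) / sum(v * v)
          if (t > 1e-9 && t < 1 - 1e-9) {
            splits[[k]] <- c(splits[[k]], t)
          }
        }
      }
    }
  }
  out <- list()
  for (k in seq_len(np)) {
    ts <- sort(unique(c(0, splits[[k]], 1)))
    a <- pieces[[k]]$a; b <- pieces[[k]]$b
    for (s in seq_len(length(ts) - 1)) {
      p1 <- a + ts[s] * (b - a); p2 <- a + ts[s + 1] * (b - a)
      out[[length(out) + 1L]] <- list(a = p1, b = p2, row = pieces[[k]]$row)
    }
  }
  out
}

#' Build the multimodal transport network
#'
#' Nodes every road/waterway polyline at shared endpoints and crossings,
#' computes per-mode traversal minutes on each edge from the speed table and
#' the accessibility rule ([applicable_modes()]), applies segment
#' constraints, and attaches each village by a walking connector from its
#' centroid to the nearest network vertex.
#'
#' @param villages Villages layer (or NULL for a village-free network).
#' @param road_network Roads layer; waterway segments are rows with
#'   `road_type = "waterway"`.
#' @param constraint_set Optional constraints layer.
#' @param speeds Speed table.
#' @param max_connector_km Villages farther than this from any vertex raise
#'   an isolation warning (they are still connected; downstream results
#'   remain computable but should be read with care). Default 5 km.
#' @return A `transport_network`: list of `vertices` (id, x, y), `edges`
#'   (endpoints, segment attributes, named per-mode minutes) and
#'   `village_vertices` (per-village connector bookkeeping).
#' @export
build_network <- function(villages = NULL, road_network, constraint_set = NULL,
                          speeds = speed_table(), max_connector_km = 5) {
  segs <- node_segments(road_network)
  eff <- rep(NA_character_, nrow(road_network))
  if (!is.null(constraint_set) && nrow(constraint_set) > 0) {
    m <- match(constraint_set$segment_id, road_network$segment_id)
    if (anyNA(m)) {
      stop("constraint references unknown segment: ",
           paste(constraint_set$segment_id[is.na(m)], collapse = ", "),
           call. = FALSE)
    }
    eff[m] <- constraint_set$effect
  }
  keys <- character(0)
  coords <- list()
  get_vid <- function(p) {
    k <- vertex_key(p[1], p[2])
    i <- match(k, keys)
    if (is.na(k)) stop("bad coordinate")
    if (is.na(i)) {
      keys[[length(keys) + 1L]] <<- k
      coords[[length(coords) + 1L]] <<- p
      i <- length(keys)
    }
    i
  }
  from <- integer(0); to <- integer(0); len <- numeric(0); rowi <- integer(0)
  for (s in segs) {
    l <- sqrt(sum((s$b - s$a)^2))
    if (l < 1e-9) next
    from <- c(from, get_vid(s$a)); to <- c(to, get_vid(s$b))
    len <- c(len, l); rowi <- c(rowi, s$row)
  }
  xy <- do.call(rbind, coords)
  # deterministic ids: vertices numbered in (x, y) order
  ord <- order(xy[, 1], xy[, 2])
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  ids <- sprintf("v%04d", rank)
  vertices <- tibble::tibble(id = ids, x = xy[, 1], y = xy[, 2])
  vertices <- vertices[order(vertices$id), ]

  rt <- road_network$road_type[rowi]
  wd <- road_network$width_ft[rowi]
  frm <- road_network$fixed_route_modes[rowi]
  cons <- eff[rowi]
  minutes <- vector("list", length(rowi))
  modes <- vector("list", length(rowi))
  for (i in seq_along(rowi)) {
    mm <- applicable_modes(rt[i], wd[i], frm[[i]], cons[i])
    modes[[i]] <- mm
    minutes[[i]] <- vapply(mm, function(m)
      segment_time(len[i], m, rt[i], speeds), numeric(1))
  }
  edges <- tibble::tibble(
    from = ids[from], to = ids[to],
    segment_id = road_network$segment_id[rowi],
    length_km = len, road_type = rt, width_ft = wd,
    fixed_route_modes = frm, modes = modes, minutes = minutes
  )
  edges <- edges[order(edges$from, edges$to), ]

  village_vertices <- tibble::tibble(
    village_id = character(), attach = character(), connector_km = numeric())
  if (!is.null(villages) && nrow(villages) > 0) {
    d2 <- outer(villages$cx, vertices$x, "-")^2 +
      outer(villages$cy, vertices$y, "-")^2
    nearest <- apply(d2, 1, which.min)
    dist <- sqrt(d2[cbind(seq_len(nrow(villages)), nearest)])
    far <- dist > max_connector_km
    if (any(far)) {
      warning("isolation warning: village(s) farther than ", max_connector_km,
              " km from the network: ",
              paste(villages$village_id[far], collapse = ", "), call. = FALSE)
    }
    village_vertices <- tibble::tibble(
      village_id = villages$village_id,
      attach = vertices$id[nearest], connector_km = dist)
    cedges <- tibble::tibble(
      from = villages$village_id, to = vertices$id[nearest],
      segment_id = paste0("connector_", villages$village_id),
      length_km = dist, road_type = "unpaved", width_ft = 3,
      fixed_route_modes = rep(list(character()), nrow(villages)),
      modes = rep(list("walk"), nrow(villages)),
      minutes = lapply(dist, function(d) c(walk = 60 * d / WALK_KMH)))
    vertices <- dplyr::bind_rows(vertices, tibble::tibble(
      id = villages$village_id, x = villages$cx, y = villages$cy))
    edges <- dplyr::bind_rows(edges, cedges)
  }
  structure(list(vertices = vertices, edges = edges,
                 village_vertices = village_vertices, speeds = speeds),
            class = "transport_network")
}

#' @export
print.transport_network <- function(x, ...) {
  cat("<transport_network> ", nrow(x$vertices), " vertices, ",
      nrow(x$edges), " edges, ", nrow(x$village_vertices),
      " village connectors\n", sep = "")
  invisible(x)
}

# per-edge weight (minutes) under a mode policy; Inf = impassable
policy_weights <- function(network, mode_policy) {
  ed <- network$edges
  vapply(seq_len(nrow(ed)), function(i) {
    mins <- ed$minutes[[i]]
    if (length(mins) == 0) return(Inf)
    if (mode_policy == "fastest_available") return(min(mins))
    if (mode_policy == "rickshaw_only") {
      for (m in c("rickshaw", "walk", "boat")) {
        if (m %in% names(mins)) return(mins[[m]])
      }
      return(Inf)
    }
    m <- sub("^single_mode:", "", mode_policy)
    if (m %in% names(mins)) return(mins[[m]])
    # villages attach by walking regardless of the single-mode policy
    if (startsWith(ed$segment_id[i], "connector_") &&
        "walk" %in% names(mins)) return(mins[["walk"]])
    Inf
  }, numeric(1))
}

# chosen mode per edge under a policy (fastest applicable; ties to the
# faster-listed mode order of applicable_modes)
policy_modes <- function(network, mode_policy) {
  ed <- network$edges
  vapply(seq_len(nrow(ed)), function(i) {
    mins <- ed$minutes[[i]]
    if (length(mins) == 0) return(NA_character_)
    if (mode_policy == "fastest_available") return(names(mins)[which.min(mins)])
    if (mode_policy == "rickshaw_only") {
      for (m in c("rickshaw", "walk", "boat")) if (m %in% names(mins)) return(m)
      return(NA_character_)
    }
    m <- sub("^single_mode:", "", mode_policy)
    if (m %in% names(mins)) return(m)
    if (startsWith(ed$segment_id[i], "connector_") &&
        "walk" %in% names(mins)) return("walk")
    NA_character_
  }, character(1))
}

adjacency <- function(network, w) {
  n <- nrow(network$vertices)
  idx <- stats::setNames(seq_len(n), network$vertices$id)
  fi <- idx[network$edges$from]; ti <- idx[network$edges$to]
  keep <- is.finite(w)
  adj <- vector("list", n)
  ii <- c(fi[keep], ti[keep]); jj <- c(ti[keep], fi[keep])
  ww <- c(w[keep], w[keep]); ee <- rep(which(keep), 2)
  sp <- split(seq_along(ii), ii)
  for (k in names(sp)) {
    s <- sp[[k]]
    adj[[as.integer(k)]] <- list(to = jj[s], w = ww[s], edge = ee[s])
  }
  list(adj = adj, idx = idx)
}

# distance-only Dijkstra (O(V^2)); used for batch computations
dijkstra_dist <- function(adjl, source) {
  n <- length(adjl$adj)
  dist <- rep(Inf, n); dist[source] <- 0
  done <- rep(FALSE, n)
  for (it in seq_len(n)) {
    d <- dist; d[done] <- Inf
    u <- which.min(d)
    if (!is.finite(d[u])) break
    done[u] <- TRUE
    a <- adjl$adj[[u]]
    if (is.null(a)) next
    nd <- dist[u] + a$w
    imp <- nd < dist[a$to]
    dist[a$to[imp]] <- nd[imp]
  }
  dist
}

# TRUE if path a beats path b under (already equal cost/hops) lexicographic
# vertex-id order
path_lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

# label: (cost, hops, path); TRUE if la strictly better
label_less <- function(ca, ha, pa, cb, hb, pb, tol = 1e-9) {
  if (ca < cb - tol) return(TRUE)
  if (ca > cb + tol) return(FALSE)
  if (ha != hb) return(ha < hb)
  path_lex_less(pa, pb)
}

#' Minimum-travel-time path between two network locations
#'
#' Dijkstra over the per-edge minutes selected by the mode policy. Ties in
#' total minutes break by fewer edges, then by the lexicographically
#' smallest vertex-id sequence, so the returned path is unique and
#' reproducible.
#'
#' @param network A `transport_network`.
#' @param origin Vertex id or village id.
#' @param destination Vertex id or village id.
#' @param mode_policy `"fastest_available"` (each edge at its fastest
#'   applicable mode), `"rickshaw_only"` (rickshaw on vehicle-passable
#'   roads, walking on sub-5-ft roads, boat on water) or
#'   `"single_mode:<mode>"`.
#' @return List: `path` (vertex ids, origin first; just the origin when
#'   origin == destination), `minutes`, `distance_km`, `legs` (tibble of
#'   (mode, length_km, road_type) per traversed edge).
#' @export
shortest_time_path <- function(network, origin, destination,
                               mode_policy = "fastest_available") {
  w <- policy_weights(network, mode_policy)
  em <- policy_modes(network, mode_policy)
  adjl <- adjacency(network, w)
  if (!origin %in% names(adjl$idx) || !destination %in% names(adjl$idx)) {
    stop("unknown vertex or village id", call. = FALSE)
  }
  s <- adjl$idx[[origin]]; t <- adjl$idx[[destination]]
  ids <- network$vertices$id
  n <- length(adjl$adj)
  if (s == t) {
    return(list(path = ids[s], minutes = 0, distance_km = 0,
                legs = tibble::tibble(mode = character(),
                                      length_km = numeric(),
                                      road_type = character())))
  }
  cost <- rep(Inf, n); hop <- rep(NA_integer_, n)
  paths <- vector("list", n); pedge <- vector("list", n)
  cost[s] <- 0; hop[s] <- 0L; paths[[s]] <- ids[s]; pedge[[s]] <- integer()
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(cost))
    if (length(cand) == 0) break
    u <- cand[1]
    for (v in cand[-1]) {
      if (label_less(cost[v], hop[v], paths[[v]], cost[u], hop[u], paths[[u]])) u <- v
    }
    done[u] <- TRUE
    if (u == t) break
    a <- adjl$adj[[u]]
    if (is.null(a)) next
    for (k in seq_along(a$to)) {
      v <- a$to[k]
      if (done[v]) next
      nc <- cost[u] + a$w[k]; nh <- hop[u] + 1L
      np <- c(paths[[u]], ids[v])
      if (!is.finite(cost[v]) ||
          label_less(nc, nh, np, cost[v], hop[v], paths[[v]])) {
        cost[v] <- nc; hop[v] <- nh; paths[[v]] <- np
        pedge[[v]] <- c(pedge[[u]], a$edge[k])
      }
    }
  }
  if (!is.finite(cost[t])) {
    stop("unreachable: no path from ", origin, " to ", destination,
         " under policy ", mode_policy, call. = FALSE)
  }
  eidx <- pedge[[t]]
  legs <- tibble::tibble(
    mode = em[eidx],
    length_km = network$edges$length_km[eidx],
    road_type = network$edges$road_type[eidx])
  list(path = paths[[t]], minutes = cost[t],
       distance_km = sum(legs$length_km), legs = legs)
}

snap_to_vertex <- function(network, x, y, tol = 0.1, what = "point") {
  vv <- network$vertices
  d <- sqrt((vv$x - x)^2 + (vv$y - y)^2)
  i <- which.min(d)
  if (d[i] > tol) {
    stop(what, " lies ", round(d[i], 3), " km from the nearest network ",
         "vertex (tolerance ", tol, " km)", call. = FALSE)
  }
  vv$id[i]
}

hub_vertices <- function(network, hub_tbl) {
  vapply(seq_len(nrow(hub_tbl)), function(i)
    snap_to_vertex(network, hub_tbl$x[i], hub_tbl$y[i],
                   what = paste0("hub ", hub_tbl$hub_id[i])), character(1))
}

#' Nearest pick-up point of a village
#'
#' The hub or sub-hub minimising travel time from the village centroid under
#' the fastest-available policy; ties break hub before sub-hub, then by id.
#'
#' @param network A `transport_network` (built with the village attached).
#' @param village_id Village id.
#' @param hub_tbl Hubs layer.
#' @return List: `hub` (one-row tibble) and `minutes`.
#' @export
closest_hub <- function(network, village_id, hub_tbl) {
  w <- policy_weights(network, "fastest_available")
  adjl <- adjacency(network, w)
  if (!village_id %in% names(adjl$idx)) {
    stop("unknown village id: ", village_id, call. = FALSE)
  }
  dist <- dijkstra_dist(adjl, adjl$idx[[village_id]])
  hv <- hub_vertices(network, hub_tbl)
  mins <- unname(dist[adjl$idx[hv]])
  if (all(!is.finite(mins))) {
    stop("unreachable: village ", village_id, " reaches no hub", call. = FALSE)
  }
  ord <- order(round(mins, 6), match(hub_tbl$kind, c("hub", "sub_hub")),
               hub_tbl$hub_id)
  best <- ord[1]
  list(hub = hub_tbl[best, ], minutes = mins[best])
}

#' Build the hub-to-facility route catalog
#'
#' One route per anchoring hub (kind `"hub"`): the minimum-time path from
#' the hub to its nearest health facility under the fastest-available
#' policy. Sub-hubs lying on the path are attached in travel order with
#' their remaining time to the facility. A route whose legs use the nasiman
#' (deemed unsafe for patients) is kept in the catalog but flagged
#' `active = FALSE`, so catchment assignment skips it.
#'
#' @param network A `transport_network`.
#' @param hub_tbl Hubs layer (anchors = kind `"hub"`; sub-hubs attach to
#'   routes whose path passes them).
#' @param facility_tbl Facilities layer.
#' @return Route catalog tibble: `route_id`, `name`, `origin_hub`,
#'   `facility`, `mode` (label of modes used), `distance_km`, `time_min`,
#'   `path`, `legs`, `pickups` (list: pickup_id, kind, vertex, remaining
#'   minutes to facility), `active`, `catchment_population` (0 until
#'   [assign_catchments()]).
#' @export
build_route_catalog <- function(network, hub_tbl, facility_tbl) {
  anchors <- hub_tbl[hub_tbl$kind == "hub", , drop = FALSE]
  anchors <- anchors[order(anchors$hub_id), , drop = FALSE]
  subs <- hub_tbl[hub_tbl$kind == "sub_hub", , drop = FALSE]
  fv <- vapply(seq_len(nrow(facility_tbl)), function(i)
    snap_to_vertex(network, facility_tbl$x[i], facility_tbl$y[i],
                   what = paste0("facility ", facility_tbl$facility_id[i])),
    character(1))
  sv <- if (nrow(subs)) hub_vertices(network, subs) else character()
  rows <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    hv <- snap_to_vertex(network, anchors$x[i], anchors$y[i],
                         what = paste0("hub ", anchors$hub_id[i]))
    best <- NULL; best_f <- NA_integer_
    for (f in seq_len(nrow(facility_tbl))) {
      sp <- tryCatch(shortest_time_path(network, hv, fv[f]),
                     error = function(e) NULL)
      if (is.null(sp)) next
      if (is.null(best) || sp$minutes < best$minutes - 1e-9 ||
          (abs(sp$minutes - best$minutes) <= 1e-9 &&
             facility_tbl$facility_id[f] < facility_tbl$facility_id[best_f])) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best)) {
      stop("unreachable: hub ", anchors$hub_id[i], " reaches no facility",
           call. = FALSE)
    }
    cum <- cumsum(c(0, 60 * best$legs$length_km /
      vapply(seq_len(nrow(best$legs)), function(k)
        lookup_speed(best$legs$mode[k], best$legs$road_type[k],
                     network$speeds), numeric(1))))
    on_path <- match(sv, best$path)
    keep <- which(!is.na(on_path))
    pick <- tibble::tibble(
      pickup_id = c(anchors$hub_id[i], subs$hub_id[keep],
                    facility_tbl$facility_id[best_f]),
      kind = c("hub", rep("sub_hub", length(keep)), "facility"),
      vertex = c(hv, sv[keep], fv[best_f]),
      remaining_min = c(best$minutes,
                        best$minutes - cum[on_path[keep]],
                        0))
    pick <- pick[order(match(pick$vertex, best$path)), ]
    rows[[i]] <- tibble::tibble(
      route_id = sprintf("%02d", i),
      name = paste(anchors$name[i], "to", facility_tbl$name[best_f]),
      origin_hub = anchors$hub_id[i],
      facility = facility_tbl$facility_id[best_f],
      mode = paste(unique(best$legs$mode[best$legs$mode != "walk"]),
                   collapse = "+"),
      distance_km = best$distance_km, time_min = best$minutes,
      path = list(best$path), legs = list(best$legs), pickups = list(pick),
      active = !"nasiman" %in% best$legs$mode,
      catchment_population = 0L)
  }
  cat <- dplyr::bind_rows(rows)
  class(cat) <- c("route_catalog", class(cat))
  cat
}

#' Assign each village to a route and pick-up point
#'
#' Every non-excluded village maps to the pick-up point (hub, sub-hub or
#' facility end of an active route) minimising its travel time under the
#' fastest-available policy; ties break by pick-up kind (hub, then sub-hub,
#' then facility end), then pick-up id, then route id. Manual overrides
#' (village to route) are applied afterwards, re-selecting the best pick-up
#' on the forced route — this is the hook for local knowledge the automatic
#' time criterion cannot see.
#'
#' @param route_catalog From [build_route_catalog()].
#' @param villages Villages layer.
#' @param network A `transport_network` containing the villages.
#' @param manual_overrides Optional tibble (village_id, route_id).
#' @param exclusion_list Village ids excluded from the analysis (e.g.
#'   villages attending an out-of-study hospital).
#' @return List: `assignments` (village_id, route_id, pickup_id, access_min)
#'   and `routes` (catalog with `catchment_population` and
#'   `catchment_village_ids` filled in). Villages reaching no active route
#'   are reported in an `unassigned` warning and omitted.
#' @export
assign_catchments <- function(route_catalog, villages, network,
                              manual_overrides = NULL,
                              exclusion_list = character()) {
  act <- route_catalog[route_catalog$active, , drop = FALSE]
  if (nrow(act) == 0) stop("no active routes", call. = FALSE)
  picks <- dplyr::bind_rows(lapply(seq_len(nrow(act)), function(i) {
    p <- act$pickups[[i]]
    p$route_id <- act$route_id[i]
    p
  }))
  w <- policy_weights(network, "fastest_available")
  adjl <- adjacency(network, w)
  uverts <- unique(picks$vertex)
  dmat <- vapply(uverts, function(v) dijkstra_dist(adjl, adjl$idx[[v]]),
                 numeric(length(adjl$adj)))
  vids <- setdiff(villages$village_id, exclusion_list)
  kind_rank <- match(picks$kind, c("hub", "sub_hub", "facility"))
  rows <- vector("list", length(vids))
  unassigned <- character()
  for (i in seq_along(vids)) {
    vi <- adjl$idx[[vids[i]]]
    mins <- unname(dmat[vi, match(picks$vertex, uverts)])
    if (all(!is.finite(mins))) {
      unassigned <- c(unassigned, vids[i])
      next
    }
    # round before ordering so exact geometric ties stay ties across
    # serialisation round trips
    ord <- order(round(mins, 6), kind_rank, picks$pickup_id, picks$route_id)
    b <- ord[1]
    rows[[i]] <- tibble::tibble(
      village_id = vids[i], route_id = picks$route_id[b],
      pickup_id = picks$pickup_id[b], access_min = mins[b])
  }
  if (length(unassigned)) {
    warning("unassigned: village(s) reach no active route: ",
            paste(unassigned, collapse = ", "), call. = FALSE)
  }
  asg <- dplyr::bind_rows(rows)
  if (!is.null(manual_overrides) && nrow(manual_overrides) > 0) {
    for (i in seq_len(nrow(manual_overrides))) {
      v <- manual_overrides$village_id[i]
      r <- manual_overrides$route_id[i]
      if (!r %in% act$route_id) {
        stop("override names an inactive or unknown route: ", r, call. = FALSE)
      }
      pr <- picks[picks$route_id == r, , drop = FALSE]
      vi <- adjl$idx[[v]]
      mins <- unname(dmat[vi, match(pr$vertex, uverts)])
      b <- order(round(mins, 6), match(pr$kind, c("hub", "sub_hub", "facility")),
                 pr$pickup_id)[1]
      asg[asg$village_id == v, c("route_id", "pickup_id", "access_min")] <-
        list(r, pr$pickup_id[b], mins[b])
    }
  }
  pops <- stats::setNames(villages$population, villages$village_id)
  route_catalog$catchment_village_ids <- lapply(
    route_catalog$route_id, function(r) asg$village_id[asg$route_id == r])
  route_catalog$catchment_population <- vapply(
    route_catalog$catchment_village_ids,
    function(v) as.integer(sum(pops[v])), integer(1))
  list(assignments = asg, routes = route_catalog)
}

#' Exclude a route and reassign its villages
#'
#' Marks the route inactive (as done for the nasiman-served corridor, judged
#' unsafe for patient transport) and re-runs [assign_catchments()] so its
#' villages fall to their next-nearest active routes; total population is
#' conserved. Re-including the route and reassigning restores the original
#' catchments.
#'
#' @inheritParams assign_catchments
#' @param route_id Route to exclude.
#' @return As [assign_catchments()].
#' @export
exclude_route <- function(route_catalog, route_id, villages, network,
                          manual_overrides = NULL,
                          exclusion_list = character()) {
  if (!route_id %in% route_catalog$route_id) {
    stop("unknown route: ", route_id, call. = FALSE)
  }
  route_catalog$active[route_catalog$route_id == route_id] <- FALSE
  assign_catchments(route_catalog, villages, network, manual_overrides,
                    exclusion_list)
}

#' Estimated pick-up-request-to-facility arrival time for a village
#'
#' Access time from the village centroid to its assigned pick-up point plus
#' the route's remaining travel time from that pick-up to the facility. The
#' facility end counts as a pick-up with zero remaining time, so a village
#' at the facility vertex estimates 0.
#'
#' @param network A `transport_network`.
#' @param village_id Village id.
#' @param assignments From [assign_catchments()].
#' @param route_catalog The (assigned) route catalog.
#' @return Minutes.
#' @export
estimate_arrival <- function(network, village_id, assignments,
                             route_catalog) {
  a <- assignments[assignments$village_id == village_id, , drop = FALSE]
  if (nrow(a) == 0) stop("unassigned village: ", village_id, call. = FALSE)
  p <- route_catalog$pickups[[match(a$route_id, route_catalog$route_id)]]
  rem <- p$remaining_min[match(a$pickup_id, p$pickup_id)]
  unname(a$access_min + rem)
}
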