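EXPOSURE_TYPES <- c("aqi", "noise_db", "gvi")

#' Routing configuration
#'
#' @param sensitivities strictly positive, strictly increasing sensitivity
#'   coefficients `s` for the impedance sweep. The default eleven values
#'   span five orders of magnitude so that both weak (AQI) and strong
#'   (noise) spatial contrasts produce alternative routes.
#' @param max_detour maximum detour fraction relative to the shortest route
#'   (default 0.15, i.e. 15%, the detour cyclists are typically willing to
#'   accept).
#' @param noise_ramp dB ramp passed to [cost_coefficient()].
#' @param criterion how the exposure-optimal route is picked among
#'   detour-feasible candidates: `"exposure"` (default) takes the best
#'   length-weighted mean of the optimised exposure; `"composite_cost"`
#'   takes the lowest composite route cost evaluated at each candidate's
#'   own sensitivity.
#' @return a `routing_config` list.
#' @export
routing_config <- function(sensitivities = c(0.1, 0.5, 1, 2, 5, 10, 100,
                                             1000, 1e4, 1e5, 1e6),
                           max_detour = 0.15,
                           noise_ramp = c(45, 75),
                           criterion = c("exposure", "composite_cost")) {
  stopifnot(length(sensitivities) >= 1, all(sensitivities > 0),
            all(diff(sensitivities) > 0), max_detour > 0)
  structure(list(sensitivities = sensitivities, max_detour = max_detour,
                 noise_ramp = noise_ramp, criterion = match.arg(criterion)),
            class = "routing_config")
}

#' Composite edge cost under the environmental impedance function
#'
#' \deqn{C_e = C_t + C_t \cdot ce \cdot s}
#' where \eqn{C_t} is the base (distance-proportional) edge cost, \eqn{ce}
#' the environmental cost coefficient in \[0, 1\] and \eqn{s} the
#' sensitivity coefficient. The environmental surcharge is proportional to
#' both the exposure level and the distance travelled, and the composite
#' cost is never below the base cost.
#'
#' @param ct base edge cost (metres), positive.
#' @param ce environmental cost coefficient in \[0, 1\].
#' @param s sensitivity coefficient, >= 0.
#' @return `ct + ct * ce * s` (vectorised).
#' @examples
#' composite_edge_cost(80, 0.25, 2) # 120
#' @export
composite_edge_cost <- function(ct, ce, s) {
  if (any(ct <= 0)) stop("base cost ct must be positive")
  if (any(ce < 0 | ce > 1)) stop("cost coefficient ce must lie in [0, 1]")
  if (any(s < 0)) stop("sensitivity s must be non-negative")
  ct + ct * ce * s
}

# Routing context: igraph, node index, per-node adjacency sorted by edge id
# (the deterministic tie-break order), and lazily-computed ce columns.
routing_context <- function(net, noise_ramp = c(45, 75)) {
  nodes <- net$nodes; edges <- net$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes$id))
  vidx <- seq_len(nrow(nodes)); names(vidx) <- nodes$id
  ui <- vidx[edges$u]; vi <- vidx[edges$v]
  eord <- order(edges$id, method = "radix")
  adj <- vector("list", nrow(nodes))
  for (k in eord) {
    adj[[ui[k]]] <- rbind(adj[[ui[k]]], c(k, vi[k]))
    adj[[vi[k]]] <- rbind(adj[[vi[k]]], c(k, ui[k]))
  }
  ce <- sapply(EXPOSURE_TYPES, function(t) {
    v <- edges[[t]]
    if (all(is.na(v))) rep(NA_real_, length(v))
    else if (anyNA(v)) rep(NA_real_, length(v))  # force impute_missing first
    else cost_coefficient(t, v, noise_ramp = noise_ramp)
  })
  list(net = net, g = g, vidx = vidx, adj = adj, len = edges$length, ce = ce)
}

ctx_weights <- function(ctx, exposure_type, s) {
  if (s == 0) return(ctx$len)
  ce <- ctx$ce[, exposure_type]
  if (anyNA(ce))
    stop("edges have missing ", exposure_type,
         " values; run impute_missing() first")
  ctx$len * (1 + ce * s)
}

# Greedy lexicographic walk over the shortest-path DAG: starting at the
# origin, repeatedly take the smallest-id incident edge that can still
# complete a minimum-cost path (prefix + w(e) + dist(other end, dest) ==
# total, within tolerance). This returns the lexicographically smallest
# edge-id sequence among all minimum-cost paths.
walk_lex_path <- function(ctx, w, d_o, d_d, o, d, total) {
  tol <- 1e-9 * max(1, total)
  n_e <- length(w)
  e_seq <- integer(0); n_seq <- o
  u <- o; prefix <- 0
  for (step in seq_len(2L * n_e + 1L)) {
    if (u == d) return(list(edges = e_seq, nodes = n_seq))
    A <- ctx$adj[[u]]
    slack <- prefix + w[A[, 1L]] + d_d[A[, 2L]] - total
    k <- which(slack <= tol)
    if (!length(k)) k <- which(slack <= 1e-6 * max(1, total))
    if (!length(k)) stop("internal: path reconstruction failed")
    k <- k[1L]
    prefix <- prefix + w[A[k, 1L]]
    u <- A[k, 2L]
    e_seq <- c(e_seq, A[k, 1L]); n_seq <- c(n_seq, u)
  }
  stop("internal: path reconstruction did not terminate")
}

# Assemble a route object from edge/node index sequences.
build_route <- function(ctx, e_seq, n_seq, w, s, shortest_length = NA_real_) {
  edges <- ctx$net$edges
  lens <- ctx$len[e_seq]
  total <- sum(lens)
  wmean <- function(v) {
    v <- v[e_seq]
    if (anyNA(v)) NA_real_ else sum(v * lens) / total
  }
  geoms <- lapply(seq_along(e_seq), function(i) {
    g <- edges$geometry[[e_seq[i]]]
    from_id <- ctx$net$nodes$id[n_seq[i]]
    if (edges$u[e_seq[i]] != from_id) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
    g
  })
  geometry <- geoms[[1L]]
  for (g in geoms[-1L]) geometry <- rbind(geometry, g[-1L, , drop = FALSE])
  structure(list(
    edge_ids = edges$id[e_seq],
    node_ids = ctx$net$nodes$id[n_seq],
    length = total,
    mean_aqi = wmean(edges$aqi),
    mean_noise_db = wmean(edges$noise_db),
    mean_gvi = wmean(edges$gvi),
    composite_cost = sum(w[e_seq]),
    sensitivity_used = s,
    detour_fraction = if (is.na(shortest_length)) NA_real_
                      else (total - shortest_length) / shortest_length,
    geometry = geometry
  ), class = "exposure_route")
}

#' @export
print.exposure_route <- function(x, ...) {
  cat("<exposure_route> ", length(x$edge_ids), " edges, ",
      round(x$length, 1), " m (s = ", x$sensitivity_used, ")\n", sep = "")
  cat("  mean aqi=", signif(x$mean_aqi, 4), " noise_db=",
      signif(x$mean_noise_db, 4), " gvi=", signif(x$mean_gvi, 4), "\n", sep = "")
  invisible(x)
}

#' Least-cost path under the environmental impedance function
#'
#' Dijkstra least-cost routing with edge weights
#' \eqn{C_e = C_t (1 + ce \cdot s)}; `s = 0` yields the pure shortest
#' (distance-minimal) path. Among equal-cost paths the lexicographically
#' smallest edge-id sequence is returned, making results reproducible.
#'
#' @param net a [street_network()].
#' @param origin,dest node ids.
#' @param exposure_type one of `"aqi"`, `"noise_db"`, `"gvi"` (may be
#'   omitted when `s = 0`).
#' @param s sensitivity coefficient (>= 0).
#' @param noise_ramp passed to [cost_coefficient()].
#' @param ctx optional precomputed routing context (internal use).
#' @return an `exposure_route`: ordered edge/node ids, length,
#'   length-weighted mean exposures, composite cost at `s`, and geometry.
#' @export
least_cost_path <- function(net, origin, dest, exposure_type = NULL, s = 0,
                            noise_ramp = c(45, 75), ctx = NULL) {
  if (is.null(ctx)) ctx <- routing_context(net, noise_ramp)
  o <- ctx$vidx[[as.character(origin)]]
  d <- ctx$vidx[[as.character(dest)]]
  if (is.null(o) || is.null(d)) stop("origin or destination node not in network")
  if (s > 0 && is.null(exposure_type))
    stop("exposure_type is required when s > 0")
  w <- if (s == 0) ctx$len else ctx_weights(ctx, match.arg(exposure_type, EXPOSURE_TYPES), s)
  d_o <- igraph::distances(ctx$g, v = o, weights = w)[1L, ]
  total <- d_o[[d]]
  if (!is.finite(total))
    stop("nodes ", origin, " and ", dest, " are not connected")
  d_d <- igraph::distances(ctx$g, v = d, weights = w)[1L, ]
  p <- walk_lex_path(ctx, w, d_o, d_d, o, d, total)
  build_route(ctx, p$edges, p$nodes, w, s)
}

#' Sensitivity sweep: alternative routes across impedance weights
#'
#' Runs [least_cost_path()] once per sensitivity coefficient and
#' deduplicates identical edge-id sequences, keeping the smallest
#' sensitivity that produced each distinct route. Each candidate is
#' annotated with its detour fraction relative to the `s = 0` shortest
#' route.
#'
#' @inheritParams least_cost_path
#' @param config a [routing_config()].
#' @param shortest optional precomputed `s = 0` route.
#' @return list of candidate `exposure_route`s (the shortest route is
#'   attached as attribute `"shortest"`).
#' @export
sensitivity_sweep <- function(net, origin, dest, exposure_type,
                              config = routing_config(), shortest = NULL,
                              ctx = NULL) {
  exposure_type <- match.arg(exposure_type, EXPOSURE_TYPES)
  if (is.null(ctx)) ctx <- routing_context(net, config$noise_ramp)
  if (is.null(shortest))
    shortest <- least_cost_path(net, origin, dest, s = 0, ctx = ctx)
  shortest$detour_fraction <- 0
  out <- list(); seen <- character(0)
  for (s in config$sensitivities) {
    r <- least_cost_path(net, origin, dest, exposure_type, s, ctx = ctx)
    key <- paste(r$edge_ids, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    r$detour_fraction <- (r$length - shortest$length) / shortest$length
    out[[length(out) + 1L]] <- r
  }
  attr(out, "shortest") <- shortest
  out
}

#' Select the detour-constrained exposure-optimal route
#'
#' Among candidates whose detour fraction does not exceed `max_detour`
#' (boundary included, 1e-6 relative tolerance), picks the route with the
#' best length-weighted mean of the optimised exposure: the minimum for
#' `aqi` and `noise_db`, the maximum for `gvi`. Ties are broken by shorter
#' length, then lower sensitivity. If no candidate strictly improves on the
#' shortest route, the shortest route is returned with `improved = FALSE`.
#'
#' @param candidates list of `exposure_route`s from [sensitivity_sweep()].
#' @param shortest the `s = 0` route.
#' @param exposure_type exposure being optimised.
#' @param max_detour maximum detour fraction.
#' @param criterion see [routing_config()].
#' @return an `optimal_route_result`: list with `shortest`, `optimal`,
#'   `improved`, `exposure_change` (optimal minus shortest mean of the
#'   optimised exposure), `unconstrained_detour` (detour fraction of the
#'   best candidate ignoring the cap; 0 when nothing improves), and
#'   `exposure_type`.
#' @export
select_optimal <- function(candidates, shortest, exposure_type,
                           max_detour = 0.15,
                           criterion = c("exposure", "composite_cost")) {
  exposure_type <- match.arg(exposure_type, EXPOSURE_TYPES)
  criterion <- match.arg(criterion)
  field <- paste0("mean_", exposure_type)
  sgn <- if (exposure_type == "gvi") -1 else 1  # minimise sgn * mean
  base <- sgn * shortest[[field]]

  pick <- function(cands, score) {
    if (!length(cands)) return(NULL)
    o <- order(score,
               vapply(cands, `[[`, numeric(1), "length"),
               vapply(cands, `[[`, numeric(1), "sensitivity_used"))
    cands[[o[1L]]]
  }
  improves <- function(route) {
    !is.null(route) &&
      sgn * route[[field]] < base - 1e-9 * max(1, abs(base))
  }

  # unconstrained best (for the detour-distance distribution)
  sc_all <- vapply(candidates, function(r) sgn * r[[field]], numeric(1))
  best_all <- pick(candidates, sc_all)
  unconstrained_detour <- if (improves(best_all)) best_all$detour_fraction else 0

  cap <- max_detour * (1 + 1e-6) + 1e-12
  ok <- vapply(candidates, function(r) r$detour_fraction <= cap, logical(1))
  feas <- candidates[ok]
  best <- if (criterion == "exposure") {
    pick(feas, vapply(feas, function(r) sgn * r[[field]], numeric(1)))
  } else {
    pick(feas, vapply(feas, `[[`, numeric(1), "composite_cost"))
  }

  if (improves(best)) {
    structure(list(shortest = shortest, optimal = best, improved = TRUE,
                   exposure_change = best[[field]] - shortest[[field]],
                   unconstrained_detour = unconstrained_detour,
                   exposure_type = exposure_type),
              class = "optimal_route_result")
  } else {
    structure(list(shortest = shortest, optimal = shortest, improved = FALSE,
                   exposure_change = 0,
                   unconstrained_detour = unconstrained_detour,
                   exposure_type = exposure_type),
              class = "optimal_route_result")
  }
}

#' Shortest and exposure-optimal routes for one origin-destination pair
#'
#' @inheritParams least_cost_path
#' @param exposure_type exposure to optimise.
#' @param config a [routing_config()].
#' @return an `optimal_route_result` (see [select_optimal()]).
#' @export
route_od <- function(net, origin, dest, exposure_type,
                     config = routing_config(), ctx = NULL) {
  exposure_type <- match.arg(exposure_type, EXPOSURE_TYPES)
  if (is.null(ctx)) ctx <- routing_context(net, config$noise_ramp)
  shortest <- least_cost_path(net, origin, dest, s = 0, ctx = ctx)
  shortest$detour_fraction <- 0
  cands <- sensitivity_sweep(net, origin, dest, exposure_type, config,
                             shortest = shortest, ctx = ctx)
  select_optimal(cands, shortest, exposure_type, config$max_detour,
                 config$criterion)
}

#' All ordered origin-destination pairs of a station table
#'
#' @param stations data frame with a `station_id` column (k rows).
#' @return tibble of the `k * (k - 1)` ordered pairs, self-pairs excluded.
#' @export
od_pairs <- function(stations) {
  ids <- as.character(stations$station_id)
  grid <- expand.grid(dest = ids, origin = ids,
                      stringsAsFactors = FALSE)[, c("origin", "dest")]
  tibble::as_tibble(grid[grid$origin != grid$dest, ])
}

#' Batch routing: shortest plus three exposure-optimal routes per OD pair
#'
#' Snaps every station to its nearest network node, then for every ordered
#' station pair computes the shortest route and, for each of AQI, noise and
#' GVI, the detour-constrained exposure-optimal route across the
#' sensitivity sweep. Unreachable pairs are excluded with a logged count.
#'
#' @param net a [street_network()] with complete exposure attributes (run
#'   [impute_missing()] first if needed).
#' @param stations data frame with `station_id`, `x`, `y`.
#' @param config a [routing_config()].
#' @param pairs optional tibble (`origin`, `dest`) of station ids; defaults
#'   to all ordered pairs.
#' @return a `batch_routes` object: list with
#' \describe{
#'   \item{summary}{long tibble, one row per OD pair x route type
#'     (`shortest`, `aqi_optimal`, `noise_db_optimal`, `gvi_optimal`) with
#'     length, detour fraction, mean exposures, `improved`,
#'     `exposure_change`, `unconstrained_detour`, `sensitivity_used`.}
#'   \item{routes}{named list (`"origin->dest"`) of the four route objects.}
#'   \item{stations}{station table with snapped `node_id`.}
#'   \item{diagnostics}{unreachable pairs, count of optimal routes that used
#'     the largest sensitivity (a warning suggests widening the sweep when
#'     positive).}
#' }
#' @export
batch_route <- function(net, stations, config = routing_config(),
                        pairs = NULL) {
  ctx <- routing_context(net, config$noise_ramp)
  if (anyNA(ctx$ce))
    stop("network has missing exposure values; run impute_missing() for ",
         "each exposure type first")
  stations <- tibble::as_tibble(stations)
  stopifnot(all(c("station_id", "x", "y") %in% names(stations)))
  stations$station_id <- as.character(stations$station_id)
  snaps <- lapply(seq_len(nrow(stations)),
                  function(i) snap_point(net, stations$x[i], stations$y[i]))
  stations$node_id <- vapply(snaps, `[[`, character(1), "node_id")
  stations$snap_distance <- vapply(snaps, `[[`, numeric(1), "snap_distance")

  if (is.null(pairs)) pairs <- od_pairs(stations)
  node_of <- stats::setNames(stations$node_id, stations$station_id)
  o_idx <- ctx$vidx[node_of[pairs$origin]]
  d_idx <- ctx$vidx[node_of[pairs$dest]]

  svids <- ctx$vidx[unique(stations$node_id)]
  srow <- stats::setNames(seq_along(svids), names(svids))

  # distance matrices (stations x all nodes), one per weight configuration
  wcfg <- list(list(type = NA_character_, s = 0, w = ctx$len))
  for (t in EXPOSURE_TYPES)
    for (s in config$sensitivities)
      wcfg[[length(wcfg) + 1L]] <- list(type = t, s = s,
                                        w = ctx_weights(ctx, t, s))
  dmats <- lapply(wcfg, function(cf)
    igraph::distances(ctx$g, v = svids, weights = cf$w))

  route_for <- function(icfg, oi, di) {
    cf <- wcfg[[icfg]]; D <- dmats[[icfg]]
    o_node <- ctx$net$nodes$id[oi]; d_node <- ctx$net$nodes$id[di]
    d_o <- D[srow[[o_node]], ]; d_d <- D[srow[[d_node]], ]
    total <- d_o[[di]]
    if (!is.finite(total)) return(NULL)
    p <- walk_lex_path(ctx, cf$w, d_o, d_d, oi, di, total)
    build_route(ctx, p$edges, p$nodes, cf$w, cf$s)
  }

  smax <- max(config$sensitivities)
  routes <- list(); rows <- list(); unreachable <- list(); n_smax <- 0L
  for (p in seq_len(nrow(pairs))) {
    oi <- o_idx[[p]]; di <- d_idx[[p]]
    key <- paste0(pairs$origin[p], "->", pairs$dest[p])
    if (oi == di) {
      # both stations snap to the same node: degenerate, skip like unreachable
      unreachable[[length(unreachable) + 1L]] <-
        data.frame(origin = pairs$origin[p], dest = pairs$dest[p],
                   reason = "same snapped node")
      next
    }
    shortest <- route_for(1L, oi, di)
    if (is.null(shortest)) {
      unreachable[[length(unreachable) + 1L]] <-
        data.frame(origin = pairs$origin[p], dest = pairs$dest[p],
                   reason = "disconnected")
      next
    }
    shortest$detour_fraction <- 0
    pair_routes <- list(shortest = shortest)
    rows[[length(rows) + 1L]] <- data.frame(
      origin = pairs$origin[p], dest = pairs$dest[p], route_type = "shortest",
      length = shortest$length, detour_fraction = 0,
      mean_aqi = shortest$mean_aqi, mean_noise_db = shortest$mean_noise_db,
      mean_gvi = shortest$mean_gvi, improved = NA,
      exposure_change = NA_real_, unconstrained_detour = NA_real_,
      sensitivity_used = 0, stringsAsFactors = FALSE)
    for (ti in seq_along(EXPOSURE_TYPES)) {
      t <- EXPOSURE_TYPES[ti]
      cands <- list(); seen <- character(0)
      for (si in seq_along(config$sensitivities)) {
        icfg <- 1L + (ti - 1L) * length(config$sensitivities) + si
        r <- route_for(icfg, oi, di)
        kk <- paste(r$edge_ids, collapse = "\r")
        if (kk %in% seen) next
        seen <- c(seen, kk)
        r$detour_fraction <- (r$length - shortest$length) / shortest$length
        cands[[length(cands) + 1L]] <- r
      }
      res <- select_optimal(cands, shortest, t, config$max_detour,
                            config$criterion)
      if (res$improved && res$optimal$sensitivity_used == smax)
        n_smax <- n_smax + 1L
      pair_routes[[t]] <- res$optimal
      rows[[length(rows) + 1L]] <- data.frame(
        origin = pairs$origin[p], dest = pairs$dest[p],
        route_type = paste0(t, "_optimal"),
        length = res$optimal$length,
        detour_fraction = res$optimal$detour_fraction,
        mean_aqi = res$optimal$mean_aqi,
        mean_noise_db = res$optimal$mean_noise_db,
        mean_gvi = res$optimal$mean_gvi,
        improved = res$improved, exposure_change = res$exposure_change,
        unconstrained_detour = res$unconstrained_detour,
        sensitivity_used = res$optimal$sensitivity_used,
        stringsAsFactors = FALSE)
    }
    routes[[key]] <- pair_routes
  }
  unreachable <- if (length(unreachable)) do.call(rbind, unreachable)
                 else data.frame(origin = character(0), dest = character(0),
                                 reason = character(0))
  if (nrow(unreachable))
    message(nrow(unreachable), " OD pair(s) excluded (unreachable or degenerate)")
  if (n_smax > 0)
    warning(n_smax, " optimal route(s) used the largest sensitivity ",
            "coefficient; consider extending the sweep")
  structure(list(summary = dplyr::bind_rows(rows), routes = routes,
                 stations = stations,
                 diagnostics = list(unreachable = tibble::as_tibble(unreachable),
                                    n_used_max_sensitivity = n_smax),
                 config = config),
            class = "batch_routes")
}

#' @export
print.batch_routes <- function(x, ...) {
  cat("<batch_routes> ", length(x$routes), " routed OD pairs, ",
      nrow(x$diagnostics$unreachable), " excluded\n", sep = "")
  invisible(x)
}
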