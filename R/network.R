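#' Street networks for exposure-adjusted routing
#'
#' A `street_network` holds an undirected graph of nodes (projected planar
#' coordinates in metres) and edges with polyline geometries and optional
#' per-edge exposure attributes: `aqi` (composite Air Quality Index, 1 good
#' to 5 very poor), `noise_db` (Lden, A-weighted day-evening-night sound
#' level in dB) and `gvi` (Green View Index, fraction of visible green
#' vegetation in \[0, 1\]). Missing exposure values are stored as `NA`,
#' never silently treated as zero; see [impute_missing()].
#'
#' The network is undirected: cycling is assumed bidirectional, matching the
#' usual treatment of OSM-derived cycling networks.
#'
#' @param nodes a data frame with columns `id` (unique, coerced to
#'   character), `x`, `y` (finite, metres in a projected CRS).
#' @param edges a data frame with columns `id` (unique character), `u`, `v`
#'   (node ids), a `geometry` list column of n x 2 coordinate matrices
#'   (>= 2 vertices), and optional `aqi`, `noise_db`, `gvi` columns.
#'   An optional `length` column is validated against the polyline arc
#'   length (1e-6 relative tolerance); when absent it is computed.
#'
#' @return an object of class `street_network`: a list with tibbles
#'   `nodes` and `edges`.
#' @examples
#' nodes <- data.frame(id = c("a", "b"), x = c(0, 100), y = c(0, 0))
#' edges <- data.frame(id = "e1", u = "a", v = "b")
#' edges$geometry <- list(cbind(c(0, 100), c(0, 0)))
#' net <- street_network(nodes, edges)
#' @export
street_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("id", "u", "v", "geometry") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  edges$id <- as.character(edges$id)
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)

  if (anyDuplicated(nodes$id))
    stop("duplicate node id(s): ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (anyDuplicated(edges$id))
    stop("duplicate edge id(s): ", paste(unique(edges$id[duplicated(edges$id)]), collapse = ", "))
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y)))
    stop("node coordinates must be finite")

  missing_ref <- setdiff(c(edges$u, edges$v), nodes$id)
  if (length(missing_ref))
    stop("edge(s) reference undeclared node(s): ", paste(missing_ref, collapse = ", "))

  geom_len <- vapply(edges$geometry, function(g) {
    g <- as.matrix(g)
    if (nrow(g) < 2L) stop("edge geometry must have >= 2 vertices")
    polyline_length(g)
  }, numeric(1))
  if (any(geom_len <= 0)) stop("zero-length edge(s) are not allowed")
  if ("length" %in% names(edges)) {
    bad <- !is.na(edges$length) &
      abs(edges$length - geom_len) > 1e-6 * pmax(1, geom_len)
    if (any(bad))
      stop("stored edge length disagrees with polyline arc length for edge(s): ",
           paste(edges$id[bad], collapse = ", "))
  }
  edges$length <- geom_len

  for (col in c("aqi", "noise_db", "gvi"))
    if (!col %in% names(edges)) edges[[col]] <- NA_real_
  check_range <- function(v, lo, hi, what) {
    bad <- !is.na(v) & (v < lo | v > hi)
    if (any(bad)) stop(what, " value(s) outside [", lo, ", ", hi, "]")
  }
  check_range(edges$aqi, 1, 5, "aqi")
  check_range(edges$noise_db, 0, 120, "noise_db")
  check_range(edges$gvi, 0, 1, "gvi")

  structure(
    list(nodes = nodes,
         edges = edges[, c("id", "u", "v", "length", "aqi", "noise_db", "gvi", "geometry")]),
    class = "street_network"
  )
}

#' @export
print.street_network <- function(x, ...) {
  n_missing <- vapply(x$edges[c("aqi", "noise_db", "gvi")],
                      function(v) sum(is.na(v)), integer(1))
  cat("<street_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", round(sum(x$edges$length) / 1000, 1), " km)\n", sep = "")
  cat("  missing exposure values: aqi=", n_missing[["aqi"]],
      " noise_db=", n_missing[["noise_db"]], " gvi=", n_missing[["gvi"]], "\n", sep = "")
  invisible(x)
}

#' Bounding box of a street network
#'
#' @param net a [street_network()].
#' @param margin metres added on every side.
#' @return numeric vector `c(xmin, xmax, ymin, ymax)`.
#' @export
network_bbox <- function(net, margin = 0) {
  c(min(net$nodes$x) - margin, max(net$nodes$x) + margin,
    min(net$nodes$y) - margin, max(net$nodes$y) + margin)
}

# Heuristic degree-coordinate detection: a whole network that fits inside
# [-180, 180] x [-90, 90] AND spans < 10 units is almost certainly in
# geographic degrees (a metric network spanning < 10 m is degenerate).
check_planar_metres <- function(nodes) {
  if (nrow(nodes) < 2L) return(invisible(TRUE))
  span <- max(diff(range(nodes$x)), diff(range(nodes$y)))
  inside_deg <- all(abs(nodes$x) <= 180) && all(abs(nodes$y) <= 90)
  if (inside_deg && span < 10)
    stop("coordinates look like geographic degrees; ",
         "project the network to planar metres first")
  invisible(TRUE)
}

#' Read a street network from GeoJSON
#'
#' Expects an RFC 7946-structured FeatureCollection in *projected planar
#' metres* (no CRS transformation is performed; files in geographic degrees
#' are rejected by a bounding-box heuristic). LineString features are edges
#' and must carry properties `id`, `u`, `v` and optionally `aqi`,
#' `noise_db`, `gvi` (missing or `null` values load as `NA`). Point
#' features, when present, declare the nodes (property `id`); an edge
#' referencing an undeclared node is then a validation error. When no Point
#' features are present, nodes are derived from edge endpoints.
#'
#' @param path path to a GeoJSON file.
#' @return a [street_network()].
#' @seealso [write_network()]
#' @export
load_network <- function(path) {
  gj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                 error = function(e) stop("malformed GeoJSON: ", conditionMessage(e)))
  if (is.null(gj$type) || gj$type != "FeatureCollection" || is.null(gj$features))
    stop("malformed GeoJSON: expected a FeatureCollection with features")

  pts <- list(); lines <- list()
  for (f in gj$features) {
    gt <- f$geometry$type
    if (identical(gt, "Point")) pts[[length(pts) + 1L]] <- f
    else if (identical(gt, "LineString")) lines[[length(lines) + 1L]] <- f
    else stop("unsupported geometry type in network file: ", gt)
  }
  if (!length(lines)) stop("network file contains no LineString features")

  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  edges <- do.call(rbind, lapply(lines, function(f) {
    p <- f$properties
    if (is.null(p$id) || is.null(p$u) || is.null(p$v))
      stop("edge feature missing required properties id/u/v")
    data.frame(id = as.character(p$id), u = as.character(p$u),
               v = as.character(p$v), length = num_or_na(p$length),
               aqi = num_or_na(p$aqi), noise_db = num_or_na(p$noise_db),
               gvi = num_or_na(p$gvi), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(edges$id))
    stop("duplicate edge id(s) in file: ",
         paste(unique(edges$id[duplicated(edges$id)]), collapse = ", "))
  geoms <- lapply(lines, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(c2) c(as.numeric(c2[[1]]), as.numeric(c2[[2]]))))
    if (is.null(m) || nrow(m) < 2L) stop("LineString with fewer than 2 vertices")
    m
  })
  edges$geometry <- geoms

  if (length(pts)) {
    nodes <- do.call(rbind, lapply(pts, function(f) {
      p <- f$properties
      if (is.null(p$id)) stop("node feature missing property id")
      data.frame(id = as.character(p$id),
                 x = as.numeric(f$geometry$coordinates[[1]]),
                 y = as.numeric(f$geometry$coordinates[[2]]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    first <- t(vapply(geoms, function(g) g[1L, ], numeric(2)))
    last <- t(vapply(geoms, function(g) g[nrow(g), ], numeric(2)))
    nodes <- data.frame(id = c(edges$u, edges$v),
                        x = c(first[, 1L], last[, 1L]),
                        y = c(first[, 2L], last[, 2L]),
                        stringsAsFactors = FALSE)
    nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  }
  check_planar_metres(nodes)
  street_network(nodes, edges)
}

#' Write a street network to GeoJSON
#'
#' Emits Point features for nodes followed by LineString features for edges,
#' at full numeric precision so that `load_network(write_network(net))`
#' round-trips ids, lengths and exposure attributes exactly.
#'
#' @param net a [street_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  node_feats <- lapply(seq_len(nrow(net$nodes)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(net$nodes$x[i], net$nodes$y[i])),
         properties = list(id = net$nodes$id[i]))
  })
  edge_feats <- lapply(seq_len(nrow(net$edges)), function(i) {
    g <- net$edges$geometry[[i]]
    props <- list(id = net$edges$id[i], u = net$edges$u[i], v = net$edges$v[i],
                  length = net$edges$length[i])
    for (col in c("aqi", "noise_db", "gvi")) {
      v <- net$edges[[col]][i]
      if (!is.na(v)) props[[col]] <- v
    }
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(g)), function(k) g[k, ])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = c(node_feats, edge_feats))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Snap a point to the nearest network node and edge
#'
#' The nearest node (Euclidean distance) is the routing terminal used by all
#' higher-level functions; the nearest edge is reported for diagnostics.
#' Ties are broken deterministically by the smallest id (C-locale string
#' order).
#'
#' @param net a [street_network()].
#' @param x,y point coordinates (metres).
#' @return a list with `node_id`, `edge_id`, `snap_distance` (point-to-node,
#'   metres) and `edge_distance` (point-to-edge, metres).
#' @export
snap_point <- function(net, x, y) {
  if (nrow(net$nodes) == 0L) stop("cannot snap to an empty network")
  nd <- sqrt((net$nodes$x - x)^2 + (net$nodes$y - y)^2)
  cand <- which(nd <= min(nd) + 1e-12)
  node_i <- cand[order(net$nodes$id[cand], method = "radix")[1L]]

  ed <- vapply(net$edges$geometry, function(g) point_polyline_distance(x, y, g),
               numeric(1))
  cand_e <- which(ed <= min(ed) + 1e-12)
  edge_i <- cand_e[order(net$edges$id[cand_e], method = "radix")[1L]]

  list(node_id = net$nodes$id[node_i], edge_id = net$edges$id[edge_i],
       snap_distance = nd[node_i], edge_distance = ed[edge_i])
}
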