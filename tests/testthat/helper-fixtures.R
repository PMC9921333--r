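# Fixtures and independent oracles, all built in code.

straight_edge <- function(id, u, v, p1, p2, ...) {
  e <- data.frame(id = id, u = u, v = v, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) e[[nm]] <- extra[[nm]]
  e$geometry <- list(rbind(p1, p2))
  e
}

# Triangle: direct edge a-b (100 m, worst exposure) vs detour a-c-b
# (2 x 60 m, best exposure). ce(aqi=5)=1, ce(aqi=1)=0; same pattern for
# noise on the 45-75 ramp.
triangle_net <- function() {
  cy <- sqrt(60^2 - 50^2)
  nodes <- data.frame(id = c("a", "b", "c"),
                      x = c(0, 100, 50), y = c(0, 0, cy),
                      stringsAsFactors = FALSE)
  edges <- rbind(
    straight_edge("e1", "a", "b", c(0, 0), c(100, 0),
                  aqi = 5, noise_db = 75, gvi = 0),
    straight_edge("e2", "a", "c", c(0, 0), c(50, cy),
                  aqi = 1, noise_db = 45, gvi = 0.6),
    straight_edge("e3", "c", "b", c(50, cy), c(100, 0),
                  aqi = 1, noise_db = 45, gvi = 0.6))
  street_network(nodes, edges)
}

# Four nodes, two competing paths a-b-d (100+100) vs a-c-d (150+100); the
# a-c edge bends to make its arc length 150 m.
square_net <- function() {
  nodes <- data.frame(id = c("a", "b", "c", "d"),
                      x = c(0, 100, 0, 100), y = c(0, 0, -100, -100),
                      stringsAsFactors = FALSE)
  bend_x <- -sqrt(75^2 - 50^2)  # each half of the bent a-c edge is 75 m
  edges <- rbind(
    straight_edge("e1", "a", "b", c(0, 0), c(100, 0), aqi = 2),
    straight_edge("e2", "b", "d", c(100, 0), c(100, -100), aqi = 2),
    straight_edge("e3", "a", "c", c(0, 0), c(0, -100), aqi = 2),
    straight_edge("e4", "c", "d", c(0, -100), c(100, -100), aqi = 2))
  edges$geometry[[3]] <- rbind(c(0, 0), c(bend_x, -50), c(0, -100))
  street_network(nodes, edges)
}

# Random connected planar-coordinate network: spanning tree plus extra
# edges, no parallel edges or self loops. noise_db in [45, 75] so the cost
# coefficient spans [0, 1].
random_net <- function(n_nodes, max_edges = 12) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  x <- runif(n_nodes, 0, 1000); y <- runif(n_nodes, 0, 1000)
  pairs <- matrix(ncol = 2, nrow = 0)
  for (k in 2:n_nodes) pairs <- rbind(pairs, c(sample(k - 1, 1), k))
  all_pairs <- t(combn(n_nodes, 2))
  key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  avail <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% key, ,
                     drop = FALSE]
  n_extra <- min(nrow(avail), max(0, sample(0:(max_edges - n_nodes + 1), 1)))
  if (n_extra > 0)
    pairs <- rbind(pairs, avail[sample(nrow(avail), n_extra), , drop = FALSE])
  m <- nrow(pairs)
  edges <- do.call(rbind, lapply(seq_len(m), function(i) {
    straight_edge(sprintf("e%02d", i), ids[pairs[i, 1]], ids[pairs[i, 2]],
                  c(x[pairs[i, 1]], y[pairs[i, 1]]),
                  c(x[pairs[i, 2]], y[pairs[i, 2]]),
                  noise_db = runif(1, 45, 75))
  }))
  street_network(data.frame(id = ids, x = x, y = y,
                            stringsAsFactors = FALSE), edges)
}

# Exhaustive enumeration oracle: all node-simple paths between two nodes,
# as lists of edge indices (parallel-edge free networks).
enumerate_simple_paths <- function(net, origin, dest) {
  edges <- net$edges
  nbrs <- function(u) {
    i <- which(edges$u == u | edges$v == u)
    data.frame(e = i, v = ifelse(edges$u[i] == u, edges$v[i], edges$u[i]),
               stringsAsFactors = FALSE)
  }
  out <- list()
  walk <- function(u, visited, eseq) {
    if (u == dest) { out[[length(out) + 1L]] <<- eseq; return(invisible()) }
    nb <- nbrs(u)
    for (k in seq_len(nrow(nb))) {
      if (nb$v[k] %in% visited) next
      walk(nb$v[k], c(visited, nb$v[k]), c(eseq, nb$e[k]))
    }
  }
  walk(origin, origin, integer(0))
  out
}

# Oracle least-cost path: minimum of Ct*(1 + ce*s) summed over enumerated
# simple paths; ties resolved by lexicographically smallest edge-id
# sequence.
oracle_least_cost <- function(net, origin, dest, exposure_type, s) {
  paths <- enumerate_simple_paths(net, origin, dest)
  ce <- if (s == 0) rep(0, nrow(net$edges))
        else cost_coefficient(exposure_type, net$edges[[exposure_type]])
  w <- net$edges$length * (1 + ce * s)
  costs <- vapply(paths, function(p) sum(w[p]), numeric(1))
  best <- which(costs <= min(costs) * (1 + 1e-12))
  seqs <- lapply(paths[best], function(p) net$edges$id[p])
  keys <- vapply(seqs, paste, character(1), collapse = "\r")
  k <- order(keys, method = "radix")[1L]
  list(cost = costs[best[k]], edge_ids = seqs[[k]])
}

# Monte-Carlo area oracle for buffered polylines: uniform points in the
# inflated joint bounding box; the same point set estimates intersection
# and union so the Jaccard ratio is internally consistent.
mc_point_dist <- function(px, py, geom) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(geom) - 1L)) {
    ax <- geom[i, 1]; ay <- geom[i, 2]
    bx <- geom[i + 1, 1]; by <- geom[i + 1, 2]
    vx <- bx - ax; vy <- by - ay; l2 <- vx^2 + vy^2
    t <- if (l2 == 0) 0 else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / l2, 0), 1)
    d <- pmin(d, sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2))
  }
  d
}

mc_jaccard <- function(geomA, geomB, radius, n_pts) {
  bb <- rbind(geomA, geomB)
  xr <- range(bb[, 1]) + c(-radius, radius) * 1.01
  yr <- range(bb[, 2]) + c(-radius, radius) * 1.01
  px <- runif(n_pts, xr[1], xr[2]); py <- runif(n_pts, yr[1], yr[2])
  inA <- mc_point_dist(px, py, geomA) <= radius
  inB <- mc_point_dist(px, py, geomB) <= radius
  box <- diff(xr) * diff(yr)
  list(jaccard = sum(inA & inB) / sum(inA | inB),
       areaA = box * mean(inA), areaB = box * mean(inB))
}

# Random gently-turning polyline for overlap tests.
random_polyline <- function(n_seg = 4, step = 60) {
  ang <- runif(1, 0, 2 * pi)
  pts <- matrix(runif(2, 0, 100), ncol = 2)
  for (i in seq_len(n_seg)) {
    ang <- ang + runif(1, -0.8, 0.8)
    pts <- rbind(pts, pts[nrow(pts), ] + step * c(cos(ang), sin(ang)))
  }
  pts
}

write_tmp_geojson <- function(obj) {
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  path
}
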