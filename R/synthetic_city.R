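#' Synthetic-city configuration
#'
#' Parameters of the fully synthetic study area used to exercise the whole
#' pipeline: a jittered grid street network, three spatially smooth,
#' cross-correlated exposure fields (AQI raised and greenery depressed
#' towards the centre, emulating a dense urban core), docking stations
#' densest near the centre, and gravity-model trips.
#'
#' @param grid_n nodes per grid side (>= 2); the network has `grid_n^2`
#'   nodes and `2 * grid_n * (grid_n - 1)` edges.
#' @param spacing grid spacing in metres.
#' @param jitter uniform node-position noise in metres.
#' @param seed RNG seed; identical configs produce bit-identical cities.
#' @param field_smoothing Gaussian kernel width in grid cells for the
#'   exposure fields; larger values give smoother fields (the infinite
#'   limit is a spatially constant field).
#' @param target_corr named vector of target correlations between the
#'   latent exposure fields: `aqi_noise`, `aqi_gvi`, `noise_gvi`. Defaults
#'   (+0.7, -0.5, -0.4) reproduce the typical urban pattern of air
#'   pollution and noise rising together while greenery falls with both.
#' @param n_stations number of docking stations (placed on distinct nodes,
#'   denser near the centre).
#' @param gravity_beta distance-decay rate (1/m) of the gravity trip model;
#'   pair weights are proportional to `exp(-gravity_beta * distance)`.
#' @param total_trips total trip count distributed multinomially over
#'   ordered OD pairs.
#' @param centre_effect strength of the radial city-centre gradient added
#'   to the latent fields (0 disables it).
#' @param ring logical; plant a quiet-and-green ring road (low noise, high
#'   GVI at intermediate radius) around a noisy centre - a known spatial
#'   structure useful for end-to-end recovery checks.
#' @return a `city_config` list.
#' @export
city_config <- function(grid_n = 12, spacing = 100, jitter = 10, seed = 1,
                        field_smoothing = 2,
                        target_corr = c(aqi_noise = 0.7, aqi_gvi = -0.5,
                                        noise_gvi = -0.4),
                        n_stations = 20, gravity_beta = 0.002,
                        total_trips = 10000, centre_effect = 1,
                        ring = FALSE) {
  stopifnot(grid_n >= 2, spacing > 0, jitter >= 0, field_smoothing >= 0,
            all(abs(target_corr) < 1), n_stations >= 1, gravity_beta >= 0,
            total_trips >= 0, centre_effect >= 0)
  stopifnot(all(c("aqi_noise", "aqi_gvi", "noise_gvi") %in% names(target_corr)))
  structure(list(grid_n = grid_n, spacing = spacing, jitter = jitter,
                 seed = seed, field_smoothing = field_smoothing,
                 target_corr = target_corr, n_stations = n_stations,
                 gravity_beta = gravity_beta, total_trips = total_trips,
                 centre_effect = centre_effect, ring = ring),
            class = "city_config")
}

#' Generate the synthetic street network
#'
#' A `grid_n x grid_n` lattice with node positions jittered uniformly by up
#' to `jitter` metres and straight-line edges between lattice neighbours.
#' The network is connected and has exactly `2 * grid_n * (grid_n - 1)`
#' edges.
#'
#' @param cfg a [city_config()].
#' @return a [street_network()] without exposure attributes.
#' @export
generate_network <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$grid_n
  rc <- expand.grid(col = seq_len(n), row = seq_len(n))
  x <- (rc$col - 1) * cfg$spacing + stats::runif(n * n, -cfg$jitter, cfg$jitter)
  y <- (rc$row - 1) * cfg$spacing + stats::runif(n * n, -cfg$jitter, cfg$jitter)
  pad <- function(i, w) formatC(i, width = w, flag = "0")
  nodes <- data.frame(id = paste0("n", pad(seq_len(n * n), nchar(n * n))),
                      x = x, y = y, stringsAsFactors = FALSE)
  at <- function(row, col) (row - 1L) * n + col
  from <- integer(0); to <- integer(0)
  for (r in seq_len(n)) for (c in seq_len(n - 1L)) {
    from <- c(from, at(r, c)); to <- c(to, at(r, c + 1L))
  }
  for (r in seq_len(n - 1L)) for (c in seq_len(n)) {
    from <- c(from, at(r, c)); to <- c(to, at(r + 1L, c))
  }
  m <- length(from)
  edges <- data.frame(id = paste0("e", pad(seq_len(m), nchar(m))),
                      u = nodes$id[from], v = nodes$id[to],
                      stringsAsFactors = FALSE)
  edges$geometry <- lapply(seq_len(m), function(i)
    cbind(c(x[from[i]], x[to[i]]), c(y[from[i]], y[to[i]])))
  street_network(nodes, edges)
}

# Latent standard-normal fields smoothed with a Gaussian kernel over edge
# midpoints and rescaled to unit marginal variance. In the infinite
# smoothing limit the weights become uniform and the field constant.
smooth_fields <- function(mid, k, ell) {
  n <- nrow(mid)
  eps <- matrix(stats::rnorm(n * k), n, k)
  if (ell <= 0) return(eps)
  d2 <- as.matrix(stats::dist(mid))^2
  K <- exp(-d2 / (2 * ell^2))
  W <- K / rowSums(K)
  Z <- W %*% eps
  Z / sqrt(rowSums(W^2))
}

#' Generate correlated exposure fields on the network edges
#'
#' Three Gaussian random fields, smoothed over edge midpoints, are linearly
#' mixed to the configured target correlations, overlaid with a radial
#' city-centre gradient (more pollution and noise, less greenery towards
#' the centre) and mapped into valid ranges: AQI into \[1, 5\] with mean
#' near 1.9, noise into \[45, 80\] dB, GVI into \[0, 0.6\]. With
#' `cfg$ring = TRUE` a quiet, green ring at intermediate radius and a loud,
#' grey core are planted on top.
#'
#' @param cfg a [city_config()].
#' @param net the network from [generate_network()].
#' @return the network with `aqi`, `noise_db` and `gvi` filled on every
#'   edge.
#' @export
generate_exposure_fields <- function(cfg, net) {
  set.seed(cfg$seed + 1L)
  mid <- t(vapply(net$edges$geometry,
                  function(g) points_along(g, polyline_length(g) / 2)[1L, ],
                  numeric(2)))
  ell <- cfg$field_smoothing * cfg$spacing
  Z <- smooth_fields(mid, 3L, ell)

  tc <- cfg$target_corr
  R <- matrix(c(1, tc[["aqi_noise"]], tc[["aqi_gvi"]],
                tc[["aqi_noise"]], 1, tc[["noise_gvi"]],
                tc[["aqi_gvi"]], tc[["noise_gvi"]], 1), 3, 3)
  A <- tryCatch(chol(R), error = function(e)
    stop("target_corr is not a positive-definite correlation structure"))
  Z <- Z %*% A

  if (cfg$centre_effect > 0) {
    ctr <- c(mean(range(net$nodes$x)), mean(range(net$nodes$y)))
    dc <- sqrt((mid[, 1L] - ctr[1L])^2 + (mid[, 2L] - ctr[2L])^2)
    cs <- if (stats::sd(dc) > 0) -(dc - mean(dc)) / stats::sd(dc) else rep(0, nrow(mid))
    w <- cfg$centre_effect
    Z[, 1L] <- (Z[, 1L] + w * cs) / sqrt(1 + w^2)
    Z[, 2L] <- (Z[, 2L] + w * cs) / sqrt(1 + w^2)
    Z[, 3L] <- (Z[, 3L] - w * cs) / sqrt(1 + w^2)
  }

  aqi <- 1 + 4 * stats::pnorm(0.9 * Z[, 1L] - 1.016)  # mean near 1.9
  noise <- 45 + 35 * stats::pnorm(Z[, 2L])
  gvi <- 0.6 * stats::pnorm(Z[, 3L])

  if (isTRUE(cfg$ring)) {
    ctr <- c(mean(range(net$nodes$x)), mean(range(net$nodes$y)))
    dc <- sqrt((mid[, 1L] - ctr[1L])^2 + (mid[, 2L] - ctr[2L])^2)
    rmax <- max(dc)
    ring_band <- dc >= 0.45 * rmax & dc <= 0.7 * rmax
    core <- dc < 0.3 * rmax
    noise[ring_band] <- pmin(noise[ring_band], 47)
    gvi[ring_band] <- pmax(gvi[ring_band], 0.5)
    noise[core] <- pmax(noise[core], 74)
    gvi[core] <- pmin(gvi[core], 0.1)
  }

  net$edges$aqi <- unname(aqi)
  net$edges$noise_db <- unname(noise)
  net$edges$gvi <- unname(gvi)
  net
}

#' Generate docking stations and gravity-model trips
#'
#' Stations are placed on distinct network nodes, sampled with probability
#' decaying with distance from the centre (denser downtown). Trip counts
#' over the ordered OD pairs are multinomial with gravity weights
#' `exp(-gravity_beta * distance)`; self-pairs are excluded and zero-count
#' pairs are omitted from the table.
#'
#' @param cfg a [city_config()].
#' @param net the network.
#' @return list with `stations` (tibble: station_id, x, y, node_id) and
#'   `trips` (tibble: origin_station, destination_station, trip_count).
#' @export
generate_stations_and_trips <- function(cfg, net) {
  set.seed(cfg$seed + 2L)
  n_nodes <- nrow(net$nodes)
  if (cfg$n_stations > n_nodes)
    stop("n_stations exceeds the number of network nodes")
  ctr <- c(mean(range(net$nodes$x)), mean(range(net$nodes$y)))
  dc <- sqrt((net$nodes$x - ctr[1L])^2 + (net$nodes$y - ctr[2L])^2)
  prob <- exp(-dc / (0.4 * max(dc, 1)))
  pick <- sample.int(n_nodes, cfg$n_stations, prob = prob)
  pick <- pick[order(net$nodes$id[pick], method = "radix")]
  stations <- tibble::tibble(
    station_id = paste0("s", formatC(seq_len(cfg$n_stations),
                                     width = nchar(cfg$n_stations), flag = "0")),
    x = net$nodes$x[pick], y = net$nodes$y[pick],
    node_id = net$nodes$id[pick])

  pairs <- od_pairs(stations)
  if (nrow(pairs) == 0L || cfg$total_trips == 0) {
    trips <- tibble::tibble(origin_station = character(0),
                            destination_station = character(0),
                            trip_count = integer(0))
    return(list(stations = stations, trips = trips))
  }
  xy <- stats::setNames(split(cbind(stations$x, stations$y),
                              seq_len(nrow(stations))), stations$station_id)
  oi <- match(pairs$origin, stations$station_id)
  di <- match(pairs$dest, stations$station_id)
  d <- sqrt((stations$x[oi] - stations$x[di])^2 +
            (stations$y[oi] - stations$y[di])^2)
  wts <- exp(-cfg$gravity_beta * d)
  counts <- as.integer(stats::rmultinom(1L, cfg$total_trips, wts))
  keep <- counts > 0L
  trips <- tibble::tibble(origin_station = pairs$origin[keep],
                          destination_station = pairs$dest[keep],
                          trip_count = counts[keep])
  list(stations = stations, trips = trips)
}

#' Generate a complete synthetic city
#'
#' @param cfg a [city_config()].
#' @return a `synthetic_city`: list with `config`, `network` (exposure
#'   attributes filled), `stations`, `trips`.
#' @export
generate_city <- function(cfg = city_config()) {
  net <- generate_network(cfg)
  net <- generate_exposure_fields(cfg, net)
  st <- generate_stations_and_trips(cfg, net)
  structure(list(config = cfg, network = net, stations = st$stations,
                 trips = st$trips),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("<synthetic_city> grid_n=", x$config$grid_n, ", ",
      nrow(x$network$edges), " edges, ", nrow(x$stations), " stations, ",
      sum(x$trips$trip_count), " trips\n", sep = "")
  invisible(x)
}

# Inverse-distance-weighted interpolation of per-edge values onto points.
idw_at <- function(mid, values, px, py, power = 2) {
  out <- numeric(length(px))
  for (i in seq_along(px)) {
    d2 <- (mid[, 1L] - px[i])^2 + (mid[, 2L] - py[i])^2
    w <- 1 / (d2 + 1e-6)^(power / 2)
    out[i] <- sum(w * values) / sum(w)
  }
  out
}

#' Rasterise a per-edge field to an ESRI ASCII-style grid
#'
#' Inverse-distance interpolation of edge-midpoint values onto a regular
#' grid covering the network (used to emit the AQI raster the assignment
#' stage consumes).
#'
#' @param net a [street_network()].
#' @param values numeric per-edge values.
#' @param cell_size cell size in metres (default 13, matching the AQI layer
#'   resolution the layout emulates).
#' @param margin metres added around the network bounding box.
#' @return a `raster_grid`.
#' @export
rasterize_field <- function(net, values, cell_size = 13, margin = 26) {
  bb <- network_bbox(net, margin)
  nc <- as.integer(ceiling((bb[2L] - bb[1L]) / cell_size))
  nr <- as.integer(ceiling((bb[4L] - bb[3L]) / cell_size))
  mid <- t(vapply(net$edges$geometry,
                  function(g) points_along(g, polyline_length(g) / 2)[1L, ],
                  numeric(2)))
  cx <- bb[1L] + (seq_len(nc) - 0.5) * cell_size
  cy <- bb[3L] + (nr - seq_len(nr) + 0.5) * cell_size  # row 1 = north
  px <- rep(cx, times = nr)
  py <- rep(cy, each = nc)
  v <- idw_at(mid, values, px, py)
  structure(list(origin_x = bb[1L], origin_y = bb[3L], cell_size = cell_size,
                 nodata = -9999,
                 values = matrix(v, nrow = nr, ncol = nc, byrow = TRUE)),
            class = "raster_grid")
}

# Noise band polygons: coarse square cells carrying the band midpoint of
# the interpolated noise field (a simple stand-in for contoured dB bands).
noise_band_polygons <- function(net, cell = 50, band_width = 5) {
  bb <- network_bbox(net, cell)
  nc <- as.integer(ceiling((bb[2L] - bb[1L]) / cell))
  nr <- as.integer(ceiling((bb[4L] - bb[3L]) / cell))
  mid <- t(vapply(net$edges$geometry,
                  function(g) points_along(g, polyline_length(g) / 2)[1L, ],
                  numeric(2)))
  polys <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    x0 <- bb[1L] + (c - 1L) * cell; y0 <- bb[3L] + (r - 1L) * cell
    v <- idw_at(mid, net$edges$noise_db, x0 + cell / 2, y0 + cell / 2)
    band <- band_width * floor(v / band_width) + band_width / 2
    polys[[length(polys) + 1L]] <- noise_polygon(
      c(x0, x0 + cell, x0 + cell, x0), c(y0, y0, y0 + cell, y0 + cell),
      min(max(band, 0), 120))
  }
  structure(polys, class = "noise_layer")
}

#' Write a synthetic city to disk
#'
#' Emits exactly the formats the pipeline consumes: the bare network
#' (`network.geojson`, no exposure attributes), the attributed network
#' (`network_exposure.geojson`), an AQI raster (`aqi.asc`), noise band
#' polygons (`noise.geojson`), a GVI table (`gvi.csv`), stations
#' (`stations.csv`), trips (`trips.csv`) and the configuration
#' (`config.yaml`).
#'
#' @param city a [generate_city()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_city <- function(city, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- city$network
  bare <- net
  bare$edges$aqi <- NA_real_; bare$edges$noise_db <- NA_real_
  bare$edges$gvi <- NA_real_
  write_network(bare, file.path(dir, "network.geojson"))
  write_network(net, file.path(dir, "network_exposure.geojson"))
  write_ascii_grid(rasterize_field(net, net$edges$aqi),
                   file.path(dir, "aqi.asc"))
  write_noise_polygons(noise_band_polygons(net), file.path(dir, "noise.geojson"))
  utils::write.csv(data.frame(edge_id = net$edges$id, gvi = net$edges$gvi),
                   file.path(dir, "gvi.csv"), row.names = FALSE)
  utils::write.csv(city$stations[, c("station_id", "x", "y")],
                   file.path(dir, "stations.csv"), row.names = FALSE)
  utils::write.csv(city$trips, file.path(dir, "trips.csv"), row.names = FALSE)
  cfg <- city$config
  cfg$target_corr <- as.list(cfg$target_corr)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
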