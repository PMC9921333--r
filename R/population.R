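#' Read a station table
#'
#' @param path CSV with columns `station_id`, `x`, `y` (metres).
#' @return tibble with unique character `station_id`.
#' @export
load_stations <- function(path) {
  st <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("station_id", "x", "y") %in% names(st)))
  st$station_id <- as.character(st$station_id)
  if (anyDuplicated(st$station_id)) stop("duplicate station id(s)")
  st
}

#' Read an origin-destination trip table
#'
#' Self-loop rows (origin equal to destination) are dropped with a message
#' reporting their count; such trips have no route. All stations referenced
#' must exist in the station table when one is supplied.
#'
#' @param path CSV with columns `origin_station`, `destination_station`,
#'   `trip_count` (non-negative integers).
#' @param stations optional station table for referential validation.
#' @return tibble of trips.
#' @export
load_trips <- function(path, stations = NULL) {
  tr <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("origin_station", "destination_station", "trip_count")
                %in% names(tr)))
  tr$origin_station <- as.character(tr$origin_station)
  tr$destination_station <- as.character(tr$destination_station)
  if (any(tr$trip_count < 0)) stop("negative trip_count")
  self <- tr$origin_station == tr$destination_station
  if (any(self)) {
    message("dropped ", sum(self), " self-loop trip row(s) (",
            sum(tr$trip_count[self]), " trips)")
    tr <- tr[!self, , drop = FALSE]
  }
  if (!is.null(stations)) {
    unknown <- setdiff(c(tr$origin_station, tr$destination_station),
                       as.character(stations$station_id))
    if (length(unknown))
      stop("trip table references unknown station(s): ",
           paste(unknown, collapse = ", "))
  }
  tr
}

#' Per-route exposure and time-in-class summary
#'
#' Converts a route to trip minutes at a constant cycling speed and
#' measures the minutes ridden on edges whose exposure exceeds each class
#' threshold (strict `>`, so a route exactly at the threshold contributes
#' nothing). Class membership is decided per edge from the edge's mean
#' exposure.
#'
#' @param route an `exposure_route` (see [least_cost_path()]).
#' @param net the [street_network()] the route was computed on.
#' @param speed cycling speed in km/h (default 15, a typical bike-share
#'   speed).
#' @param thresholds list with `aqi_gt`, `noise_gt_db`, `gvi_gt` class
#'   thresholds (defaults 2.0 AQI, 65 dB, 0.2 GVI).
#' @return one-row tibble: length, total minutes, mean exposures and
#'   `minutes_aqi_gt`, `minutes_noise_gt`, `minutes_gvi_gt`.
#' @export
route_summary <- function(route, net, speed = 15,
                          thresholds = list(aqi_gt = 2.0, noise_gt_db = 65.0,
                                            gvi_gt = 0.2)) {
  stopifnot(speed > 0)
  idx <- match(route$edge_ids, net$edges$id)
  if (anyNA(idx)) stop("route references edges absent from the network")
  e <- net$edges[idx, ]
  if (anyNA(e$aqi) || anyNA(e$noise_db) || anyNA(e$gvi))
    stop("route edges carry missing exposure values; impute first")
  m_per_min <- speed * 1000 / 60
  mins <- function(sel) sum(e$length[sel]) / m_per_min
  tibble::tibble(
    length_m = route$length,
    minutes = route$length / m_per_min,
    mean_aqi = route$mean_aqi,
    mean_noise_db = route$mean_noise_db,
    mean_gvi = route$mean_gvi,
    minutes_aqi_gt = mins(e$aqi > thresholds$aqi_gt),
    minutes_noise_gt = mins(e$noise_db > thresholds$noise_gt_db),
    minutes_gvi_gt = mins(e$gvi > thresholds$gvi_gt)
  )
}

#' Voronoi catchment polygons of docking stations
#'
#' Tessellates a rectangular study boundary so that every point of a
#' station's cell is nearer (Euclidean) to that station than to any other.
#' Cells partition the boundary exactly.
#'
#' @param stations data frame with `station_id`, `x`, `y`; coordinates must
#'   be distinct and inside the boundary.
#' @param boundary rectangle `c(xmin, xmax, ymin, ymax)`.
#' @return tibble with `station_id`, `polygon` (list of n x 2 matrices,
#'   unclosed rings) and `area_m2`.
#' @export
voronoi_catchments <- function(stations, boundary) {
  stopifnot(nrow(stations) >= 1, length(boundary) == 4)
  x <- stations$x; y <- stations$y
  if (anyDuplicated(cbind(x, y))) stop("duplicate station coordinates")
  if (any(x < boundary[1] | x > boundary[2] | y < boundary[3] | y > boundary[4]))
    stop("station(s) outside the study boundary")
  if (nrow(stations) == 1L) {
    poly <- cbind(boundary[c(1, 2, 2, 1)], boundary[c(3, 3, 4, 4)])
    return(tibble::tibble(station_id = as.character(stations$station_id),
                          polygon = list(poly),
                          area_m2 = diff(boundary[1:2]) * diff(boundary[3:4])))
  }
  dd <- deldir::deldir(x, y, rw = boundary, suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  polys <- unname(lapply(tiles, function(t) cbind(t$x, t$y)))
  areas <- unname(vapply(tiles, function(t) t$area, numeric(1)))
  # tile.list preserves input point order
  tibble::tibble(station_id = as.character(stations$station_id),
                 polygon = polys, area_m2 = areas)
}

# Join per-pair route means to trips; weight = trip_count (weighted) or 1.
trip_weights <- function(summary, trips, weighted) {
  if (!weighted)
    return(dplyr::mutate(summary, .w = 1))
  tr <- dplyr::summarise(
    dplyr::group_by(trips, .data$origin_station, .data$destination_station),
    .w = sum(.data$trip_count), .groups = "drop")
  out <- dplyr::left_join(summary, tr,
                          by = c(origin = "origin_station",
                                 dest = "destination_station"))
  out$.w[is.na(out$.w)] <- 0
  out
}

#' Aggregate route exposures to departure stations
#'
#' Averages route-mean exposures over the OD pairs departing from each
#' station, either unweighted (every pair counts once) or weighted by
#' realised trip counts. Pairs without trips get weight zero in the
#' weighted variant.
#'
#' @param summary the `summary` tibble of a [batch_route()] result.
#' @param trips trip table ([load_trips()]); required when
#'   `weighted = TRUE`.
#' @param weighted logical.
#' @return tibble: `station_id`, `route_type`, `trip_weighted`, `mean_aqi`,
#'   `mean_noise_db`, `mean_gvi`, `n_od_pairs`, `n_trips`.
#' @export
aggregate_by_station <- function(summary, trips = NULL, weighted = FALSE) {
  if (weighted && is.null(trips)) stop("trips are required when weighted = TRUE")
  df <- trip_weights(summary, trips, weighted)
  df <- dplyr::filter(df, .data$.w > 0)
  out <- dplyr::summarise(
    dplyr::group_by(df, station_id = .data$origin, .data$route_type),
    mean_aqi = stats::weighted.mean(.data$mean_aqi, .data$.w),
    mean_noise_db = stats::weighted.mean(.data$mean_noise_db, .data$.w),
    mean_gvi = stats::weighted.mean(.data$mean_gvi, .data$.w),
    n_od_pairs = dplyr::n(),
    n_trips = if (weighted) sum(.data$.w) else NA_real_,
    .groups = "drop")
  out$trip_weighted <- weighted
  out
}

#' Station catchments with aggregated departing-trip exposures
#'
#' Combines [voronoi_catchments()] with [aggregate_by_station()] (both
#' weighted and unweighted variants) into one per-station table.
#'
#' @param summary `summary` tibble from [batch_route()].
#' @param stations station table.
#' @param trips trip table.
#' @param boundary rectangle `c(xmin, xmax, ymin, ymax)`.
#' @return tibble with catchment polygon, area and the exposure means per
#'   route type and weighting.
#' @export
catchment_summaries <- function(summary, stations, trips, boundary) {
  cells <- voronoi_catchments(stations, boundary)
  agg <- dplyr::bind_rows(
    aggregate_by_station(summary, trips, weighted = FALSE),
    aggregate_by_station(summary, trips, weighted = TRUE))
  dplyr::left_join(agg, cells, by = "station_id")
}

#' Availability and mean change of exposure-optimal routes
#'
#' The core comparison table: for each exposure type, the share of OD pairs
#' (and of trips) for which a strictly improving exposure-optimal route
#' exists within the detour cap, the mean exposure change conditional on
#' improvement, and mean route distance and additional distance. Mean
#' additional distance is conditional on improvement (`n_improved` reports
#' the conditioning set size).
#'
#' @param summary `summary` tibble from [batch_route()].
#' @param trips optional trip table; when supplied, trip-weighted rows are
#'   included alongside unweighted ones.
#' @return tibble with one row per route type x weighting: mean exposures,
#'   `share_available_pct`, `mean_change`, `mean_distance_m`,
#'   `mean_additional_m`, `n_pairs`, `n_improved`.
#' @export
availability_and_change <- function(summary, trips = NULL) {
  one <- function(weighted) {
    df <- trip_weights(summary, trips, weighted)
    df <- dplyr::filter(df, .data$.w > 0)
    sh_len <- stats::setNames(
      df$length[df$route_type == "shortest"],
      paste(df$origin[df$route_type == "shortest"],
            df$dest[df$route_type == "shortest"]))
    df$shortest_length <- sh_len[paste(df$origin, df$dest)]
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$route_type),
      mean_aqi = stats::weighted.mean(.data$mean_aqi, .data$.w),
      mean_noise_db = stats::weighted.mean(.data$mean_noise_db, .data$.w),
      mean_gvi = stats::weighted.mean(.data$mean_gvi, .data$.w),
      mean_distance_m = stats::weighted.mean(.data$length, .data$.w),
      share_available_pct =
        if (all(is.na(.data$improved))) NA_real_
        else 100 * stats::weighted.mean(.data$improved, .data$.w),
      mean_change =
        if (all(is.na(.data$improved)) || !any(.data$improved)) NA_real_
        else stats::weighted.mean(.data$exposure_change[.data$improved],
                                  .data$.w[.data$improved]),
      mean_additional_m =
        if (all(is.na(.data$improved)) || !any(.data$improved)) NA_real_
        else stats::weighted.mean(
          (.data$length - .data$shortest_length)[.data$improved],
          .data$.w[.data$improved]),
      n_pairs = dplyr::n(),
      n_improved = sum(.data$improved, na.rm = TRUE),
      .groups = "drop")
    out$trip_weighted <- weighted
    out
  }
  res <- one(FALSE)
  if (!is.null(trips)) res <- dplyr::bind_rows(res, one(TRUE))
  res
}

#' Distribution of detour distances of exposure-optimal routes
#'
#' Uses the *unconstrained* best route per pair (the maximal-improvement
#' route across the whole sensitivity sweep, ignoring the detour cap) and
#' reports its detour-fraction histogram plus the share of pairs whose
#' maximal improvement is reachable within the threshold.
#'
#' @param summary `summary` tibble from [batch_route()].
#' @param trips optional trip table for trip-weighted counts and shares.
#' @param threshold detour threshold (default 0.15).
#' @param binwidth histogram bin width on the detour fraction (default
#'   0.05).
#' @return list with `histogram` (tibble: route_type, bin_left, bin_right,
#'   n, trip_weighted_n) and `shares` (tibble: route_type,
#'   within_threshold_pct, trip_weighted_within_pct).
#' @export
detour_distribution <- function(summary, trips = NULL, threshold = 0.15,
                                binwidth = 0.05) {
  df <- dplyr::filter(summary, .data$route_type != "shortest")
  df <- trip_weights(df, trips, !is.null(trips))
  if (is.null(trips)) df$.w <- 1
  hmax <- max(df$unconstrained_detour, threshold) + binwidth
  breaks <- seq(0, hmax + binwidth, by = binwidth)
  df$bin <- findInterval(df$unconstrained_detour, breaks,
                         rightmost.closed = TRUE)
  hist <- dplyr::summarise(
    dplyr::group_by(df, .data$route_type, .data$bin),
    n = dplyr::n(), trip_weighted_n = sum(.data$.w), .groups = "drop")
  hist$bin_left <- breaks[hist$bin]
  hist$bin_right <- breaks[hist$bin + 1L]
  cap <- threshold * (1 + 1e-6) + 1e-12
  shares <- dplyr::summarise(
    dplyr::group_by(df, .data$route_type),
    within_threshold_pct =
      100 * mean(.data$unconstrained_detour <= cap),
    trip_weighted_within_pct =
      if (all(.data$.w == 1)) NA_real_
      else 100 * stats::weighted.mean(.data$unconstrained_detour <= cap,
                                      .data$.w),
    .groups = "drop")
  list(histogram = hist[, c("route_type", "bin_left", "bin_right", "n",
                            "trip_weighted_n")],
       shares = shares)
}
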