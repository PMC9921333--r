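#' @importFrom dplyr .data
NULL

#' Write batch routes as GeoJSON LineStrings
#'
#' One LineString feature per OD pair and route type, with the route's
#' summary fields as properties.
#'
#' @param batch a [batch_route()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_routes <- function(batch, path) {
  feats <- list()
  for (key in names(batch$routes)) {
    od <- strsplit(key, "->", fixed = TRUE)[[1L]]
    for (rt in names(batch$routes[[key]])) {
      r <- batch$routes[[key]][[rt]]
      g <- r$geometry
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "LineString",
                        coordinates = lapply(seq_len(nrow(g)), function(k) g[k, ])),
        properties = list(origin = od[1L], dest = od[2L], route_type = rt,
                          length = r$length, mean_aqi = r$mean_aqi,
                          mean_noise_db = r$mean_noise_db,
                          mean_gvi = r$mean_gvi,
                          sensitivity_used = r$sensitivity_used,
                          detour_fraction = r$detour_fraction))
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write catchment polygons with summary properties as GeoJSON
#'
#' @param catchments tibble from [catchment_summaries()] or a join carrying
#'   a `polygon` list column plus scalar property columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catchments <- function(catchments, path) {
  prop_cols <- setdiff(names(catchments), "polygon")
  feats <- lapply(seq_len(nrow(catchments)), function(i) {
    poly <- catchments$polygon[[i]]
    ring <- lapply(c(seq_len(nrow(poly)), 1L), function(k) poly[k, ])
    props <- as.list(catchments[i, prop_cols, drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

# Mean per-trip minutes spent above each exposure-class threshold, for
# shortest vs exposure-optimal routes (unweighted and trip-weighted).
class_minutes_table <- function(batch, net, trips, speed, thresholds) {
  rows <- list()
  for (key in names(batch$routes)) {
    od <- strsplit(key, "->", fixed = TRUE)[[1L]]
    for (rt in names(batch$routes[[key]])) {
      rs <- route_summary(batch$routes[[key]][[rt]], net, speed, thresholds)
      rs$origin <- od[1L]; rs$dest <- od[2L]; rs$route_type <- rt
      rows[[length(rows) + 1L]] <- rs
    }
  }
  df <- dplyr::bind_rows(rows)
  df$route_type[df$route_type != "shortest"] <-
    paste0(df$route_type[df$route_type != "shortest"], "_optimal")
  one <- function(weighted) {
    d <- trip_weights(df, trips, weighted)
    d <- dplyr::filter(d, .data$.w > 0)
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$route_type),
      minutes = stats::weighted.mean(.data$minutes, .data$.w),
      minutes_aqi_gt = stats::weighted.mean(.data$minutes_aqi_gt, .data$.w),
      minutes_noise_gt = stats::weighted.mean(.data$minutes_noise_gt, .data$.w),
      minutes_gvi_gt = stats::weighted.mean(.data$minutes_gvi_gt, .data$.w),
      .groups = "drop")
    out$trip_weighted <- weighted
    out
  }
  dplyr::bind_rows(one(FALSE), one(TRUE))
}

#' Run the full exposure-assessment pipeline on a synthetic city
#'
#' End-to-end flow: generate and write the synthetic city, reload it
#' through the file-based interfaces, attach exposures from the raster /
#' polygon / tabular layers, impute any gaps, route every ordered station
#' pair (shortest plus three exposure-optimal routes), aggregate exposures
#' to Voronoi catchments, compute availability, class-minute and
#' detour-distribution summaries, run the route-similarity analysis, and
#' write all outputs plus a manifest.
#'
#' All randomness derives from `city$seed`; two runs with the same
#' configuration produce byte-identical summary CSVs.
#'
#' @param out_dir output directory.
#' @param city a [city_config()].
#' @param routing a [routing_config()].
#' @param speed cycling speed in km/h for minute budgets.
#' @param thresholds exposure-class thresholds (see [route_summary()]).
#' @param similarity_method overlap denominator
#'   (see [shared_route_proportion()]).
#' @return invisibly, a list with the batch result and every summary table.
#' @export
run_pipeline <- function(out_dir, city = city_config(),
                         routing = routing_config(), speed = 15,
                         thresholds = list(aqi_gt = 2.0, noise_gt_db = 65.0,
                                           gvi_gt = 0.2),
                         similarity_method = "jaccard") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warn_log <- character(0)
  handler <- function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  city_dir <- file.path(out_dir, "city")
  cobj <- generate_city(city)
  write_city(cobj, city_dir)

  net <- load_network(file.path(city_dir, "network.geojson"))
  grid <- read_ascii_grid(file.path(city_dir, "aqi.asc"))
  noise <- read_noise_polygons(file.path(city_dir, "noise.geojson"))
  gvi <- utils::read.csv(file.path(city_dir, "gvi.csv"),
                         stringsAsFactors = FALSE)
  net <- withCallingHandlers(
    assign_exposures(net, aqi_grid = grid, noise_layer = noise,
                     gvi_table = gvi), warning = handler)
  n_missing <- vapply(net$edges[c("aqi", "noise_db", "gvi")],
                      function(v) sum(is.na(v)), integer(1))
  for (t in EXPOSURE_TYPES)
    net <- suppressMessages(impute_missing(net, t))

  stations <- load_stations(file.path(city_dir, "stations.csv"))
  trips <- suppressMessages(load_trips(file.path(city_dir, "trips.csv"),
                                       stations))

  batch <- withCallingHandlers(
    suppressMessages(batch_route(net, stations, routing)), warning = handler)
  utils::write.csv(batch$summary, file.path(out_dir, "routes_summary.csv"),
                   row.names = FALSE)
  write_routes(batch, file.path(out_dir, "routes.geojson"))

  table1 <- availability_and_change(batch$summary, trips)
  utils::write.csv(table1, file.path(out_dir, "exposure_summary.csv"),
                   row.names = FALSE)

  boundary <- network_bbox(net, city$spacing / 2)
  catch <- catchment_summaries(batch$summary, stations, trips, boundary)
  utils::write.csv(catch[, setdiff(names(catch), "polygon")],
                   file.path(out_dir, "catchments.csv"), row.names = FALSE)
  write_catchments(catch, file.path(out_dir, "catchments.geojson"))

  det <- detour_distribution(batch$summary, trips, routing$max_detour)
  utils::write.csv(det$histogram, file.path(out_dir, "detour_histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(det$shares, file.path(out_dir, "detour_shares.csv"),
                   row.names = FALSE)

  cmin <- class_minutes_table(batch, net, trips, speed, thresholds)
  utils::write.csv(cmin, file.path(out_dir, "class_minutes.csv"),
                   row.names = FALSE)

  sim <- similarity_pipeline(batch, trips, method = similarity_method)
  utils::write.csv(sim$by_station,
                   file.path(out_dir, "similarity_by_station.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)

  manifest <- list(
    package = "exporoute",
    package_version = as.character(utils::packageVersion("exporoute")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = city$seed,
    city_config = unclass(city)[setdiff(names(unclass(city)), NULL)],
    routing_config = unclass(routing),
    speed_kmh = speed,
    thresholds = thresholds,
    similarity_method = similarity_method,
    counts = list(
      n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
      n_stations = nrow(stations),
      n_od_pairs = nrow(stations) * (nrow(stations) - 1),
      n_routed_pairs = length(batch$routes),
      n_unreachable = nrow(batch$diagnostics$unreachable),
      n_imputed = as.list(n_missing),
      n_trips = sum(trips$trip_count),
      n_used_max_sensitivity = batch$diagnostics$n_used_max_sensitivity),
    warnings = warn_log)
  manifest$city_config$target_corr <- as.list(city$target_corr)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)

  invisible(list(network = net, batch = batch, table1 = table1,
                 catchments = catch, detours = det, class_minutes = cmin,
                 similarity = sim, manifest = manifest))
}
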