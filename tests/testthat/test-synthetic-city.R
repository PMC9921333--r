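test_that("grid networks have n^2 nodes and 2n(n-1) edges, connected", {
  for (n in c(2, 3, 6)) {
    net <- generate_network(city_config(grid_n = n, n_stations = 2))
    expect_equal(nrow(net$nodes), n^2)
    expect_equal(nrow(net$edges), 2 * n * (n - 1))
    g <- igraph::graph_from_data_frame(net$edges[, c("u", "v")],
                                       directed = FALSE)
    expect_true(igraph::is_connected(g))
  }
  # jitter = 0 gives a perfectly regular grid
  net0 <- generate_network(city_config(grid_n = 4, jitter = 0,
                                       n_stations = 2))
  expect_true(all(abs(net0$edges$length - 100) < 1e-9))
})

test_that("identical configurations generate bit-identical cities", {
  cfg <- city_config(grid_n = 5, n_stations = 6, seed = 33, total_trips = 700)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$stations, b$stations)
  expect_identical(a$trips, b$trips)
  # a different seed changes the fields
  c_ <- generate_city(city_config(grid_n = 5, n_stations = 6, seed = 34,
                                  total_trips = 700))
  expect_false(identical(a$network$edges$aqi, c_$network$edges$aqi))
})

test_that("exposure fields stay within their declared ranges", {
  for (seed in c(1, 17)) {
    net <- generate_city(city_config(grid_n = 7, n_stations = 5,
                                     seed = seed, ring = seed == 17))$network
    expect_true(all(net$edges$aqi >= 1 & net$edges$aqi <= 5))
    expect_true(all(net$edges$noise_db >= 45 & net$edges$noise_db <= 80))
    expect_true(all(net$edges$gvi >= 0 & net$edges$gvi <= 0.6))
  }
})

test_that("field correlations carry the configured coupling signs", {
  net <- generate_exposure_fields(
    city_config(grid_n = 11, n_stations = 2, seed = 42),
    generate_network(city_config(grid_n = 11, n_stations = 2, seed = 42)))
  e <- net$edges
  expect_gt(cor(e$aqi, e$noise_db), 0)
  expect_lt(cor(e$gvi, e$noise_db), 0)
  expect_lt(cor(e$gvi, e$aqi), 0)
  expect_error(
    generate_exposure_fields(
      city_config(grid_n = 3, n_stations = 2,
                  target_corr = c(aqi_noise = 0.9, aqi_gvi = -0.9,
                                  noise_gvi = 0.9)),
      generate_network(city_config(grid_n = 3, n_stations = 2))),
    "positive-definite")
})

test_that("the infinite-smoothing limit yields constant fields", {
  cfg <- city_config(grid_n = 5, n_stations = 2, field_smoothing = 1e7,
                     centre_effect = 0, seed = 4)
  net <- generate_exposure_fields(cfg, generate_network(cfg))
  expect_lt(diff(range(net$edges$aqi)), 1e-6)
  expect_lt(diff(range(net$edges$noise_db)), 1e-6)
  ce <- cost_coefficient("noise_db", net$edges$noise_db)
  expect_lt(diff(range(ce)), 1e-6)
})

test_that("stations land on distinct nodes and trips follow the gravity model", {
  cfg <- city_config(grid_n = 6, n_stations = 10, seed = 8,
                     total_trips = 5000)
  city <- generate_city(cfg)
  expect_equal(length(unique(city$stations$node_id)), 10)
  expect_equal(sum(city$trips$trip_count), 5000)
  expect_true(all(city$trips$origin_station != city$trips$destination_station))
  # ordered OD pairs count k(k-1)
  for (k in 2:30) {
    st <- data.frame(station_id = paste0("s", seq_len(k)))
    expect_equal(nrow(od_pairs(st)), k * (k - 1))
  }
  # two stations -> exactly 2 ordered pairs possible
  c2 <- generate_city(city_config(grid_n = 4, n_stations = 2, seed = 5,
                                  total_trips = 100))
  expect_lte(nrow(c2$trips), 2)
  expect_equal(sum(c2$trips$trip_count), 100)
  # zero trips -> empty table
  c0 <- generate_city(city_config(grid_n = 4, n_stations = 3, seed = 5,
                                  total_trips = 0))
  expect_equal(nrow(c0$trips), 0)
  expect_error(generate_stations_and_trips(
    city_config(grid_n = 2, n_stations = 50), generate_network(
      city_config(grid_n = 2, n_stations = 4))), "exceeds")
})

test_that("beta = 0 gravity weights spread trips uniformly over pairs", {
  cfg <- city_config(grid_n = 6, n_stations = 6, seed = 13,
                     gravity_beta = 0, total_trips = 30000)
  city <- generate_city(cfg)
  n_pairs <- 6 * 5
  counts <- rep(0, n_pairs)
  counts[seq_len(nrow(city$trips))] <- city$trips$trip_count
  expected <- 30000 / n_pairs
  chi2 <- sum((counts - expected)^2 / expected)
  # 29 df; 99.9% quantile ~ 58
  expect_lt(chi2, qchisq(0.999, n_pairs - 1))
})

test_that("written city files reload into the same exposures and trips", {
  cfg <- city_config(grid_n = 4, n_stations = 4, seed = 6, total_trips = 300)
  city <- generate_city(cfg)
  dir <- tempfile()
  write_city(city, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "network.geojson", "network_exposure.geojson", "aqi.asc",
    "noise.geojson", "gvi.csv", "stations.csv", "trips.csv",
    "config.yaml")))))
  back <- load_network(file.path(dir, "network_exposure.geojson"))
  expect_identical(back$edges$aqi, city$network$edges$aqi)
  st <- load_stations(file.path(dir, "stations.csv"))
  expect_identical(st$station_id, city$stations$station_id)
  tr <- load_trips(file.path(dir, "trips.csv"), st)
  expect_equal(sum(tr$trip_count), 300)
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$grid_n, 4)
  # the emitted raster reproduces edge AQI to sub-class accuracy
  grid <- read_ascii_grid(file.path(dir, "aqi.asc"))
  bare <- load_network(file.path(dir, "network.geojson"))
  sampled <- vapply(bare$edges$geometry, function(g)
    sample_raster_along_edge(grid, g), numeric(1))
  expect_lt(mean(abs(sampled - city$network$edges$aqi)), 0.35)
})

test_that("a planted quiet-green ring is recovered by noise-optimal routing", {
  cfg <- city_config(grid_n = 9, n_stations = 2, seed = 19, ring = TRUE,
                     total_trips = 10)
  city <- generate_city(cfg)
  net <- city$network
  # OD pairs crossing the centre diagonally (the grid leaves such pairs
  # lateral room to detour around the core within the 15% cap)
  n <- cfg$grid_n
  ids <- net$nodes$id
  crossing <- list(
    c(ids[1], ids[n * n]), c(ids[n], ids[n * n - n + 1]),
    c(ids[2], ids[n * n - 1]), c(ids[n - 1], ids[n * n - n + 2]),
    c(ids[n + 1], ids[n * n - n]), c(ids[2 * n], ids[n * n - 2 * n + 1]),
    c(ids[3], ids[n * n - 2]), c(ids[n - 2], ids[n * n - n + 3]),
    c(ids[2 * n + 1], ids[n * n - 2 * n]),
    c(ids[3 * n], ids[n * n - 3 * n + 1]))
  improved <- vapply(crossing, function(od) {
    res <- route_od(net, od[1], od[2], "noise_db")
    res$improved && res$optimal$mean_noise_db < res$shortest$mean_noise_db
  }, logical(1))
  expect_gte(mean(improved), 0.9)
})
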