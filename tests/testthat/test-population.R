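test_that("route summaries convert length to minutes and class minutes", {
  # one straight 2500 m route: 10 minutes at 15 km/h
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 1250, 2500), y = 0)
  edges <- rbind(
    straight_edge("e1", "a", "b", c(0, 0), c(1250, 0),
                  aqi = 2, noise_db = 70, gvi = 0.1),
    straight_edge("e2", "b", "c", c(1250, 0), c(2500, 0),
                  aqi = 2, noise_db = 60, gvi = 0.1))
  net <- street_network(nodes, edges)
  r <- least_cost_path(net, "a", "c")
  rs <- route_summary(r, net, speed = 15)
  expect_equal(rs$minutes, 10)
  # half the length above 65 dB -> 5 minutes in class
  expect_equal(rs$minutes_noise_gt, 5)
  # everything at 60 dB -> 0 minutes above 65
  net2 <- net
  net2$edges$noise_db <- c(60, 60)
  rs2 <- route_summary(least_cost_path(net2, "a", "c"), net2, speed = 15)
  expect_equal(rs2$minutes_noise_gt, 0)
  # class minutes are monotone in the threshold
  for (th in c(50, 60, 65, 71)) {
    m1 <- route_summary(r, net, 15, list(aqi_gt = 2, noise_gt_db = th,
                                         gvi_gt = 0.2))$minutes_noise_gt
    m2 <- route_summary(r, net, 15, list(aqi_gt = 2, noise_gt_db = th + 5,
                                         gvi_gt = 0.2))$minutes_noise_gt
    expect_gte(m1, m2)
  }
  # strict '>' threshold: edges exactly at the threshold do not count
  net3 <- net
  net3$edges$noise_db <- c(65, 65)
  expect_equal(route_summary(least_cost_path(net3, "a", "c"), net3,
                             15)$minutes_noise_gt, 0)
})

test_that("Voronoi catchments partition the boundary", {
  # one station owns the whole boundary
  one <- data.frame(station_id = "s1", x = 5, y = 5)
  v1 <- voronoi_catchments(one, c(0, 10, 0, 20))
  expect_equal(v1$area_m2, 200)
  # two stations split by the perpendicular bisector
  two <- data.frame(station_id = c("s1", "s2"), x = c(2, 8), y = c(5, 5))
  v2 <- voronoi_catchments(two, c(0, 10, 0, 10))
  expect_equal(sort(v2$area_m2), c(50, 50))
  # off-centre pair: analytic areas from the bisector at x = 5 of (3,5)-(7,5)
  two2 <- data.frame(station_id = c("s1", "s2"), x = c(1, 7), y = c(5, 5))
  v22 <- voronoi_catchments(two2, c(0, 10, 0, 10))
  expect_equal(v22$area_m2[v22$station_id == "s1"], 40)  # bisector x = 4
  # four corner stations of a square -> equal quadrants
  four <- data.frame(station_id = paste0("s", 1:4),
                     x = c(1, 9, 1, 9), y = c(1, 1, 9, 9))
  v4 <- voronoi_catchments(four, c(0, 10, 0, 10))
  expect_equal(v4$area_m2, rep(25, 4))
  # areas always sum to the boundary area
  set.seed(1)
  st <- data.frame(station_id = paste0("s", 1:12),
                   x = runif(12, 0, 100), y = runif(12, 0, 80))
  v <- voronoi_catchments(st, c(0, 100, 0, 80))
  expect_equal(sum(v$area_m2), 8000, tolerance = 1e-6)
  # every cell interior point is nearest its own station (sampled)
  for (i in seq_len(nrow(v))) {
    poly <- v$polygon[[i]]
    cx <- mean(poly[, 1]); cy <- mean(poly[, 2])
    inside <- polyclip::pointinpolygon(list(x = cx, y = cy),
                                       list(x = poly[, 1], y = poly[, 2]))
    if (inside == 1) {
      d <- sqrt((st$x - cx)^2 + (st$y - cy)^2)
      expect_equal(which.min(d), i)
    }
  }
  dup <- data.frame(station_id = c("s1", "s2"), x = c(5, 5), y = c(5, 5))
  expect_error(voronoi_catchments(dup, c(0, 10, 0, 10)), "duplicate")
})

fake_summary <- function(od, noise) {
  tibble::tibble(origin = od[, 1], dest = od[, 2], route_type = "shortest",
                 length = 1000, detour_fraction = 0, mean_aqi = 2,
                 mean_noise_db = noise, mean_gvi = 0.2, improved = NA,
                 exposure_change = NA_real_, unconstrained_detour = NA_real_,
                 sensitivity_used = 0)
}

test_that("station aggregation weights by trips exactly", {
  od <- cbind(c("s1", "s1"), c("s2", "s3"))
  summ <- fake_summary(od, c(60, 70))
  trips <- tibble::tibble(origin_station = c("s1", "s1"),
                          destination_station = c("s2", "s3"),
                          trip_count = c(3, 1))
  w <- aggregate_by_station(summ, trips, weighted = TRUE)
  expect_equal(w$mean_noise_db, 62.5)  # (3*60 + 1*70)/4
  u <- aggregate_by_station(summ, weighted = FALSE)
  expect_equal(u$mean_noise_db, 65)
  # uniform trip counts make weighted equal unweighted
  trips$trip_count <- c(5, 5)
  expect_equal(aggregate_by_station(summ, trips, TRUE)$mean_noise_db, 65)
  # single OD pair: mean equals that route's value
  one <- fake_summary(cbind("s1", "s2"), 58)
  expect_equal(aggregate_by_station(one, weighted = FALSE)$mean_noise_db, 58)
})

test_that("weighted and unweighted means coincide under uniform trips", {
  set.seed(3)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    st <- paste0("s", seq_len(k))
    od <- as.matrix(expand.grid(st, st, stringsAsFactors = FALSE))
    od <- od[od[, 1] != od[, 2], ]
    summ <- fake_summary(od, runif(nrow(od), 45, 80))
    trips <- tibble::tibble(origin_station = od[, 1],
                            destination_station = od[, 2],
                            trip_count = 7)
    a <- aggregate_by_station(summ, trips, TRUE)
    b <- aggregate_by_station(summ, trips, FALSE)
    expect_equal(a$mean_noise_db, b$mean_noise_db, tolerance = 1e-12)
  }
})

test_that("availability shares and conditional changes follow the hand case", {
  # 3 OD pairs, 2 improving by -4 and -6 dB
  base <- fake_summary(cbind(c("s1", "s1", "s2"), c("s2", "s3", "s1")), 60)
  opt <- base
  opt$route_type <- "noise_db_optimal"
  opt$improved <- c(TRUE, TRUE, FALSE)
  opt$exposure_change <- c(-4, -6, 0)
  opt$unconstrained_detour <- c(0.05, 0.1, 0)
  opt$length <- c(1100, 1050, 1000)
  summ <- rbind(base, opt)
  out <- availability_and_change(summ)
  row <- out[out$route_type == "noise_db_optimal", ]
  expect_equal(row$share_available_pct, 200 / 3)
  expect_equal(row$mean_change, -5)
  expect_equal(row$mean_additional_m, 75)  # conditional on improvement
  expect_equal(row$n_improved, 2)
  # no pair improves -> share 0, change missing
  opt0 <- opt; opt0$improved <- FALSE; opt0$exposure_change <- 0
  out0 <- availability_and_change(rbind(base, opt0))
  r0 <- out0[out0$route_type == "noise_db_optimal", ]
  expect_equal(r0$share_available_pct, 0)
  expect_true(is.na(r0$mean_change))
  # every pair improves by exactly -1 -> share 100, mean -1
  opt1 <- opt; opt1$improved <- TRUE; opt1$exposure_change <- -1
  r1 <- availability_and_change(rbind(base, opt1))
  r1 <- r1[r1$route_type == "noise_db_optimal", ]
  expect_equal(r1$share_available_pct, 100)
  expect_equal(r1$mean_change, -1)
})

test_that("detour distribution counts within-threshold shares", {
  base <- fake_summary(cbind(c("s1", "s1", "s2"), c("s2", "s3", "s1")), 60)
  opt <- base
  opt$route_type <- "noise_db_optimal"
  opt$improved <- TRUE
  opt$unconstrained_detour <- c(0.05, 0.10, 0.20)
  d <- detour_distribution(rbind(base, opt), threshold = 0.15)
  sh <- d$shares[d$shares$route_type == "noise_db_optimal", ]
  expect_equal(sh$within_threshold_pct, 200 / 3)
  # all optimal identical to shortest -> all detours zero
  opt0 <- opt; opt0$unconstrained_detour <- 0
  d0 <- detour_distribution(rbind(base, opt0), threshold = 0.15)
  expect_equal(d0$shares$within_threshold_pct, 100)
  h0 <- d0$histogram
  expect_true(all(h0$bin_left[h0$n > 0] == 0))
  # single pair beyond the threshold -> share 0
  one <- fake_summary(cbind("s1", "s2"), 60)
  oneopt <- one; oneopt$route_type <- "noise_db_optimal"
  oneopt$improved <- TRUE; oneopt$unconstrained_detour <- 0.2
  d1 <- detour_distribution(rbind(one, oneopt), threshold = 0.15)
  expect_equal(d1$shares$within_threshold_pct, 0)
})

test_that("trip loading drops self-loops and validates stations", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(origin_station = c("s1", "s2", "s1"),
                       destination_station = c("s2", "s2", "s3"),
                       trip_count = c(5, 9, 2)), path, row.names = FALSE)
  st <- data.frame(station_id = c("s1", "s2", "s3"), x = 1:3, y = 1:3)
  expect_message(tr <- load_trips(path, st), "self-loop")
  expect_equal(nrow(tr), 2)
  expect_equal(sum(tr$trip_count), 7)
  st2 <- st[1:2, ]
  expect_error(suppressMessages(load_trips(path, st2)), "unknown station")
})
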