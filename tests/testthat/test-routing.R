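test_that("composite edge cost follows the impedance function", {
  expect_equal(composite_edge_cost(100, 0.5, 0), 100)
  expect_equal(composite_edge_cost(100, 0, 10), 100)
  expect_equal(composite_edge_cost(80, 0.25, 2), 120)
  # never below the base cost
  ct <- runif(50, 1, 500); ce <- runif(50); s <- runif(50, 0, 100)
  expect_true(all(composite_edge_cost(ct, ce, s) >= ct))
  expect_error(composite_edge_cost(-1, 0.5, 1), "positive")
  expect_error(composite_edge_cost(10, 1.5, 1), "\\[0, 1\\]")
  expect_error(composite_edge_cost(10, 0.5, -1), "non-negative")
})

test_that("least-cost paths match hand-enumerable cases", {
  # single-edge graph
  nodes <- data.frame(id = c("a", "b"), x = c(0, 100), y = 0)
  net1 <- street_network(nodes, straight_edge("e1", "a", "b",
                                              c(0, 0), c(100, 0)))
  r <- least_cost_path(net1, "a", "b")
  expect_equal(r$edge_ids, "e1")
  expect_equal(r$length, 100)

  # square: 100+100 beats 150+100 at s = 0 (brute-force enumeration agrees)
  sq <- square_net()
  r2 <- least_cost_path(sq, "a", "d")
  expect_equal(r2$edge_ids, c("e1", "e2"))
  expect_equal(r2$length, 200)
  oracle <- oracle_least_cost(sq, "a", "d", "aqi", 0)
  expect_equal(r2$edge_ids, oracle$edge_ids)

  # triangle: direct at s = 0, detour at s = 2 (costs 300 vs 120)
  tri <- triangle_net()
  expect_equal(least_cost_path(tri, "a", "b")$edge_ids, "e1")
  r3 <- least_cost_path(tri, "a", "b", "aqi", s = 2)
  expect_equal(r3$edge_ids, c("e2", "e3"))
  expect_equal(r3$composite_cost, 120)
  expect_equal(least_cost_path(tri, "a", "b", "aqi", s = 2,
                               ctx = NULL)$length, 120)

  # disconnected pair
  iso <- street_network(
    data.frame(id = c("a", "b", "c", "d"), x = c(0, 100, 500, 600), y = 0),
    rbind(straight_edge("e1", "a", "b", c(0, 0), c(100, 0)),
          straight_edge("e2", "c", "d", c(500, 0), c(600, 0))))
  expect_error(least_cost_path(iso, "a", "c"), "not connected")
})

test_that("routing equals exhaustive enumeration on random graphs", {
  set.seed(42)
  config <- routing_config()
  for (rep in 1:25) {
    net <- random_net(sample(4:7, 1))
    ids <- net$nodes$id
    od <- sample(ids, 2)
    for (s in c(0, config$sensitivities)) {
      got <- least_cost_path(net, od[1], od[2], "noise_db", s)
      want <- oracle_least_cost(net, od[1], od[2], "noise_db", s)
      expect_equal(got$composite_cost, want$cost, tolerance = 1e-9)
      expect_identical(got$edge_ids, want$edge_ids)
    }
  }
})

test_that("routes are direction-symmetric on the undirected network", {
  set.seed(7)
  for (rep in 1:10) {
    net <- random_net(6)
    od <- sample(net$nodes$id, 2)
    f <- least_cost_path(net, od[1], od[2], "noise_db", 5)
    b <- least_cost_path(net, od[2], od[1], "noise_db", 5)
    expect_equal(f$composite_cost, b$composite_cost, tolerance = 1e-9)
    expect_setequal(f$edge_ids, b$edge_ids)
  }
})

test_that("sensitivity sweep deduplicates and spans the alternatives", {
  tri <- triangle_net()
  cands <- sensitivity_sweep(tri, "a", "b", "aqi")
  expect_length(cands, 2)  # direct (low s) and detour (high s) only
  expect_true(all(vapply(cands, `[[`, numeric(1), "detour_fraction") >= 0))

  # uniform exposure field collapses the sweep to the single shortest route
  uni <- tri
  uni$edges$aqi <- 3
  cu <- sensitivity_sweep(uni, "a", "b", "aqi")
  expect_length(cu, 1)
  expect_equal(cu[[1]]$edge_ids, "e1")
})

test_that("select_optimal applies the detour cap and strict improvement", {
  tri <- triangle_net()
  shortest <- least_cost_path(tri, "a", "b")
  shortest$detour_fraction <- 0
  cands <- sensitivity_sweep(tri, "a", "b", "aqi", shortest = shortest)

  # detour route is 20% longer: blocked at the 15% cap...
  res15 <- select_optimal(cands, shortest, "aqi", max_detour = 0.15)
  expect_false(res15$improved)
  expect_identical(res15$optimal$edge_ids, shortest$edge_ids)
  expect_equal(res15$exposure_change, 0)
  # ...but its unconstrained detour is still reported
  expect_equal(res15$unconstrained_detour, 0.2)

  # allowed at a 30% cap, and picked for its mean AQI 1 < 5
  res30 <- select_optimal(cands, shortest, "aqi", max_detour = 0.3)
  expect_true(res30$improved)
  expect_equal(res30$optimal$edge_ids, c("e2", "e3"))
  expect_equal(res30$exposure_change, 1 - 5)

  # empty candidate list
  res0 <- select_optimal(list(), shortest, "aqi")
  expect_false(res0$improved)

  # greenery is maximised, not minimised
  resg <- select_optimal(cands, shortest, "gvi", max_detour = 0.3)
  expect_true(resg$improved)
  expect_equal(resg$exposure_change, 0.6)
})

test_that("uniform exposure fields never produce an 'improvement'", {
  cfg <- city_config(grid_n = 5, n_stations = 4, seed = 5,
                     field_smoothing = 1e6, centre_effect = 0,
                     total_trips = 100)
  city <- generate_city(cfg)
  net <- city$network
  expect_lt(diff(range(net$edges$aqi)), 1e-9)
  b <- batch_route(net, city$stations)
  opt <- dplyr::filter(b$summary, route_type != "shortest")
  expect_true(all(!opt$improved))
  expect_true(all(opt$detour_fraction == 0))
  # bit-identical fallback to the shortest route
  for (key in names(b$routes)) {
    sh <- b$routes[[key]]$shortest
    for (t in c("aqi", "noise_db", "gvi"))
      expect_identical(b$routes[[key]][[t]]$edge_ids, sh$edge_ids)
  }
})

test_that("sweep solutions trace the distance-exposure Pareto trade-off", {
  set.seed(99)
  for (rep in 1:5) {
    cfg <- city_config(grid_n = 6, n_stations = 2, seed = 100 + rep,
                       total_trips = 10)
    city <- generate_city(cfg)
    net <- city$network
    ids <- net$nodes$id
    o <- ids[1]; d <- ids[length(ids)]
    env_cost <- function(r) {
      i <- match(r$edge_ids, net$edges$id)
      sum(net$edges$length[i] *
            cost_coefficient("noise_db", net$edges$noise_db[i]))
    }
    prev_env <- Inf; prev_len <- 0
    for (s in routing_config()$sensitivities) {
      r <- least_cost_path(net, o, d, "noise_db", s)
      e <- env_cost(r)
      expect_lte(e, prev_env + 1e-9)
      expect_gte(r$length, prev_len - 1e-9)
      prev_env <- e; prev_len <- r$length
    }
  }
})

test_that("batch routing logs unreachable pairs and respects the cap", {
  # network with an isolated island holding one station
  cfg <- city_config(grid_n = 4, n_stations = 3, seed = 2, total_trips = 50)
  city <- generate_city(cfg)
  net <- city$network
  far_nodes <- data.frame(id = c("z1", "z2"), x = c(9000, 9100), y = 0)
  far_edge <- straight_edge("zz", "z1", "z2", c(9000, 0), c(9100, 0),
                            aqi = 2, noise_db = 50, gvi = 0.4)
  net2 <- street_network(rbind(as.data.frame(net$nodes), far_nodes),
                         rbind(as.data.frame(net$edges[, c("id", "u", "v",
                                                           "aqi", "noise_db",
                                                           "gvi", "geometry")]),
                               far_edge))
  st <- rbind(city$stations[1:2, c("station_id", "x", "y")],
              data.frame(station_id = "sz", x = 9000, y = 0))
  expect_message(b <- batch_route(net2, st), "excluded")
  expect_equal(nrow(b$diagnostics$unreachable), 4)  # 2 stations x sz, both ways
  opt <- dplyr::filter(b$summary, route_type != "shortest")
  expect_true(all(opt$detour_fraction <= 0.15 * (1 + 1e-6) + 1e-12))
})
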