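test_that("a one-reach configuration yields a single order-1 outlet", {
  net <- generate_network(generator_config(n_reaches = 1, seed = 8))
  expect_equal(nrow(net$reaches), 1L)
  expect_true(is.na(net$reaches$downstream_id))
  expect_equal(net$reaches$order, 1L)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_reaches = 120, seed = 19)
  n1 <- generate_study(cfg)
  n2 <- generate_study(cfg)
  expect_identical(n1$reaches, n2$reaches)
  expect_identical(n1$ponds, n2$ponds)
  # and the source stage does not perturb the network realization
  cfg_u <- generator_config(n_reaches = 120, seed = 19,
                            source_mode = "uniform")
  n3 <- generate_study(cfg_u)
  expect_identical(n3$reaches[, c("reach_id", "downstream_id", "length_m",
                                  "q_m3d")],
                   n1$reaches[, c("reach_id", "downstream_id", "length_m",
                                  "q_m3d")])
})

test_that("outlet discharge closes the water balance", {
  cfg <- generator_config(n_reaches = 500, seed = 101)
  net <- generate_network(cfg)
  outlet <- which(is.na(net$reaches$downstream_id))
  expect_rel_equal(net$reaches$q_m3d[outlet],
                   cfg$runoff_coeff * sum(net$reaches$inc_area_m2) / 365.25,
                   tol = 1e-9)
})

test_that("generated invariants hold: tree topology, positive attributes", {
  net <- generate_study(generator_config(n_reaches = 300, seed = 33))
  r <- net$reaches
  expect_true(all(r$q_m3d > 0))
  expect_true(all(r$length_m > 0))
  expect_true(all(r$order >= 1))
  expect_equal(sum(is.na(r$downstream_id)), 1L)  # single rooted tree
  # every pond polygon is a simple closed ring with positive area
  for (w in net$ponds$polygon) {
    ring <- wkt_polygon(w)[[1]]
    expect_equal(ring[1, ], ring[nrow(ring), ])
    expect_gt(pondnet:::ring_area(ring), 0)
  }
})

test_that("centered circular ponds have circularity 1 and connectivity 0", {
  cfg <- generator_config(n_reaches = 100, seed = 12, pond_fraction = 0.2,
                          aspect_ratio_range = c(1, 1),
                          offset_fraction_range = c(0, 0),
                          segmentation_threshold = Inf)
  net <- generate_ponds(generate_network(cfg), cfg)
  p <- net$ponds
  circ <- circularity(p$poly_area_m2, p$perimeter_m)
  expect_true(all(abs(circ - 1) < 1e-3))
  conn <- pond_connectivity(net)
  expect_true(all(abs(conn$connectivity) < 1e-9))
})

test_that("elongated ponds match the analytic ellipse circularity", {
  cfg <- generator_config(n_reaches = 150, seed = 14, pond_fraction = 0.2,
                          aspect_ratio_range = c(10, 10),
                          segmentation_threshold = Inf)
  net <- generate_ponds(generate_network(cfg), cfg)
  p <- net$ponds
  # analytic: A = pi a b, P via Ramanujan with a/b = 10
  analytic <- vapply(p$area_m2, function(A) {
    b <- sqrt(A / (10 * pi)); a <- 10 * b
    4 * pi * A / ellipse_perimeter(a, b)^2
  }, numeric(1))
  circ <- circularity(p$poly_area_m2, p$perimeter_m)
  expect_true(all(abs(circ - analytic) < 1e-3))
  expect_true(all(circ < 0.5))  # far from circular
})

test_that("the achieved pond fraction sits within binomial bounds", {
  cfg <- generator_config(n_reaches = 1000, seed = 77, pond_fraction = 0.2,
                          segmentation_threshold = Inf)
  net <- generate_ponds(generate_network(cfg), cfg)
  k <- nrow(net$ponds)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.2)
  expect_gte(k, bounds[1]); expect_lte(k, bounds[2])
})

test_that("large ponds are segmented across consecutive reaches", {
  cfg <- generator_config(n_reaches = 200, seed = 41, pond_fraction = 0.15,
                          pond_area_lognormal = c(log(8e5), 0.3),
                          segmentation_threshold = 5e5)
  net <- generate_ponds(generate_network(cfg), cfg)
  segged <- table(net$ponds$pond_id)
  expect_gt(sum(segged == 2), 0)
  for (id in names(segged)[segged == 2]) {
    k <- which(net$ponds$pond_id == id)
    ridx <- net$ponds$reach_index[k]
    expect_true(net$downstream[ridx[1]] == ridx[2] ||
                  net$downstream[ridx[2]] == ridx[1])
  }
})

test_that("uniform sources have constant areal yield; variable are seeded", {
  cfg_u <- generator_config(n_reaches = 50, seed = 5, source_mode = "uniform")
  net <- generate_network(cfg_u)
  lu <- generate_sources(net, cfg_u)
  yield <- lu / net$reaches$inc_area_m2
  expect_true(all(abs(yield - yield[1]) < 1e-12))
  cfg_v <- generator_config(n_reaches = 50, seed = 5,
                            source_mode = "variable")
  expect_identical(generate_sources(net, cfg_v),
                   generate_sources(net, cfg_v))
})

test_that("invalid configurations name the offending keys", {
  expect_error(generator_config(n_reaches = 0), "n_reaches")
  expect_error(generator_config(pond_fraction = 2), "pond_fraction")
  expect_error(generator_config(slope_range = c(2, 1)), "slope_range")
})
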