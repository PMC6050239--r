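# Fixtures and brute-force oracles. Oracles deliberately avoid the package's
# topological-order machinery: they follow downstream pointers reach by
# reach, so agreement is a genuine cross-check.

# internal geometry primitives exercised directly in tests
ring_area <- pondnet:::ring_area
ring_perimeter <- pondnet:::ring_perimeter
ring_centroid <- pondnet:::ring_centroid

# minimal Y junction: two headwaters joining into one outlet reach
y_network <- function(inc_area = c(1, 1, 2), inc_load = c(100, 100, 50),
                      q = c(1000, 1000, 2000), vel = 2000) {
  river_network(data.frame(
    reach_id = c("A", "B", "C"),
    downstream_id = c("C", "C", NA),
    length_m = c(1000, 1200, 800), slope = 0.01,
    q_m3d = q, velocity_md = vel,
    inc_area_m2 = inc_area, inc_load_kgyr = inc_load,
    stringsAsFactors = FALSE))
}

# random tree reach table (no package generator involved)
random_tree_table <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(seq_len(n - 1), function(k) sample.int(k, 1), 1L) )
  id <- sprintf("N%03d", seq_len(n))
  data.frame(reach_id = id,
             downstream_id = c(NA, id[parent[-1]]),
             length_m = runif(n, 200, 3000),
             slope = runif(n, 1e-3, 0.03),
             q_m3d = runif(n, 500, 5e5),
             velocity_md = runif(n, 1000, 40000),
             inc_area_m2 = rlnorm(n, log(1e6), 0.7),
             inc_load_kgyr = rlnorm(n, log(300), 0.9),
             stringsAsFactors = FALSE)
}

# a circular pond segment row centered on reach i's local midpoint
circle_pond_row <- function(net, reach_id, area, offset_fraction = 0,
                            pond_id = paste0("P", reach_id),
                            segment_id = paste0("P", reach_id, "_S1")) {
  i <- match(reach_id, net$reaches$reach_id)
  L <- net$reaches$length_m[i]
  r <- sqrt(area / pi)
  ring <- ellipse_ring(c(L / 2, offset_fraction * L), r, r, n = 128L)
  data.frame(pond_id = pond_id, segment_id = segment_id, reach_id = reach_id,
             area_m2 = area, depth_m = NA_real_,
             polygon = wkt_from_ring(ring), stringsAsFactors = FALSE)
}

# brute-force upstream sets by walking every reach's downstream chain
oracle_upstream_sets <- function(reaches) {
  n <- nrow(reaches)
  ds <- match(reaches$downstream_id, reaches$reach_id)
  sets <- rep(list(integer(0)), n)
  for (j in seq_len(n)) {
    i <- j
    repeat {
      sets[[i]] <- c(sets[[i]], j)
      if (is.na(ds[i])) break
      i <- ds[i]
    }
  }
  names(sets) <- reaches$reach_id
  sets
}

# per-reach decay factors computed from first principles (depth power law,
# recorded velocity, width by continuity), bypassing stream_hydraulics()
oracle_factors <- function(net, params, scenario) {
  r <- net$reaches
  q_s <- r$q_m3d / 86400
  d <- 0.261 * q_s^0.3966
  tau <- r$length_m / r$velocity_md
  nu <- ifelse(q_s <= params$cutoff_m3s, params$nu_s_small, params$nu_s_large)
  full <- exp(-nu * tau / d)
  half <- exp(-nu * tau / d / 2)
  if (!is.null(net$ponds) && scenario == "with_ponds") {
    for (k in seq_len(nrow(net$ponds))) {
      i <- net$ponds$reach_index[k]
      f <- exp(-params$nu_p * net$ponds$area_m2[k] / r$q_m3d[i])
      full[i] <- f
      half[i] <- f   # complete mixing: incremental load sees full residence
    }
  }
  list(full = full, half = half)
}

# path-product routing oracle: each catchment's source is propagated
# independently down its chain and contributions are summed (decay is linear
# in load, so superposition is exact)
oracle_route <- function(net, params, scenario = "with_ponds") {
  r <- net$reaches
  n <- nrow(r)
  ds <- match(r$downstream_id, r$reach_id)
  f <- oracle_factors(net, params, scenario)
  out <- numeric(n)
  for (k in seq_len(n)) {
    contrib <- r$inc_load_kgyr[k] * f$half[k]
    i <- k
    repeat {
      out[i] <- out[i] + contrib
      if (is.na(ds[i])) break
      i <- ds[i]
      contrib <- contrib * f$full[i]
    }
  }
  names(out) <- r$reach_id
  out
}

# a network holding one pond on an interior reach plus an upstream source
# reach and a downstream outlet; the pond reach carries no incremental load,
# so pond and replacement see identical inflow
pond_pair_network <- function(pond_area, L = 1000, q_m3d = 50000,
                              vel = 5000, load = 1000) {
  reaches <- data.frame(
    reach_id = c("UP", "PD", "OUT"),
    downstream_id = c("PD", "OUT", NA),
    length_m = c(500, L, 500), slope = 0.01,
    q_m3d = q_m3d, velocity_md = vel,
    inc_area_m2 = 1e6, inc_load_kgyr = c(load, 0, 0),
    stringsAsFactors = FALSE)
  net <- river_network(reaches)
  river_network(reaches, circle_pond_row(net, "PD", pond_area))
}

# replacement wetted surface L*b of the pond-pair network's pond reach,
# computed from first principles
pair_replacement_surface <- function(L = 1000, q_m3d = 50000, vel = 5000) {
  d <- 0.261 * (q_m3d / 86400)^0.3966
  b <- q_m3d / (vel * d)
  L * b
}

expect_rel_equal <- function(object, expected, tol = 1e-9) {
  expect_true(all(abs(object - expected) <=
                    tol * pmax(abs(expected), .Machine$double.eps)),
              label = sprintf("max rel err %.3g",
                              max(abs(object - expected) /
                                    pmax(abs(expected), 1e-300))))
}
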