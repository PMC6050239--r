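test_that("Damkohler numbers multiply reciprocal hydraulic load by nu", {
  expect_equal(damkohler(0.5, 2), 1)
  expect_equal(damkohler(0.7, 0), 0)
  expect_error(damkohler(-1, 1), "negative")
})

test_that("the Damkohler ratio factorizes as HDI times nu_p/nu_s", {
  set.seed(404)
  for (k in 1:25) {
    area <- runif(1, 1e3, 1e6); s_rep <- runif(1, 1e2, 1e5)
    q <- runif(1, 1e3, 1e6)
    nu_p <- runif(1, 0.001, 0.1); nu_s <- runif(1, 0.01, 1)
    da_ratio <- damkohler(area / q, nu_p) / damkohler(s_rep / q, nu_s)
    expect_equal(da_ratio, hdi(area, s_rep) * nu_p / nu_s,
                 tolerance = 1e-12)
  }
})

test_that("HDI sums segment areas over replacement surfaces", {
  expect_equal(hdi(10, 10), 1)
  expect_equal(hdi(c(3, 1), c(1, 1)), 2)
  expect_error(hdi(1, 0), "zero replacement")
})

test_that("circularity matches analytic shapes", {
  r <- 3.2
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  a <- 5
  expect_equal(circularity(a^2, 4 * a), pi / 4)
  # 10:1 rectangle: A = 10, P = 22 per unit side -> 40 pi / 484
  expect_equal(circularity(10, 22), 40 * pi / 484)
  expect_equal(round(circularity(10, 22), 4), 0.2596)
  expect_error(circularity(1, 0), "perimeter")
})

test_that("circularity is invariant under similarity transforms and below
          one for non-circles", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  base <- circularity(ring_area(sq), ring_perimeter(sq))
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- 37 * sq %*% R + matrix(c(5, -9), nrow(sq), 2, byrow = TRUE)
  expect_equal(circularity(ring_area(moved), ring_perimeter(moved)), base,
               tolerance = 1e-12)
  expect_lt(base, 1)
})

test_that("pond connectivity is the scaled centroid-to-midpoint distance", {
  net <- pond_pair_network(pond_area = 1e4)   # centered on the reach
  expect_equal(pond_connectivity(net)$connectivity, 0, tolerance = 1e-9)

  # centroid displaced by a full reach length -> connectivity 1
  tab <- pond_pair_network(pond_area = 1e4)$reaches
  net1 <- river_network(tab[, !(names(tab) %in% "pond_segment_id")],
                        circle_pond_row(river_network(tab), "PD", 1e4,
                                        offset_fraction = 1))
  expect_equal(pond_connectivity(net1)$connectivity, 1, tolerance = 1e-9)
})

test_that("a segmented pond's connectivity is the mean over segments", {
  tab <- data.frame(reach_id = c("A", "B", "C"),
                    downstream_id = c("B", "C", NA),
                    length_m = 1000, slope = 0.01, q_m3d = 86400,
                    velocity_md = 5000, inc_area_m2 = 1e6,
                    inc_load_kgyr = 10)
  net0 <- river_network(tab)
  segs <- rbind(
    circle_pond_row(net0, "A", 1e4, offset_fraction = 0.2, pond_id = "PP",
                    segment_id = "PP_S1"),
    circle_pond_row(net0, "B", 1e4, offset_fraction = 0.4, pond_id = "PP",
                    segment_id = "PP_S2"))
  net <- river_network(tab, segs)
  expect_equal(pond_connectivity(net)$connectivity, 0.3, tolerance = 1e-9)
})

test_that("connectivity is invariant under rigid motions of the local frame", {
  # rotate+translate both the pond polygon and the reach polyline together
  L <- 1000
  ring <- ellipse_ring(c(L / 2, 120), 80, 40, n = 64L)
  line <- rbind(c(0, 0), c(L, 0))
  th <- 1.1; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(-300, 77)
  ring2 <- ring %*% R + matrix(shift, nrow(ring), 2, byrow = TRUE)
  line2 <- line %*% R + matrix(shift, 2, 2, byrow = TRUE)
  mk <- function(rg, ln) {
    tab <- data.frame(reach_id = "A", downstream_id = NA, length_m = L,
                      slope = 0.01, q_m3d = 86400, velocity_md = 5000,
                      inc_area_m2 = 1e6, inc_load_kgyr = 10,
                      geometry = paste0("LINESTRING (",
                                        paste(apply(ln, 1, paste,
                                                    collapse = " "),
                                              collapse = ", "), ")"))
    ponds <- data.frame(pond_id = "P", segment_id = "P_S1", reach_id = "A",
                        area_m2 = NA_real_, depth_m = NA_real_,
                        polygon = wkt_from_ring(rg))
    river_network(tab, ponds)
  }
  c1 <- pond_connectivity(mk(ring, line))$connectivity
  c2 <- pond_connectivity(mk(ring2, line2))$connectivity
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("pond density is cumulative pond area over drainage area", {
  net <- pond_pair_network(pond_area = 1e4)  # inc areas 1e6 each
  dens <- pond_density(net)
  expect_equal(unname(dens["UP"]), 0)
  expect_equal(unname(dens["PD"]), 1e4 / 2e6)
  expect_equal(unname(dens["OUT"]), 1e4 / 3e6)
})

test_that("densities above one are flagged for omission", {
  tab <- data.frame(reach_id = "A", downstream_id = NA, length_m = 500,
                    slope = 0.01, q_m3d = 86400, velocity_md = 5000,
                    inc_area_m2 = 1e3, inc_load_kgyr = 10)
  net0 <- river_network(tab)
  net <- river_network(tab, circle_pond_row(net0, "A", 5e3))
  expect_message(dens <- pond_density(net), "flagged")
  expect_equal(attr(dens, "omitted"), "A")
  rm_ <- suppressMessages(reach_metrics(net))
  expect_true(is.na(rm_$pond_density[1]))
})

test_that("cumulative HDI is one without upstream ponds and reflects added
          pond surface", {
  net <- pond_pair_network(pond_area = 2 * pair_replacement_surface())
  ch <- cumulative_hdi(net)
  expect_equal(unname(ch["UP"]), 1)
  # at the pond reach: (S_up + 2 S_rep) / (S_up + S_rep) with S in L*b
  h <- pondnet:::stream_hydraulics(net, hydraulic_params())
  s_up <- h$surface_m2[match("UP", net$reaches$reach_id)]
  s_rep <- pair_replacement_surface()
  expect_equal(unname(ch["PD"]), (s_up + 2 * s_rep) / (s_up + s_rep),
               tolerance = 1e-9)
})

test_that("cumulative metrics match brute-force upstream recomputation", {
  net <- generate_study(generator_config(n_reaches = 40, seed = 55,
                                         pond_fraction = 0.3))
  sets <- oracle_upstream_sets(net$reaches)
  h <- pondnet:::stream_hydraulics(net, hydraulic_params())
  rep_h <- replacement_reaches(net)
  existing <- h$surface_m2; replaced <- h$surface_m2
  existing[net$ponds$reach_index] <- net$ponds$area_m2
  replaced[net$ponds$reach_index] <- rep_h$surface_m2
  ch <- cumulative_hdi(net)
  brute_ch <- vapply(sets, function(s) sum(existing[s]) / sum(replaced[s]),
                     numeric(1))
  expect_rel_equal(as.numeric(ch), unname(brute_ch[names(ch)]), tol = 1e-9)

  dens <- pond_density(net)
  parea <- numeric(nrow(net$reaches))
  parea[net$ponds$reach_index] <- net$ponds$area_m2
  brute_d <- vapply(sets, function(s)
    sum(parea[s]) / sum(net$reaches$inc_area_m2[s]), numeric(1))
  expect_rel_equal(as.numeric(dens), unname(brute_d[names(dens)]),
                   tol = 1e-9)
})

test_that("cumulative connectivity averages each unique upstream pond once", {
  conn <- data.frame(pond_id = "X", connectivity = 0.3)
  tab <- data.frame(reach_id = c("A", "B"), downstream_id = c("B", NA),
                    length_m = 1000, slope = 0.01, q_m3d = 86400,
                    velocity_md = 5000, inc_area_m2 = 1e6, inc_load_kgyr = 1)
  net0 <- river_network(tab)
  net <- river_network(tab, circle_pond_row(net0, "A", 1e4, pond_id = "X",
                                            segment_id = "X_S1"))
  cc <- cumulative_connectivity(net)
  expect_equal(unname(cc["B"]), pond_connectivity(net)$connectivity)

  # random tree: mean over the brute-force upstream pond set
  net2 <- generate_study(generator_config(n_reaches = 60, seed = 91,
                                          pond_fraction = 0.25))
  cc2 <- cumulative_connectivity(net2)
  conn2 <- pond_connectivity(net2)
  sets <- oracle_upstream_sets(net2$reaches)
  term_reach <- vapply(conn2$pond_id, function(id) {
    k <- which(net2$ponds$pond_id == id)
    ridx <- net2$ponds$reach_index[k]
    inside <- seq_len(nrow(net2$reaches)) %in% ridx
    ridx[vapply(ridx, function(i) {
      j <- net2$downstream[i]; is.na(j) || !inside[j]
    }, logical(1))][1]
  }, integer(1))
  for (i in seq_len(nrow(net2$reaches))) {
    ups <- sets[[net2$reaches$reach_id[i]]]
    vals <- conn2$connectivity[term_reach %in% ups]
    if (length(vals)) expect_equal(unname(cc2[i]), mean(vals),
                                   tolerance = 1e-9)
    else expect_true(is.na(cc2[i]))
  }
})
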