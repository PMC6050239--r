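# Synthetic NHD-like study systems: random recursive tree networks with
# lognormal catchments and reach lengths, drainage-area-scaled discharge,
# elliptical ponds with controllable size, aspect ratio and centroid offset,
# and uniform or lognormal nitrogen sources. Everything is reproducible from
# (config, seed); each stage draws from its own seed derived from the master
# so adding ponds never perturbs the network realization.

#' Generator configuration
#'
#' Defaults emulate the statistical structure of medium-resolution NHDPlus
#' reach attributes at desk scale: catchments of a few km^2 (lognormal),
#' reach lengths around 1.5 km (lognormal), runoff of 0.5 m yr^-1 so that
#' discharge scales with drainage area, ponds on 15% of reaches (the share
#' of reaches covered by ponded waters in the study regions), elliptical
#' pond outlines with moderate elongation and centroid offsets, and larger
#' ponds split across two consecutive reaches.
#'
#' @param n_reaches number of reaches.
#' @param seed master seed; every stage derives its own stream from it.
#' @param area_lognormal c(meanlog, sdlog) of incremental catchment areas,
#'   log m^2.
#' @param runoff_coeff areal runoff, m yr^-1; discharge is
#'   runoff_coeff * DA / 365.25 in m^3 d^-1.
#' @param length_lognormal c(meanlog, sdlog) of reach lengths, log m.
#' @param slope_range uniform range of reach slopes.
#' @param pond_fraction share of reaches carrying a pond segment.
#' @param pond_area_lognormal c(meanlog, sdlog) of pond areas, log m^2.
#' @param aspect_ratio_range uniform range of ellipse major:minor ratios.
#' @param offset_fraction_range uniform range of centroid offsets as a
#'   fraction of reach length (perpendicular to the reach).
#' @param segmentation_threshold pond area (m^2) above which a pond is split
#'   across its reach and the downstream neighbour.
#' @param source_mode `"uniform"` (fixed areal yield) or `"variable"`
#'   (lognormal loads).
#' @param source_yield areal nitrogen yield for uniform sources,
#'   kg m^-2 yr^-1 (default 1e-3, i.e. 10 kg ha^-1 yr^-1).
#' @param source_lognormal c(meanlog, sdlog) of variable loads, log kg yr^-1.
#' @param topology `"recursive"` (each reach attaches to a uniformly chosen
#'   existing reach) or `"cascade"` (balanced binary tree) for controlled
#'   experiments.
#' @param hydraulics a [hydraulic_params()] whose velocity model generates
#'   mean annual velocities (default power law v = 2.5e4 Q^0.1 m d^-1 with Q
#'   in m^3 s^-1, i.e. ~0.3 m s^-1 at unit discharge).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_reaches = 200L, seed = 1L,
                             area_lognormal = c(log(2e6), 0.8),
                             runoff_coeff = 0.5,
                             length_lognormal = c(log(1500), 0.6),
                             slope_range = c(1e-4, 0.05),
                             pond_fraction = 0.15,
                             pond_area_lognormal = c(log(5e4), 1.0),
                             aspect_ratio_range = c(1, 6),
                             offset_fraction_range = c(0, 0.6),
                             segmentation_threshold = 5e5,
                             source_mode = c("variable", "uniform"),
                             source_yield = 1e-3,
                             source_lognormal = c(log(500), 1.0),
                             topology = c("recursive", "cascade"),
                             hydraulics = hydraulic_params(
                               velocity_model = list(name = "power_law",
                                                     k = 2.5e4, m = 0.1))) {
  source_mode <- match.arg(source_mode)
  topology <- match.arg(topology)
  bad <- character(0)
  if (n_reaches < 1L) bad <- c(bad, "n_reaches")
  if (pond_fraction < 0 || pond_fraction > 1) bad <- c(bad, "pond_fraction")
  if (runoff_coeff <= 0) bad <- c(bad, "runoff_coeff")
  for (nm in c("slope_range", "aspect_ratio_range", "offset_fraction_range")) {
    v <- get(nm)
    if (length(v) != 2L || v[1] > v[2]) bad <- c(bad, nm)
  }
  if (length(bad))
    stop("invalid generator config: ", paste(bad, collapse = ", "))
  structure(list(n_reaches = as.integer(n_reaches), seed = as.integer(seed),
                 area_lognormal = area_lognormal,
                 runoff_coeff = runoff_coeff,
                 length_lognormal = length_lognormal,
                 slope_range = slope_range, pond_fraction = pond_fraction,
                 pond_area_lognormal = pond_area_lognormal,
                 aspect_ratio_range = aspect_ratio_range,
                 offset_fraction_range = offset_fraction_range,
                 segmentation_threshold = segmentation_threshold,
                 source_mode = source_mode, source_yield = source_yield,
                 source_lognormal = source_lognormal, topology = topology,
                 hydraulics = hydraulics),
            class = "generator_config")
}

# independent substream per generator stage, derived from the master seed
stage_seed <- function(config, k) (config$seed %% 1000000000L) + k

with_stage_seed <- function(config, k, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(stage_seed(config, k))
  expr
}

#' Generate a synthetic stream network (no ponds)
#'
#' Random recursive tree rooted at the outlet: reach k (k > 1) drains to a
#' uniformly chosen earlier reach. Incremental areas are lognormal, drainage
#' area accumulates downstream, discharge is runoff_coeff * DA, Strahler
#' orders are computed from topology, velocity comes from the configured
#' velocity model, depth from the discharge power law, width from
#' continuity. Deterministic given the config seed.
#'
#' @param config a [generator_config()].
#' @return a `river_network` of streams only.
#' @export
generate_network <- function(config = generator_config()) {
  n <- config$n_reaches
  with_stage_seed(config, 1L, {
    parent <- if (n == 1L) NA_integer_ else switch(config$topology,
      recursive = c(NA_integer_,
                    vapply(2:n, function(k) sample.int(k - 1L, 1L),
                           integer(1))),
      cascade = c(NA_integer_, seq_len(n - 1L) %/% 2L + 1L)[seq_len(n)])
    inc_area <- stats::rlnorm(n, config$area_lognormal[1],
                              config$area_lognormal[2])
    len <- stats::rlnorm(n, config$length_lognormal[1],
                         config$length_lognormal[2])
    slope <- stats::runif(n, config$slope_range[1], config$slope_range[2])
    id <- sprintf("R%04d", seq_len(n))
    reaches <- data.frame(reach_id = id,
                          downstream_id = ifelse(is.na(parent), NA, id[parent]),
                          length_m = len, slope = slope,
                          q_m3d = NA_real_, inc_area_m2 = inc_area,
                          inc_load_kgyr = 0, stringsAsFactors = FALSE)
    # discharge needs accumulated drainage area; build once, fill, rebuild
    tmp <- river_network(transform(reaches, q_m3d = 1))
    da <- accumulate_upstream(tmp, "inc_area_m2")
    reaches$q_m3d <- config$runoff_coeff * as.numeric(da)[
      match(reaches$reach_id, names(da))] / 365.25
    q_s <- reaches$q_m3d / SECONDS_PER_DAY
    reaches$velocity_md <- stream_velocity(q_s, params = config$hydraulics)
    river_network(reaches)
  })
}

#' Add elliptical ponds to a generated network
#'
#' A `pond_fraction` share of reaches receives a pond: an ellipse with
#' lognormal area and uniform aspect ratio, major axis along the reach,
#' centroid at the reach midpoint displaced perpendicular to the reach by a
#' uniform fraction of the reach length. Perimeters follow from the polygon;
#' the vertex count is chosen so discretization error is small against
#' Ramanujan's ellipse-perimeter approximation. Ponds whose area exceeds
#' `segmentation_threshold` are split across the host reach and its
#' downstream neighbour (when free), with area shares proportional to the
#' semi-major-axis overlap with each reach.
#'
#' @param net a `river_network` from [generate_network()].
#' @param config a [generator_config()].
#' @return a `river_network` with ponds attached.
#' @export
generate_ponds <- function(net, config = generator_config()) {
  n <- nrow(net$reaches)
  if (n == 0L) stop("empty network")
  if (config$pond_fraction == 0) return(net)
  with_stage_seed(config, 2L, {
    take <- stats::runif(n) < config$pond_fraction
    host <- which(take)
    if (!length(host)) return(net)
    segs <- list()
    used <- logical(n)
    for (i in host) {
      if (used[i]) next
      A <- stats::rlnorm(1, config$pond_area_lognormal[1],
                         config$pond_area_lognormal[2])
      ar <- stats::runif(1, config$aspect_ratio_range[1],
                         config$aspect_ratio_range[2])
      off <- stats::runif(1, config$offset_fraction_range[1],
                          config$offset_fraction_range[2])
      L <- net$reaches$length_m[i]
      pid <- sprintf("P%s", net$reaches$reach_id[i])
      j <- net$downstream[i]
      split2 <- A > config$segmentation_threshold && !is.na(j) &&
        !used[j] && !(j %in% host)
      if (split2) {
        a <- sqrt(A * ar / pi)  # semi-major of the whole pond
        w1 <- min(net$reaches$length_m[i], a)
        w2 <- min(net$reaches$length_m[j], a)
        sh <- c(w1, w2) / (w1 + w2)
        for (s in 1:2) {
          ii <- c(i, j)[s]
          segs[[length(segs) + 1L]] <-
            pond_segment_row(net, ii, pid, sprintf("%s_S%d", pid, s),
                             A * sh[s], ar, off)
          used[ii] <- TRUE
        }
      } else {
        segs[[length(segs) + 1L]] <-
          pond_segment_row(net, i, pid, sprintf("%s_S1", pid), A, ar, off)
        used[i] <- TRUE
      }
    }
    ponds <- do.call(rbind, segs)
    river_network(net$reaches[, setdiff(names(net$reaches),
                                        "pond_segment_id")], ponds)
  })
}

# an elliptical segment polygon in the host reach's local frame:
# reach runs (0,0) -> (L,0); centroid at (L/2, off*L)
pond_segment_row <- function(net, i, pond_id, segment_id, area, aspect,
                             offset_fraction) {
  L <- net$reaches$length_m[i]
  b <- sqrt(area / (pi * aspect))
  a <- aspect * b
  ring <- ellipse_ring(c(L / 2, offset_fraction * L), a, b, theta = 0,
                       n = 96L)
  data.frame(pond_id = pond_id, segment_id = segment_id,
             reach_id = net$reaches$reach_id[i], area_m2 = area,
             depth_m = NA_real_, polygon = wkt_from_ring(ring),
             stringsAsFactors = FALSE)
}

#' Generate incremental nitrogen source loads
#'
#' Uniform mode applies a fixed areal yield (load proportional to
#' incremental catchment area); variable mode samples lognormal loads.
#' Deterministic given the config seed.
#'
#' @param net a `river_network`.
#' @param config a [generator_config()].
#' @return named numeric vector of loads (kg yr^-1) by `reach_id`.
#' @export
generate_sources <- function(net, config = generator_config()) {
  n <- nrow(net$reaches)
  loads <- switch(config$source_mode,
    uniform = config$source_yield * net$reaches$inc_area_m2,
    variable = with_stage_seed(config, 3L,
      stats::rlnorm(n, config$source_lognormal[1],
                    config$source_lognormal[2])))
  names(loads) <- net$reaches$reach_id
  loads
}

#' Generate a complete synthetic study system
#'
#' Network, ponds and sources in one call; the network realization is
#' unchanged by the pond and source stages.
#'
#' @param config a [generator_config()].
#' @return a `river_network` with ponds and `inc_load_kgyr` populated.
#' @export
generate_study <- function(config = generator_config()) {
  net <- generate_network(config)
  net <- generate_ponds(net, config)
  net$reaches$inc_load_kgyr <- as.numeric(generate_sources(net, config))
  net
}
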