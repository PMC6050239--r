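# Physical metrics of ponded waters and their cumulative network variants:
# Damkohler numbers, hydrologic dominance index (HDI), pond connectivity,
# circularity, pond density, cumulative HDI, cumulative connectivity.

#' Damkohler number
#'
#' Ratio of physical retention timescale to biological reaction timescale:
#' the reciprocal hydraulic load (time to displace a unit water column,
#' d m^-1) times the uptake velocity (m d^-1). For a pond this is
#' (A_p/Q_p) nu_p; for a stream (L b / Q_s) nu_s.
#'
#' @param recip_hydraulic_load d m^-1, >= 0.
#' @param nu uptake velocity, m d^-1, >= 0.
#' @return dimensionless Damkohler number.
#' @export
damkohler <- function(recip_hydraulic_load, nu) {
  if (any(recip_hydraulic_load < 0) || any(nu < 0)) stop("negative input")
  recip_hydraulic_load * nu
}

#' Hydrologic dominance index of a ponded water
#'
#' HDI = A_p / (L b): the pond's surface area over the wetted surface area
#' of its stream replacement. For segmented ponds both numerator and
#' denominator are summed over all segments. Since Q_p = Q_s, the Damkohler
#' ratio factorizes as Da_p/Da_s = HDI * (nu_p/nu_s); a pond dominates
#' removal when HDI exceeds nu_s/nu_p.
#'
#' @param pond_areas_m2 segment surface areas, m^2.
#' @param replacement_surfaces_m2 L*b of the intersecting replacement
#'   reaches, m^2.
#' @return dimensionless HDI.
#' @export
hdi <- function(pond_areas_m2, replacement_surfaces_m2) {
  denom <- sum(replacement_surfaces_m2)
  if (denom <= 0) stop("zero replacement surface area")
  sum(pond_areas_m2) / denom
}

#' Circularity of a polygon
#'
#' 4 pi A / P^2: one for a circle, approaching zero for elongated shapes.
#'
#' @param area_m2 polygon area, m^2.
#' @param perimeter_m polygon perimeter, m (> 0).
#' @return dimensionless circularity in (0, 1] (up to polygon
#'   discretization).
#' @export
circularity <- function(area_m2, perimeter_m) {
  if (any(perimeter_m <= 0)) stop("non-positive perimeter")
  4 * pi * area_m2 / perimeter_m^2
}

#' Pond connectivity (centeredness on the network)
#'
#' Per segment, the Euclidean distance from the segment polygon's planar
#' centroid to the midpoint (at half arc length) of the intersecting reach,
#' scaled by the reach length: L_centroid / L. A unique ponded water's value
#' is the mean over its segments. Small values mean the pond sits centered
#' on the flowline and is more likely well mixed by through-flow.
#'
#' @param net a `river_network` with ponds.
#' @return data.frame: `pond_id`, `connectivity`, plus per-segment values in
#'   attribute `"segments"`.
#' @export
pond_connectivity <- function(net) {
  if (is.null(net$ponds)) stop("network has no ponded waters")
  p <- net$ponds
  seg_c <- vapply(seq_len(nrow(p)), function(k) {
    i <- p$reach_index[k]
    line <- reach_polyline(net, i)
    mid <- polyline_midpoint(line)
    L <- net$reaches$length_m[i]
    if (L <= 0) stop("pond segment on zero-length reach")
    sqrt(sum((c(p$centroid_x[k], p$centroid_y[k]) - mid)^2)) / L
  }, numeric(1))
  agg <- tapply(seg_c, p$pond_id, mean)
  out <- data.frame(pond_id = names(agg), connectivity = as.numeric(agg),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "segments") <- data.frame(segment_id = p$segment_id,
                                      pond_id = p$pond_id,
                                      connectivity = seg_c,
                                      stringsAsFactors = FALSE)
  out
}

#' Per-pond metric table
#'
#' Computes, for every unique ponded water: total area, perimeter,
#' circularity, connectivity, HDI against its stream replacement, the two
#' reciprocal hydraulic loads, and the Damkohler numbers and their ratio
#' under the supplied uptake velocities.
#'
#' @param net a `river_network` with ponds.
#' @param params a [removal_params()] object.
#' @param hydraulics a [hydraulic_params()] object.
#' @return data.frame keyed by `pond_id` with columns `area_m2`,
#'   `perimeter_m`, `circularity`, `connectivity`, `hdi`, `da_p`, `da_s`,
#'   `da_ratio`, `da_m2` (cumulative drainage area at the pond's most
#'   downstream segment).
#' @export
pond_metrics <- function(net, params = removal_params(),
                         hydraulics = hydraulic_params()) {
  if (is.null(net$ponds)) stop("network has no ponded waters")
  p <- net$ponds
  rep_h <- replacement_reaches(net, hydraulics)
  conn <- pond_connectivity(net)
  da <- accumulate_upstream(net, "inc_area_m2")
  nu_s <- nu_stream(net$reaches$q_m3d, params)

  ids <- unique(p$pond_id)
  rows <- lapply(ids, function(id) {
    k <- which(p$pond_id == id)
    ridx <- p$reach_index[k]
    # most downstream segment = the one whose downstream reach is outside
    inside <- logical(nrow(net$reaches)); inside[ridx] <- TRUE
    term <- k[vapply(ridx, function(i) {
      j <- net$downstream[i]; is.na(j) || !inside[j]
    }, logical(1))][1]
    a_tot <- sum(p$area_m2[k])
    q_out <- net$reaches$q_m3d[p$reach_index[term]]
    rhl_p <- a_tot / q_out
    s_rep <- sum(rep_h$surface_m2[k])
    rhl_s <- s_rep / q_out
    # perimeter/circularity over the exterior of the whole pond: for
    # segmented ponds, use summed areas with summed exterior perimeters
    per <- sum(p$perimeter_m[k])
    data.frame(pond_id = id, area_m2 = a_tot, perimeter_m = per,
               circularity = circularity(a_tot, per),
               connectivity = conn$connectivity[match(id, conn$pond_id)],
               hdi = hdi(p$area_m2[k], rep_h$surface_m2[k]),
               da_p = damkohler(rhl_p, params$nu_p),
               da_s = damkohler(rhl_s, nu_s[p$reach_index[term]]),
               da_m2 = as.numeric(da[p$reach_index[term]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$da_ratio <- out$da_p / out$da_s
  rownames(out) <- NULL
  out
}

#' Pond density along the network
#'
#' Cumulative upstream ponded-water surface area over cumulative upstream
#' drainage area at every reach. Values above one indicate inconsistent
#' catchment areas; they are flagged and should be omitted from threshold
#' analyses.
#'
#' @param net a `river_network`.
#' @return named numeric vector of densities with attribute `"omitted"`
#'   listing reach ids where density > 1.
#' @export
pond_density <- function(net) {
  da <- accumulate_upstream(net, "inc_area_m2")
  if (any(da <= 0)) stop("zero cumulative drainage area")
  parea <- numeric(nrow(net$reaches))
  if (!is.null(net$ponds))
    parea[net$ponds$reach_index] <- net$ponds$area_m2
  cum_parea <- accumulate_upstream(net, parea)
  dens <- as.numeric(cum_parea) / as.numeric(da)
  names(dens) <- net$reaches$reach_id
  omitted <- names(dens)[dens > 1]
  if (length(omitted))
    message(length(omitted), " reach(es) with pond density > 1 flagged")
  attr(dens, "omitted") <- omitted
  dens
}

#' Cumulative hydrologic dominance index
#'
#' Ratio of accumulated wetted surface area in the existing network (pond
#' segment areas on pond reaches, L*b on stream reaches) to the accumulated
#' wetted surface area with all ponds replaced by streams (L*b everywhere,
#' replacement widths on pond reaches). Surface areas, being extensive, are
#' accumulated independently before dividing. Equals one wherever no ponded
#' water lies upstream; values above one mark pond-dominated hydrology.
#'
#' @param net a `river_network`.
#' @param hydraulics a [hydraulic_params()] object.
#' @return named numeric vector over reaches.
#' @export
cumulative_hdi <- function(net, hydraulics = hydraulic_params()) {
  h <- stream_hydraulics(net, hydraulics)
  existing <- h$surface_m2
  replaced <- h$surface_m2
  if (!is.null(net$ponds)) {
    rep_h <- replacement_reaches(net, hydraulics)
    existing[net$ponds$reach_index] <- net$ponds$area_m2
    replaced[net$ponds$reach_index] <- rep_h$surface_m2
  }
  num <- accumulate_upstream(net, existing)
  den <- accumulate_upstream(net, replaced)
  if (any(den <= 0)) stop("zero replaced surface area")
  out <- as.numeric(num) / as.numeric(den)
  names(out) <- net$reaches$reach_id
  out
}

#' Cumulative pond connectivity
#'
#' Arithmetic mean of pond connectivity over the N_i unique ponded waters
#' upstream of each reach; NA where no pond lies upstream. Each pond counts
#' once regardless of segmentation and is located at its most downstream
#' segment's reach.
#'
#' @param net a `river_network`.
#' @param connectivities optional data.frame from [pond_connectivity()];
#'   computed when missing.
#' @return named numeric vector over reaches (NA when N_i = 0), with the
#'   pond count in attribute `"n_upstream"`.
#' @export
cumulative_connectivity <- function(net, connectivities = NULL) {
  n <- nrow(net$reaches)
  csum <- numeric(n); cnt <- numeric(n)
  if (!is.null(net$ponds)) {
    if (is.null(connectivities)) connectivities <- pond_connectivity(net)
    p <- net$ponds
    for (id in unique(p$pond_id)) {
      k <- which(p$pond_id == id)
      ridx <- p$reach_index[k]
      inside <- logical(n); inside[ridx] <- TRUE
      term <- ridx[vapply(ridx, function(i) {
        j <- net$downstream[i]; is.na(j) || !inside[j]
      }, logical(1))][1]
      csum[term] <- csum[term] +
        connectivities$connectivity[match(id, connectivities$pond_id)]
      cnt[term] <- cnt[term] + 1
    }
  }
  s <- accumulate_upstream(net, csum)
  m <- accumulate_upstream(net, cnt)
  out <- ifelse(m > 0, as.numeric(s) / as.numeric(m), NA_real_)
  names(out) <- net$reaches$reach_id
  attr(out, "n_upstream") <- as.numeric(m)
  out
}

#' Per-reach metric table
#'
#' @param net a `river_network`.
#' @param hydraulics a [hydraulic_params()] object.
#' @return data.frame: `reach_id`, `order`, `pond_density` (NA where flagged
#'   > 1), `cumulative_hdi`, `cumulative_connectivity`.
#' @export
reach_metrics <- function(net, hydraulics = hydraulic_params()) {
  dens <- pond_density(net)
  omitted <- attr(dens, "omitted")
  dens_out <- as.numeric(dens)
  dens_out[match(omitted, names(dens))] <- NA_real_
  data.frame(reach_id = net$reaches$reach_id, order = net$reaches$order,
             pond_density = dens_out,
             cumulative_hdi = as.numeric(cumulative_hdi(net, hydraulics)),
             cumulative_connectivity =
               as.numeric(cumulative_connectivity(net)),
             stringsAsFactors = FALSE)
}
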