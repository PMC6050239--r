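# First-order routing of annual total-nitrogen loads through the network,
# for the existing (with-ponds) network and for the counterfactual in which
# every ponded water is replaced by a stream.

#' Uptake-velocity parameter set
#'
#' First-order benthic uptake velocities, split between small streams and
#' large rivers at a mean-annual-discharge cutoff, plus the ponded-water
#' uptake velocity. All in m d^-1.
#'
#' @param nu_s_small uptake velocity of streams with Q <= cutoff.
#' @param nu_s_large uptake velocity of rivers with Q > cutoff.
#' @param nu_p uptake velocity of ponded waters.
#' @param cutoff_m3s discharge cutoff between the two stream classes
#'   (m^3 s^-1; default 2.83).
#' @param region label carried through outputs.
#' @return object of class `removal_params`.
#' @export
removal_params <- function(nu_s_small = 0.2, nu_s_large = 0.05, nu_p = 0.02,
                           cutoff_m3s = 2.83, region = "synthetic") {
  stopifnot(nu_s_small >= 0, nu_s_large >= 0, nu_p >= 0, cutoff_m3s > 0)
  structure(list(nu_s_small = nu_s_small, nu_s_large = nu_s_large,
                 nu_p = nu_p, cutoff_m3s = cutoff_m3s, region = region),
            class = "removal_params")
}

nu_stream <- function(q_m3d, params) {
  ifelse(q_m3d / SECONDS_PER_DAY <= params$cutoff_m3s,
         params$nu_s_small, params$nu_s_large)
}

#' Load transfer through a stream reach
#'
#' Upstream load decays over the full travel time,
#' exp(-nu_s tau / d); load generated in the reach's own catchment enters at
#' the reach midpoint and decays over half the travel time.
#'
#' @param load_up load entering the upstream end, kg y^-1.
#' @param load_inc load generated within the catchment, kg y^-1.
#' @param nu_s stream uptake velocity, m d^-1.
#' @param tau_d travel time, d.
#' @param depth_m mean depth, m (> 0 whenever decay is active).
#' @return load exiting the reach, kg y^-1.
#' @export
stream_transfer <- function(load_up, load_inc, nu_s, tau_d, depth_m) {
  if (any(load_up < 0) || any(load_inc < 0)) stop("negative load")
  ex <- nu_s * tau_d / depth_m
  if (any(!is.finite(ex) & (nu_s * tau_d) > 0)) stop("zero depth with decay")
  ex[!is.finite(ex)] <- 0
  load_up * exp(-ex) + load_inc * exp(-ex / 2)
}

#' Load transfer through a ponded-water segment
#'
#' The segment is completely mixed: inflowing and locally generated loads
#' both decay by exp(-nu_p A_p / Q_p), with A_p/Q_p the reciprocal hydraulic
#' load (d m^-1).
#'
#' @param load_up load entering from upstream, kg y^-1.
#' @param load_inc load generated within the catchment, kg y^-1.
#' @param nu_p pond uptake velocity, m d^-1.
#' @param area_m2 segment surface area, m^2.
#' @param q_m3d segment discharge, m^3 d^-1 (> 0).
#' @return load exiting the segment, kg y^-1.
#' @export
pond_transfer <- function(load_up, load_inc, nu_p, area_m2, q_m3d) {
  if (any(load_up < 0) || any(load_inc < 0)) stop("negative load")
  if (any(q_m3d <= 0)) stop("non-positive pond discharge")
  (load_up + load_inc) * exp(-nu_p * area_m2 / q_m3d)
}

#' Route nitrogen loads through the network
#'
#' Propagates incremental source loads downstream in topological order with
#' first-order decay. Under `"with_ponds"`, reaches covered by a pond segment
#' use the completely mixed pond transfer; under `"ponds_replaced"` those
#' reaches use the hydraulics of their stream replacement with the ordinary
#' stream transfer. All other reaches route identically in both scenarios.
#'
#' @param net a `river_network` with `inc_load_kgyr` set.
#' @param params a [removal_params()] object.
#' @param scenario `"with_ponds"` or `"ponds_replaced"`.
#' @param hydraulics a [hydraulic_params()] object.
#' @return object of class `removal_result`: data.frame with per-reach
#'   `load_up` (inflow from upstream), `load_in` (inflow plus incremental),
#'   `load_out`, `load_nodecay` (cumulative source with no decay),
#'   `load_accum_out` (= `load_out`; routing is cumulative) and `r_accum`,
#'   the cumulative proportion removed 1 - load_accum_out / load_nodecay.
#' @export
route_network <- function(net, params = removal_params(),
                          scenario = c("with_ponds", "ponds_replaced"),
                          hydraulics = hydraulic_params()) {
  scenario <- match.arg(scenario)
  r <- net$reaches
  if (is.null(r$inc_load_kgyr) || anyNA(r$inc_load_kgyr))
    stop("every reach needs inc_load_kgyr")
  n <- nrow(r)
  hyd <- stream_hydraulics(net, hydraulics)
  nu_s <- nu_stream(r$q_m3d, params)
  seg_at <- rep(NA_integer_, n)
  if (!is.null(net$ponds)) seg_at[net$ponds$reach_index] <- seq_len(nrow(net$ponds))
  if (scenario == "ponds_replaced" && !is.null(net$ponds)) {
    rep_h <- replacement_reaches(net, hydraulics)
    hyd$tau_d[net$ponds$reach_index] <- rep_h$tau_d
    hyd$depth_m[net$ponds$reach_index] <- rep_h$depth_m
  }

  load_up <- numeric(n)
  comp <- numeric(n)
  load_out <- numeric(n)
  inc <- r$inc_load_kgyr
  ds <- net$downstream
  is_pond <- scenario == "with_ponds" & !is.na(seg_at)
  for (i in net$topo_order) {
    load_out[i] <-
      if (is_pond[i]) {
        s <- seg_at[i]
        pond_transfer(load_up[i], inc[i], params$nu_p,
                      net$ponds$area_m2[s], r$q_m3d[i])
      } else {
        stream_transfer(load_up[i], inc[i], nu_s[i], hyd$tau_d[i],
                        hyd$depth_m[i])
      }
    j <- ds[i]
    if (!is.na(j)) {  # compensated junction sum
      y <- load_out[i] - comp[j]
      t <- load_up[j] + y
      comp[j] <- (t - load_up[j]) - y
      load_up[j] <- t
    }
  }
  nodecay <- accumulate_upstream(net, inc)
  r_accum <- ifelse(nodecay > 0, 1 - load_out / nodecay, 0)
  structure(data.frame(reach_id = r$reach_id, scenario = scenario,
                       load_up = load_up, load_in = load_up + inc,
                       load_out = load_out,
                       load_nodecay = as.numeric(nodecay),
                       load_accum_out = load_out, r_accum = r_accum,
                       stringsAsFactors = FALSE),
            class = c("removal_result", "data.frame"),
            scenario = scenario, params = params, hydraulics = hydraulics)
}

# load entering a pond (or its replacement set) from outside it, the load
# generated inside it, and the load exiting its terminal segments, given a
# routed result. A multi-reach pond's segments sit on consecutive reaches;
# terminal segments are those whose downstream reach is outside the pond.
pond_io <- function(result, net, pond_id) {
  segs <- which(net$ponds$pond_id == pond_id)
  if (!length(segs)) stop("unknown pond_id: ", pond_id)
  ridx <- net$ponds$reach_index[segs]
  inside <- logical(nrow(net$reaches)); inside[ridx] <- TRUE
  out_terminal <- 0; external_in <- 0
  for (i in ridx) {
    j <- net$downstream[i]
    if (is.na(j) || !inside[j])
      out_terminal <- out_terminal + result$load_out[i]
    # inflow from parents outside the pond
    par <- which(net$downstream == i)
    ext <- par[!inside[par]]
    if (length(ext)) external_in <- external_in + sum(result$load_out[ext])
  }
  entering <- external_in + sum(net$reaches$inc_load_kgyr[ridx])
  list(entering = entering, exiting = out_terminal)
}

#' Proportion of load removed by each ponded water and by its replacement
#'
#' For a single-segment pond the proportions are the closed forms
#' 1 - exp(-Da_p) and 1 - exp(-Da_s): the pond is completely mixed and the
#' per-reach efficiency ratio is the full-travel-time exponential, so the
#' local efficiencies are independent of how loads are distributed across
#' the landscape. A segmented pond gets a single whole-pond value under the
#' routed scenario: one minus total load exiting its terminal segments over
#' total load entering it (external inflow plus internally generated); the
#' same aggregation over the replacement reaches gives R_s. That aggregate
#' depends weakly on the mix of external inflows entering different
#' segments.
#'
#' @param result_p routed `removal_result` for `"with_ponds"`.
#' @param result_s routed `removal_result` for `"ponds_replaced"`.
#' @param net the `river_network` both were routed on.
#' @return data.frame: `pond_id`, `r_p`, `r_s`, `delta_r` (= r_p - r_s;
#'   positive means the ponded water dominates removal), `n_segments`.
#'   Segmented ponds with zero entering load get NA proportions and a
#'   warning.
#' @export
pond_proportions <- function(result_p, result_s, net) {
  if (is.null(net$ponds)) stop("network has no ponded waters")
  params <- attr(result_p, "params")
  hydraulics <- attr(result_p, "hydraulics")
  rep_h <- replacement_reaches(net, hydraulics)
  nu_s <- nu_stream(net$reaches$q_m3d, params)
  ids <- unique(net$ponds$pond_id)
  nseg <- table(net$ponds$pond_id)
  prop <- function(result, id) {
    io <- pond_io(result, net, id)
    if (io$entering <= 0) return(NA_real_)
    1 - io$exiting / io$entering
  }
  r_p <- vapply(ids, function(id) {
    k <- which(net$ponds$pond_id == id)
    if (length(k) == 1L) {
      i <- net$ponds$reach_index[k]
      1 - exp(-params$nu_p * net$ponds$area_m2[k] / net$reaches$q_m3d[i])
    } else prop(result_p, id)
  }, numeric(1))
  r_s <- vapply(ids, function(id) {
    k <- which(net$ponds$pond_id == id)
    if (length(k) == 1L) {
      i <- net$ponds$reach_index[k]
      m <- match(net$ponds$segment_id[k], rep_h$segment_id)
      1 - exp(-nu_s[i] * rep_h$tau_d[m] / rep_h$depth_m[m])
    } else prop(result_s, id)
  }, numeric(1))
  if (anyNA(r_p) || anyNA(r_s))
    warning("pond(s) with zero entering load: proportion undefined")
  data.frame(pond_id = ids, r_p = r_p, r_s = r_s, delta_r = r_p - r_s,
             n_segments = as.integer(table(net$ponds$pond_id)[ids]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare the with-ponds and ponds-replaced scenarios
#'
#' Per pond, the difference in proportion removed Delta R = R_p - R_s; per
#' reach, the difference in cumulative proportion removed
#' Delta R_accum = R_accum,p - R_accum,s. Positive values mean nitrogen
#' removal is dominated by ponded waters.
#'
#' @param result_p,result_s routed results for the two scenarios.
#' @param net the shared `river_network`.
#' @return object of class `pond_comparison`: list with `ponds` (per-pond
#'   proportions) and `reaches` (per-reach `r_accum_p`, `r_accum_s`,
#'   `delta_r_accum`).
#' @export
compare_scenarios <- function(result_p, result_s, net) {
  if (!identical(result_p$reach_id, result_s$reach_id) ||
      !identical(result_p$reach_id, net$reaches$reach_id))
    stop("results and network do not align")
  if (!identical(result_p$load_nodecay, result_s$load_nodecay))
    stop("results routed with different sources")
  reaches <- data.frame(reach_id = net$reaches$reach_id,
                        r_accum_p = result_p$r_accum,
                        r_accum_s = result_s$r_accum,
                        delta_r_accum = result_p$r_accum - result_s$r_accum,
                        stringsAsFactors = FALSE)
  ponds <- if (is.null(net$ponds)) NULL else
    pond_proportions(result_p, result_s, net)
  structure(list(ponds = ponds, reaches = reaches),
            class = "pond_comparison")
}

#' @export
print.pond_comparison <- function(x, ...) {
  cat("Scenario comparison (with ponds vs ponds replaced by streams)\n")
  if (!is.null(x$ponds)) {
    ok <- x$ponds$delta_r[!is.na(x$ponds$delta_r)]
    cat(sprintf("  %d ponded waters; %.1f%% pond-dominant (delta R > 0)\n",
                nrow(x$ponds), 100 * mean(ok > 0)))
    cat(sprintf("  median delta R = %.4f\n", stats::median(ok)))
  } else cat("  no ponded waters\n")
  cat(sprintf("  delta R_accum range: [%.4f, %.4f]\n",
              min(x$reaches$delta_r_accum), max(x$reaches$delta_r_accum)))
  invisible(x)
}
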