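# Hydraulic geometry of streams and of the stream that replaces each ponded
# water. Discharge is carried in m^3 d^-1 (NHD/SPARROW convention) and
# converted to m^3 s^-1 only inside the depth power law, whose coefficient
# is defined for that unit.

SECONDS_PER_DAY <- 86400

#' Hydraulic parameter set
#'
#' @param depth_coeff,depth_exp coefficients of the depth power law
#'   d = depth_coeff * Q^depth_exp with Q in m^3 s^-1; the defaults come from
#'   a hydraulic-geometry regression over 112 US river sites.
#' @param sinuosity channel sinuosity applied to travel times (>= 1). The
#'   default 1 reflects artificial lake flowlines, which trace the most
#'   direct path; setting 2 reproduces the meander sensitivity case.
#' @param velocity_model list with `name` one of `"from_input"` (use the
#'   recorded mean annual velocity; default), `"constant"` (`v0`, m d^-1), or
#'   `"power_law"` (v = k * Q^m, with Q in m^3 s^-1, `k` in m d^-1). The
#'   velocity estimator is pluggable because published travel-time methods
#'   (e.g. Jobson's regressions) are regional fits; users with such a fit can
#'   express it here.
#' @return object of class `hydraulic_params`.
#' @export
hydraulic_params <- function(depth_coeff = 0.261, depth_exp = 0.3966,
                             sinuosity = 1,
                             velocity_model = list(name = "from_input")) {
  stopifnot(depth_coeff > 0, sinuosity >= 1)
  if (is.character(velocity_model))
    velocity_model <- list(name = velocity_model)
  if (!velocity_model$name %in% c("from_input", "constant", "power_law"))
    stop("unknown velocity_model: ", velocity_model$name)
  structure(list(depth_coeff = depth_coeff, depth_exp = depth_exp,
                 sinuosity = sinuosity, velocity_model = velocity_model),
            class = "hydraulic_params")
}

#' Stream depth from the discharge power law
#'
#' d = 0.261 Q^0.3966 (defaults), Q in m^3 s^-1, d in metres.
#'
#' @param q_m3s discharge, m^3 s^-1 (vectorized).
#' @param params a [hydraulic_params()] object.
#' @return depth, m.
#' @export
stream_depth <- function(q_m3s, params = hydraulic_params()) {
  if (any(q_m3s < 0)) stop("negative discharge")
  params$depth_coeff * q_m3s^params$depth_exp
}

#' Stream velocity from the configured estimator
#'
#' @param q_m3s discharge, m^3 s^-1.
#' @param da_m2,length_m,slope drainage area, reach length and slope; present
#'   so regional travel-time regressions using them can be plugged in.
#' @param params a [hydraulic_params()] object.
#' @param velocity_md recorded mean annual velocity (m d^-1), required by the
#'   `"from_input"` model.
#' @return velocity, m d^-1.
#' @export
stream_velocity <- function(q_m3s, da_m2 = NULL, length_m = NULL, slope = NULL,
                            params = hydraulic_params(), velocity_md = NULL) {
  vm <- params$velocity_model
  switch(vm$name,
    from_input = {
      if (is.null(velocity_md) || anyNA(velocity_md))
        stop("velocity_model 'from_input' needs recorded velocity_md")
      velocity_md
    },
    constant = {
      if (is.null(vm$v0)) stop("constant velocity model needs v0")
      rep_len(vm$v0, length(q_m3s))
    },
    power_law = {
      if (is.null(vm$k) || is.null(vm$m))
        stop("power_law velocity model needs k and m")
      vm$k * q_m3s^vm$m
    },
    stop("unknown velocity_model: ", vm$name))
}

#' Travel time through a reach
#'
#' tau = sinuosity * L / v, in days.
#'
#' @param length_m reach length, m.
#' @param velocity_md velocity, m d^-1 (> 0).
#' @param sinuosity channel sinuosity (>= 1).
#' @return travel time, d.
#' @export
travel_time <- function(length_m, velocity_md, sinuosity = 1) {
  if (any(velocity_md <= 0)) stop("non-positive velocity")
  if (any(sinuosity < 1)) stop("sinuosity below 1")
  sinuosity * length_m / velocity_md
}

# hydraulics (depth, velocity, width, travel time, wetted surface) for every
# reach treated as a stream; width closes continuity b = Q/(v d), so
# tau/d = sinuosity * L b / Q exactly.
stream_hydraulics <- function(net, params = hydraulic_params()) {
  r <- net$reaches
  q_s <- r$q_m3d / SECONDS_PER_DAY
  d <- stream_depth(q_s, params)
  v <- stream_velocity(q_s, da_m2 = r$da_m2, length_m = r$length_m,
                       slope = r$slope, params = params,
                       velocity_md = r$velocity_md)
  b <- r$q_m3d / (v * d)
  tau <- travel_time(r$length_m, v, params$sinuosity)
  data.frame(reach_id = r$reach_id, q_m3d = r$q_m3d, depth_m = d,
             velocity_md = v, width_m = b, tau_d = tau,
             surface_m2 = r$length_m * b, stringsAsFactors = FALSE)
}

#' Replace every ponded-water segment by an equivalent stream reach
#'
#' Builds, for each pond segment, the stream reach that would occupy its
#' intersecting flowline: discharge equals the pond segment's (Q_p = Q_s over
#' the annual average), depth from the power law, velocity from the
#' configured estimator, width from continuity b = Q/(v d), and travel time
#' tau = sinuosity * L / v. The replacement inherits the host reach's length
#' and slope, taken as representative of the most direct path.
#'
#' @param net a `river_network` with ponds.
#' @param params a [hydraulic_params()] object.
#' @return data.frame, one row per pond segment: `segment_id`, `pond_id`,
#'   `reach_id`, `q_m3d`, `depth_m`, `velocity_md`, `width_m`, `tau_d`,
#'   `surface_m2` (L * b).
#' @export
replacement_reaches <- function(net, params = hydraulic_params()) {
  if (is.null(net$ponds)) stop("network has no ponded waters")
  p <- net$ponds
  r <- net$reaches[p$reach_index, , drop = FALSE]
  if (any(is.na(r$slope))) stop("replacement requires reach slope")
  h <- stream_hydraulics(net, params)[p$reach_index, , drop = FALSE]
  # continuity closure check: v * d * b must return Q
  stopifnot(all(abs(h$velocity_md * h$depth_m * h$width_m - h$q_m3d) <=
                  1e-9 * h$q_m3d))
  data.frame(segment_id = p$segment_id, pond_id = p$pond_id,
             reach_id = p$reach_id, q_m3d = h$q_m3d, depth_m = h$depth_m,
             velocity_md = h$velocity_md, width_m = h$width_m,
             tau_d = h$tau_d, surface_m2 = h$surface_m2,
             stringsAsFactors = FALSE)
}
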