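# Threshold detection: pond-density thresholds per stream order via LOWESS
# with residual envelopes, the analytic HDI threshold, and the
# pond-connectivity breakpoint via one-breakpoint segmented regression.

#' Threshold-detection configuration
#'
#' @param trim_fraction central share of predictor values retained before
#'   smoothing (default 0.98: the lowest and highest 1% are discarded to
#'   damp extreme values).
#' @param lowess_span smoother span f for [stats::lowess()].
#' @param lowess_iter robustifying iterations.
#' @param breakpoint_percentile upper predictor percentile retained for the
#'   connectivity breakpoint fit (default 0.99).
#' @param ci_level confidence level for breakpoint intervals.
#' @param grid_size number of log-spaced evaluation points for the density
#'   threshold rule.
#' @param min_points minimum observations required per stream order.
#' @return object of class `threshold_config`.
#' @export
threshold_config <- function(trim_fraction = 0.98, lowess_span = 0.5,
                             lowess_iter = 2, breakpoint_percentile = 0.99,
                             ci_level = 0.95, grid_size = 200L,
                             min_points = 20L) {
  stopifnot(trim_fraction > 0, trim_fraction <= 1,
            lowess_span > 0, lowess_span <= 1,
            ci_level > 0, ci_level < 1, grid_size >= 10L)
  structure(list(trim_fraction = trim_fraction, lowess_span = lowess_span,
                 lowess_iter = lowess_iter,
                 breakpoint_percentile = breakpoint_percentile,
                 ci_level = ci_level, grid_size = as.integer(grid_size),
                 min_points = as.integer(min_points)),
            class = "threshold_config")
}

new_threshold_estimate <- function(kind, value = NA_real_, found = FALSE,
                                   ci = c(NA_real_, NA_real_), order = NA,
                                   n = NA_integer_, extra = list()) {
  structure(c(list(kind = kind, value = value, found = found,
                   ci = ci, stream_order = order, n = n), extra),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("%s threshold%s: ", x$kind,
              if (!is.na(x$stream_order))
                paste0(" (order ", x$stream_order, ")") else ""))
  if (isTRUE(x$found)) {
    cat(format(x$value, digits = 4))
    if (!anyNA(x$ci))
      cat(sprintf("  [%s, %s] CI", format(x$ci[1], digits = 4),
                  format(x$ci[2], digits = 4)))
    cat(sprintf("  (n = %d)\n", x$n))
  } else cat(sprintf("not found (n = %s)\n", x$n))
  invisible(x)
}

# interpolate lowess output onto a grid, constant beyond the data range
lowess_on_grid <- function(lw, grid) {
  stats::approx(lw$x, lw$y, xout = grid, rule = 2, ties = mean)$y
}

# LOWESS fit of y on x plus residual envelopes: the same smoother applied to
# the positive residuals (added to the fit: upper limit) and to the negative
# residuals (added: lower limit). Smooths are clamped to their sign so the
# envelope ordering lower <= fit <= upper always holds on the grid.
lowess_envelope <- function(x, y, grid, span, iter) {
  lw <- stats::lowess(x, y, f = span, iter = iter)
  fit_at_x <- stats::approx(lw$x, lw$y, xout = x, rule = 2, ties = mean)$y
  res <- y - fit_at_x
  fit_g <- lowess_on_grid(lw, grid)
  env <- function(keep, clampf) {
    if (sum(keep) < 3L) return(rep(0, length(grid)))
    lwr <- stats::lowess(x[keep], res[keep], f = span, iter = iter)
    clampf(lowess_on_grid(lwr, grid))
  }
  upper <- fit_g + env(res > 0, function(v) pmax(v, 0))
  lower <- fit_g + env(res < 0, function(v) pmin(v, 0))
  list(grid = grid, fit = fit_g, lower = lower, upper = upper)
}

#' Pond-density threshold per stream order
#'
#' For each stream order: the predictor is trimmed to its central
#' `trim_fraction`, a LOWESS of the response (difference in cumulative
#' proportion removed) on pond density is fitted, residual envelopes are
#' formed by smoothing positive and negative residuals, and the threshold is
#' the smallest density on a log-spaced grid from which the lower envelope
#' stays above zero at every larger density.
#'
#' @param x pond densities (dimensionless).
#' @param y differences in cumulative proportion removed (Delta R_accum).
#' @param order Strahler stream order per observation; a single combined
#'   estimate is returned when NULL.
#' @param config a [threshold_config()] object.
#' @return list of `threshold_estimate` objects, one per order (names are
#'   the orders). Orders with fewer than `min_points` observations are
#'   flagged `found = FALSE` with `n` recorded, not an error.
#' @export
density_threshold <- function(x, y, order = NULL, config = threshold_config()) {
  stopifnot(length(x) == length(y))
  if (is.null(order)) order <- rep(1L, length(x))
  stopifnot(length(order) == length(x))
  keep <- is.finite(x) & is.finite(y) & !is.na(order)
  x <- x[keep]; y <- y[keep]; order <- order[keep]
  out <- lapply(sort(unique(order)), function(o) {
    xi <- x[order == o]; yi <- y[order == o]
    if (length(xi) < config$min_points)
      return(new_threshold_estimate("density", order = o, n = length(xi),
                                    extra = list(reason = "insufficient data")))
    tail_p <- (1 - config$trim_fraction) / 2
    qs <- stats::quantile(xi, c(tail_p, 1 - tail_p), names = FALSE)
    inb <- xi >= qs[1] & xi <= qs[2]
    xi <- xi[inb]; yi <- yi[inb]
    lo <- max(min(xi), 1e-12)
    grid <- exp(seq(log(lo), log(max(xi)), length.out = config$grid_size))
    ev <- lowess_envelope(xi, yi, grid, config$lowess_span, config$lowess_iter)
    above <- rev(cumprod(rev(ev$lower > 0))) > 0  # TRUE from d* to the end
    if (!any(above))
      return(new_threshold_estimate("density", order = o, n = length(xi),
                                    extra = list(envelope = ev)))
    new_threshold_estimate("density", value = grid[which(above)[1]],
                           found = TRUE, order = o, n = length(xi),
                           extra = list(envelope = ev))
  })
  names(out) <- sort(unique(order))
  out
}

#' Analytic HDI threshold
#'
#' A ponded water removes the same proportion as its stream replacement when
#' their Damkohler numbers are equal, i.e. at HDI = nu_s / nu_p; above it the
#' pond dominates.
#'
#' @param nu_s stream uptake velocity, m d^-1.
#' @param nu_p pond uptake velocity, m d^-1 (> 0).
#' @return dimensionless threshold HDI.
#' @export
hdi_threshold <- function(nu_s, nu_p) {
  if (any(nu_p <= 0)) stop("nu_p must be positive")
  nu_s / nu_p
}

# Davies-type significance bound for a slope change at an unknown breakpoint:
# max over a candidate grid of the |t| statistic of the hinge term, with the
# upper bound p <= Phi(-M) + V exp(-M^2/2)/sqrt(8 pi), V = total variation of
# the t process over the grid (two-sided via doubling, capped at 1).
davies_pvalue <- function(x, y, k = 10L) {
  qs <- stats::quantile(x, seq(0.1, 0.9, length.out = k), names = FALSE)
  qs <- unique(qs)
  tt <- vapply(qs, function(psi) {
    X <- cbind(1, x, pmax(x - psi, 0))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- length(y) - ncol(X)
    XtX_inv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / df * XtX_inv[3, 3])
    fit$coefficients[3] / se
  }, numeric(1))
  M <- max(abs(tt))
  V <- sum(abs(diff(tt)))
  p <- stats::pnorm(-M) + V * exp(-M^2 / 2) / sqrt(8 * pi)
  min(1, 2 * p)
}

# one-breakpoint segmented fit by Muggeo's iteration with grid-search
# fallback; returns psi, its SE (delta method at convergence), slopes, rss
segmented_fit <- function(x, y, psi0 = NULL, max_iter = 50L, tol = 1e-8) {
  rng <- range(x)
  clamp <- function(p) min(max(p, rng[1] + 1e-9 * diff(rng)),
                           rng[2] - 1e-9 * diff(rng))
  psi <- if (is.null(psi0)) stats::median(x) else clamp(psi0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- pmax(x - psi, 0)
    V <- -(x > psi)
    X <- cbind(1, x, U, V)
    fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) break
    beta_u <- fit$coefficients[3]; gamma <- fit$coefficients[4]
    if (abs(beta_u) < 1e-12) break
    step <- gamma / beta_u
    psi_new <- clamp(psi + step)
    if (abs(psi_new - psi) < tol * diff(rng)) { psi <- psi_new; converged <- TRUE; break }
    psi <- psi_new
  }
  if (!converged) {
    # grid search over candidate breaks minimizing RSS, then local refine
    cand <- stats::quantile(x, seq(0.02, 0.98, length.out = 100),
                            names = FALSE)
    rss_at <- function(p) {
      X <- cbind(1, x, pmax(x - p, 0))
      sum(stats::lm.fit(X, y)$residuals^2)
    }
    rss <- vapply(cand, rss_at, numeric(1))
    best <- which.min(rss)
    lob <- cand[max(1, best - 1)]; hib <- cand[min(length(cand), best + 1)]
    psi <- if (hib > lob)
      stats::optimize(rss_at, c(lob, hib))$minimum else cand[best]
  }
  # final fit at psi for SEs
  U <- pmax(x - psi, 0); V <- -(x > psi)
  X <- cbind(1, x, U, V)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - ncol(X)
  XtX_inv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  se_psi <- NA_real_
  if (!is.null(XtX_inv) && df > 0) {
    s2 <- rss / df
    se_gamma <- sqrt(s2 * XtX_inv[4, 4])
    beta_u <- fit$coefficients[3]
    if (abs(beta_u) > 1e-12) se_psi <- se_gamma / abs(beta_u)
  }
  list(psi = psi, se_psi = se_psi, coefficients = fit$coefficients,
       rss = rss, converged = converged)
}

#' Pond-connectivity breakpoint
#'
#' Restricts to connectivities at or below the configured upper percentile,
#' fits a continuous two-segment piecewise-linear regression of the
#' difference in proportion removed on connectivity with one free breakpoint
#' (iterative breakpoint update, grid-search fallback), and tests the slope
#' change with a Davies-type bound. The breakpoint and a normal-theory
#' confidence interval from its standard error are returned; `found = FALSE`
#' when the slope change is not significant at the configured level.
#'
#' @param c_values pond connectivities.
#' @param delta_r per-pond differences in proportion removed (R_p - R_s).
#' @param config a [threshold_config()] object.
#' @return a `threshold_estimate` with `value` (breakpoint), `ci`, `found`,
#'   and the fitted segment slopes in `$slopes`.
#' @export
connectivity_threshold <- function(c_values, delta_r,
                                   config = threshold_config()) {
  keep <- is.finite(c_values) & is.finite(delta_r)
  x <- c_values[keep]; y <- delta_r[keep]
  if (length(x) < 30L)
    return(new_threshold_estimate("connectivity", n = length(x),
                                  extra = list(reason = "insufficient data")))
  cut <- stats::quantile(x, config$breakpoint_percentile, names = FALSE)
  inb <- x <= cut
  x <- x[inb]; y <- y[inb]
  fit <- segmented_fit(x, y)
  pval <- davies_pvalue(x, y)
  alpha <- 1 - config$ci_level
  z <- stats::qnorm(1 - alpha / 2)
  ci <- if (is.na(fit$se_psi)) c(NA_real_, NA_real_) else
    fit$psi + c(-1, 1) * z * fit$se_psi
  new_threshold_estimate("connectivity", value = fit$psi,
                         found = pval < alpha, ci = ci, n = length(x),
                         extra = list(p_value = pval,
                                      slopes = c(below = unname(fit$coefficients[2]),
                                                 above = unname(fit$coefficients[2] +
                                                                  fit$coefficients[3])),
                                      converged = fit$converged))
}
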