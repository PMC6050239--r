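# Log-linear model of pond-versus-stream dominance and its variance
# partition: ln(R_p) - ln(R_s) on ln(connectivity), ln(circularity),
# ln(drainage area), with sequential (Type I) sums of squares.

#' Fit the log-linear dominance model
#'
#' Ordinary least squares of the log-ratio of proportions removed,
#' ln(R_p) - ln(R_s), on the logs of pond connectivity, circularity and
#' cumulative upstream drainage area. Records with a non-positive value in
#' the response or any predictor are dropped and counted (no pseudo-count
#' offsets).
#'
#' @param r_p,r_s proportions removed by each pond and its replacement.
#' @param connectivity,circ,da aligned predictor vectors (pond
#'   connectivity, circularity, drainage area m^2).
#' @return object of class `dominance_model` wrapping the `lm` fit, with
#'   `n_obs` and `dropped` counts.
#' @export
fit_dominance_model <- function(r_p, r_s, connectivity, circ, da) {
  n_in <- length(r_p)
  stopifnot(length(r_s) == n_in, length(connectivity) == n_in,
            length(circ) == n_in, length(da) == n_in)
  ok <- is.finite(r_p) & is.finite(r_s) & is.finite(connectivity) &
    is.finite(circ) & is.finite(da) &
    r_p > 0 & r_s > 0 & connectivity > 0 & circ > 0 & da > 0
  d <- data.frame(y = log(r_p[ok]) - log(r_s[ok]),
                  ln_c = log(connectivity[ok]), ln_s = log(circ[ok]),
                  ln_da = log(da[ok]))
  for (v in c("ln_c", "ln_s", "ln_da"))
    if (stats::var(d[[v]]) < .Machine$double.eps * 100)
      stop("singular design: predictor '", v, "' has zero variance")
  fit <- stats::lm(y ~ ln_c + ln_s + ln_da, data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design: collinear term(s) ", paste(bad, collapse = ", "))
  }
  structure(list(fit = fit, n_obs = sum(ok), dropped = n_in - sum(ok),
                 data = d),
            class = "dominance_model")
}

#' @export
coef.dominance_model <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.dominance_model <- function(object, ...) stats::residuals(object$fit)

#' @export
print.dominance_model <- function(x, ...) {
  b <- stats::coef(x$fit)
  cat("Dominance model  ln(R_p) - ln(R_s) ~ ln(c) + ln(s) + ln(DA)\n")
  cat(sprintf("  n = %d (%d dropped), R^2 = %.3f\n", x$n_obs, x$dropped,
              summary(x$fit)$r.squared))
  cat("  coefficients:\n")
  print(round(b, 4))
  invisible(x)
}

#' @export
summary.dominance_model <- function(object, ...) summary(object$fit, ...)

#' Partition explained variance among the dominance-model terms
#'
#' Sequential (Type I) sums of squares in the given entry order, converted
#' to percent of total response variance. Drainage area enters first by
#' default because it carries most of the explained variance (it is strongly
#' negatively rank-correlated with the HDI); the order is a parameter so
#' sensitivity can be examined.
#'
#' @param model a `dominance_model`.
#' @param order character vector over `"da"`, `"connectivity"`,
#'   `"circularity"` giving the entry order.
#' @return object of class `variance_partition`: data.frame with `term`,
#'   `percent_variance`, `order_index`, plus attribute `total_r2` (percent).
#' @export
partition_variance <- function(model,
                               order = c("da", "connectivity", "circularity")) {
  map <- c(da = "ln_da", connectivity = "ln_c", circularity = "ln_s")
  if (!all(order %in% names(map)) || anyDuplicated(order) ||
      length(order) != 3L)
    stop("order must be a permutation of: ", paste(names(map), collapse = ", "))
  terms <- map[order]
  f <- stats::reformulate(terms, response = "y")
  fit <- stats::lm(f, data = model$data)
  av <- stats::anova(fit)
  ss <- av[["Sum Sq"]]
  tot <- sum(ss)
  pct <- 100 * ss[seq_along(terms)] / tot
  r2 <- 100 * summary(fit)$r.squared
  out <- data.frame(term = order, percent_variance = pct,
                    order_index = seq_along(order),
                    stringsAsFactors = FALSE)
  structure(out, class = c("variance_partition", "data.frame"),
            total_r2 = r2)
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partition (sequential SS):\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-13s %6.2f%%\n", x$term[i], x$percent_variance[i]))
  cat(sprintf("  total R^2     %6.2f%%\n", attr(x, "total_r2")))
  invisible(x)
}

#' Spearman rank correlation between drainage area and HDI
#'
#' Convenience statistic: Pearson correlation of midrank-transformed values.
#'
#' @param da,hdi aligned numeric vectors.
#' @return the rank correlation coefficient.
#' @export
spearman_da_hdi <- function(da, hdi) {
  ok <- is.finite(da) & is.finite(hdi)
  stats::cor(rank(da[ok]), rank(hdi[ok]))
}
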