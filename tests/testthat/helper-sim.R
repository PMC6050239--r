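# simulated dominance-model data with a known log-ratio structure
sim_dominance_data <- function(n, beta = c(0.5, -0.2, 0.3, -0.4), sd = 0,
                               seed = 1) {
  set.seed(seed)
  cc <- runif(n, 0.05, 0.8)
  ss <- runif(n, 0.1, 1)
  da <- rlnorm(n, log(1e7), 1)
  eta <- beta[1] + beta[2] * log(cc) + beta[3] * log(ss) +
    beta[4] * log(da) + rnorm(n, 0, sd)
  # invert the log-ratio into two positive proportions
  r_s <- runif(n, 0.05, 0.3)
  r_p <- pmin(r_s * exp(eta), 0.999)
  list(r_p = r_p, r_s = r_s, cc = cc, ss = ss, da = da,
       y = log(r_p) - log(r_s))
}
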