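# shared fixtures and fast MCMC settings for the unit tests

fast_mcmc <- function(seed, iterations = 4000, thin = 2) {
  mcmcConfig(chains = 3, iterations = iterations, burnin_frac = 0.5,
             thin = thin, adapt = 500, seed = seed)
}

# reference truth used across the density-inference tests
truth_params <- function(rho = 1036) hydroParams(rho, 12e-6, 3.73e-5)

# independent brute-force OLS via the normal equations (oracle for the
# regression slope/SE used in glide segmentation)
ols_oracle <- function(t, y) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  list(slope = beta[2], se = se)
}

# summary row helper
param_row <- function(fit, pattern) {
  fit$summaries[grepl(pattern, fit$summaries$parameter), , drop = FALSE]
}
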