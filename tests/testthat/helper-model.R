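# Shared fixtures, all built in code.

# Hardwired population with the standard parameter set (sigmoid slope 1.9,
# threshold 0.99, peaks 0.485, sigma 6 deg); eye tuning width overridable.
std_grid <- function(rho = 20) build_population(eye_width = rho)

# Default 92-unit input layer, eye tuning width overridable.
std_layer <- function(rho = 15) input_layer(eye_width = rho)

# A short schedule for fast tests.
tiny_schedule <- function(seed = 1, epochs = 1, locations = c(-10, 0, 10),
                          nfix = 3) {
  make_schedule(seed, epochs = epochs, retinal_locations = locations,
                fixations_per_period = nfix)
}

# Independent straight-line fit via the normal equations, used as an oracle
# for linearity_r2 (kept free of stats::lm on purpose).
normal_equations_r2 <- function(x, v) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% v)
  fitted <- X %*% beta
  sse <- sum((v - fitted)^2)
  sst <- sum((v - mean(v))^2)
  list(r_squared = 1 - sse / sst, intercept = beta[1], slope = beta[2])
}
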