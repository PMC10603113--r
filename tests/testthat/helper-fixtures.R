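# shared fixtures: random admissible parameter draws under a caller's seed

rand_calibration <- function() {
  slope <- runif(1, -0.05, 0.05)
  while (abs(slope) <= 1e-6) slope <- runif(1, -0.05, 0.05)
  linear_calibration(slope, runif(1, -1, 4),
                     convention = sample(c("percent", "fraction"), 1))
}

rand_fourpl <- function() {
  fourpl(A = runif(1, 0, 0.5), B = runif(1, 1, 2),
         C = runif(1, 10, 60), D = runif(1, 1, 5))
}

# closed-form OLS on (x, y): independent oracle for the lm-based fit
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# default truth with rate-block amplitudes jittered towards the stable side
# (the printed equations blow up in finite time for stronger growth or Fe2+
# production, so random admissible sets are drawn from weaker growth and
# production and stronger consumption)
jitter_truth <- function(frac = 0.15) {
  syms <- lan_to_symbols(default_truth())
  down <- c("E_S", "E_R", "J_S")
  syms[down] <- syms[down] * runif(length(down), 1 - frac, 1)
  syms["J_R"] <- syms["J_R"] * runif(1, 1, 1 + frac)
  lan_from_symbols(syms)
}
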