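# Independent oracles used across tests; none of these call package code.

## closed-form simple linear regression (sum formulas)
ols_line <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

## mean of a normal left-truncated at t
truncnorm_mean <- function(mu, sigma, t) {
  a <- (t - mu) / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}

## standard three-component event panel (micelle / complex / micelle)
micelle_complex_panel <- data.frame(
  mu = c(106, 274, 461), sigma = 0.08 * c(106, 274, 461),
  count = c(4000, 3000, 2000))
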