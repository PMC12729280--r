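# Independent oracles used by the suite. These deliberately avoid the code
# paths they check.

# Classic fixed-step RK4 for dX/dt = f(X), vectorised over a bank of
# parameter sets: X is a vector, f returns a vector. Returns the states at
# the requested output times (which must be multiples of dt).
rk4_integrate <- function(f, x0, t_out, dt) {
  t_end <- max(t_out)
  n_steps <- round(t_end / dt)
  stopifnot(all(abs(t_out / dt - round(t_out / dt)) < 1e-9))
  out <- matrix(NA_real_, nrow = length(t_out), ncol = length(x0))
  x <- x0
  hit <- match(0, round(t_out / dt))
  if (!is.na(hit)) out[hit, ] <- x
  for (i in seq_len(n_steps)) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    hit <- match(i, round(t_out / dt))
    if (!is.na(hit)) out[hit, ] <- x
  }
  out
}

# Brute-force re-implementation of the change-point scan: closed-form OLS
# on the window, explicit loop over post-window samples.
brute_force_transition <- function(time_h, biomass, window_end_h = 92,
                                   k_sd = 2) {
  inw <- time_h <= window_end_h
  tw <- time_h[inw]; xw <- biomass[inw]
  b <- sum((tw - mean(tw)) * (xw - mean(xw))) / sum((tw - mean(tw))^2)
  a <- mean(xw) - b * mean(tw)
  dev <- abs(biomass - (a + b * time_h))
  thr <- max(mean(dev[inw]) + k_sd * sd(dev[inw]), 1e-8 * max(abs(biomass), 1))
  for (i in which(!inw)) if (dev[i] > thr) return(time_h[i])
  NA_real_
}

# numerical derivative of a curve on a fine grid
max_slope_numeric <- function(fun, t_max = 700, n = 20001) {
  tt <- seq(0, t_max, length.out = n)
  x <- fun(tt)
  max(diff(x) / diff(tt))
}

make_series <- function(t, x, ...) growth_series(time_h = t, biomass_gL = x, ...)
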