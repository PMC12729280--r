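test_that("logistic closed form: intercept, asymptote, inflection", {
  expect_equal(logistic_growth(0, X0 = 0.33, K = 4.5, mu = 0.03), 0.33)
  expect_equal(logistic_growth(1e6, X0 = 0.33, K = 4.5, mu = 0.03), 4.5,
               tolerance = 1e-9)
  # half-capacity at t* = ln((K - X0)/X0)/mu, cross-checked by root finding
  X0 <- 0.4; K <- 5; mu <- 0.02
  t_star <- log((K - X0) / X0) / mu
  expect_equal(logistic_growth(t_star, X0, K, mu), K / 2)
  t_root <- uniroot(function(t) logistic_growth(t, X0, K, mu) - K / 2,
                    c(0, 1000), tol = 1e-12)$root
  expect_equal(t_star, t_root, tolerance = 1e-8)
  expect_error(logistic_growth(1, X0 = -1, K = 4, mu = 0.1), "positive")
  expect_error(logistic_growth(1, X0 = 0.3, K = 0, mu = 0.1), "positive")
})

test_that("logistic rate has fixed points at 0 and K and peaks at K/2", {
  expect_equal(logistic_rate(0, K = 4, mu = 0.1), 0)
  expect_equal(logistic_rate(4, K = 4, mu = 0.1), 0)
  expect_equal(logistic_rate(2, K = 4, mu = 0.1), 0.1 * 4 / 4)
  grid <- seq(0, 4, length.out = 4001)
  expect_equal(grid[which.max(logistic_rate(grid, 4, 0.1))], 2,
               tolerance = 1e-3)
})

test_that("logistic with lag holds X0 through the lag and reduces cleanly", {
  p <- list(X0 = 0.33, K = 4.5, mu = 0.03, t_lag = 50)
  expect_equal(logistic_lag_growth(c(0, 10, 49.9), p$X0, p$K, p$mu, p$t_lag),
               rep(p$X0, 3))
  expect_equal(logistic_lag_growth(p$t_lag, p$X0, p$K, p$mu, p$t_lag), p$X0)
  tt <- seq(0, 700, by = 7)
  expect_equal(logistic_lag_growth(tt, p$X0, p$K, p$mu, 0),
               logistic_growth(tt, p$X0, p$K, p$mu))
})

test_that("Gompertz: asymptote, value at t = lambda, max slope = mumax", {
  expect_equal(gompertz_growth(1e6, Xmax = 4, mumax = 0.01, lam = 40), 4,
               tolerance = 1e-9)
  # at t = lambda the double exponent collapses to exp(-e)
  expect_equal(gompertz_growth(40, Xmax = 4, mumax = 0.01, lam = 40),
               4 * exp(-exp(1)))
  # Zwietering convention: mumax is the maximum slope in g/L/h
  sl <- max_slope_numeric(function(t) gompertz_growth(t, 4.5, 0.012, 40))
  expect_equal(sl, 0.012, tolerance = 1e-4)
  expect_error(gompertz_growth(1, Xmax = 0, mumax = 0.01, lam = 0), "positive")
})

test_that("Baranyi-Roberts: start, asymptote, lambda = 0 closed form", {
  p <- list(X0 = 0.33, mumax = 0.02, lam = 30, C = 2.6)
  expect_equal(baranyi_growth(0, p$X0, p$mumax, p$lam, p$C), p$X0)
  expect_equal(baranyi_growth(1e6, p$X0, p$mumax, p$lam, p$C),
               p$X0 * exp(p$C), tolerance = 1e-6)
  # lambda = 0: y = mumax*t - log(1 + (e^(mumax t) - 1)/e^C), evaluated
  # directly at moderate t where naive arithmetic is exact
  tt <- seq(0, 300, by = 25)
  direct <- p$X0 * exp(p$mumax * tt -
                         log(1 + (exp(p$mumax * tt) - 1) / exp(p$C)))
  expect_equal(baranyi_growth(tt, p$X0, p$mumax, 0, p$C), direct,
               tolerance = 1e-9)
  # mumax -> 0 limit is the constant X0
  expect_equal(baranyi_growth(c(0, 100, 700), p$X0, 0, p$lam, p$C),
               rep(p$X0, 3))
  expect_error(baranyi_growth(1, 0.33, 0.02, 30, -1), "non-negative")
})

test_that("hybrid two-phase: intercept, continuity, asymptote, degeneracy", {
  p <- list(X0 = 0.33, a = 0.01, t_s = 300, K = 4.4, r = 0.02)
  expect_equal(hybrid_growth(0, p$X0, p$a, p$t_s, p$K, p$r), p$X0)
  expect_equal(hybrid_growth(1e6, p$X0, p$a, p$t_s, p$K, p$r), p$K,
               tolerance = 1e-9)
  Xs <- p$X0 + p$a * p$t_s
  expect_equal(hybrid_growth(p$t_s, p$X0, p$a, p$t_s, p$K, p$r), Xs,
               tolerance = 1e-14)
  expect_equal(hybrid_growth(p$t_s - 1e-9, p$X0, p$a, p$t_s, p$K, p$r), Xs,
               tolerance = 1e-8)
  # linear phase reaching K makes the logistic branch undefined
  expect_error(hybrid_growth(1, X0 = 1, a = 0.01, t_s = 500, K = 2, r = 0.1),
               "degenerate stitch")
})

test_that("Monod x Gauss: half-saturation, symmetry, monotone in aeration", {
  p <- list(mumax = 0.0136, KB = 0.5, Topt = 26, sigma = 3.3)
  expect_equal(monod_gauss(26, 0.5, p$mumax, p$KB, p$Topt, p$sigma), 0.0068)
  expect_equal(monod_gauss(26, 1e12, p$mumax, p$KB, p$Topt, p$sigma),
               p$mumax, tolerance = 1e-9)
  d <- seq(0.5, 10, by = 0.5)
  expect_equal(monod_gauss(26 + d, 1, p$mumax, p$KB, p$Topt, p$sigma),
               monod_gauss(26 - d, 1, p$mumax, p$KB, p$Topt, p$sigma))
  B <- seq(0, 5, by = 0.05)
  expect_true(all(diff(monod_gauss(26, B, p$mumax, p$KB, p$Topt, p$sigma)) > 0))
  expect_error(monod_gauss(26, -1, p$mumax, p$KB, p$Topt, p$sigma))
  expect_error(monod_gauss(26, 1, p$mumax, p$KB, p$Topt, 0), "positive")
  expect_error(monod_gauss(26, 1, p$mumax, 0, p$Topt, p$sigma), "positive")
})

test_that("all six forward models stay finite and non-negative to 700 h", {
  tt <- seq(0, 700, by = 3.5)
  curves <- list(
    logistic_growth(tt, 0.33, 4.5, 1),
    logistic_lag_growth(tt, 0.33, 4.5, 1, 100),
    gompertz_growth(tt, 4.5, 1, 100),
    baranyi_growth(tt, 0.33, 1, 100, 2.6),  # mumax*t = 700 stresses A(t)
    hybrid_growth(tt, 0.33, 0.01, 300, 4.4, 1),
    monod_gauss(seq(15, 40, length.out = length(tt)), tt / 100,
                0.0136, 0.5, 26, 3.3))
  for (x in curves) {
    expect_true(all(is.finite(x)))
    expect_true(all(x >= 0))
  }
})

test_that("sigmoid models are monotone non-decreasing for valid parameters", {
  tt <- seq(0, 700, by = 3.5)
  set.seed(21)
  for (i in 1:25) {
    X0 <- runif(1, 0.1, 1); K <- runif(1, 2, 6); mu <- runif(1, 0.002, 0.2)
    lam <- runif(1, 0, 150)
    expect_true(all(diff(logistic_growth(tt, X0, K, mu)) >= 0))
    expect_true(all(diff(gompertz_growth(tt, K, runif(1, 1e-3, 0.1), lam)) >= 0))
    a <- runif(1, 0, 0.01); t_s <- runif(1, 50, 400)
    if (X0 + a * t_s < K)
      expect_true(all(diff(hybrid_growth(tt, X0, a, t_s, K,
                                         runif(1, 0, 0.1))) >= -1e-12))
  }
})
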