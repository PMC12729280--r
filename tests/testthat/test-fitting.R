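test_that("goodness_of_fit matches hand arithmetic and flags degenerate R2", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$r2, 1); expect_equal(g$rmse, 0)
  obs <- c(1, 2, 3, 7)
  g0 <- goodness_of_fit(obs, rep(mean(obs), 4))
  expect_equal(g0$r2, 0)
  # SSres = 1, SStot = 2
  g1 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g1$r2, 0.5)
  expect_equal(g1$rmse, sqrt(1 / 3))
  gz <- goodness_of_fit(c(2, 2, 2), c(2, 2.1, 2))
  expect_false(gz$r2_defined)
  expect_true(is.na(gz$r2))
  expect_error(goodness_of_fit(1:3, 1:4), "equal length")
})

test_that("fit_model recovers noise-free logistic parameters essentially exactly", {
  tt <- seq(0, 700, length.out = 30)
  truth <- c(X0 = 0.33, K = 4.5, mu = 0.03)
  s <- make_series(tt, logistic_growth(tt, 0.33, 4.5, 0.03))
  fit <- fit_model(s, "logistic")
  expect_true(fit$converged)
  expect_equal(unname(abs(fit$params - truth) / truth), rep(0, 3),
               tolerance = 1e-4)
  expect_equal(fit$r2, 1, tolerance = 1e-8)
  expect_lt(fit$rmse, 1e-8)
  expect_length(fit$residuals, fit$n_obs)
})

test_that("fit_model rejects degenerate and insufficient data", {
  s <- make_series(seq(0, 90, by = 10), rep(1, 10))
  expect_error(fit_model(s, "logistic"), "degenerate")
  s2 <- make_series(c(0, 50, 100), c(0.3, 0.5, 0.8))
  expect_error(fit_model(s2, "logistic"), "insufficient")
  expect_error(fit_model(s2, "unknown_model"), "unknown model")
  expect_error(fit_model(s2, "monod_gauss"), "fit_surface")
})

test_that("fit_model recovers the hybrid stitch time on noise-free data", {
  sched <- default_schedule(700)
  s <- generate_two_phase_curve(0.33, 0.01, 300, 4.4, 0.02,
                                schedule = sched, noise_cv = 0, seed = 1)
  fit <- fit_model(s, "hybrid_two_phase")
  interval <- max(diff(sched))
  expect_lt(abs(fit$params[["t_s"]] - 300), interval)
  expect_lt(fit$rmse, 1e-6)
})

test_that("fitting is invariant to row order (sorted internally)", {
  tt <- seq(0, 700, length.out = 25)
  s <- make_series(tt, logistic_growth(tt, 0.4, 4, 0.025))
  fit1 <- fit_model(s, "logistic", seed = 3)
  s_shuf <- s
  perm <- sample(seq_len(nrow(s)))
  s_shuf[seq_len(nrow(s)), ] <- s[perm, ]
  fit2 <- fit_model(s_shuf, "logistic", seed = 3)
  expect_equal(fit1$params, fit2$params)
  expect_equal(fit1$r2, fit2$r2)
})

test_that("user-supplied inits and bounds are honoured and reported", {
  tt <- seq(0, 700, length.out = 25)
  s <- make_series(tt, logistic_growth(tt, 0.4, 4, 0.025))
  fit <- fit_model(s, "logistic", init = c(mu = 0.05),
                   bounds = list(upper = c(K = 5)))
  expect_equal(fit$init_used[["mu"]], 0.05)
  expect_equal(fit$bounds_used$upper[["K"]], 5)
  expect_equal(fit$params[["K"]], 4, tolerance = 1e-4)
})

test_that("compare_models ranks the generating model first at zero noise", {
  tt <- seq(0, 700, length.out = 30)
  s <- make_series(tt, logistic_growth(tt, 0.33, 4.5, 0.03),
                   reactor_id = "R1")
  cmp <- compare_models(list(s), c("logistic", "gompertz"))
  expect_s3_class(cmp, "model_comparison")
  r2 <- cmp$r2[match(c("logistic", "gompertz"), cmp$model)]
  expect_gte(r2[1], r2[2])
  expect_equal(cmp$rank[cmp$model == "logistic"], 1L)
  # successful fits never lose to the mean-only predictor
  expect_true(all(cmp$r2[!cmp$failed] >= 0))
})

test_that("compare_models flags failures, validates input, is deterministic", {
  expect_error(compare_models(list(), "logistic"), "at least one series")
  tt <- seq(0, 700, length.out = 30)
  s <- make_series(tt, logistic_growth(tt, 0.33, 4.5, 0.03), reactor_id = "A")
  expect_error(compare_models(list(s), character(0)), "empty model set")
  expect_error(compare_models(list(s), "nope"), "unknown model")
  # a 5-parameter model on a 5-point series fails; the table still appears
  s_small <- make_series(c(0, 100, 250, 400, 700),
                         logistic_growth(c(0, 100, 250, 400, 700),
                                         0.33, 4.5, 0.03),
                         reactor_id = "B")
  cmp <- compare_models(list(s_small), c("logistic", "hybrid_two_phase"))
  expect_true(cmp$failed[cmp$model == "hybrid_two_phase"])
  expect_false(cmp$failed[cmp$model == "logistic"])
  expect_match(cmp$message[cmp$model == "hybrid_two_phase"], "insufficient")
  # identical series give identical rows
  s2 <- s; attr(s2, "reactor_id") <- "A2"
  cmp2 <- compare_models(list(s, s2), "logistic", seed = 9)
  expect_equal(cmp2$r2[1], cmp2$r2[2])
  expect_equal(cmp2$xmax_gL[1], cmp2$xmax_gL[2])
})

test_that("write_comparison_csv emits one wide row per reactor", {
  tt <- seq(0, 700, length.out = 20)
  s <- make_series(tt, logistic_growth(tt, 0.33, 4.2, 0.03), reactor_id = "PBR5")
  cmp <- compare_models(list(s), c("logistic", "gompertz"))
  f <- withr::local_tempfile(fileext = ".csv")
  cfgs <- list(PBR5 = reactor_config("PBR5", 5.5, 4))
  write_comparison_csv(cmp, f, cfgs)
  out <- read.csv(f)
  expect_equal(nrow(out), 1L)
  expect_equal(out$aeration_vvm, 1.375)
  expect_true(all(c("logistic_r2", "logistic_rmse", "logistic_xmax",
                    "gompertz_r2") %in% names(out)))
})
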