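#' Model registry
#'
#' Registered model families, keyed by canonical name. Each entry carries
#' the parameter names with units, a vectorised prediction function, and
#' data-driven default bounds and initial guesses used by [fit_model()].
#'
#' Default heuristics (biomass models): X0 = first observation; capacities
#' (K, Xmax, X0*e^C) from the maximum observation; rates from a two-point
#' log slope over the first third of the series; lags start at 0; the
#' hybrid stitch time from [detect_transition()] when it fires, otherwise
#' the time at which the series reaches 60% of its maximum.
#'
#' @return [model_registry()] returns a named list of model definitions;
#'   [model_names()] the canonical keys; [model_info()] one definition.
#' @param name canonical model key, e.g. "logistic".
#' @examples
#' model_names()
#' model_info("gompertz")$param_units
#' @name model_registry
NULL

# slope of log(X) over the first third of a series; crude mu estimate
.log_slope_init <- function(t, x) {
  n <- length(t)
  k <- max(3L, ceiling(n / 3))
  k <- min(k, n)
  tt <- t[seq_len(k)]; xx <- pmax(x[seq_len(k)], 1e-9)
  if (length(unique(tt)) < 2) return(0.01)
  sl <- stats::coef(stats::lm(log(xx) ~ tt))[[2]]
  max(sl, 1e-4)
}

# linear slope over the first third, floor at a tiny positive value
.lin_slope_init <- function(t, x) {
  n <- length(t)
  k <- max(3L, ceiling(n / 3))
  k <- min(k, n)
  tt <- t[seq_len(k)]; xx <- x[seq_len(k)]
  if (length(unique(tt)) < 2) return(1e-3)
  max(stats::coef(stats::lm(xx ~ tt))[[2]], 1e-4)
}

.ts_init <- function(t, x) {
  est <- tryCatch(
    detect_transition(growth_series(time_h = t, biomass_gL = x)),
    error = function(e) NULL)
  if (!is.null(est) && !is.na(est$t_s)) return(est$t_s)
  target <- min(x) + 0.6 * (max(x) - min(x))
  idx <- which(x >= target)
  if (length(idx)) t[idx[1]] else stats::median(t)
}

.registry <- list(
  logistic = list(
    kind = "biomass",
    params = c("X0", "K", "mu"),
    param_units = c(X0 = "g/L", K = "g/L", mu = "1/h"),
    predict = function(t, p) logistic_growth(t, p[["X0"]], p[["K"]], p[["mu"]]),
    init = function(t, x) c(X0 = max(x[1], 1e-3), K = max(x), mu = .log_slope_init(t, x)),
    lower = function(t, x) c(X0 = 1e-6, K = 1e-6, mu = 0),
    upper = function(t, x) c(X0 = max(x) * 2, K = 10 * max(x), mu = 10),
    xmax = function(p) p[["K"]]
  ),
  logistic_lag = list(
    kind = "biomass",
    params = c("X0", "K", "mu", "t_lag"),
    param_units = c(X0 = "g/L", K = "g/L", mu = "1/h", t_lag = "h"),
    predict = function(t, p)
      logistic_lag_growth(t, p[["X0"]], p[["K"]], p[["mu"]], p[["t_lag"]]),
    init = function(t, x) c(X0 = max(x[1], 1e-3), K = max(x),
                            mu = .log_slope_init(t, x), t_lag = 0),
    lower = function(t, x) c(X0 = 1e-6, K = 1e-6, mu = 0, t_lag = 0),
    upper = function(t, x) c(X0 = max(x) * 2, K = 10 * max(x), mu = 10,
                             t_lag = max(t)),
    xmax = function(p) p[["K"]]
  ),
  gompertz = list(
    kind = "biomass",
    params = c("Xmax", "mumax", "lam"),
    param_units = c(Xmax = "g/L", mumax = "g/L/h", lam = "h"),
    predict = function(t, p) gompertz_growth(t, p[["Xmax"]], p[["mumax"]], p[["lam"]]),
    init = function(t, x) c(Xmax = max(x), mumax = .lin_slope_init(t, x), lam = 0),
    lower = function(t, x) c(Xmax = 1e-6, mumax = 0, lam = 0),
    upper = function(t, x) c(Xmax = 10 * max(x), mumax = 10, lam = max(t)),
    xmax = function(p) p[["Xmax"]]
  ),
  baranyi_roberts = list(
    kind = "biomass",
    params = c("X0", "mumax", "lam", "C"),
    param_units = c(X0 = "g/L", mumax = "1/h", lam = "h", C = "ln(X/X0)"),
    predict = function(t, p)
      baranyi_growth(t, p[["X0"]], p[["mumax"]], p[["lam"]], p[["C"]]),
    init = function(t, x) {
      x0 <- max(x[1], 1e-3)
      c(X0 = x0, mumax = .log_slope_init(t, x), lam = 0,
        C = max(log(max(x) / x0), 0.1))
    },
    lower = function(t, x) c(X0 = 1e-6, mumax = 0, lam = 0, C = 0),
    upper = function(t, x) c(X0 = max(x) * 2, mumax = 10, lam = max(t),
                             C = max(log(10 * max(x) / max(x[1], 1e-3)), 1)),
    xmax = function(p) p[["X0"]] * exp(p[["C"]])
  ),
  hybrid_two_phase = list(
    kind = "biomass",
    params = c("X0", "a", "t_s", "K", "r"),
    param_units = c(X0 = "g/L", a = "g/L/h", t_s = "h", K = "g/L", r = "1/h"),
    predict = function(t, p)
      hybrid_growth(t, p[["X0"]], p[["a"]], p[["t_s"]], p[["K"]], p[["r"]]),
    init = function(t, x) {
      mu <- .log_slope_init(t, x)
      c(X0 = max(x[1], 1e-3), a = .lin_slope_init(t, x), t_s = .ts_init(t, x),
        K = max(x), r = mu)
    },
    lower = function(t, x) c(X0 = 1e-6, a = 0, t_s = 0, K = 1e-6, r = 0),
    upper = function(t, x) c(X0 = max(x) * 2, a = 10, t_s = max(t),
                             K = 10 * max(x), r = 10),
    # the SSE is piecewise in t_s with many shallow basins; seed extra
    # starts with the stitch time at several time quantiles
    extra_starts = function(t, x, init) {
      lapply(stats::quantile(t, c(0.2, 0.35, 0.5, 0.65, 0.8)), function(ts) {
        s <- init; s[["t_s"]] <- ts; s
      })
    },
    xmax = function(p) p[["K"]]
  ),
  monod_gauss = list(
    kind = "surface",
    params = c("mumax", "KB", "Topt", "sigma"),
    param_units = c(mumax = "g/L/h", KB = "vvm", Topt = "degC", sigma = "degC"),
    predict = function(d, p)
      monod_gauss(d$T_mean_C, d$B_vvm, p[["mumax"]], p[["KB"]],
                  p[["Topt"]], p[["sigma"]]),
    init = function(d) {
      span <- diff(range(d$T_mean_C))
      c(mumax = max(d$slope, 1e-6), KB = stats::median(d$B_vvm),
        Topt = mean(d$T_mean_C), sigma = max(span / 2, 0.5))
    },
    lower = function(d) c(mumax = 1e-9, KB = 1e-6, Topt = 15, sigma = 1e-3),
    upper = function(d) c(mumax = 10, KB = 10, Topt = 40, sigma = 15)
  )
)

#' @rdname model_registry
#' @export
model_registry <- function() .registry

#' @rdname model_registry
#' @export
model_names <- function() names(.registry)

#' @rdname model_registry
#' @export
model_info <- function(name) {
  if (!name %in% names(.registry))
    stop(sprintf("unknown model '%s'; registered models: %s", name,
                 paste(names(.registry), collapse = ", ")), call. = FALSE)
  .registry[[name]]
}
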