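#' Reactor configuration
#'
#' @param reactor_id label.
#' @param airflow_L_min air flow set on the rotameter, L/min (> 0).
#' @param working_volume_L working culture volume, L (default 4).
#' @return object of class \code{reactor_config}.
#' @export
reactor_config <- function(reactor_id, airflow_L_min, working_volume_L = 4) {
  .check_positive(airflow_L_min, "airflow_L_min")
  .check_positive(working_volume_L, "working_volume_L")
  structure(list(reactor_id = as.character(reactor_id),
                 airflow_L_min = airflow_L_min,
                 working_volume_L = working_volume_L),
            class = "reactor_config")
}

#' Convert an air flow to vvm
#'
#' vvm (vessel volumes per minute) = air flow (L/min) / working volume (L).
#'
#' @inheritParams reactor_config
#' @return aeration intensity, vvm.
#' @examples
#' to_vvm(1.0, 4)   # 0.25
#' to_vvm(13.0, 4)  # 3.25
#' @export
to_vvm <- function(airflow_L_min, working_volume_L) {
  if (any(airflow_L_min <= 0) || any(working_volume_L <= 0))
    stop("air flow and working volume must be positive", call. = FALSE)
  airflow_L_min / working_volume_L
}

#' Initial growth slope of a series
#'
#' Ordinary least-squares slope of biomass vs time over the early window
#' \code{[0, t_max_h]}, used as the linear-phase growth rate.
#'
#' @param series a [growth_series()].
#' @param t_max_h end of the window, hours (default 100).
#' @return slope, g/L/h.
#' @export
initial_slope <- function(series, t_max_h = 100) {
  stopifnot(inherits(series, "growth_series"))
  inw <- series$time_h <= t_max_h
  if (sum(inw) < 2L)
    stop("insufficient data: need >= 2 samples with time_h <= t_max_h",
         call. = FALSE)
  stats::coef(stats::lm(series$biomass_gL[inw] ~ series$time_h[inw]))[[2]]
}

#' Mean temperature over the early window
#'
#' @inheritParams initial_slope
#' @return arithmetic mean of the in-window temperature records, degrees C.
#' @export
mean_temperature <- function(series, t_max_h = 100) {
  stopifnot(inherits(series, "growth_series"))
  temps <- series$temperature_C[series$time_h <= t_max_h]
  temps <- temps[is.finite(temps)]
  if (!length(temps))
    stop("no temperature records inside the window", call. = FALSE)
  mean(temps)
}

#' Build aeration-temperature surface points from series
#'
#' One (B, T_mean, slope) triple per reactor: aeration converted to vvm
#' from its config, the early-window mean temperature, and the
#' early-window OLS slope.
#'
#' @param series_list list of [growth_series()].
#' @param configs list of [reactor_config()] in matching order (or keyed by
#'   reactor id).
#' @param t_max_h early window, hours (default 100).
#' @return data frame with columns \code{reactor_id}, \code{B_vvm},
#'   \code{T_mean_C}, \code{slope}.
#' @export
surface_points <- function(series_list, configs, t_max_h = 100) {
  if (inherits(series_list, "growth_series")) series_list <- list(series_list)
  if (!is.null(names(configs))) {
    configs <- configs[vapply(series_list, attr, "", "reactor_id")]
  }
  stopifnot(length(series_list) == length(configs))
  do.call(rbind, Map(function(s, cfg) {
    data.frame(reactor_id = attr(s, "reactor_id"),
               B_vvm = to_vvm(cfg$airflow_L_min, cfg$working_volume_L),
               T_mean_C = mean_temperature(s, t_max_h),
               slope = initial_slope(s, t_max_h))
  }, series_list, configs))
}

#' Fit the Monod-by-Gauss surface to (temperature, aeration, slope) points
#'
#' Bounded nonlinear least squares of [monod_gauss()] to per-reactor slope
#' observations. Default bounds: Topt in [15, 40] degC, sigma in (0, 15]
#' degC, KB in (0, 10] vvm; initial guesses: Topt = mean observed T,
#' sigma = half the observed T span, KB = median B, mumax = max slope.
#'
#' With a temperature span narrower than sigma the thermal parameters are
#' only weakly identified; the fit warns when the estimated sigma exceeds
#' the observed span and reports residual-based approximate standard
#' errors so that such cases are visible. A design with a single distinct
#' temperature leaves Topt and sigma unidentifiable: they are flagged,
#' not estimated meaningfully.
#'
#' @param points data frame with columns \code{B_vvm}, \code{T_mean_C},
#'   \code{slope} (see [surface_points()]).
#' @param init,bounds optional overrides as in [fit_model()].
#' @param seed integer for the multi-start jitter.
#' @param n_starts optimiser starts (default 8).
#' @return object of class \code{surface_fit}: \code{params} (mumax, KB,
#'   Topt, sigma), \code{r2}, \code{rmse}, \code{n_points}, approximate
#'   \code{std_errors}, and \code{unidentifiable} flags.
#' @export
fit_surface <- function(points, init = NULL, bounds = NULL, seed = 1L,
                        n_starts = 8L) {
  req <- c("B_vvm", "T_mean_C", "slope")
  if (!all(req %in% names(points)))
    stop("'points' needs columns B_vvm, T_mean_C, slope", call. = FALSE)
  if (nrow(points) < 4L)
    stop("insufficient data: need >= 4 surface points", call. = FALSE)
  if (nrow(unique(points[req])) == 1L)
    stop("unidentifiable: all surface points identical", call. = FALSE)
  m <- model_info("monod_gauss")
  one_T <- length(unique(points$T_mean_C)) < 2L
  one_B <- length(unique(points$B_vvm)) < 2L
  init0 <- m$init(points)
  if (one_T) init0[["sigma"]] <- 1  # arbitrary; flagged below
  if (!is.null(init)) init0[names(init)] <- init
  lower <- m$lower(points); upper <- m$upper(points)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  res_fun <- function(p) {
    names(p) <- m$params
    m$predict(points, as.list(p)) - points$slope
  }
  fit <- .ls_fit(res_fun, init0, lower, upper, seed = seed, n_starts = n_starts)
  pred <- m$predict(points, as.list(fit$par))
  gof <- goodness_of_fit(points$slope, pred)
  se <- .surface_std_errors(points, fit$par, m)
  span <- diff(range(points$T_mean_C))
  if (!one_T && fit$par[["sigma"]] > span)
    warning(sprintf(paste0("estimated sigma (%.3g degC) exceeds the observed ",
                           "temperature span (%.3g degC); thermal parameters ",
                           "are weakly identified"),
                    fit$par[["sigma"]], span), call. = FALSE)
  structure(list(params = fit$par, param_units = m$param_units,
                 r2 = gof$r2, rmse = gof$rmse, r2_defined = gof$r2_defined,
                 n_points = nrow(points), residuals = points$slope - pred,
                 fitted = pred, converged = fit$converged,
                 std_errors = se,
                 unidentifiable = c(Topt = one_T, sigma = one_T,
                                    KB = one_B, mumax = FALSE),
                 init_used = init0,
                 bounds_used = list(lower = lower, upper = upper)),
            class = "surface_fit")
}

# residual-based approximate standard errors from a numerical Jacobian
.surface_std_errors <- function(points, par, m) {
  n <- nrow(points); p <- length(par)
  if (n <= p) return(stats::setNames(rep(NA_real_, p), names(par)))
  J <- matrix(NA_real_, n, p)
  h <- pmax(abs(par), 1e-4) * 1e-6
  f0 <- m$predict(points, as.list(par))
  for (j in seq_len(p)) {
    pj <- par; pj[j] <- pj[j] + h[j]
    J[, j] <- (m$predict(points, as.list(pj)) - f0) / h[j]
  }
  s2 <- sum((points$slope - f0)^2) / (n - p)
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  if (is.null(cov)) return(stats::setNames(rep(NA_real_, p), names(par)))
  stats::setNames(sqrt(pmax(diag(cov), 0)), names(par))
}

#' @export
print.surface_fit <- function(x, ...) {
  cat(sprintf("<surface_fit> Monod x Gauss on %d points%s\n", x$n_points,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- data.frame(estimate = signif(x$params, 5),
                    std_error = signif(x$std_errors, 3),
                    unit = x$param_units[names(x$params)],
                    flag = ifelse(x$unidentifiable[names(x$params)],
                                  "unidentifiable", ""))
  print(est)
  cat(sprintf("R2 = %s, RMSE = %.4g g/L/h\n",
              if (x$r2_defined) sprintf("%.4f", x$r2) else "undefined",
              x$rmse))
  invisible(x)
}

#' Evaluate a fitted surface on a temperature-by-aeration lattice
#'
#' Convenience export for plotting the rate surface: a long-format grid of
#' predicted growth rates.
#'
#' @param fit a [fit_surface()] result (or a named parameter vector).
#' @param T_grid temperatures, degrees C.
#' @param B_grid aeration intensities, vvm.
#' @return data frame with columns \code{T_C}, \code{B_vvm}, \code{mu}.
#' @export
surface_grid <- function(fit, T_grid = seq(20, 32, by = 0.5),
                         B_grid = seq(0.1, 3.5, by = 0.1)) {
  par <- if (inherits(fit, "surface_fit")) fit$params else fit
  g <- expand.grid(T_C = T_grid, B_vvm = B_grid)
  g$mu <- monod_gauss(g$T_C, g$B_vvm, par[["mumax"]], par[["KB"]],
                      par[["Topt"]], par[["sigma"]])
  g
}
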