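#' Goodness-of-fit metrics
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} and \eqn{RMSE = \sqrt{SS_{res}/n}}.
#' RMSE uses denominator n (not n - p), the usual convention in
#' growth-model comparisons. When the observations have zero total sum of
#' squares R2 is undefined; it is returned as NA with
#' \code{r2_defined = FALSE} rather than a guessed value.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return list with \code{r2}, \code{rmse}, \code{r2_defined}.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))  # r2 = 0.5
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length", call. = FALSE)
  if (length(observed) < 2L) stop("need at least 2 observations", call. = FALSE)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  rmse <- sqrt(ss_res / length(observed))
  if (ss_tot == 0)
    return(list(r2 = NA_real_, rmse = rmse, r2_defined = FALSE))
  list(r2 = 1 - ss_res / ss_tot, rmse = rmse, r2_defined = TRUE)
}

# Projected Levenberg-Marquardt refinement with a forward-difference
# Jacobian; converges to machine precision on zero-residual problems where
# quasi-Newton methods stall.
.lm_refine <- function(residual_fun, par, lower, upper, maxit = 100L) {
  clip <- function(p) pmin(pmax(p, lower), upper)
  par <- clip(par)
  r <- residual_fun(par)
  if (any(!is.finite(r))) return(list(par = par, sse = 1e300))
  sse <- sum(r^2)
  lambda <- 1e-3
  for (it in seq_len(maxit)) {
    h <- pmax(abs(par), 1e-4) * 1e-7
    J <- vapply(seq_along(par), function(j) {
      pj <- par; pj[j] <- pj[j] + h[j]
      (residual_fun(clip(pj)) - r) / h[j]
    }, numeric(length(r)))
    JtJ <- crossprod(J); Jtr <- crossprod(J, r)
    improved <- FALSE
    for (k in 1:12) {
      step <- tryCatch(
        solve(JtJ + lambda * diag(diag(JtJ) + 1e-12, nrow(JtJ)), -Jtr),
        error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- clip(par + drop(step))
      rc <- residual_fun(cand)
      sc <- if (any(!is.finite(rc))) Inf else sum(rc^2)
      if (sc < sse) {
        par <- cand; r <- rc
        improved <- TRUE
        converged_step <- (sse - sc) <= 1e-14 * (sse + 1e-300)
        sse <- sc
        lambda <- max(lambda / 10, 1e-12)
        if (converged_step) return(list(par = par, sse = sse))
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  list(par = par, sse = sse)
}

# Bounded least-squares core shared by fit_model() and fit_surface().
# Multi-start L-BFGS-B on the SSE (parameter-scaled), deterministic in
# `seed`: the first starts are the heuristic init plus any model-supplied
# extra starts, the rest log-jittered within bounds. The best basin is
# refined with projected Levenberg-Marquardt; exact SSE ties are broken by
# lexicographic order of the parameter vector.
.ls_fit <- function(residual_fun, init, lower, upper, seed = 1L,
                    n_starts = 5L, extra_starts = list()) {
  sse <- function(p) {
    r <- residual_fun(p)
    if (any(!is.finite(r))) return(1e300)
    sum(r^2)
  }
  init <- pmin(pmax(init, lower), upper)
  starts <- c(list(init),
              lapply(extra_starts, function(s) pmin(pmax(s, lower), upper)))
  n_jit <- max(0L, n_starts - length(starts))
  if (n_jit > 0L) {
    jit <- withr_seed(seed, {
      lapply(seq_len(n_jit), function(i) {
        p <- init * exp(stats::rnorm(length(init), 0, 0.35))
        # jitter additive for params that may sit at 0 (lags, stitch times)
        zero <- init == 0
        p[zero] <- stats::runif(sum(zero), lower[zero],
                                pmin(upper[zero], abs(upper[zero]) * 0.5))
        pmin(pmax(p, lower), upper)
      })
    })
    starts <- c(starts, jit)
  }
  runs <- lapply(starts, function(s) {
    sc <- pmax(abs(s), (upper - lower) * 1e-3, 1e-8)
    coarse <- tryCatch(
      stats::optim(s, sse, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, parscale = sc)),
      error = function(e) list(par = s, value = sse(s), convergence = 99L))
    fine <- .lm_refine(residual_fun, coarse$par, lower, upper)
    list(par = fine$par, value = fine$sse,
         convergence = coarse$convergence)
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best_val <- min(vals)
  cand <- which(vals <= best_val * (1 + 1e-12) + 1e-300)
  if (length(cand) > 1L) {
    pars <- t(vapply(runs[cand], `[[`, numeric(length(init)), "par"))
    ord <- do.call(order, as.data.frame(pars))
    best <- runs[[cand[ord[1]]]]
  } else best <- runs[[cand]]
  names(best$par) <- names(init)
  list(par = best$par, sse = best$value,
       converged = best$convergence == 0)
}

# evaluate expr with a local RNG state seeded from `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

#' Fit a registered growth model to a series
#'
#' Bounded nonlinear least squares (multi-start L-BFGS-B on the sum of
#' squared concentration residuals). Deterministic given the series, the
#' starting values/bounds and \code{seed}. Non-convergence is reported in
#' the result, not raised.
#'
#' @param series a [growth_series()].
#' @param model_name canonical key from [model_names()] (biomass models).
#' @param init optional named vector of starting values (defaults from
#'   registry heuristics).
#' @param bounds optional list with named vectors \code{lower}, \code{upper}.
#' @param seed integer controlling multi-start jitter (default 1).
#' @param n_starts number of optimiser starts (default 5).
#' @return object of class \code{growth_fit}: parameter estimates, R2,
#'   RMSE, residuals, convergence metadata, and the Xmax summary the model
#'   implies (logistic/hybrid K, Gompertz Xmax, Baranyi X0*e^C).
#' @examples
#' s <- generate_two_phase_curve(X0 = 0.33, a = 0.01, t_s = 300, K = 4.4,
#'                               r = 0.02, noise_cv = 0, seed = 1)
#' fit <- fit_model(s, "logistic")
#' fit$r2
#' @export
fit_model <- function(series, model_name, init = NULL, bounds = NULL,
                      seed = 1L, n_starts = 5L) {
  stopifnot(inherits(series, "growth_series"))
  m <- model_info(model_name)
  if (m$kind != "biomass")
    stop(sprintf("'%s' is not a biomass-vs-time model; use fit_surface()",
                 model_name), call. = FALSE)
  ord <- order(series$time_h)
  t <- series$time_h[ord]; x <- series$biomass_gL[ord]
  p_count <- length(m$params)
  if (length(t) < p_count + 1L)
    stop(sprintf("insufficient data: %d observations for %d parameters",
                 length(t), p_count), call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate data: biomass has no variation", call. = FALSE)
  init0 <- m$init(t, x)
  if (!is.null(init)) init0[names(init)] <- init
  lower <- m$lower(t, x); upper <- m$upper(t, x)
  if (!is.null(bounds)) {
    if (!is.null(bounds$lower)) lower[names(bounds$lower)] <- bounds$lower
    if (!is.null(bounds$upper)) upper[names(bounds$upper)] <- bounds$upper
  }
  res_fun <- function(p) {
    names(p) <- m$params
    pred <- tryCatch(m$predict(t, as.list(p)), error = function(e) rep(NA_real_, length(t)))
    pred - x
  }
  extra <- if (is.null(m$extra_starts)) list() else m$extra_starts(t, x, init0)
  fit <- .ls_fit(res_fun, init0, lower, upper, seed = seed,
                 n_starts = n_starts, extra_starts = extra)
  pred <- m$predict(t, as.list(fit$par))
  gof <- goodness_of_fit(x, pred)
  structure(list(model_name = model_name, params = fit$par,
                 param_units = m$param_units,
                 r2 = gof$r2, rmse = gof$rmse, r2_defined = gof$r2_defined,
                 residuals = x - pred, fitted = pred, n_obs = length(t),
                 converged = fit$converged, sse = fit$sse,
                 xmax = m$xmax(as.list(fit$par)),
                 init_used = init0,
                 bounds_used = list(lower = lower, upper = upper),
                 reactor_id = attr(series, "reactor_id")),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s on '%s' (n = %d)%s\n", x$model_name,
              x$reactor_id, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  est <- data.frame(estimate = signif(x$params, 5),
                    unit = x$param_units[names(x$params)])
  print(est)
  cat(sprintf("R2 = %s, RMSE = %.4g g/L, Xmax = %.4g g/L\n",
              if (x$r2_defined) sprintf("%.4f", x$r2) else "undefined",
              x$rmse, x$xmax))
  invisible(x)
}

#' Fit several models to several series and tabulate the comparison
#'
#' Fits every model in \code{models} to every series, ranks models per
#' series by R2 (ties broken by lower RMSE), and returns a long-format
#' comparison table. A model that fails on one series is flagged in that
#' row (\code{failed = TRUE}), never silently dropped.
#'
#' @param series_list list of [growth_series()] (a single series is
#'   accepted).
#' @param models character vector of registry keys (biomass models).
#' @param seed integer passed to each fit.
#' @param ... passed to [fit_model()].
#' @return object of class \code{model_comparison}: a data frame with one
#'   row per (reactor, model): \code{r2}, \code{rmse}, \code{xmax_gL},
#'   \code{rank}, \code{failed}; the fit objects are attached as
#'   \code{attr(, "fits")}.
#' @export
compare_models <- function(series_list, models = c("logistic", "logistic_lag",
                                                   "gompertz", "baranyi_roberts",
                                                   "hybrid_two_phase"),
                           seed = 1L, ...) {
  if (inherits(series_list, "growth_series")) series_list <- list(series_list)
  if (!length(series_list)) stop("need at least one series", call. = FALSE)
  if (!length(models)) stop("empty model set", call. = FALSE)
  for (mn in models) model_info(mn)  # fail fast on unknown names
  rows <- list(); fits <- list()
  for (s in series_list) {
    rid <- attr(s, "reactor_id")
    for (mn in models) {
      fit <- tryCatch(fit_model(s, mn, seed = seed, ...),
                      error = function(e) e)
      failed <- inherits(fit, "error")
      rows[[length(rows) + 1L]] <- data.frame(
        reactor_id = rid, model = mn,
        r2 = if (failed) NA_real_ else fit$r2,
        rmse = if (failed) NA_real_ else fit$rmse,
        xmax_gL = if (failed) NA_real_ else fit$xmax,
        converged = if (failed) FALSE else fit$converged,
        failed = failed,
        message = if (failed) conditionMessage(fit) else "")
      if (!failed) fits[[paste(rid, mn, sep = "/")]] <- fit
    }
  }
  tab <- do.call(rbind, rows)
  tab$rank <- NA_integer_
  for (rid in unique(tab$reactor_id)) {
    idx <- which(tab$reactor_id == rid & !tab$failed & !is.na(tab$r2))
    if (length(idx)) {
      ord <- order(-tab$r2[idx], tab$rmse[idx])
      tab$rank[idx[ord]] <- seq_along(idx)
    }
  }
  structure(tab, class = c("model_comparison", "data.frame"), fits = fits)
}

#' Write a model comparison as a wide CSV
#'
#' One row per reactor with \code{{model}_r2}, \code{{model}_rmse},
#' \code{{model}_xmax} column triplets, mirroring the usual growth-model
#' comparison table layout. Optional aeration metadata columns are included
#' when reactor configs are supplied.
#'
#' @param comparison a [compare_models()] result.
#' @param path output CSV path.
#' @param configs optional list of [reactor_config()] keyed by reactor id.
#' @return \code{path}, invisibly.
#' @export
write_comparison_csv <- function(comparison, path, configs = NULL) {
  stopifnot(inherits(comparison, "model_comparison"))
  reactors <- unique(comparison$reactor_id)
  models <- unique(comparison$model)
  out <- data.frame(reactor_id = reactors)
  if (!is.null(configs)) {
    out$aeration_L_min <- vapply(reactors, function(r)
      if (!is.null(configs[[r]])) configs[[r]]$airflow_L_min else NA_real_,
      numeric(1))
    out$aeration_vvm <- vapply(reactors, function(r)
      if (!is.null(configs[[r]]))
        to_vvm(configs[[r]]$airflow_L_min, configs[[r]]$working_volume_L)
      else NA_real_, numeric(1))
  }
  for (mn in models) {
    sub <- comparison[comparison$model == mn, ]
    sub <- sub[match(reactors, sub$reactor_id), ]
    out[[paste0(mn, "_r2")]] <- round(sub$r2, 4)
    out[[paste0(mn, "_rmse")]] <- round(sub$rmse, 4)
    out[[paste0(mn, "_xmax")]] <- round(sub$xmax_gL, 2)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
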