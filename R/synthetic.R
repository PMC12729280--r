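#' Synthetic photobioreactor campaigns
#'
#' Seeded generators that emulate the statistical structure of a batch
#' microalgal campaign run under atmospheric CO2: inoculation near
#' 0.33 g/L, no lag phase, an early linear phase, logistic saturation to a
#' capacity that rises with aeration and plateaus above ~1.3 vvm,
#' room-temperature drift within 24.5-28.5 degC, 700 h duration with daily
#' then irregular sampling, evaporation with periodic top-ups, and
#' multiplicative observation noise. Ground truth is always returned so
#' recovery can be tested.
#'
#' @name synthetic_data
NULL

# canonical rate-surface parameters used by the simulator
.canonical_surface <- c(mumax = 0.0136, KB = 0.5, Topt = 26, sigma = 3.3)

#' Default sampling schedule
#'
#' Daily samples over the first 100 h, then progressively sparser and
#' irregular out to \code{duration_h}.
#'
#' @param duration_h campaign length, hours (default 700).
#' @return numeric vector of sampling times, hours.
#' @export
default_schedule <- function(duration_h = 700) {
  s <- c(seq(0, 96, by = 24), 120, 168, 240, 312, 360, 432, 528, 600, 672)
  s <- s[s < duration_h]
  sort(unique(c(s, duration_h)))
}

#' Aeration-to-capacity map of the simulator
#'
#' Smooth saturating map from aeration intensity to the carrying capacity
#' the simulated culture approaches: ~1.3-1.6 g/L below 0.5 vvm, rising to
#' ~4.7-4.8 g/L above 1.3 vvm, with a mild decline beyond 3 vvm
#' (mechanical stress). A simulator convenience calibrated only to the
#' qualitative plateau shape, not a mechanistic claim.
#'
#' @param B aeration intensity, vvm.
#' @return carrying capacity, g/L.
#' @export
capacity_from_aeration <- function(B) {
  1.2 + 3.6 / (1 + exp(-6 * (B - 0.85))) - 0.3 * pmax(0, B - 3)
}

#' Campaign scenario
#'
#' Bundle of simulator settings. Defaults state the emulated experiment:
#' eight 4 L reactors aerated 1-13 L/min, 700 h, inoculum 0.33 g/L, 2%
#' multiplicative observation noise, temperatures centred on 26.5 degC
#' spanning +/- 2 degC, evaporation 1.2 mL/h with top-ups every 96 h.
#'
#' @param reactors list of [reactor_config()]; default mirrors an 8-reactor
#'   aeration ladder (1, 2, 3.6, 3.7, 5.5, 7.6, 8, 13 L/min at 4 L).
#' @param duration_h campaign length, hours.
#' @param schedule sampling times (default [default_schedule()]).
#' @param X0_gL inoculum concentration, g/L.
#' @param noise_cv multiplicative observation noise CV (default 0.02).
#' @param temp_base,temp_spread reactor mean temperatures are drawn
#'   uniformly from temp_base +/- temp_spread, degrees C.
#' @param evaporation_mL_per_h constant evaporation rate.
#' @param topup_interval_h interval between compensating water additions.
#' @param surface_params named vector (mumax, KB, Topt, sigma) of the rate
#'   surface that sets each reactor's linear-phase slope.
#' @param cal a [calibration_spec()] used to back-convert to OD readings.
#' @return object of class \code{campaign_scenario}.
#' @export
campaign_scenario <- function(reactors = NULL, duration_h = 700,
                              schedule = default_schedule(duration_h),
                              X0_gL = 0.33, noise_cv = 0.02,
                              temp_base = 26.5, temp_spread = 2,
                              evaporation_mL_per_h = 1.2,
                              topup_interval_h = 96,
                              surface_params = .canonical_surface,
                              cal = calibration_spec()) {
  if (is.null(reactors)) {
    flows <- c(1.0, 2.0, 3.6, 3.7, 5.5, 7.6, 8.0, 13.0)
    reactors <- lapply(seq_along(flows), function(i)
      reactor_config(paste0("PBR", i), flows[i], 4))
  }
  .check_positive(duration_h, "duration_h")
  .check_nonneg(noise_cv, "noise_cv")
  if (any(schedule < 0) || any(schedule > duration_h))
    stop("schedule must lie within [0, duration_h]", call. = FALSE)
  structure(list(reactors = reactors, duration_h = duration_h,
                 schedule = sort(unique(schedule)), X0_gL = X0_gL,
                 noise_cv = noise_cv, temp_base = temp_base,
                 temp_spread = temp_spread,
                 evaporation_mL_per_h = evaporation_mL_per_h,
                 topup_interval_h = topup_interval_h,
                 surface_params = surface_params, cal = cal),
            class = "campaign_scenario")
}

#' Simulate one reactor of a campaign
#'
#' The truth curve is a hybrid two-phase model whose linear slope comes
#' from the scenario's rate surface evaluated at the reactor's aeration
#' and drawn mean temperature; the carrying capacity comes from
#' [capacity_from_aeration()]; the stitch time is where the linear phase
#' reaches 60% of capacity; the logistic rate is slope-matched at the
#' stitch (r = a / (0.24 K)). Observations are the measured concentration
#' (truth rescaled to the actual, evaporating suspension volume) times
#' multiplicative Gaussian noise, back-converted to OD with an
#' automatically chosen dilution that keeps readings in the calibration
#' range.
#'
#' @param scenario a [campaign_scenario()].
#' @param reactor a [reactor_config()].
#' @param seed integer; the series is bit-identical for equal seeds.
#' @return a [growth_series()]; ground truth (hybrid parameters, mean
#'   temperature, aeration, volume events) in \code{attr(, "truth")}.
#' @export
generate_reactor_series <- function(scenario, reactor, seed = 1L) {
  stopifnot(inherits(scenario, "campaign_scenario"),
            inherits(reactor, "reactor_config"))
  sp <- scenario$surface_params
  withr_seed(seed, {
    B <- to_vvm(reactor$airflow_L_min, reactor$working_volume_L)
    T_mean <- stats::runif(1, scenario$temp_base - scenario$temp_spread,
                           scenario$temp_base + scenario$temp_spread)
    a <- monod_gauss(T_mean, B, sp[["mumax"]], sp[["KB"]], sp[["Topt"]],
                     sp[["sigma"]])
    K <- capacity_from_aeration(B)
    X0 <- scenario$X0_gL
    t_s <- min((0.6 * K - X0) / max(a, 1e-6), 0.9 * scenario$duration_h)
    r <- a / (0.24 * K)
    tt <- scenario$schedule
    truth_corr <- hybrid_growth(tt, X0, a, t_s, K, r)
    # volume ledger: evaporation with periodic compensating top-ups
    ev_times <- seq(scenario$topup_interval_h, scenario$duration_h,
                    by = scenario$topup_interval_h)
    ev_added <- rep(scenario$evaporation_mL_per_h * scenario$topup_interval_h,
                    length(ev_times))
    vol <- vapply(tt, function(t) {
      reactor$working_volume_L - scenario$evaporation_mL_per_h * t / 1000 +
        sum(ev_added[ev_times <= t]) / 1000
    }, numeric(1))
    meas <- truth_corr * reactor$working_volume_L / vol
    obs <- pmax(meas * (1 + stats::rnorm(length(tt), 0, scenario$noise_cv)),
                1e-6)
    # 2-hourly temperature trace; samples carry the nearest trace value
    trace_t <- seq(0, scenario$duration_h, by = 2)
    trace_T <- pmin(pmax(T_mean + stats::rnorm(length(trace_t), 0, 0.4),
                         24.5), 28.5)
    samp_T <- trace_T[pmax(1L, findInterval(tt, trace_t))]
    k_cal <- scenario$cal$k_cal
    od_hi <- scenario$cal$od_range[2]
    n_dil <- pmax(1, ceiling(obs / (k_cal * od_hi)))
    od <- obs / (k_cal * n_dil)
    added <- vapply(tt, function(t)
      sum(ev_added[ev_times == t]), numeric(1))
    s <- growth_series(time_h = tt, od750 = od, dilution_factor = n_dil,
                       temperature_C = samp_T, added_mL = added,
                       reactor_id = reactor$reactor_id,
                       nominal_volume_L = reactor$working_volume_L,
                       cal = scenario$cal)
    attr(s, "truth") <- list(
      model = "hybrid_two_phase",
      params = c(X0 = X0, a = a, t_s = t_s, K = K, r = r),
      B_vvm = B, T_mean_C = T_mean, volume_L = vol,
      events = data.frame(time_h = ev_times, added_mL = ev_added),
      temp_trace = data.frame(time_h = trace_t, temperature_C = trace_T),
      seed = seed)
    s
  })
}

#' Simulate a whole campaign
#'
#' @inheritParams generate_reactor_series
#' @return named list of [growth_series()], one per reactor; per-reactor
#'   seeds are derived as \code{seed + index}.
#' @export
generate_campaign <- function(scenario = campaign_scenario(), seed = 1L) {
  out <- lapply(seq_along(scenario$reactors), function(i)
    generate_reactor_series(scenario, scenario$reactors[[i]],
                            seed = (seed + i) %% .Machine$integer.max))
  names(out) <- vapply(scenario$reactors, `[[`, "", "reactor_id")
  out
}

#' Simulate a pure two-phase curve
#'
#' Hybrid linear-logistic truth sampled on a schedule with multiplicative
#' noise; no volume bookkeeping. Supports change-point and fitting tests.
#'
#' @param X0,a,t_s,K,r hybrid model parameters (see [hybrid_growth()]).
#' @param schedule sampling times, hours.
#' @param noise_cv multiplicative noise CV.
#' @param seed integer.
#' @param reactor_id label.
#' @return a [growth_series()] with the truth parameters in
#'   \code{attr(, "truth")}.
#' @export
generate_two_phase_curve <- function(X0, a, t_s, K, r,
                                     schedule = default_schedule(700),
                                     noise_cv = 0, seed = 1L,
                                     reactor_id = "sim") {
  truth <- hybrid_growth(schedule, X0, a, t_s, K, r)
  obs <- withr_seed(seed,
    pmax(truth * (1 + stats::rnorm(length(schedule), 0, noise_cv)), 1e-6))
  s <- growth_series(time_h = schedule, biomass_gL = obs,
                     reactor_id = reactor_id)
  attr(s, "truth") <- list(model = "hybrid_two_phase",
                           params = c(X0 = X0, a = a, t_s = t_s, K = K, r = r),
                           seed = seed)
  s
}

#' Simulate surface points on a temperature-by-aeration lattice
#'
#' Slope observations from [monod_gauss()] with multiplicative noise.
#'
#' @param params named vector (mumax, KB, Topt, sigma).
#' @param T_grid temperatures, degrees C.
#' @param B_grid aeration intensities, vvm.
#' @param noise_cv multiplicative noise CV.
#' @param n_reps replicates per lattice point.
#' @param seed integer.
#' @return data frame with columns \code{reactor_id}, \code{B_vvm},
#'   \code{T_mean_C}, \code{slope}.
#' @export
generate_surface_data <- function(params = .canonical_surface,
                                  T_grid = c(24.5, 25.5, 26.5, 27.5, 28.5),
                                  B_grid = c(0.25, 0.5, 0.9, 1.38, 1.9, 3.25),
                                  noise_cv = 0, n_reps = 1L, seed = 1L) {
  if (!length(T_grid) || !length(B_grid))
    stop("empty lattice", call. = FALSE)
  g <- expand.grid(T_mean_C = T_grid, B_vvm = B_grid)
  g <- g[rep(seq_len(nrow(g)), each = n_reps), ]
  mu <- monod_gauss(g$T_mean_C, g$B_vvm, params[["mumax"]], params[["KB"]],
                    params[["Topt"]], params[["sigma"]])
  eps <- withr_seed(seed, stats::rnorm(length(mu), 0, noise_cv))
  data.frame(reactor_id = sprintf("pt%03d", seq_len(nrow(g))),
             B_vvm = g$B_vvm, T_mean_C = g$T_mean_C,
             slope = mu * (1 + eps), row.names = NULL)
}
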