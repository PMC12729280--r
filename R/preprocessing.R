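#' Calibration specification for OD-to-biomass conversion
#'
#' The spectrophotometer calibration: biomass concentration is
#' \code{od * k_cal * dilution}, valid while the (possibly diluted) reading
#' stays inside the instrument's linear absorbance range.
#'
#' @param k_cal calibration coefficient, g/L per OD750 unit (default 0.4).
#' @param od_range length-2 numeric, linear absorbance range (default
#'   c(0.3, 0.6)); readings outside it trigger warnings, not errors,
#'   because historical rows may predate dilution to range.
#' @return an object of class \code{calibration_spec}.
#' @export
calibration_spec <- function(k_cal = 0.4, od_range = c(0.3, 0.6)) {
  .check_positive(k_cal, "k_cal")
  if (length(od_range) != 2L || !is.numeric(od_range) ||
      od_range[1] >= od_range[2])
    stop("'od_range' must be an increasing numeric pair", call. = FALSE)
  structure(list(k_cal = k_cal, od_range = as.numeric(od_range)),
            class = "calibration_spec")
}

#' Convert optical density to biomass concentration
#'
#' Applies the empirical calibration \code{X = od * k_cal * n}, where
#' \code{n} is the dilution factor applied before reading.
#'
#' @param od absorbance at 750 nm (>= 0; vector allowed).
#' @param n dilution factor (>= 1; recycled).
#' @param cal a [calibration_spec()].
#' @return biomass concentration, g/L. A warning is issued (once per call)
#'   when any reading falls outside the calibration's linear range.
#' @examples
#' od_to_biomass(0.5, n = 2)  # 0.4 g/L
#' @export
od_to_biomass <- function(od, n = 1, cal = calibration_spec()) {
  if (!inherits(cal, "calibration_spec")) stop("'cal' must be a calibration_spec")
  if (any(!is.finite(od)) || any(od < 0))
    stop("'od' must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 1))
    stop("dilution factor 'n' must be >= 1", call. = FALSE)
  out_of_range <- od < cal$od_range[1] | od > cal$od_range[2]
  if (any(out_of_range))
    warning(sprintf("%d OD reading(s) outside linear range [%g, %g]",
                    sum(out_of_range), cal$od_range[1], cal$od_range[2]),
            call. = FALSE)
  od * cal$k_cal * n
}

#' Growth series container
#'
#' One reactor's biomass-vs-time record: a data frame with columns
#' \code{time_h}, \code{biomass_gL} (volume-corrected concentration once
#' [apply_volume_correction()] has run, otherwise as measured),
#' \code{biomass_meas_gL}, \code{od750}, \code{dilution_factor},
#' \code{temperature_C}, \code{added_mL} and \code{volume_L}, plus
#' reactor-level attributes.
#'
#' @param time_h sampling times, hours since inoculation, strictly increasing.
#' @param biomass_gL biomass concentration per sample, g/L. Either this or
#'   \code{od750} must be supplied; if only OD is given, biomass is computed
#'   via [od_to_biomass()].
#' @param od750 absorbance readings (optional).
#' @param dilution_factor per-sample dilution (default 1).
#' @param temperature_C per-sample temperature, degrees C (optional, NA ok).
#' @param added_mL water added at this sample time, mL (default 0).
#' @param reactor_id label.
#' @param nominal_volume_L nominal working volume, L (default 4).
#' @param cal a [calibration_spec()] used when converting OD.
#' @return object of class \code{growth_series} (a data frame).
#' @export
growth_series <- function(time_h, biomass_gL = NULL, od750 = NULL,
                          dilution_factor = 1, temperature_C = NA_real_,
                          added_mL = 0, reactor_id = "reactor",
                          nominal_volume_L = 4, cal = calibration_spec()) {
  time_h <- as.numeric(time_h)
  if (length(time_h) == 0L) stop("empty series", call. = FALSE)
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("'time_h' must be finite and >= 0", call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("'time_h' must be strictly increasing", call. = FALSE)
  n <- length(time_h)
  if (is.null(biomass_gL)) {
    if (is.null(od750)) stop("supply 'biomass_gL' or 'od750'", call. = FALSE)
    biomass_gL <- od_to_biomass(od750, rep_len(dilution_factor, n), cal)
  }
  if (is.null(od750)) od750 <- NA_real_
  if (length(biomass_gL) != n)
    stop("'biomass_gL' length must match 'time_h'", call. = FALSE)
  if (any(biomass_gL < 0, na.rm = TRUE))
    stop("'biomass_gL' must be non-negative", call. = FALSE)
  df <- data.frame(
    time_h = time_h,
    biomass_gL = as.numeric(biomass_gL),
    biomass_meas_gL = as.numeric(biomass_gL),
    od750 = rep_len(as.numeric(od750), n),
    dilution_factor = rep_len(as.numeric(dilution_factor), n),
    temperature_C = rep_len(as.numeric(temperature_C), n),
    added_mL = rep_len(as.numeric(added_mL), n),
    volume_L = rep_len(as.numeric(nominal_volume_L), n)
  )
  structure(df, class = c("growth_series", "data.frame"),
            reactor_id = as.character(reactor_id)[1],
            nominal_volume_L = nominal_volume_L,
            calibration = cal)
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("<growth_series> reactor '%s': %d samples over %.0f h, biomass %.3g-%.3g g/L\n",
              attr(x, "reactor_id"), nrow(x), max(x$time_h),
              min(x$biomass_gL), max(x$biomass_gL)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Correct measured concentrations for evaporation and top-ups
#'
#' Maintains a volume ledger
#' \eqn{V(t) = V_{nom} - e \cdot t + \sum_{t_i \le t} a_i}
#' (constant evaporation rate \eqn{e} between events, additions \eqn{a_i}
#' applied at their recorded times) and normalises each measured
#' concentration to the nominal working volume:
#' \eqn{X_{corr}(t) = X_{meas}(t) \cdot V(t) / V_{nom}}. Both series are
#' retained: \code{biomass_gL} holds the corrected values,
#' \code{biomass_meas_gL} the originals, and \code{volume_L} the ledger.
#'
#' @param series a [growth_series()].
#' @param events data frame with columns \code{time_h} and \code{added_mL}
#'   (may be empty / NULL); rows with zero additions are ignored. If the
#'   series itself carries an \code{added_mL} column those events are used
#'   when \code{events} is NULL.
#' @param nominal_volume_L nominal working volume, L.
#' @param evaporation_rate_mL_per_h constant evaporation rate, mL/h.
#' @return the series with corrected biomass and the volume ledger filled.
#' @export
apply_volume_correction <- function(series, events = NULL,
                                    nominal_volume_L = attr(series, "nominal_volume_L"),
                                    evaporation_rate_mL_per_h = 0) {
  stopifnot(inherits(series, "growth_series"))
  .check_positive(nominal_volume_L, "nominal_volume_L")
  .check_nonneg(evaporation_rate_mL_per_h, "evaporation_rate_mL_per_h")
  if (is.null(events))
    events <- data.frame(time_h = series$time_h, added_mL = series$added_mL)
  events <- events[is.finite(events$added_mL) & events$added_mL > 0, , drop = FALSE]
  if (nrow(events) && any(events$added_mL < 0))
    stop("additions must be non-negative", call. = FALSE)
  if (nrow(events) && is.unsorted(events$time_h))
    events <- events[order(events$time_h), , drop = FALSE]
  vol <- vapply(series$time_h, function(t) {
    nominal_volume_L - evaporation_rate_mL_per_h * t / 1000 +
      sum(events$added_mL[events$time_h <= t]) / 1000
  }, numeric(1))
  if (any(vol <= 0))
    stop("inconsistent volume ledger: non-positive volume at a sample time",
         call. = FALSE)
  series$volume_L <- vol
  series$biomass_gL <- series$biomass_meas_gL * vol / nominal_volume_L
  attr(series, "nominal_volume_L") <- nominal_volume_L
  series
}

.series_columns <- c("reactor_id", "time_h", "od750", "dilution_factor",
                     "temperature_C", "added_mL")

#' Read a growth series from CSV
#'
#' Expects a comma-separated file with header columns \code{reactor_id},
#' \code{time_h}, \code{od750}, \code{dilution_factor}, and optional
#' \code{temperature_C} and \code{added_mL} (blank allowed). Biomass is
#' filled via [od_to_biomass()]; malformed rows are reported with their
#' line numbers.
#'
#' @param path CSV file path.
#' @param cal a [calibration_spec()].
#' @param nominal_volume_L nominal working volume, L.
#' @return a [growth_series()].
#' @seealso [write_series()] for the inverse; the pair round-trips exactly.
#' @export
load_series <- function(path, cal = calibration_spec(), nominal_volume_L = 4) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("reactor_id", "time_h", "od750", "dilution_factor")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L) stop("empty data section in ", path, call. = FALSE)
  bad <- which(!is.finite(df$time_h) | !is.finite(df$od750) |
                 !is.finite(df$dilution_factor) | df$od750 < 0 |
                 df$dilution_factor < 1)
  if (length(bad))
    stop(sprintf("malformed row(s) at line(s): %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  if (any(diff(df$time_h) <= 0))
    stop("non-monotone time_h in ", path, call. = FALSE)
  if (is.null(df$temperature_C)) df$temperature_C <- NA_real_
  if (is.null(df$added_mL)) df$added_mL <- 0
  df$added_mL[is.na(df$added_mL)] <- 0
  growth_series(time_h = df$time_h, od750 = df$od750,
                dilution_factor = df$dilution_factor,
                temperature_C = df$temperature_C, added_mL = df$added_mL,
                reactor_id = df$reactor_id[1],
                nominal_volume_L = nominal_volume_L, cal = cal)
}

#' Write a growth series to CSV
#'
#' Emits the documented input schema so that
#' \code{load_series(write_series(s, f))} reproduces the raw columns
#' bit-identically.
#'
#' @param series a [growth_series()].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "growth_series"))
  out <- data.frame(reactor_id = attr(series, "reactor_id"),
                    series[, c("time_h", "od750", "dilution_factor",
                               "temperature_C", "added_mL")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
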