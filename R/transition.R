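#' Detect the linear-to-logistic transition time
#'
#' Change-point procedure for curves that grow linearly before saturating:
#' (1) ordinary least squares on the samples with \code{time_h <=
#' window_end_h}; (2) the line is extrapolated to every sample; (3)
#' absolute deviations \code{|obs - pred|} are computed; (4) a threshold is
#' set at mean + \code{k_sd} * SD of the within-window absolute deviations
#' (SD uses the n-1 denominator; a zero-variance window degenerates to
#' threshold = mean); (5) the transition time \code{t_s} is the time of the
#' first post-window sample whose deviation strictly exceeds the threshold
#' for \code{persist} consecutive samples. If no exceedance occurs,
#' \code{t_s} is NA ("none found").
#'
#' @param series a [growth_series()].
#' @param window_end_h end of the linear fit window, hours (default 92).
#' @param k_sd threshold multiplier on the deviation SD (default 2).
#' @param persist number of consecutive exceedances required (default 1).
#' @return object of class \code{transition_estimate}: \code{t_s} (NA when
#'   none found), the linear fit (\code{intercept}, \code{slope}),
#'   \code{threshold}, \code{window_end_h}, and per-sample
#'   \code{deviations}.
#' @examples
#' s <- generate_two_phase_curve(X0 = 0.33, a = 0.01, t_s = 300, K = 4.4,
#'                               r = 0.02, noise_cv = 0, seed = 1)
#' detect_transition(s)$t_s
#' @export
detect_transition <- function(series, window_end_h = 92, k_sd = 2,
                              persist = 1L) {
  stopifnot(inherits(series, "growth_series"))
  .check_positive(window_end_h, "window_end_h")
  .check_nonneg(k_sd, "k_sd")
  t <- series$time_h; x <- series$biomass_gL
  inw <- t <= window_end_h
  if (sum(inw) < 3L)
    stop("insufficient data: need >= 3 samples inside the linear window",
         call. = FALSE)
  if (!any(!inw))
    stop("insufficient data: no samples beyond the linear window",
         call. = FALSE)
  fit <- stats::lm(x[inw] ~ t[inw])
  co <- stats::coef(fit)
  pred <- co[[1]] + co[[2]] * t
  dev <- abs(x - pred)
  mu_d <- mean(dev[inw])
  sd_d <- stats::sd(dev[inw])
  threshold <- mu_d + k_sd * (if (is.finite(sd_d)) sd_d else 0)
  # floor against machine-precision false positives on noise-free data
  threshold <- max(threshold, 1e-8 * max(abs(x), 1))
  post <- which(!inw)
  exceed <- dev[post] > threshold
  t_s <- NA_real_
  if (persist <= 1L) {
    hit <- which(exceed)
    if (length(hit)) t_s <- t[post[hit[1]]]
  } else {
    runs <- rle(exceed)
    pos <- cumsum(runs$lengths) - runs$lengths + 1L
    k <- which(runs$values & runs$lengths >= persist)
    if (length(k)) t_s <- t[post[pos[k[1]]]]
  }
  structure(list(t_s = t_s, linear_intercept = co[[1]],
                 linear_slope = co[[2]], threshold = threshold,
                 window_end_h = window_end_h, k_sd = k_sd,
                 deviations = dev,
                 reactor_id = attr(series, "reactor_id")),
            class = "transition_estimate")
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf("<transition_estimate> reactor '%s'\n", x$reactor_id))
  cat(sprintf("  linear window: [0, %g] h; fit X = %.4g + %.4g t\n",
              x$window_end_h, x$linear_intercept, x$linear_slope))
  cat(sprintf("  threshold (mean + %g SD): %.4g g/L\n", x$k_sd, x$threshold))
  if (is.na(x$t_s)) cat("  no transition found\n")
  else cat(sprintf("  t_s = %g h\n", x$t_s))
  invisible(x)
}
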