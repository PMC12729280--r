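#' Primary growth models
#'
#' Forward (noise-free) evaluation of the six growth formulations used
#' throughout the package. All biomass models share one contract: given a
#' vector of times in hours and a named parameter list, return biomass
#' concentration in g/L. The aeration-temperature rate surface
#' [monod_gauss()] maps (temperature, aeration) to a growth rate instead.
#'
#' @name growth_models
NULL

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  invisible(x)
}

#' Logistic growth curve (closed form)
#'
#' Closed-form solution of the logistic equation
#' \deqn{X(t) = \frac{K}{1 + \frac{K - X_0}{X_0} e^{-\mu t}}}
#' describing sigmoidal growth towards a carrying capacity.
#'
#' @param t time since inoculation, hours (vector allowed).
#' @param X0 initial biomass concentration, g/L (> 0).
#' @param K carrying capacity, g/L (> 0).
#' @param mu specific growth rate, 1/h.
#' @return biomass concentration, g/L.
#' @examples
#' logistic_growth(0, X0 = 0.33, K = 4.5, mu = 0.03)  # returns X0
#' @seealso [logistic_rate()] for the differential form.
#' @export
logistic_growth <- function(t, X0, K, mu) {
  .check_positive(X0, "X0"); .check_positive(K, "K")
  K / (1 + ((K - X0) / X0) * exp(-mu * t))
}

#' Logistic rate (right-hand side of the logistic ODE)
#'
#' \deqn{dX/dt = \mu X (1 - X/K)}
#'
#' @param X biomass concentration, g/L.
#' @inheritParams logistic_growth
#' @return growth rate, g/L/h.
#' @note parameters may be vectors (recycled against \code{X}), so a bank
#'   of logistic systems can be advanced in one call.
#' @export
logistic_rate <- function(X, K, mu) {
  if (any(!is.finite(K)) || any(K <= 0))
    stop("'K' must be positive and finite", call. = FALSE)
  mu * X * (1 - X / K)
}

#' Logistic growth with a lag phase
#'
#' Holds the culture at \code{X0} until \code{t_lag}, then follows the
#' logistic closed form with the clock shifted by the lag. Continuous at
#' \code{t_lag} by construction.
#'
#' @inheritParams logistic_growth
#' @param t_lag lag-phase duration, hours (>= 0).
#' @return biomass concentration, g/L.
#' @export
logistic_lag_growth <- function(t, X0, K, mu, t_lag) {
  .check_positive(X0, "X0"); .check_positive(K, "K")
  .check_nonneg(t_lag, "t_lag")
  ifelse(t < t_lag, X0, logistic_growth(pmax(t - t_lag, 0), X0, K, mu))
}

#' Modified Gompertz growth curve (Zwietering parameterisation)
#'
#' Asymmetric sigmoid
#' \deqn{X(t) = X_{max} \exp\{-\exp[\frac{\mu_{max} e}{X_{max}}(\lambda - t) + 1]\}}
#' where \eqn{e} is Euler's number, \code{mumax} is the maximum slope of the
#' curve (g/L/h, not a specific rate) and \code{lam} the lag duration. The
#' curve has no independent intercept: X(0) is implied by the three
#' parameters.
#'
#' @inheritParams logistic_growth
#' @param Xmax asymptotic biomass, g/L (> 0).
#' @param mumax maximum slope, g/L/h (>= 0).
#' @param lam lag duration, hours (>= 0).
#' @return biomass concentration, g/L.
#' @export
gompertz_growth <- function(t, Xmax, mumax, lam) {
  .check_positive(Xmax, "Xmax")
  .check_nonneg(mumax, "mumax"); .check_nonneg(lam, "lam")
  inner <- (mumax * exp(1) / Xmax) * (lam - t) + 1
  Xmax * exp(-exp(inner))
}

#' Baranyi-Roberts growth curve
#'
#' Smooth lag-to-exponential transition via the adjustment function
#' \deqn{A(t) = t + \frac{1}{\mu_{max}}
#'   \ln(e^{-\mu_{max} t} + e^{-\mu_{max}\lambda} - e^{-\mu_{max}(t+\lambda)})}
#' with log response
#' \deqn{y(t) = \mu_{max} A(t) -
#'   \ln\left(1 + \frac{e^{\mu_{max} A(t)} - 1}{e^C}\right),}
#' where \code{C} is the asymptote of \eqn{\ln(X/X_0)}. The function
#' returns concentration \eqn{X = X_0 e^{y}} so all models share one output
#' contract. Both logs are evaluated in log-sum-exp form so the curve stays
#' finite for \eqn{\mu_{max} t} well beyond 700.
#'
#' @inheritParams logistic_growth
#' @param mumax maximum specific growth rate, 1/h (>= 0).
#' @param lam lag duration, hours (>= 0).
#' @param C asymptotic value of ln(X/X0), dimensionless (>= 0).
#' @return biomass concentration, g/L.
#' @export
baranyi_growth <- function(t, X0, mumax, lam, C) {
  .check_positive(X0, "X0")
  .check_nonneg(mumax, "mumax"); .check_nonneg(lam, "lam")
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C < 0)
    stop("'C' must be a single non-negative finite number", call. = FALSE)
  # mumax -> 0 limit: A(t) -> t and y -> 0, so X stays at X0
  if (mumax < 1e-12) return(rep(X0, length(t)))
  # A(t): log(e^u + e^v - e^(u+v)) with u = -mumax*t, v = -mumax*lam;
  # all exponents are <= 0 so plain exp() cannot overflow, and the
  # argument equals 1 - (1-e^u)(1-e^v) in (0, 1].
  u <- -mumax * t
  v <- -mumax * lam
  At <- t + log(exp(u) + exp(v) - exp(u + v)) / mumax
  z <- mumax * At
  # y = z - log(1 + (e^z - 1) e^-C) = z + C - log(e^z + e^C - 1)
  m <- pmax(z, C)
  L <- m + log(exp(z - m) + exp(C - m) - exp(-m))
  X0 * exp(z + C - L)
}

#' Hybrid two-phase growth curve (linear then logistic)
#'
#' Linear growth \eqn{X = X_0 + a t} up to the stitch time \code{t_s}, then a
#' logistic approach to the carrying capacity that starts exactly at
#' \eqn{X(t_s) = X_0 + a t_s}:
#' \deqn{X(t) = \frac{K}{1 + \frac{K - X(t_s)}{X(t_s)} e^{-r (t - t_s)}},
#'   \quad t \ge t_s.}
#' Continuity at \code{t_s} holds by construction. The linear segment
#' reflects light/CO2-limited growth at low culture density.
#'
#' @inheritParams logistic_growth
#' @param a linear-phase slope, g/L/h (>= 0).
#' @param t_s transition (stitch) time, hours (>= 0).
#' @param r logistic rate of the saturation phase, 1/h (>= 0).
#' @return biomass concentration, g/L.
#' @export
hybrid_growth <- function(t, X0, a, t_s, K, r) {
  .check_positive(X0, "X0"); .check_positive(K, "K")
  .check_nonneg(a, "a"); .check_nonneg(t_s, "t_s"); .check_nonneg(r, "r")
  Xs <- X0 + a * t_s
  if (Xs >= K)
    stop("degenerate stitch: X0 + a*t_s must be below the carrying capacity K",
         call. = FALSE)
  ifelse(t < t_s,
         X0 + a * t,
         K / (1 + ((K - Xs) / Xs) * exp(-r * (t - t_s))))
}

#' Monod-by-Gauss aeration-temperature rate surface
#'
#' Growth rate as a function of sparging intensity \code{B} (vvm) and
#' temperature \code{T_C}:
#' \deqn{\mu(T, B) = \mu_{max} \frac{B}{K_B + B}
#'   \exp\left(-\frac{(T - T_{opt})^2}{2 \sigma^2}\right)}
#' The Monod term captures saturation of gas exchange with aeration; the
#' Gaussian term a thermal optimum. Temperature and aeration are assumed
#' independent (no cross term).
#'
#' @param T_C temperature, degrees C (vector allowed).
#' @param B sparging intensity, vvm (>= 0; vector allowed).
#' @param mumax maximum growth rate scale, g/L/h (> 0).
#' @param KB half-saturation aeration, vvm (> 0).
#' @param Topt optimal temperature, degrees C.
#' @param sigma thermal window width, degrees C (> 0).
#' @return growth rate, g/L/h.
#' @examples
#' monod_gauss(26, 0.5, mumax = 0.0136, KB = 0.5, Topt = 26, sigma = 3.3)
#' @export
monod_gauss <- function(T_C, B, mumax, KB, Topt, sigma) {
  .check_positive(mumax, "mumax"); .check_positive(KB, "KB")
  .check_positive(sigma, "sigma")
  if (any(B < 0)) stop("'B' must be non-negative", call. = FALSE)
  mumax * B / (KB + B) * exp(-(T_C - Topt)^2 / (2 * sigma^2))
}
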