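# Gating-variable kinetics.
#
# The spiking gates m, h, n follow alpha/beta transition-rate kinetics
# (shifted by VthNa / VthK); the T-channel gates p, q are given directly as
# steady-state/time-constant pairs (shifted by VthT). Steady states and
# time constants of the alpha/beta gates are
#   theta_inf = alpha/(alpha+beta),  tau = 1/(alpha+beta).

GATE_NAMES <- c("m", "h", "n", "p", "q")

# u/(exp(u/c)-1) with the removable singularity at u = 0 replaced by its
# analytic limit; used by alpha_m, beta_m, alpha_n.
.sgrowth <- function(u, c) {
  s <- u / c
  out <- u / expm1(s)
  small <- is.finite(s) & abs(s) < 1e-7
  if (any(small)) out[small] <- c - u[small] / 2
  out
}

# d/du of .sgrowth
.sgrowthDeriv <- function(u, c) {
  s <- u / c
  E <- expm1(s)
  out <- (E - s * exp(s)) / (E * E)
  small <- is.finite(s) & abs(s) < 1e-5
  if (any(small)) out[small] <- -0.5 + s[small] / 6
  out
}

.logistic <- function(s) 1 / (1 + exp(-s))

#' Transition rates of the alpha/beta gates
#'
#' The forward (\code{alpha}) and backward (\code{beta}) transition rates of
#' the spiking gates, in 1/ms. Removable singularities in
#' \eqn{\alpha_m, \beta_m, \alpha_n} (terms of the form
#' \eqn{a\,u/(e^{u/c}-1)}) are evaluated by their analytic limit when the
#' exponent magnitude falls below 1e-7.
#'
#' @param gate one of \code{"m"}, \code{"h"}, \code{"n"}.
#' @param V membrane potential (mV); vectorized.
#' @param params a [trnParams()] object.
#' @return rate(s) in 1/ms.
#' @export
gateAlpha <- function(gate, V, params) {
  switch(gate,
    m = 0.32 * .sgrowth(13 - V + params$VthNa, 4),
    h = 0.128 * exp((17 - V + params$VthNa) / 18),
    n = 0.032 * .sgrowth(15 - V + params$VthK, 5),
    stop("gate '", gate, "' has no alpha/beta form", call. = FALSE))
}

#' @rdname gateAlpha
#' @export
gateBeta <- function(gate, V, params) {
  switch(gate,
    m = 0.28 * .sgrowth(V - 40 - params$VthNa, 5),
    h = 4 * .logistic((V - 40 - params$VthNa) / 5),
    n = 0.5 * exp((10 - V + params$VthK) / 10),
    stop("gate '", gate, "' has no alpha/beta form", call. = FALSE))
}

#' Steady-state activation/inactivation curves
#'
#' \code{gateInf} returns \eqn{\theta_\infty(V)}: for m, h, n this is
#' \eqn{\alpha/(\alpha+\beta)}; p and q are logistic in the shifted voltage.
#' \code{gateTau} returns the voltage-dependent time constant \eqn{\tau(V)}
#' in ms. \code{gateInfDeriv} is the analytic derivative
#' \eqn{d\theta_\infty/dV}, needed by the reduced model's equivalent
#' potential dynamics. \code{gatePhi} is the fixed rate scale
#' \eqn{\phi_\theta}.
#'
#' @inheritParams gateAlpha
#' @param gate one of \code{"m"}, \code{"h"}, \code{"n"}, \code{"p"},
#'   \code{"q"}.
#' @return a numeric vector matching \code{V}.
#' @examples
#' p <- trnParams()
#' gateInf("q", p$VthT - 80, p)  # logistic midpoint: 0.5
#' @export
gateInf <- function(gate, V, params) {
  switch(gate,
    m = , h = , n = {
      a <- gateAlpha(gate, V, params)
      a / (a + gateBeta(gate, V, params))
    },
    p = .logistic((52 + V - params$VthT) / 7.4),
    q = .logistic(-(80 + V - params$VthT) / 5),
    stop("unknown gate '", gate, "'", call. = FALSE))
}

#' @rdname gateInf
#' @export
gateTau <- function(gate, V, params) {
  switch(gate,
    m = , h = , n = {
      1 / (gateAlpha(gate, V, params) + gateBeta(gate, V, params))
    },
    p = 3 + 1 / (exp((V + 27 - params$VthT) / 10) +
                   exp(-(V + 102 - params$VthT) / 15)),
    q = 85 + 1 / (exp((V + 48 - params$VthT) / 4) +
                    exp(-(V + 407 - params$VthT) / 50)),
    stop("unknown gate '", gate, "'", call. = FALSE))
}

# d(alpha)/dV and d(beta)/dV, analytic
.gateAlphaDeriv <- function(gate, V, params) {
  switch(gate,
    m = -0.32 * .sgrowthDeriv(13 - V + params$VthNa, 4),
    h = -gateAlpha("h", V, params) / 18,
    n = -0.032 * .sgrowthDeriv(15 - V + params$VthK, 5))
}

.gateBetaDeriv <- function(gate, V, params) {
  switch(gate,
    m = 0.28 * .sgrowthDeriv(V - 40 - params$VthNa, 5),
    h = {
      s <- .logistic((V - 40 - params$VthNa) / 5)
      4 * s * (1 - s) / 5
    },
    n = -gateBeta("n", V, params) / 10)
}

#' @rdname gateInf
#' @export
gateInfDeriv <- function(gate, V, params) {
  switch(gate,
    m = , h = , n = {
      a <- gateAlpha(gate, V, params)
      b <- gateBeta(gate, V, params)
      da <- .gateAlphaDeriv(gate, V, params)
      db <- .gateBetaDeriv(gate, V, params)
      (da * b - a * db) / (a + b)^2
    },
    p = {
      s <- gateInf("p", V, params)
      s * (1 - s) / 7.4
    },
    q = {
      s <- gateInf("q", V, params)
      -s * (1 - s) / 5
    },
    stop("unknown gate '", gate, "'", call. = FALSE))
}

#' @rdname gateInf
#' @export
gatePhi <- function(gate, params) {
  switch(gate,
    m = params$phi_m, h = params$phi_h, n = params$phi_n,
    p = params$phi_p, q = params$phi_q,
    stop("unknown gate '", gate, "'", call. = FALSE))
}

#' Evaluate a single kinetic expression
#'
#' Convenience accessor for the voltage-dependent kinetic functions of one
#' gate: the transition rates (\code{"alpha"}, \code{"beta"}; only the
#' alpha/beta gates m, h, n), the steady state (\code{"inf"}) and the time
#' constant (\code{"tau"}).
#'
#' @inheritParams gateInf
#' @param which one of \code{"alpha"}, \code{"beta"}, \code{"inf"},
#'   \code{"tau"}.
#' @return a numeric vector matching \code{V}.
#' @examples
#' p <- trnParams()
#' rateValue("m", "alpha", -42, p)  # analytic limit at the singular voltage
#' @export
rateValue <- function(gate, which, V, params) {
  if (!gate %in% GATE_NAMES)
    stop("unknown gate '", gate, "'", call. = FALSE)
  if (any(!is.finite(V))) stop("V must be finite", call. = FALSE)
  switch(match.arg(which, c("alpha", "beta", "inf", "tau")),
    alpha = gateAlpha(gate, V, params),
    beta  = gateBeta(gate, V, params),
    inf   = gateInf(gate, V, params),
    tau   = gateTau(gate, V, params))
}

#' Invert a steady-state curve: the equivalent potential
#'
#' Returns the equivalent potential \eqn{v_\theta = \theta_\infty^{-1}(\theta)}:
#' the voltage at which the gate's steady-state curve equals the given
#' fraction. Unique by strict monotonicity of \eqn{\theta_\infty}. The p and
#' q curves are inverted in closed form; m, h, n numerically by
#' \code{uniroot}. Fractions are clamped to the open interval
#' \eqn{[10^{-12}, 1-10^{-12}]}.
#'
#' @inheritParams gateInf
#' @param fraction gating fraction(s) in [0, 1].
#' @return equivalent potential(s) in mV.
#' @examples
#' p <- trnParams()
#' inverseSteadyState("q", 0.5, p)  # the q_inf midpoint voltage
#' @export
inverseSteadyState <- function(gate, fraction, params) {
  if (any(!is.finite(fraction) | fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]", call. = FALSE)
  f <- pmin(pmax(fraction, 1e-12), 1 - 1e-12)
  lg <- function(x) log(x / (1 - x))
  switch(gate,
    p = params$VthT - 52 + 7.4 * lg(f),
    q = params$VthT - 80 - 5 * lg(f),
    m = , h = , n = {
      vapply(f, function(fi) {
        stats::uniroot(function(v) gateInf(gate, v, params) - fi,
                       lower = -300, upper = 200, extendInt = "yes",
                       tol = 1e-12)$root
      }, numeric(1))
    },
    stop("unknown gate '", gate, "'", call. = FALSE))
}
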