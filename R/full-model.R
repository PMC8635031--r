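# The six-variable conductance-based TRN neuron model.
#
# State: membrane potential V (mV) and gating fractions m, h, n (spike
# currents) and p, q (T-type calcium). Voltage dynamics:
#   C dV/dt = -(I_L + I_KL + I_Na + I_K + I_T) + 1e-3*Isyn(t)/A
# with I_Na = gNa m^3 h (V-ENa), I_K = gK n^4 (V-EK),
# I_T = gT p^2 q (V-ET), and each gate relaxing as
#   dtheta/dt = phi * (theta_inf(V) - theta)/tau(V).

#' Full-model state vector
#'
#' Builds the named state vector of the six-variable model. With the
#' default \code{gates = "steady"} the five gating fractions are set to
#' their steady-state values at \code{V}.
#'
#' @param V membrane potential (mV).
#' @param gates either \code{"steady"} or a named vector with entries
#'   \code{m, h, n, p, q} in [0, 1].
#' @param params a [trnParams()] object.
#' @return named numeric vector \code{c(V, m, h, n, p, q)}.
#' @export
fullState <- function(V, gates = "steady", params) {
  if (identical(gates, "steady")) {
    g <- vapply(GATE_NAMES, function(th) gateInf(th, V, params), numeric(1))
  } else {
    if (!all(GATE_NAMES %in% names(gates)))
      stop("gates must name m, h, n, p, q", call. = FALSE)
    g <- unlist(gates)[GATE_NAMES]
    if (any(g < 0 | g > 1))
      stop("gating fractions must lie in [0, 1]", call. = FALSE)
  }
  c(V = unname(V), g)
}

#' Per-channel ionic current densities
#'
#' Evaluates the five membrane currents (uA/cm^2) of the full model at a
#' given state: \eqn{I_{Na} = g_{Na} m^3 h (V - E_{Na})},
#' \eqn{I_K = g_K n^4 (V - E_K)}, \eqn{I_T = g_T p^2 q (V - E_T)}, and the
#' two ohmic leaks. Positive values are outward.
#'
#' @param state named vector \code{c(V, m, h, n, p, q)} (see [fullState()]).
#' @param params a [trnParams()] object.
#' @return named vector \code{c(I_Na, I_K, I_T, I_L, I_KL)}.
#' @export
ionicCurrents <- function(state, params) {
  V <- state[["V"]]
  c(I_Na = params$gNa * state[["m"]]^3 * state[["h"]] * (V - params$ENa),
    I_K  = params$gK * state[["n"]]^4 * (V - params$EK),
    I_T  = params$gT * state[["p"]]^2 * state[["q"]] * (V - params$ET),
    I_L  = params$gL * (V - params$EL),
    I_KL = params$gKL * (V - params$EKL))
}

# scalar core: derivative given effective stimulus density (uA/cm^2)
.fullDeriv <- function(y, Ieff, params) {
  V <- y[1L]
  m <- min(max(y[2L], 0), 1); h <- min(max(y[3L], 0), 1)
  n <- min(max(y[4L], 0), 1); p <- min(max(y[5L], 0), 1)
  q <- min(max(y[6L], 0), 1)
  Iion <- params$gNa * m^3 * h * (V - params$ENa) +
    params$gK * n^4 * (V - params$EK) +
    params$gT * p^2 * q * (V - params$ET) +
    params$gL * (V - params$EL) + params$gKL * (V - params$EKL)
  am <- 0.32 * .sgrowth(13 - V + params$VthNa, 4)
  bm <- 0.28 * .sgrowth(V - 40 - params$VthNa, 5)
  ah <- 0.128 * exp((17 - V + params$VthNa) / 18)
  bh <- 4 * .logistic((V - 40 - params$VthNa) / 5)
  an <- 0.032 * .sgrowth(15 - V + params$VthK, 5)
  bn <- 0.5 * exp((10 - V + params$VthK) / 10)
  pinf <- .logistic((52 + V - params$VthT) / 7.4)
  taup <- 3 + 1 / (exp((V + 27 - params$VthT) / 10) +
                     exp(-(V + 102 - params$VthT) / 15))
  qinf <- .logistic(-(80 + V - params$VthT) / 5)
  tauq <- 85 + 1 / (exp((V + 48 - params$VthT) / 4) +
                      exp(-(V + 407 - params$VthT) / 50))
  c((Ieff - Iion) / params$C,
    params$phi_m * (am * (1 - m) - bm * m),
    params$phi_h * (ah * (1 - h) - bh * h),
    params$phi_n * (an * (1 - n) - bn * n),
    params$phi_p * (pinf - p) / taup,
    params$phi_q * (qinf - q) / tauq)
}

#' Right-hand side of the full model
#'
#' Time derivative of the six-variable state under a stimulus protocol.
#' The gate equations for m, h, n use the identity
#' \eqn{\phi[\alpha(1-\theta) - \beta\theta] =
#' \phi(\theta_\infty - \theta)/\tau}.
#'
#' @param t time (ms).
#' @param state named vector \code{c(V, m, h, n, p, q)}.
#' @param params a [trnParams()] object.
#' @param protocol a [stimProtocol()].
#' @return named vector of time derivatives.
#' @export
fullRHS <- function(t, state, params, protocol) {
  Ieff <- synCurrentDensity(protocolAmplitude(protocol, t), params)
  d <- .fullDeriv(unname(state[c("V", GATE_NAMES)]), Ieff, params)
  names(d) <- c("V", GATE_NAMES)
  d
}

# resting state: lowest root of the steady-state current balance, then a
# short relaxation to absorb focus transients
.fullRestingState <- function(params, Ieff = 0, settle = 500,
                              solver = solverOptions()) {
  f <- function(V) {
    sum(ionicCurrents(fullState(V, "steady", params), params)) - Ieff
  }
  Vg <- seq(-110, 0, by = 0.1)
  fv <- vapply(Vg, f, numeric(1))
  sc <- which(fv[-1] * fv[-length(fv)] < 0)
  V0 <- if (length(sc)) {
    stats::uniroot(f, c(Vg[sc[1]], Vg[sc[1] + 1]), tol = 1e-10)$root
  } else params$EL
  y0 <- fullState(V0, "steady", params)
  if (settle > 0) {
    sol <- .odeRun(y0, c(0, settle), "full", params, solver, Ieff = Ieff)
    y0 <- sol[nrow(sol), -1L]
  }
  y0
}

#' Simulate the full model
#'
#' Integrates the six-variable model over a stimulus protocol and returns a
#' trace of the state and the per-channel current densities.
#'
#' @param params a [trnParams()] object.
#' @param protocol a [stimProtocol()].
#' @param init \code{"steady"} (rest found at zero stimulus, then relaxed
#'   for \code{settle} ms) or a named state vector (see [fullState()]).
#' @param solver a [solverOptions()] list.
#' @param settle settling time (ms) used by \code{init = "steady"}.
#' @return a \code{"trnTrace"} data.frame with columns \code{t, V, m, h, n,
#'   p, q}, the five currents, and \code{I_stim} (the applied density,
#'   uA/cm^2).
#' @examples
#' \donttest{
#' p <- trnParams(EL = -77, gKL = 0.00793, gT = 2)
#' tr <- simulateFull(p, stepProtocol(-0.03, 0, 200, 400))
#' detectSpikes(tr)
#' }
#' @export
simulateFull <- function(params, protocol, init = "steady",
                         solver = solverOptions(), settle = 2000) {
  y0 <- if (identical(init, "steady")) {
    .fullRestingState(params, 0, settle, solver)
  } else {
    if (!all(c("V", GATE_NAMES) %in% names(init)))
      stop("init must name V, m, h, n, p, q", call. = FALSE)
    unlist(init)[c("V", GATE_NAMES)]
  }
  raw <- .integrateProtocol("full", y0, protocol, params, solver)
  for (g in GATE_NAMES) raw[[g]] <- pmin(pmax(raw[[g]], 0), 1)
  V <- raw$V
  tr <- data.frame(t = raw$t, V = V, m = raw$m, h = raw$h, n = raw$n,
                   p = raw$p, q = raw$q,
                   I_Na = params$gNa * raw$m^3 * raw$h * (V - params$ENa),
                   I_K = params$gK * raw$n^4 * (V - params$EK),
                   I_T = params$gT * raw$p^2 * raw$q * (V - params$ET),
                   I_L = params$gL * (V - params$EL),
                   I_KL = params$gKL * (V - params$EKL),
                   I_stim = synCurrentDensity(raw$I_stim_syn, params))
  structure(tr, class = c("trnTrace", "data.frame"),
            model = "full", params = params, protocol = protocol,
            solver = solver)
}
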