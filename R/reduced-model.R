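# The reduced three-variable model.
#
# x plays the role of the membrane potential, y the collapsed
# intermediate-gate potential (h, n, p), z the slow T-inactivation
# potential (v_q). Voltage dynamics:
#   C rho_V dx/dt = -gNa m_inf^3(x) h_inf(y) (x-ENa)
#                   - gK n_inf^4(y) (x-EK)
#                   - gT p_inf^2(y) q_inf(z) (x-ET)
#                   - I_L - I_KL + 1e-3*Isyn(t)/A,
# with rho_V recomputed at the current state. y and z follow weighted
# equivalent-potential relaxation; both nullclines are exactly the
# diagonal (dy/dt = 0 at y = x, dz/dt = 0 at z = x).

# floor applied to rho_V before dividing (prevents blow-up at pathological
# states)
.RHO_V_FLOOR <- 1e-6

# scalar core: d(x,y,z)/dt given effective stimulus density (uA/cm^2)
.reducedDeriv <- function(x, y, z, Ieff, params, k) {
  w <- .weightsCore(x, x, y, y, y, z, params, k)
  rho_V <- w[[1L]]
  if (rho_V < .RHO_V_FLOOR) {
    warning("rho_V below floor ", .RHO_V_FLOOR, "; clipped", call. = FALSE)
    rho_V <- .RHO_V_FLOOR
  }
  Fion <- fTotal(x, y, y, y, z, params)
  dx <- (Ieff - Fion) / (params$C * rho_V)
  # steepness convention for the collapsed y group: theta_inf' at the
  # relaxing variable itself (default, exact chain rule) or at the
  # driving voltage x; the two closures agree to first order near y = x.
  # The z row is the exact chain rule for z = v_q and always uses
  # q_inf'(z).
  at_x <- identical(params$steepness, "driving")
  sl <- function(g, v) gateInfDeriv(g, if (at_x) x else v, params)
  dy <- w[[3L]] * params$phi_h *
    (gateInf("h", x, params) - gateInf("h", y, params)) /
    (gateTau("h", x, params) * sl("h", y)) +
    w[[4L]] * params$phi_n *
      (gateInf("n", x, params) - gateInf("n", y, params)) /
      (gateTau("n", x, params) * sl("n", y)) +
    w[[5L]] * params$phi_p *
      (gateInf("p", x, params) - gateInf("p", y, params)) /
      (gateTau("p", x, params) * sl("p", y))
  dz <- params$phi_q *
    (gateInf("q", x, params) - gateInf("q", z, params)) /
    (gateTau("q", x, params) * gateInfDeriv("q", z, params))
  c(dx, dy, dz)
}

# fast (x, y) subsystem with z frozen as a parameter
.fastDeriv <- function(x, y, z, Ieff, params, k) {
  .reducedDeriv(x, y, z, Ieff, params, k)[1:2]
}

#' Right-hand side of the reduced model
#'
#' Time derivative of the reduced state \code{c(x, y, z)} under a stimulus
#' protocol. The grouping weights are recomputed at the current state with
#' \eqn{v_m} identified with \code{x} and \eqn{v_h, v_n, v_p} with
#' \code{y}.
#'
#' @param t time (ms).
#' @param state named vector \code{c(x, y, z)} (mV).
#' @param params a [trnParams()] object.
#' @param protocol a [stimProtocol()].
#' @param k weight constant \eqn{\rho_p}; defaults to \code{params$k}.
#' @return named vector \code{c(x, y, z)} of derivatives (mV/ms).
#' @export
reducedRHS <- function(t, state, params, protocol, k = params$k) {
  Ieff <- synCurrentDensity(protocolAmplitude(protocol, t), params)
  d <- .reducedDeriv(state[["x"]], state[["y"]], state[["z"]], Ieff,
                     params, k)
  names(d) <- c("x", "y", "z")
  d
}

#' Recover per-channel currents from the reduced state
#'
#' The channel structure of the full model survives reduction: each current
#' is re-evaluated with \eqn{m_\infty(x)}, \eqn{h_\infty(y)},
#' \eqn{n_\infty(y)}, \eqn{p_\infty(y)} and \eqn{q_\infty(z)} in place of
#' the gating fractions. Their sum equals the ionic term of the reduced
#' voltage equation.
#'
#' @param state named vector \code{c(x, y, z)} (mV).
#' @param params a [trnParams()] object.
#' @return named vector \code{c(I_Na, I_K, I_T, I_L, I_KL)} (uA/cm^2,
#'   positive outward).
#' @export
recoverChannelCurrents <- function(state, params) {
  x <- state[["x"]]; y <- state[["y"]]; z <- state[["z"]]
  c(I_Na = params$gNa * gateInf("m", x, params)^3 *
      gateInf("h", y, params) * (x - params$ENa),
    I_K = params$gK * gateInf("n", y, params)^4 * (x - params$EK),
    I_T = params$gT * gateInf("p", y, params)^2 *
      gateInf("q", z, params) * (x - params$ET),
    I_L = params$gL * (x - params$EL),
    I_KL = params$gKL * (x - params$EKL))
}

# resting state of the reduced model: lowest diagonal equilibrium, then a
# short relaxation
.reducedRestingState <- function(params, k = params$k, Ieff = 0,
                                 settle = 500, solver = solverOptions()) {
  f <- function(V) fTotal(V, V, V, V, V, params) - Ieff
  Vg <- seq(-110, 0, by = 0.1)
  fv <- f(Vg)
  sc <- which(fv[-1] * fv[-length(fv)] < 0)
  V0 <- if (length(sc)) {
    stats::uniroot(f, c(Vg[sc[1]], Vg[sc[1] + 1]), tol = 1e-10)$root
  } else params$EL
  y0 <- c(x = V0, y = V0, z = V0)
  if (settle > 0) {
    sol <- .odeRun(y0, c(0, settle), "reduced", params, solver, k, Ieff)
    y0 <- sol[nrow(sol), -1L]
    names(y0) <- c("x", "y", "z")
  }
  y0
}

#' Simulate the reduced model
#'
#' Integrates the three-variable model over a stimulus protocol. The trace
#' carries the reduced state and the per-channel currents recovered from
#' it (see [recoverChannelCurrents()]).
#'
#' @inheritParams simulateFull
#' @param init \code{"steady"} (lowest diagonal equilibrium at zero
#'   stimulus, relaxed for \code{settle} ms) or a named vector
#'   \code{c(x, y, z)}.
#' @param k weight constant; defaults to \code{params$k}.
#' @return a \code{"trnTrace"} data.frame with columns \code{t, x, y, z},
#'   the five recovered currents, and \code{I_stim}.
#' @examples
#' \donttest{
#' p <- trnParams(gKL = 0.0152)
#' tr <- simulateReduced(p, stepProtocol(-0.05, 0, 200, 1000))
#' detectSpikes(tr)
#' }
#' @export
simulateReduced <- function(params, protocol, init = "steady",
                            solver = solverOptions(), settle = 2000,
                            k = params$k) {
  y0 <- if (identical(init, "steady")) {
    .reducedRestingState(params, k, 0, settle, solver)
  } else {
    if (!all(c("x", "y", "z") %in% names(init)))
      stop("init must name x, y, z", call. = FALSE)
    unlist(init)[c("x", "y", "z")]
  }
  raw <- .integrateProtocol("reduced", y0, protocol, params, solver, k)
  x <- raw$x; y <- raw$y; z <- raw$z
  tr <- data.frame(t = raw$t, x = x, y = y, z = z,
                   I_Na = params$gNa * gateInf("m", x, params)^3 *
                     gateInf("h", y, params) * (x - params$ENa),
                   I_K = params$gK * gateInf("n", y, params)^4 *
                     (x - params$EK),
                   I_T = params$gT * gateInf("p", y, params)^2 *
                     gateInf("q", z, params) * (x - params$ET),
                   I_L = params$gL * (x - params$EL),
                   I_KL = params$gKL * (x - params$EKL),
                   I_stim = synCurrentDensity(raw$I_stim_syn, params))
  structure(tr, class = c("trnTrace", "data.frame"),
            model = "reduced", params = params, protocol = protocol,
            solver = solver, k = k)
}
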