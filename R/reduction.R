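# Reduction machinery: equivalent potentials, the ionic current expressed
# through them, its partial derivatives, and the optimal grouping weights.
#
# Every gating fraction theta is mapped to the equivalent potential
# v_theta = theta_inf^{-1}(theta), making all state variables commensurate
# (mV). The six equivalent-potential variables are then collapsed into
#   x = rho_V V + rho_m v_m          (fast group)
#   y = rho_h v_h + rho_n v_n + rho_p v_p   (intermediate group)
#   z = v_q                          (slow group)
# with non-negative weights normalized within each group. The weights
# minimize the first-order discrepancy between the reduced and full voltage
# dynamics, which has the closed-form solution implemented in
# computeWeights(): rho_p is pinned to a small constant k, rho_h and rho_n
# split (1-k) in proportion to dF/dv_h and dF/dv_n, and rho_V solves a
# quadratic balancing dF/dV, dF/dv_m and the m-gate relaxation rate
# C*phi_m/tau_m.

#' Equivalent potentials of a full-model state
#'
#' Converts the five gating fractions of a full-model state into their
#' equivalent potentials \eqn{v_\theta = \theta_\infty^{-1}(\theta)}.
#'
#' @param state named vector \code{c(V, m, h, n, p, q)}.
#' @param params a [trnParams()] object.
#' @return named vector \code{c(v_m, v_h, v_n, v_p, v_q)} (mV).
#' @export
equivalentPotentials <- function(state, params) {
  v <- vapply(GATE_NAMES, function(th)
    inverseSteadyState(th, state[[th]], params), numeric(1))
  names(v) <- paste0("v_", GATE_NAMES)
  v
}

#' Total ionic current through equivalent potentials
#'
#' The membrane current density (uA/cm^2) with each gating fraction
#' replaced by the steady-state curve evaluated at its equivalent
#' potential:
#' \deqn{F = g_{Na} m_\infty^3(v_m) h_\infty(v_h)(V-E_{Na})
#'       + g_K n_\infty^4(v_n)(V-E_K)
#'       + g_T p_\infty^2(v_p) q_\infty(v_q)(V-E_T) + I_L + I_{KL}.}
#' By default \code{v_m = V}, matching the reduced voltage equation where
#' the fast activation is slaved to the membrane potential.
#'
#' @param V membrane potential (mV).
#' @param v_h,v_n,v_p,v_q equivalent potentials (mV).
#' @param params a [trnParams()] object.
#' @param v_m equivalent potential of the m gate; defaults to \code{V}.
#' @return current density (uA/cm^2), positive outward.
#' @export
fTotal <- function(V, v_h, v_n, v_p, v_q, params, v_m = V) {
  params$gNa * gateInf("m", v_m, params)^3 * gateInf("h", v_h, params) *
    (V - params$ENa) +
    params$gK * gateInf("n", v_n, params)^4 * (V - params$EK) +
    params$gT * gateInf("p", v_p, params)^2 * gateInf("q", v_q, params) *
      (V - params$ET) +
    params$gL * (V - params$EL) + params$gKL * (V - params$EKL)
}

#' Partial derivatives of the ionic current
#'
#' Analytic partial derivatives of [fTotal()] with respect to the membrane
#' potential and the equivalent potentials of the m, h, n and p gates —
#' the ingredients of the closed-form reduction weights.
#'
#' @inheritParams fTotal
#' @return named vector \code{c(dV, dv_m, dv_h, dv_n, dv_p)}.
#' @export
partialsOfF <- function(V, v_m, v_h, v_n, v_p, v_q, params) {
  V <- unname(V); v_m <- unname(v_m); v_h <- unname(v_h)
  v_n <- unname(v_n); v_p <- unname(v_p); v_q <- unname(v_q)
  minf <- gateInf("m", v_m, params)
  hinf <- gateInf("h", v_h, params)
  ninf <- gateInf("n", v_n, params)
  pinf <- gateInf("p", v_p, params)
  qinf <- gateInf("q", v_q, params)
  c(dV = params$gNa * minf^3 * hinf + params$gK * ninf^4 +
      params$gT * pinf^2 * qinf + params$gL + params$gKL,
    dv_m = 3 * params$gNa * minf^2 * gateInfDeriv("m", v_m, params) *
      hinf * (V - params$ENa),
    dv_h = params$gNa * minf^3 * gateInfDeriv("h", v_h, params) *
      (V - params$ENa),
    dv_n = 4 * params$gK * ninf^3 * gateInfDeriv("n", v_n, params) *
      (V - params$EK),
    dv_p = 2 * params$gT * pinf * gateInfDeriv("p", v_p, params) * qinf *
      (V - params$ET))
}

# scalar fast path used inside the reduced RHS: returns
# c(rho_V, rho_m, rho_h, rho_n, rho_p) without class dressing.
# Root policy for rho_V: prefer the principal quadratic root; fall back to
# the companion root, then clamp into [0,1].
.weightsCore <- function(V, v_m, v_h, v_n, v_p, v_q, params, k,
                         warn = FALSE) {
  P <- partialsOfF(V, v_m, v_h, v_n, v_p, v_q, params)
  Fh <- P[["dv_h"]]; Fn <- P[["dv_n"]]
  den <- Fh + Fn
  if (!is.finite(den) || abs(den) < 1e-300) {
    rho_h <- rho_n <- (1 - k) / 2
  } else {
    rho_h <- (1 - k) * Fh / den
    rho_n <- (1 - k) * Fn / den
  }
  a <- params$C * params$phi_m / gateTau("m", V, params)
  B <- P[["dV"]]; D <- P[["dv_m"]]
  BD <- B + D
  if (abs(BD) < 1e-12) {
    rho_V <- a / (a + B)
  } else {
    disc <- (a + B)^2 - 4 * a * BD
    if (disc < 0) {
      rho_V <- NA_real_
    } else {
      r1 <- (-(a + B) + sqrt(disc)) / (-2 * BD)
      r2 <- (-(a + B) - sqrt(disc)) / (-2 * BD)
      rho_V <- if (r1 >= 0 && r1 <= 1) r1 else r2
    }
    if (!is.finite(rho_V) || rho_V < 0 || rho_V > 1) {
      if (warn)
        warning("no admissible rho_V root in [0,1]; clamping", call. = FALSE)
      rho_V <- min(max(if (is.finite(rho_V)) rho_V else a / (a + B), 0), 1)
    }
  }
  c(rho_V = rho_V, rho_m = 1 - rho_V,
    rho_h = rho_h, rho_n = rho_n, rho_p = k)
}

#' Optimal grouping weights
#'
#' Computes the five reduction weights at a given equivalent-potential
#' state: \eqn{\rho_p = k}; \eqn{\rho_h} and \eqn{\rho_n} share
#' \eqn{1 - k} in proportion to \eqn{\partial F/\partial v_h} and
#' \eqn{\partial F/\partial v_n}; \eqn{\rho_V} is the quadratic root
#' balancing \eqn{\partial F/\partial V}, \eqn{\partial F/\partial v_m} and
#' the m-gate rate \eqn{C\phi_m/\tau_m(V)}, chosen in [0, 1] (clamped with
#' a warning when no admissible root exists); \eqn{\rho_m = 1 - \rho_V}.
#' The weights are state-dependent and are recomputed at every evaluation
#' of the reduced vector field.
#'
#' @inheritParams partialsOfF
#' @param k the fixed value of \eqn{\rho_p}; defaults to \code{params$k}.
#' @return an object of class \code{"reductionWeights"}: a named list with
#'   \code{rho_V, rho_m, rho_h, rho_n, rho_p} and \code{k}.
#' @examples
#' p <- trnParams()
#' w <- computeWeights(-65, -65, -65, -65, -65, -65, p)
#' w$rho_V + w$rho_m  # 1
#' @export
computeWeights <- function(V, v_m, v_h, v_n, v_p, v_q, params,
                           k = params$k) {
  if (k <= 0 || k >= 1) stop("k must lie strictly in (0, 1)", call. = FALSE)
  w <- .weightsCore(V, v_m, v_h, v_n, v_p, v_q, params, k, warn = TRUE)
  structure(c(as.list(w), list(k = k)), class = "reductionWeights")
}

#' @export
print.reductionWeights <- function(x, ...) {
  cat("Reduction weights (state-dependent)\n")
  cat(sprintf("  rho_V = %.6f, rho_m = %.6f\n", x$rho_V, x$rho_m))
  cat(sprintf("  rho_h = %.6f, rho_n = %.6f, rho_p = %.6f (k = %g)\n",
              x$rho_h, x$rho_n, x$rho_p, x$k))
  invisible(x)
}

#' Collapse a full-model state to the reduced variables
#'
#' Converts a six-variable state to the three reduced coordinates by
#' computing the equivalent potentials and the grouping weights at that
#' state: \eqn{x = \rho_V V + \rho_m v_m},
#' \eqn{y = \rho_h v_h + \rho_n v_n + \rho_p v_p}, \eqn{z = v_q}.
#'
#' @inheritParams equivalentPotentials
#' @param k weight constant; defaults to \code{params$k}.
#' @return named vector \code{c(x, y, z)} (mV).
#' @export
reduceState <- function(state, params, k = params$k) {
  v <- equivalentPotentials(state, params)
  w <- .weightsCore(state[["V"]], v[["v_m"]], v[["v_h"]], v[["v_n"]],
                    v[["v_p"]], v[["v_q"]], params, k)
  c(x = unname(w[["rho_V"]] * state[["V"]] + w[["rho_m"]] * v[["v_m"]]),
    y = unname(w[["rho_h"]] * v[["v_h"]] + w[["rho_n"]] * v[["v_n"]] +
                 w[["rho_p"]] * v[["v_p"]]),
    z = unname(v[["v_q"]]))
}
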