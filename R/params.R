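#' Parameter set for the TRN neuron model
#'
#' Constructs the full set of biophysical parameters shared by the
#' six-variable conductance model and its three-variable reduction: membrane
#' capacitance and area, maximal conductances and reversal potentials of the
#' fast sodium (\eqn{I_{Na}}), delayed-rectifier potassium (\eqn{I_K}),
#' low-threshold T-type calcium (\eqn{I_T}) and the two leak currents
#' (\eqn{I_L}, \eqn{I_{KL}}), the kinetic shift thresholds, the fixed rate
#' scales \eqn{\phi_\theta}, and the slow-group weight constant \code{k}.
#'
#' The defaults are the analysis set used throughout the bifurcation work
#' (\code{gT = 2.25}, \code{gKL = 0.0065}, \code{EL = -70}); simulation
#' presets override individual values (see [presetConfig()]).
#'
#' @param gT,gKL,gNa,gK,gL maximal conductances (mS/cm^2).
#' @param EL,EKL,ENa,EK,ET reversal potentials (mV).
#' @param C membrane capacitance (uF/cm^2).
#' @param A membrane area (cm^2); used to normalize the synaptic current
#'   (see [synCurrentDensity()]).
#' @param VthNa,VthK,VthT kinetic shift thresholds (mV) entering the gating
#'   rate functions.
#' @param phi_m,phi_h,phi_n,phi_p,phi_q dimensionless rate scales of the
#'   gating variables.
#' @param k the fixed weight of the T-channel activation equivalent
#'   potential in the reduced intermediate variable, \eqn{\rho_p = k};
#'   must lie strictly in (0, 1).
#' @param steepness where the steady-state slope \eqn{\theta_\infty'} in
#'   the relaxation of the collapsed intermediate variable y is
#'   evaluated: \code{"local"} (default) at the relaxing variable itself
#'   — the exact equivalent-potential chain rule — or \code{"driving"}
#'   at the instantaneous membrane potential x. The two closures agree
#'   to first order near the diagonal \eqn{y = x}; see the methods
#'   vignette for the trade-off between them.
#' @return An object of class \code{"trnParams"} (a named list).
#' @examples
#' p <- trnParams()
#' p$gT
#' @export
trnParams <- function(gT = 2.25, gKL = 0.0065, EL = -70,
                      C = 1, A = 1.43e-4,
                      gL = 0.06, gNa = 100, gK = 10,
                      EKL = -100, ENa = 50, EK = -100, ET = 120,
                      VthNa = -55, VthK = -55, VthT = -3,
                      phi_m = 1, phi_h = 1, phi_n = 1,
                      phi_p = 6.9, phi_q = 3.7,
                      k = 0.01, steepness = c("local", "driving")) {
  steepness <- match.arg(steepness)
  p <- list(C = C, A = A,
            gL = gL, gKL = gKL, gNa = gNa, gK = gK, gT = gT,
            EL = EL, EKL = EKL, ENa = ENa, EK = EK, ET = ET,
            VthNa = VthNa, VthK = VthK, VthT = VthT,
            phi_m = phi_m, phi_h = phi_h, phi_n = phi_n,
            phi_p = phi_p, phi_q = phi_q,
            k = k, steepness = steepness)
  class(p) <- "trnParams"
  validateParams(p)
  p
}

#' Validate a TRN parameter set
#'
#' Checks the structural invariants of a parameter set: non-negative
#' conductances, positive capacitance and area, finite reversal potentials
#' and thresholds, and \code{k} strictly inside (0, 1).
#'
#' @param p a \code{"trnParams"} object or plain named list.
#' @return \code{p}, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validateParams <- function(p) {
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", field, "' must be a single finite number",
           call. = FALSE)
    v
  }
  for (g in c("gL", "gKL", "gNa", "gK", "gT"))
    if (num1(g) < 0) stop("conductance '", g, "' must be >= 0", call. = FALSE)
  if (num1("C") <= 0) stop("capacitance 'C' must be > 0", call. = FALSE)
  if (num1("A") <= 0) stop("membrane area 'A' must be > 0", call. = FALSE)
  for (f in c("EL", "EKL", "ENa", "EK", "ET", "VthNa", "VthK", "VthT",
              "phi_m", "phi_h", "phi_n", "phi_p", "phi_q")) num1(f)
  kk <- num1("k")
  if (kk <= 0 || kk >= 1) stop("'k' must lie strictly in (0, 1)", call. = FALSE)
  if (!identical(p$steepness, "driving") && !identical(p$steepness, "local"))
    stop("'steepness' must be \"driving\" or \"local\"", call. = FALSE)
  invisible(p)
}

#' Update a parameter set
#'
#' Returns a copy of \code{p} with the named fields replaced, re-validated.
#' Unknown fields are an error.
#'
#' @param p a \code{"trnParams"} object.
#' @param ... named replacement values, e.g. \code{gKL = 0.0152}.
#' @return a new \code{"trnParams"} object.
#' @export
updateParams <- function(p, ...) {
  upd <- list(...)
  if (length(upd) == 0L) return(p)
  if (is.null(names(upd)) || any(names(upd) == ""))
    stop("all replacement values must be named", call. = FALSE)
  bad <- setdiff(names(upd), names(p))
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  p[names(upd)] <- upd
  class(p) <- "trnParams"
  validateParams(p)
  p
}

#' @export
print.trnParams <- function(x, ...) {
  cat("TRN neuron model parameters\n")
  cat(sprintf("  C = %g uF/cm^2, A = %g cm^2\n", x$C, x$A))
  cat(sprintf("  gNa = %g, gK = %g, gT = %g, gL = %g, gKL = %g mS/cm^2\n",
              x$gNa, x$gK, x$gT, x$gL, x$gKL))
  cat(sprintf("  ENa = %g, EK = %g, ET = %g, EL = %g, EKL = %g mV\n",
              x$ENa, x$EK, x$ET, x$EL, x$EKL))
  cat(sprintf("  VthNa = %g, VthK = %g, VthT = %g mV\n",
              x$VthNa, x$VthK, x$VthT))
  cat(sprintf("  phi: m=%g h=%g n=%g p=%g q=%g;  k = %g (steepness: %s)\n",
              x$phi_m, x$phi_h, x$phi_n, x$phi_p, x$phi_q, x$k,
              x$steepness))
  invisible(x)
}
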