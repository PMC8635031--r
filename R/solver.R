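# Integration plumbing shared by the full and reduced simulators. The
# right-hand sides are evaluated in compiled code (src/trn.c) for speed;
# fullRHS()/reducedRHS() are the reference R implementations of the same
# vector fields and the two are cross-checked in the test suite.

#' Solver options for the model simulators
#'
#' @param method \code{"lsoda"} (adaptive, default) or \code{"rk4"}
#'   (fixed-step, for strict step-size control and reproducibility checks).
#' @param rtol,atol relative/absolute tolerances of the adaptive solver.
#' @param dt fixed step (ms) used by \code{"rk4"}.
#' @param dt_out output sampling interval (ms).
#' @param hmax maximum internal step (ms) of the adaptive solver.
#' @return a named list of class \code{"solverOptions"}.
#' @export
solverOptions <- function(method = c("lsoda", "rk4"),
                          rtol = 1e-8, atol = 1e-10,
                          dt = 0.01, dt_out = 0.05, hmax = NULL) {
  method <- match.arg(method)
  stopifnot(rtol > 0, atol > 0, dt > 0, dt_out > 0)
  structure(list(method = method, rtol = rtol, atol = atol,
                 dt = dt, dt_out = dt_out, hmax = hmax),
            class = "solverOptions")
}

# parameter vector handed to the compiled derivatives; the layout is fixed
# by src/trn.c
.parmVector <- function(params, k = params$k, Ieff = 0, z = 0) {
  c(params$C, params$A, params$gL, params$gKL, params$gNa, params$gK,
    params$gT, params$EL, params$EKL, params$ENa, params$EK, params$ET,
    params$VthNa, params$VthK, params$VthT,
    params$phi_m, params$phi_h, params$phi_n, params$phi_p, params$phi_q,
    k, Ieff, z, as.numeric(identical(params$steepness, "driving")))
}

.MODEL_FUNCS <- c(full = "trn_full_derivs", reduced = "trn_reduced_derivs",
                  fast = "trn_fast_derivs")

# one constant-stimulus integration leg on an explicit time grid
.odeRun <- function(y0, times, model, params, solver, k = params$k,
                    Ieff = 0, z = 0) {
  pv <- .parmVector(params, k, Ieff, z)
  sol <- withCallingHandlers(
    if (solver$method == "rk4") {
      t0 <- times[1]; t1 <- times[length(times)]
      fine <- seq(t0, t1, by = solver$dt)
      if (fine[length(fine)] < t1 - 1e-9) fine <- c(fine, t1)
      full <- deSolve::rk4(y = y0, times = fine,
                           func = .MODEL_FUNCS[[model]],
                           parms = pv, dllname = "trnreduce",
                           initfunc = "trn_initmod")
      full[findInterval(times, fine), , drop = FALSE]
    } else {
      deSolve::ode(y = y0, times = times, func = .MODEL_FUNCS[[model]],
                   parms = pv, dllname = "trnreduce",
                   initfunc = "trn_initmod", method = "lsoda",
                   rtol = solver$rtol, atol = solver$atol,
                   hmax = if (is.null(solver$hmax)) Inf else solver$hmax,
                   maxsteps = 50000)
    },
    warning = function(w) {
      if (grepl("step size|too much accuracy|istate|maxsteps",
                conditionMessage(w), ignore.case = TRUE))
        stop("integration failure near t = ",
             round(times[length(times)], 3), " ms: ", conditionMessage(w),
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  sol
}

# integrate across the piecewise-constant protocol; returns a data.frame
# with t, the state columns, and the applied Isyn
.integrateProtocol <- function(model, y0, protocol, params, solver,
                               k = params$k) {
  pieces <- .protocolPieces(protocol)
  state <- y0
  out <- vector("list", nrow(pieces))
  for (i in seq_len(nrow(pieces))) {
    t0 <- pieces$t0[i]; t1 <- pieces$t1[i]
    times <- seq(t0, t1, by = solver$dt_out)
    if (times[length(times)] < t1 - 1e-9) times <- c(times, t1)
    Ieff <- synCurrentDensity(pieces$amplitude[i], params)
    sol <- as.data.frame(.odeRun(state, times, model, params, solver,
                                 k, Ieff))
    names(sol)[1] <- "t"
    sol$I_stim_syn <- pieces$amplitude[i]
    state <- unlist(sol[nrow(sol), names(y0)])
    if (any(!is.finite(state)))
      stop("integration failure (non-finite state) near t = ",
           round(t1, 3), " ms", call. = FALSE)
    out[[i]] <- if (i == 1L) sol else sol[-1L, , drop = FALSE]
  }
  do.call(rbind, out)
}
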