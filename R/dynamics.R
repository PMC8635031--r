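# Fast-slow bifurcation toolkit for the reduced model.
#
# The slow variable z is frozen as a parameter of the fast (x, y)
# subsystem. Equilibria of the fast subsystem lie on the diagonal y = x
# and are the roots of the current-voltage relation I(V, z); the
# bifurcation detectors bisect on root counts (fold), limit-cycle
# existence (saddle-homoclinic, fold-cycle) and eigenvalue sign changes
# (Andronov-Hopf) respectively.

#' Current-voltage relation of the reduced model
#'
#' The net membrane current \eqn{I(V, z)} (uA/cm^2) obtained by setting
#' the intermediate variable to its nullcline value \eqn{y = V} and
#' treating the slow variable \code{z} as a parameter, minus the applied
#' stimulus density. Zeros of \eqn{I(V, z)} are the equilibria of the
#' fast subsystem.
#'
#' @param V membrane potential(s), mV; vectorized.
#' @param z slow variable (mV).
#' @param params a [trnParams()] object.
#' @param Isyn applied current on the Isyn scale (nA; see
#'   [synCurrentDensity()]).
#' @return net current density (uA/cm^2).
#' @examples
#' p <- trnParams()
#' sum(abs(diff(sign(ivRelation(seq(-90, 0, 0.05), -65, p)))) > 0)  # 3 roots
#' @export
ivRelation <- function(V, z, params, Isyn = 0) {
  fTotal(V, V, V, V, z, params) - synCurrentDensity(Isyn, params)
}

# all sign-change roots of f on [lo, hi] scanned at `step`, refined by
# uniroot
.scanRoots <- function(f, lo, hi, step = 0.01) {
  Vg <- seq(lo, hi, by = step)
  fv <- f(Vg)
  idx <- which(fv[-1L] * fv[-length(fv)] < 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(f, c(Vg[i], Vg[i + 1L]),
                   f.lower = fv[i], f.upper = fv[i + 1L],
                   tol = 1e-12)$root, numeric(1))
  exact <- Vg[fv == 0]
  sort(unique(c(roots, exact)))
}

.countIVRoots <- function(z, params, Isyn = 0, Vrange = c(-100, 20),
                          step = 0.01) {
  length(.scanRoots(function(V) ivRelation(V, z, params, Isyn),
                    Vrange[1], Vrange[2], step))
}

# central-difference Jacobian of a vector field f: R^n -> R^n
.numJacobian <- function(f, x0, eps = 1e-6) {
  n <- length(x0)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dx <- numeric(n); dx[j] <- eps
    J[, j] <- (f(x0 + dx) - f(x0 - dx)) / (2 * eps)
  }
  J
}

#' Classify an equilibrium from its eigenvalues
#'
#' Standard linear-stability labels: \emph{focus} if a complex-conjugate
#' pair is present, \emph{node} otherwise; \emph{stable} iff all real
#' parts are negative; \emph{saddle} when real parts have both signs. A
#' real part within \code{tol} of zero raises a \code{"marginal"}
#' attribute instead of forcing a class.
#'
#' @param eigenvalues complex vector (2 or 3 values, 1/ms).
#' @param tol margin below which a real part counts as zero.
#' @return classification string; attribute \code{marginal} flags a
#'   near-zero real part.
#' @export
classifyStability <- function(eigenvalues, tol = 1e-9) {
  re <- Re(eigenvalues)
  marginal <- any(abs(re) < tol)
  focus <- any(abs(Im(eigenvalues)) > tol)
  label <- if (focus) {
    if (all(re < 0)) "stable focus" else "unstable focus"
  } else if (all(re < 0)) {
    "stable node"
  } else if (all(re > 0)) {
    "unstable node"
  } else {
    "saddle"
  }
  attr(label, "marginal") <- marginal
  label
}

.makeFixedPoint <- function(V, y, z, subsystem, J, residual) {
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(V = V, y = y, z = z, subsystem = subsystem,
                 eigenvalues = ev,
                 classification = classifyStability(ev),
                 residual = residual),
            class = "fixedPoint")
}

#' @export
print.fixedPoint <- function(x, ...) {
  cat(sprintf("%s fixed point at V = %.4f mV (%s)\n", x$subsystem, x$V,
              x$classification))
  cat("  eigenvalues:",
      paste(sprintf("%.5g%+.5gi", Re(x$eigenvalues), Im(x$eigenvalues)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Equilibria of the fast subsystem
#'
#' Locates every root of the I-V relation on \code{Vrange} (dense sign
#' scan plus bisection refinement) with the slow variable \code{z} frozen,
#' and classifies each by the eigenvalues of the 2x2 Jacobian of the
#' fast \code{(x, y)} subsystem at \code{(V, y = V)}.
#'
#' @inheritParams ivRelation
#' @param k weight constant; defaults to \code{params$k}.
#' @param Vrange voltage scan range (mV).
#' @param step scan grid step (mV).
#' @return list of \code{"fixedPoint"} objects in increasing V order.
#' @export
findEquilibriaFast <- function(z, Isyn = 0, params, k = params$k,
                               Vrange = c(-100, 20), step = 0.01) {
  Ieff <- synCurrentDensity(Isyn, params)
  roots <- .scanRoots(function(V) ivRelation(V, z, params, Isyn),
                      Vrange[1], Vrange[2], step)
  lapply(roots, function(V0) {
    f2 <- function(u) .fastDeriv(u[1L], u[2L], z, Ieff, params, k)
    J <- .numJacobian(f2, c(V0, V0))
    .makeFixedPoint(V0, V0, z, "fast-2D", J, max(abs(f2(c(V0, V0)))))
  })
}

#' Probe the fast subsystem for a spiking limit cycle
#'
#' Integrates the fast \code{(x, y)} subsystem at frozen \code{z} from a
#' standardized superthreshold initial condition (\code{x0 = -20} mV,
#' \code{y0 = z}), discards a transient, and tests for sustained
#' periodicity via upward threshold crossings. Reports amplitude extremes
#' and the period, or convergence to an equilibrium. An undecided outcome
#' within the time budget is returned as \code{exists = NA}
#' (status \code{"inconclusive"}), never silently as absence.
#'
#' @inheritParams findEquilibriaFast
#' @param x0,y0 initial condition (mV).
#' @param transient settling time discarded before analysis (ms).
#' @param window observation window (ms).
#' @param threshold spike-crossing threshold used for periodicity (mV).
#' @param solver a [solverOptions()]; the default probe tolerance is
#'   rtol 1e-6.
#' @return list of class \code{"cycleProbe"}: \code{exists}
#'   (TRUE/FALSE/NA), \code{V_max}, \code{V_min}, \code{period} (ms),
#'   \code{n_spikes}, \code{status}.
#' @export
limitCycleProbe <- function(z, Isyn = 0, params, k = params$k,
                            x0 = -20, y0 = z,
                            transient = 200, window = 500,
                            threshold = -20,
                            solver = solverOptions(rtol = 1e-6,
                                                   atol = 1e-8)) {
  Ieff <- synCurrentDensity(Isyn, params)
  times <- seq(0, transient + window, by = solver$dt_out)
  sol <- .odeRun(c(x = x0, y = y0), times, "fast", params, solver, k,
                 Ieff, z = z)
  df <- as.data.frame(sol)
  names(df)[1] <- "t"
  obs <- df[df$t >= transient, ]
  sp <- detectSpikes(obs, threshold = threshold, refractory = 2)
  out <- list(z = z, Isyn = Isyn, exists = NA, V_max = NA_real_,
              V_min = NA_real_, period = NA_real_, n_spikes = sp$n,
              status = "inconclusive")
  out$state_end <- c(x = df$x[nrow(df)], y = df$y[nrow(df)])
  if (sp$n >= 3) {
    isis <- diff(sp$times)
    period <- stats::median(utils::tail(isis, 3))
    # a genuine cycle must persist to the end of the window (a decaying
    # transient of several spikes must not count)
    if (max(sp$times) >= max(obs$t) - max(2 * period, 50)) {
      tail_df <- obs[obs$t >= max(obs$t) - 2 * period, ]
      out$exists <- TRUE
      out$period <- period
      out$V_max <- max(tail_df$x)
      out$V_min <- min(tail_df$x)
      out$status <- "cycle"
      return(structure(out, class = "cycleProbe"))
    }
  }
  tail_df <- obs[obs$t >= max(obs$t) - 100, ]
  if (diff(range(tail_df$x)) < 0.05) {
    out$exists <- FALSE
    out$status <- "converged"
  }
  structure(out, class = "cycleProbe")
}

#' @export
print.cycleProbe <- function(x, ...) {
  cat(sprintf("Limit-cycle probe at z = %g, Isyn = %g: %s\n",
              x$z, x$Isyn, x$status))
  if (isTRUE(x$exists))
    cat(sprintf("  period %.4g ms, V in [%.3f, %.3f] mV\n",
                x$period, x$V_min, x$V_max))
  invisible(x)
}

# cycle-existence predicate with adaptive window extension (covers the
# slow saddle-node-ghost passages near a SNIC-like cycle loss) before
# giving up
.cycleExists <- function(z, Isyn, params, k, window = 500, ...) {
  for (w in window * c(1, 3, 9)) {
    pr <- limitCycleProbe(z, Isyn, params, k, window = w, ...)
    if (!is.na(pr$exists)) return(pr)
  }
  stop("limit-cycle probe inconclusive at z = ", z, ", Isyn = ", Isyn,
       call. = FALSE)
}

# continuation-style bisection on cycle existence in z: each probe is
# seeded from the cycle state found at the nearest z where the cycle
# exists, so a shrinking basin of attraction does not hide the cycle
.bisectCycle <- function(Isyn, params, k, zBracket, tol, probeWindow) {
  seed <- NULL
  probe <- function(z) {
    pr <- if (is.null(seed)) {
      .cycleExists(z, Isyn, params, k, window = probeWindow)
    } else {
      .cycleExists(z, Isyn, params, k, window = probeWindow,
                   x0 = seed[[1L]], y0 = seed[[2L]])
    }
    if (isTRUE(pr$exists)) seed <<- pr$state_end
    pr
  }
  lo <- zBracket[1]; hi <- zBracket[2]
  if (!isTRUE(probe(lo)$exists) || !isFALSE(probe(hi)$exists))
    stop("zBracket must have a cycle at the lower end and none at the ",
         "upper end", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (isTRUE(probe(mid)$exists)) lo <- mid else hi <- mid
  }
  list(lo = lo, hi = hi, probe = probe)
}

.makeBifurcation <- function(type, axis, bracket, tol, Isyn = NULL,
                             method, extra = list()) {
  structure(c(list(type = type, parameter_axis = axis,
                   value = mean(bracket), bracket = bracket,
                   tolerance = tol, Isyn = Isyn, method = method),
              extra),
            class = "bifurcationPoint")
}

#' @export
print.bifurcationPoint <- function(x, ...) {
  cat(sprintf("%s bifurcation at %s = %.6g (bracket [%.6g, %.6g], tol %g)\n",
              x$type, x$parameter_axis, x$value, x$bracket[1], x$bracket[2],
              x$tolerance))
  invisible(x)
}

#' Fold (saddle-node) bifurcation of the fast subsystem
#'
#' Bisects on the slow variable \code{z} for the value at which the root
#' count of the I-V relation changes — where the stable node and the
#' saddle coalesce (simultaneously \eqn{I = 0} and
#' \eqn{\partial I/\partial V = 0}). The returned point carries the
#' coalescence voltage \code{V_c} and the tangency residual
#' \code{tangency} = min over V of max(|I|, |dI/dV|) at the located z.
#'
#' @inheritParams findEquilibriaFast
#' @param zBracket bracket in z (mV) with differing root counts at the
#'   ends.
#' @param tol bisection tolerance (mV).
#' @return a \code{"bifurcationPoint"} of type \code{"fold"}.
#' @export
findFold <- function(Isyn = 0, params, zBracket = c(-90, -55),
                     tol = 1e-3, Vrange = c(-100, 20), step = 0.01) {
  count <- function(z) .countIVRoots(z, params, Isyn, Vrange, step)
  lo <- zBracket[1]; hi <- zBracket[2]
  clo <- count(lo); chi <- count(hi)
  if (clo == chi)
    stop("no I-V root-count change in the z bracket [", lo, ", ", hi, "]",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count(mid) == clo) lo <- mid else hi <- mid
  }
  zf <- (lo + hi) / 2
  # tangency residual at the located z
  Vg <- seq(Vrange[1], Vrange[2], by = step)
  Iv <- ivRelation(Vg, zf, params, Isyn)
  dI <- (ivRelation(Vg + 1e-5, zf, params, Isyn) -
           ivRelation(Vg - 1e-5, zf, params, Isyn)) / 2e-5
  worst <- pmax(abs(Iv), abs(dI))
  i_c <- which.min(worst)
  .makeBifurcation("fold", "z", c(lo, hi), tol, Isyn,
                   "bisection on I-V root count",
                   extra = list(V_c = Vg[i_c], tangency = worst[i_c],
                                counts = c(clo, chi)))
}

#' Saddle-homoclinic orbit bifurcation of the fast subsystem
#'
#' Bisects on \code{z} for the disappearance of the fast-subsystem spiking
#' limit cycle while the saddle and node persist. The detector verifies
#' that the equilibrium count does not change across the located value
#' (otherwise the event is a fold of equilibria and is reclassified with
#' a warning), that a saddle is present on the no-cycle side, and records
#' the period-growth signature (period at \code{value - 0.05} over period
#' at \code{value - 0.5}).
#'
#' @inheritParams findFold
#' @param k weight constant; defaults to \code{params$k}.
#' @param zBracket bracket (mV): cycle must exist at the lower end and be
#'   absent at the upper end.
#' @param tol bisection tolerance (mV).
#' @param probeWindow observation window (ms) of each cycle probe.
#' @return a \code{"bifurcationPoint"} of type \code{"saddle-homoclinic"}
#'   with fields \code{period_near}, \code{period_far},
#'   \code{period_ratio} and \code{saddle_present}.
#' @export
findHomoclinic <- function(Isyn = 0, params, k = params$k,
                           zBracket = c(-68, -61), tol = 1e-2,
                           probeWindow = 500) {
  bi <- .bisectCycle(Isyn, params, k, zBracket, tol, probeWindow)
  lo <- bi$lo; hi <- bi$hi
  zc <- (lo + hi) / 2
  n_below <- .countIVRoots(zc - 5 * tol, params, Isyn)
  n_above <- .countIVRoots(zc + 5 * tol, params, Isyn)
  type <- "saddle-homoclinic"
  if (n_below != n_above) {
    warning("cycle disappearance coincides with an equilibrium-count ",
            "change; reclassifying as fold", call. = FALSE)
    type <- "fold"
  }
  eqs <- findEquilibriaFast(zc + 10 * tol, Isyn, params, k)
  saddle <- any(vapply(eqs, function(e) e$classification == "saddle",
                       logical(1)))
  p_near <- bi$probe(zc - 0.05)$period
  p_far <- bi$probe(zc - 0.5)$period
  .makeBifurcation(type, "z", c(lo, hi), tol, Isyn,
                   "bisection on limit-cycle existence",
                   extra = list(period_near = p_near, period_far = p_far,
                                period_ratio = p_near / p_far,
                                saddle_present = saddle))
}

#' Fold limit cycle bifurcation
#'
#' \code{findFoldCycle} bisects on \code{z} (fast subsystem, fixed
#' \code{Isyn}) for the loss of the stable spiking limit cycle with finite
#' period at the boundary; a period-divergence signature (boundary period
#' at least 1.5x the period 10 percent inside the branch) triggers
#' reclassification as saddle-homoclinic. \code{findFoldCycleIsyn} sweeps
#' the injected current of the full three-variable system from a
#' spike-like initial condition and bisects for the onset of a sustained
#' stable limit cycle (tonic spiking) — the minimum excitation current.
#'
#' @inheritParams findHomoclinic
#' @param zBracket bracket (mV): cycle at the lower end, none at the
#'   upper.
#' @return a \code{"bifurcationPoint"} of type \code{"fold-cycle"} (or
#'   \code{"saddle-homoclinic"} after reclassification).
#' @export
findFoldCycle <- function(Isyn, params, k = params$k,
                          zBracket = c(-70, -50), tol = 1e-2,
                          probeWindow = 500) {
  bi <- .bisectCycle(Isyn, params, k, zBracket, tol, probeWindow)
  lo <- bi$lo; hi <- bi$hi
  zc <- (lo + hi) / 2
  inside <- zc - 0.1 * (zc - zBracket[1])
  p_edge <- bi$probe(zc - 2 * tol)$period
  p_inside <- bi$probe(inside)$period
  type <- "fold-cycle"
  if (is.finite(p_edge) && is.finite(p_inside) &&
      p_edge / p_inside >= 1.5) {
    warning("period divergence at the cycle boundary; reclassifying as ",
            "saddle-homoclinic", call. = FALSE)
    type <- "saddle-homoclinic"
  }
  .makeBifurcation(type, "z", c(lo, hi), tol, Isyn,
                   "bisection on limit-cycle existence",
                   extra = list(period_edge = p_edge,
                                period_inside = p_inside))
}

# long-run simulation of the 3D reduced model under constant drive;
# returns the trace restricted to the analysis window
.longRunTrace <- function(Isyn, params, k, init, simTime, lastWindow,
                          solver = solverOptions(rtol = 1e-6, atol = 1e-8)) {
  y0 <- if (identical(init, "rest")) {
    # rest under the applied current itself, so a bistable window is
    # probed from its resting attractor, not from a step transient; the
    # small kick exposes an unstable rest within the horizon without
    # leaving a stable one's basin
    r0 <- .reducedRestingState(params, k, synCurrentDensity(Isyn, params),
                               settle = 1000, solver = solver)
    r0[["x"]] <- r0[["x"]] + 0.5
    r0
  } else if (identical(init, "spike")) {
    c(x = -20, y = -70, z = -70)
  } else {
    unlist(init)[c("x", "y", "z")]
  }
  tr <- simulateReduced(params, constantProtocol(Isyn, simTime),
                        init = y0, solver = solver, k = k)
  tr[tr$t >= simTime - lastWindow, ]
}

#' @rdname findFoldCycle
#' @param bracket Isyn bracket (nA): no sustained cycle at the lower end,
#'   sustained at the upper.
#' @param simTime,lastWindow simulation horizon and analysis window (ms)
#'   of each long-run probe.
#' @param minSpikes spike count in the analysis window that counts as
#'   sustained.
#' @export
findFoldCycleIsyn <- function(params, k = params$k,
                              bracket = c(0.01, 0.09), tol = 1e-3,
                              simTime = 6000, lastWindow = 1500,
                              minSpikes = 5) {
  sustained <- function(I) {
    tr <- .longRunTrace(I, params, k, "spike", simTime, lastWindow)
    detectSpikes(tr)$n >= minSpikes
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (sustained(lo) || !sustained(hi))
    stop("bracket must go from no sustained cycle (low) to sustained ",
         "(high)", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sustained(mid)) hi <- mid else lo <- mid
  }
  tr <- .longRunTrace(hi + tol, params, k, "spike", simTime, lastWindow)
  sp <- detectSpikes(tr)
  period <- if (sp$n >= 3) stats::median(diff(sp$times)) else NA_real_
  .makeBifurcation("fold-cycle", "Isyn", c(lo, hi), tol, NULL,
                   "bisection on sustained spiking from a spike-like init",
                   extra = list(period_at_onset = period))
}

#' Global equilibria of the three-variable system
#'
#' Equilibria of the full reduced system lie on the diagonal
#' \code{x = y = z = V} (both the y- and z-nullclines are the diagonal),
#' so they are the roots of the I-V relation evaluated along it. Each is
#' classified by the eigenvalues of the 3x3 Jacobian of the reduced
#' vector field.
#'
#' @inheritParams findEquilibriaFast
#' @return list of \code{"fixedPoint"} objects (subsystem
#'   \code{"full-3D"}) in increasing V order.
#' @export
globalEquilibria <- function(Isyn = 0, params, k = params$k,
                             Vrange = c(-100, 20), step = 0.01) {
  Ieff <- synCurrentDensity(Isyn, params)
  roots <- .scanRoots(function(V) fTotal(V, V, V, V, V, params) - Ieff,
                      Vrange[1], Vrange[2], step)
  lapply(roots, function(V0) {
    f3 <- function(u) .reducedDeriv(u[1L], u[2L], u[3L], Ieff, params, k)
    J <- .numJacobian(f3, c(V0, V0, V0))
    .makeFixedPoint(V0, V0, V0, "full-3D", J,
                    max(abs(f3(c(V0, V0, V0)))))
  })
}

# max real part of the complex-pair eigenvalues at the lowest global
# equilibrium; NA if the pair is absent
.lowestEqPairRe <- function(Isyn, params, k) {
  eqs <- globalEquilibria(Isyn, params, k)
  if (length(eqs) == 0L) return(NA_real_)
  ev <- eqs[[1L]]$eigenvalues
  cplx <- ev[abs(Im(ev)) > 1e-7]
  if (length(cplx) == 0L) return(NA_real_)
  max(Re(cplx))
}

#' Andronov-Hopf bifurcations along the equilibrium branch
#'
#' Tracks the eigenvalues of the 3x3 Jacobian at the lowest global
#' equilibrium over a grid in the injected current and bisects each sign
#' change of the real part of the complex-conjugate pair. A crossing of a
#' purely real eigenvalue is not a Hopf point and is skipped with a
#' warning. With \code{criticality = TRUE} a numerical small-orbit test
#' is run just past each crossing: emergence of a bounded stable orbit on
#' the unstable side marks the point supercritical.
#'
#' @inheritParams findEquilibriaFast
#' @param IsynRange grid range (nA) for eigenvalue tracking.
#' @param gridStep grid step (nA).
#' @param tol bisection tolerance (nA).
#' @param criticality run the small-orbit criticality probe.
#' @return list of \code{"bifurcationPoint"} objects of type
#'   \code{"hopf"}, each with the eigenvalues at the point and (if
#'   requested) a \code{criticality} field.
#' @export
findHopf <- function(IsynRange = c(-0.08, 0.01), params, k = params$k,
                     gridStep = 0.002, tol = 1e-4, criticality = FALSE) {
  grid <- seq(IsynRange[1], IsynRange[2], by = gridStep)
  re <- vapply(grid, .lowestEqPairRe, numeric(1), params = params, k = k)
  out <- list()
  for (i in seq_len(length(grid) - 1L)) {
    if (!is.finite(re[i]) || !is.finite(re[i + 1L])) {
      if (is.finite(re[i]) != is.finite(re[i + 1L]))
        warning("complex pair lost between Isyn = ", grid[i], " and ",
                grid[i + 1L], "; real-eigenvalue crossing is not Hopf",
                call. = FALSE)
      next
    }
    if (re[i] * re[i + 1L] < 0) {
      lo <- grid[i]; hi <- grid[i + 1L]
      rlo <- re[i]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        rm <- .lowestEqPairRe(mid, params, k)
        if (!is.finite(rm)) break
        if (sign(rm) == sign(rlo)) { lo <- mid; rlo <- rm } else hi <- mid
      }
      Ic <- (lo + hi) / 2
      eqs <- globalEquilibria(Ic, params, k)
      bp <- .makeBifurcation("hopf", "Isyn", c(lo, hi), tol, NULL,
                             "bisection on Re of the complex pair",
                             extra = list(
                               V_eq = eqs[[1L]]$V,
                               eigenvalues = eqs[[1L]]$eigenvalues))
      if (criticality)
        bp$criticality <- .hopfCriticality(bp, re[i], params, k)
      out <- c(out, list(bp))
    }
  }
  out
}

# small-orbit test: just past the crossing on the unstable side a stable
# orbit must emerge for a supercritical point
.hopfCriticality <- function(bp, re_below, params, k, delta = 5e-4) {
  dir <- if (re_below < 0) 1 else -1   # side where the pair is unstable
  Ip <- bp$value + dir * delta
  eqs <- globalEquilibria(Ip, params, k)
  V0 <- eqs[[1L]]$V
  tr <- .longRunTrace(Ip, params, k,
                      init = c(x = V0 + 0.5, y = V0, z = V0),
                      simTime = 4000, lastWindow = 1000)
  amp <- diff(range(tr$x))
  if (amp > 1e-3) "supercritical (stable orbit emerges)" else "undetermined"
}

#' Fold of global equilibria in the injected current
#'
#' Bisects the injected current for the coalescence of the stable resting
#' equilibrium of the three-variable system with the saddle (change of
#' the diagonal root count), closing the bistable window.
#'
#' @inheritParams findHopf
#' @param bracket Isyn bracket (nA) with differing equilibrium counts.
#' @return a \code{"bifurcationPoint"} of type \code{"fold"} on the Isyn
#'   axis.
#' @export
findFoldEquilibria <- function(params, k = params$k,
                               bracket = c(0.10, 0.16), tol = 1e-4,
                               Vrange = c(-100, 20), step = 0.01) {
  count <- function(I)
    length(.scanRoots(function(V)
      fTotal(V, V, V, V, V, params) - synCurrentDensity(I, params),
      Vrange[1], Vrange[2], step))
  lo <- bracket[1]; hi <- bracket[2]
  clo <- count(lo); chi <- count(hi)
  if (clo == chi)
    stop("no equilibrium-count change in the Isyn bracket", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count(mid) == clo) lo <- mid else hi <- mid
  }
  .makeBifurcation("fold", "Isyn", c(lo, hi), tol, NULL,
                   "bisection on diagonal equilibrium count",
                   extra = list(counts = c(clo, chi)))
}

#' Classify the long-run regime of a trace window
#'
#' Labels a (late-time) trace window as \code{"stationary"},
#' \code{"subthreshold oscillation"}, \code{"tonic"} or
#' \code{"bursting"} from its spikes and voltage range. A window that
#' fits no rule is \code{"inconclusive"}.
#'
#' @param trace a \code{"trnTrace"} (or window of one).
#' @param threshold spike threshold (mV).
#' @param gapThreshold burst gap (ms).
#' @param quietRange voltage range (mV) below which a spikeless window
#'   counts as stationary.
#' @return list with \code{regime}, \code{n_spikes}, \code{V_max},
#'   \code{V_min}.
#' @export
classifyRegime <- function(trace, threshold = 0, gapThreshold = 30,
                           quietRange = 0.5) {
  vcol <- intersect(c("V", "x"), names(trace))[1]
  sp <- detectSpikes(trace, threshold = threshold)
  v <- trace[[vcol]]
  regime <- if (sp$n == 0L) {
    if (diff(range(v)) < quietRange) "stationary" else
      "subthreshold oscillation"
  } else if (sp$n == 1L) {
    "inconclusive"
  } else {
    isis <- diff(sp$times)
    # bursting needs both a long silent gap and heterogeneous intervals;
    # a uniform train slower than the gap is still tonic
    if (max(isis) > gapThreshold && max(isis) / min(isis) > 2)
      "bursting" else "tonic"
  }
  list(regime = regime, n_spikes = sp$n, V_max = max(v), V_min = min(v))
}

#' One-parameter bifurcation diagram in the injected current
#'
#' Assembles, over a grid of injected currents: the global equilibria and
#' their stability; the long-run regime reached from a rest-like and a
#' spike-like initial condition (exposing bistable windows); and the four
#' organizing bifurcation points — the two Andronov-Hopf points bounding
#' the periodic-bursting branch (SHB1, SHB2), the fold-cycle onset of
#' tonic spiking (FCB) and the fold of equilibria closing the bistable
#' window (FB).
#'
#' @inheritParams findHopf
#' @param IsynRange sweep range (nA).
#' @param gridStep sweep step (nA).
#' @param inits initial-condition policies (subset of \code{"rest"},
#'   \code{"spike"}).
#' @param simTime,lastWindow long-run horizon and analysis window (ms).
#' @param detectBifurcations annotate the four bifurcation points (can be
#'   slow; the Hopf and fold points are cheap, the fold-cycle point runs
#'   a bisection of long simulations).
#' @return an object of class \code{"branchDiagram"} with components
#'   \code{equilibria} (data.frame), \code{regimes} (data.frame) and
#'   \code{bifurcations} (named list).
#' @export
oneParameterDiagram <- function(IsynRange = c(-0.08, 0.16), params,
                                k = params$k, gridStep = 0.002,
                                inits = c("rest", "spike"),
                                simTime = 2000, lastWindow = 600,
                                detectBifurcations = TRUE) {
  grid <- seq(IsynRange[1], IsynRange[2], by = gridStep)
  eq_rows <- list()
  reg_rows <- list()
  for (I in grid) {
    eqs <- globalEquilibria(I, params, k)
    for (e in eqs)
      eq_rows[[length(eq_rows) + 1L]] <-
        data.frame(Isyn = I, V = e$V,
                   classification = as.character(e$classification),
                   stable = grepl("^stable", e$classification))
    for (init in inits) {
      tr <- .longRunTrace(I, params, k, init, simTime, lastWindow)
      cl <- classifyRegime(tr)
      reg_rows[[length(reg_rows) + 1L]] <-
        data.frame(Isyn = I, init = init, regime = cl$regime,
                   n_spikes = cl$n_spikes, V_max = cl$V_max,
                   V_min = cl$V_min)
    }
  }
  bifs <- list()
  if (detectBifurcations) {
    grab <- function(expr) tryCatch(expr, error = function(e) {
      warning(conditionMessage(e), call. = FALSE); NULL
    })
    hopfs <- grab(findHopf(c(IsynRange[1], min(0.01, IsynRange[2])),
                           params, k, gridStep = gridStep))
    if (length(hopfs) >= 1) bifs$SHB1 <- hopfs[[1]]
    if (length(hopfs) >= 2) bifs$SHB2 <- hopfs[[2]]
    if (IsynRange[2] > 0.06)
      bifs$FCB <- grab(findFoldCycleIsyn(params, k,
                                         bracket = c(max(0.01, IsynRange[1]),
                                                     min(0.09, IsynRange[2]))))
    if (IsynRange[2] > 0.14)
      bifs$FB <- grab(findFoldEquilibria(params, k,
                                         bracket = c(0.10,
                                                     min(0.16, IsynRange[2]))))
  }
  structure(list(equilibria = do.call(rbind, eq_rows),
                 regimes = do.call(rbind, reg_rows),
                 bifurcations = bifs,
                 IsynRange = IsynRange, gridStep = gridStep),
            class = "branchDiagram")
}

#' @export
print.branchDiagram <- function(x, ...) {
  cat(sprintf("One-parameter diagram over Isyn in [%g, %g] (step %g)\n",
              x$IsynRange[1], x$IsynRange[2], x$gridStep))
  cat(sprintf("  %d equilibrium branch points, %d regime probes\n",
              nrow(x$equilibria), nrow(x$regimes)))
  for (nm in names(x$bifurcations))
    if (!is.null(x$bifurcations[[nm]]))
      cat(sprintf("  %s: %s at Isyn = %.6g\n", nm,
                  x$bifurcations[[nm]]$type, x$bifurcations[[nm]]$value))
  invisible(x)
}
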