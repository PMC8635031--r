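# Shared fixtures and independent oracles.

# the analysis parameter set used throughout the bifurcation work
sec4Params <- function(...) trnParams(...)

# the firing-pattern-comparison parameter set
fig2Params <- function() trnParams(gKL = 0.0152)

# independent bisection oracle for inverting a monotone function on [lo, hi]
bisectInverse <- function(f, target, lo, hi, tol = 1e-10) {
  flo <- f(lo) - target
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid) - target
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}

# derivative of the compiled vector field via a tiny forward step of the
# fixed-step integrator; independent of the R reference implementations
cDerivApprox <- function(model, y0, params, Ieff = 0, z = 0, h = 1e-8) {
  sol <- trnreduce:::.odeRun(y0, c(0, h), model, params,
                             solverOptions(method = "rk4", dt = h,
                                           dt_out = h),
                             Ieff = Ieff, z = z)
  (unlist(sol[2, -1]) - y0) / h
}

# central finite difference of a scalar function
fdiff <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)
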