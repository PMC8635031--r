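test_that("ionic currents vanish at their reversal potentials and with zero conductances", {
  p0 <- trnParams()
  p0 <- updateParams(p0, gNa = 0, gK = 0, gT = 0, gKL = 0)
  st <- fullState(p0$EL, "steady", p0)
  expect_true(all(abs(ionicCurrents(st, p0)) < 1e-12))
  p <- trnParams()
  st <- fullState(p$EK, gates = c(m = 0.5, h = 0.5, n = 1, p = 0.5,
                                  q = 0.5), params = p)
  expect_identical(unname(ionicCurrents(st, p)[["I_K"]]), 0)
})

test_that("ionic currents match an independent hand evaluation at rest", {
  p <- trnParams()
  V <- -70
  st <- fullState(V, "steady", p)
  got <- ionicCurrents(st, p)
  # literal re-evaluation, written out independently of the implementation
  m <- st[["m"]]; h <- st[["h"]]; n <- st[["n"]]; pq <- st[["p"]]
  q <- st[["q"]]
  expect_equal(got[["I_Na"]], 100 * m^3 * h * (V - 50), tolerance = 1e-12)
  expect_equal(got[["I_K"]], 10 * n^4 * (V + 100), tolerance = 1e-12)
  expect_equal(got[["I_T"]], 2.25 * pq^2 * q * (V - 120), tolerance = 1e-12)
  expect_equal(got[["I_L"]], 0.06 * (V + 70), tolerance = 1e-12)
  expect_equal(got[["I_KL"]], 0.0065 * (V + 100), tolerance = 1e-12)
  # and the gate values themselves against the printed kinetics
  am <- 0.32 * (13 - V - 55) / (exp((13 - V - 55) / 4) - 1)
  bm <- 0.28 * (V - 40 + 55) / (exp((V - 40 + 55) / 5) - 1)
  expect_equal(m, am / (am + bm), tolerance = 1e-12)
  expect_equal(q, 1 / (1 + exp((80 + V + 3) / 5)), tolerance = 1e-12)
})

test_that("the full vector field vanishes at a self-consistent equilibrium", {
  p <- trnParams()
  f <- function(V) sum(ionicCurrents(fullState(V, "steady", p), p))
  Vstar <- uniroot(f, c(-90, -60), tol = 1e-13)$root
  d <- fullRHS(0, fullState(Vstar, "steady", p), p,
               constantProtocol(0, 10))
  expect_true(all(abs(d) < 1e-9))
})

test_that("subthreshold voltage drift is set by the leak currents", {
  p <- trnParams()
  st <- fullState(-85, "steady", p)
  cur <- ionicCurrents(st, p)
  d <- fullRHS(0, st, p, constantProtocol(0, 10))
  # active currents are negligible at -85 mV with gates at steady state
  expect_equal(sign(d[["V"]]), -sign(cur[["I_L"]] + cur[["I_KL"]]))
})

test_that("release from hyperpolarization triggers a rebound burst", {
  p <- trnParams(EL = -77, gKL = 0.00793, gT = 2)
  tr <- simulateFull(p, stepProtocol(-0.03, 0, 200, 400),
                     settle = 1000)
  sp <- detectSpikes(tr)
  rebound <- sp$times[sp$times > 200 & sp$times < 350]
  expect_gte(length(rebound), 2)
  # T-current is inward (depolarizing) at burst onset
  onset <- tr[tr$t > 200 & tr$t < rebound[1], ]
  expect_lt(min(onset$I_T), 0)
})

test_that("trajectories respect gating bounds and reversal-potential bounds", {
  p <- trnParams()
  tr <- simulateFull(p, constantProtocol(0.2, 500), settle = 1000)
  for (g in c("m", "h", "n", "p", "q"))
    expect_true(all(tr[[g]] >= 0 & tr[[g]] <= 1), info = g)
  expect_true(all(tr$V >= min(p$EK, p$EKL, p$EL) &
                    tr$V <= max(p$ENa, p$ET)))
  expect_false(any(!is.finite(tr$V)))
})

test_that("zero stimulus settles to rest or a sustained orbit without NaN", {
  p <- trnParams()
  tr <- simulateFull(p, constantProtocol(0, 500), settle = 2000)
  expect_false(any(!is.finite(as.matrix(tr[-1]))))
  late <- tr[tr$t > 400, ]
  d_end <- fullRHS(500, unlist(tr[nrow(tr), c("V", "m", "h", "n", "p",
                                              "q")]),
                   p, constantProtocol(0, 500))
  settled <- abs(d_end[["V"]]) < 1e-6
  periodic <- detectSpikes(late)$n > 0 || diff(range(late$V)) > 0.5
  expect_true(settled || periodic)
})

test_that("the fixed-step integrator converges at its nominal order", {
  p <- trnParams()
  y0 <- fullState(-70, "steady", p)
  y0[["V"]] <- -65   # off equilibrium, smooth subthreshold response
  run <- function(dt, method = "rk4") {
    sv <- solverOptions(method = method, dt = dt, dt_out = 10,
                       rtol = 1e-12, atol = 1e-14)
    tr <- simulateFull(p, constantProtocol(0, 20), init = y0, solver = sv)
    tr$V[nrow(tr)]
  }
  ref <- run(1e-3, "lsoda")
  e1 <- abs(run(0.08) - ref)
  e2 <- abs(run(0.04) - ref)
  expect_lt(e2, e1)
  # fourth-order scheme: halving the step should cut the error by ~16
  expect_gt(e1 / e2, 8)
  # and halving the step changes the final voltage imperceptibly
  expect_lt(abs(run(0.02) - run(0.01)), 0.1)
})

test_that("the compiled full-model vector field matches the R reference", {
  p <- trnParams()
  states <- list(fullState(-70, "steady", p),
                 fullState(-40, gates = c(m = 0.3, h = 0.6, n = 0.2,
                                          p = 0.4, q = 0.05), params = p),
                 fullState(0, gates = c(m = 0.9, h = 0.05, n = 0.6,
                                        p = 0.8, q = 0.01), params = p))
  for (st in states) {
    rr <- fullRHS(0, st, p, constantProtocol(0.1, 10))
    cc <- cDerivApprox("full", st, p,
                       Ieff = synCurrentDensity(0.1, p))
    expect_equal(unname(cc), unname(rr), tolerance = 1e-5)
  }
})

test_that("constant depolarization yields an initial burst then regular tonic spiking", {
  p <- fig2Params()
  tr <- simulateFull(p, constantProtocol(0.2, 1000), settle = 1500)
  sp <- detectSpikes(tr)
  expect_gt(sp$n, 10)
  isis <- diff(sp$times)
  # decelerating burst at onset: early intervals shorter than the tonic ones
  expect_lt(isis[1], utils::tail(isis, 1))
  late <- sp$times[sp$times > 900]
  cv <- stats::sd(diff(late)) / mean(diff(late))
  expect_lt(cv, 0.05)
})
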