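test_that("equivalent potentials round-trip their gating fractions", {
  p <- trnParams()
  st <- fullState(-63, "steady", p)
  v <- equivalentPotentials(st, p)
  for (g in c("m", "h", "n", "p", "q"))
    expect_lt(abs(gateInf(g, v[[paste0("v_", g)]], p) - st[[g]]), 1e-8)
})

test_that("F agrees with the summed ionic currents and degenerates to the leaks", {
  p <- trnParams()
  V <- -58
  st <- fullState(V, "steady", p)
  expect_equal(fTotal(V, V, V, V, V, p), sum(ionicCurrents(st, p)),
               tolerance = 1e-12)
  # distinct equivalent potentials: substitute the implied fractions
  vh <- -70; vn <- -50; vp <- -62; vq <- -80
  st2 <- fullState(V, gates = c(m = gateInf("m", V, p),
                                h = gateInf("h", vh, p),
                                n = gateInf("n", vn, p),
                                p = gateInf("p", vp, p),
                                q = gateInf("q", vq, p)), params = p)
  expect_equal(fTotal(V, vh, vn, vp, vq, p), sum(ionicCurrents(st2, p)),
               tolerance = 1e-12)
  p0 <- updateParams(p, gNa = 0, gK = 0, gT = 0)
  expect_equal(fTotal(V, -10, -20, -90, -100, p0),
               p0$gL * (V - p0$EL) + p0$gKL * (V - p0$EKL),
               tolerance = 1e-12)
})

test_that("F matches an independent hand evaluation at -65 mV", {
  p <- trnParams()
  V <- -65
  minf <- gateInf("m", V, p); hinf <- gateInf("h", V, p)
  ninf <- gateInf("n", V, p); pinf <- gateInf("p", V, p)
  qinf <- gateInf("q", V, p)
  byhand <- 100 * minf^3 * hinf * (V - 50) + 10 * ninf^4 * (V + 100) +
    2.25 * pinf^2 * qinf * (V - 120) + 0.06 * (V + 70) +
    0.0065 * (V + 100)
  expect_equal(fTotal(V, V, V, V, V, p), byhand, tolerance = 1e-12)
})

test_that("analytic partials of F match finite differences", {
  p <- trnParams()
  states <- list(c(-65, -65, -65, -65, -65, -65),
                 c(-40, -45, -60, -55, -62, -70),
                 c(-20, -25, -50, -40, -58, -66))
  for (s in states) {
    P <- partialsOfF(s[1], s[2], s[3], s[4], s[5], s[6], p)
    fd <- c(
      dV = fdiff(function(u) fTotal(u, s[3], s[4], s[5], s[6], p,
                                    v_m = s[2]), s[1]),
      dv_m = fdiff(function(u) fTotal(s[1], s[3], s[4], s[5], s[6], p,
                                      v_m = u), s[2]),
      dv_h = fdiff(function(u) fTotal(s[1], u, s[4], s[5], s[6], p,
                                      v_m = s[2]), s[3]),
      dv_n = fdiff(function(u) fTotal(s[1], s[3], u, s[5], s[6], p,
                                      v_m = s[2]), s[4]),
      dv_p = fdiff(function(u) fTotal(s[1], s[3], s[4], u, s[6], p,
                                      v_m = s[2]), s[5]))
    for (nm in names(fd))
      expect_equal(P[[nm]], fd[[nm]], tolerance = 1e-4,
                   info = paste(nm, paste(s, collapse = ",")))
  }
})

test_that("partials reflect the channel structure", {
  p0 <- updateParams(trnParams(), gT = 0)
  P <- partialsOfF(-60, -60, -60, -60, -60, -60, p0)
  expect_identical(unname(P[["dv_p"]]), 0)
  # h and p act anti-synergistically between E_K and E_T
  p <- trnParams()
  for (V in c(-60, -40, -20)) {
    P <- partialsOfF(V, V, -60, -60, -60, -65, p)
    expect_gt(P[["dv_h"]], 0)
    expect_lt(P[["dv_p"]], 0)
  }
})

test_that("grouping weights satisfy their constraints and closed forms", {
  p <- trnParams()
  w <- computeWeights(-65, -65, -65, -65, -65, -65, p)
  expect_equal(w$rho_p, 0.01)
  expect_equal(w$rho_V + w$rho_m, 1, tolerance = 1e-12)
  expect_equal(w$rho_h + w$rho_n + w$rho_p, 1, tolerance = 1e-12)
  # rho_h : rho_n proportional to the h and n partials
  P <- partialsOfF(-65, -65, -65, -65, -65, -65, p)
  expect_equal(w$rho_h,
               (1 - 0.01) * P[["dv_h"]] / (P[["dv_h"]] + P[["dv_n"]]),
               tolerance = 1e-12)
  expect_equal(w$rho_n,
               (1 - 0.01) * P[["dv_n"]] / (P[["dv_h"]] + P[["dv_n"]]),
               tolerance = 1e-12)
  expect_error(computeWeights(-65, -65, -65, -65, -65, -65, p, k = 1),
               "k must")
})

test_that("weight normalization holds across sampled states", {
  p <- trnParams()
  set.seed(7)
  for (i in 1:60) {
    V <- runif(1, -100, 40)
    y <- runif(1, -100, -40)
    z <- runif(1, -100, -40)
    w <- suppressWarnings(computeWeights(V, V, y, y, y, z, p))
    expect_equal(w$rho_V + w$rho_m, 1, tolerance = 1e-12)
    expect_equal(w$rho_h + w$rho_n + w$rho_p, 1, tolerance = 1e-12)
    expect_true(all(c(w$rho_V, w$rho_m, w$rho_h, w$rho_n, w$rho_p) >= 0))
    expect_true(w$rho_V >= 0 && w$rho_V <= 1)
  }
})

test_that("reduceState collapses a full state onto commensurate coordinates", {
  p <- trnParams()
  st <- fullState(-63, "steady", p)
  r <- reduceState(st, p)
  expect_true(all(is.finite(r)))
  expect_equal(r[["z"]],
               inverseSteadyState("q", st[["q"]], p), tolerance = 1e-8)
  # at a steady full state all equivalent potentials equal V, so x and y do
  expect_equal(unname(r[c("x", "y")]), c(-63, -63), tolerance = 1e-6)
})
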