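test_that("removable singularities return the analytic limit and the curve is continuous there", {
  p <- trnParams()
  # alpha_m at 13 - V + VthNa = 0, limit 0.32 * 4
  expect_equal(rateValue("m", "alpha", -42, p), 1.28, tolerance = 1e-9)
  # beta_m at V - 40 - VthNa = 0, limit 0.28 * 5
  expect_equal(rateValue("m", "beta", -15, p), 1.4, tolerance = 1e-9)
  # alpha_n at 15 - V + VthK = 0, limit 0.032 * 5
  expect_equal(rateValue("n", "alpha", -40, p), 0.16, tolerance = 1e-9)
  for (case in list(c("m", -42), c("n", -40))) {
    v <- as.numeric(case[2])
    near <- rateValue(case[1], "alpha", v + c(-1e-6, 1e-6), p)
    expect_lt(max(abs(near - rateValue(case[1], "alpha", v, p))), 1e-5)
  }
})

test_that("T-channel steady states sit at their logistic midpoints", {
  p <- trnParams()
  expect_equal(gateInf("q", p$VthT - 80, p), 0.5, tolerance = 1e-12)
  expect_equal(gateInf("p", p$VthT - 52, p), 0.5, tolerance = 1e-12)
})

test_that("steady-state curves are bounded, monotone, and time constants positive", {
  p <- trnParams()
  V <- seq(-120, 60, by = 0.5)
  increasing <- c(m = TRUE, h = FALSE, n = TRUE, p = TRUE, q = FALSE)
  for (g in names(increasing)) {
    s <- gateInf(g, V, p)
    expect_true(all(s > 0 & s < 1), info = g)
    d <- diff(s)
    if (increasing[[g]]) expect_true(all(d > 0), info = g)
    else expect_true(all(d < 0), info = g)
    expect_true(all(gateTau(g, V, p) > 0), info = g)
  }
  # n_inf strictly increasing on the printed example grid
  expect_true(all(diff(gateInf("n", c(-60, -50, -40), p)) > 0))
})

test_that("analytic steady-state derivatives match finite differences", {
  p <- trnParams()
  for (g in c("m", "h", "n", "p", "q")) {
    for (V in c(-80, -55, -30, 0)) {
      expect_equal(gateInfDeriv(g, V, p),
                   fdiff(function(v) gateInf(g, v, p), V),
                   tolerance = 1e-4, info = paste(g, V))
    }
  }
})

test_that("rate lookup rejects unknown gates and inapplicable forms", {
  p <- trnParams()
  expect_error(rateValue("r", "alpha", -60, p), "unknown gate")
  expect_error(rateValue("p", "alpha", -60, p), "alpha/beta")
  expect_error(rateValue("m", "alpha", NaN, p), "finite")
})

test_that("inverseSteadyState is a two-sided inverse of the steady-state curves", {
  p <- trnParams()
  for (g in c("m", "h", "n", "p", "q")) {
    for (V in c(-90, -60, -40)) {
      expect_equal(inverseSteadyState(g, gateInf(g, V, p), p), V,
                   tolerance = 1e-8, info = paste(g, V))
    }
    for (f in c(0.05, 0.3, 0.9)) {
      v <- inverseSteadyState(g, f, p)
      expect_lt(abs(gateInf(g, v, p) - f), 1e-10)
    }
  }
  # independent bisection oracle for n_inf at 0.3
  oracle <- bisectInverse(function(v) gateInf("n", v, p), 0.3, -120, 60)
  expect_equal(inverseSteadyState("n", 0.3, p), oracle, tolerance = 1e-8)
  # q_inf closed-form midpoint
  expect_equal(inverseSteadyState("q", 0.5, p), p$VthT - 80,
               tolerance = 1e-10)
  expect_error(inverseSteadyState("m", 1.2, p), "\\[0, 1\\]")
})

test_that("parameter validation catches invalid fields", {
  expect_error(trnParams(gNa = -1), "gNa")
  expect_error(trnParams(C = 0), "'C'")
  expect_error(trnParams(k = 1.5), "'k'")
  expect_error(updateParams(trnParams(), nope = 1), "unknown parameter")
  p2 <- updateParams(trnParams(), gKL = 0.0152)
  expect_equal(p2$gKL, 0.0152)
})
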