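test_that("the I-V relation has the expected root structure", {
  p <- trnParams()
  V <- seq(-90, 0, by = 0.02)
  roots0 <- sum(abs(diff(sign(ivRelation(V, -65, p, Isyn = 0)))) > 0)
  expect_identical(roots0, 3L)
  # strong depolarizing current removes the low-voltage roots
  rootsD <- sum(abs(diff(sign(ivRelation(V, -65, p, Isyn = 0.10)))) > 0)
  expect_identical(rootsD, 1L)
  # outward potassium current dominates at high voltage
  expect_gt(ivRelation(60, -65, p), 0)
})

test_that("fast-subsystem equilibria are located, ordered and classified", {
  p <- trnParams()
  eqs <- findEquilibriaFast(-65, 0, p)
  expect_length(eqs, 3)
  Vs <- vapply(eqs, function(e) e$V, numeric(1))
  expect_true(all(diff(Vs) > 0))
  cls <- vapply(eqs, function(e) as.character(e$classification),
                character(1))
  expect_match(cls[1], "^stable")
  expect_identical(cls[2], "saddle")
  expect_match(cls[3], "^unstable")
  for (e in eqs) expect_lt(e$residual, 1e-8)
  # very low z: a single unstable equilibrium remains
  eqs2 <- findEquilibriaFast(-80, 0, p)
  expect_length(eqs2, 1)
  expect_match(as.character(eqs2[[1]]$classification), "^unstable")
})

test_that("a perturbed stable equilibrium relaxes back (simulation oracle)", {
  p <- trnParams()
  eqs <- findEquilibriaFast(-65, 0, p)
  Vs <- eqs[[1]]$V
  pr <- limitCycleProbe(-65, 0, p, x0 = Vs + 0.1, y0 = Vs,
                        transient = 0, window = 200)
  expect_false(isTRUE(pr$exists))
  expect_lt(abs(pr$state_end[["x"]] - Vs), 1e-3)
})

test_that("eigenvalue classification follows the standard rules", {
  expect_identical(as.character(classifyStability(c(-1, -2))),
                   "stable node")
  expect_identical(as.character(classifyStability(c(-0.1 + 2i, -0.1 - 2i))),
                   "stable focus")
  expect_identical(as.character(classifyStability(c(0.3, -0.5))), "saddle")
  expect_identical(as.character(classifyStability(c(1, 2, 0.5))),
                   "unstable node")
  m <- classifyStability(c(1e-12, -1))
  expect_true(attr(m, "marginal"))
})

test_that("the spiking limit cycle exists below the bistable window and not above it", {
  p <- trnParams()
  pr <- limitCycleProbe(-70, 0, p)
  expect_true(pr$exists)
  expect_gt(pr$period, 0)
  expect_gt(pr$V_max, pr$V_min)
  pr2 <- limitCycleProbe(-60, 0, p)
  expect_false(pr2$exists)
  expect_identical(pr2$status, "converged")
})

test_that("fold detection brackets a genuine tangency and is grid-stable", {
  p <- trnParams()
  f <- findFold(0, p)
  expect_identical(f$type, "fold")
  # posterior: the bracket ends really differ in root count
  n_lo <- length(findEquilibriaFast(f$bracket[1] - 1e-3, 0, p))
  n_hi <- length(findEquilibriaFast(f$bracket[2] + 1e-3, 0, p))
  expect_false(n_lo == n_hi)
  expect_lt(f$tangency, 1e-3)
  # refining the scan grid does not move the fold beyond tolerance
  f2 <- findFold(0, p, step = 0.005)
  expect_lt(abs(f2$value - f$value), f$tolerance)
  expect_error(findFold(0, p, zBracket = c(-60, -58)), "root-count")
})

test_that("the cycle period grows towards the homoclinic value", {
  p <- trnParams()
  hc <- findHomoclinic(0, p)
  expect_identical(hc$type, "saddle-homoclinic")
  expect_true(hc$saddle_present)
  zc <- hc$value
  periods <- vapply(c(zc - 2, zc - 0.5, zc - 0.05), function(z)
    limitCycleProbe(z, 0, p, window = 1500)$period, numeric(1))
  expect_true(all(diff(periods) > 0))
  expect_gte(hc$period_ratio, 1.5)
  # the bistable z-interval is [fold, homoclinic] with fold < homoclinic
  fd <- findFold(0, p)
  expect_lt(fd$value, hc$value)
  n_mid <- length(findEquilibriaFast((fd$value + hc$value) / 2, 0, p))
  expect_identical(n_mid, 3L)
  # grid/window refinement stability
  hc2 <- findHomoclinic(0, p, probeWindow = 1000)
  expect_lt(abs(hc2$value - hc$value), 2 * hc$tolerance)
})

test_that("global equilibria satisfy their defining equations and known stability", {
  p <- trnParams()
  for (I in c(0, -0.03, -0.06)) {
    eqs <- globalEquilibria(I, p)
    expect_gte(length(eqs), 1)
    for (e in eqs) expect_lt(e$residual, 1e-8)
  }
  # strong inhibition: the lowest intersection is a stable state
  low6 <- globalEquilibria(-0.06, p)[[1]]
  expect_match(as.character(low6$classification), "^stable")
  # weak inhibition: the lowest intersection is an unstable focus
  low3 <- globalEquilibria(-0.03, p)[[1]]
  expect_identical(as.character(low3$classification), "unstable focus")
})

test_that("Hopf points sit where the complex pair crosses the imaginary axis", {
  p <- trnParams()
  hp <- findHopf(c(-0.08, 0.01), p)
  expect_length(hp, 2)
  for (b in hp) {
    ev <- b$eigenvalues
    pair <- ev[abs(Im(ev)) > 1e-7]
    expect_length(pair, 2)
    expect_lt(max(abs(Re(pair))), 1e-4)
    # bracket posterior: the sign of Re really changes
    re_lo <- trnreduce:::.lowestEqPairRe(b$bracket[1] - 5e-4, p, p$k)
    re_hi <- trnreduce:::.lowestEqPairRe(b$bracket[2] + 5e-4, p, p$k)
    expect_lt(re_lo * re_hi, 0)
  }
  # between the two crossings the rest state is periodically bursting
  tr <- trnreduce:::.longRunTrace(-0.03, p, p$k, "rest", 5000, 1500)
  expect_identical(classifyRegime(tr)$regime, "bursting")
})

test_that("spike detection counts constructed crossings", {
  tri <- data.frame(t = seq(0, 100, by = 0.5))
  tri$V <- 20 * (2 * abs((tri$t / 20) %% 1 - 0.5) - 0.5) * 2
  expect_identical(detectSpikes(tri)$n, 5L)
  flat <- data.frame(t = 0:100, V = rep(-65, 101))
  expect_identical(detectSpikes(flat)$n, 0L)
  # refractory merging: double crossings within 2 ms count once
  wig <- data.frame(t = c(0, 1, 1.2, 1.4, 10),
                    V = c(-10, 5, -3, 6, -10))
  expect_identical(detectSpikes(wig)$n, 1L)
})

test_that("burst segmentation splits on the inter-spike gap", {
  bs <- burstStatistics(c(0, 5, 10, 60, 65, 130), gapThreshold = 30)
  expect_identical(bs$counts, c(3L, 2L, 1L))
  expect_identical(bs$n_bursts, 3L)
  expect_equal(bs$period, 65)
  tonic <- burstStatistics(seq(0, 200, by = 10), gapThreshold = 30)
  expect_identical(tonic$n_bursts, 1L)
  expect_error(burstStatistics(numeric(0)), "at least one spike")
  expect_error(burstStatistics(c(5, 3)), "increasing")
})

test_that("regime classification distinguishes the firing modes", {
  p <- trnParams()
  rest <- trnreduce:::.longRunTrace(-0.07, p, p$k, "rest", 2500, 600)
  expect_identical(classifyRegime(rest)$regime, "stationary")
  burst <- trnreduce:::.longRunTrace(-0.03, p, p$k, "rest", 5000, 1500)
  expect_identical(classifyRegime(burst)$regime, "bursting")
  tonic <- trnreduce:::.longRunTrace(0.14, p, p$k, "spike", 4000, 800)
  expect_identical(classifyRegime(tonic)$regime, "tonic")
})
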