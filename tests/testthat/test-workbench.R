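test_that("stimulus protocols validate and evaluate", {
  pr <- stepProtocol(-0.05, 0, 200, 1000)
  expect_equal(protocolAmplitude(pr, c(0, 100, 199.9, 200, 500)),
               c(-0.05, -0.05, -0.05, 0, 0))
  expect_error(stimProtocol(data.frame(t_start = 10, t_end = 5,
                                       amplitude = 1)), "t_start < t_end")
  expect_error(stimProtocol(data.frame(t_start = c(0, 50),
                                       t_end = c(100, 150),
                                       amplitude = c(1, 2))), "overlap")
  expect_error(stimProtocol(data.frame(t_start = 0, t_end = 10,
                                       amplitude = Inf)), "finite")
  p <- trnParams()
  expect_equal(synCurrentDensity(-0.03, p), -0.03e-3 / p$A)
})

test_that("presets encode the published protocol parameters", {
  cfg <- presetConfig("fig8-panel1")
  expect_equal(cfg$protocol$segments$amplitude, -0.03)
  expect_equal(cfg$paramSet$gKL, 0.0065)
  expect_equal(cfg$paramSet$gT, 2.25)
  expect_equal(cfg$k, 0.01)
  cfg2 <- presetConfig("fig2c")
  expect_equal(cfg2$paramSet$gKL, 0.0152)
  expect_equal(cfg2$protocol$segments$amplitude, -0.05)
  expect_identical(cfg2$analysis, "compare")
  expect_error(presetConfig("fig99"), "unknown preset")
  for (nm in presetNames()) expect_s3_class(presetConfig(nm),
                                            "experimentConfig")
})

test_that("config loading fills defaults, honours overrides and rejects bad keys", {
  empty <- withr::local_tempfile(fileext = ".json")
  writeLines("", empty)
  cfg <- loadConfig(empty)
  expect_equal(cfg$paramSet$gT, 2.25)
  expect_equal(cfg$paramSet$gKL, 0.0065)
  expect_identical(cfg$model, "reduced")

  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(model = "full", params = list(gKL = 0.0152),
                            protocol = list(type = "constant",
                                            amplitude = 0.2,
                                            duration = 50)),
                       path, auto_unbox = TRUE)
  cfg2 <- loadConfig(path)
  expect_identical(cfg2$model, "full")
  expect_equal(cfg2$paramSet$gKL, 0.0152)

  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(gnat = 1), bad, auto_unbox = TRUE)
  expect_error(loadConfig(bad), "gnat")
  badp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(params = list(gNa = -1)), badp,
                       auto_unbox = TRUE)
  expect_error(loadConfig(badp), "gNa")
})

test_that("traces round-trip through the CSV writer with standard headers", {
  p <- trnParams()
  tr <- simulateReduced(p, constantProtocol(0, 20), settle = 100,
                        solver = solverOptions(rtol = 1e-6, atol = 1e-8))
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_identical(header[1:4], c("t_ms", "x_mV", "y_mV", "z_mV"))
  back <- readTrace(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_identical(attr(back, "model"), "reduced")
  expect_true(file.exists(paste0(path, ".meta.json")))
})

test_that("bifurcation reports carry the stable JSON schema", {
  p <- trnParams()
  f <- findFold(0, p)
  path <- withr::local_tempfile(fileext = ".json")
  writeBifurcationReport(list(fold = f), path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_named(rep[[1]], c("type", "parameter_axis", "value", "bracket",
                           "tolerance", "method"))
  expect_equal(rep[[1]]$value, f$value)
})

test_that("experiments are deterministic byte-for-byte", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run <- function(out) {
    cfg <- experimentConfig(model = "reduced", analysis = "simulate",
                            protocol = list(type = "constant",
                                            amplitude = 0.2,
                                            duration = 60),
                            solver = list(rtol = 1e-6, atol = 1e-8),
                            out = out)
    runExperiment(cfg)
  }
  run(out1); run(out2)
  f1 <- file.path(out1, "trace-reduced.csv")
  f2 <- file.path(out2, "trace-reduced.csv")
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
})

test_that("the summary schema is stable across analyses", {
  cfg1 <- experimentConfig(model = "reduced", analysis = "simulate",
                           protocol = list(type = "constant",
                                           amplitude = 0, duration = 40),
                           solver = list(rtol = 1e-6, atol = 1e-8))
  b1 <- runExperiment(cfg1)
  cfg2 <- experimentConfig(analysis = "ivcurve", z_values = c(-65),
                           Isyn = 0)
  b2 <- runExperiment(cfg2)
  expect_identical(names(b1$summary), names(b2$summary))
  expect_identical(b2$summary$checks$n_roots_z65, 3L)
})

test_that("stage failures name the failing stage", {
  cfg <- experimentConfig(model = "reduced", analysis = "simulate",
                          protocol = list(type = "constant",
                                          amplitude = 0, duration = 40))
  cfg$paramSet <- NULL  # corrupt after validation to force a failure
  expect_error(runExperiment(cfg), "stage 'simulate")
})
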