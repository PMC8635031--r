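# Experiment configuration, presets and the comparison runner.

.CONFIG_KEYS <- c("preset", "model", "analysis", "params", "protocol",
                  "k", "solver", "out", "format", "expected", "init",
                  "simTime", "z_values", "Isyn", "IsynRange", "gridStep")

.PROTOCOL_KEYS <- c("type", "amplitude", "t_on", "t_off", "duration",
                    "segments")

#' Build an experiment configuration
#'
#' Validates and normalizes a configuration for [runExperiment()]. Unknown
#' keys are rejected by name; parameter overrides are applied to the
#' default parameter set and re-validated.
#'
#' @param model \code{"full"}, \code{"reduced"} or \code{"both"}.
#' @param analysis one of \code{"simulate"}, \code{"compare"},
#'   \code{"ivcurve"}, \code{"fastslow"}, \code{"bifurcate"}.
#' @param params named list of [trnParams()] overrides.
#' @param protocol either a [stimProtocol()] or a list with \code{type}
#'   (\code{"constant"}/\code{"step"}), \code{amplitude}, \code{t_on},
#'   \code{t_off}, \code{duration}.
#' @param k weight constant.
#' @param solver named list of [solverOptions()] overrides.
#' @param out output directory (optional; artifacts are written when set).
#' @param ... analysis-specific settings: \code{z_values}, \code{Isyn}
#'   (ivcurve/fastslow), \code{IsynRange}, \code{gridStep} (bifurcate),
#'   \code{init}, \code{simTime}, \code{expected} (named expected values
#'   checked into the summary), \code{format}, \code{preset}.
#' @return an object of class \code{"experimentConfig"}.
#' @export
experimentConfig <- function(model = "reduced", analysis = "simulate",
                             params = list(), protocol = NULL,
                             k = 0.01, solver = list(), out = NULL, ...) {
  cfg <- c(list(model = model, analysis = analysis, params = params,
                protocol = protocol, k = k, solver = solver, out = out),
           list(...))
  bad <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg$model <- match.arg(cfg$model, c("reduced", "full", "both"))
  cfg$analysis <- match.arg(cfg$analysis,
                            c("simulate", "compare", "ivcurve",
                              "fastslow", "bifurcate"))
  p <- do.call(updateParams, c(list(trnParams()), cfg$params))
  cfg$paramSet <- updateParams(p, k = cfg$k)
  cfg$solverOpts <- do.call(solverOptions, cfg$solver)
  if (!is.null(cfg$protocol) && !inherits(cfg$protocol, "stimProtocol")) {
    pr <- cfg$protocol
    bad <- setdiff(names(pr), .PROTOCOL_KEYS)
    if (length(bad))
      stop("unknown protocol key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg$protocol <- if (!is.null(pr$segments)) {
      stimProtocol(as.data.frame(pr$segments), pr$duration)
    } else if (identical(pr$type, "step")) {
      stepProtocol(pr$amplitude, pr$t_on %||% 0, pr$t_off, pr$duration)
    } else {
      constantProtocol(pr$amplitude, pr$duration)
    }
  }
  structure(cfg, class = "experimentConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.experimentConfig <- function(x, ...) {
  cat(sprintf("Experiment config: analysis '%s', model '%s'%s\n",
              x$analysis, x$model,
              if (!is.null(x$preset)) paste0(" (preset '", x$preset, "')")
              else ""))
  invisible(x)
}

#' Load an experiment configuration from file
#'
#' Reads a JSON (\code{.json}) or YAML (\code{.yml}/\code{.yaml},
#' requires the \pkg{yaml} package) configuration and validates it
#' through [experimentConfig()]. An empty file yields the all-defaults
#' configuration. Schema violations are reported with the offending key.
#'
#' @param path configuration file path.
#' @return an \code{"experimentConfig"} object.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (nchar(paste(readLines(path, warn = FALSE),
                         collapse = "")) == 0) {
    list()
  } else if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$preset)) {
    cfg <- presetConfig(raw$preset)
    raw$preset <- NULL
    over <- raw
    for (nm in names(over)) cfg[[nm]] <- over[[nm]]
    raw <- cfg[intersect(names(cfg), .CONFIG_KEYS)]
    raw$preset <- cfg$preset
  }
  do.call(experimentConfig, raw)
}

#' Per-figure experiment presets
#'
#' Ready-made configurations for the published simulation and analysis
#' protocols: the rebound-burst demonstration (\code{"fig1"}), the three
#' full-vs-reduced comparison protocols (\code{"fig2a"}, \code{"fig2b"},
#' \code{"fig2c"}, and \code{"fig2-compare"} running all three), the I-V
#' curve family (\code{"fig3-iv"}), the rebound-burst and tonic-spiking
#' phase-plane runs (\code{"fig4"}, \code{"fig6"}), the fast-slow
#' diagrams (\code{"fig5a"}..\code{"fig5d"}), the one-parameter diagram
#' (\code{"fig7-diagram"}), and the four firing-regime panels
#' (\code{"fig8-panel1"}..\code{"fig8-panel4"}).
#'
#' @param name preset name; \code{presetNames()} lists them.
#' @return an \code{"experimentConfig"}.
#' @export
presetConfig <- function(name) {
  make <- function(...) {
    cfg <- experimentConfig(...)
    cfg$preset <- name
    cfg
  }
  switch(name,
    "fig1" = make(model = "full",
                  params = list(EL = -77, gKL = 0.00793, gT = 2),
                  protocol = list(type = "step", amplitude = -0.03,
                                  t_on = 0, t_off = 200, duration = 600)),
    "fig2a" = make(model = "both", analysis = "compare",
                   params = list(gKL = 0.0152),
                   protocol = list(type = "constant", amplitude = 0.2,
                                   duration = 1000)),
    "fig2b" = make(model = "both", analysis = "compare",
                   params = list(gKL = 0.0152),
                   protocol = list(type = "step", amplitude = 0.2,
                                   t_on = 0, t_off = 200,
                                   duration = 1000)),
    "fig2c" = make(model = "both", analysis = "compare",
                   params = list(gKL = 0.0152),
                   protocol = list(type = "step", amplitude = -0.05,
                                   t_on = 0, t_off = 200,
                                   duration = 1000)),
    "fig2-compare" = make(model = "both", analysis = "compare",
                          params = list(gKL = 0.0152)),
    "fig3-iv" = make(analysis = "ivcurve",
                     z_values = c(-75, -70, -65, -60),
                     Isyn = c(0, -0.05, 0.1)),
    "fig4" = make(protocol = list(type = "step", amplitude = -0.03,
                                  t_on = 50, t_off = 250,
                                  duration = 650)),
    "fig5a" = make(analysis = "fastslow", Isyn = 0),
    "fig5b" = make(analysis = "fastslow", Isyn = 0.1),
    "fig5c" = make(analysis = "fastslow", Isyn = -0.03),
    "fig5d" = make(analysis = "fastslow", Isyn = -0.06),
    "fig6" = make(protocol = list(type = "step", amplitude = 0.1,
                                  t_on = 50, t_off = 350,
                                  duration = 500)),
    "fig7-diagram" = make(analysis = "bifurcate",
                          IsynRange = c(-0.08, 0.16), gridStep = 0.005),
    "fig8-panel1" = make(protocol = list(type = "constant",
                                         amplitude = -0.03,
                                         duration = 3000),
                         simTime = 3000),
    "fig8-panel2" = make(protocol = list(type = "constant",
                                         amplitude = -0.01,
                                         duration = 3000),
                         simTime = 3000),
    "fig8-panel3" = make(protocol = list(type = "constant",
                                         amplitude = 0.07,
                                         duration = 2000),
                         init = "dual", simTime = 2000),
    "fig8-panel4" = make(protocol = list(type = "constant",
                                         amplitude = 0.14,
                                         duration = 2000),
                         init = "dual", simTime = 2000),
    stop("unknown preset '", name, "'", call. = FALSE))
}

#' @rdname presetConfig
#' @export
presetNames <- function() {
  c("fig1", "fig2a", "fig2b", "fig2c", "fig2-compare", "fig3-iv", "fig4",
    "fig5a", "fig5b", "fig5c", "fig5d", "fig6", "fig7-diagram",
    "fig8-panel1", "fig8-panel2", "fig8-panel3", "fig8-panel4")
}

#' Write a bifurcation report to JSON
#'
#' Serializes one or more [findFold()]-family results as a JSON array of
#' objects with the fields \code{type}, \code{parameter_axis},
#' \code{value}, \code{bracket}, \code{tolerance}, \code{method}.
#'
#' @param bifurcations a \code{"bifurcationPoint"} or list of them
#'   (possibly named).
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeBifurcationReport <- function(bifurcations, path) {
  if (inherits(bifurcations, "bifurcationPoint"))
    bifurcations <- list(bifurcations)
  rep <- lapply(bifurcations, function(b)
    list(type = b$type, parameter_axis = b$parameter_axis,
         value = b$value, bracket = b$bracket,
         tolerance = b$tolerance, method = b$method))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# fixed summary schema shared by every analysis
.summarySkeleton <- function(config) {
  list(preset = config$preset %||% NA,
       analysis = config$analysis,
       model = config$model,
       n_spikes = NA,
       spikes_per_burst = NA,
       regime = NA,
       bifurcations = list(),
       checks = list(),
       pass = NA)
}

#' Run a configured experiment
#'
#' Executes the analysis named in the configuration — simulation,
#' full-vs-reduced comparison, I-V curve family, fast-slow z sweep, or
#' one-parameter bifurcation diagram — and returns an artifact bundle.
#' The pipeline is fully deterministic (no random numbers anywhere), so
#' re-running a configuration reproduces every artifact byte for byte.
#' When \code{config$out} is set, traces are written as CSV and reports
#' and the summary as JSON under that directory.
#'
#' @param config an \code{"experimentConfig"} (see [experimentConfig()],
#'   [presetConfig()], [loadConfig()]).
#' @return a list with (depending on the analysis) \code{traces},
#'   \code{spikes}, \code{bursts}, \code{iv}, \code{branch},
#'   \code{diagram}, \code{bifurcations}, and always \code{summary}
#'   (fixed schema) and \code{config}.
#' @export
runExperiment <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  # the three-protocol comparison preset aggregates its sub-experiments
  if (identical(config$preset, "fig2-compare")) {
    subs <- lapply(c("fig2a", "fig2b", "fig2c"), function(nm) {
      sub <- presetConfig(nm)
      sub$out <- if (!is.null(config$out)) file.path(config$out, nm)
      runExperiment(sub)
    })
    names(subs) <- c("fig2a", "fig2b", "fig2c")
    summary <- .summarySkeleton(config)
    summary$checks <- lapply(subs, function(s)
      s$summary$checks$spike_count_match)
    summary$pass <- all(vapply(summary$checks, isTRUE, logical(1)))
    if (!is.null(config$out)) {
      dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    return(invisible(list(config = config, sub = subs,
                          summary = summary)))
  }

  p <- config$paramSet
  sv <- config$solverOpts
  summary <- .summarySkeleton(config)
  bundle <- list(config = config)

  if (config$analysis %in% c("simulate", "compare")) {
    protocol <- config$protocol %||% constantProtocol(0, 500)
    models <- switch(config$model, both = c("full", "reduced"),
                     config$model)
    if (config$analysis == "compare") models <- c("full", "reduced")
    inits <- if (identical(config$init, "dual")) c("rest", "spike")
             else "rest"
    traces <- list()
    spikes <- list()
    for (m in models) {
      for (ini in inits) {
        key <- if (length(inits) > 1) paste(m, ini, sep = "-") else m
        traces[[key]] <- stage(paste0("simulate-", key), {
          if (m == "full") {
            init <- if (ini == "spike")
              fullState(-20, "steady", p) else "steady"
            simulateFull(p, protocol, init = init, solver = sv)
          } else {
            init <- if (ini == "spike") c(x = -20, y = -70, z = -70)
                    else "steady"
            simulateReduced(p, protocol, init = init, solver = sv,
                            k = config$k)
          }
        })
        spikes[[key]] <- detectSpikes(traces[[key]])
      }
    }
    bundle$traces <- traces
    bundle$spikes <- spikes
    counts <- vapply(spikes, function(s) s$n, numeric(1))
    summary$n_spikes <- as.list(counts)
    first <- spikes[[1]]
    if (first$n > 0) {
      bs <- burstStatistics(first)
      bundle$bursts <- bs
      summary$spikes_per_burst <- as.list(bs$counts)
    }
    last <- traces[[1]][traces[[1]]$t >=
                          max(traces[[1]]$t) - 0.3 * diff(range(traces[[1]]$t)), ]
    summary$regime <- classifyRegime(last)$regime
    if (config$analysis == "compare") {
      summary$checks$spike_count_match <-
        abs(counts[["full"]] - counts[["reduced"]]) <= 1
    }
  } else if (config$analysis == "ivcurve") {
    zs <- config$z_values %||% c(-75, -70, -65, -60)
    Is <- config$Isyn %||% 0
    Vg <- seq(-100, 20, by = 0.1)
    iv <- do.call(rbind, lapply(Is, function(I)
      do.call(rbind, lapply(zs, function(z)
        data.frame(Isyn = I, z = z, V = Vg,
                   I = ivRelation(Vg, z, p, I))))))
    bundle$iv <- iv
    bundle$equilibria <- findEquilibriaFast(-65, Is[1], p, config$k)
    summary$checks$n_roots_z65 <- length(bundle$equilibria)
  } else if (config$analysis == "fastslow") {
    I <- config$Isyn %||% 0
    zg <- seq(-80, -50, by = 0.25)
    branch <- do.call(rbind, lapply(zg, function(z) {
      eqs <- findEquilibriaFast(z, I, p, config$k)
      if (length(eqs) == 0L) return(NULL)
      data.frame(z = z, V = vapply(eqs, function(e) e$V, numeric(1)),
                 classification = vapply(eqs, function(e)
                   as.character(e$classification), character(1)))
    }))
    bundle$branch <- branch
    bifs <- list()
    bifs$fold <- stage("fold", findFold(I, p))
    if (I < 0.05) {
      bifs$homoclinic <- stage("homoclinic",
                               findHomoclinic(I, p, config$k,
                                              zBracket = c(-68, -61)))
    } else {
      bifs$fold_cycle <- stage("fold-cycle",
                               findFoldCycle(I, p, config$k,
                                             zBracket = c(-65, -50)))
    }
    bundle$bifurcations <- bifs
    summary$bifurcations <- lapply(bifs, function(b)
      list(type = b$type, value = b$value))
  } else if (config$analysis == "bifurcate") {
    rng <- config$IsynRange %||% c(-0.08, 0.16)
    stepI <- config$gridStep %||% 0.005
    dg <- stage("diagram",
                oneParameterDiagram(rng, p, config$k, gridStep = stepI,
                                    simTime = config$simTime %||% 2000))
    bundle$diagram <- dg
    summary$bifurcations <- lapply(dg$bifurcations, function(b)
      list(type = b$type, value = b$value))
  }

  if (!is.null(config$expected)) {
    for (nm in names(config$expected)) {
      got <- summary$bifurcations[[nm]]$value %||% summary$checks[[nm]]
      summary$checks[[nm]] <- got
      summary$pass <- isTRUE(summary$pass %||% TRUE) &&
        !is.null(got) && is.numeric(got) &&
        abs(got - config$expected[[nm]]) <=
          (config$expected[["tolerance"]] %||% 0.1)
    }
  }
  bundle$summary <- summary

  if (!is.null(config$out)) {
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bundle$traces))
      writeTrace(bundle$traces[[nm]],
                 file.path(config$out, paste0("trace-", nm, ".csv")))
    if (!is.null(bundle$iv))
      utils::write.csv(bundle$iv, file.path(config$out, "ivcurves.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(bundle$branch))
      utils::write.csv(bundle$branch, file.path(config$out, "branch.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(bundle$bifurcations))
      writeBifurcationReport(bundle$bifurcations,
                             file.path(config$out, "bifurcations.json"))
    if (!is.null(bundle$diagram)) {
      utils::write.csv(bundle$diagram$equilibria,
                       file.path(config$out, "diagram-equilibria.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(bundle$diagram$regimes,
                       file.path(config$out, "diagram-regimes.csv"),
                       row.names = FALSE, quote = FALSE)
      if (length(bundle$diagram$bifurcations))
        writeBifurcationReport(bundle$diagram$bifurcations,
                               file.path(config$out, "bifurcations.json"))
    }
    jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(bundle)
}
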