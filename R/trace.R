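# Trace objects and their CSV/JSON serialization.

#' @export
print.trnTrace <- function(x, ...) {
  model <- attr(x, "model")
  vcol <- if (identical(model, "reduced")) "x" else "V"
  cat(sprintf("%s-model trace: %d samples over [%g, %g] ms\n",
              if (is.null(model)) "?" else model, nrow(x),
              min(x$t), max(x$t)))
  cat(sprintf("  %s range [%.3f, %.3f] mV\n", vcol,
              min(x[[vcol]]), max(x[[vcol]])))
  invisible(x)
}

# column header mapping for on-disk traces
.traceHeader <- function(trace) {
  nm <- names(trace)
  nm[nm == "t"] <- "t_ms"
  nm[nm == "V"] <- "V_mV"
  nm[nm == "x"] <- "x_mV"
  nm[nm == "y"] <- "y_mV"
  nm[nm == "z"] <- "z_mV"
  nm
}

#' Write a trace to CSV (with a JSON metadata sidecar)
#'
#' Writes the trace with on-disk headers \code{t_ms,V_mV,m,...} (full
#' model) or \code{t_ms,x_mV,y_mV,z_mV,...} (reduced model) at full
#' precision, plus a \code{<path>.meta.json} sidecar recording the model,
#' parameters, protocol and solver settings.
#'
#' @param trace a \code{"trnTrace"} data.frame.
#' @param path output CSV path.
#' @param sidecar write the metadata sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(trace, path, sidecar = TRUE) {
  df <- as.data.frame(trace)
  names(df) <- .traceHeader(trace)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    protocol <- attr(trace, "protocol")
    meta <- list(model = attr(trace, "model"),
                 params = unclass(attr(trace, "params")),
                 protocol = if (!is.null(protocol))
                   list(segments = protocol$segments,
                        duration = protocol$duration),
                 solver = unclass(attr(trace, "solver")),
                 k = attr(trace, "k"))
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a trace written by [writeTrace()]
#'
#' @param path CSV path.
#' @return a \code{"trnTrace"} data.frame (metadata attributes restored
#'   from the sidecar when present).
#' @export
readTrace <- function(path) {
  df <- utils::read.csv(path)
  nm <- names(df)
  nm[nm == "t_ms"] <- "t"
  nm[nm == "V_mV"] <- "V"
  nm[nm == "x_mV"] <- "x"
  nm[nm == "y_mV"] <- "y"
  nm[nm == "z_mV"] <- "z"
  names(df) <- nm
  class(df) <- c("trnTrace", "data.frame")
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(df, "model") <- meta$model
    attr(df, "k") <- meta$k
  }
  df
}
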