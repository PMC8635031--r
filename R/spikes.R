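# Spike detection and burst segmentation on simulated traces.

#' Detect spikes in a voltage trace
#'
#' A spike is an upward crossing of \code{threshold} by the membrane
#' potential (column \code{V} for full-model traces, \code{x} for reduced
#' ones), with crossings closer than \code{refractory} to the previous
#' accepted spike discarded. Crossing times are linearly interpolated.
#'
#' @param trace a \code{"trnTrace"} data.frame (or any data.frame with a
#'   time column \code{t} and a voltage column \code{V} or \code{x}).
#' @param threshold crossing threshold (mV).
#' @param refractory minimum separation between spikes (ms).
#' @return an object of class \code{"spikeTrain"}: list with \code{times}
#'   (ms) and \code{n}.
#' @export
detectSpikes <- function(trace, threshold = 0, refractory = 2) {
  vcol <- intersect(c("V", "x"), names(trace))[1]
  if (is.na(vcol)) stop("trace has no voltage column (V or x)", call. = FALSE)
  v <- trace[[vcol]]
  t <- trace$t
  up <- which(v[-length(v)] < threshold & v[-1L] >= threshold)
  times <- numeric(0)
  for (i in up) {
    tc <- t[i] + (threshold - v[i]) / (v[i + 1L] - v[i]) * (t[i + 1L] - t[i])
    if (length(times) == 0L || tc - times[length(times)] > refractory)
      times <- c(times, tc)
  }
  structure(list(times = times, n = length(times), threshold = threshold,
                 refractory = refractory),
            class = "spikeTrain")
}

#' @export
print.spikeTrain <- function(x, ...) {
  cat(sprintf("Spike train: %d spike(s)", x$n))
  if (x$n > 0)
    cat(sprintf(" over [%.6g, %.6g] ms", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Burst segmentation of a spike train
#'
#' Splits a spike train into bursts wherever the inter-spike interval
#' exceeds \code{gapThreshold}. A tonic train (all intervals below the
#' gap) is a single burst containing every spike.
#'
#' @param spikes a [detectSpikes()] result, or a numeric vector of spike
#'   times (ms).
#' @param gapThreshold inter-spike gap (ms) separating bursts.
#' @return an object of class \code{"burstStats"}: list with
#'   \code{counts} (spikes per burst), \code{n_bursts}, \code{bursts}
#'   (list of spike-index vectors), \code{starts} (burst onset times), and
#'   \code{period} (mean inter-burst onset interval; \code{NA} with fewer
#'   than two bursts).
#' @export
burstStatistics <- function(spikes, gapThreshold = 30) {
  times <- if (inherits(spikes, "spikeTrain")) spikes$times else spikes
  if (length(times) == 0L)
    stop("burstStatistics needs at least one spike", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("spike times must be strictly increasing", call. = FALSE)
  breaks <- which(diff(times) > gapThreshold)
  starts_idx <- c(1L, breaks + 1L)
  ends_idx <- c(breaks, length(times))
  bursts <- Map(seq, starts_idx, ends_idx)
  starts <- times[starts_idx]
  structure(list(counts = lengths(bursts),
                 n_bursts = length(bursts),
                 bursts = bursts,
                 starts = starts,
                 period = if (length(starts) >= 2) mean(diff(starts))
                          else NA_real_,
                 gapThreshold = gapThreshold),
            class = "burstStats")
}

#' @export
print.burstStats <- function(x, ...) {
  cat(sprintf("%d burst(s); spikes per burst: %s\n", x$n_bursts,
              paste(x$counts, collapse = ", ")))
  if (is.finite(x$period))
    cat(sprintf("  mean inter-burst period: %.6g ms\n", x$period))
  invisible(x)
}
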