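# Stimulus protocols: piecewise-constant injected current I_syn(t).
#
# Amplitudes carry the units the model equation normalizes: the synaptic
# current I_syn in nA, converted to a membrane current density (uA/cm^2) by
# the factor 1e-3/A before entering dV/dt. All published step/constant
# stimuli are quoted on this I_syn scale, so protocol amplitudes can be
# taken straight from those values.

#' Synaptic current to membrane current density
#'
#' Converts a synaptic current \code{Isyn} (nA) into the membrane current
#' density (uA/cm^2) that enters the voltage equation, via the
#' normalization \eqn{10^{-3} I_{syn}/A} with \code{A} the membrane area.
#'
#' @param Isyn synaptic current(s), nA.
#' @param params a [trnParams()] object (supplies the area \code{A}).
#' @return current density in uA/cm^2.
#' @export
synCurrentDensity <- function(Isyn, params) 1e-3 * Isyn / params$A

#' Piecewise-constant stimulus protocols
#'
#' \code{stimProtocol} builds a protocol from explicit segments
#' (\code{t_start}, \code{t_end}, \code{amplitude}); times in ms, amplitude
#' on the \code{Isyn} scale (nA, see [synCurrentDensity()]). Segments must
#' be non-overlapping with \code{t_start < t_end}; gaps carry zero
#' stimulus. \code{stepProtocol} and \code{constantProtocol} are the usual
#' shortcuts for a single step and a constant hold.
#'
#' @param segments a data.frame with numeric columns \code{t_start},
#'   \code{t_end}, \code{amplitude}.
#' @param duration total protocol duration (ms); defaults to the last
#'   segment end.
#' @return an object of class \code{"stimProtocol"}.
#' @examples
#' stepProtocol(-0.05, t_on = 0, t_off = 200, duration = 1000)
#' @export
stimProtocol <- function(segments, duration = NULL) {
  need <- c("t_start", "t_end", "amplitude")
  if (!is.data.frame(segments) || !all(need %in% names(segments)))
    stop("segments must be a data.frame with columns t_start, t_end, amplitude",
         call. = FALSE)
  seg <- segments[order(segments$t_start), need, drop = FALSE]
  if (nrow(seg)) {
    if (any(!is.finite(as.matrix(seg))))
      stop("segment times and amplitudes must be finite", call. = FALSE)
    if (any(seg$t_start >= seg$t_end))
      stop("each segment needs t_start < t_end", call. = FALSE)
    if (nrow(seg) > 1L && any(seg$t_start[-1L] < seg$t_end[-nrow(seg)] - 1e-12))
      stop("segments must not overlap", call. = FALSE)
    if (any(seg$t_start < 0))
      stop("segments must start at t >= 0", call. = FALSE)
  }
  if (is.null(duration)) duration <- if (nrow(seg)) max(seg$t_end) else 0
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be a positive number", call. = FALSE)
  if (nrow(seg) && max(seg$t_end) > duration + 1e-12)
    stop("segments extend beyond the protocol duration", call. = FALSE)
  structure(list(segments = seg, duration = duration),
            class = "stimProtocol")
}

#' @rdname stimProtocol
#' @param amplitude stimulus amplitude (Isyn scale, nA).
#' @param t_on,t_off step onset and offset (ms).
#' @export
stepProtocol <- function(amplitude, t_on = 0, t_off, duration) {
  stimProtocol(data.frame(t_start = t_on, t_end = t_off,
                          amplitude = amplitude),
               duration = duration)
}

#' @rdname stimProtocol
#' @export
constantProtocol <- function(amplitude, duration) {
  stimProtocol(data.frame(t_start = 0, t_end = duration,
                          amplitude = amplitude),
               duration = duration)
}

#' Stimulus amplitude at given times
#'
#' @param protocol a [stimProtocol()].
#' @param t time(s) in ms.
#' @return amplitude(s) on the Isyn scale (nA); zero outside all segments.
#' @export
protocolAmplitude <- function(protocol, t) {
  amp <- numeric(length(t))
  seg <- protocol$segments
  if (nrow(seg)) {
    for (i in seq_len(nrow(seg))) {
      inside <- t >= seg$t_start[i] & t < seg$t_end[i]
      amp[inside] <- seg$amplitude[i]
    }
    # closed at the final protocol instant
    at_end <- t == seg$t_end[nrow(seg)] & t == protocol$duration
    amp[at_end] <- seg$amplitude[nrow(seg)]
  }
  amp
}

# Decompose [0, duration] into maximal constant-amplitude pieces:
# data.frame(t0, t1, amplitude)
.protocolPieces <- function(protocol) {
  seg <- protocol$segments
  brk <- sort(unique(c(0, protocol$duration, seg$t_start, seg$t_end)))
  brk <- brk[brk >= 0 & brk <= protocol$duration]
  t0 <- brk[-length(brk)]
  t1 <- brk[-1L]
  keep <- t1 - t0 > 1e-12
  t0 <- t0[keep]; t1 <- t1[keep]
  data.frame(t0 = t0, t1 = t1,
             amplitude = protocolAmplitude(protocol, (t0 + t1) / 2))
}

#' @export
print.stimProtocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol, duration %g ms\n", x$duration))
  if (nrow(x$segments) == 0L) {
    cat("  (zero stimulus throughout)\n")
  } else {
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  [%g, %g) ms: Isyn = %g\n",
                  x$segments$t_start[i], x$segments$t_end[i],
                  x$segments$amplitude[i]))
  }
  invisible(x)
}
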