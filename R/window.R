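## Diastolic analysis-window selection from a membrane-potential trace:
## from the maximal diastolic potential (MDP) to the first upward crossing
## of the L-type activation threshold (-50 mV by default).

## Local maxima of Vm above 0 mV delimit action potentials; cycle k runs
## from peak k to peak k+1. Boundary samples count as peaks so traces cut
## at a spike still delimit their cycles.
.apPeaks <- function(vm) {
  n <- length(vm)
  if (n < 2L) return(integer(0))
  core <- integer(0)
  if (n >= 3L)
    core <- which(vm[2:(n - 1)] > 0 &
                  vm[2:(n - 1)] >= vm[1:(n - 2)] &
                  vm[2:(n - 1)] >= vm[3:n]) + 1L
  if (vm[1] > 0 && vm[1] >= vm[2]) core <- c(1L, core)
  if (vm[n] > 0 && vm[n] >= vm[n - 1]) core <- c(core, n)
  ## collapse runs of equal-valued samples to their first index
  if (length(core) > 1L)
    core <- core[c(TRUE, diff(core) > 1L |
                           vm[core[-1]] != vm[core[-length(core)]])]
  core
}

## half-up rounding onto the frame grid (deterministic at midpoints)
.toFrame <- function(tMs, t0Ms, dtMs) {
  as.integer(floor((tMs - t0Ms) / dtMs + 0.5)) + 1L
}

#' Select the diastolic analysis window from a voltage trace
#'
#' Locates the maximal diastolic potential (the minimum Vm; earliest
#' sample on ties) and the first upward crossing of \code{thresholdMv}
#' after it (linearly interpolated between samples), and maps both times
#' onto the stack's frame grid by rounding. For traces spanning several
#' action-potential cycles, \code{cycle} selects which inter-peak interval
#' to search (peaks = local Vm maxima above 0 mV); with fewer than two
#' peaks the whole trace is used.
#'
#' @param trace a \code{\link{VoltageTrace}} covering the stack's span.
#' @param thresholdMv upward-crossing threshold in mV (default -50, the
#'   L-type Ca channel activation threshold).
#' @param stackDtMs frame interval of the stack in ms (default 5).
#' @param stackT0Ms time of the stack's first frame on the trace clock
#'   (default 0).
#' @param nFramesStack number of frames in the stack; window frames must
#'   fall inside it. Use \code{Inf} to skip the bounds check.
#' @param cycle 1-based index of the cycle to analyse (default 1).
#' @return an \code{\link{AnalysisWindow}}.
#' @examples
#' tr <- VoltageTrace(seq(0, 300, by = 5), -70 + 0.1 * seq(0, 300, by = 5))
#' selectWindow(tr, nFramesStack = 61)  # MDP at 0 ms, crossing at 200 ms
#' @export
selectWindow <- function(trace, thresholdMv = -50, stackDtMs = 5,
                         stackT0Ms = 0, nFramesStack = Inf, cycle = 1) {
  stopifnot(is(trace, "VoltageTrace"))
  t <- trace@tMs; vm <- trace@vmMv
  if (is.finite(nFramesStack)) {
    stackEnd <- stackT0Ms + (nFramesStack - 1) * stackDtMs
    if (t[1] > stackT0Ms || t[length(t)] < stackEnd)
      stop("voltage trace does not cover the stack's time span")
  }
  ## restrict to the requested cycle when several AP peaks exist
  peaks <- .apPeaks(vm)
  lo <- 1L; hi <- length(t)
  if (length(peaks) >= 2L) {
    if (cycle < 1L || cycle > length(peaks) - 1L)
      stop("cycle index out of range: trace has ", length(peaks) - 1L,
           " complete cycle(s)")
    lo <- peaks[cycle]; hi <- peaks[cycle + 1L]
  }
  seg <- lo:hi
  iMdp <- seg[which.min(vm[seg])]          # which.min takes the earliest tie
  tMdp <- t[iMdp]
  ## first upward threshold crossing after the MDP
  tCross <- NA_real_
  for (i in iMdp:(hi - 1L)) {
    if (i + 1L > length(t)) break
    if (vm[i] <= thresholdMv && vm[i + 1L] > thresholdMv) {
      tCross <- t[i] + (thresholdMv - vm[i]) / (vm[i + 1L] - vm[i]) *
        (t[i + 1L] - t[i])
      break
    }
  }
  if (vm[iMdp] > thresholdMv)
    stop("Vm at the MDP (", vm[iMdp], " mV) is already above the threshold")
  if (is.na(tCross))
    stop("no upward crossing of ", thresholdMv, " mV after the MDP")
  startFrame <- .toFrame(tMdp, stackT0Ms, stackDtMs)
  endFrame <- .toFrame(tCross, stackT0Ms, stackDtMs)
  if (startFrame < 1L || (is.finite(nFramesStack) && endFrame > nFramesStack))
    stop("analysis window falls outside the stack (frames ", startFrame,
         "..", endFrame, ")")
  new("AnalysisWindow", startFrame = startFrame, endFrame = endFrame,
      tMdpMs = tMdp, tThresholdMs = tCross,
      thresholdMv = as.numeric(thresholdMv))
}
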