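#' Segment a recording into per-beat search windows
#'
#' One window per pacing stimulus that is followed by at least \code{window}
#' ms of signal (truncated final beats are dropped). Each window starts after
#' a post-stimulus blanking interval, which excludes the pacing artifact from
#' the later derivative search, and ends at
#' \code{min(window, time to next stimulus)} so consecutive windows never
#' overlap. The generous default window accommodates epicardial arrival
#' delays that can exceed 150 ms in deteriorating preparations.
#'
#' Without pacing times (sinus rhythm) a convenience detector is used:
#' steep negative slopes of the mean channel (threshold 5 x a robust noise
#' estimate, 250 ms refractory period) anchor the beats, and the nominal
#' stimulus time is placed \code{sinusLead} ms before each detected slope.
#'
#' @param recording a [UegRecording-class] (filter first).
#' @param blanking post-stimulus blanking in ms.
#' @param window search window length in ms (from the stimulus).
#' @param sinusLead ms between the nominal stimulus and the detected
#'   steepest slope in sinus mode.
#' @param useMeanChannel detect sinus beats on the mean across channels
#'   (default); set \code{FALSE} only with a single-channel recording.
#' @return a data.frame with columns \code{beatIndex}, \code{stimulusTime},
#'   \code{blankingEnd}, \code{searchStart}, \code{searchEnd} (all ms).
#' @examples
#' g <- ElectrodeGrid(6, 8)
#' rec <- simulateRecording(g, planarWave(100), beatTrainSpec(nBeats = 3),
#'                          fs = 500)
#' segmentBeats(rec)
#' @export
segmentBeats <- function(recording, blanking = 10, window = 400,
                         sinusLead = 200, useMeanChannel = TRUE) {
  stopifnot(is(recording, "UegRecording"))
  if (blanking < 0 || window <= blanking)
    stop("configuration error: need 0 <= blanking < window")
  stim <- recording@pacingTimes
  if (!length(stim)) {
    if (!useMeanChannel && ncol(recording@samples) > 1L)
      stop("configuration error: no pacing times and no reference channel")
    stim <- detectSinusBeats(recording, sinusLead)
    if (!length(stim))
      stop("no beats detected on the reference channel")
  }
  durMs <- recordingDurationMs(recording)
  keep <- stim + window <= durMs
  stim <- stim[keep]
  if (!length(stim))
    stop("no stimulus is followed by a full search window")
  nxt <- c(stim[-1L], Inf)
  searchEnd <- pmin(stim + window, nxt)
  data.frame(
    beatIndex = seq_along(stim),
    stimulusTime = stim,
    blankingEnd = stim + blanking,
    searchStart = stim + blanking,
    searchEnd = searchEnd
  )
}

# threshold crossing of the mean-channel derivative; convenience path for
# un-paced (sinus) recordings
detectSinusBeats <- function(recording, sinusLead) {
  fs <- recording@fs
  m <- rowMeans(recording@samples)
  d <- c(0, diff(m)) * fs / 1000               # units/ms
  thr <- -5 * mad(d)
  cand <- which(d < thr)
  if (!length(cand)) return(numeric(0))
  refractory <- as.integer(round(0.250 * fs))
  events <- integer(0)
  i <- 1L
  while (i <= length(cand)) {
    grp <- cand[cand >= cand[i] & cand < cand[i] + refractory]
    events <- c(events, grp[which.min(d[grp])])
    i <- i + length(grp)
  }
  tm <- (events - 1L) / fs * 1000 - sinusLead
  tm[tm >= 0]
}
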