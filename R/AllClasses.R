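#' ElectrodeGrid: geometry of a rectangular epicardial electrode array
#'
#' Rectangular grid of unipolar electrodes with fixed inter-electrode spacing
#' and an optional list of malfunctioning (bad) channels. Electrode labels are
#' \code{(row, col)} starting at 1; electrode \code{(r, c)} sits at physical
#' position \code{((c - 1) * spacing, (r - 1) * spacing)} mm (x along columns,
#' y along rows). Channels are ordered row-major.
#'
#' @slot nRows,nCols integer, grid dimensions (each >= 2).
#' @slot spacing numeric, inter-electrode spacing in mm (> 0).
#' @slot badChannels integer matrix with columns \code{row}, \code{col};
#'   channels known to malfunction, always treated as invalid downstream.
#'
#' @examples
#' ElectrodeGrid(11, 11, spacing = 5)
#' ElectrodeGrid(6, 8, spacing = 5, badChannels = rbind(c(2, 6)))
#' @export
setClass("ElectrodeGrid",
  representation(
    nRows = "integer",
    nCols = "integer",
    spacing = "numeric",
    badChannels = "matrix"
  )
)

setValidity("ElectrodeGrid", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || is.na(object@nRows) || object@nRows < 2L)
    msg <- c(msg, "nRows must be a single integer >= 2")
  if (length(object@nCols) != 1L || is.na(object@nCols) || object@nCols < 2L)
    msg <- c(msg, "nCols must be a single integer >= 2")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number (mm)")
  bc <- object@badChannels
  if (ncol(bc) != 2L) {
    msg <- c(msg, "badChannels must have two columns (row, col)")
  } else if (nrow(bc) > 0L) {
    if (any(bc[, 1L] < 1L | bc[, 1L] > object@nRows |
            bc[, 2L] < 1L | bc[, 2L] > object@nCols))
      msg <- c(msg, "badChannels labels fall outside the grid")
    if (anyDuplicated(bc))
      msg <- c(msg, "badChannels contains duplicate labels")
  }
  if (length(msg)) msg else TRUE
})

#' WavefrontSpec: kinematic depolarization wavefront with known ground truth
#'
#' Describes an activation wavefront sweeping the mapped epicardium, either
#' planar (constant direction) or focal (radiating from a point source).
#' The ground-truth activation time at position \code{x} (mm), relative to the
#' pacing stimulus, is \code{onsetDelay + (x . direction) / speed} for planar
#' waves and \code{onsetDelay + |x - sourcePosition| / speed} for focal ones,
#' with speed converted from cm/s to mm/ms.
#'
#' @slot kind \code{"planar"} or \code{"focal"}.
#' @slot speed conduction speed in cm/s (> 0).
#' @slot direction unit vector (planar only).
#' @slot sourcePosition mm coordinates of the focus (focal only).
#' @slot onsetDelay ms from pacing stimulus to activation at the reference
#'   point (the coordinate origin for planar waves, the source for focal).
#' @seealso [planarWave()], [focalWave()], [groundTruthAT()]
#' @export
setClass("WavefrontSpec",
  representation(
    kind = "character",
    speed = "numeric",
    direction = "numeric",
    sourcePosition = "numeric",
    onsetDelay = "numeric"
  )
)

setValidity("WavefrontSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("planar", "focal"))
    msg <- c(msg, "kind must be 'planar' or 'focal'")
  if (!is.finite(object@speed) || object@speed <= 0)
    msg <- c(msg, "speed must be positive (cm/s)")
  if (object@kind == "planar") {
    if (length(object@direction) != 2L ||
        abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
      msg <- c(msg, "planar wavefront needs a unit-norm direction of length 2")
  }
  if (object@kind == "focal" && length(object@sourcePosition) != 2L)
    msg <- c(msg, "focal wavefront needs a sourcePosition of length 2 (mm)")
  if (!is.finite(object@onsetDelay) || object@onsetDelay < 0)
    msg <- c(msg, "onsetDelay must be non-negative (ms)")
  if (length(msg)) msg else TRUE
})

#' BeatTrainSpec: paced beat-train and artifact model for the UEG simulator
#'
#' Parameters of the simulated paced rhythm and of the nuisance components the
#' preprocessing stage is meant to remove. The QRS is a derivative-of-Gaussian
#' biphasic deflection (R-then-S) whose steepest negative slope falls exactly
#' at the channel's ground-truth activation time.
#'
#' @slot pacingRate beats/min; pacing stimulus k occurs at
#'   \code{k * 60000 / pacingRate} ms, k = 0, 1, ...
#' @slot nBeats number of paced beats.
#' @slot qrsWidth total QRS width in ms (deflection support ~ +/- width/2).
#' @slot qrsAmplitude peak amplitude of the deflection (signal units).
#' @slot tWaveAmplitude amplitude of a broad positive T wave 180 ms after
#'   activation (0 disables).
#' @slot noiseSd additive white Gaussian noise SD.
#' @slot baselineWanderAmplitude,baselineWanderFreq sinusoidal baseline wander
#'   (default 0.3 Hz, inside the high-pass stopband).
#' @slot pacingArtifactAmplitude amplitude of a 2-sample rectangular stimulus
#'   spike applied to every channel at each pacing time.
#' @slot seed integer RNG seed; identical spec + seed gives a bit-identical
#'   recording.
#' @seealso [beatTrainSpec()], [simulateRecording()]
#' @export
setClass("BeatTrainSpec",
  representation(
    pacingRate = "numeric",
    nBeats = "integer",
    qrsWidth = "numeric",
    qrsAmplitude = "numeric",
    tWaveAmplitude = "numeric",
    noiseSd = "numeric",
    baselineWanderAmplitude = "numeric",
    baselineWanderFreq = "numeric",
    pacingArtifactAmplitude = "numeric",
    seed = "integer"
  )
)

setValidity("BeatTrainSpec", function(object) {
  msg <- character()
  if (!is.finite(object@pacingRate) || object@pacingRate <= 0)
    msg <- c(msg, "pacingRate must be positive (beats/min)")
  if (is.na(object@nBeats) || object@nBeats < 1L)
    msg <- c(msg, "nBeats must be >= 1")
  if (!is.finite(object@qrsWidth) || object@qrsWidth <= 0)
    msg <- c(msg, "qrsWidth must be positive (ms)")
  for (s in c("qrsAmplitude", "tWaveAmplitude", "noiseSd",
              "baselineWanderAmplitude", "pacingArtifactAmplitude")) {
    v <- slot(object, s)
    if (!is.finite(v) || v < 0) msg <- c(msg, paste(s, "must be >= 0"))
  }
  if (!is.finite(object@baselineWanderFreq) || object@baselineWanderFreq <= 0)
    msg <- c(msg, "baselineWanderFreq must be positive (Hz)")
  if (length(msg)) msg else TRUE
})

#' UegRecording: multichannel unipolar epicardial electrogram recording
#'
#' Sample matrix (rows = time samples, columns = channels in row-major grid
#' order), sampling rate, grid geometry and pacing metadata. Synthetic
#' recordings additionally carry the per-channel ground-truth activation time
#' (ms relative to each pacing stimulus) for oracle use; it is \code{NA} for
#' bad channels and empty for real data.
#'
#' @slot samples numeric matrix \code{[nSamples x nChannels]}.
#' @slot fs sampling rate in Hz.
#' @slot grid an \code{ElectrodeGrid}.
#' @slot pacingTimes pacing stimulus times in ms (strictly increasing;
#'   empty for sinus rhythm).
#' @slot pacingRate beats/min, \code{NA} for sinus rhythm.
#' @slot groundTruthAT numeric per-channel ground-truth AT (ms relative to
#'   stimulus) or \code{numeric(0)} when unknown.
#' @seealso [simulateRecording()], [bandpassFilter()]
#' @export
setClass("UegRecording",
  representation(
    samples = "matrix",
    fs = "numeric",
    grid = "ElectrodeGrid",
    pacingTimes = "numeric",
    pacingRate = "numeric",
    groundTruthAT = "numeric"
  )
)

setValidity("UegRecording", function(object) {
  msg <- character()
  nch <- object@grid@nRows * object@grid@nCols
  if (ncol(object@samples) != nch)
    msg <- c(msg, sprintf("samples must have %d columns (one per electrode)",
                          nch))
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive sampling rate (Hz)")
  if (length(object@pacingTimes) > 1L &&
      any(diff(object@pacingTimes) <= 0))
    msg <- c(msg, "pacingTimes must be strictly increasing")
  if (length(object@groundTruthAT) &&
      length(object@groundTruthAT) != nch)
    msg <- c(msg, "groundTruthAT must have one entry per channel")
  if (length(msg)) msg else TRUE
})

#' ActivationMap: per-electrode activation times for one beat
#'
#' Activation times in ms relative to the beat's pacing stimulus, with a
#' per-electrode validity mask. Bad channels of the grid are always invalid;
#' channels whose deflection amplitude fails the validity floor are invalid
#' too, and their AT is \code{NA}.
#'
#' @slot beatIndex 1-based beat number.
#' @slot stimulusTime pacing stimulus time in ms (recording clock).
#' @slot at numeric per-channel activation time (ms after stimulus), \code{NA}
#'   where invalid.
#' @slot valid logical per-channel mask.
#' @slot grid the \code{ElectrodeGrid} the map lives on.
#' @seealso [detectActivationTimes()], [buildIsochrones()],
#'   [fitPlaneVelocity()]
#' @export
setClass("ActivationMap",
  representation(
    beatIndex = "integer",
    stimulusTime = "numeric",
    at = "numeric",
    valid = "logical",
    grid = "ElectrodeGrid"
  )
)

setValidity("ActivationMap", function(object) {
  msg <- character()
  nch <- object@grid@nRows * object@grid@nCols
  if (length(object@at) != nch || length(object@valid) != nch)
    msg <- c(msg, "at and valid must have one entry per electrode")
  if (any(is.na(object@at[object@valid])))
    msg <- c(msg, "valid electrodes must carry a finite activation time")
  if (any(!is.na(object@at[!object@valid])))
    msg <- c(msg, "invalid electrodes must have NA activation time")
  bad <- badChannelIndices(object@grid)
  if (length(bad) && any(object@valid[bad]))
    msg <- c(msg, "bad channels can never be valid")
  if (length(msg)) msg else TRUE
})

#' IsochroneSet: discretised activation map
#'
#' Assignment of every valid electrode to an isochrone level. Level k covers
#' activation times in \code{[minAT + (k-1) * interval, minAT + k * interval)}
#' (the latest electrode is included in the last level); \code{levels} holds
#' the upper edge of each band, so the levels span the observed AT range and
#' there are \code{ceiling((maxAT - minAT) / interval)} of them (at least 1).
#'
#' @slot interval isochrone step in ms.
#' @slot levels increasing numeric vector of band upper edges (ms).
#' @slot regionAssignment integer level index per electrode (NA if invalid).
#' @slot arrival earliest valid AT (wave arrival time on the grid), ms.
#' @slot latest latest valid AT, ms.
#' @slot grid the underlying \code{ElectrodeGrid}.
#' @seealso [buildIsochrones()]
#' @export
setClass("IsochroneSet",
  representation(
    interval = "numeric",
    levels = "numeric",
    regionAssignment = "integer",
    arrival = "numeric",
    latest = "numeric",
    grid = "ElectrodeGrid"
  )
)

setValidity("IsochroneSet", function(object) {
  msg <- character()
  if (!is.finite(object@interval) || object@interval <= 0)
    msg <- c(msg, "interval must be positive (ms)")
  if (length(object@levels) < 1L || is.unsorted(object@levels, strictly = TRUE))
    msg <- c(msg, "levels must be a non-empty strictly increasing vector")
  ra <- object@regionAssignment
  if (any(!is.na(ra) & (ra < 1L | ra > length(object@levels))))
    msg <- c(msg, "regionAssignment indices must point into levels")
  if (length(msg)) msg else TRUE
})

#' VelocityEstimate: wave propagation velocity for one beat
#'
#' WPV in cm/s together with how it was obtained: \code{"two_point"} (the
#' Euclidean distance between two electrodes divided by their activation-time
#' difference) or \code{"plane_fit"} (least-squares plane through the
#' activation map; speed is the inverse gradient magnitude).
#'
#' @slot beatIndex beat the estimate belongs to.
#' @slot wpv speed in cm/s (> 0, finite).
#' @slot method \code{"two_point"} or \code{"plane_fit"}.
#' @slot direction unit vector of propagation (plane fit; for two_point the
#'   normalised p1 -> p2 direction).
#' @slot points integer matrix of the electrode pair \code{(row, col)} used
#'   (two_point; empty for plane_fit).
#' @slot residual RMS residual of the plane fit in ms (NA for two_point).
#' @seealso [estimateWpvTwoPoint()], [fitPlaneVelocity()],
#'   [restitutionSummary()]
#' @export
setClass("VelocityEstimate",
  representation(
    beatIndex = "integer",
    wpv = "numeric",
    method = "character",
    direction = "numeric",
    points = "matrix",
    residual = "numeric"
  )
)

setValidity("VelocityEstimate", function(object) {
  msg <- character()
  if (!is.finite(object@wpv) || object@wpv <= 0)
    msg <- c(msg, "wpv must be positive and finite (cm/s)")
  if (!object@method %in% c("two_point", "plane_fit"))
    msg <- c(msg, "method must be 'two_point' or 'plane_fit'")
  if (length(msg)) msg else TRUE
})

#' HemodynamicRecord: continuous hemodynamics of one perfusion experiment
#'
#' Cardiac output and pressure channels sampled along the working-mode phase
#' of a single ex vivo perfusion run, plus pre/post heart weights.
#'
#' @slot experimentId identifier.
#' @slot times minutes from the start of working mode (strictly increasing).
#' @slot cardiacOutput L/min (>= 0), same length as \code{times}.
#' @slot pressures named list of numeric channels in mmHg (e.g.
#'   \code{aortic}, \code{atrial}), each the same length as \code{times}.
#' @slot heartWeightPre,heartWeightPost grams (> 0), NA when not weighed.
#' @seealso [deteriorationRate()], [homeostasisDuration()],
#'   [simulatePerfusionRun()]
#' @export
setClass("HemodynamicRecord",
  representation(
    experimentId = "character",
    times = "numeric",
    cardiacOutput = "numeric",
    pressures = "list",
    heartWeightPre = "numeric",
    heartWeightPost = "numeric"
  )
)

setValidity("HemodynamicRecord", function(object) {
  msg <- character()
  n <- length(object@times)
  if (n && is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing (minutes)")
  if (length(object@cardiacOutput) != n)
    msg <- c(msg, "cardiacOutput must match times in length")
  if (any(!is.finite(object@cardiacOutput)) ||
      any(object@cardiacOutput < 0))
    msg <- c(msg, "cardiacOutput must be finite and >= 0")
  for (nm in names(object@pressures)) {
    if (length(object@pressures[[nm]]) != n)
      msg <- c(msg, sprintf("pressure channel '%s' must match times", nm))
  }
  for (s in c("heartWeightPre", "heartWeightPost")) {
    v <- slot(object, s)
    if (length(v) != 1L || (!is.na(v) && v <= 0))
      msg <- c(msg, paste(s, "must be a single positive weight (g) or NA"))
  }
  if (length(msg)) msg else TRUE
})

#' TrendSummary: derived trend statistics for a biomarker panel
#'
#' Per-experiment hourly slopes, their across-experiment mean +/- SD, and
#' per-timepoint percent change from baseline with reference-range excursion
#' flags, for each analyte of a long-format biomarker table.
#'
#' @slot slopes data.frame: analyte, unit, experimentId, slope (unit/hour).
#' @slot slopeSummary data.frame: analyte, unit, meanSlope, sdSlope, n.
#' @slot timepoints data.frame: analyte, experimentId, timeMin, value,
#'   percentChange, flag (\code{low} / \code{in-range} / \code{high}, NA when
#'   no reference limits exist).
#' @seealso [trendSummary()], [hourlySlope()]
#' @export
setClass("TrendSummary",
  representation(
    slopes = "data.frame",
    slopeSummary = "data.frame",
    timepoints = "data.frame"
  )
)
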