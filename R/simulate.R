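#' Beat-train specification for the UEG simulator
#'
#' @param pacingRate pacing rate in beats/min; the hearts this pipeline
#'   targets are paced at 100, 120 and 150 bpm.
#' @param nBeats number of beats to simulate.
#' @param qrsWidth QRS width in ms (support of the biphasic deflection).
#' @param qrsAmplitude peak deflection amplitude (arbitrary signal units).
#' @param tWaveAmplitude amplitude of a broad positive T wave (0 = none).
#' @param noiseSd additive white Gaussian noise SD.
#' @param baselineWanderAmplitude,baselineWanderFreq sinusoidal baseline
#'   wander; the default 0.3 Hz lies inside the 0.5 Hz high-pass stopband.
#' @param pacingArtifactAmplitude amplitude of the 2-sample stimulus spike.
#' @param seed RNG seed: identical spec + seed gives a bit-identical
#'   recording.
#' @return a [BeatTrainSpec-class].
#' @export
beatTrainSpec <- function(pacingRate = 100, nBeats = 5, qrsWidth = 40,
                          qrsAmplitude = 1, tWaveAmplitude = 0.15,
                          noiseSd = 0, baselineWanderAmplitude = 0,
                          baselineWanderFreq = 0.3,
                          pacingArtifactAmplitude = 0, seed = 1L) {
  new("BeatTrainSpec", pacingRate = as.numeric(pacingRate),
      nBeats = as.integer(nBeats), qrsWidth = as.numeric(qrsWidth),
      qrsAmplitude = as.numeric(qrsAmplitude),
      tWaveAmplitude = as.numeric(tWaveAmplitude),
      noiseSd = as.numeric(noiseSd),
      baselineWanderAmplitude = as.numeric(baselineWanderAmplitude),
      baselineWanderFreq = as.numeric(baselineWanderFreq),
      pacingArtifactAmplitude = as.numeric(pacingArtifactAmplitude),
      seed = as.integer(seed))
}

# run expr under a given seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# biphasic R-then-S deflection: derivative-of-Gaussian, unit peak amplitude,
# steepest *negative* slope exactly at u = 0
qrsDeflection <- function(u, sigma) {
  -exp(0.5) * (u / sigma) * exp(-u^2 / (2 * sigma^2))
}

#' Simulate a paced multichannel UEG recording with known ground truth
#'
#' Generates a paced beat train on every electrode of \code{grid}: each beat
#' is a biphasic QRS deflection whose steepest negative slope falls exactly
#' at the channel's ground-truth activation time (given by the kinematic
#' \code{wavefront}), optionally followed by a broad T wave, plus baseline
#' wander, white noise and a rectangular pacing-stimulus artifact. Channels
#' listed as bad in the grid receive the nuisance components only (no
#' deflection). The ground-truth activation-time table is attached to the
#' returned recording for oracle use.
#'
#' @param grid an [ElectrodeGrid-class].
#' @param wavefront a [WavefrontSpec-class].
#' @param beats a [BeatTrainSpec-class].
#' @param fs sampling rate in Hz (>= 100); the two acquisition systems this
#'   emulates ran at 2048 Hz (11 x 11 grid) and 500 Hz (6 x 8 grid).
#' @return a [UegRecording-class] with \code{groundTruth()} filled in.
#' @examples
#' g <- ElectrodeGrid(6, 8, spacing = 5)
#' w <- planarWave(speed = 100, direction = c(1, 0), onsetDelay = 130)
#' rec <- simulateRecording(g, w, beatTrainSpec(pacingRate = 100, nBeats = 3),
#'                          fs = 500)
#' rec
#' @export
simulateRecording <- function(grid, wavefront, beats, fs = 2048) {
  stopifnot(is(grid, "ElectrodeGrid"), is(wavefront, "WavefrontSpec"),
            is(beats, "BeatTrainSpec"))
  fs <- as.numeric(fs)
  if (fs < 100)
    stop("configuration error: fs must be at least 100 Hz")
  if (beats@qrsWidth / 1000 * fs < 4)
    stop("configuration error: qrsWidth must span at least 4 samples at fs")
  intervalMs <- 60000 / beats@pacingRate
  if (intervalMs < beats@qrsWidth)
    stop("configuration error: pacing interval shorter than qrsWidth")

  pos <- electrodePositions(grid)
  at <- groundTruthAT(wavefront, pos)          # ms relative to stimulus
  bad <- badChannelIndices(grid)
  goodAt <- if (length(bad)) at[-bad] else at
  if (any(goodAt <= 0))
    stop("configuration error: wavefront activates before the stimulus; ",
         "increase onsetDelay")
  if (any(goodAt + beats@qrsWidth / 2 >= intervalMs))
    stop("configuration error: activation too late for the pacing interval")

  nCh <- nrow(pos)
  pacing <- (seq_len(beats@nBeats) - 1) * intervalMs
  nSamp <- as.integer(round(beats@nBeats * intervalMs * fs / 1000))
  tMs <- (seq_len(nSamp) - 1) / fs * 1000
  sigma <- beats@qrsWidth / 6                 # deflection support ~ +/- 3 sigma

  x <- matrix(0, nSamp, nCh)
  for (j in seq_len(nCh)) {
    if (j %in% bad) next
    for (stim in pacing) {
      u <- tMs - stim - at[j]
      sel <- which(abs(u) <= 4 * sigma)
      x[sel, j] <- x[sel, j] +
        beats@qrsAmplitude * qrsDeflection(u[sel], sigma)
      if (beats@tWaveAmplitude > 0) {
        ut <- tMs - stim - at[j] - 180        # T wave 180 ms after activation
        selT <- which(abs(ut) <= 160)
        x[selT, j] <- x[selT, j] +
          beats@tWaveAmplitude * exp(-ut[selT]^2 / (2 * 40^2))
      }
    }
  }

  withSeed(beats@seed, {
    if (beats@baselineWanderAmplitude > 0) {
      phase <- runif(nCh, 0, 2 * pi)
      w <- 2 * pi * beats@baselineWanderFreq / 1000
      for (j in seq_len(nCh))
        x[, j] <- x[, j] +
          beats@baselineWanderAmplitude * sin(w * tMs + phase[j])
    }
    if (beats@noiseSd > 0)
      x <- x + matrix(rnorm(nSamp * nCh, sd = beats@noiseSd), nSamp, nCh)
  })

  if (beats@pacingArtifactAmplitude > 0) {
    for (stim in pacing) {
      i0 <- as.integer(round(stim * fs / 1000)) + 1L
      idx <- i0:min(i0 + 1L, nSamp)
      x[idx, ] <- x[idx, ] + beats@pacingArtifactAmplitude
    }
  }

  gt <- at
  if (length(bad)) gt[bad] <- NA_real_
  UegRecording(x, fs = fs, grid = grid, pacingTimes = pacing,
               pacingRate = beats@pacingRate, groundTruthAT = gt)
}
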