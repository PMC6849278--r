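# Shared fixtures and independent oracles for the test suite.

# onset delay keeping every electrode's ground-truth AT positive with a
# safety margin, for arbitrary planar directions
onsetFor <- function(grid, dir, speed, margin = 15) {
  pos <- electrodePositions(grid)
  proj <- as.numeric(pos %*% (dir / sqrt(sum(dir^2))))
  margin + max(0, -min(proj)) / (speed / 100)
}

# the 8 compass directions
compassDirections <- function() {
  lapply(seq(0, 7) * pi / 4, function(a) c(cos(a), sin(a)))
}

# closed-form single-pass magnitude of an analog Butterworth band-pass of
# the given overall order (prototype order = order / 2)
butterBandpassGain <- function(f, fc1 = 0.5, fc2 = 40, order = 4) {
  om <- (f^2 - fc1 * fc2) / (f * (fc2 - fc1))
  1 / sqrt(1 + om^(2 * (order / 2)))
}

# amplitude of a steady sinusoid from its central samples (RMS * sqrt(2))
sineAmplitude <- function(y, idx) sqrt(2 * mean(y[idx]^2))

# independent plane-fit speed (cm/s) via explicit normal equations
planeFitOracleSpeed <- function(pos, at) {
  X <- cbind(1, pos)
  beta <- solve(crossprod(X), crossprod(X, at))
  100 / sqrt(beta[2L]^2 + beta[3L]^2)
}

# a recording shifted later in time by deltaMs (zeros prepended)
shiftRecording <- function(rec, deltaMs) {
  fs <- samplingRate(rec)
  nPad <- as.integer(round(deltaMs * fs / 1000))
  x <- samples(rec)
  UegRecording(rbind(matrix(0, nPad, ncol(x)), x), fs = fs,
               grid = electrodeGrid(rec),
               pacingTimes = pacingTimes(rec) + deltaMs,
               pacingRate = rec@pacingRate,
               groundTruthAT = groundTruth(rec))
}

# exact sign-flip permutation p-value for paired data (two-sided t statistic)
pairedPermutationP <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  tStat <- function(v) mean(v) / (stats::sd(v) / sqrt(length(v)))
  tobs <- abs(tStat(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tperm <- apply(signs, 1L, function(s) abs(tStat(s * d)))
  mean(tperm >= tobs - 1e-12)
}

# one-way ANOVA F computed from sums of squares (no model-fitting code)
manualF <- function(vals, grp) {
  grp <- factor(grp)
  gm <- tapply(vals, grp, mean)
  ns <- tapply(vals, grp, length)
  ssb <- sum(ns * (gm - mean(vals))^2)
  ssw <- sum((vals - gm[grp])^2)
  k <- nlevels(grp)
  (ssb / (k - 1)) / (ssw / (length(vals) - k))
}

# label-permutation p-value for the one-way ANOVA F statistic
anovaPermutationP <- function(vals, grp, B = 4000, seed = 1) {
  set.seed(seed)
  fobs <- manualF(vals, grp)
  fperm <- replicate(B, manualF(vals, sample(grp)))
  mean(fperm >= fobs - 1e-12)
}

# standard noiseless planar-wave recording used across tests
cleanPlanarRecording <- function(grid = ElectrodeGrid(11, 11, 5),
                                 speed = 100, dir = c(1, 0),
                                 onsetDelay = 130, pacingRate = 100,
                                 nBeats = 3, fs = 2048, ...) {
  simulateRecording(grid, planarWave(speed, dir, onsetDelay),
                    beatTrainSpec(pacingRate = pacingRate, nBeats = nBeats,
                                  ...),
                    fs = fs)
}

# an ActivationMap built directly from activation times (oracle input path)
mapFromAT <- function(grid, at, beatIndex = 1L) {
  valid <- !is.na(at)
  new("ActivationMap", beatIndex = as.integer(beatIndex), stimulusTime = 0,
      at = at, valid = valid, grid = grid)
}
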