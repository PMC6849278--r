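#' Default synthetic perfusion scenario
#'
#' Analyte-level parameters of the synthetic perfusion generator. Hourly
#' drift rates (mean +/- SD across experiments) follow the drifts reported
#' for hemoperfused ex vivo porcine hearts: sodium +3.9 +/- 1.2 and chloride
#' +4.7 +/- 2.4 mmol/L per hour, total calcium +0.3 +/- 0.2, phosphate
#' +0.2 +/- 0.08 and magnesium +0.2 +/- 0.1 mmol/L per hour, ammonia
#' +132.5 +/- 34.2 umol/L per hour from a 305 +/- 76 umol/L baseline,
#' potassium flat at 7 +/- 0.3 mmol/L, and glucose and lactate consumed at
#' about 1 mmol/L per hour. Baseline levels and reference ranges are
#' plausible porcine values chosen for the simulator, not measured ones.
#'
#' @return data.frame with columns \code{analyte}, \code{unit},
#'   \code{baselineMean}, \code{baselineSd}, \code{ratePerHour},
#'   \code{rateSd}, \code{noiseSd}, \code{refLow}, \code{refHigh}.
#' @export
perfusionScenario <- function() {
  data.frame(
    analyte = c("sodium", "potassium", "chloride", "calcium_total",
                "phosphate", "magnesium", "ammonia", "glucose", "lactate"),
    unit = c("mmol/L", "mmol/L", "mmol/L", "mmol/L", "mmol/L", "mmol/L",
             "umol/L", "mmol/L", "mmol/L"),
    baselineMean = c(145, 7, 110, 2.6, 2.6, 1.5, 305, 6, 5),
    baselineSd = c(4, 0.3, 5, 0.2, 0.4, 0.2, 76, 0.5, 1),
    ratePerHour = c(3.9, 0, 4.7, 0.3, 0.2, 0.2, 132.5, -1, -1),
    rateSd = c(1.2, 0, 2.4, 0.2, 0.08, 0.1, 34.2, 0.3, 0.3),
    noiseSd = c(1, 0.2, 1.5, 0.08, 0.1, 0.05, 20, 0.4, 0.4),
    refLow = c(135, 3.5, 97, 2.1, 0.8, 0.7, 10, 4, 0.5),
    refHigh = c(147, 5.1, 106, 2.6, 1.5, 1.05, 50, 7.8, 2.2)
  )
}

# truncated normal draw by rejection (bounds far enough from the mean that
# a handful of attempts always suffices)
rnormWithin <- function(mean, sd, lower = -Inf, upper = Inf) {
  for (i in 1:1000) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lower && v <= upper) return(v)
  }
  min(max(mean, lower), upper)
}

#' Simulate a set of ex vivo perfusion experiments
#'
#' Generates, per experiment: hourly biomarker series with per-experiment
#' linear drifts drawn around the scenario's rates; a hemodynamic record
#' whose cardiac output declines linearly in percent of baseline at a drawn
#' deterioration rate (baseline CO 5.1 +/- 1.7 L/min, deterioration
#' 12.5 +/- 2.7 percent of baseline per hour) with aortic (75 +/- 8 mmHg)
#' and atrial (13 +/- 2 mmHg) pressures held at their working-mode targets;
#' baseline draws respect the platform's inclusion criteria (CO >= 3 L/min,
#' AP >= 60 mmHg, ATP 10-20 mmHg at the start of working mode) by rejection
#' sampling; and paired heart weights (pre
#' 513 +/- 104 g, gain 144 +/- 41 g). The drawn ground-truth parameters are
#' returned so every trend statistic can be checked against them.
#'
#' @param nExperiments number of perfusion runs (the study design uses 7).
#' @param durationMin working-mode duration in minutes.
#' @param cadenceMin biomarker sampling cadence (baseline at 0, then every
#'   \code{cadenceMin}; blood panels are drawn hourly).
#' @param hemoCadenceMin cadence of the continuous hemodynamic channels.
#' @param scenario analyte parameter table, see [perfusionScenario()].
#' @param noiseScale multiplies every measurement-noise SD (0 = noiseless;
#'   per-experiment rate variability is kept either way).
#' @param seed integer seed; identical arguments + seed reproduce the run.
#' @return list with elements \code{biomarkers} (long data.frame),
#'   \code{hemodynamics} (list of [HemodynamicRecord-class]) and
#'   \code{truth} (list of data.frames \code{analytes} and \code{hemo} with
#'   the drawn ground-truth parameters, including the analytic time at which
#'   cardiac output crosses 3 L/min).
#' @examples
#' run <- simulatePerfusionRun(nExperiments = 2, noiseScale = 0, seed = 7)
#' hourlySlope(subset(run$biomarkers, analyte == "sodium"))
#' @export
simulatePerfusionRun <- function(nExperiments = 7, durationMin = 240,
                                 cadenceMin = 60, hemoCadenceMin = 10,
                                 scenario = perfusionScenario(),
                                 noiseScale = 1, seed = 1L) {
  if (nExperiments < 1 || durationMin <= 0 || cadenceMin <= 0 ||
      hemoCadenceMin <= 0 || noiseScale < 0)
    stop("configuration error: counts, durations and noiseScale must be ",
         "positive (noiseScale may be 0)")
  withSeed(seed, {
    tBio <- seq(0, durationMin, by = cadenceMin)
    tHemo <- seq(0, durationMin, by = hemoCadenceMin)
    bio <- list()
    hemo <- list()
    truthA <- list()
    truthH <- list()
    for (e in seq_len(nExperiments)) {
      eid <- sprintf("E%02d", e)
      rate <- stats::rnorm(nrow(scenario), scenario$ratePerHour,
                           scenario$rateSd)
      base <- stats::rnorm(nrow(scenario), scenario$baselineMean,
                           scenario$baselineSd)
      for (k in seq_len(nrow(scenario))) {
        vals <- base[k] + rate[k] * tBio / 60 +
          stats::rnorm(length(tBio), 0, scenario$noiseSd[k] * noiseScale)
        bio[[length(bio) + 1L]] <- data.frame(
          experiment_id = eid, analyte = scenario$analyte[k],
          unit = scenario$unit[k], time_min = tBio, value = vals,
          ref_low = scenario$refLow[k], ref_high = scenario$refHigh[k])
      }
      truthA[[e]] <- data.frame(experimentId = eid,
                                analyte = scenario$analyte,
                                baseline = base, ratePerHour = rate)

      # baseline hemodynamics are drawn subject to the platform's inclusion
      # criteria at working-mode start (CO >= 3 L/min, AP >= 60 mmHg,
      # ATP 10-20 mmHg): excluded hearts are redrawn, not clamped
      co0 <- rnormWithin(5.1, 1.7, lower = 3)
      det <- rnormWithin(12.5, 2.7, lower = 1)      # % of baseline per hour
      co <- pmax(0, co0 * (1 - det / 100 * tHemo / 60)) +
        stats::rnorm(length(tHemo), 0, 0.05 * noiseScale)
      co <- pmax(co, 0)
      aortic <- rnormWithin(75, 8, lower = 60) +
        stats::rnorm(length(tHemo), 0, 1 * noiseScale)
      atrial <- rnormWithin(13, 2, lower = 10, upper = 20) +
        stats::rnorm(length(tHemo), 0, 0.5 * noiseScale)
      wPre <- rnormWithin(513, 104, lower = 250)
      wGain <- rnormWithin(144, 41, lower = 10)
      hemo[[e]] <- HemodynamicRecord(
        eid, tHemo, co,
        pressures = list(aortic = aortic, atrial = atrial),
        heartWeightPre = wPre, heartWeightPost = wPre + wGain)
      truthH[[e]] <- data.frame(
        experimentId = eid, co0 = co0, deteriorationRate = det,
        coCrossingMin = 60 * (1 - 3 / co0) * 100 / det,
        weightPre = wPre, weightGain = wGain)
    }
    list(
      biomarkers = biomarkerSeries(do.call(rbind, bio)),
      hemodynamics = hemo,
      truth = list(analytes = do.call(rbind, truthA),
                   hemo = do.call(rbind, truthH))
    )
  })
}
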