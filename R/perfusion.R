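#' Validate a long-format biomarker table
#'
#' The perfusion analytics consume a long table with one row per analyte,
#' experiment and sampling time: columns \code{experiment_id},
#' \code{analyte}, \code{unit}, \code{time_min} (minutes from reperfusion;
#' the baseline, pre-connection sample sits at time 0), \code{value}, and
#' optionally \code{ref_low} / \code{ref_high} (reference limits in the same
#' unit, NA when none exist).
#'
#' @param df a data.frame.
#' @return the validated data.frame (with ref columns added as NA when
#'   missing), ordered by analyte, experiment and time.
#' @export
biomarkerSeries <- function(df) {
  need <- c("experiment_id", "analyte", "unit", "time_min", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("biomarker table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!all(is.finite(df$value)))
    stop("biomarker values must be finite")
  if (any(!nzchar(df$unit)))
    stop("unit must be non-empty")
  for (rc in c("ref_low", "ref_high"))
    if (is.null(df[[rc]])) df[[rc]] <- NA_real_
  df <- df[order(df$analyte, df$experiment_id, df$time_min), , drop = FALSE]
  sp <- split(df$time_min, interaction(df$analyte, df$experiment_id,
                                       drop = TRUE))
  if (any(vapply(sp, function(tt) any(diff(tt) <= 0), logical(1))))
    stop("times must be strictly increasing within each ",
         "analyte/experiment series")
  rownames(df) <- NULL
  df
}

#' Read a delimited biomarker table
#'
#' @param path file with a header row and the columns described in
#'   [biomarkerSeries()].
#' @param sep field separator (default tab).
#' @return a validated long-format data.frame.
#' @export
readBiomarkerTable <- function(path, sep = "\t") {
  biomarkerSeries(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE))
}

#' Percent change from baseline
#'
#' \code{100 * (later - baseline) / baseline}; e.g. a mean heart weight going
#' from 513 g to 657 g is a 28\% increase.
#'
#' @param baseline,later numeric (vectorised; baseline must be nonzero).
#' @return percent change.
#' @export
percentChange <- function(baseline, later) {
  if (any(baseline == 0))
    stop("percent change undefined for a zero baseline")
  100 * (later - baseline) / baseline
}

#' Reference-range excursion flags
#'
#' @param values numeric measurements.
#' @param refLow,refHigh reference limits (scalar or per-value; NA when a
#'   limit does not exist).
#' @return character vector: \code{"low"}, \code{"in-range"} or
#'   \code{"high"}; NA where both limits are missing. Every sample with at
#'   least one limit gets exactly one flag.
#' @export
excursionFlags <- function(values, refLow = NA_real_, refHigh = NA_real_) {
  refLow <- rep_len(refLow, length(values))
  refHigh <- rep_len(refHigh, length(values))
  out <- rep(NA_character_, length(values))
  has <- !is.na(refLow) | !is.na(refHigh)
  out[has] <- "in-range"
  out[has & !is.na(refLow) & values < refLow] <- "low"
  out[has & !is.na(refHigh) & values > refHigh] <- "high"
  out
}

#' Per-experiment hourly slopes of a biomarker series
#'
#' Ordinary least-squares slope of concentration versus time (converted to
#' per-hour) for every analyte/experiment series. Reported per hour because
#' perfusion panels are sampled every 60 min after reperfusion.
#'
#' @param series a long-format table (see [biomarkerSeries()]).
#' @return data.frame: \code{analyte}, \code{unit}, \code{experimentId},
#'   \code{slope} (unit/hour).
#' @examples
#' df <- data.frame(experiment_id = "E1", analyte = "ammonia",
#'                  unit = "umol/L", time_min = c(0, 60, 120, 180),
#'                  value = 300 + 132.5 * c(0, 1, 2, 3))
#' hourlySlope(df)  # slope 132.5 umol/L per hour
#' @export
hourlySlope <- function(series) {
  series <- biomarkerSeries(series)
  sp <- split(series, series[c("analyte", "experiment_id")], drop = TRUE)
  rows <- lapply(sp, function(d) {
    if (nrow(d) < 2L)
      stop("hourly slope needs at least 2 time points (analyte ",
           d$analyte[1L], ", experiment ", d$experiment_id[1L], ")")
    hours <- d$time_min / 60
    fit <- stats::lm.fit(cbind(1, hours), d$value)
    data.frame(analyte = d$analyte[1L], unit = d$unit[1L],
               experimentId = d$experiment_id[1L],
               slope = unname(fit$coefficients[2L]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$analyte, out$experimentId), , drop = FALSE]
}

#' Full trend summary for a biomarker panel
#'
#' Combines, per analyte: per-experiment OLS hourly slopes and their
#' across-experiment mean +/- sample SD; per-timepoint percent change from
#' the baseline (first) sample of each series; and reference-range excursion
#' flags where limits exist.
#'
#' @param series a long-format table (see [biomarkerSeries()]).
#' @return a [TrendSummary-class].
#' @export
trendSummary <- function(series) {
  series <- biomarkerSeries(series)
  slopes <- hourlySlope(series)
  sm <- lapply(split(slopes, slopes$analyte), function(d) {
    data.frame(analyte = d$analyte[1L], unit = d$unit[1L],
               meanSlope = mean(d$slope),
               sdSlope = if (nrow(d) > 1L) stats::sd(d$slope) else 0,
               n = nrow(d))
  })
  sm <- do.call(rbind, sm)
  rownames(sm) <- NULL

  sp <- split(series, series[c("analyte", "experiment_id")], drop = TRUE)
  tp <- lapply(sp, function(d) {
    base <- d$value[1L]
    data.frame(analyte = d$analyte, experimentId = d$experiment_id,
               timeMin = d$time_min, value = d$value,
               percentChange = percentChange(base, d$value),
               flag = excursionFlags(d$value, d$ref_low, d$ref_high))
  })
  tp <- do.call(rbind, tp)
  rownames(tp) <- NULL
  new("TrendSummary", slopes = slopes, slopeSummary = sm, timepoints = tp)
}

setMethod("show", "TrendSummary", function(object) {
  cat("TrendSummary:", nrow(object@slopeSummary), "analyte(s),",
      length(unique(object@slopes$experimentId)), "experiment(s)\n")
  print(object@slopeSummary)
})

#' @rdname TrendSummary-accessors
#' @param x a [TrendSummary-class].
#' @export
setGeneric("trendSlopes", function(x) standardGeneric("trendSlopes"))

#' Accessors for TrendSummary
#'
#' @param x a [TrendSummary-class].
#' @return \code{trendSlopes}: per-experiment slopes;
#'   \code{trendSlopeSummary}: per-analyte mean +/- SD slope;
#'   \code{trendTimepoints}: percent change and excursion flag per sample.
#' @name TrendSummary-accessors
#' @export
setGeneric("trendSlopeSummary", function(x) {
  standardGeneric("trendSlopeSummary")
})

#' @rdname TrendSummary-accessors
#' @export
setGeneric("trendTimepoints", function(x) standardGeneric("trendTimepoints"))

#' @rdname TrendSummary-accessors
#' @export
setMethod("trendSlopes", "TrendSummary", function(x) x@slopes)

#' @rdname TrendSummary-accessors
#' @export
setMethod("trendSlopeSummary", "TrendSummary", function(x) x@slopeSummary)

#' @rdname TrendSummary-accessors
#' @export
setMethod("trendTimepoints", "TrendSummary", function(x) x@timepoints)

#' Construct a HemodynamicRecord
#'
#' @param experimentId identifier.
#' @param times minutes from the start of working mode.
#' @param cardiacOutput L/min, same length as \code{times}.
#' @param pressures named list of mmHg channels (e.g. \code{aortic},
#'   \code{atrial}).
#' @param heartWeightPre,heartWeightPost grams (NA if not weighed).
#' @return a [HemodynamicRecord-class].
#' @export
HemodynamicRecord <- function(experimentId, times, cardiacOutput,
                              pressures = list(),
                              heartWeightPre = NA_real_,
                              heartWeightPost = NA_real_) {
  new("HemodynamicRecord", experimentId = as.character(experimentId),
      times = as.numeric(times), cardiacOutput = as.numeric(cardiacOutput),
      pressures = pressures, heartWeightPre = as.numeric(heartWeightPre),
      heartWeightPost = as.numeric(heartWeightPost))
}

setMethod("show", "HemodynamicRecord", function(object) {
  cat(sprintf(
    "HemodynamicRecord '%s': %d samples over %g min, CO %.1f -> %.1f L/min\n",
    object@experimentId, length(object@times),
    diff(range(object@times)), head(object@cardiacOutput, 1L),
    tail(object@cardiacOutput, 1L)))
})

#' Cardiac-output deterioration rate
#'
#' Expresses cardiac output as percent of its baseline (first) value,
#' regresses it on time by OLS and returns the negated slope, so a heart
#' losing a quarter of its baseline output over two hours deteriorates at
#' 12.5 \%/hour.
#'
#' @param record a [HemodynamicRecord-class] with >= 2 samples and positive
#'   baseline cardiac output.
#' @return deterioration rate in percent of baseline per hour (positive =
#'   declining).
#' @export
deteriorationRate <- function(record) {
  stopifnot(is(record, "HemodynamicRecord"))
  co <- record@cardiacOutput
  if (length(co) < 2L)
    stop("deterioration rate needs at least 2 cardiac-output samples")
  if (co[1L] <= 0)
    stop("baseline cardiac output must be positive")
  pct <- 100 * co / co[1L]
  hours <- record@times / 60
  fit <- stats::lm.fit(cbind(1, hours), pct)
  -unname(fit$coefficients[2L])
}

#' Homeostasis duration of a perfusion run
#'
#' Time from the start of working mode until the physiological criterion
#' first fails persistently (on \code{persistence} consecutive samples); if
#' it never does, the full record length. The default criterion reuses the
#' experiments' own inclusion thresholds: cardiac output >= 3 L/min, mean
#' aortic pressure >= 60 mmHg and atrial pressure within 10-20 mmHg.
#' Pressure conditions are skipped when the record carries no such channel.
#' The persistence rule (default 2 consecutive samples) keeps single-sample
#' noise from ending a run.
#'
#' @param record a [HemodynamicRecord-class].
#' @param coMin minimum cardiac output, L/min.
#' @param aorticMin minimum mean aortic pressure, mmHg.
#' @param atrialRange allowed atrial pressure range, mmHg.
#' @param persistence consecutive failing samples required.
#' @return duration in minutes.
#' @export
homeostasisDuration <- function(record, coMin = 3, aorticMin = 60,
                                atrialRange = c(10, 20), persistence = 2L) {
  stopifnot(is(record, "HemodynamicRecord"))
  n <- length(record@times)
  if (n == 0L) return(0)
  ok <- record@cardiacOutput >= coMin
  pr <- record@pressures
  if (!is.null(pr$aortic)) ok <- ok & pr$aortic >= aorticMin
  if (!is.null(pr$atrial))
    ok <- ok & pr$atrial >= atrialRange[1L] & pr$atrial <= atrialRange[2L]
  persistence <- max(1L, as.integer(persistence))
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (ok[i]) 0L else run + 1L
    if (run >= persistence)
      return(record@times[i - persistence + 1L] - record@times[1L])
  }
  record@times[n] - record@times[1L]
}

#' Paired heart-weight change test
#'
#' Paired t-test on pre- versus post-perfusion heart weights, with the mean
#' difference and the percent change of the means. If every pair changes by
#' exactly the same amount the t statistic degenerates (zero variance of the
#' differences); this is reported as p = 0 (or p = 1 for no change at all)
#' with \code{degenerate = TRUE} instead of an error.
#'
#' @param pre,post paired weights in grams (equal length, n >= 2).
#' @param alpha significance criterion (default 0.05).
#' @return list: \code{meanDifference} (g), \code{percentChange} (of the
#'   mean), \code{statistic}, \code{pValue}, \code{significant},
#'   \code{degenerate}.
#' @examples
#' weightChangeTest(pre = c(480, 530, 560), post = c(610, 640, 720))
#' @export
weightChangeTest <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post))
    stop("pre and post weights must be paired (equal length)")
  if (length(pre) < 2L)
    stop("need at least 2 pairs")
  d <- post - pre
  meanDiff <- mean(d)
  pct <- percentChange(mean(pre), mean(post))
  if (stats::sd(d) == 0) {
    p <- if (meanDiff == 0) 1 else 0
    return(list(meanDifference = meanDiff, percentChange = pct,
                statistic = if (meanDiff == 0) 0 else Inf * sign(meanDiff),
                pValue = p, significant = p <= alpha, degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(meanDifference = meanDiff, percentChange = pct,
       statistic = unname(tt$statistic), pValue = tt$p.value,
       significant = tt$p.value <= alpha, degenerate = FALSE)
}

#' One-way ANOVA across sampling hours
#'
#' Routine one-way analysis of variance of concentration against sampling
#' time (treated as a categorical group), per analyte, pooling experiments
#' within each hour. Raw p-values are reported without multiplicity
#' adjustment.
#'
#' @param series a long-format table (see [biomarkerSeries()]).
#' @return data.frame: \code{analyte}, \code{fStatistic}, \code{pValue}.
#' @export
anovaAcrossHours <- function(series) {
  series <- biomarkerSeries(series)
  rows <- lapply(split(series, series$analyte), function(d) {
    grp <- factor(d$time_min)
    if (nlevels(grp) < 2L || any(table(grp) < 2L))
      stop("ANOVA for analyte ", d$analyte[1L],
           " needs >= 2 groups with >= 2 values each")
    if (all(d$value == d$value[1L]))
      stop("ANOVA for analyte ", d$analyte[1L],
           " is degenerate: all values identical")
    fit <- stats::aov(value ~ grp, data = data.frame(value = d$value,
                                                     grp = grp))
    s <- summary(fit)[[1L]]
    data.frame(analyte = d$analyte[1L], fStatistic = s[["F value"]][1L],
               pValue = s[["Pr(>F)"]][1L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
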