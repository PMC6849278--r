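linSeries <- function(slope, base = 300, times = c(0, 60, 120, 180),
                      id = "E1", analyte = "ammonia", unit = "umol/L") {
  data.frame(experiment_id = id, analyte = analyte, unit = unit,
             time_min = times, value = base + slope * times / 60)
}

test_that("hourly slope recovers exact linear drifts and flags degenerate input", {
  expect_equal(hourlySlope(linSeries(132.5))$slope, 132.5)
  expect_equal(hourlySlope(linSeries(0))$slope, 0)
  expect_error(hourlySlope(linSeries(1, times = 0)), "2 time points")
})

test_that("slopes and percent change are scale-equivariant", {
  s <- linSeries(3.9, base = 140)
  k <- 7.3
  s2 <- s; s2$value <- k * s2$value
  expect_equal(hourlySlope(s2)$slope, k * hourlySlope(s)$slope)
  expect_equal(percentChange(s2$value[1], s2$value[4]),
               percentChange(s$value[1], s$value[4]))
})

test_that("percent change matches the worked weight example", {
  expect_equal(round(percentChange(513, 657)), 28)
  expect_equal(percentChange(100, 100), 0)
  expect_equal(percentChange(100, 50), -50)
  expect_error(percentChange(0, 10), "zero baseline")
})

test_that("excursion flags partition every referenced sample", {
  f <- excursionFlags(c(1, 5, 9, 5), refLow = 2, refHigh = 8)
  expect_equal(f, c("low", "in-range", "high", "in-range"))
  expect_true(all(!is.na(f)))
  # no limits -> no flag
  expect_true(all(is.na(excursionFlags(1:3))))
  # one-sided limits still produce exactly one flag per sample
  f2 <- excursionFlags(c(1, 9), refHigh = 8)
  expect_equal(f2, c("in-range", "high"))
})

test_that("trend summary aggregates slopes with mean +/- sample SD", {
  df <- rbind(linSeries(3.0, id = "E1", analyte = "sodium", unit = "mmol/L"),
              linSeries(4.8, id = "E2", analyte = "sodium", unit = "mmol/L"))
  df$ref_low <- 136; df$ref_high <- 144
  ts <- trendSummary(df)
  sm <- trendSlopeSummary(ts)
  expect_equal(sm$meanSlope, 3.9)
  expect_equal(sm$sdSlope, sd(c(3.0, 4.8)))
  tp <- trendTimepoints(ts)
  expect_equal(tp$percentChange[tp$timeMin == 0], c(0, 0))
  expect_true(all(tp$flag %in% c("low", "in-range", "high")))
})

test_that("deterioration rate matches the closed-form percent decline", {
  # 100% -> 75% of baseline over 120 min is 12.5%/h
  r <- HemodynamicRecord("E1", times = c(0, 60, 120),
                         cardiacOutput = 5 * c(1, 0.875, 0.75))
  expect_equal(deteriorationRate(r), 12.5)
  r0 <- HemodynamicRecord("E1", times = c(0, 60, 120),
                          cardiacOutput = c(5, 5, 5))
  expect_equal(deteriorationRate(r0), 0)
  expect_error(deteriorationRate(HemodynamicRecord("E", 0, 5)), "2")
})

test_that("homeostasis duration implements the persistent-failure rule", {
  tt <- seq(0, 240, by = 3)
  # criterion always met: full record length
  ok <- HemodynamicRecord("E", tt, rep(5, length(tt)),
                          pressures = list(aortic = rep(75, length(tt)),
                                           atrial = rep(13, length(tt))))
  expect_equal(homeostasisDuration(ok), 240)
  # CO crosses 3 L/min at t = 171 min and stays below
  co <- ifelse(tt < 171, 5, 2.5)
  fail <- HemodynamicRecord("E", tt, co)
  expect_equal(homeostasisDuration(fail), 171)
  # a single-sample dip does not end the run
  co2 <- rep(5, length(tt)); co2[30] <- 2
  expect_equal(homeostasisDuration(HemodynamicRecord("E", tt, co2)), 240)
  # pressure criteria participate when channels exist
  lowAp <- HemodynamicRecord("E", tt, rep(5, length(tt)),
                             pressures = list(aortic = ifelse(tt < 60, 75,
                                                              40)))
  expect_equal(homeostasisDuration(lowAp), 60)
})

test_that("exponential cardiac-output decay crosses at the analytic time", {
  co0 <- 5.1; tau <- 180
  tt <- seq(0, 400, by = 5)
  r <- HemodynamicRecord("E", tt, co0 * exp(-tt / tau))
  tStar <- tau * log(co0 / 3)
  expect_lte(abs(homeostasisDuration(r) - tStar), 5)
})

test_that("weight change test handles regular, degenerate and identical pairs", {
  same <- weightChangeTest(c(500, 520, 540), c(500, 520, 540))
  expect_equal(same$meanDifference, 0)
  expect_equal(same$pValue, 1)
  shift <- weightChangeTest(c(500, 520, 540), c(510, 530, 550))
  expect_true(shift$degenerate)
  expect_equal(shift$pValue, 0)
  expect_equal(shift$statistic, Inf)
  expect_error(weightChangeTest(c(1, 2), c(1, 2, 3)), "paired")
})

test_that("paired t-test agrees with the exact sign-flip permutation oracle", {
  set.seed(11)
  pre <- rnorm(16, 513, 104)
  post <- pre + rnorm(16, 60, 90)
  res <- weightChangeTest(pre, post)
  expect_lt(abs(res$pValue - pairedPermutationP(pre, post)), 0.02)
  expect_false(res$degenerate)
})

test_that("one-way ANOVA across hours behaves like the classical F test", {
  # equal group means and spreads: F = 0, p = 1
  flat <- data.frame(experiment_id = rep(paste0("E", 1:3), times = 2),
                     analyte = "urea", unit = "mmol/L",
                     time_min = rep(c(0, 60), each = 3),
                     value = rep(c(3.4, 3.5, 3.6), times = 2))
  res <- anovaAcrossHours(flat)
  expect_equal(res$fStatistic, 0)
  expect_equal(res$pValue, 1)

  # two groups: F equals the squared two-sample t
  set.seed(21)
  df2 <- data.frame(experiment_id = rep(paste0("E", 1:6), times = 2),
                    analyte = "sodium", unit = "mmol/L",
                    time_min = rep(c(0, 60), each = 6),
                    value = c(rnorm(6, 140, 3), rnorm(6, 144, 3)))
  res2 <- anovaAcrossHours(df2)
  t2 <- t.test(value ~ time_min, data = df2, var.equal = TRUE)$statistic^2
  expect_equal(res2$fStatistic, unname(t2))

  # and with the label-permutation oracle
  set.seed(22)
  df3 <- data.frame(experiment_id = rep(paste0("E", 1:8), times = 3),
                    analyte = "chloride", unit = "mmol/L",
                    time_min = rep(c(0, 60, 120), each = 8),
                    value = c(rnorm(8, 105, 4), rnorm(8, 107, 4),
                              rnorm(8, 109, 4)))
  res3 <- anovaAcrossHours(df3)
  pPerm <- anovaPermutationP(df3$value, df3$time_min, B = 4000, seed = 3)
  expect_lt(abs(res3$pValue - pPerm), 0.04)

  expect_error(anovaAcrossHours(linSeries(1)), "2 groups|2 values")
})

test_that("the perfusion generator is deterministic and returns its ground truth", {
  r1 <- simulatePerfusionRun(nExperiments = 2, seed = 33)
  r2 <- simulatePerfusionRun(nExperiments = 2, seed = 33)
  expect_identical(r1$biomarkers, r2$biomarkers)
  expect_identical(r1$truth, r2$truth)
  expect_false(identical(
    r1$biomarkers,
    simulatePerfusionRun(nExperiments = 2, seed = 34)$biomarkers))
  expect_error(simulatePerfusionRun(nExperiments = 0), "configuration")
})

test_that("noiseless synthetic runs are recovered exactly", {
  run <- simulatePerfusionRun(nExperiments = 3, noiseScale = 0, seed = 7)
  sl <- hourlySlope(run$biomarkers)
  truth <- run$truth$analytes
  key <- paste(sl$analyte, sl$experimentId)
  tkey <- paste(truth$analyte, truth$experimentId)
  expect_equal(sl$slope, truth$ratePerHour[match(key, tkey)],
               tolerance = 1e-9)
  for (e in seq_along(run$hemodynamics)) {
    expect_equal(deteriorationRate(run$hemodynamics[[e]]),
                 run$truth$hemo$deteriorationRate[e], tolerance = 1e-9)
  }
})

test_that("noisy synthetic runs are recovered within Monte-Carlo oracle bands", {
  # oracle: distribution of the across-experiment mean sodium slope under
  # the generator's own sampling design (7 runs, hourly samples, noise 1)
  set.seed(55)
  hours <- c(0, 60, 120, 180, 240) / 60
  sxx <- sum((hours - mean(hours))^2)
  reps <- replicate(1000, {
    rates <- rnorm(7, 3.9, 1.2)
    est <- rates + vapply(seq_len(7), function(i) {
      e <- rnorm(length(hours), 0, 1)
      sum((hours - mean(hours)) * e) / sxx
    }, numeric(1))
    mean(est)
  })
  lo <- mean(reps) - 4 * sd(reps); hi <- mean(reps) + 4 * sd(reps)
  run <- simulatePerfusionRun(nExperiments = 7, seed = 101)
  sodium <- trendSlopeSummary(trendSummary(
    run$biomarkers[run$biomarkers$analyte == "sodium", ]))
  expect_gt(sodium$meanSlope, lo)
  expect_lt(sodium$meanSlope, hi)
  # homeostasis (judged on the cardiac-output criterion) ends near the
  # analytic crossing time when that falls inside the recorded span; CO
  # noise around the threshold can move the persistent failure by a couple
  # of samples either way
  for (e in seq_len(7)) {
    cross <- run$truth$hemo$coCrossingMin[e]
    h <- run$hemodynamics[[e]]
    coOnly <- HemodynamicRecord(h@experimentId, h@times, h@cardiacOutput)
    got <- homeostasisDuration(coOnly)
    if (cross < 230) expect_lte(abs(got - cross), 20 + 1e-9)
  }
})
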