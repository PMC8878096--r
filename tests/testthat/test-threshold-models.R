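ref <- barleyHaloTTParams()

test_that("probit transform and boundary handling", {
  expect_equal(probitFraction(0.5), 0)
  expect_equal(probitFraction(0.8413), 1, tolerance = 1e-3)
  gs <- c(0.1, 0.25, 0.7)
  expect_equal(probitFraction(gs) + probitFraction(1 - gs), rep(0, 3))
  expect_error(probitFraction(1.1), "0, 1")
  expect_true(is.na(probitFraction(0)))
  expect_true(is.na(probitFraction(1)))
  expect_equal(probitFraction(1, n = 10), qnorm(19 / 20))
})

test_that("thermal-time constants follow the sub/supra forms", {
  tt <- thermalTimeConstants(25, Tb = 15, Tc_g = 40, tg = 76.8)
  expect_equal(tt$theta_sub, 768)
  expect_equal(tt$theta_supra, (40 - 15) * 76.8)
  ttc <- thermalTimeConstants(25, 15, 40, 76.8, supraForm = "conventional")
  expect_equal(ttc$theta_supra, (40 - 25) * 76.8)
  # at the base temperature no thermal time accumulates
  tt0 <- thermalTimeConstants(15, 15, 40, 50)
  expect_true(is.na(tt0$theta_sub))
  expect_true("below_base_temperature" %in% tt0$flags)
  # linearity in tg
  tt2 <- thermalTimeConstants(25, 15, 40, 2 * 76.8)
  expect_equal(tt2$theta_sub, 2 * tt$theta_sub)
  expect_equal(tt2$theta_supra, 2 * tt$theta_supra)
})

test_that("halotime fit recovers generator parameters on noise-free curves", {
  curves <- dense_model_curves(ref, temps = 20, psis = c(0, -0.1, -0.2, -0.3))
  fit <- fitHalotime(curves)
  expect_s4_class(fit, "ProbitFit")
  expect_equal(theta(fit), 17.65, tolerance = 0.01)
  expect_equal(psiB50(fit), -0.23, tolerance = 0.01)
  expect_equal(sigmaPsiB(fit), 0.21, tolerance = 0.01)
  expect_gt(r2(fit), 0.999)
})

test_that("halotime fit rejects degenerate inputs", {
  # single water potential: the spread of a single-threshold population is
  # unidentifiable and the precondition fails
  one_psi <- dense_model_curves(ref, temps = 20, psis = 0)
  expect_error(fitHalotime(one_psi), "water-potential levels")
  # curves at different temperatures are not a halotime design
  two_T <- dense_model_curves(ref, temps = c(20, 21), psis = c(0, -0.1))
  expect_error(fitHalotime(two_T), "single temperature")
  # a vanishing threshold spread makes every percentile time identical and
  # the probit regression degenerate
  p0 <- haloTTParams(psiB50 = -1, sigmaPsiB = 1e-9, thetaHalo = 17.65,
                     kT = 0, Tb = 15, To = 20, Tc = 40)
  cfg <- simConfig(params = p0, temperatures = 20, psis = 0, replicates = 1,
                   seedsPerDish = 50, viability = 1, noise = 0,
                   thresholds = "stratified")
  cv <- treatmentCurves(GerminationExperiment(
    simulateExperiment(cfg)$records))
  expect_error(fitHalotime(cv))
})

test_that("halotime fit matches the exhaustive brute-force SSE oracle", {
  # small count-backed toy: two psi levels, 20 seeds each
  cfg <- simConfig(temperatures = 20, psis = c(0, -0.3), replicates = 1,
                   seedsPerDish = 20, viability = 1, noise = 0,
                   observationTimes = seq(12, 336, by = 12),
                   thresholds = "stratified")
  curves <- treatmentCurves(GerminationExperiment(
    simulateExperiment(cfg)$records))
  fit <- fitHalotime(curves)
  pts <- fit@points
  oracle <- halotime_bruteforce(
    pts,
    theta_grid = seq(10, 30, by = 0.5),
    loc_grid = seq(-0.5, 0, by = 0.01),
    sigma_grid = seq(0.05, 0.5, by = 0.01))
  # maximizing R^2 over theta with the inner regression minimizes the same
  # SSE (the probit responses are fixed): the optimized fit must dominate
  # the exhaustive grid ...
  y <- qnorm(pts$g)
  x <- pts$psi - theta(fit) / pts$tg
  sse_fit <- sum((y - (x - psiB50(fit)) / sigmaPsiB(fit))^2)
  expect_lte(sse_fit, oracle$sse + 1e-9)
  # ... and land on the same optimum within the oracle's grid resolution
  expect_equal(theta(fit), oracle$theta, tolerance = 0.05)
  expect_equal(psiB50(fit), oracle$location, tolerance = 0.08)
  expect_equal(sigmaPsiB(fit), oracle$sigma, tolerance = 0.08)
})

test_that("joint halothermal fit recovers all five parameters on the
           noise-free factorial design", {
  cfg <- simConfig(replicates = 1, seedsPerDish = 400,
                   observationTimes = seq(4, 1600, by = 4),
                   viability = 1, noise = 0, thresholds = "stratified")
  curves <- treatmentCurves(GerminationExperiment(
    simulateExperiment(cfg)$records))
  fit <- suppressWarnings(fitHalothermal(curves, Tb = 15, To = 20, Tc = 40))
  expect_equal(psiB50(fit), -0.23, tolerance = 0.05)
  expect_equal(sigmaPsiB(fit), 0.21, tolerance = 0.05)
  expect_equal(thetaHaloTT(fit), 17.65 * 5, tolerance = 0.05)
  expect_equal(thetaHalo(fit), 17.65, tolerance = 0.05)
  expect_equal(kT(fit), 0.104, tolerance = 0.05)
})

test_that("at a single sub-optimal temperature the halothermal constant
           reduces to the halotime constant", {
  curves <- dense_model_curves(ref, temps = 18, psis = c(0, -0.1, -0.2))
  halo <- fitHalotime(curves)
  htt <- fitHalothermal(curves, Tb = 15, To = 20)
  expect_equal(thetaHaloTT(htt) / (18 - 15), theta(halo), tolerance = 2e-3)
  expect_equal(psiB50(htt), psiB50(halo), tolerance = 1e-3)
  expect_equal(sigmaPsiB(htt), sigmaPsiB(halo), tolerance = 1e-3)
  # kT is pinned to zero without supra-optimal temperatures
  expect_identical(kT(htt), 0)
})

test_that("joint fit matches a brute-force (theta, kT) grid on a toy set", {
  curves <- dense_model_curves(ref, temps = c(18, 21),
                               psis = c(0, -0.1, -0.2),
                               times = seq(24, 1200, by = 24))
  fit <- fitHalothermal(curves, Tb = 15, To = 20)
  pts <- halott:::probit_points(curves, "observed")
  y <- pts$probit
  supra <- pmax(0, pts$temperature - 20)
  denom <- (pts$temperature - 15) * pts$tg
  best <- list(r2 = -Inf)
  for (th in seq(60, 120, by = 1)) for (k in seq(0, 0.3, by = 0.005)) {
    x <- pts$psi - k * supra - th / denom
    f <- lm.fit(cbind(1, x), y)
    r2 <- 1 - sum(f$residuals^2) / sum((y - mean(y))^2)
    if (is.finite(r2) && r2 > best$r2) best <- list(r2 = r2, th = th, k = k)
  }
  expect_equal(thetaHaloTT(fit), best$th, tolerance = 0.02)
  expect_equal(kT(fit), best$k, tolerance = 0.06)
  expect_gte(r2(fit), best$r2 - 1e-6)
})

test_that("joint fit rejects impossible designs", {
  curves <- dense_model_curves(ref, temps = 20, psis = c(0, -0.1))
  expect_error(fitHalothermal(curves, Tb = 25, To = 30),
               "below the base temperature")
  one <- dense_model_curves(ref, temps = 20, psis = 0)
  expect_error(fitHalothermal(one, Tb = 15, To = 20), "collinear")
})

test_that("predicted time courses behave like the forward model", {
  times <- c(24, 48, 96, 192, 384, 1e6)
  cv <- predictTimeCourse(ref, 20, 0, times)
  # asymptotic fraction Phi((psi - psiB50)/sigma) = Phi(0.23/0.21)
  expect_equal(cv@cum_fraction[length(times)], pnorm(0.23 / 0.21),
               tolerance = 1e-3)
  expect_equal(pnorm(0.23 / 0.21), 0.863, tolerance = 1e-3)
  # at psi_adj = psiB50 the asymptote is one half
  cv50 <- predictTimeCourse(ref, 20, ref@psiB50, c(1e7, 2e7))
  expect_equal(cv50@cum_fraction[2], 0.5, tolerance = 1e-4)
  # outside the thermal range: all-zero, flagged
  cv0 <- predictTimeCourse(ref, 42, 0, times)
  expect_true(all(cv0@cum_fraction == 0))
  expect_true("outside_thermal_range" %in% cv0@flags)
  expect_true(all(predictTimeCourse(ref, 15, 0, times)@cum_fraction == 0))
})

test_that("forward model then refit round-trips the parameter set", {
  curves <- dense_model_curves(ref, temps = c(16, 18, 20, 21, 22),
                               psis = c(0, -0.1, -0.2, -0.3))
  fit <- fitHalothermal(curves, Tb = 15, To = 20, Tc = 40)
  expect_equal(psiB50(fit), ref@psiB50, tolerance = 0.02 / abs(ref@psiB50))
  expect_equal(sigmaPsiB(fit), ref@sigmaPsiB,
               tolerance = 0.02 / ref@sigmaPsiB)
  expect_equal(thetaHaloTT(fit), ref@thetaHaloTT, tolerance = 0.02)
  expect_gt(r2(fit), 1 - 1e-4)
})

test_that("fitted model orders median germination time with stress", {
  fitted <- fitHalothermal(
    dense_model_curves(ref, temps = c(16, 18, 20), psis = c(0, -0.1, -0.2)),
    Tb = 15, To = 20, Tc = 40)
  t50_at <- function(T, psi)
    timeToPercentile(predictTimeCourse(fitted, T, psi,
                                       seq(4, 20000, by = 4)), 0.5)
  # drier -> slower at fixed sub-optimal temperature
  expect_true(t50_at(18, 0) < t50_at(18, -0.1))
  expect_true(t50_at(18, -0.1) < t50_at(18, -0.2))
  # colder toward Tb -> slower at fixed psi
  expect_true(t50_at(20, 0) < t50_at(18, 0))
  expect_true(t50_at(18, 0) < t50_at(16, 0))
})

test_that("accessors and show methods expose the fitted quantities", {
  expect_equal(cardinalTemperatures(ref), c(Tb = 15, To = 20, Tc = 40))
  expect_equal(thetaHalo(ref), 17.65)
  expect_equal(thetaHaloTT(ref), 88.25)
  expect_output(show(ref), "halothermal")
  curves <- dense_model_curves(ref, temps = 20, psis = c(0, -0.1, -0.2))
  fit <- fitHalotime(curves)
  expect_output(show(fit), "psi_b\\(50\\)")
  expect_error(haloTTParams(psiB50 = -0.2, sigmaPsiB = 0.2,
                            thetaHaloTT = 50, Tb = 25, To = 20), "Tb")
  expect_equal(naclToPsi(1), -4.4)
  expect_equal(naclToPsi(0), 0)
})
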