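#' Probit transform of a germination fraction
#'
#' The probit is the standard-normal quantile; it linearises a cumulative
#' normal threshold distribution. Boundary fractions cannot be probit
#' transformed: 0 is dropped from regressions (returns NA) and 1 is replaced
#' by the small-sample correction (2n - 1)/(2n) when the number of seeds n is
#' known.
#'
#' @param g germination fraction in [0, 1]
#' @param n number of seeds behind the fraction (used only for the g = 1
#'   correction)
#' @return qnorm(g); NA for g = 0 or for g = 1 with unknown n
#' @export
probitFraction <- function(g, n = NULL) {
  if (any(g < 0 | g > 1)) stop("fractions must lie in [0, 1]")
  out <- numeric(length(g))
  for (i in seq_along(g)) {
    gi <- g[i]
    if (gi == 0) { out[i] <- NA_real_; next }
    if (gi == 1) {
      if (is.null(n) || is.na(n)) { out[i] <- NA_real_; next }
      gi <- (2 * n - 1) / (2 * n)
    }
    out[i] <- qnorm(gi)
  }
  out
}

#' Thermal-time constants for one percentile time
#'
#' Sub-optimal form: (T - Tb) * tg. Supra-optimal form as printed in the
#' classical tabulations: (Tc(g) - Tb) * tg; the conventional alternative
#' (Tc(g) - T) * tg is available via \code{supraForm = "conventional"}.
#'
#' @param temperature_C incubation temperature, degC
#' @param Tb base temperature, degC
#' @param Tc_g ceiling temperature for the percentile, degC
#' @param tg time to the percentile, hours
#' @param supraForm "printed" (default) or "conventional"
#' @return list with \code{theta_sub}, \code{theta_supra} (degC h) and
#'   \code{flags}; \code{theta_sub} is NA (flagged) when T <= Tb
#' @export
thermalTimeConstants <- function(temperature_C, Tb, Tc_g, tg,
                                 supraForm = c("printed", "conventional")) {
  supraForm <- match.arg(supraForm)
  flags <- character(0)
  if (temperature_C <= Tb) {
    sub <- NA_real_
    flags <- c(flags, "below_base_temperature")
  } else sub <- (temperature_C - Tb) * tg
  supra <- if (supraForm == "printed") (Tc_g - Tb) * tg
           else (Tc_g - temperature_C) * tg
  list(theta_sub = sub, theta_supra = supra, flags = flags)
}

## ---- repeated probit regression machinery -------------------------------

## simple regression of y on x returning slope/intercept/R2; NULL when the
## design or response is degenerate
probit_reg <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  if (!is.finite(sxx) || sxx < 1e-14 || syy < 1e-14) return(NULL)
  b <- sum((x - mx) * (y - my)) / sxx
  a <- my - b * mx
  res <- y - a - b * x
  list(a = a, b = b, r2 = 1 - sum(res^2) / syy, residuals = res)
}

## probit points (psi, temperature, g, tg, probit) for a set of curves.
## percentiles = "observed": each distinct positive cumulative count level of
## a count-backed curve, at its first attainment time (the classical repeated
## probit regression on observed fractions); continuous model curves fall
## back to the decile grid. A numeric vector fixes the grid instead, each
## level intersected with the fractions the curve actually reaches.
probit_points <- function(curves, percentiles = "observed") {
  observed <- identical(percentiles, "observed")
  if (!observed && any(percentiles <= 0 | percentiles > 1))
    stop("percentiles must lie in (0, 1]")
  rows <- lapply(curves, function(cv) {
    n <- cv@n_seeds
    if (observed && !is.na(n)) {
      counts <- round(cv@cum_fraction * n)
      gs0 <- unique(counts[counts > 0]) / n
    } else if (observed) {
      gs0 <- seq(0.1, 0.9, by = 0.1)
    } else {
      gs0 <- percentiles
    }
    gs <- vapply(gs0[gs0 > 0], function(g) {
      if (g == 1) { if (is.na(n)) NA_real_ else (2 * n - 1) / (2 * n) } else g
    }, numeric(1))
    gs <- unique(gs[!is.na(gs)])
    if (length(gs) == 0) return(NULL)
    tg <- vapply(gs, function(g) timeToPercentile(cv, g), numeric(1))
    keep <- !is.na(tg)
    if (!any(keep)) return(NULL)
    data.frame(psi = cv@psi_MPa, temperature = cv@temperature_C,
               g = gs[keep], tg = tg[keep], probit = qnorm(gs[keep]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(psi = numeric(0),
                                      temperature = numeric(0),
                                      g = numeric(0), tg = numeric(0),
                                      probit = numeric(0))
  rownames(out) <- NULL
  out
}

## maximize r2_of(theta) over a log-spaced grid, refined by golden section;
## r2_of must return -Inf for invalid candidates
theta_search <- function(r2_of, thetaRange, nGrid = 200, relTol = 1e-4) {
  grid <- exp(seq(log(thetaRange[1]), log(thetaRange[2]),
                  length.out = nGrid))
  vals <- vapply(grid, r2_of, numeric(1))
  if (all(!is.finite(vals)))
    stop("repeated probit regression is degenerate: no admissible theta ",
         "(fitted slope non-positive or regression undefined everywhere)")
  i <- which.max(vals)
  lo <- log(grid[max(1, i - 1)])
  hi <- log(grid[min(nGrid, i + 1)])
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- r2_of(exp(x1)); f2 <- r2_of(exp(x2))
  while ((b - a) > relTol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- r2_of(exp(x2))
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- r2_of(exp(x1))
    }
  }
  theta <- exp((a + b) / 2)
  if (!is.finite(r2_of(theta))) theta <- grid[i]
  theta
}

#' Fit the halotime model at a single temperature
#'
#' Repeated probit regression: for each candidate halotime constant theta the
#' probits of the percentile fractions g are regressed on
#' x = psi - theta / t(g), pooling all water-potential levels; the slope and
#' intercept of the winning regression (maximal R^2 over theta) give the
#' threshold spread sigma = 1/slope and median psi_b(50) = -intercept/slope.
#' The search uses a log-spaced theta grid refined by golden section and is
#' fully deterministic.
#'
#' @param curves list of \linkS4class{TreatmentCurve} sharing one
#'   temperature, spanning at least two water-potential levels
#' @param percentiles probit-point source: \code{"observed"} (default) takes
#'   every distinct positive cumulative count level of each curve at its
#'   first attainment time — the classical repeated probit regression on
#'   observed fractions; a numeric vector (e.g. \code{seq(0.1, 0.9, 0.1)})
#'   fixes a percentile grid instead, intersected per curve with the
#'   fractions actually reached. Continuous model curves always use the
#'   decile grid. Fractions of 0 are dropped; fractions of 1 are replaced by
#'   the small-sample correction (2n - 1)/(2n).
#' @param thetaRange search range for theta, MPa h
#' @param nGrid number of log-spaced grid candidates before refinement
#' @return a \linkS4class{ProbitFit} with \code{model = "halotime"}
#' @export
fitHalotime <- function(curves, percentiles = "observed",
                        thetaRange = c(1e-2, 1e5), nGrid = 200) {
  temps <- unique(vapply(curves, function(cv) cv@temperature_C, numeric(1)))
  if (length(temps) != 1)
    stop("fitHalotime requires curves at a single temperature; got ",
         paste(temps, collapse = ", "))
  pts <- probit_points(curves, percentiles)
  if (nrow(pts) < 3)
    stop("fewer than 3 usable probit points (percentiles reached)")
  if (length(unique(pts$psi)) < 2)
    stop("need reached percentiles at >= 2 water-potential levels")
  r2_of <- function(theta) {
    fit <- probit_reg(pts$psi - theta / pts$tg, pts$probit)
    if (is.null(fit) || fit$b <= 0) return(-Inf)
    fit$r2
  }
  th <- theta_search(r2_of, thetaRange, nGrid)
  fit <- probit_reg(pts$psi - th / pts$tg, pts$probit)
  if (is.null(fit))
    stop("degenerate probit regression: covariate has no spread")
  if (fit$b <= 0)
    stop("model violation: fitted threshold spread is non-positive")
  pts$x <- pts$psi - th / pts$tg
  new("ProbitFit", model = "halotime", theta = th,
      location50 = -fit$a / fit$b, sigma = 1 / fit$b, kT = 0,
      r2 = fit$r2, temperature_C = temps, nPoints = nrow(pts),
      points = pts, residuals = fit$residuals)
}

#' Fit the halothermal-time model jointly over temperatures
#'
#' Joint repeated probit regression over all sub- and supra-optimal curves:
#' probit(g) is regressed on
#' x = psi - kT * max(0, T - To) - theta / ((T - Tb) * t(g)).
#' The halothermal time constant theta (MPa degC h) is searched on a
#' log-spaced grid refined by golden section; at each candidate theta the
#' supra-optimal threshold-shift kT is profiled out by one-dimensional
#' optimisation (kT is fixed at 0 when no temperature above To is supplied).
#'
#' @param curves list of \linkS4class{TreatmentCurve} spanning the design;
#'   curves at temperatures at or below \code{Tb} carry no thermal-time
#'   information and are dropped with a warning
#' @param Tb,To base and optimum temperatures, degC (fixed, not estimated;
#'   see [estimateCardinalTemperatures()])
#' @param Tc optional ceiling temperature, degC, stored in the result
#' @param percentiles,nGrid as in [fitHalotime()]
#' @param thetaRange search range for theta, MPa degC h
#' @param kTRange search interval for kT, MPa per degC
#' @return a \linkS4class{HaloTTParams}; \code{thetaHalo} is
#'   \code{thetaHaloTT / (To - Tb)}
#' @export
fitHalothermal <- function(curves, Tb, To, Tc = NA_real_,
                           percentiles = "observed",
                           thetaRange = c(1e-1, 1e6), nGrid = 200,
                           kTRange = c(-0.5, 1.5)) {
  stopifnot(Tb < To)
  temps <- vapply(curves, function(cv) cv@temperature_C, numeric(1))
  if (all(temps <= Tb))
    stop("all temperatures are at or below the base temperature Tb")
  if (any(temps <= Tb)) {
    warning("dropping ", sum(temps <= Tb),
            " curve(s) at temperatures <= Tb")
    curves <- curves[temps > Tb]
    temps <- temps[temps > Tb]
  }
  pts <- probit_points(curves, percentiles)
  if (nrow(pts) < 3)
    stop("fewer than 3 usable probit points (percentiles reached)")
  if (length(unique(pts$psi)) < 2 && length(unique(pts$temperature)) < 2)
    stop("collinear design: need >= 2 water potentials or >= 2 temperatures")
  supra <- pmax(0, pts$temperature - To)
  denom <- (pts$temperature - Tb) * pts$tg
  haveSupra <- any(supra > 0)
  fit_at <- function(theta, kT) {
    probit_reg(pts$psi - kT * supra - theta / denom, pts$probit)
  }
  r2_at <- function(theta, kT) {
    fit <- fit_at(theta, kT)
    if (is.null(fit) || fit$b <= 0) return(-Inf)
    fit$r2
  }
  best_kT <- function(theta) {
    if (!haveSupra) return(0)
    opt <- optimize(function(k) r2_at(theta, k), interval = kTRange,
                    maximum = TRUE, tol = 1e-6)
    opt$maximum
  }
  th <- theta_search(function(theta) r2_at(theta, best_kT(theta)),
                     thetaRange, nGrid)
  kT <- best_kT(th)
  fit <- fit_at(th, kT)
  if (is.null(fit))
    stop("degenerate probit regression: covariate has no spread")
  if (fit$b <= 0)
    stop("model violation: fitted threshold spread is non-positive")
  new("HaloTTParams",
      psiB50 = -fit$a / fit$b, sigmaPsiB = 1 / fit$b,
      thetaHalo = th / (To - Tb), thetaHaloTT = th,
      kT = if (haveSupra) kT else 0,
      Tb = Tb, To = To, Tc = Tc, r2 = fit$r2)
}

#' Predict a germination time course from halothermal-time parameters
#'
#' Forward model: the fraction germinated by time t at (T, psi) is
#' Phi((psi_adj - theta / ((T - Tb) t) - psiB50) / sigma) with
#' psi_adj = psi - kT * max(0, T - To). The asymptote as t grows is
#' Phi((psi_adj - psiB50) / sigma). Temperatures outside (Tb, Tc) cannot
#' accumulate halothermal time: an all-zero curve flagged
#' \code{"outside_thermal_range"} is returned.
#'
#' @param params a \linkS4class{HaloTTParams}
#' @param temperature_C,psi_MPa treatment conditions
#' @param times_h strictly increasing prediction times, hours
#' @return a \linkS4class{TreatmentCurve} with continuous fractions
#'   (\code{n_seeds = NA})
#' @export
predictTimeCourse <- function(params, temperature_C, psi_MPa, times_h) {
  stopifnot(length(times_h) > 0, all(times_h > 0),
            !is.unsorted(times_h, strictly = TRUE))
  outside <- temperature_C <= params@Tb ||
    (!is.na(params@Tc) && temperature_C >= params@Tc)
  if (outside) {
    return(new("TreatmentCurve", temperature_C = temperature_C,
               psi_MPa = psi_MPa, times_h = as.numeric(times_h),
               cum_fraction = rep(0, length(times_h)),
               n_seeds = NA_real_, flags = "outside_thermal_range"))
  }
  psi_adj <- psi_MPa - params@kT * max(0, temperature_C - params@To)
  z <- (psi_adj - params@thetaHaloTT /
          ((temperature_C - params@Tb) * times_h) - params@psiB50) /
    params@sigmaPsiB
  new("TreatmentCurve", temperature_C = temperature_C, psi_MPa = psi_MPa,
      times_h = as.numeric(times_h),
      cum_fraction = pmin(1, pmax(0, pnorm(z))),
      n_seeds = NA_real_)
}

setMethod("show", "ProbitFit", function(object) {
  cat(sprintf("ProbitFit (%s model%s)\n", object@model,
              if (!is.na(object@temperature_C))
                sprintf(", T = %g degC", object@temperature_C) else ""))
  cat(sprintf("  theta       = %.4g %s\n", object@theta,
              if (object@model == "halotime") "MPa h" else "MPa degC h"))
  cat(sprintf("  psi_b(50)   = %.4f MPa\n", object@location50))
  cat(sprintf("  sigma_psi_b = %.4f MPa\n", object@sigma))
  cat(sprintf("  R^2 = %.4f on %d probit points\n", object@r2,
              object@nPoints))
  invisible(NULL)
})

setMethod("show", "HaloTTParams", function(object) {
  cat("HaloTTParams (halothermal-time model)\n")
  cat(sprintf("  psi_b(50)    = %.3f MPa\n", object@psiB50))
  cat(sprintf("  sigma_psi_b  = %.3f MPa\n", object@sigmaPsiB))
  cat(sprintf("  theta_Halo   = %.3f MPa h (at To)\n", object@thetaHalo))
  cat(sprintf("  theta_HaloTT = %.3f MPa degC h\n", object@thetaHaloTT))
  cat(sprintf("  kT           = %.4f MPa/degC above To\n", object@kT))
  cat(sprintf("  Tb / To / Tc = %g / %g / %g degC\n", object@Tb, object@To,
              object@Tc))
  if (!is.na(object@r2)) cat(sprintf("  R^2 = %.4f\n", object@r2))
  invisible(NULL)
})

setMethod("psiB50", "ProbitFit", function(object) object@location50)
setMethod("psiB50", "HaloTTParams", function(object) object@psiB50)
setMethod("sigmaPsiB", "ProbitFit", function(object) object@sigma)
setMethod("sigmaPsiB", "HaloTTParams", function(object) object@sigmaPsiB)
setMethod("theta", "ProbitFit", function(object) object@theta)
setMethod("thetaHalo", "HaloTTParams", function(object) object@thetaHalo)
setMethod("thetaHaloTT", "HaloTTParams", function(object) object@thetaHaloTT)
setMethod("kT", "ProbitFit", function(object) object@kT)
setMethod("kT", "HaloTTParams", function(object) object@kT)
setMethod("r2", "ProbitFit", function(object) object@r2)
setMethod("r2", "HaloTTParams", function(object) object@r2)
setMethod("cardinalTemperatures", "HaloTTParams", function(object)
  c(Tb = object@Tb, To = object@To, Tc = object@Tc))

#' Construct a halothermal-time parameter set
#'
#' @param psiB50 median base water potential, MPa
#' @param sigmaPsiB threshold standard deviation, MPa
#' @param thetaHalo halotime constant at To, MPa h (used to derive
#'   \code{thetaHaloTT} when the latter is not given)
#' @param thetaHaloTT halothermal time constant, MPa degC h
#' @param kT supra-optimal threshold shift, MPa per degC
#' @param Tb,To,Tc cardinal temperatures, degC
#' @param r2 optional fit R^2
#' @return a \linkS4class{HaloTTParams}
#' @export
haloTTParams <- function(psiB50, sigmaPsiB, thetaHalo = NULL,
                         thetaHaloTT = NULL, kT = 0, Tb, To, Tc = NA_real_,
                         r2 = NA_real_) {
  if (is.null(thetaHaloTT)) {
    if (is.null(thetaHalo)) stop("supply thetaHalo or thetaHaloTT")
    thetaHaloTT <- thetaHalo * (To - Tb)
  }
  if (is.null(thetaHalo)) thetaHalo <- thetaHaloTT / (To - Tb)
  new("HaloTTParams", psiB50 = psiB50, sigmaPsiB = sigmaPsiB,
      thetaHalo = thetaHalo, thetaHaloTT = thetaHaloTT, kT = kT,
      Tb = Tb, To = To, Tc = Tc, r2 = r2)
}

#' Reference halothermal-time parameter set for barley
#'
#' The parameter set used as the simulator default: median base water
#' potential -0.23 MPa, threshold spread 0.21 MPa, halotime constant
#' 17.65 MPa h at the 20 degC optimum (so thetaHaloTT = 88.25 MPa degC h
#' with Tb = 15 degC), supra-optimal shift kT = 0.104 MPa/degC, and cardinal
#' temperatures 15/20/40 degC — estimates reported for barley cv. AJJ
#' germinating under combined temperature and osmotic stress.
#'
#' @return a \linkS4class{HaloTTParams}
#' @export
barleyHaloTTParams <- function() {
  haloTTParams(psiB50 = -0.23, sigmaPsiB = 0.21, thetaHalo = 17.65,
               kT = 0.104, Tb = 15, To = 20, Tc = 40, r2 = 0.953)
}

#' Osmotic potential of an NaCl solution
#'
#' Fixed linear conversion: -4.4 MPa per mol/L NaCl (the van 't Hoff value
#' at 25 degC). All model fitting works on the water-potential (MPa) scale;
#' this helper converts molar salinity inputs onto it.
#'
#' @param mol_L NaCl concentration, mol/L
#' @return osmotic potential, MPa (non-positive)
#' @export
naclToPsi <- function(mol_L) {
  stopifnot(all(mol_L >= 0))
  -4.4 * mol_L
}
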