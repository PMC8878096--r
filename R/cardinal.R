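#' Germination rate at a percentile, by temperature
#'
#' Extracts GR(g) = 1 / t(g) at one water potential across every tested
#' temperature. Temperatures at which the percentile is never reached are
#' reported with rate 0 and \code{reached = FALSE}: under a threshold model
#' a temperature at or beyond the thermal limits has zero germination rate,
#' and these zeros anchor the rate-versus-temperature regression limbs.
#'
#' @param x a \linkS4class{GerminationExperiment} or list of
#'   \linkS4class{TreatmentCurve}
#' @param psi_MPa water potential at which rates are taken (default 0)
#' @param g percentile (default 0.5, i.e. GR50)
#' @return data.frame: \code{temperature_C}, \code{gr}, \code{reached}
#' @export
gr50ByTemperature <- function(x, psi_MPa = 0, g = 0.5) {
  curves <- if (is(x, "GerminationExperiment")) treatmentCurves(x) else x
  curves <- Filter(function(cv) cv@psi_MPa == psi_MPa, curves)
  if (length(curves) == 0)
    stop("no curves at psi = ", psi_MPa, " MPa")
  rows <- lapply(curves, function(cv) {
    r <- germinationRate(cv, g)
    data.frame(temperature_C = cv@temperature_C, gr = as.numeric(r),
               reached = attr(r, "reached"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature_C), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate cardinal temperatures from germination rate versus temperature
#'
#' Two conventions are reported side by side. Grid mode: the optimum To is
#' the tested temperature with maximal GR(g) (ties broken toward the lower
#' temperature). Regression mode: GR(g) is regressed on temperature
#' separately over the sub-optimal limb (T <= grid To) and the supra-optimal
#' limb (T >= grid To); the base temperature Tb is the x-intercept of the
#' sub-optimal line, the ceiling Tc the x-intercept of the supra-optimal
#' line, and the regression To the intersection of the two lines.
#'
#' @param gr data.frame with columns \code{temperature_C} and \code{gr}
#'   (germination rate, 1/h), e.g. from [gr50ByTemperature()]; zero rates at
#'   unreached temperatures participate in the limbs
#' @return list: \code{To_grid}, \code{To_regression}, \code{Tb}, \code{Tc},
#'   \code{sub_line} and \code{supra_line} (intercept, slope), and
#'   \code{flags}
#' @export
estimateCardinalTemperatures <- function(gr) {
  stopifnot(all(c("temperature_C", "gr") %in% names(gr)))
  gr <- gr[order(gr$temperature_C), , drop = FALSE]
  if (nrow(gr) < 2) stop("need >= 2 temperatures")
  flags <- character(0)
  imax <- which(gr$gr == max(gr$gr))[1]
  To_grid <- gr$temperature_C[imax]
  if (imax == 1 || imax == nrow(gr)) {
    flags <- c(flags, "To_at_grid_edge")
    if (all(diff(gr$gr) >= 0) || all(diff(gr$gr) <= 0))
      flags <- c(flags, "monotone_gr")
  }
  line_fit <- function(sub) {
    if (nrow(sub) < 2 || length(unique(sub$temperature_C)) < 2)
      return(NULL)
    cf <- coef(lm(gr ~ temperature_C, data = sub))
    c(intercept = unname(cf[1]), slope = unname(cf[2]))
  }
  subL <- line_fit(gr[gr$temperature_C <= To_grid, , drop = FALSE])
  supL <- line_fit(gr[gr$temperature_C >= To_grid, , drop = FALSE])
  x_int <- function(L) {
    if (is.null(L) || abs(L["slope"]) < 1e-15) return(NA_real_)
    unname(-L["intercept"] / L["slope"])
  }
  Tb <- x_int(subL)
  Tc <- x_int(supL)
  To_reg <- NA_real_
  if (!is.null(subL) && !is.null(supL) &&
      abs(subL["slope"] - supL["slope"]) > 1e-15)
    To_reg <- unname((supL["intercept"] - subL["intercept"]) /
                       (subL["slope"] - supL["slope"]))
  if (is.null(subL)) flags <- c(flags, "sub_optimal_line_undefined")
  if (is.null(supL)) flags <- c(flags, "supra_optimal_line_undefined")
  list(To_grid = To_grid, To_regression = To_reg, Tb = Tb, Tc = Tc,
       sub_line = subL, supra_line = supL, flags = flags)
}

#' Supra-optimal threshold-shift coefficient kT
#'
#' Above the optimum temperature the effective median threshold psi_b(50)
#' moves toward zero; kT is the least-squares slope of the fitted psi_b(50)
#' values against (T - To).
#'
#' @param psi_b50 fitted median base water potentials, MPa (one per
#'   supra-optimal temperature)
#' @param temperature_C the corresponding temperatures, degC
#' @param To optimum temperature, degC
#' @return list: \code{kT} (MPa per degC), \code{psiB50_at_To} (intercept),
#'   \code{n}
#' @export
estimateKT <- function(psi_b50, temperature_C, To) {
  stopifnot(length(psi_b50) == length(temperature_C))
  if (length(psi_b50) < 2)
    stop("need >= 2 supra-optimal fits to estimate kT")
  dT <- temperature_C - To
  cf <- coef(lm(psi_b50 ~ dT))
  list(kT = unname(cf[2]), psiB50_at_To = unname(cf[1]),
       n = length(psi_b50))
}

#' Per-treatment model constants from fitted parameters and observed times
#'
#' For every treatment curve: the observed interpolated time to percentile g,
#' the germination rate GR(g) = 1/t(g), the sub- and supra-optimal
#' thermal-time constants, the halotime constant (psi - psi_b(50)) * t(g)
#' and the halothermal constant (psi - psi_b(50)) * (T - Tb) * t(g), all
#' evaluated from \code{params} and the observed t(g).
#'
#' @param curves list of \linkS4class{TreatmentCurve}
#' @param params a \linkS4class{HaloTTParams}
#' @param g percentile (default 0.5)
#' @param supraForm passed to [thermalTimeConstants()]
#' @return data.frame, one row per treatment: \code{temperature_C, psi_MPa,
#'   t_g_h, gr_g, theta_T1, theta_T2, theta_halo, theta_halott, reached}
#' @export
tabulateConstants <- function(curves, params, g = 0.5,
                              supraForm = c("printed", "conventional")) {
  supraForm <- match.arg(supraForm)
  rows <- lapply(curves, function(cv) {
    tg <- timeToPercentile(cv, g)
    reached <- !is.na(tg)
    if (!reached)
      return(data.frame(temperature_C = cv@temperature_C,
                        psi_MPa = cv@psi_MPa, t_g_h = NA_real_, gr_g = 0,
                        theta_T1 = NA_real_, theta_T2 = NA_real_,
                        theta_halo = NA_real_, theta_halott = NA_real_,
                        reached = FALSE))
    tt <- thermalTimeConstants(cv@temperature_C, params@Tb, params@Tc, tg,
                               supraForm)
    th_halo <- (cv@psi_MPa - params@psiB50) * tg
    th_htt <- if (cv@temperature_C > params@Tb)
      th_halo * (cv@temperature_C - params@Tb) else NA_real_
    data.frame(temperature_C = cv@temperature_C, psi_MPa = cv@psi_MPa,
               t_g_h = tg, gr_g = 1 / tg,
               theta_T1 = tt$theta_sub, theta_T2 = tt$theta_supra,
               theta_halo = th_halo, theta_halott = th_htt,
               reached = TRUE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature_C, -out$psi_MPa), , drop = FALSE]
  rownames(out) <- NULL
  out
}
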