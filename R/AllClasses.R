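#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats qnorm pnorm aggregate coef lm lm.fit median model.matrix
#'   optimize pf quantile rbinom rlnorm rnorm sd setNames var
#' @importFrom utils read.csv write.csv
NULL

#' GerminationExperiment: germination time courses over a factorial design
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"cumulative"}:
#' a matrix of cumulative germinated counts with one row per observation time
#' (union of all dishes' schedules, hours since sowing, stored in
#' \code{rowData()$time_h}) and one column per Petri dish. Counts for a dish
#' are carried forward between that dish's own observations, so each column is
#' the dish's right-continuous counting step function sampled on the union
#' grid. \code{colData()} carries the design: \code{temperature_C},
#' \code{psi_MPa} (water potential, MPa, non-positive), \code{replicate}
#' (dish id within treatment) and \code{seeds_sown}.
#'
#' The original long-format records (one row per dish per observation) are
#' kept in \code{metadata()$records} so that file round trips are lossless.
#'
#' @seealso [readCounts()], [GerminationExperiment()], [treatmentCurve()]
#' @export
setClass("GerminationExperiment", contains = "SummarizedExperiment")

setValidity("GerminationExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("temperature_C", "psi_MPa", "replicate", "seeds_sown")
  miss <- setdiff(need, colnames(cd))
  if (length(miss) > 0)
    return(paste0("colData is missing column(s): ", paste(miss, collapse = ", ")))
  if (!"cumulative" %in% SummarizedExperiment::assayNames(object))
    return("assay 'cumulative' is required")
  if (any(cd$psi_MPa > 0))
    return("psi_MPa must be <= 0 (water potential)")
  if (any(cd$seeds_sown <= 0))
    return("seeds_sown must be positive")
  m <- SummarizedExperiment::assay(object, "cumulative")
  if (nrow(m) > 0) {
    tt <- SummarizedExperiment::rowData(object)$time_h
    if (is.null(tt) || is.unsorted(tt, strictly = TRUE))
      return("rowData()$time_h must be strictly increasing")
    if (any(m < 0)) return("cumulative counts must be non-negative")
    if (any(sweep(m, 2, cd$seeds_sown, ">")))
      return("cumulative count exceeds seeds_sown")
    if (nrow(m) > 1 && any(apply(m, 2, function(x) any(diff(x) < 0))))
      return("cumulative counts must be non-decreasing in time within a dish")
  }
  TRUE
})

#' TreatmentCurve: cumulative germination fraction over time
#'
#' One treatment's (temperature x water potential) cumulative germination
#' fraction, pooled over replicate dishes. Model-predicted curves (from
#' [predictTimeCourse()]) use \code{n_seeds = NA} and continuous fractions;
#' curves built from observed counts have \code{cum_fraction * n_seeds}
#' integer-valued.
#'
#' @slot temperature_C incubation temperature, degrees Celsius
#' @slot psi_MPa water potential, MPa (<= 0)
#' @slot times_h strictly increasing observation times, hours
#' @slot cum_fraction cumulative germinated fraction in [0, 1], non-decreasing
#' @slot n_seeds total seeds pooled into the curve (NA for model curves)
#' @slot flags character vector of quality flags (e.g. "outside_thermal_range")
#' @export
setClass("TreatmentCurve",
  representation(
    temperature_C = "numeric",
    psi_MPa       = "numeric",
    times_h       = "numeric",
    cum_fraction  = "numeric",
    n_seeds       = "numeric",
    flags         = "character"
  ),
  prototype(flags = character(0))
)

setValidity("TreatmentCurve", function(object) {
  if (length(object@times_h) != length(object@cum_fraction))
    return("times_h and cum_fraction must have the same length")
  if (length(object@times_h) > 0) {
    if (is.unsorted(object@times_h, strictly = TRUE))
      return("times_h must be strictly increasing")
    if (any(object@times_h <= 0)) return("times_h must be positive")
    if (any(object@cum_fraction < -1e-12 | object@cum_fraction > 1 + 1e-12))
      return("cum_fraction must lie in [0, 1]")
    if (any(diff(object@cum_fraction) < -1e-12))
      return("cum_fraction must be non-decreasing")
  }
  if (length(object@psi_MPa) == 1 && !is.na(object@psi_MPa) && object@psi_MPa > 0)
    return("psi_MPa must be <= 0")
  TRUE
})

#' ProbitFit: one fitted population-threshold model
#'
#' Result of repeated probit regression: the time constant \code{theta} was
#' selected by maximising the R^2 of the linear regression of probit(g) on the
#' model covariate, whose slope and intercept give the spread and median of
#' the normal base-water-potential threshold distribution.
#'
#' @slot model "halotime" or "halothermal"
#' @slot theta time constant: MPa h (halotime) or MPa degC h (halothermal)
#' @slot location50 median base water potential Psi_b(50), MPa
#' @slot sigma threshold spread sigma_Psi_b, MPa (> 0)
#' @slot kT supra-optimal threshold shift, MPa per degC (0 for halotime fits)
#' @slot r2 coefficient of determination of the probit regression
#' @slot temperature_C the single temperature fitted (NA for joint fits)
#' @slot nPoints number of (psi, g, tg) probit points used
#' @slot points data.frame of the regression points (psi, temperature, g, tg,
#'   probit, x)
#' @slot residuals residuals of the winning probit regression
#' @export
setClass("ProbitFit",
  representation(
    model         = "character",
    theta         = "numeric",
    location50    = "numeric",
    sigma         = "numeric",
    kT            = "numeric",
    r2            = "numeric",
    temperature_C = "numeric",
    nPoints       = "integer",
    points        = "data.frame",
    residuals     = "numeric"
  )
)

setValidity("ProbitFit", function(object) {
  if (!object@model %in% c("halotime", "halothermal", "thermal"))
    return("model must be 'halotime', 'halothermal' or 'thermal'")
  if (!is.na(object@sigma) && object@sigma <= 0)
    return("sigma must be positive")
  if (!is.na(object@theta) && object@theta <= 0)
    return("theta must be positive")
  if (!is.na(object@r2) && (object@r2 < -1e-9 || object@r2 > 1 + 1e-9))
    return("r2 must lie in [0, 1]")
  TRUE
})

#' HaloTTParams: full halothermal-time parameter set
#'
#' The parameter set of the halothermal-time germination model: the normal
#' distribution of base water potentials across the seed population
#' (\code{psiB50}, \code{sigmaPsiB}), the halothermal time constant
#' \code{thetaHaloTT} (MPa degC h) and its single-temperature reduction
#' \code{thetaHalo} = thetaHaloTT / (To - Tb) (MPa h), the supra-optimal
#' threshold-shift coefficient \code{kT} (MPa per degC above To), and the
#' cardinal temperatures \code{Tb} < \code{To} < \code{Tc}.
#'
#' @slot psiB50 median base water potential, MPa
#' @slot sigmaPsiB threshold standard deviation, MPa (> 0)
#' @slot thetaHalo halotime constant at To, MPa h
#' @slot thetaHaloTT halothermal time constant, MPa degC h
#' @slot kT threshold shift above To, MPa per degC
#' @slot Tb,To,Tc base, optimum and ceiling temperatures, degC
#' @slot r2 fit R^2 (NA for parameter sets not produced by a fit)
#' @export
setClass("HaloTTParams",
  representation(
    psiB50      = "numeric",
    sigmaPsiB   = "numeric",
    thetaHalo   = "numeric",
    thetaHaloTT = "numeric",
    kT          = "numeric",
    Tb          = "numeric",
    To          = "numeric",
    Tc          = "numeric",
    r2          = "numeric"
  ),
  prototype(r2 = NA_real_, Tc = NA_real_)
)

setValidity("HaloTTParams", function(object) {
  if (object@sigmaPsiB <= 0) return("sigmaPsiB must be positive")
  if (object@thetaHaloTT <= 0) return("thetaHaloTT must be positive")
  if (!is.na(object@Tb) && !is.na(object@To) && object@Tb >= object@To)
    return("Tb must be below To")
  if (!is.na(object@To) && !is.na(object@Tc) && object@To >= object@Tc)
    return("To must be below Tc")
  TRUE
})
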