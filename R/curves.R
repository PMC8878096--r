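#' Build a pooled cumulative germination curve for one treatment
#'
#' Pools all replicate dishes of one (temperature, water potential)
#' treatment: at every time in the union of the dishes' observation
#' schedules, each dish contributes its last observed cumulative count
#' (carried forward), and the pooled fraction is the summed count divided by
#' the total seeds sown.
#'
#' @param records observation records for a single treatment (all rows share
#'   \code{temperature_C} and \code{psi_MPa})
#' @param viability optional germinable fraction in (0, 1]; when supplied the
#'   denominator is \code{viability * seeds_sown} (viability-corrected
#'   fractions). Default \code{NULL}: all sown seeds stay in the denominator.
#' @return a \linkS4class{TreatmentCurve}
#' @export
buildCurve <- function(records, viability = NULL) {
  if (nrow(records) == 0) stop("no records supplied")
  records <- validateRecords(records)
  if (length(unique(records$temperature_C)) != 1 ||
      length(unique(records$psi_MPa)) != 1)
    stop("records span more than one (temperature, psi) treatment")
  times <- sort(unique(records$time_h))
  key <- interaction(records$replicate, drop = TRUE)
  total <- 0
  counts <- numeric(length(times))
  for (k in levels(key)) {
    sub <- records[key == k, , drop = FALSE]
    counts <- counts + step_count_at(sub$time_h, sub$cum_germinated, times)
    total <- total + sub$seeds_sown[1]
  }
  denom <- if (is.null(viability)) total else {
    stopifnot(viability > 0, viability <= 1)
    viability * total
  }
  new("TreatmentCurve",
      temperature_C = records$temperature_C[1],
      psi_MPa       = records$psi_MPa[1],
      times_h       = times,
      cum_fraction  = pmin(1, counts / denom),
      n_seeds       = as.numeric(total))
}

#' Extract one treatment's pooled curve from a GerminationExperiment
#'
#' @param x a \linkS4class{GerminationExperiment}
#' @param temperature_C,psi_MPa treatment to extract
#' @param ... passed to [buildCurve()]
#' @return a \linkS4class{TreatmentCurve}
#' @export
treatmentCurve <- function(x, temperature_C, psi_MPa, ...) {
  rec <- germinationRecords(x)
  sub <- rec[rec$temperature_C == temperature_C & rec$psi_MPa == psi_MPa, ,
             drop = FALSE]
  if (nrow(sub) == 0)
    stop(sprintf("no records for treatment (T=%g, psi=%g)",
                 temperature_C, psi_MPa))
  buildCurve(sub, ...)
}

#' All treatment curves of an experiment
#'
#' @param x a \linkS4class{GerminationExperiment}
#' @param ... passed to [buildCurve()]
#' @return named list of \linkS4class{TreatmentCurve}, ordered by
#'   (temperature, psi)
#' @export
treatmentCurves <- function(x, ...) {
  tr <- treatments(x)
  out <- lapply(seq_len(nrow(tr)), function(i)
    treatmentCurve(x, tr$temperature_C[i], tr$psi_MPa[i], ...))
  names(out) <- sprintf("T%g_psi%g", tr$temperature_C, tr$psi_MPa)
  out
}

#' Interpolated time to a germination percentile
#'
#' Time at which the cumulative germination fraction reaches \code{g},
#' by linear interpolation of the cumulative curve between the bracketing
#' observations (the classical T50 interpolation rule, applied to any
#' percentile). If the first observation already exceeds \code{g} the
#' interpolation anchors at (0, 0); if the final fraction never reaches
#' \code{g} the percentile is not reached and \code{NA} is returned.
#'
#' @param curve a \linkS4class{TreatmentCurve}
#' @param g target cumulative fraction, in (0, 1)
#' @param ... unused
#' @return time in hours, or \code{NA} if the percentile is never reached
#' @export
setMethod("timeToPercentile", "TreatmentCurve", function(curve, g, ...) {
  if (length(g) != 1 || is.na(g) || g <= 0 || g >= 1)
    stop("g must be a single fraction strictly between 0 and 1")
  f <- curve@cum_fraction
  t <- curve@times_h
  if (length(f) == 0 || max(f) < g - 1e-12) return(NA_real_)
  j <- which(f >= g - 1e-12)[1]
  fj <- f[j]
  if (abs(fj - g) <= 1e-12) return(t[j])
  if (j == 1) {
    ti <- 0; fi <- 0
  } else {
    ti <- t[j - 1]; fi <- f[j - 1]
  }
  ti + (g - fi) * (t[j] - ti) / (fj - fi)
})

#' Germination rate at a percentile
#'
#' Reciprocal of [timeToPercentile()]. A percentile that is never reached is
#' reported as rate 0, with attribute \code{reached = FALSE} so callers can
#' distinguish "infinitely slow" from a true measurement.
#'
#' @param curve a \linkS4class{TreatmentCurve}
#' @param g target cumulative fraction, in (0, 1)
#' @param ... unused
#' @return rate in 1/hours, with logical attribute \code{reached}
#' @export
setMethod("germinationRate", "TreatmentCurve", function(curve, g, ...) {
  tg <- timeToPercentile(curve, g)
  if (is.na(tg)) return(structure(0, reached = FALSE))
  structure(1 / tg, reached = TRUE)
})

setMethod("show", "TreatmentCurve", function(object) {
  cat(sprintf("TreatmentCurve: T = %g degC, psi = %g MPa\n",
              object@temperature_C, object@psi_MPa))
  cat(sprintf("  %d observations over %g-%g h; final fraction %.3f",
              length(object@times_h),
              if (length(object@times_h)) min(object@times_h) else NA,
              if (length(object@times_h)) max(object@times_h) else NA,
              if (length(object@cum_fraction))
                max(object@cum_fraction) else NA))
  if (!is.na(object@n_seeds)) cat(sprintf(" (n = %g seeds)", object@n_seeds))
  cat("\n")
  if (length(object@flags) > 0)
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(NULL)
})

## convenience accessors used throughout
curveTimes <- function(curve) curve@times_h
curveFractions <- function(curve) curve@cum_fraction
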