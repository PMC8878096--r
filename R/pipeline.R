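#' Pipeline configuration
#'
#' @param counts path to a counts CSV, a records data.frame, or a
#'   \linkS4class{GerminationExperiment}
#' @param seedlings optional path to a seedlings CSV or data.frame
#' @param outDir output directory for the report files
#' @param percentiles probit-point source passed to the fitting functions:
#'   \code{"observed"} (default) or a numeric percentile grid (see
#'   [fitHalotime()])
#' @param supraForm supra-optimal thermal-time form, "printed" or
#'   "conventional" (see [thermalTimeConstants()])
#' @param Tb,To,Tc optional cardinal-temperature overrides, degC; when NULL,
#'   Tb and To are taken from [estimateCardinalTemperatures()] on GR50 at
#'   the wettest tested water potential (grid-mode To; regression Tb,
#'   falling back to the lowest tested temperature if the regression is
#'   undefined)
#' @param alpha ANOVA significance level recorded in the run log
#' @param hoursPerDay day length used for the daily index schedule
#' @param seed RNG seed recorded in the log (the pipeline itself is
#'   deterministic; the seed matters only when \code{counts} is generated
#'   upstream)
#' @return a list of class \code{"runConfig"}
#' @export
runConfig <- function(counts, seedlings = NULL, outDir = ".",
                      percentiles = "observed",
                      supraForm = c("printed", "conventional"),
                      Tb = NULL, To = NULL, Tc = NULL, alpha = 0.05,
                      hoursPerDay = 24, seed = NULL) {
  supraForm <- match.arg(supraForm)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(counts = counts, seedlings = seedlings, outDir = outDir,
                 percentiles = percentiles, supraForm = supraForm,
                 Tb = Tb, To = To, Tc = Tc, alpha = alpha,
                 hoursPerDay = hoursPerDay, seed = seed),
            class = "runConfig")
}

#' Run the full germination-analysis pipeline
#'
#' Executes read -> curves -> indices -> per-temperature halotime fits ->
#' cardinal temperatures -> kT -> joint halothermal fit -> constants table ->
#' two-way ANOVA, writing \code{index_table.csv}, \code{probit_fits.csv},
#' \code{constants.csv}, \code{halott_params.csv}, \code{anova.csv} and a
#' machine-readable \code{run_log.json} to the output directory. A stage
#' failure is logged with its stage name and the run continues; partial
#' outputs are retained.
#'
#' @param config a [runConfig()]
#' @param verbose print one status line per stage
#' @return (invisibly) a list with the in-memory results: \code{experiment},
#'   \code{curves}, \code{indexTable}, \code{perDish}, \code{halotimeFits},
#'   \code{cardinal}, \code{kT}, \code{params}, \code{constants},
#'   \code{anova}, \code{files}, \code{log}
#' @export
runPipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config = list(percentiles = config$percentiles,
                            supraForm = config$supraForm,
                            alpha = config$alpha,
                            hoursPerDay = config$hoursPerDay,
                            seed = config$seed),
              package_version = as.character(utils::packageVersion("halott")),
              stages = list())
  res <- list(files = character(0))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      if (verbose) message("[", name, "] FAILED: ", conditionMessage(e))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    el <- proc.time()[["elapsed"]] - t0
    ok <- !inherits(out, "stage_error")
    log$stages[[name]] <<- list(ok = ok, elapsed_s = round(el, 3),
                                error = if (ok) NULL else out$message)
    if (ok && verbose) message(sprintf("[%s] done (%.2fs)", name, el))
    if (ok) out else NULL
  }

  ge <- stage("read", {
    x <- config$counts
    if (is.character(x)) x <- readCounts(x)
    if (is(x, "GerminationExperiment")) x else GerminationExperiment(x)
  })
  if (is.null(ge)) {
    writeRunLog(log, config$outDir)
    return(invisible(c(res, list(log = log))))
  }
  res$experiment <- ge

  seedlings <- NULL
  if (!is.null(config$seedlings))
    seedlings <- stage("seedlings", {
      if (is.character(config$seedlings)) readSeedlings(config$seedlings)
      else config$seedlings
    })

  curves <- stage("curves", treatmentCurves(ge))
  res$curves <- curves

  idx <- stage("indices", {
    perDish <- experimentIndices(ge, seedlings,
                                 hours_per_day = config$hoursPerDay)
    tab <- indexTable(ge, seedlings, hours_per_day = config$hoursPerDay)
    f <- file.path(config$outDir, "index_table.csv")
    write.csv(format_num(tab, digits = 4), f, row.names = FALSE,
              quote = FALSE)
    list(perDish = perDish, table = tab, file = f)
  })
  if (!is.null(idx)) {
    res$perDish <- idx$perDish; res$indexTable <- idx$table
    res$files <- c(res$files, index_table = idx$file)
  }

  fits <- stage("halotime_fits", {
    temps <- sort(unique(vapply(curves, function(cv) cv@temperature_C,
                                numeric(1))))
    out <- list()
    for (tt in temps) {
      cvs <- Filter(function(cv) cv@temperature_C == tt, curves)
      out[[as.character(tt)]] <- tryCatch(
        fitHalotime(cvs, percentiles = config$percentiles),
        error = function(e) structure(list(message = conditionMessage(e)),
                                      class = "fit_error"))
    }
    out
  })
  res$halotimeFits <- fits

  card <- stage("cardinal_temperatures", {
    psis <- sort(unique(vapply(curves, function(cv) cv@psi_MPa,
                               numeric(1))), decreasing = TRUE)
    gr <- gr50ByTemperature(curves, psi_MPa = psis[1])
    estimateCardinalTemperatures(gr)
  })
  res$cardinal <- card
  Tb <- config$Tb
  To <- config$To
  Tc <- config$Tc
  if (is.null(To)) To <- if (!is.null(card)) card$To_grid else NA_real_
  if (is.null(Tb)) {
    Tb <- if (!is.null(card) && is.finite(card$Tb)) card$Tb else NA_real_
    allT <- sort(unique(vapply(curves, function(cv) cv@temperature_C,
                               numeric(1))))
    if (!is.finite(Tb) || Tb >= To) Tb <- min(allT)
  }
  if (is.null(Tc)) Tc <- if (!is.null(card) && is.finite(card$Tc))
    card$Tc else NA_real_

  kt <- stage("kT", {
    supra <- vapply(fits, function(f)
      is(f, "ProbitFit") && f@temperature_C > To, logical(1))
    if (sum(supra) < 2)
      stop("fewer than 2 supra-optimal halotime fits; kT not estimable")
    estimateKT(vapply(fits[supra], psiB50, numeric(1)),
               vapply(fits[supra], function(f) f@temperature_C, numeric(1)),
               To)
  })
  res$kT <- kt

  params <- stage("halothermal_fit", {
    if (!is.finite(Tb) || !is.finite(To) || Tb >= To)
      stop("no usable (Tb, To) pair for the joint fit")
    fitHalothermal(curves, Tb = Tb, To = To, Tc = Tc,
                   percentiles = config$percentiles)
  })
  res$params <- params

  fpf <- stage("report_probit_fits", {
    f <- file.path(config$outDir, "probit_fits.csv")
    reportProbitFits(if (is.null(fits)) list() else fits, f)
    f
  })
  if (!is.null(fpf)) res$files <- c(res$files, probit_fits = fpf)

  if (!is.null(params)) {
    cons <- stage("constants", {
      tabulateConstants(curves, params, supraForm = config$supraForm)
    })
    res$constants <- cons
    fc <- stage("report_constants", {
      f <- file.path(config$outDir, "constants.csv")
      reportConstants(cons, f)
      f
    })
    if (!is.null(fc)) res$files <- c(res$files, constants = fc)
    fp <- stage("report_halott_params", {
      f <- file.path(config$outDir, "halott_params.csv")
      reportHaloTTParams(params, f)
      f
    })
    if (!is.null(fp)) res$files <- c(res$files, halott_params = fp)
  }

  if (!is.null(idx)) {
    aov_tab <- stage("anova", anovaIndexTable(idx$perDish))
    res$anova <- aov_tab
    fa <- stage("report_anova", {
      f <- file.path(config$outDir, "anova.csv")
      write.csv(format_num(aov_tab, digits = 6), f, row.names = FALSE,
                quote = FALSE)
      f
    })
    if (!is.null(fa)) res$files <- c(res$files, anova = fa)
  }

  res$log <- log
  writeRunLog(log, config$outDir)
  invisible(res)
}

writeRunLog <- function(log, outDir) {
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(NULL)
}

format_num <- function(df, digits) {
  for (col in names(df))
    if (is.numeric(df[[col]])) df[[col]] <- signif(df[[col]], digits)
  df
}

#' Write the per-temperature probit-fit table
#'
#' One row per temperature: psi_b(50), sigma_psi_b (MPa, 2 decimals), R and
#' R^2 (3 decimals), and the number of probit points. Temperatures whose fit
#' failed appear with empty cells and the failure message. Empty input
#' yields a header-only file.
#'
#' @param fits named list of \linkS4class{ProbitFit} (or fit_error objects)
#'   as produced by the pipeline's per-temperature fitting stage
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
reportProbitFits <- function(fits, path) {
  cols <- c("temperature_C", "psi_b50_MPa", "sigma_psi_b_MPa", "R", "R2",
            "n_points", "note")
  rows <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (is(f, "ProbitFit"))
      rows[[nm]] <- data.frame(
        temperature_C = f@temperature_C,
        psi_b50_MPa = round(f@location50, 2),
        sigma_psi_b_MPa = round(f@sigma, 2),
        R = round(sqrt(max(0, f@r2)), 3), R2 = round(f@r2, 3),
        n_points = f@nPoints, note = "")
    else
      rows[[nm]] <- data.frame(temperature_C = as.numeric(nm),
                               psi_b50_MPa = NA_real_,
                               sigma_psi_b_MPa = NA_real_, R = NA_real_,
                               R2 = NA_real_, n_points = NA_integer_,
                               note = gsub("[,\n]", ";", f$message))
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                     cols))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the per-treatment constants table
#'
#' Mirrors the classical tabulation: per (temperature, psi) the sub- and
#' supra-optimal thermal-time constants, halotime and halothermal constants,
#' and the percentile germination rate.
#'
#' @param constants data.frame from [tabulateConstants()]
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
reportConstants <- function(constants, path) {
  out <- data.frame(
    temperature_C = constants$temperature_C,
    psi_MPa = round(constants$psi_MPa, 2),
    TTsub_thetaT1_degC_h = round(constants$theta_T1, 1),
    TTsupra_thetaT2_degC_h = round(constants$theta_T2, 1),
    theta_halo_MPa_h = round(constants$theta_halo, 2),
    theta_halott_MPa_degC_h = round(constants$theta_halott, 1),
    GR_g_per_h = round(constants$gr_g, 4),
    reached = constants$reached)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the halothermal-parameter table
#'
#' Single-row summary holding the eight model parameters (MPa values to 2
#' decimals) plus the fit R^2.
#'
#' @param params a \linkS4class{HaloTTParams} (NULL yields a header-only
#'   file)
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
reportHaloTTParams <- function(params, path) {
  cols <- c("psi_b50_MPa", "sigma_psi_b_MPa", "theta_halo_MPa_h",
            "theta_halott_MPa_degC_h", "k_T_MPa_per_degC", "T_b_degC",
            "T_o_degC", "T_c_degC", "R2")
  if (is.null(params)) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                  cols))
  } else {
    out <- data.frame(
      psi_b50_MPa = round(params@psiB50, 2),
      sigma_psi_b_MPa = round(params@sigmaPsiB, 2),
      theta_halo_MPa_h = round(params@thetaHalo, 2),
      theta_halott_MPa_degC_h = round(params@thetaHaloTT, 2),
      k_T_MPa_per_degC = round(params@kT, 3),
      T_b_degC = round(params@Tb, 1), T_o_degC = round(params@To, 1),
      T_c_degC = round(params@Tc, 1), R2 = round(params@r2, 3))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
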