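#' Construct a GerminationExperiment from observation records
#'
#' Builds the dish-by-time cumulative count matrix on the union of all
#' observation times. Each dish's count is a right-continuous step function
#' of time (0 at sowing); sampling it on the union grid carries the last
#' observed count forward between that dish's own observations.
#'
#' @param records long-format records as returned by [readCounts()] /
#'   [validateRecords()], or a path to a counts CSV
#' @return a \linkS4class{GerminationExperiment}
#' @examples
#' rec <- data.frame(temperature_C = 20, psi_MPa = 0, replicate = 1,
#'                   time_h = c(24, 48, 72), cum_germinated = c(0, 4, 9),
#'                   seeds_sown = 10)
#' ge <- GerminationExperiment(rec)
#' SummarizedExperiment::assay(ge, "cumulative")
#' @export
GerminationExperiment <- function(records) {
  if (is.character(records)) records <- readCounts(records)
  records <- validateRecords(records)
  key <- interaction(records$temperature_C, records$psi_MPa,
                     records$replicate, drop = TRUE, lex.order = TRUE)
  dishes <- unique(records[, c("temperature_C", "psi_MPa", "replicate",
                               "seeds_sown")])
  times <- sort(unique(records$time_h))
  m <- matrix(0L, nrow = length(times), ncol = nrow(dishes))
  for (j in seq_len(nrow(dishes))) {
    sub <- records[records$temperature_C == dishes$temperature_C[j] &
                   records$psi_MPa == dishes$psi_MPa[j] &
                   records$replicate == dishes$replicate[j], , drop = FALSE]
    m[, j] <- step_count_at(sub$time_h, sub$cum_germinated, times)
  }
  colnames(m) <- sprintf("T%g_psi%g_rep%g", dishes$temperature_C,
                         dishes$psi_MPa, dishes$replicate)
  cd <- S4Vectors::DataFrame(dishes, row.names = colnames(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays  = list(cumulative = m),
    rowData = S4Vectors::DataFrame(time_h = times),
    colData = cd,
    metadata = list(records = records)
  )
  new("GerminationExperiment", se)
}

## cumulative count of a dish's step function at arbitrary times
## (obs_t strictly increasing, count 0 before the first observation)
step_count_at <- function(obs_t, obs_n, at) {
  idx <- findInterval(at, obs_t)
  c(0L, as.integer(obs_n))[idx + 1L]
}

#' @describeIn GerminationExperiment the original long-format records
#' @param x a GerminationExperiment
#' @export
germinationRecords <- function(x) {
  stopifnot(is(x, "GerminationExperiment"))
  S4Vectors::metadata(x)$records
}

#' @describeIn GerminationExperiment the distinct (temperature, psi)
#'   treatments, with replicate and seed tallies
#' @export
treatments <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  agg <- aggregate(cbind(n_dishes = replicate) ~ temperature_C + psi_MPa,
                   data = transform(cd, replicate = 1), FUN = sum)
  tot <- aggregate(seeds_sown ~ temperature_C + psi_MPa, data = cd, FUN = sum)
  out <- merge(agg, tot, by = c("temperature_C", "psi_MPa"))
  out[order(out$temperature_C, out$psi_MPa), , drop = FALSE]
}

setMethod("show", "GerminationExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("GerminationExperiment with", ncol(object), "dishes,",
      nrow(object), "observation times\n")
  cat("  temperatures (degC):",
      paste(sort(unique(cd$temperature_C)), collapse = ", "), "\n")
  cat("  water potentials (MPa):",
      paste(sort(unique(cd$psi_MPa)), collapse = ", "), "\n")
  tt <- SummarizedExperiment::rowData(object)$time_h
  if (length(tt) > 0)
    cat("  observation window:", min(tt), "-", max(tt), "h\n")
  invisible(NULL)
})
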