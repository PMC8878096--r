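counts_schema <- c("temperature_C", "psi_MPa", "replicate", "time_h",
                   "cum_germinated", "seeds_sown")

seedlings_schema <- c("temperature_C", "psi_MPa", "replicate", "seedling_id",
                      "length_cm", "dry_weight_mg", "root_dry_mg",
                      "shoot_dry_mg")

#' Validate a long-format table of germination observation records
#'
#' Checks the invariants every downstream computation relies on: counts are
#' non-negative integers bounded by \code{seeds_sown}, water potentials are
#' non-positive, observation times are positive, and within each dish the
#' cumulative count is non-decreasing over time. Records are returned sorted
#' by (temperature, water potential, replicate, time).
#'
#' @param records data.frame with columns \code{temperature_C, psi_MPa,
#'   replicate, time_h, cum_germinated, seeds_sown}
#' @return the validated, sorted data.frame
#' @export
validateRecords <- function(records) {
  miss <- setdiff(counts_schema, names(records))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in counts_schema)
    if (!is.numeric(records[[col]]))
      stop("column '", col, "' must be numeric")
  if (any(records$psi_MPa > 0))
    stop("psi_MPa must be <= 0 (water potential in MPa)")
  if (any(records$time_h <= 0))
    stop("time_h must be positive")
  if (any(records$seeds_sown <= 0))
    stop("seeds_sown must be positive")
  if (any(records$cum_germinated < 0))
    stop("cum_germinated must be non-negative")
  if (any(records$cum_germinated != round(records$cum_germinated)))
    stop("cum_germinated must be integer counts")
  bad <- records$cum_germinated > records$seeds_sown
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "cum_germinated (%d) exceeds seeds_sown (%d) in dish (T=%g, psi=%g, rep=%g)",
      records$cum_germinated[i], records$seeds_sown[i],
      records$temperature_C[i], records$psi_MPa[i], records$replicate[i]))
  }
  ord <- order(records$temperature_C, records$psi_MPa, records$replicate,
               records$time_h)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  key <- interaction(records$temperature_C, records$psi_MPa,
                     records$replicate, drop = TRUE)
  for (k in levels(key)) {
    sub <- records[key == k, , drop = FALSE]
    if (anyDuplicated(sub$time_h))
      stop(sprintf("duplicate observation time in dish (T=%g, psi=%g, rep=%g)",
                   sub$temperature_C[1], sub$psi_MPa[1], sub$replicate[1]))
    if (any(diff(sub$cum_germinated) < 0))
      stop(sprintf(
        "cumulative count decreases over time in dish (T=%g, psi=%g, rep=%g)",
        sub$temperature_C[1], sub$psi_MPa[1], sub$replicate[1]))
    if (length(unique(sub$seeds_sown)) != 1)
      stop(sprintf("seeds_sown changes within dish (T=%g, psi=%g, rep=%g)",
                   sub$temperature_C[1], sub$psi_MPa[1], sub$replicate[1]))
  }
  records
}

#' Read germination counts from a long-format CSV
#'
#' Expected header: \code{temperature_C,psi_MPa,replicate,time_h,
#' cum_germinated,seeds_sown}; one row per dish per observation time, counts
#' cumulative. All [validateRecords()] invariants are enforced on read.
#'
#' @param path path to the CSV file
#' @return validated data.frame of observation records, sorted by
#'   (temperature, water potential, replicate, time)
#' @seealso [writeCounts()], [GerminationExperiment()]
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validateRecords(read.csv(path))
}

#' Write germination counts to CSV
#'
#' Inverse of [readCounts()]: writes the long-format schema so that
#' read -> write -> read round-trips exactly.
#'
#' @param records validated records data.frame (or a
#'   \linkS4class{GerminationExperiment}, whose original records are used)
#' @param path output CSV path
#' @return \code{path}, invisibly
#' @export
writeCounts <- function(records, path) {
  if (is(records, "GerminationExperiment"))
    records <- germinationRecords(records)
  write.csv(records[, counts_schema], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read seedling measurements from CSV
#'
#' Expected header: \code{temperature_C,psi_MPa,replicate,seedling_id,
#' length_cm,dry_weight_mg,root_dry_mg,shoot_dry_mg}; one row per measured
#' seedling (conventionally three per dish). Used by the vigour indices
#' SVI-I, SVI-II and the root:shoot ratio.
#'
#' @param path path to the CSV file
#' @return validated data.frame of seedling measurements
#' @export
readSeedlings <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  miss <- setdiff(seedlings_schema, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  meas <- c("length_cm", "dry_weight_mg", "root_dry_mg", "shoot_dry_mg")
  for (col in meas)
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("column '", col, "' must be non-negative")
  ord <- order(df$temperature_C, df$psi_MPa, df$replicate, df$seedling_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
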