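#' Daily germination schedule of one dish
#'
#' Collapses a dish's cumulative observation records onto integer days
#' (\code{day = ceiling(time_h / hours_per_day)}); newly germinated seeds are
#' credited to the day of the observation at which they were first counted.
#'
#' @param records observation records for a single dish
#' @param hours_per_day hours per "day" for index computation (default 24;
#'   the index literature works on a daily scale while model fitting works in
#'   hours)
#' @return data.frame with columns \code{day}, \code{newly_germinated},
#'   \code{cum_germinated}; attribute \code{seeds_sown}
#' @export
dailySchedule <- function(records, hours_per_day = 24) {
  stopifnot(nrow(records) > 0, hours_per_day > 0)
  day <- ceiling(records$time_h / hours_per_day)
  cum <- tapply(records$cum_germinated, day, max)
  days <- as.numeric(names(cum))
  cum <- as.numeric(cum)
  out <- data.frame(day = days,
                    newly_germinated = diff(c(0, cum)),
                    cum_germinated = cum)
  attr(out, "seeds_sown") <- records$seeds_sown[1]
  out
}

#' Germination percentage
#'
#' 100 x (final germinated count) / (seeds sown).
#' @param final_germinated final cumulative germinated count
#' @param seeds_sown number of seeds sown
#' @return percentage in [0, 100]
#' @export
gp <- function(final_germinated, seeds_sown) {
  if (any(seeds_sown <= 0)) stop("seeds_sown must be positive")
  100 * final_germinated / seeds_sown
}

#' Mean germination time
#'
#' Count-weighted mean day of germination, sum(f * x) / sum(f) over
#' germination days x with daily counts f. Undefined (NA) when nothing
#' germinates.
#' @param days germination days
#' @param counts seeds newly germinated on each day
#' @return MGT in days, or NA if no seed germinated
#' @export
mgt <- function(days, counts) {
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  sum(counts * days) / tot
}

#' Germination rate index
#'
#' Sum over days of (percent germinating on that day) / (day number).
#' @param days germination days
#' @param percents percent of sown seeds germinating on each day
#' @return GRI in percent per day
#' @export
gri <- function(days, percents) {
  if (length(days) == 0) return(0)
  sum(percents / days)
}

#' Germination index (descending-weight count)
#'
#' Seeds germinating on day d receive weight (test_length - d + 1), so the
#' weights descend from \code{test_length} on day 1 to 1 on the last day of
#' the test; germination after the test length gets weight 0.
#' @param days germination days
#' @param counts seeds newly germinated on each day
#' @param test_length test duration in days (default 10, the classical form)
#' @return weighted count
#' @export
gi <- function(days, counts, test_length = 10) {
  if (length(days) == 0) return(0)
  sum(pmax(0, test_length - days + 1) * counts)
}

#' Coefficient of velocity of germination
#'
#' 100 x sum(N_i) / sum(N_i * T_i) over daily counts N_i at days T_i; takes
#' its theoretical maximum of 100 when every germinating seed germinates on
#' day 1.
#' @param days germination days
#' @param counts seeds newly germinated on each day
#' @return CVG (dimensionless), NA if no seed germinated
#' @export
cvg <- function(days, counts) {
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  100 * tot / sum(counts * days)
}

#' Germination energy
#'
#' Telescoping sum of daily count increments over day numbers:
#' sum_k (X_k - X_{k-1}) / Y_k with X cumulative counts on count days Y and
#' X_0 = 0.
#' @param days count days
#' @param cum_counts cumulative germinated counts on those days
#' @return GE (dimensionless)
#' @export
ge <- function(days, cum_counts) {
  if (length(days) == 0) return(0)
  sum(diff(c(0, cum_counts)) / days)
}

#' Timson germination index
#'
#' Sum of the cumulative germination percentage over each day of the test
#' period (cumulative percent carried forward between count days). Maximum is
#' 100 x period, attained when all seeds germinate on day 1.
#' @param days count days
#' @param cum_percent cumulative germination percentages on those days
#' @param period test period in days
#' @return TGI in percent-days
#' @export
tgi <- function(days, cum_percent, period) {
  stopifnot(period >= 1)
  if (length(days) == 0) return(0)
  daily <- step_percent_at(days, cum_percent, seq_len(period))
  sum(daily)
}

step_percent_at <- function(obs_d, obs_p, at) {
  idx <- findInterval(at, obs_d)
  c(0, obs_p)[idx + 1L]
}

#' Mean germination rate
#'
#' Reciprocal of mean germination time.
#' @param mgt mean germination time in days
#' @return MGR in 1/days
#' @export
mgr <- function(mgt) 1 / mgt

#' Seed vigour index I (length-based)
#'
#' Mean seedling length (cm) x germination percentage.
#' @param mean_length_cm mean seedling length, cm
#' @param gp_percent germination percentage
#' @export
svi1 <- function(mean_length_cm, gp_percent) mean_length_cm * gp_percent

#' Seed vigour index II (weight-based)
#'
#' Mean seedling dry weight (mg) x germination percentage.
#' @param mean_dry_weight_mg mean seedling dry weight, mg
#' @param gp_percent germination percentage
#' @export
svi2 <- function(mean_dry_weight_mg, gp_percent) mean_dry_weight_mg * gp_percent

#' Time to 50\% germination
#'
#' Linear interpolation of the cumulative count between the bracketing count
#' days: t_i + (N/2 - n_i)(t_j - t_i)/(n_j - n_i), where N is the final
#' germinated count and n_i < N/2 <= n_j.
#' @param days count days
#' @param cum_counts cumulative germinated counts on those days
#' @param final_count final germinated count N (defaults to the last
#'   cumulative count)
#' @return T50 in days, NA when no seed germinates
#' @export
t50 <- function(days, cum_counts, final_count = NULL) {
  if (length(days) == 0) return(NA_real_)
  if (is.null(final_count)) final_count <- cum_counts[length(cum_counts)]
  if (final_count <= 0) return(NA_real_)
  target <- final_count / 2
  j <- which(cum_counts >= target - 1e-12)[1]
  if (is.na(j)) return(NA_real_)
  if (abs(cum_counts[j] - target) <= 1e-12) return(days[j])
  if (j == 1) { ti <- 0; ni <- 0 } else { ti <- days[j - 1]; ni <- cum_counts[j - 1] }
  ti + (target - ni) * (days[j] - ti) / (cum_counts[j] - ni)
}

#' Root:shoot dry-weight ratio
#'
#' @param root_dry_mg root dry weight, mg
#' @param shoot_dry_mg shoot dry weight, mg (> 0)
#' @export
rsr <- function(root_dry_mg, shoot_dry_mg) {
  if (any(shoot_dry_mg <= 0)) stop("shoot dry weight must be positive")
  root_dry_mg / shoot_dry_mg
}

index_names <- c("GP", "MGT", "GRI", "GI", "CVG", "GE", "TGI", "MGR",
                 "SVI_I", "SVI_II", "T50", "RSR")

#' All twelve germination indices for one dish
#'
#' @param records observation records for one dish
#' @param seedlings optional seedling measurements for the same dish
#' @param hours_per_day day length used to build the daily schedule
#' @param test_length test duration in days for GI and the Timson index
#'   (default: last observation day of the dish)
#' @return named numeric vector of the twelve indices (seedling-based entries
#'   NA when no seedling data are supplied)
#' @export
dishIndices <- function(records, seedlings = NULL, hours_per_day = 24,
                        test_length = NULL) {
  sched <- dailySchedule(records, hours_per_day)
  sown <- attr(sched, "seeds_sown")
  if (is.null(test_length)) test_length <- max(sched$day)
  germ <- sched[sched$newly_germinated > 0, , drop = FALSE]
  final <- sched$cum_germinated[nrow(sched)]
  gp_v <- gp(final, sown)
  mgt_v <- mgt(germ$day, germ$newly_germinated)
  out <- c(
    GP  = gp_v,
    MGT = mgt_v,
    GRI = gri(germ$day, 100 * germ$newly_germinated / sown),
    GI  = gi(germ$day, germ$newly_germinated, test_length),
    CVG = cvg(germ$day, germ$newly_germinated),
    GE  = ge(germ$day, germ$cum_germinated),
    TGI = tgi(sched$day, 100 * sched$cum_germinated / sown, test_length),
    MGR = mgr(mgt_v),
    SVI_I  = NA_real_,
    SVI_II = NA_real_,
    T50 = t50(germ$day, germ$cum_germinated, final),
    RSR = NA_real_
  )
  if (!is.null(seedlings) && nrow(seedlings) > 0) {
    out["SVI_I"]  <- svi1(mean(seedlings$length_cm), gp_v)
    out["SVI_II"] <- svi2(mean(seedlings$dry_weight_mg), gp_v)
    sh <- mean(seedlings$shoot_dry_mg)
    if (sh > 0) out["RSR"] <- mean(seedlings$root_dry_mg) / sh
  }
  out
}

#' Per-dish index values for a whole experiment
#'
#' @param x a \linkS4class{GerminationExperiment} or validated records
#' @param seedlings optional seedling measurement data.frame
#'   ([readSeedlings()] schema)
#' @param hours_per_day,test_length see [dishIndices()]; \code{test_length}
#'   defaults to the last observation day of the whole experiment so every
#'   dish is scored on a common window
#' @return data.frame with one row per dish: design columns plus the twelve
#'   indices
#' @export
experimentIndices <- function(x, seedlings = NULL, hours_per_day = 24,
                              test_length = NULL) {
  rec <- if (is(x, "GerminationExperiment")) germinationRecords(x)
         else validateRecords(x)
  if (is.null(test_length))
    test_length <- max(ceiling(rec$time_h / hours_per_day))
  key <- unique(rec[, c("temperature_C", "psi_MPa", "replicate")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- rec[rec$temperature_C == key$temperature_C[i] &
               rec$psi_MPa == key$psi_MPa[i] &
               rec$replicate == key$replicate[i], , drop = FALSE]
    sdl <- NULL
    if (!is.null(seedlings))
      sdl <- seedlings[seedlings$temperature_C == key$temperature_C[i] &
                       seedlings$psi_MPa == key$psi_MPa[i] &
                       seedlings$replicate == key$replicate[i], , drop = FALSE]
    cbind(key[i, , drop = FALSE],
          as.data.frame(as.list(dishIndices(sub, sdl, hours_per_day,
                                            test_length))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$temperature_C, out$psi_MPa, out$replicate), , drop = FALSE]
}

#' Treatment-level index table (replicate mean and standard error)
#'
#' Computes every index per dish via [dishIndices()], then aggregates to
#' replicate means and standard errors per (temperature, water potential)
#' treatment — the replicate-level values are what feeds [anovaTwoWay()].
#'
#' @inheritParams experimentIndices
#' @return long-format data.frame: \code{temperature_C, psi_MPa, index,
#'   mean, se, n}
#' @export
indexTable <- function(x, seedlings = NULL, hours_per_day = 24,
                       test_length = NULL) {
  per <- experimentIndices(x, seedlings, hours_per_day, test_length)
  tr <- unique(per[, c("temperature_C", "psi_MPa")])
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    sub <- per[per$temperature_C == tr$temperature_C[i] &
               per$psi_MPa == tr$psi_MPa[i], , drop = FALSE]
    for (idx in index_names) {
      v <- sub[[idx]]
      v_ok <- v[!is.na(v)]
      n <- length(v_ok)
      rows[[length(rows) + 1L]] <- data.frame(
        temperature_C = tr$temperature_C[i],
        psi_MPa = tr$psi_MPa[i],
        index = idx,
        mean = if (n > 0) mean(v_ok) else NA_real_,
        se = if (n > 1) sd(v_ok) / sqrt(n) else if (n == 1) 0 else NA_real_,
        n = n)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
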