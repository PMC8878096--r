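#' Simulation configuration for germination experiments
#'
#' Defaults emulate the laboratory design the models were developed for:
#' 6 constant temperatures (15-40 degC in 5 degC steps) crossed with 5 water
#' potentials (0 to -2 MPa in 0.5 MPa steps), 3 replicate dishes of 10 seeds,
#' daily (24 h) observations to 336 h, 95 percent seed viability, and the
#' reference barley halothermal parameter set as ground truth. Per-seed
#' germination timing carries multiplicative lognormal noise (sd 0.15 on the
#' log scale; threshold-model residuals live on the rate scale).
#'
#' @param params \linkS4class{HaloTTParams} ground truth
#' @param temperatures,psis design grids (degC; MPa, non-positive)
#' @param replicates dishes per treatment
#' @param seedsPerDish seeds sown per dish
#' @param observationTimes observation schedule, hours (increasing)
#' @param viability germinable fraction in (0, 1]
#' @param noise lognormal sd of the per-seed timing factor (0 = none)
#' @param thresholds "random" (iid normal draws) or "stratified"
#'   (mid-quantiles of the threshold distribution, for deterministic
#'   noise-free populations)
#' @param seed RNG seed; NULL leaves the RNG state alone
#' @param seedlings logical: also synthesise seedling measurements
#' @param seedlingParams parameters of the simple linear seedling response
#'   (base length cm, base dry weight mg, decline per MPa and per degC from
#'   To, relative noise sd, root weight fraction and its decline per MPa)
#' @return a list of class \code{"simConfig"}
#' @export
simConfig <- function(params = barleyHaloTTParams(),
                      temperatures = c(15, 20, 25, 30, 35, 40),
                      psis = c(0, -0.5, -1.0, -1.5, -2.0),
                      replicates = 3,
                      seedsPerDish = 10,
                      observationTimes = seq(24, 336, by = 24),
                      viability = 0.95,
                      noise = 0.15,
                      thresholds = c("random", "stratified"),
                      seed = NULL,
                      seedlings = FALSE,
                      seedlingParams = list(len0 = 10, wt0 = 2,
                                            declinePsi = 0.25,
                                            declineT = 0.03, relSd = 0.05,
                                            rootFrac = 0.35,
                                            rootDeclinePsi = 0.05)) {
  thresholds <- match.arg(thresholds)
  stopifnot(is(params, "HaloTTParams"),
            length(temperatures) > 0, length(psis) > 0, all(psis <= 0),
            replicates >= 1, seedsPerDish >= 1,
            length(observationTimes) > 0, all(observationTimes > 0),
            !is.unsorted(observationTimes, strictly = TRUE),
            viability > 0, viability <= 1, noise >= 0)
  structure(list(params = params, temperatures = temperatures, psis = psis,
                 replicates = replicates, seedsPerDish = seedsPerDish,
                 observationTimes = observationTimes, viability = viability,
                 noise = noise, thresholds = thresholds, seed = seed,
                 seedlings = seedlings, seedlingParams = seedlingParams),
            class = "simConfig")
}

#' Draw per-seed base-water-potential thresholds
#'
#' @param n number of seeds
#' @param psi_b50 median threshold, MPa
#' @param sigma threshold standard deviation, MPa (>= 0)
#' @param stratified if TRUE, return the deterministic mid-quantiles
#'   Phi^-1((i - 0.5)/n) of the threshold distribution instead of random
#'   draws (an exact finite-population discretisation used by noise-free
#'   fixtures)
#' @return numeric vector of n thresholds, MPa
#' @export
drawThresholds <- function(n, psi_b50, sigma, stratified = FALSE) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (stratified)
    qnorm((seq_len(n) - 0.5) / n, mean = psi_b50, sd = sigma)
  else
    rnorm(n, mean = psi_b50, sd = sigma)
}

#' Germination time of a seed with a given threshold
#'
#' Inverts the halothermal-time relation for a seed with base water
#' potential \code{threshold}: t = thetaHaloTT / ((psi_adj - threshold)
#' (T - Tb)) with psi_adj = psi - kT max(0, T - To). A seed never germinates
#' (Inf) when T is outside (Tb, Tc) or the adjusted water potential does not
#' exceed its threshold. \code{noise} multiplies the time by a lognormal
#' factor with median 1.
#'
#' @param threshold per-seed base water potential(s), MPa
#' @param temperature_C,psi_MPa environment
#' @param params \linkS4class{HaloTTParams}
#' @param noise lognormal sd of the timing factor (0 = deterministic)
#' @return germination times in hours (Inf = never); vectorised over
#'   \code{threshold}
#' @export
germinationTime <- function(threshold, temperature_C, psi_MPa, params,
                            noise = 0) {
  n <- length(threshold)
  if (temperature_C <= params@Tb ||
      (!is.na(params@Tc) && temperature_C >= params@Tc))
    return(rep(Inf, n))
  psi_adj <- psi_MPa - params@kT * max(0, temperature_C - params@To)
  force_ <- psi_adj - threshold
  t <- rep(Inf, n)
  ok <- force_ > 0
  t[ok] <- params@thetaHaloTT / (force_[ok] * (temperature_C - params@Tb))
  if (noise > 0 && any(ok))
    t[ok] <- t[ok] * rlnorm(sum(ok), meanlog = 0, sdlog = noise)
  t
}

#' Simulate a germination experiment
#'
#' For every dish: Bernoulli viability thinning, per-seed threshold draws,
#' halothermal germination times with optional timing noise, and cumulative
#' counts at each observation time. Optionally synthesises three seedling
#' measurements per germinating dish from a simple documented linear
#' response (length and dry weight decline with |psi| and with distance from
#' To, plus Gaussian noise) to exercise the vigour indices.
#'
#' @param config a [simConfig()]
#' @return list with \code{records} (long-format observation records passing
#'   [validateRecords()]) and \code{seedlings} (data.frame or NULL)
#' @export
simulateExperiment <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$params
  obs <- config$observationTimes
  rec <- list(); sdl <- list()
  for (Tc_ in config$temperatures) for (psi in config$psis)
    for (rep_ in seq_len(config$replicates)) {
      n <- config$seedsPerDish
      viable <- if (config$viability < 1)
        rbinom(n, 1, config$viability) == 1 else rep(TRUE, n)
      thr <- drawThresholds(n, p@psiB50, p@sigmaPsiB,
                            stratified = config$thresholds == "stratified")
      t <- germinationTime(thr, Tc_, psi, p, noise = config$noise)
      t[!viable] <- Inf
      cum <- vapply(obs, function(tt) sum(t <= tt), integer(1))
      rec[[length(rec) + 1L]] <- data.frame(
        temperature_C = Tc_, psi_MPa = psi, replicate = rep_,
        time_h = obs, cum_germinated = cum, seeds_sown = n)
      if (config$seedlings && any(is.finite(t))) {
        sp <- config$seedlingParams
        scale_ <- max(0.05, 1 - sp$declinePsi * abs(psi) -
                        sp$declineT * abs(Tc_ - p@To))
        len <- pmax(0.1, sp$len0 * scale_ *
                      (1 + rnorm(3, 0, sp$relSd)))
        wt <- pmax(0.05, sp$wt0 * scale_ * (1 + rnorm(3, 0, sp$relSd)))
        rootFrac <- min(0.9, max(0.05,
          sp$rootFrac * (1 - sp$rootDeclinePsi * abs(psi))))
        sdl[[length(sdl) + 1L]] <- data.frame(
          temperature_C = Tc_, psi_MPa = psi, replicate = rep_,
          seedling_id = 1:3, length_cm = len, dry_weight_mg = wt,
          root_dry_mg = wt * rootFrac, shoot_dry_mg = wt * (1 - rootFrac))
      }
    }
  records <- validateRecords(do.call(rbind, rec))
  seedlings <- if (length(sdl) > 0) do.call(rbind, sdl) else NULL
  if (!is.null(seedlings)) rownames(seedlings) <- NULL
  list(records = records, seedlings = seedlings)
}

#' Write the bundled deterministic fixture suite
#'
#' Generates small reference datasets used by the tests and examples:
#' \itemize{
#'   \item \code{paper_scale_counts.csv} / \code{paper_scale_seedlings.csv} —
#'     the full factorial design (6 temperatures x 5 potentials x 3 dishes of
#'     10 seeds), random thresholds, default noise and viability;
#'   \item \code{noise_free_dense_counts.csv} — stratified thresholds, no
#'     timing noise, full viability, one dish of 400 seeds per treatment on
#'     a dense 4 h schedule, at temperatures bracketing the optimum (for
#'     parameter-recovery tests);
#'   \item \code{degenerate_none_counts.csv} — a treatment in which no seed
#'     germinates;
#'   \item \code{degenerate_first_day_counts.csv} — every seed germinates
#'     before the first observation.
#' }
#' All files are deterministic (fixed internal seeds) and byte-identical
#' across runs.
#'
#' @param dir output directory (created if needed)
#' @return named character vector of the files written, invisibly
#' @export
fixtureSuite <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c()
  ## paper-scale factorial design
  cfg <- simConfig(seed = 101, seedlings = TRUE)
  sim <- simulateExperiment(cfg)
  f1 <- file.path(dir, "paper_scale_counts.csv")
  writeCounts(sim$records, f1)
  f1b <- file.path(dir, "paper_scale_seedlings.csv")
  write.csv(sim$seedlings, f1b, row.names = FALSE, quote = FALSE)
  ## noise-free dense design near the optimum
  cfg2 <- simConfig(temperatures = c(16, 18, 20, 21, 22),
                    psis = c(0, -0.1, -0.2, -0.3),
                    replicates = 1, seedsPerDish = 400,
                    observationTimes = seq(4, 1600, by = 4),
                    viability = 1, noise = 0, thresholds = "stratified")
  sim2 <- simulateExperiment(cfg2)
  f2 <- file.path(dir, "noise_free_dense_counts.csv")
  writeCounts(sim2$records, f2)
  ## degenerate: nothing germinates (psi far below every threshold)
  cfg3 <- simConfig(temperatures = 25, psis = -2, replicates = 3,
                    viability = 1, noise = 0, thresholds = "stratified")
  sim3 <- simulateExperiment(cfg3)
  f3 <- file.path(dir, "degenerate_none_counts.csv")
  writeCounts(sim3$records, f3)
  ## degenerate: everything germinates before the first observation
  fastp <- haloTTParams(psiB50 = -1.5, sigmaPsiB = 0.1, thetaHalo = 2,
                        kT = 0, Tb = 15, To = 20, Tc = 40)
  cfg4 <- simConfig(params = fastp, temperatures = 20, psis = 0,
                    replicates = 3, viability = 1, noise = 0,
                    thresholds = "stratified")
  sim4 <- simulateExperiment(cfg4)
  f4 <- file.path(dir, "degenerate_first_day_counts.csv")
  writeCounts(sim4$records, f4)
  out <- c(paper_scale = f1, paper_scale_seedlings = f1b,
           noise_free_dense = f2, degenerate_none = f3,
           degenerate_first_day = f4)
  invisible(out)
}
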