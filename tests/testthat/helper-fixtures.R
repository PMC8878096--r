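# shared fixture builders and independent oracles

# long-format records for one dish
dish_records <- function(T, psi, rep, times, cum, sown = 10) {
  data.frame(temperature_C = T, psi_MPa = psi, replicate = rep,
             time_h = times, cum_germinated = cum, seeds_sown = sown)
}

# brute-force pooled-curve oracle: replay every dish's step function seed by
# seed and count germinated seeds at each query time
pooled_fraction_oracle <- function(dishes, at) {
  # dishes: list of data.frames with times, cum, sown
  total <- sum(vapply(dishes, function(d) d$sown[1], numeric(1)))
  counts <- vapply(at, function(tt) {
    sum(vapply(dishes, function(d) {
      seen <- d$cum[d$times <= tt]
      if (length(seen) == 0) 0 else max(seen)
    }, numeric(1)))
  }, numeric(1))
  counts / total
}

# exhaustive 3-D SSE grid oracle for the halotime probit fit: minimise the
# sum of squared probit residuals over (theta, location, sigma)
halotime_bruteforce <- function(pts, theta_grid, loc_grid, sigma_grid) {
  best <- list(sse = Inf)
  y <- qnorm(pts$g)
  for (th in theta_grid) {
    x <- pts$psi - th / pts$tg
    for (loc in loc_grid) for (sg in sigma_grid) {
      sse <- sum((y - (x - loc) / sg)^2)
      if (sse < best$sse)
        best <- list(sse = sse, theta = th, location = loc, sigma = sg)
    }
  }
  best
}

# model curves at several (T, psi) on a dense time grid
dense_model_curves <- function(params, temps, psis,
                               times = seq(4, 1600, by = 4)) {
  out <- list()
  for (T in temps) for (psi in psis)
    out[[length(out) + 1L]] <- predictTimeCourse(params, T, psi, times)
  out
}
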