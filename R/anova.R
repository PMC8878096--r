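#' Two-way factorial ANOVA of a germination parameter
#'
#' Sequential (Type I) decomposition of a per-dish response into temperature,
#' water-potential, interaction and residual sums of squares, computed from
#' first principles by incremental least-squares projections (QR fits of the
#' nested model sequence 1, +T, +T+psi, +T+psi+T:psi). On a balanced design
#' this equals the classical cell-mean decomposition and the sums of squares
#' add exactly to the total.
#'
#' @param data data.frame of per-dish values (e.g. one index column of
#'   [experimentIndices()])
#' @param response name of the response column
#' @param factorA,factorB names of the factor columns (defaults
#'   \code{"temperature_C"} and \code{"psi_MPa"})
#' @return data.frame with rows \code{temperature}, \code{psi},
#'   \code{temperature:psi}, \code{residual}: columns \code{df, ss, ms, F,
#'   p}; attribute \code{flags} collects degeneracies ("no_residual_df"
#'   when there is one replicate per cell, "zero_residual_variance" when
#'   replicates are identical)
#' @export
anovaTwoWay <- function(data, response, factorA = "temperature_C",
                        factorB = "psi_MPa") {
  stopifnot(all(c(response, factorA, factorB) %in% names(data)))
  keep <- !is.na(data[[response]])
  data <- data[keep, , drop = FALSE]
  y <- data[[response]]
  A <- factor(data[[factorA]])
  B <- factor(data[[factorB]])
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("both factors need >= 2 levels")
  n <- length(y)
  rss <- function(X) {
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  ss_tot <- sum((y - mean(y))^2)
  r0 <- ss_tot                                  # intercept-only RSS
  r1 <- rss(model.matrix(~A))
  r2 <- rss(model.matrix(~A + B))
  r3 <- rss(model.matrix(~A * B))
  dfA <- nlevels(A) - 1L
  dfB <- nlevels(B) - 1L
  dfAB <- dfA * dfB
  dfRes <- n - nlevels(A) * nlevels(B)
  ss <- c(r0 - r1, r1 - r2, r2 - r3, r3)
  df <- c(dfA, dfB, dfAB, dfRes)
  flags <- character(0)
  if (dfRes <= 0) flags <- c(flags, "no_residual_df")
  msRes <- if (dfRes > 0) r3 / dfRes else NA_real_
  zeroRes <- !is.na(msRes) && msRes <= .Machine$double.eps * max(ss_tot, 1)
  if (zeroRes) flags <- c(flags, "zero_residual_variance")
  ms <- ifelse(df > 0, ss / df, NA_real_)
  Fv <- rep(NA_real_, 4)
  pv <- rep(NA_real_, 4)
  if (dfRes > 0) {
    for (i in 1:3) {
      Fv[i] <- if (zeroRes) Inf else ms[i] / msRes
      pv[i] <- if (is.finite(Fv[i])) pf(Fv[i], df[i], dfRes,
                                        lower.tail = FALSE) else 0
    }
  }
  out <- data.frame(
    term = c("temperature", "psi", "temperature:psi", "residual"),
    df = df, ss = ss, ms = ms, F = Fv, p = pv)
  attr(out, "flags") <- flags
  attr(out, "ss_total") <- ss_tot
  out
}

#' ANOVA of every germination index
#'
#' Runs [anovaTwoWay()] on each of the twelve indices of a per-dish index
#' table and stacks the results.
#'
#' @param perDish per-dish index values from [experimentIndices()]
#' @param indices which index columns to analyse (default: all twelve that
#'   have at least two non-missing replicates per level)
#' @return long data.frame: \code{index, term, df, ss, ms, F, p}
#' @export
anovaIndexTable <- function(perDish, indices = index_names) {
  rows <- list()
  for (idx in indices) {
    if (!idx %in% names(perDish)) next
    v <- perDish[[idx]]
    if (sum(!is.na(v)) < 4 || length(unique(v[!is.na(v)])) < 2) next
    tab <- tryCatch(anovaTwoWay(perDish, idx), error = function(e) NULL)
    if (is.null(tab)) next
    tab$index <- idx
    rows[[length(rows) + 1L]] <- tab[, c("index", "term", "df", "ss", "ms",
                                         "F", "p")]
  }
  if (length(rows) == 0)
    return(data.frame(index = character(0), term = character(0),
                      df = integer(0), ss = numeric(0), ms = numeric(0),
                      F = numeric(0), p = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
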