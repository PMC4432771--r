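# Aggregation operators: collapse the index values of a residue group into a
# single descriptor value.  Degenerate cases (empty group, undefined
# statistic) return the missing-value sentinel NA, never an error, so the
# descriptor table stays rectangular.

#' Aggregation operator names
#'
#' The twenty supported aggregation operators, in the canonical order used
#' by descriptor names; see [aggregate_values()] for the definitions.
#' @export
AGGREGATORS <- c("N1", "N2", "N3", "AM", "GM", "HM", "Q1", "Q2", "Q3",
                 "MX", "MN", "V", "SD", "CV", "SK", "RG", "IQ",
                 "TIC", "MIC", "SIC")

#' Aggregate a vector of index values into one descriptor value
#'
#' Supported operators:
#' * Minkowski norms: `N1` (Manhattan), `N2` (Euclidean), `N3` (third norm).
#' * Central tendency: `AM` arithmetic mean, `GM` geometric mean of absolute
#'   values (zero if any value is 0), `HM` harmonic mean (NA if any value is
#'   0), `Q1`/`Q2`/`Q3` quartiles (linear interpolation), `MX`/`MN` extremes.
#' * Dispersion: `V` population variance, `SD` its square root, `CV` =
#'   SD/|AM| (NA when AM = 0), `SK` population skewness (NA when SD = 0),
#'   `RG` range, `IQ` interquartile range.
#' * Information content over equivalence classes formed by rounding the
#'   values to `precision` decimals, with class counts n_g and n = length:
#'   `TIC` = n log2 n - sum n_g log2 n_g, `MIC` = -sum (n_g/n) log2 (n_g/n),
#'   `SIC` = MIC / log2 n (NA when n = 1).
#'
#' Empty input returns NA for every operator.
#'
#' @param values numeric vector (the index values of one group).
#' @param name operator name (see `AGGREGATORS`).
#' @param precision decimal rounding used to form equivalence classes for
#'   the information measures.
#' @return A single numeric value, or NA for degenerate cases.
#' @export
aggregate_values <- function(values, name, precision = 6) {
  if (!name %in% AGGREGATORS)
    stop("unknown aggregation operator '", name, "'; supported: ",
         paste(AGGREGATORS, collapse = ", "))
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) return(NA_real_)
  switch(name,
    N1 = sum(abs(v)),
    N2 = sqrt(sum(v^2)),
    N3 = sum(abs(v)^3)^(1 / 3),
    AM = mean(v),
    GM = if (any(v == 0)) 0 else exp(mean(log(abs(v)))),
    HM = if (any(v == 0)) NA_real_ else n / sum(1 / v),
    Q1 = unname(stats::quantile(v, 0.25, type = 7)),
    Q2 = unname(stats::quantile(v, 0.50, type = 7)),
    Q3 = unname(stats::quantile(v, 0.75, type = 7)),
    MX = max(v),
    MN = min(v),
    V  = mean((v - mean(v))^2),
    SD = sqrt(mean((v - mean(v))^2)),
    CV = {
      am <- mean(v)
      if (am == 0) NA_real_ else sqrt(mean((v - am)^2)) / abs(am)
    },
    SK = {
      m <- mean(v); s2 <- mean((v - m)^2)
      if (s2 == 0) NA_real_ else mean((v - m)^3) / s2^1.5
    },
    RG = max(v) - min(v),
    IQ = unname(diff(stats::quantile(v, c(0.25, 0.75), type = 7))),
    TIC = unname(.info_content(v, precision)["TIC"]),
    MIC = unname(.info_content(v, precision)["MIC"]),
    SIC = unname(.info_content(v, precision)["SIC"])
  )
}

.info_content <- function(v, precision) {
  n <- length(v)
  ng <- table(round(v, precision))
  p <- as.numeric(ng) / n
  mic <- -sum(p * log2(p))
  tic <- n * log2(n) - sum(as.numeric(ng) * log2(as.numeric(ng)))
  sic <- if (n == 1L) NA_real_ else mic / log2(n)
  c(TIC = tic, MIC = mic, SIC = sic)
}

#' Aggregate with several operators at once
#'
#' @inheritParams aggregate_values
#' @param names character vector of operator names.
#' @return Named numeric vector, one entry per operator.
#' @export
aggregate_all <- function(values, names = AGGREGATORS, precision = 6) {
  vapply(names, function(nm)
    unname(aggregate_values(values, nm, precision)), numeric(1))
}
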