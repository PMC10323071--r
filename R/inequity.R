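#' Decile scores on the 0-1 scale
#'
#' Assigns each area to a decile of the variable's distribution and scores
#' deciles on a continuous 0-1 scale: the first decile scores 0, the second
#' 1/9, the third 2/9, and so on up to 1 for the tenth. Decile cut points
#' are sample quantiles with linear interpolation between order statistics;
#' values tied with a cut point fall in the lower decile. Used as the
#' exposure in slope-index-of-inequality regressions, so the regression
#' slope reads as the outcome difference between the top and bottom decile.
#'
#' @param values numeric vector, one value per area (>= 10 areas).
#' @return Numeric vector of scores in `{0, 1/9, ..., 1}`, nondecreasing in
#'   the input.
#' @export
decile_score <- function(values) {
  if (length(values) < 10L) stop("need at least 10 areas to form deciles")
  if (length(unique(values)) == 1L)
    stop("all values identical: deciles do not exist")
  cuts <- stats::quantile(values, probs = seq(0.1, 0.9, by = 0.1),
                          type = 7, names = FALSE)
  d <- 1L + vapply(values, function(v) sum(cuts < v), integer(1))
  (d - 1) / 9
}

#' Composite socioeconomic Z-score
#'
#' Standardizes each SES variable to mean 0 and SD 1 (denominator n - 1),
#' reverses the disadvantage-oriented variables so that higher always means
#' better conditions, and averages across variables. The result is the
#' area's composite socioeconomic score.
#'
#' @param ses data frame with one row per area containing the SES columns.
#' @param variables columns to combine.
#' @param reversed subset of `variables` for which higher raw values mean
#'   worse conditions (negated after standardization).
#' @return Numeric vector of composite scores (mean 0 across areas).
#' @export
composite_z <- function(ses,
                        variables = c("water_access", "overcrowding",
                                      "school_attendance", "high_school",
                                      "unemployment"),
                        reversed = c("overcrowding", "unemployment")) {
  stopifnot(all(variables %in% names(ses)),
            all(reversed %in% variables))
  if (nrow(ses) < 2L) stop("need at least 2 areas")
  Z <- vapply(variables, function(v) {
    x <- ses[[v]]
    if (stats::sd(x) == 0) stop("zero-variance variable: ", v)
    z <- as.numeric(scale(x))
    if (v %in% reversed) -z else z
  }, numeric(nrow(ses)))
  rowMeans(Z)
}

#' Gap statistics of area-level life expectancy
#'
#' The P90 - P10 gap (percentiles by linear interpolation of order
#' statistics) and the max - min range of point-estimate LE across areas.
#'
#' @param le_points numeric vector of per-area life expectancies (>= 2).
#' @return Named numeric vector `c(p90_p10 = ..., range = ...)`, in years.
#' @export
gap_stats <- function(le_points) {
  if (length(le_points) < 2L) stop("need at least 2 areas")
  q <- stats::quantile(le_points, probs = c(0.1, 0.9), type = 7,
                       names = FALSE)
  c(p90_p10 = q[2] - q[1], range = max(le_points) - min(le_points))
}

#' Slope index of inequality for one posterior draw
#'
#' Ordinary least squares of per-area LE on the decile score (unweighted,
#' no spatial term): the slope is the modeled LE difference between areas in
#' the top and bottom decile. Returns the classical OLS standard error.
#'
#' @param le_draw numeric vector of per-area LE for one posterior draw.
#' @param score decile scores from [decile_score], same areas in the same
#'   order.
#' @return Named vector `c(coef = slope, se = standard error)`.
#' @export
sii_per_draw <- function(le_draw, score) {
  n <- length(le_draw)
  stopifnot(length(score) == n, n >= 3L)
  sxx <- sum((score - mean(score))^2)
  if (sxx == 0) stop("decile score is constant")
  slope <- sum((score - mean(score)) * (le_draw - mean(le_draw))) / sxx
  intercept <- mean(le_draw) - slope * mean(score)
  rss <- sum((le_draw - intercept - slope * score)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  c(coef = slope, se = se)
}

#' Pool per-draw regression estimates with Rubin's formula
#'
#' Across m repeated analyses (one per posterior draw) with estimates
#' `coefs` and standard errors `ses`: the pooled estimate is the mean of the
#' coefficients, the within variance U is the mean squared SE, the between
#' variance B is the sample variance of the coefficients, and the total
#' variance is `T = U + (1 + 1/m) B`. The confidence interval uses the
#' normal quantile by default or the Barnard-Rubin degrees-of-freedom
#' adjustment `nu = (m - 1) (1 + U / ((1 + 1/m) B))^2` with a t quantile.
#'
#' @param coefs,ses numeric vectors of per-draw estimates and standard
#'   errors (m >= 2).
#' @param conf confidence level (default 0.95).
#' @param df_adjust use the Barnard-Rubin t interval instead of normal.
#' @return One-row data frame of class `sii_result`: `coef, se, ci_low,
#'   ci_high, m, within_var, between_var, total_var`.
#' @export
rubin_pool <- function(coefs, ses, conf = 0.95, df_adjust = FALSE) {
  m <- length(coefs)
  if (m < 2L) stop("need at least 2 draws to pool")
  stopifnot(length(ses) == m)
  pooled <- mean(coefs)
  U <- mean(ses^2)
  B <- stats::var(coefs)
  Tv <- U + (1 + 1 / m) * B
  crit <- if (df_adjust && B > 0) {
    nu <- (m - 1) * (1 + U / ((1 + 1 / m) * B))^2
    stats::qt(1 - (1 - conf) / 2, df = nu)
  } else {
    stats::qnorm(1 - (1 - conf) / 2)
  }
  structure(
    data.frame(coef = pooled, se = sqrt(Tv),
               ci_low = pooled - crit * sqrt(Tv),
               ci_high = pooled + crit * sqrt(Tv),
               m = m, within_var = U, between_var = B, total_var = Tv),
    class = c("sii_result", "data.frame"))
}

#' Slope index of inequality over all draws, variables and sexes
#'
#' For each SES variable (and the composite score), converts the variable to
#' decile scores, regresses every posterior draw's per-area LE on the score
#' (univariately, per sex), and pools the 2000-odd slopes with Rubin's
#' formula. Decile cut points are computed once on the pooled area set (SES
#' does not vary by sex).
#'
#' @param le_draws long data frame `draw, area, sex, age, le` (from
#'   [le_draws] or read from disk).
#' @param ses data frame with column `area` and the SES variables.
#' @param variables SES columns to analyze; the composite score is added as
#'   `composite_z` unless `add_composite = FALSE`.
#' @param index_age LE index age to analyze (default 0, LE at birth).
#' @param add_composite include the composite Z-score as a variable.
#' @param conf,df_adjust passed to [rubin_pool].
#' @return Data frame: one row per (variable, sex) with the pooled SII and
#'   its confidence interval.
#' @export
sii_analysis <- function(le_draws, ses,
                         variables = c("water_access", "overcrowding",
                                       "school_attendance", "high_school",
                                       "unemployment"),
                         index_age = 0L, add_composite = TRUE,
                         conf = 0.95, df_adjust = FALSE) {
  stopifnot(all(c("draw", "area", "sex", "age", "le") %in% names(le_draws)),
            "area" %in% names(ses))
  d <- le_draws[le_draws$age == index_age, ]
  if (nrow(d) == 0L) stop("no draws at index age ", index_age)
  vars <- ses[match(sort(unique(d$area)), ses$area), , drop = FALSE]
  if (anyNA(vars$area)) stop("areas in draws missing from the SES table")
  work <- vars[variables]
  if (add_composite)
    work$composite_z <- composite_z(ses, variables = variables)[
      match(vars$area, ses$area)]
  out <- NULL
  for (s in sort(unique(d$sex))) {
    ds <- d[d$sex == s, ]
    le_mat <- with(ds, tapply(le, list(draw, area), identity))
    le_mat <- le_mat[, vars$area, drop = FALSE]
    for (v in names(work)) {
      score <- decile_score(work[[v]])
      fits <- apply(le_mat, 1L, sii_per_draw, score = score)
      pooled <- rubin_pool(fits["coef", ], fits["se", ],
                           conf = conf, df_adjust = df_adjust)
      out <- rbind(out, cbind(data.frame(variable = v, sex = s,
                                         stringsAsFactors = FALSE), pooled))
    }
  }
  rownames(out) <- NULL
  out
}
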