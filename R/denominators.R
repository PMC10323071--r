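#' Census proportion of each area within its higher-level unit
#'
#' For every (age, sex) stratum, the share of the unit's census population
#' living in each area: `share[a,x,s] = census[a,x,s] / sum over the unit`.
#' Strata whose unit total is zero get share 0 and are flagged.
#'
#' @param census data frame `area, age, sex, count`.
#' @param units data frame `area, unit` mapping every area to exactly one
#'   unit.
#' @return Data frame `area, unit, age, sex, share, zero_unit` where shares
#'   within each (unit, age, sex) sum to 1 (or 0 for flagged strata).
#' @export
census_share <- function(census, units) {
  stopifnot(all(c("area", "age", "sex", "count") %in% names(census)),
            all(c("area", "unit") %in% names(units)))
  if (anyDuplicated(units$area)) stop("an area maps to more than one unit")
  miss <- setdiff(unique(census$area), units$area)
  if (length(miss))
    stop("areas missing from the unit mapping: ", paste(miss, collapse = ", "))
  x <- census
  x$unit <- units$unit[match(x$area, units$area)]
  tot <- ave(x$count, x$unit, x$age, x$sex, FUN = sum)
  x$share <- ifelse(tot > 0, x$count / tot, 0)
  x$zero_unit <- tot == 0
  x[c("area", "unit", "age", "sex", "share", "zero_unit")]
}

#' Graduate grouped projections to single ages per unit
#'
#' Runs the PCLM once per (unit, sex, period) on the 5-year band totals,
#' with open-ended terminal ages that may differ by sex, selecting lambda by
#' AIC unless given. Band totals are exactly rescaled to the projections.
#'
#' @param projections data frame `unit, age_band or band_lower, sex, period,
#'   count`.
#' @param open_age named vector: open-ended maximum age per sex.
#' @param lambda fixed smoothing weight, or `NULL` to select per problem.
#' @param lambda_grid AIC grid used when `lambda` is NULL.
#' @return Data frame `unit, age, sex, period, count` at single ages.
#' @export
graduate_projections <- function(projections,
                                 open_age = c(F = 103L, M = 100L),
                                 lambda = NULL,
                                 lambda_grid = 10^seq(-2, 6, by = 1)) {
  p <- projections
  if (!"band_lower" %in% names(p)) {
    if (!"age_band" %in% names(p)) stop("need band_lower or age_band column")
    p$band_lower <- as.integer(sub("[-+].*$", "", p$age_band))
  }
  stopifnot(all(c("unit", "sex", "period", "count") %in% names(p)))
  keys <- interaction(p$unit, p$sex, p$period, drop = TRUE)
  out <- do.call(rbind, lapply(split(p, keys), function(d) {
    d <- d[order(d$band_lower), ]
    ages <- 0:open_age[[d$sex[1L]]]
    C <- band_composition(d$band_lower, ages)
    prob <- composite_link_problem(d$count, C)
    l <- if (is.null(lambda)) as.numeric(select_lambda(prob, lambda_grid)) else lambda
    mu <- pclm_graduate(prob, lambda = l, rescale = TRUE)
    data.frame(unit = d$unit[1L], age = ages, sex = d$sex[1L],
               period = d$period[1L], count = as.numeric(mu))
  }))
  rownames(out) <- NULL
  out
}

#' Allocate unit-level single-age projections to areas by shares
#'
#' `pop[a,x,s,t] = share[a,x,s] * projection[unit(a),x,s,t]`; unit totals
#' are conserved exactly within every stratum. Fractional populations are
#' retained (denominators feed rates, not counts).
#'
#' @param projection_single data frame `unit, age, sex, period, count` (from
#'   [graduate_projections]).
#' @param shares data frame from [census_share].
#' @return Data frame `area, unit, age, sex, period, count` of class
#'   `population_estimate`, with a `provenance` attribute.
#' @export
allocate <- function(projection_single, shares) {
  key_s <- paste(shares$unit, shares$age, shares$sex)
  key_p <- paste(projection_single$unit, projection_single$age,
                 projection_single$sex)
  missing_strata <- setdiff(unique(key_s), unique(key_p))
  if (length(missing_strata))
    stop("strata in shares missing from projections: ",
         paste(utils::head(missing_strata, 10), collapse = "; "))
  out <- merge(shares[c("area", "unit", "age", "sex", "share")],
               projection_single, by = c("unit", "age", "sex"))
  out$count <- out$share * out$count
  out <- out[order(out$period, out$sex, out$area, out$age),
             c("area", "unit", "age", "sex", "period", "count")]
  rownames(out) <- NULL
  structure(out, class = c("population_estimate", "data.frame"),
            provenance = "census-share allocation of graduated projections")
}

#' Person-year exposure over the analysis period
#'
#' Sums annual mid-year populations over the requested periods (the default
#' convention for a pooled multi-year death count); alternatively uses a
#' single mid-period population multiplied by the number of years.
#'
#' @param pop a [allocate] result (or any data frame `area, age, sex,
#'   period, count`).
#' @param periods character vector of period labels to include.
#' @param method `"sum"` (default) adds the annual populations; `"midyear"`
#'   multiplies the single given period by `n_years`.
#' @param n_years used by `method = "midyear"`.
#' @return Data frame `area, age, sex, count` of person-years.
#' @export
build_exposure <- function(pop, periods, method = c("sum", "midyear"),
                           n_years = length(periods)) {
  method <- match.arg(method)
  have <- unique(pop$period)
  miss <- setdiff(periods, have)
  if (length(miss))
    stop("missing period(s): ", paste(miss, collapse = ", "))
  d <- pop[pop$period %in% periods, ]
  agg <- stats::aggregate(count ~ area + age + sex, data = d, FUN = sum)
  if (method == "midyear") {
    if (length(periods) != 1L)
      stop("midyear method expects exactly one period")
    agg$count <- agg$count * n_years
  }
  agg[order(agg$sex, agg$area, agg$age), c("area", "age", "sex", "count")]
}

#' Two-stage single-age denominator estimation
#'
#' The full correction chain for small-area denominators when single-age
#' populations exist only for a census year and projections exist only as
#' 5-year bands at a higher administrative level: (1) census proportions of
#' each area within its unit by single age and sex; (2) PCLM graduation of
#' the unit projections to single ages for the census and analysis periods;
#' (3) allocation of the graduated census-year projections by the census
#' proportions, whose within-unit proportions are then (4) applied to the
#' analysis-period projections; (5) person-year exposure as the sum over the
#' analysis years.
#'
#' @param census data frame `area, age, sex, count` (census year).
#' @param projections grouped projections `unit, age_band, sex, period,
#'   count`.
#' @param units data frame `area, unit`.
#' @param census_period,analysis_periods period labels in `projections`.
#' @inheritParams graduate_projections
#' @inheritParams build_exposure
#' @return List with `population` (per period), `exposure` (person-years
#'   `area, age, sex, count`), `shares`, and `projections_single`.
#' @export
estimate_denominators <- function(census, projections, units,
                                  census_period = "2010",
                                  analysis_periods = c("2015", "2016", "2017"),
                                  open_age = c(F = 103L, M = 100L),
                                  lambda = NULL,
                                  lambda_grid = 10^seq(-2, 6, by = 1),
                                  method = c("sum", "midyear")) {
  method <- match.arg(method)
  shares0 <- census_share(census, units)
  proj_single <- graduate_projections(projections, open_age = open_age,
                                      lambda = lambda,
                                      lambda_grid = lambda_grid)
  corrected <- allocate(proj_single[proj_single$period == census_period, ],
                        shares0)
  # proportions of the corrected census-year counts within each unit;
  # re-derived from the corrected counts (they coincide with the census
  # shares whenever the unit scaling is uniform, but the chain keeps the
  # stage explicit)
  shares1 <- census_share(corrected[c("area", "age", "sex", "count")], units)
  pop <- allocate(proj_single[proj_single$period %in% analysis_periods, ],
                  shares1)
  exposure <- if (method == "sum") {
    build_exposure(pop, analysis_periods, method = "sum")
  } else {
    mid <- analysis_periods[ceiling(length(analysis_periods) / 2)]
    build_exposure(pop, mid, method = "midyear",
                   n_years = length(analysis_periods))
  }
  list(population = pop, exposure = exposure, shares = shares1,
       projections_single = proj_single)
}
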