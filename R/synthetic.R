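#' Rook adjacency of a rectangular lattice
#'
#' Areas are laid out row-major on an `nrow x ncol` grid; horizontally or
#' vertically adjacent cells are neighbors. This deterministic graph stands
#' in for polygon contiguity of real census geographies.
#'
#' @param nrow,ncol lattice dimensions.
#' @param ids area identifiers in row-major order (default `A001`, ...).
#' @return Data frame of undirected edges with columns `area_i, area_j`.
#' @export
lattice_adjacency <- function(nrow, ncol, ids = NULL) {
  n <- nrow * ncol
  if (is.null(ids)) ids <- sprintf("A%03d", seq_len(n))
  stopifnot(length(ids) == n)
  idx <- matrix(seq_len(n), nrow = nrow, ncol = ncol, byrow = TRUE)
  e <- rbind(
    cbind(as.vector(idx[, -ncol, drop = FALSE]), as.vector(idx[, -1, drop = FALSE])),
    cbind(as.vector(idx[-nrow, , drop = FALSE]), as.vector(idx[-1, , drop = FALSE]))
  )
  data.frame(area_i = ids[e[, 1]], area_j = ids[e[, 2]],
             stringsAsFactors = FALSE)
}

# Spatially autocorrelated standard-normal field on a lattice graph:
# z = (I - rho * Wn)^{-1} e with Wn the row-normalized adjacency, then
# standardized. rho in [0, 1) controls smoothness.
latent_field <- function(edges, ids, rho) {
  n <- length(ids)
  e <- rnorm(n)
  if (rho <= 0 || nrow(edges) == 0L) return(as.numeric(scale(e)))
  W <- matrix(0, n, n)
  i <- match(edges$area_i, ids); j <- match(edges$area_j, ids)
  W[cbind(i, j)] <- 1; W[cbind(j, i)] <- 1
  Wn <- W / pmax(rowSums(W), 1)
  z <- solve(diag(n) - rho * Wn, e)
  as.numeric(scale(z))
}

# Map a latent advantage score (higher = better) onto the five observed SES
# variables with marginals calibrated to plausible census spreads. Noise
# makes them noisy monotone transforms; unemployment and overcrowding are
# oriented so that HIGHER raw values mean WORSE conditions.
ses_from_latent <- function(z, noise_sd = 0.3) {
  n <- length(z)
  e <- function() rnorm(n, sd = noise_sd)
  data.frame(
    water_access      = 93 + 7 * plogis(1.5 * z + e()),          # % ~93-100
    overcrowding      = 3 * plogis(-1.5 * z + e())^2,            # % ~0-3
    school_attendance = 85 + 14 * plogis(1.3 * z + e()),         # % ~85-99
    high_school       = 50 + 40 * plogis(1.2 * z + e()),         # % ~50-90
    unemployment      = 3 + 3 * plogis(-1.4 * z + e())           # % ~3-6
  )
}

# Stable-population age composition for a sex: survivorship from the true
# schedule discounted by growth rate r, normalized to sum to 1.
stable_age_structure <- function(log_std, r = 0.01) {
  m <- exp(log_std)
  x <- seq_along(m) - 1L
  lx <- c(1, exp(-cumsum(m[-length(m)])))
  w <- lx * exp(-r * x)
  w / sum(w)
}

#' Simulate a synthetic city with known mortality ground truth
#'
#' Generates the full data structure the pipeline consumes: areas on a
#' rectangular lattice nested in contiguous higher-level units, a spatially
#' autocorrelated latent socioeconomic field, per-area true spline offsets
#' from the sex-specific standard schedules (higher SES, lower mortality),
#' five observed SES variables, single-age census populations per area,
#' 5-year-grouped projections per unit for the census year and three
#' analysis years, and Poisson death counts over the pooled analysis period.
#'
#' True offsets are `alpha_a[k] = -ses_effect * z_a + noise_a[k]` with `z`
#' the latent SES field and spatially correlated knot-level noise, so higher
#' SES lowers log mortality at every age. Deaths are drawn as
#' `Poisson(exposure * m_a(x))` with
#' `log m_a(x) = log m_std(x) + B(x)' alpha_a` and exposure the sum of the
#' three annual populations (person-years of the pooled period).
#'
#' @param n_areas number of areas (>= 4); must factor into a lattice, or
#'   pass `dims`.
#' @param n_units number of higher-level units (contiguous column bands).
#' @param ses_effect slope of the true offsets on the latent SES score (log
#'   mortality per SD of SES); 0.15 spreads true LE at birth over roughly
#'   6-9 years across areas, comparable to within-city gaps in large
#'   unequal cities.
#' @param spatial_rho smoothness of the latent fields in [0, 1).
#' @param seed integer RNG seed; identical seeds give identical cities.
#' @param dims optional `c(nrow, ncol)` lattice dimensions.
#' @param mean_pop mean annual population per area (both sexes).
#' @param open_age named vector of open-ended ages per sex.
#' @param knots knot ages of the offset basis.
#' @param offset_noise_sd sd of the spatially correlated knot-level noise.
#' @param growth_rate stable-population growth rate shaping the age pyramid.
#' @return An object of class `synthetic_city`; see Details. Key elements:
#'   `deaths`, `census`, `projections`, `ses`, `adjacency`, `units` (all in
#'   the pipeline's CSV schemas), `true_offsets`, `true_rates`, `true_le`,
#'   `exposure_true`, `schedules`, `latent_ses`.
#' @export
simulate_city <- function(n_areas = 100, n_units = 15, ses_effect = 0.15,
                          spatial_rho = 0.9, seed = 1L, dims = NULL,
                          mean_pop = 12000,
                          open_age = c(F = 103L, M = 100L),
                          knots = c(0, 1, 10, 20, 40, 70),
                          offset_noise_sd = 0.05,
                          growth_rate = 0.01) {
  if (n_areas < 4) stop("n_areas must be >= 4")
  if (n_units > n_areas) stop("n_units cannot exceed n_areas")
  if (is.null(dims)) {
    nr <- floor(sqrt(n_areas))
    while (nr > 1 && n_areas %% nr != 0) nr <- nr - 1
    dims <- c(nr, n_areas / nr)
  }
  if (prod(dims) != n_areas)
    stop(sprintf("lattice dimensions %dx%d incompatible with %d areas",
                 dims[1], dims[2], n_areas))
  set.seed(as.integer(seed))

  ids <- sprintf("A%03d", seq_len(n_areas))
  adjacency <- lattice_adjacency(dims[1], dims[2], ids)
  # contiguous blocks along the row-major lattice order as higher-level units
  unit_of <- ceiling(seq_len(n_areas) / (n_areas / n_units))
  units <- data.frame(area = ids,
                      unit = sprintf("U%02d", pmin(unit_of, n_units)),
                      stringsAsFactors = FALSE)

  z <- latent_field(adjacency, ids, spatial_rho)
  ses <- cbind(data.frame(area = ids, stringsAsFactors = FALSE),
               ses_from_latent(z))

  sexes <- c("F", "M")
  schedules <- lapply(stats::setNames(sexes, sexes), function(s) {
    p <- default_schedule_params(s)
    do.call(make_standard_schedule, c(list(ages = 0:open_age[[s]]), p))
  })

  K <- length(knots)
  true_offsets <- lapply(stats::setNames(sexes, sexes), function(s) {
    noise <- vapply(seq_len(K), function(k)
      offset_noise_sd * latent_field(adjacency, ids, spatial_rho),
      numeric(n_areas))
    a <- -ses_effect * z + noise
    dimnames(a) <- list(ids, paste0("k", knots))
    a
  })

  analysis_years <- c("2015", "2016", "2017")
  census_year <- "2010"
  area_size <- exp(rnorm(n_areas, sd = 0.25))
  area_size <- area_size / mean(area_size)

  census <- NULL; exposure_true <- NULL
  true_rates <- list(); proj_single <- NULL
  for (s in sexes) {
    ages <- 0:open_age[[s]]
    struct <- stable_age_structure(schedules[[s]]$log_rate, r = growth_rate)
    B <- build_basis(ages, knots)
    m_true <- exp(sweep(true_offsets[[s]] %*% t(B), 2,
                        schedules[[s]]$log_rate, `+`))
    dimnames(m_true) <- list(ids, ages)
    true_rates[[s]] <- m_true

    # annual per-area population (sex share 50%), smooth across ages
    base_pop <- outer(area_size * mean_pop / 2, struct)      # census year
    grow <- function(y) base_pop * (1 + growth_rate)^(as.integer(y) - 2010)
    census <- rbind(census, data.frame(
      area = rep(ids, times = length(ages)),
      age = rep(ages, each = n_areas), sex = s,
      count = round(as.vector(base_pop))))
    expo <- Reduce(`+`, lapply(analysis_years, grow))
    exposure_true <- rbind(exposure_true, data.frame(
      area = rep(ids, times = length(ages)),
      age = rep(ages, each = n_areas), sex = s,
      count = as.vector(expo)))

    for (y in c(census_year, analysis_years)) {
      pop_y <- grow(y)
      unit_pop <- rowsum(pop_y, units$unit)
      ps <- data.frame(
        unit = rep(rownames(unit_pop), times = length(ages)),
        age = rep(ages, each = nrow(unit_pop)), sex = s, period = y,
        count = as.vector(unit_pop))
      proj_single <- rbind(proj_single, ps)
    }
  }

  projections <- group_population(proj_single, width = 5)

  deaths <- NULL
  for (s in sexes) {
    expo <- exposure_true[exposure_true$sex == s, ]
    lam <- expo$count *
      true_rates[[s]][cbind(match(expo$area, ids), expo$age + 1L)]
    deaths <- rbind(deaths, data.frame(
      area = expo$area, age = expo$age, sex = s,
      deaths = rpois(nrow(expo), lam)))
  }

  true_le <- lapply(true_rates, le_from_rates)

  structure(list(
    areas = ids, adjacency = adjacency, units = units,
    latent_ses = stats::setNames(z, ids), ses = ses,
    schedules = schedules, knots = knots,
    true_offsets = true_offsets, true_rates = true_rates, true_le = true_le,
    census = census, projections = projections,
    exposure_true = exposure_true, deaths = deaths,
    seed = as.integer(seed), dims = dims,
    params = list(ses_effect = ses_effect, spatial_rho = spatial_rho,
                  mean_pop = mean_pop, open_age = open_age,
                  offset_noise_sd = offset_noise_sd,
                  growth_rate = growth_rate,
                  analysis_years = analysis_years,
                  census_year = census_year)
  ), class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> %d areas (%dx%d lattice), %d units, seed %d\n",
              length(x$areas), x$dims[1], x$dims[2],
              length(unique(x$units$unit)), x$seed))
  cat(sprintf("  total deaths %d; true e0 range F [%.1f, %.1f], M [%.1f, %.1f]\n",
              sum(x$deaths$deaths),
              min(x$true_le$F[, "e0"]), max(x$true_le$F[, "e0"]),
              min(x$true_le$M[, "e0"]), max(x$true_le$M[, "e0"])))
  invisible(x)
}

#' Group single-age counts into 5-year age bands
#'
#' Aggregates single-age counts into contiguous bands of the given width;
#' the final band is open-ended at the data's maximum age. Band labels are
#' `"0-4", "5-9", ..., "100+"`.
#'
#' @param pop_single data frame with columns `unit, age, sex, count` and
#'   optionally `period`.
#' @param width band width in years (default 5).
#' @return Data frame with columns `unit, age_band, band_lower, sex,
#'   (period,) count`.
#' @export
group_population <- function(pop_single, width = 5L) {
  stopifnot(all(c("unit", "age", "sex", "count") %in% names(pop_single)))
  if (min(pop_single$age) != 0L) stop("ages must start at 0")
  has_period <- "period" %in% names(pop_single)
  keys <- c("unit", "sex", if (has_period) "period")
  split_keys <- interaction(pop_single[keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(pop_single, split_keys), function(d) {
    top <- max(d$age)
    lower <- (d$age %/% width) * width
    open_lower <- (top %/% width) * width
    lower <- pmin(lower, open_lower)
    agg <- rowsum(d$count, lower)
    lo <- as.integer(rownames(agg))
    lab <- ifelse(lo == open_lower, paste0(lo, "+"),
                  paste0(lo, "-", lo + width - 1L))
    cbind(d[rep(1L, length(lo)), keys, drop = FALSE],
          data.frame(age_band = lab, band_lower = lo, count = as.vector(agg)))
  }))
  rownames(out) <- NULL
  cols <- c("unit", "age_band", "band_lower", "sex",
            if (has_period) "period", "count")
  out[order(out$unit, out$sex, out$band_lower), cols]
}
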