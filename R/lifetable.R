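#' Single-age period life table from central death rates
#'
#' Converts a vector of single-age central death rates m_x into a complete
#' life table with the usual columns: probabilities of death q_x, the average
#' fraction of the interval lived by those dying a_x, survivors l_x from a
#' radix of 100,000, deaths d_x, person-years L_x, remaining person-years T_x
#' and remaining life expectancy e_x. The terminal age is treated as an
#' open-ended interval closed with L = l / m (everyone alive at the open age
#' lives, on average, 1/m more years under a constant hazard).
#'
#' For closed ages x >= 1 the mid-interval convention a_x = 0.5 is used, so
#' q_x = m_x / (1 + (1 - a_x) m_x). Deaths in infancy are concentrated early
#' in the interval, so a_0 defaults to the separation approximation
#' a_0 = 0.07 + 1.7 m_0, capped to [0.01, 0.5]; pass a numeric `a0` (e.g. a
#' flat 0.1) to override.
#'
#' Rates extreme enough to push q_x above 1 can arise in the tails of MCMC
#' draws; such q_x are clipped to 1 with a warning rather than an error.
#'
#' @param mx numeric vector of central death rates by single age, all > 0.
#' @param age integer vector of ages, defaults to `0:(length(mx)-1)`.
#' @param a0 infant separation factor; `NULL` (default) applies the rule
#'   above, a number in (0, 1] fixes it.
#' @param radix survivors at age 0 (default 100,000).
#' @return A data frame of class `life_table` with columns
#'   `age, mx, ax, qx, lx, dx, Lx, Tx, ex`.
#' @examples
#' lt <- make_life_table(exp(make_standard_schedule(0:100)$log_rate))
#' lt$ex[1]   # life expectancy at birth
#' @export
make_life_table <- function(mx, age = seq_along(mx) - 1L, a0 = NULL,
                            radix = 1e5) {
  mx <- as.numeric(mx)
  n <- length(mx)
  if (n < 2L) stop("need at least two ages")
  if (any(!is.finite(mx)) || any(mx <= 0))
    stop("all death rates must be finite and > 0")
  if (length(age) != n) stop("age and mx lengths differ")

  ax <- rep(0.5, n)
  ax[1L] <- if (is.null(a0)) {
    min(max(0.07 + 1.7 * mx[1L], 0.01), 0.5)
  } else {
    stopifnot(is.numeric(a0), a0 > 0, a0 <= 1)
    a0
  }

  qx <- mx / (1 + (1 - ax) * mx)
  if (any(qx > 1)) {
    warning(sprintf("%d q_x value(s) > 1 clipped to 1", sum(qx > 1)))
    qx <- pmin(qx, 1)
  }
  qx[n] <- 1                       # open-ended terminal interval

  lx <- radix * cumprod(c(1, 1 - qx[-n]))
  dx <- lx * qx
  Lx <- lx - (1 - ax) * dx
  Lx[n] <- lx[n] / mx[n]           # L_omega = l_omega / m_omega
  Tx <- rev(cumsum(rev(Lx)))
  ex <- Tx / lx
  ex[lx == 0] <- 0

  structure(
    data.frame(age = as.integer(age), mx = mx, ax = ax, qx = qx,
               lx = lx, dx = dx, Lx = Lx, Tx = Tx, ex = ex),
    class = c("life_table", "data.frame")
  )
}

#' Remaining life expectancy at a given age
#'
#' @param table a [make_life_table] result.
#' @param age integer age present in the table.
#' @return e_age = T_age / l_age, in years.
#' @export
le_at <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  i <- match(age, table$age)
  if (is.na(i)) stop(sprintf("age %s is beyond the table's open age", age))
  table$ex[i]
}

#' Posterior summaries of life expectancy over MCMC draws
#'
#' Reduces per-draw life expectancies to the posterior median (point
#' estimate) and the 2.5th / 97.5th percentile credible bounds, per
#' area, sex and index age. Percentiles use linear interpolation between
#' order statistics (R quantile type 7).
#'
#' @param le_draws data frame with columns `draw, area, sex, age, le`
#'   (one row per posterior draw per area/sex/index age).
#' @param probs lower/upper credible-interval percentiles.
#' @return Data frame with columns `area, sex, age, le, le_lower, le_upper,
#'   n_draws`, the point estimate being the posterior median.
#' @export
summarize_draws <- function(le_draws, probs = c(0.025, 0.975)) {
  need <- c("draw", "area", "sex", "age", "le")
  if (!all(need %in% names(le_draws)))
    stop("le_draws must have columns ", paste(need, collapse = ", "))
  stopifnot(length(probs) == 2L, probs[1] < probs[2])
  key <- interaction(le_draws$area, le_draws$sex, le_draws$age, drop = TRUE)
  out <- do.call(rbind, lapply(split(le_draws, key), function(d) {
    q <- stats::quantile(d$le, probs = probs, type = 7, names = FALSE)
    data.frame(area = d$area[1L], sex = d$sex[1L], age = d$age[1L],
               le = stats::median(d$le), le_lower = q[1L], le_upper = q[2L],
               n_draws = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$area, out$sex, out$age), , drop = FALSE]
}

# Vectorized life-expectancy engine: same arithmetic as make_life_table but
# computed column-by-column across all rows of an areas x ages rate matrix
# at once (the per-draw hot path). q_x > 1 is clipped silently here; the
# scalar constructor is the place that warns.
le_matrix <- function(m, index_ages, a0 = NULL) {
  nA <- nrow(m); nX <- ncol(m)
  a0v <- if (is.null(a0)) pmin(pmax(0.07 + 1.7 * m[, 1L], 0.01), 0.5) else a0
  qx <- m / (1 + 0.5 * m)
  qx[, 1L] <- pmin(m[, 1L] / (1 + (1 - a0v) * m[, 1L]), 1)
  qx <- pmin(qx, 1)
  qx[, nX] <- 1
  lx <- matrix(1, nA, nX)
  for (x in 2:nX) lx[, x] <- lx[, x - 1L] * (1 - qx[, x - 1L])
  dx <- lx * qx
  Lx <- lx - 0.5 * dx
  Lx[, 1L] <- lx[, 1L] - (1 - a0v) * dx[, 1L]
  Lx[, nX] <- lx[, nX] / m[, nX]
  Tx <- Lx
  for (x in (nX - 1L):1L) Tx[, x] <- Tx[, x + 1L] + Lx[, x]
  ex <- Tx / lx
  ex[lx == 0] <- 0
  ex[, index_ages + 1L, drop = FALSE]
}

#' Life expectancy at index ages for every area from a matrix of rates
#'
#' Helper used by both the generator (ground truth) and the posterior
#' pipeline: given an areas x ages matrix of central death rates, builds one
#' life table per row and extracts e_x at the requested index ages.
#'
#' @param rates matrix (areas x ages) of central death rates.
#' @param index_ages ages at which to report remaining life expectancy.
#' @param a0 passed to [make_life_table].
#' @return matrix (areas x index ages) of life expectancies, with
#'   `rownames(rates)` preserved.
#' @export
le_from_rates <- function(rates, index_ages = c(0L, 20L, 40L, 60L),
                          a0 = NULL) {
  stopifnot(is.matrix(rates))
  ages <- seq_len(ncol(rates)) - 1L
  if (!all(index_ages %in% ages)) stop("index age beyond the rate schedule")
  out <- matrix(NA_real_, nrow(rates), length(index_ages),
                dimnames = list(rownames(rates), paste0("e", index_ages)))
  for (a in seq_len(nrow(rates))) {
    lt <- make_life_table(rates[a, ], age = ages, a0 = a0)
    out[a, ] <- lt$ex[match(index_ages, lt$age)]
  }
  out
}
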