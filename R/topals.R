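#' Linear-spline (tent) basis for TOPALS offsets
#'
#' TOPALS models area log mortality as the standard schedule plus `B %*%
#' alpha`, where B holds piecewise-linear "tent" functions anchored at a
#' small set of knot ages. Each basis column equals 1 at its knot, decays
#' linearly to 0 at the adjacent knots, and ages beyond the last knot carry
#' the last knot's value 1 (a constant extension), so every row sums to 1.
#'
#' @param ages integer grid of single ages.
#' @param knots strictly increasing knot ages within the age range; the
#'   canonical layout `c(0, 1, 10, 20, 40, 70)` is the default.
#' @return An `n_ages x n_knots` matrix of class `topals_basis` with
#'   attribute `knots`.
#' @export
build_basis <- function(ages, knots = c(0, 1, 10, 20, 40, 70)) {
  knots <- as.numeric(knots)
  if (length(knots) < 2L) stop("need at least 2 knots")
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing")
  if (min(knots) < min(ages) || max(knots) > max(ages))
    stop("knots must lie within the age range")
  K <- length(knots)
  B <- matrix(0, length(ages), K)
  for (k in seq_len(K)) {
    left <- if (k > 1L) knots[k] - knots[k - 1L] else Inf
    right <- if (k < K) knots[k + 1L] - knots[k] else Inf
    d <- ages - knots[k]
    v <- ifelse(d < 0, pmax(0, 1 + d / left), pmax(0, 1 - d / right))
    B[, k] <- v
  }
  B[ages >= knots[K], ] <- 0
  B[ages >= knots[K], K] <- 1       # constant extension past the last knot
  dimnames(B) <- list(ages, paste0("k", knots))
  structure(B, knots = knots, class = c("topals_basis", "matrix", "array"))
}

#' Smooth city-level death rates into a TOPALS standard schedule
#'
#' Raw city-level log rates are unstable at ages with few deaths, so the
#' standard schedule is a LOESS (local quadratic) regression of the empirical
#' log rates `log((D + 0.5) / N)` on age; the 0.5 offset keeps zero-death
#' ages finite. The smoothed curve is the baseline the spatial model offsets
#' from.
#'
#' By default the local regression runs on the `log(1 + age)` scale: log
#' mortality falls steeply and near-exponentially through infancy, and a
#' local quadratic on the linear age scale is badly biased around the
#' childhood trough (the fit at ages 5-12 is dragged up by the infant
#' ages inside its window); the log-age transform spreads the infant
#' decline over a comparable distance and removes that bias. Observations
#' are precision-weighted by death counts (`deaths + 0.5`), the sampling
#' variance of an empirical log rate being roughly the reciprocal of its
#' death count. With `age_scale = "linear"` and uniform weights the
#' smoother is a plain local quadratic in age and reproduces exactly any
#' input that is polynomial in age of degree <= 2.
#'
#' @param city_deaths,city_exposure numeric vectors by single age (city
#'   totals for one sex); exposure must be > 0 at every age.
#' @param span LOESS span in (0, 1].
#' @param ages integer ages, defaults to `0:(length-1)`.
#' @param weights `"deaths"` (precision weights, default) or `"uniform"`.
#' @param age_scale regressor scale, `"log"` (default) or `"linear"`.
#' @param predict_ages ages at which the smoothed schedule is returned
#'   (default the fitted ages); trailing ages beyond the data, e.g. an open
#'   tail with no estimated exposure, are extrapolated from the local fit.
#' @return A [standard_schedule].
#' @export
smooth_standard <- function(city_deaths, city_exposure, span = 0.3,
                            ages = seq_along(city_deaths) - 1L,
                            weights = c("deaths", "uniform"),
                            age_scale = c("log", "linear"),
                            predict_ages = ages) {
  weights <- match.arg(weights)
  age_scale <- match.arg(age_scale)
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("span must be in (0, 1]")
  stopifnot(length(city_deaths) == length(city_exposure))
  if (any(city_exposure <= 0))
    stop("city exposure must be positive at every age")
  xf <- if (age_scale == "log") function(a) log(1 + a) else as.numeric
  y <- log((city_deaths + 0.5) / city_exposure)
  w <- if (weights == "deaths") city_deaths + 0.5 else rep(1, length(y))
  fit <- stats::loess(y ~ x, data = data.frame(x = xf(ages), y = y),
                      span = span, degree = 2, weights = w,
                      control = stats::loess.control(surface = "direct"))
  standard_schedule(predict_ages,
                    stats::predict(fit, newdata = data.frame(x = xf(predict_ages))),
                    smoothing_span = span)
}

#' Assemble a spatial TOPALS Poisson model
#'
#' Bundles deaths, person-year exposures, the standard schedule, the spline
#' basis and the area adjacency into the model object the sampler consumes.
#' The likelihood is `D[a,x] ~ Poisson(N[a,x] * m_a(x))` with
#' `log m_a(x) = log m_std(x) + B[x,] %*% alpha_a`; strata with zero exposure
#' are excluded from the likelihood. The prior on the offset vectors is an
#' intrinsic-CAR-style pairwise difference penalty across adjacent areas
#' (precision `tau_spatial`) plus a first-difference shape penalty within
#' each area's offset vector (precision `tau_shape`).
#'
#' @param deaths,exposure data frames with columns `area, age, (deaths|count)`
#'   for a single sex, or areas x ages matrices with area rownames.
#' @param std a [standard_schedule] covering the same ages.
#' @param adjacency data frame of undirected edges with columns
#'   `area_i, area_j`.
#' @param knots knot ages for [build_basis].
#' @param tau_spatial,tau_shape fixed prior precisions (defaults 5 and 2).
#' @return An object of class `topals_model`.
#' @export
topals_model <- function(deaths, exposure, std, adjacency,
                         knots = c(0, 1, 10, 20, 40, 70),
                         tau_spatial = 5, tau_shape = 2) {
  stopifnot(inherits(std, "standard_schedule"))
  D <- as_area_age_matrix(deaths, value_col = c("deaths", "count"))
  N <- as_area_age_matrix(exposure, value_col = c("count", "exposure"))
  if (!identical(dim(D), dim(N)) || !identical(rownames(D), rownames(N)))
    stop("deaths and exposure must cover the same areas and ages")
  if (ncol(D) != length(std$age))
    stop("schedule ages do not match the data's age range")
  areas <- rownames(D)
  W <- edge_index_matrix(adjacency, areas)
  B <- build_basis(std$age, knots = knots)
  dropped <- sum(D[N <= 0])
  if (dropped > 0)
    warning(sprintf(
      "%d death(s) in strata with zero exposure excluded from the likelihood",
      dropped))
  structure(list(areas = areas, ages = std$age, D = D, N = N,
                 log_std = std$log_rate, basis = B, edges = W,
                 tau_spatial = tau_spatial, tau_shape = tau_shape),
            class = "topals_model")
}

# deaths/exposure in long or matrix form -> areas x ages matrix
as_area_age_matrix <- function(x, value_col) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("matrix input needs area rownames")
    return(x)
  }
  stopifnot(is.data.frame(x))
  vc <- intersect(value_col, names(x))[1]
  if (is.na(vc)) stop("no value column (", paste(value_col, collapse = "/"),
                      ") in data frame")
  areas <- sort(unique(as.character(x$area)))
  ages <- sort(unique(x$age))
  if (!identical(as.integer(ages), seq.int(0L, length(ages) - 1L)))
    stop("ages must be contiguous single years from 0")
  M <- matrix(0, length(areas), length(ages),
              dimnames = list(areas, ages))
  M[cbind(match(as.character(x$area), areas), match(x$age, ages))] <- x[[vc]]
  M
}

# adjacency edge data frame -> 2-column integer matrix of area indices
edge_index_matrix <- function(adjacency, areas) {
  stopifnot(all(c("area_i", "area_j") %in% names(adjacency)))
  i <- match(as.character(adjacency$area_i), areas)
  j <- match(as.character(adjacency$area_j), areas)
  keep <- !is.na(i) & !is.na(j)
  e <- cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep]))
  e <- unique(e[e[, 1] != e[, 2], , drop = FALSE])
  if (nrow(e) == 0L && length(areas) > 1L)
    warning("adjacency has no edges among the model's areas")
  e
}

#' Unnormalized log posterior of the TOPALS model
#'
#' Poisson log likelihood (constants dropped) minus the spatial and shape
#' quadratic penalties:
#' `sum(D*log(N*m) - N*m) - tau_spatial/2 * sum_edges ||alpha_a - alpha_b||^2
#'  - tau_shape/2 * sum_a sum_k (alpha_a[k+1] - alpha_a[k])^2`.
#'
#' @param model a [topals_model].
#' @param alpha matrix (areas x knots) of spline offsets.
#' @return A single finite number.
#' @export
log_posterior <- function(model, alpha) {
  stopifnot(inherits(model, "topals_model"))
  if (!all(is.finite(alpha))) stop("alpha must be finite")
  alpha <- matrix(alpha, nrow = length(model$areas))
  eta <- sweep(alpha %*% t(model$basis), 2, model$log_std, `+`)
  lam <- model$N * exp(eta)
  ok <- model$N > 0
  ll <- sum(model$D[ok] * log(lam[ok]) - lam[ok])
  pen_sp <- 0
  if (nrow(model$edges) > 0) {
    dif <- alpha[model$edges[, 1], , drop = FALSE] -
      alpha[model$edges[, 2], , drop = FALSE]
    pen_sp <- sum(dif^2)
  }
  pen_sh <- sum(t(diff(t(alpha)))^2)
  ll - model$tau_spatial / 2 * pen_sp - model$tau_shape / 2 * pen_sh
}

#' Sample the TOPALS posterior by adaptive blockwise random-walk Metropolis
#'
#' Each iteration updates every area's offset vector as one block with a
#' spherical Gaussian proposal whose scale adapts toward a 0.3 acceptance
#' rate during burn-in (Robbins-Monro on the log scale) and is frozen
#' afterwards. Draws after burn-in are thinned by `thin`. With
#' `sample_tau = TRUE` the two prior precisions get Gamma(2, 0.5) hyperpriors
#' and are refreshed by Gibbs steps from their conditional Gamma
#' distributions.
#'
#' Reproducibility: the sampler uses R's RNG stream, so `set.seed(seed)` (done
#' internally from the `seed` argument) makes chains identical.
#'
#' @param model a [topals_model].
#' @param iterations,burn_in,thin MCMC schedule; `(iterations - burn_in) /
#'   thin` draws are retained. The analysis-scale schedule in the source
#'   study is 100,000 / 80,000 / 10 (2000 draws); the default here is a
#'   scaled-down 10,000 / 8,000 / 1 (also 2000 draws).
#' @param seed integer seed.
#' @param init_scale initial proposal standard deviation.
#' @param sample_tau sample the prior precisions instead of fixing them.
#' @return An object of class `topals_fit`: list with `alpha` (array
#'   n_draws x areas x knots), `acceptance` per area, `tau_draws` (or NULL),
#'   and `meta` (schedule, seed, dimensions).
#' @export
run_mcmc <- function(model, iterations = 10000L, burn_in = 8000L, thin = 1L,
                     seed = 1L, init_scale = 0.1, sample_tau = FALSE) {
  stopifnot(inherits(model, "topals_model"))
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  if (thin < 1L) stop("thin must be >= 1")
  n_draws <- (iterations - burn_in) %/% thin
  if (n_draws < 1L) stop("schedule retains no draws")

  set.seed(as.integer(seed))
  K <- ncol(model$basis)
  nA <- length(model$areas)
  res <- topals_mcmc_cpp(model$D, model$N, model$basis, model$log_std,
                         model$edges, model$tau_spatial, model$tau_shape,
                         iterations, burn_in, thin, init_scale, sample_tau)
  if (!res$finite)
    stop("sampler diverged: non-finite posterior encountered; state dumped in fit$last_alpha")
  acc <- as.numeric(res$acceptance)
  if (any(acc < 0.05) || any(acc > 0.95))
    warning(sprintf("post-adaptation acceptance outside [0.05, 0.95] for %d area(s)",
                    sum(acc < 0.05 | acc > 0.95)))
  alpha <- array(res$alpha, dim = c(n_draws, nA, K),
                 dimnames = list(NULL, model$areas, colnames(model$basis)))
  structure(list(
    alpha = alpha,
    acceptance = stats::setNames(acc, model$areas),
    tau_draws = if (sample_tau) {
      m <- matrix(res$tau, ncol = 2,
                  dimnames = list(NULL, c("tau_spatial", "tau_shape")))
      m
    },
    last_alpha = matrix(res$last_alpha, nA, K),
    meta = list(iterations = iterations, burn_in = burn_in, thin = thin,
                seed = as.integer(seed), n_draws = n_draws,
                n_areas = nA, n_knots = K, sample_tau = sample_tau)
  ), class = "topals_fit")
}

#' @export
print.topals_fit <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<topals_fit> %d draws (%d iter, %d burn-in, thin %d), %d areas x %d knots\n",
    m$n_draws, m$iterations, m$burn_in, m$thin, m$n_areas, m$n_knots))
  cat(sprintf("  acceptance: %.2f-%.2f (median %.2f)\n",
              min(x$acceptance), max(x$acceptance),
              stats::median(x$acceptance)))
  invisible(x)
}

#' Mortality-rate draws from offset draws
#'
#' Maps offset draws through the relational model:
#' `m_a(x) = exp(log m_std(x) + B %*% alpha_a)` per retained draw.
#'
#' @param model a [topals_model].
#' @param fit a [run_mcmc] result (or an n_draws x areas x knots array).
#' @param draws optional subset of draw indices.
#' @return Array `n_draws x areas x ages` of strictly positive rates.
#' @export
rate_draws <- function(model, fit, draws = NULL) {
  alpha <- if (inherits(fit, "topals_fit")) fit$alpha else fit
  stopifnot(length(dim(alpha)) == 3L)
  if (is.null(draws)) draws <- seq_len(dim(alpha)[1L])
  nA <- dim(alpha)[2L]
  out <- array(NA_real_, c(length(draws), nA, length(model$ages)),
               dimnames = list(NULL, dimnames(alpha)[[2L]], model$ages))
  tB <- t(model$basis)
  for (i in seq_along(draws)) {
    eta <- alpha[draws[i], , , drop = TRUE]
    eta <- matrix(eta, nrow = nA)
    out[i, , ] <- exp(sweep(eta %*% tB, 2, model$log_std, `+`))
  }
  out
}

#' Per-draw life expectancies from a fitted TOPALS model
#'
#' Builds one life table per retained draw per area and extracts life
#' expectancy at the index ages, without materializing the full rate array.
#'
#' @inheritParams rate_draws
#' @param index_ages ages at which to report LE.
#' @param sex label attached to the output rows.
#' @param a0 infant separation factor passed to [make_life_table].
#' @return Long data frame `draw, area, sex, age, le` suitable for
#'   [summarize_draws] and [sii_analysis].
#' @export
le_draws <- function(model, fit, index_ages = c(0L, 20L, 40L, 60L),
                     sex = "F", a0 = NULL) {
  alpha <- if (inherits(fit, "topals_fit")) fit$alpha else fit
  nd <- dim(alpha)[1L]; nA <- dim(alpha)[2L]
  tB <- t(model$basis)
  res <- array(NA_real_, c(nd, nA, length(index_ages)))
  for (i in seq_len(nd)) {
    eta <- matrix(alpha[i, , ], nrow = nA) %*% tB
    m <- exp(sweep(eta, 2, model$log_std, `+`))
    res[i, , ] <- le_matrix(m, index_ages = as.integer(index_ages), a0 = a0)
  }
  data.frame(
    draw = rep(seq_len(nd), times = nA * length(index_ages)),
    area = rep(rep(model$areas, each = nd), times = length(index_ages)),
    sex = sex,
    age = rep(as.integer(index_ages), each = nd * nA),
    le = as.vector(res)
  )
}

#' Split-half convergence diagnostics for retained draws
#'
#' Potential scale reduction (split-Rhat) and a crude effective sample size
#' from lag-autocorrelations, computed per offset component over the
#' retained draws.
#'
#' @param fit a [run_mcmc] result.
#' @return Data frame with one row per (area, knot): `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(fit) {
  alpha <- fit$alpha
  nd <- dim(alpha)[1L]
  half <- nd %/% 2L
  out <- expand.grid(area = dimnames(alpha)[[2L]],
                     knot = dimnames(alpha)[[3L]],
                     stringsAsFactors = FALSE)
  out$rhat <- NA_real_; out$ess <- NA_real_
  r <- 1L
  for (k in seq_len(dim(alpha)[3L])) for (a in seq_len(dim(alpha)[2L])) {
    x <- alpha[, a, k]
    x1 <- x[seq_len(half)]; x2 <- x[(nd - half + 1L):nd]
    W <- (stats::var(x1) + stats::var(x2)) / 2
    Bv <- half * (mean(x1) - mean(x2))^2 / 2
    idx <- which(out$area == dimnames(alpha)[[2L]][a] &
                   out$knot == dimnames(alpha)[[3L]][k])
    out$rhat[idx] <- if (W > 0) sqrt((W * (half - 1) / half + Bv / half * 2) / W) else NA_real_
    ac <- stats::acf(x, lag.max = min(100L, nd - 2L), plot = FALSE)$acf[-1L]
    pos <- which(ac < 0.05)
    cut <- if (length(pos)) pos[1L] - 1L else length(ac)
    out$ess[idx] <- nd / (1 + 2 * sum(ac[seq_len(cut)]))
    r <- r + 1L
  }
  out
}
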