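test_that("tent basis is 1 at its knot, 0.5 midway, rows sum to 1", {
  ages <- 0:100
  B <- build_basis(ages, knots = c(0, 1, 10, 20, 40, 70))
  expect_equal(B[1, ], c(k0 = 1, k1 = 0, k10 = 0, k20 = 0, k40 = 0, k70 = 0))
  expect_equal(unname(B[11, "k10"]), 1)
  expect_equal(unname(B[16, c("k10", "k20")]), c(0.5, 0.5))  # age 15
  expect_equal(unname(B[30, c("k20", "k40")]), c(0.55, 0.45))  # age 29
  expect_equal(unname(rowSums(B)), rep(1, 101))
  expect_true(all(B >= 0 & B <= 1))
  # beyond the last knot the last component is constant 1
  expect_true(all(B[72:101, "k70"] == 1))
  expect_error(build_basis(ages, knots = 5), "2 knots")
  expect_error(build_basis(ages, knots = c(0, 120)), "within")
})

test_that("loess smoother reproduces polynomial log rates on the linear scale", {
  ages <- 0:80
  y <- -7 + 0.04 * ages   # exactly log-linear
  N <- rep(1e6, 81)
  D <- exp(y) * N - 0.5   # so that log((D+0.5)/N) = y exactly
  for (span in c(0.3, 0.6, 1)) {
    s <- smooth_standard(D, N, span = span, ages = ages,
                         weights = "uniform", age_scale = "linear")
    expect_equal(s$log_rate, y, tolerance = 1e-6)
  }
})

test_that("smoothed city schedule tracks the truth at large exposure", {
  std_true <- do.call(make_standard_schedule,
                      c(list(ages = 0:103),
                        saele:::default_schedule_params("F")))
  struct <- saele:::stable_age_structure(std_true$log_rate, r = 0.01)
  set.seed(31)
  N <- struct * 5e7     # a metropolis-scale pooled 3-year population
  D <- rpois(length(N), N * exp(std_true$log_rate))
  s <- smooth_standard(D, N, ages = 0:103)
  err <- abs(s$log_rate - std_true$log_rate)
  expect_lt(max(err[6:91]), 0.1)   # ages 5-90
})

test_that("smoothing reduces squared deviation from truth versus raw rates", {
  std_true <- make_standard_schedule(0:100)
  set.seed(7)
  N <- rep(2e5, 101)
  D <- rpois(101, N * exp(std_true$log_rate))
  raw <- log((D + 0.5) / N)
  sm <- smooth_standard(D, N, ages = 0:100)$log_rate
  mse_raw <- mean((raw - std_true$log_rate)^2)
  mse_sm <- mean((sm - std_true$log_rate)^2)
  expect_lt(mse_sm, mse_raw)
})

test_that("log posterior matches a hand-expanded sum on a tiny model", {
  mod <- toy_model(n_areas = 2, ages = 0:2, knots = c(0, 2), m_true = 0.1,
                   exposure = 100, tau_spatial = 3, tau_shape = 4, seed = 2)
  alpha <- matrix(c(0.2, -0.1, 0.05, 0.3), 2, 2)
  lp <- log_posterior(mod, alpha)
  # hand expansion
  B <- mod$basis
  ll <- 0
  for (a in 1:2) for (x in 1:3) {
    eta <- log(0.1) + sum(B[x, ] * alpha[a, ])
    lam <- 100 * exp(eta)
    ll <- ll + mod$D[a, x] * log(lam) - lam
  }
  pen_sp <- 3 / 2 * sum((alpha[1, ] - alpha[2, ])^2)
  pen_sh <- 4 / 2 * sum((alpha[, 2] - alpha[, 1])^2)
  expect_equal(lp, ll - pen_sp - pen_sh, tolerance = 1e-10)

  # alpha = 0: pure standard-schedule likelihood, zero penalties
  lp0 <- log_posterior(mod, matrix(0, 2, 2))
  ll0 <- sum(mod$D * log(mod$N * 0.1) - mod$N * 0.1)
  expect_equal(lp0, ll0, tolerance = 1e-10)
  expect_error(log_posterior(mod, matrix(Inf, 2, 2)), "finite")
})

test_that("the shape penalty scales linearly in its precision", {
  # single area: the spatial term is irrelevant
  mod0 <- toy_model(n_areas = 1, tau_shape = 0, seed = 3)
  mod2 <- toy_model(n_areas = 1, tau_shape = 2, seed = 3)
  mod4 <- toy_model(n_areas = 1, tau_shape = 4, seed = 3)
  alpha <- matrix(c(0.3, -0.2), 1, 2)
  pen2 <- log_posterior(mod0, alpha) - log_posterior(mod2, alpha)
  pen4 <- log_posterior(mod0, alpha) - log_posterior(mod4, alpha)
  expect_equal(pen4, 2 * pen2, tolerance = 1e-10)
  expect_equal(pen2, 2 / 2 * (-0.2 - 0.3)^2, tolerance = 1e-10)
})

test_that("relabeling areas with a consistent adjacency leaves the posterior invariant", {
  city <- tiny_city(seed = 12)
  den <- list(exposure = city$exposure_true)
  s <- "F"
  Ds <- city$deaths[city$deaths$sex == s, ]
  Ns <- den$exposure[den$exposure$sex == s, ]
  std <- city$schedules[[s]]
  mod <- topals_model(Ds, Ns, std, city$adjacency)
  perm <- sample(length(mod$areas))
  relabel <- setNames(sprintf("Z%03d", order(perm)), mod$areas)
  Ds2 <- Ds; Ds2$area <- unname(relabel[Ds$area])
  Ns2 <- Ns; Ns2$area <- unname(relabel[Ns$area])
  adj2 <- data.frame(area_i = unname(relabel[city$adjacency$area_i]),
                     area_j = unname(relabel[city$adjacency$area_j]))
  mod2 <- topals_model(Ds2, Ns2, std, adj2)
  set.seed(9)
  alpha <- matrix(rnorm(length(mod$areas) * 6, sd = 0.2),
                  length(mod$areas), 6)
  alpha2 <- alpha[match(mod2$areas, unname(relabel[mod$areas])), ]
  expect_equal(log_posterior(mod, alpha), log_posterior(mod2, alpha2),
               tolerance = 1e-9)
})

test_that("MCMC bookkeeping retains the right number of draws deterministically", {
  mod <- toy_model(n_areas = 1, ages = 0:4, knots = c(0, 4))
  fit <- run_mcmc(mod, iterations = 300, burn_in = 200, thin = 10, seed = 5)
  expect_equal(dim(fit$alpha), c(10L, 1L, 2L))
  fit1 <- run_mcmc(mod, iterations = 210, burn_in = 200, thin = 10, seed = 5)
  expect_equal(dim(fit1$alpha)[1], 1L)
  # identical seeds give identical chains; different seeds do not
  fit2 <- run_mcmc(mod, iterations = 300, burn_in = 200, thin = 10, seed = 5)
  expect_identical(fit$alpha, fit2$alpha)
  fit3 <- run_mcmc(mod, iterations = 300, burn_in = 200, thin = 10, seed = 6)
  expect_false(identical(fit$alpha, fit3$alpha))
  expect_error(run_mcmc(mod, iterations = 100, burn_in = 100), "burn_in")
})

test_that("posterior mean rate approaches the Poisson MLE at large exposure", {
  set.seed(4)
  areas <- "S01"
  N <- matrix(1e7, 1, 2, dimnames = list(areas, 0:1))
  D <- matrix(rpois(2, 1e7 * 0.1), 1, 2, dimnames = list(areas, 0:1))
  std <- standard_schedule(0:1, rep(log(0.05), 2))  # deliberately off
  mod <- topals_model(D, N, std,
                      data.frame(area_i = character(0),
                                 area_j = character(0)),
                      knots = c(0, 1), tau_shape = 2)
  fit <- run_mcmc(mod, iterations = 6000, burn_in = 2000, thin = 2, seed = 1)
  rates <- rate_draws(mod, fit)
  post_mean <- apply(rates[, 1, ], 2, mean)
  mle <- as.numeric(D / N)
  expect_equal(unname(post_mean), mle, tolerance = 0.01)
})

test_that("rate draws are the exponentiated linear predictor", {
  mod <- toy_model(n_areas = 2, ages = 0:5, knots = c(0, 5), m_true = 0.05)
  # alpha = 0 reproduces the standard schedule exactly
  a0 <- array(0, c(1, 2, 2))
  r0 <- rate_draws(mod, a0)
  expect_equal(unname(r0[1, , ]),
               matrix(0.05, 2, 6), tolerance = 1e-12)
  # hand-assembled predictor
  a <- array(c(0.1, -0.3, -0.2, 0.4), c(1, 2, 2))
  r <- rate_draws(mod, a)
  want <- exp(sweep(matrix(a[1, , ], 2, 2) %*% t(mod$basis), 2,
                    mod$log_std, `+`))
  expect_equal(unname(r[1, , ]), unname(want), tolerance = 1e-12)
  # raising one knot offset raises rates only where that basis loads
  a_up <- a; a_up[1, 1, 2] <- a_up[1, 1, 2] + 0.5
  r_up <- rate_draws(mod, a_up)
  loads <- mod$basis[, 2] > 0
  expect_true(all(r_up[1, 1, loads] > r[1, 1, loads]))
  expect_equal(r_up[1, 1, !loads], r[1, 1, !loads], tolerance = 1e-12)
  expect_equal(r_up[1, 2, ], r[1, 2, ], tolerance = 1e-12)
})

test_that("an area with no exposure shrinks to the average of its neighbors", {
  # 3-area chain, middle area empty; tau_shape = 0 isolates the spatial pull
  areas <- c("L", "Mid", "R")
  ages <- 0:4
  set.seed(10)
  N <- matrix(2e5, 3, 5, dimnames = list(areas, ages))
  N["Mid", ] <- 0
  m_true <- rbind(0.05 * exp(0.6), 0.05, 0.05 * exp(-0.6))
  D <- matrix(rpois(15, N * matrix(m_true, 3, 5)), 3, 5,
              dimnames = list(areas, ages))
  std <- standard_schedule(ages, rep(log(0.05), 5))
  adj <- data.frame(area_i = c("L", "Mid"), area_j = c("Mid", "R"))
  mod <- topals_model(D, N, std, adj, knots = c(0, 4), tau_spatial = 5,
                      tau_shape = 0)
  fit <- run_mcmc(mod, iterations = 12000, burn_in = 4000, thin = 2,
                  seed = 2)
  post <- apply(fit$alpha, c(2, 3), mean)
  nb_avg <- (post["L", ] + post["R", ]) / 2
  expect_lt(max(abs(post["Mid", ] - nb_avg)), 0.12)
})

test_that("convergence diagnostics are reasonable on a well-mixed toy", {
  mod <- toy_model(n_areas = 2, ages = 0:5, knots = c(0, 5),
                   exposure = 1e5)
  fit <- run_mcmc(mod, iterations = 8000, burn_in = 4000, thin = 2, seed = 3)
  dg <- mcmc_diagnostics(fit)
  expect_true(all(dg$rhat < 1.1, na.rm = TRUE))
  expect_true(all(dg$ess > 50))
  expect_true(all(fit$acceptance > 0.1 & fit$acceptance < 0.6))
})

test_that("sampling the precisions leaves sensible posteriors", {
  mod <- toy_model(n_areas = 4, ages = 0:5, knots = c(0, 5), exposure = 1e4,
                   adjacency = data.frame(area_i = c("T01", "T02", "T03"),
                                          area_j = c("T02", "T03", "T04")))
  fit <- run_mcmc(mod, iterations = 3000, burn_in = 1000, thin = 1,
                  seed = 8, sample_tau = TRUE)
  expect_equal(dim(fit$tau_draws), c(2000L, 2L))
  expect_true(all(fit$tau_draws > 0))
})
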